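# End-to-end pipeline: discretize -> screen -> network (-> extend ->
# enrichment -> DE intersection) -> export, with every output stamped by a
# provenance record (parameters, seed, input digests).

#' Assemble a pipeline configuration
#'
#' All screening, discretization and downstream parameters in one
#' serializable record. `write_run_config()` / `read_run_config()` move it
#' to and from a YAML file, so a run is fully described by one text file
#' plus its inputs.
#'
#' @param matrix_path Expression matrix TSV (required).
#' @param baits_path Bait list file (required).
#' @param out_prefix Output path prefix (required).
#' @param annotations_path,bins_path Optional annotation / functional-bin
#'   TSVs.
#' @param extend_baits_path Optional second bait list used to extend the
#'   network after the first screen.
#' @param de_paths Optional character vector of DE-list TSVs intersected
#'   with `de_bait`'s neighborhood.
#' @param de_bait Bait whose neighborhood the DE lists are intersected with
#'   (defaults to the first bait when DE lists are given).
#' @param q,r Discretization parameters (see [discretization_params()]).
#' @param sign_mode,min_bf,alpha,adjust,n_permutations Screening parameters
#'   (see [screen_params()]).
#' @param tf_only Restrict network partners to TF-annotated genes.
#' @param fdr_threshold Enrichment significance threshold (default 0.1).
#' @param export Export format(s), subset of `c("edge-tsv", "sif",
#'   "graphml")`.
#' @param missing_token Missing-value token of the matrix file.
#' @param seed Integer seed for all randomized steps.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(matrix_path, baits_path, out_prefix,
                       annotations_path = NULL, bins_path = NULL,
                       extend_baits_path = NULL, de_paths = NULL,
                       de_bait = NULL, q = 0.06, r = 1L,
                       sign_mode = "same-sign", min_bf = 0L, alpha = 0.01,
                       adjust = "bonferroni", n_permutations = 1000L,
                       tf_only = FALSE, fdr_threshold = 0.1,
                       export = c("edge-tsv", "sif"),
                       missing_token = "NA", seed = 1L) {
  for (field in c("matrix_path", "baits_path", "out_prefix")) {
    val <- get(field)
    if (is.null(val) || !nzchar(val)) stop("config field '", field, "' is required")
  }
  cfg <- list(matrix_path = matrix_path, baits_path = baits_path,
              out_prefix = out_prefix, annotations_path = annotations_path,
              bins_path = bins_path, extend_baits_path = extend_baits_path,
              de_paths = de_paths, de_bait = de_bait, q = q, r = as.integer(r),
              sign_mode = sign_mode, min_bf = as.integer(min_bf),
              alpha = alpha, adjust = adjust,
              n_permutations = as.integer(n_permutations),
              tf_only = isTRUE(tf_only), fdr_threshold = fdr_threshold,
              export = export, missing_token = missing_token,
              seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' Write a pipeline configuration to YAML
#' @param config A [run_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path Path written by [write_run_config()] (or hand-written; keys
#'   are the arguments of [run_config()]).
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full screening pipeline
#'
#' Reads the matrix and bait list, discretizes, screens, builds (and
#' optionally extends) the network, runs the optional enrichment and DE
#' intersection, exports the requested formats, and writes a provenance
#' record (`<prefix>.provenance.yaml`) plus a machine-readable summary
#' (`<prefix>.summary.json`). Deterministic: the same config and seed give
#' byte-identical outputs.
#'
#' @param config A [run_config()] object or path to a YAML config.
#' @return Invisibly, a list with the summary and the paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  pfx <- config$out_prefix
  dir.create(dirname(pfx), recursive = TRUE, showWarnings = FALSE)

  m <- stage("read_matrix",
             read_expression_matrix(config$matrix_path, config$missing_token))
  baits <- stage("read_baits", read_bait_set(config$baits_path))
  dparams <- discretization_params(q = config$q, r = config$r)
  sparams <- screen_params(sign_mode = config$sign_mode,
                           min_bf = config$min_bf, alpha = config$alpha,
                           adjust = config$adjust,
                           n_permutations = config$n_permutations,
                           seed = config$seed)
  d <- stage("discretize", discretize_matrix(m, dparams))
  levels_path <- paste0(pfx, ".levels.tsv")
  write_discretized_matrix(d, levels_path)

  edges <- stage("screen", screen_baits(d, baits, sparams))
  edges_path <- paste0(pfx, ".edges.tsv")
  utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  annotations <- if (!is.null(config$annotations_path))
    stage("read_annotations", read_annotations(config$annotations_path))
  net <- stage("build_network",
               build_network(edges, annotations = annotations,
                             tf_only = config$tf_only,
                             params = list(q = config$q, r = config$r,
                                           seed = config$seed)))
  if (!is.null(config$extend_baits_path)) {
    more <- stage("read_extend_baits", read_bait_set(config$extend_baits_path))
    net <- stage("extend_network",
                 extend_network(net, more, d, sparams, annotations))
  }
  files <- c(levels_path, edges_path)
  for (fmt in config$export)
    files <- c(files, stage("export", export_network(net, fmt, pfx)))

  enrich_path <- NULL
  if (!is.null(config$bins_path)) {
    bins <- stage("read_bins", read_bin_map(config$bins_path))
    partners <- net$nodes$gene_id[!net$nodes$is_bait]
    enr <- stage("enrichment",
                 fisher_enrichment(intersect(partners, rownames(m)),
                                   rownames(m), bins,
                                   config$fdr_threshold))
    enrich_path <- paste0(pfx, ".enrichment.tsv")
    utils::write.table(enr, enrich_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, enrich_path)
  }

  de_path <- NULL
  if (!is.null(config$de_paths) && length(config$de_paths) > 0L) {
    de_lists <- stage("read_de_lists", lapply(config$de_paths, read_de_list))
    de_bait <- config$de_bait %||% baits[[1L]]
    de_tab <- stage("de_intersection",
                    intersect_with_de(net, de_bait, de_lists))
    de_path <- paste0(pfx, ".de_intersection.tsv")
    utils::write.table(de_tab, de_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, de_path)
  }

  inputs <- c(config$matrix_path, config$baits_path, config$annotations_path,
              config$bins_path, config$extend_baits_path, config$de_paths)
  prov <- list(config = unclass(config),
               input_md5 = as.list(tools::md5sum(inputs)))
  prov_path <- paste0(pfx, ".provenance.yaml")
  yaml::write_yaml(prov, prov_path)

  summary <- list(n_genes = nrow(m), n_conditions = ncol(m),
                  n_baits = length(baits), n_edges = nrow(net$edges),
                  n_nodes = nrow(net$nodes),
                  n_bait_bait_edges = sum(net$edges$bait_bait),
                  families = family_distribution(net),
                  outputs = c(files, prov_path))
  summary_path <- paste0(pfx, ".summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(summary = summary, network = net,
                 files = c(files, prov_path, summary_path)))
}
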