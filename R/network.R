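# Assembly of screened edges into an annotated co-expression network,
# TF-family summaries, extension with additional baits, intersection with
# differential-expression lists, and Cytoscape-friendly exports.

#' Build a co-expression network from screened edges
#'
#' Nodes are the union of edge endpoints, annotated with species, TF family
#' and display name where an annotation table provides them. With
#' `tf_only`, partner nodes lacking a TF-family label are dropped (bait
#' nodes are always retained) -- the restriction used when asking which
#' transcription factors track a pathway's structural genes.
#'
#' @param edges Edge table from [screen_baits()].
#' @param annotations Optional data frame from [read_annotations()].
#' @param tf_only Drop unannotated (non-TF) partners (default `FALSE`).
#' @param params Optional named list recorded as provenance (screening
#'   parameters, input digests); the edge table's own `"params"` attribute
#'   is folded in automatically.
#' @return An object of class `"coexpression_network"`: a list with `nodes`
#'   (data frame: `gene_id`, `species`, `tf_family`, `display_name`,
#'   `is_bait`), `edges` (the edge table, plus a `bait_bait` flag) and
#'   `params`.
#' @export
build_network <- function(edges, annotations = NULL, tf_only = FALSE,
                          params = list()) {
  stopifnot(is.data.frame(edges))
  need <- c("bait", "partner", "bf", "sign", "pvalue", "support")
  if (!all(need %in% colnames(edges)))
    stop("edge table misses column(s): ",
         paste(setdiff(need, colnames(edges)), collapse = ", "))
  prov <- utils::modifyList(as.list(attr(edges, "params") %||% list()), params)
  edges <- edges[edges$bait != edges$partner, , drop = FALSE]  # no self-loops
  baits <- unique(edges$bait)
  partners <- unique(edges$partner)
  ids <- unique(c(baits, partners))
  nodes <- data.frame(gene_id = ids,
                      species = rep(NA_character_, length(ids)),
                      tf_family = rep(NA_character_, length(ids)),
                      display_name = rep(NA_character_, length(ids)),
                      is_bait = ids %in% baits, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    idx <- match(nodes$gene_id, annotations$gene_id)
    hit <- !is.na(idx)
    for (col in c("species", "tf_family", "display_name"))
      nodes[[col]][hit] <- annotations[[col]][idx[hit]]
  }
  if (tf_only) {
    keep <- nodes$is_bait | !is.na(nodes$tf_family)
    nodes <- nodes[keep, , drop = FALSE]
    edges <- edges[edges$partner %in% nodes$gene_id, , drop = FALSE]
  }
  edges$bait_bait <- edges$partner %in% baits
  # the BF score is symmetric: a bait-bait relation appears once, oriented
  # lexicographically, so assembly order cannot matter
  bb <- edges$bait_bait
  swap <- bb & edges$bait > edges$partner
  tmp <- edges$bait[swap]
  edges$bait[swap] <- edges$partner[swap]
  edges$partner[swap] <- tmp
  key <- paste(pmin(edges$bait, edges$partner), pmax(edges$bait, edges$partner))
  edges <- edges[!(duplicated(key) & bb), , drop = FALSE]
  edges <- edges[order(match(edges$bait, ids), -edges$bf, edges$partner), ,
                 drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, params = prov),
            class = "coexpression_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.coexpression_network <- function(x, ...) {
  cat("coexpression_network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$is_bait), "baits ),", nrow(x$edges), "edges\n")
  fams <- x$nodes$tf_family[!is.na(x$nodes$tf_family)]
  if (length(fams) > 0L)
    cat("TF families:", paste(names(sort(table(fams), decreasing = TRUE)),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Distribution of TF families in a network
#'
#' Counts distinct TF nodes per family, in descending order -- the summary
#' behind "which TF families track the pathway".
#'
#' @param net A `"coexpression_network"`.
#' @return Data frame with columns `family` and `n`, sorted by descending
#'   count; counts sum to the number of family-labelled nodes.
#' @export
family_distribution <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  fams <- net$nodes$tf_family[!is.na(net$nodes$tf_family)]
  if (length(fams) == 0L)
    return(data.frame(family = character(), n = integer()))
  tab <- sort(table(fams), decreasing = TRUE)
  data.frame(family = names(tab), n = as.integer(tab), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Extend a network with additional bait genes
#'
#' Screens the new baits with the supplied parameters against the same
#' discretized matrix and unions the result into the network. Re-adding an
#' existing bait changes nothing (idempotent), and extension order does not
#' matter for a fixed parameter set. Edges between two baits are flagged in
#' the `bait_bait` column.
#'
#' @param net A `"coexpression_network"`.
#' @param new_baits Character vector of additional bait IDs.
#' @param d Discretized matrix the original network was screened on.
#' @param params The same [screen_params()] used for the original screen.
#' @param annotations Optional annotation table for the new nodes.
#' @return The extended `"coexpression_network"`.
#' @export
extend_network <- function(net, new_baits, d, params = screen_params(),
                           annotations = NULL) {
  stopifnot(inherits(net, "coexpression_network"))
  old_baits <- net$nodes$gene_id[net$nodes$is_bait]
  fresh <- setdiff(as.character(new_baits), old_baits)
  if (length(fresh) == 0L) return(net)
  new_edges <- screen_baits(d, fresh, params)
  all_edges <- rbind(net$edges[, colnames(new_edges), drop = FALSE], new_edges)
  # symmetric duplicates (bait A screening bait B and vice versa) collapse
  key <- paste(pmin(all_edges$bait, all_edges$partner),
               pmax(all_edges$bait, all_edges$partner))
  all_edges <- all_edges[!duplicated(key), , drop = FALSE]
  attr(all_edges, "params") <- attr(new_edges, "params")
  all_baits <- c(old_baits, fresh)
  rebuilt <- build_network(all_edges, annotations = annotations,
                           params = net$params)
  # preserve annotations already present on old nodes
  idx <- match(rebuilt$nodes$gene_id, net$nodes$gene_id)
  hit <- !is.na(idx)
  for (col in c("species", "tf_family", "display_name")) {
    keep <- hit & is.na(rebuilt$nodes[[col]])
    rebuilt$nodes[[col]][keep] <- net$nodes[[col]][idx[keep]]
  }
  rebuilt$nodes$is_bait <- rebuilt$nodes$gene_id %in% all_baits
  rebuilt$edges$bait_bait <- rebuilt$edges$partner %in% all_baits &
    rebuilt$edges$bait %in% all_baits
  rebuilt
}

#' Intersect a bait's neighborhood with differential-expression lists
#'
#' Returns the genes that are both co-expressed with the bait in the
#' network and present in every supplied DE list -- the meta-analysis step
#' combining a co-expression neighborhood with transgenic-line RNA-seq
#' contrasts.
#'
#' @param net A `"coexpression_network"`.
#' @param bait A bait gene ID present in the network.
#' @param de_lists A `"de_list"` or list of them (see [read_de_list()]).
#' @return Data frame with one row per retained gene: `gene_id`, `bf`, and
#'   one direction column per DE list.
#' @export
intersect_with_de <- function(net, bait, de_lists) {
  stopifnot(inherits(net, "coexpression_network"))
  if (!bait %in% net$nodes$gene_id) stop("bait '", bait, "' is not in the network")
  if (inherits(de_lists, "de_list")) de_lists <- list(de_lists)
  if (length(de_lists) == 0L) stop("at least one DE list is required")
  e <- net$edges
  nb <- unique(c(e$partner[e$bait == bait], e$bait[e$partner == bait]))
  keep <- nb
  for (de in de_lists) keep <- intersect(keep, de$gene_ids)
  bf <- vapply(keep, function(g) {
    hit <- (e$bait == bait & e$partner == g) | (e$partner == bait & e$bait == g)
    max(e$bf[hit])
  }, integer(1L))
  out <- data.frame(gene_id = keep, bf = unname(bf), stringsAsFactors = FALSE)
  for (de in de_lists) {
    col <- paste0("dir_", gsub("[^A-Za-z0-9]+", "_", de$label))
    out[[col]] <- if (is.null(de$direction)) rep(NA_character_, nrow(out))
    else unname(de$direction[keep])
  }
  rownames(out) <- NULL
  out[order(-out$bf, out$gene_id), , drop = FALSE]
}

#' Export a network for visualization
#'
#' `"sif"` writes Cytoscape SIF lines (`bait<TAB>coexp<TAB>partner`) plus a
#' node-attribute and an edge-attribute TSV; `"edge-tsv"` writes the
#' lossless edge + node tables that [read_network()] re-imports;
#' `"graphml"` writes GraphML via igraph.
#'
#' @param net A non-empty `"coexpression_network"`.
#' @param format One of `"edge-tsv"`, `"sif"`, `"graphml"`.
#' @param out_prefix Path prefix for the output files.
#' @return Character vector of the files written, invisibly.
#' @export
export_network <- function(net, format = c("edge-tsv", "sif", "graphml"),
                           out_prefix) {
  stopifnot(inherits(net, "coexpression_network"))
  format <- match.arg(format)
  if (nrow(net$edges) == 0L) stop("refusing to export an empty network")
  nodes_path <- paste0(out_prefix, ".nodes.tsv")
  files <- switch(format,
    "edge-tsv" = {
      edges_path <- paste0(out_prefix, ".edges.tsv")
      utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(net$nodes, nodes_path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "")
      c(edges_path, nodes_path)
    },
    "sif" = {
      sif_path <- paste0(out_prefix, ".sif")
      writeLines(paste(net$edges$bait, "coexp", net$edges$partner, sep = "\t"),
                 sif_path)
      edge_attr_path <- paste0(out_prefix, ".edge_attrs.tsv")
      utils::write.table(net$edges[, c("bait", "partner", "bf", "pvalue", "sign")],
                         edge_attr_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(net$nodes, nodes_path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "")
      c(sif_path, edge_attr_path, nodes_path)
    },
    "graphml" = {
      gml_path <- paste0(out_prefix, ".graphml")
      igraph::write_graph(as_igraph(net), gml_path, format = "graphml")
      gml_path
    })
  invisible(files)
}

#' Re-import a network written by `export_network(format = "edge-tsv")`
#'
#' @param out_prefix The prefix passed to [export_network()].
#' @return A `"coexpression_network"` equal (up to provenance) to the one
#'   exported.
#' @export
read_network <- function(out_prefix) {
  edges <- utils::read.delim(paste0(out_prefix, ".edges.tsv"), sep = "\t",
                             quote = "", check.names = FALSE,
                             colClasses = "character")
  for (col in c("bf", "sign")) edges[[col]] <- as.integer(edges[[col]])
  edges$pvalue <- as.numeric(edges$pvalue)
  edges$bait_bait <- as.logical(edges$bait_bait)
  nodes <- utils::read.delim(paste0(out_prefix, ".nodes.tsv"), sep = "\t",
                             quote = "", check.names = FALSE,
                             colClasses = "character")
  nodes$is_bait <- as.logical(nodes$is_bait)
  nodes[nodes == ""] <- NA_character_
  structure(list(nodes = nodes, edges = edges, params = list()),
            class = "coexpression_network")
}

#' Convert a network to an igraph object
#'
#' @param net A `"coexpression_network"`.
#' @return An undirected `igraph` graph with node and edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  nodes <- net$nodes
  nodes[is.na(nodes)] <- ""
  igraph::graph_from_data_frame(
    net$edges[, c("bait", "partner", "bf", "sign", "pvalue", "bait_bait")],
    directed = FALSE,
    vertices = data.frame(name = nodes$gene_id, species = nodes$species,
                          tf_family = nodes$tf_family,
                          display_name = nodes$display_name,
                          is_bait = nodes$is_bait))
}

#' Rank candidate TFs by network support
#'
#' The selection report used to pick TFs for follow-up: per TF partner, how
#' many baits it is co-expressed with and its strongest BF value.
#'
#' @param net A `"coexpression_network"`.
#' @return Data frame with `gene_id`, `tf_family`, `n_baits`, `max_bf`,
#'   sorted by descending `(n_baits, max_bf)`.
#' @export
rank_candidates <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  e <- net$edges[!net$edges$bait_bait, , drop = FALSE]
  if (nrow(e) == 0L)
    return(data.frame(gene_id = character(), tf_family = character(),
                      n_baits = integer(), max_bf = integer()))
  sp <- split(e, e$partner)
  out <- data.frame(
    gene_id = names(sp),
    n_baits = vapply(sp, function(x) length(unique(x$bait)), integer(1L)),
    max_bf = vapply(sp, function(x) max(x$bf), integer(1L)),
    stringsAsFactors = FALSE)
  out$tf_family <- net$nodes$tf_family[match(out$gene_id, net$nodes$gene_id)]
  out <- out[order(-out$n_baits, -out$max_bf, out$gene_id),
             c("gene_id", "tf_family", "n_baits", "max_bf")]
  rownames(out) <- NULL
  out
}
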