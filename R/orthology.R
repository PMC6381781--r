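# Cross-species homolog mapping from BLAST tabular hits, and the overlay of
# two species' bait-anchored networks to separate conserved from
# species-specific co-expression relationships.

#' Map homologs between two gene sets from BLAST hits
#'
#' Filters hits to the two gene universes and the e-value / identity
#' thresholds, then keeps per query either every passing hit
#' (`"all-pass"`), the single best hit (`"best-hit"`: lowest e-value, ties
#' by highest bitscore then lexicographic subject ID), or only reciprocal
#' best pairs (`"reciprocal-best"`: the hit is best for its query and that
#' query is the best-scoring query of its subject).
#'
#' @param hits Data frame from [read_blast_tab()].
#' @param genes_a Query-side gene universe (e.g. one species' network TFs).
#' @param genes_b Subject-side gene universe.
#' @param max_evalue Maximum e-value (default 1e-10).
#' @param min_identity Minimum percent identity (default 0).
#' @param mode Hit-selection mode; see above.
#' @return An object of class `"ortholog_map"`: list with `pairs` (data
#'   frame `gene_a`, `gene_b`, `pident`, `evalue`, `bitscore`),
#'   `thresholds` and `mode`. `summary()` reports the distinct-gene counts
#'   on each side.
#' @export
map_homologs <- function(hits, genes_a, genes_b, max_evalue = 1e-10,
                         min_identity = 0,
                         mode = c("best-hit", "all-pass", "reciprocal-best")) {
  mode <- match.arg(mode)
  if (max_evalue < 0) stop("max_evalue must be non-negative")
  if (min_identity < 0 || min_identity > 100)
    stop("min_identity must lie in [0, 100]")
  keep <- hits$qseqid %in% genes_a & hits$sseqid %in% genes_b &
    hits$evalue <= max_evalue & hits$pident >= min_identity
  h <- hits[keep, , drop = FALSE]
  h <- h[order(h$qseqid, h$evalue, -h$bitscore, h$sseqid), , drop = FALSE]
  if (mode %in% c("best-hit", "reciprocal-best")) {
    h <- h[!duplicated(h$qseqid), , drop = FALSE]
  }
  if (mode == "reciprocal-best") {
    # among the per-query best hits, a subject keeps its best-scoring query
    ord <- order(h$sseqid, h$evalue, -h$bitscore, h$qseqid)
    best_q_of_s <- h[ord, , drop = FALSE]
    best_q_of_s <- best_q_of_s[!duplicated(best_q_of_s$sseqid), , drop = FALSE]
    h <- h[paste(h$qseqid, h$sseqid) %in%
             paste(best_q_of_s$qseqid, best_q_of_s$sseqid), , drop = FALSE]
  }
  h <- h[!duplicated(paste(h$qseqid, h$sseqid)), , drop = FALSE]
  pairs <- data.frame(gene_a = h$qseqid, gene_b = h$sseqid,
                      pident = h$pident, evalue = h$evalue,
                      bitscore = h$bitscore, stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 thresholds = list(max_evalue = max_evalue,
                                   min_identity = min_identity),
                 mode = mode),
            class = "ortholog_map")
}

#' @export
summary.ortholog_map <- function(object, ...) {
  out <- list(n_pairs = nrow(object$pairs),
              n_genes_a = length(unique(object$pairs$gene_a)),
              n_genes_b = length(unique(object$pairs$gene_b)),
              mode = object$mode, thresholds = object$thresholds)
  class(out) <- "summary.ortholog_map"
  out
}

#' @export
print.summary.ortholog_map <- function(x, ...) {
  cat("ortholog_map (", x$mode, "): ", x$n_pairs, " pairs; ",
      x$n_genes_a, " distinct query genes <-> ", x$n_genes_b,
      " distinct subject genes\n", sep = "")
  invisible(x)
}

#' @export
print.ortholog_map <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

# bait-neighbor set of one gene in a network, restricted to a bait universe
bait_neighbors <- function(net, gene, baits) {
  e <- net$edges
  nb <- c(e$bait[e$partner == gene], e$partner[e$bait == gene])
  intersect(unique(nb), baits)
}

#' Overlay two species' networks through an ortholog map
#'
#' For every homolog pair with both ends in their respective networks,
#' compares the two genes' bait-neighbor sets under a supplied bait
#' correspondence and reports the Jaccard overlap; pairs at or above
#' `min_jaccard` are labelled `"conserved"`, pairs below `"divergent"`.
#' Non-bait network genes with no homolog in the map are appended with the
#' label `"species-specific"` (the triangles of a two-species network
#' figure).
#'
#' @param net_a,net_b `"coexpression_network"` objects for the two species.
#' @param map An [map_homologs()] result with `gene_a` in `net_a`'s species
#'   and `gene_b` in `net_b`'s.
#' @param bait_map Data frame with columns `bait_a`, `bait_b` giving the
#'   bait correspondence between the networks; required.
#' @param min_jaccard Overlap at or above which a pair counts as conserved
#'   (default 0.5).
#' @return Data frame: `gene_a`, `gene_b`, `n_baits_a`, `n_baits_b`,
#'   `jaccard`, `label`.
#' @export
overlay_networks <- function(net_a, net_b, map, bait_map, min_jaccard = 0.5) {
  stopifnot(inherits(net_a, "coexpression_network"),
            inherits(net_b, "coexpression_network"),
            inherits(map, "ortholog_map"))
  if (missing(bait_map) || is.null(bait_map) ||
      !all(c("bait_a", "bait_b") %in% colnames(bait_map)))
    stop("a bait correspondence table with columns bait_a, bait_b is required")
  genes_a <- net_a$nodes$gene_id
  genes_b <- net_b$nodes$gene_id
  pairs <- map$pairs[map$pairs$gene_a %in% genes_a &
                     map$pairs$gene_b %in% genes_b, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    na_ <- bait_neighbors(net_a, ga, bait_map$bait_a)
    nb_ <- bait_neighbors(net_b, gb, bait_map$bait_b)
    # translate b-side baits into a's namespace
    nb_in_a <- bait_map$bait_a[match(nb_, bait_map$bait_b)]
    u <- union(na_, nb_in_a)
    j <- if (length(u) == 0L) 0 else length(intersect(na_, nb_in_a)) / length(u)
    data.frame(gene_a = ga, gene_b = gb, n_baits_a = length(na_),
               n_baits_b = length(nb_), jaccard = j,
               label = if (j >= min_jaccard) "conserved" else "divergent",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_a = character(), gene_b = character(),
                      n_baits_a = integer(), n_baits_b = integer(),
                      jaccard = double(), label = character(),
                      stringsAsFactors = FALSE)
  lonely_a <- setdiff(genes_a[!genes_a %in% net_a$nodes$gene_id[net_a$nodes$is_bait]],
                      pairs$gene_a)
  lonely_b <- setdiff(genes_b[!genes_b %in% net_b$nodes$gene_id[net_b$nodes$is_bait]],
                      pairs$gene_b)
  if (length(lonely_a) + length(lonely_b) > 0L)
    out <- rbind(out, data.frame(
      gene_a = c(lonely_a, rep(NA_character_, length(lonely_b))),
      gene_b = c(rep(NA_character_, length(lonely_a)), lonely_b),
      n_baits_a = NA_integer_, n_baits_b = NA_integer_,
      jaccard = NA_real_, label = "species-specific",
      stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
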