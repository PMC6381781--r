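# Functional-bin over-representation of a gene set (a co-expression
# neighborhood, a DE set) against a background universe: one-sided Fisher's
# exact test per bin with Benjamini-Hochberg control across bins.

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: `q_(i) = min_{j >= i}
#' (m * p_(j) / j)`, capped at 1, returned in the input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Functional-bin enrichment by Fisher's exact test
#'
#' For each bin, tests over-representation of the gene set among the
#' background with the one-sided hypergeometric tail
#' `P(X >= k)` for `X ~ Hypergeom(N, K, n)`, where `N` is the background
#' size, `K` the background genes in the bin, `n` the set size and `k` the
#' set genes in the bin. P-values are BH-adjusted across all tested bins
#' and bins are flagged significant at `q <= fdr_threshold`.
#'
#' @param gene_set Character vector, a subset of `background`.
#' @param background Character vector: the gene universe (e.g. all genes on
#'   the expression matrix).
#' @param bins Named list mapping gene IDs to bin labels (see
#'   [read_bin_map()]); genes outside the background are ignored, and bins
#'   empty within the background are skipped.
#' @param fdr_threshold Significance threshold on the adjusted value
#'   (default 0.1).
#' @return Data frame sorted by p: `bin`, `k`, `K`, `n`, `N`, `odds_ratio`,
#'   `p`, `q`, `significant`.
#' @export
fisher_enrichment <- function(gene_set, background, bins, fdr_threshold = 0.1) {
  gene_set <- unique(as.character(gene_set))
  background <- unique(as.character(background))
  if (length(background) < 2L) stop("background must hold at least 2 genes")
  if (!all(gene_set %in% background))
    stop("gene set is not a subset of the background: ",
         paste(utils::head(setdiff(gene_set, background), 5L), collapse = ", "))
  bins <- bins[names(bins) %in% background]
  if (length(bins) == 0L)
    return(data.frame(bin = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), odds_ratio = double(),
                      p = double(), q = double(), significant = logical()))
  by_bin <- split(rep(names(bins), lengths(bins)), unlist(bins, use.names = FALSE))
  N <- length(background)
  n <- length(gene_set)
  rows <- lapply(names(by_bin), function(bin) {
    members <- unique(by_bin[[bin]])
    K <- length(members)
    k <- length(intersect(members, gene_set))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / ((K - k) * (n - k))
    data.frame(bin = bin, k = k, K = K, n = n, N = N,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= fdr_threshold
  out <- out[order(out$p, out$bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}
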