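# Rank-quantile discretization: each gene's continuous profile is reduced to
# integer levels {-r..-1, 0, +1..+r}. The most extreme q-fraction of a gene's
# conditions at each end of its ranking receive non-zero levels; everything
# else is 0. Only the ordering of values matters, so the representation is
# invariant under any strictly increasing transform of the data.

#' Discretization parameters
#'
#' @param q Quantile fraction in (0, 0.5): the proportion of conditions per
#'   non-zero level at each extreme of a gene's ranking. Default 0.06, the
#'   published default of the underlying biclustering algorithm for
#'   microarray-style data.
#' @param r Positive integer count of non-zero levels per sign; level
#'   magnitudes run 1..r, the most extreme rank scoring r. Default 1.
#' @param max_missing Maximum tolerated fraction of missing conditions per
#'   gene (default 0.2); beyond this a gene cannot be discretized.
#' @return A list of class `"discretization_params"`.
#' @export
discretization_params <- function(q = 0.06, r = 1L, max_missing = 0.2) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 0.5)
    stop("q must lie in (0, 0.5)")
  r <- as.integer(r)
  if (is.na(r) || r < 1L) stop("r must be a positive integer")
  if (2 * r * q > 1) stop("2*r*q must not exceed 1: levels would overlap")
  if (max_missing < 0 || max_missing >= 1) stop("max_missing must lie in [0, 1)")
  structure(list(q = q, r = r, max_missing = max_missing),
            class = "discretization_params")
}

#' Discretize one expression profile
#'
#' Ranks the gene's values across conditions. The `ceiling(q * n)` lowest
#' values of each of the `r` bottom blocks take levels `-r..-1` (most extreme
#' block = `-r`); the top blocks mirror this with `+1..+r`; all remaining
#' conditions take 0. Ties at a block boundary are resolved by condition
#' order (stable sort), so the output is deterministic; a constant profile
#' has no extremes and maps to all zeros. Missing values are excluded from
#' ranking and take level 0.
#'
#' @param values Numeric vector over conditions (length >= 2).
#' @param params A [discretization_params()] object.
#' @return Integer vector of levels in `{-r..r}`, same length and names as
#'   `values`.
#' @export
discretize_gene <- function(values, params = discretization_params()) {
  stopifnot(inherits(params, "discretization_params"))
  if (!is.numeric(values)) stop("values must be numeric")
  n <- length(values)
  if (n < 2L) stop("an expression profile must cover at least 2 conditions")
  lev <- integer(n)
  names(lev) <- names(values)
  miss <- !is.finite(values)
  if (mean(miss) > params$max_missing)
    stop(sprintf("%.0f%% of conditions missing exceeds max_missing = %.0f%%",
                 100 * mean(miss), 100 * params$max_missing))
  obs <- which(!miss)
  x <- values[obs]
  n_obs <- length(x)
  if (n_obs < 2L || length(unique(x)) < 2L) return(lev)
  k <- ceiling(params$q * n_obs)
  if (2L * params$r * k > n_obs)
    stop("q and r would assign more non-zero levels than available conditions")
  ord <- order(x)  # stable: ties keep condition order
  for (j in seq_len(params$r)) {
    lo <- ord[((j - 1L) * k + 1L):(j * k)]
    hi <- ord[(n_obs - j * k + 1L):(n_obs - (j - 1L) * k)]
    lev[obs[lo]] <- -(params$r - j + 1L)
    lev[obs[hi]] <- params$r - j + 1L
  }
  lev
}

#' Discretize an expression matrix
#'
#' Applies [discretize_gene()] to every row. Genes whose missing fraction
#' exceeds `params$max_missing` are dropped with a warning rather than
#' aborting the whole matrix; any other per-gene failure is re-raised with
#' the gene ID attached.
#'
#' @param m Numeric gene-by-condition matrix (see
#'   [read_expression_matrix()]).
#' @param params A [discretization_params()] object.
#' @return Integer matrix of levels with the same dimnames as `m` (minus any
#'   dropped genes) and the parameters attached as attribute `"params"`.
#' @export
discretize_matrix <- function(m, params = discretization_params()) {
  validate_expression_matrix(m)
  frac <- missing_fraction(m)
  drop <- frac > params$max_missing
  if (any(drop)) {
    warning(sum(drop), " gene(s) dropped: more than ",
            100 * params$max_missing, "% missing conditions: ",
            paste(utils::head(rownames(m)[drop], 5L), collapse = ", "))
    m <- m[!drop, , drop = FALSE]
    if (nrow(m) == 0L) stop("no genes left after the missing-value filter")
  }
  lev <- matrix(0L, nrow = nrow(m), ncol = ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    lev[i, ] <- tryCatch(discretize_gene(m[i, ], params),
                         error = function(e) stop("gene '", rownames(m)[i], "': ",
                                                  conditionMessage(e), call. = FALSE))
  }
  structure(lev, params = params)
}

#' Write a discretized matrix to TSV
#'
#' Same layout as the expression input: header of condition IDs, first
#' column gene IDs, integer levels in the body.
#'
#' @param d Integer level matrix from [discretize_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_discretized_matrix <- function(d, path) {
  body <- apply(d, 1L, paste, collapse = "\t")
  writeLines(c(paste(c("gene_id", colnames(d)), collapse = "\t"),
               paste(rownames(d), body, sep = "\t")), path)
  invisible(path)
}

#' Read a discretized matrix from TSV
#'
#' @param path Path written by [write_discretized_matrix()].
#' @return Integer level matrix.
#' @export
read_discretized_matrix <- function(path) {
  m <- read_expression_matrix(path)
  storage.mode(m) <- "integer"
  m
}
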