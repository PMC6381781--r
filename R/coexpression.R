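# The pairwise co-expression score and the bait-anchored screen. Two genes'
# discretized profiles are compared condition by condition; the BF value is
# the number of conditions in which both hold the same non-zero level (or,
# optionally, exactly opposite levels). Because only matching extreme states
# count, correlation confined to a condition subset is detected at full
# strength, where a global correlation coefficient would be diluted by the
# remaining conditions.

#' Screening parameters
#'
#' @param sign_mode `"same-sign"` counts only conditions with identical
#'   non-zero levels; `"allow-opposite"` additionally counts exactly opposite
#'   levels (opposite regulation) and reports the majority match type as the
#'   edge sign.
#' @param min_bf Non-negative integer floor on the BF value of a reported
#'   edge (default 0: the significance test alone decides).
#' @param alpha Significance level for edge calling (default 0.01).
#' @param adjust Multiplicity handling across the candidates screened per
#'   bait: `"bonferroni"` (default) tests each pair at `alpha / n_candidates`;
#'   `"none"` tests at `alpha`. A bait is screened against every other gene
#'   on the matrix, so unadjusted calling admits roughly `alpha * n_genes`
#'   false partners per bait.
#' @param n_permutations Permutations for [bf_null_pvalue()] (default 1000).
#' @param seed Integer seed governing all permutation streams.
#' @param consistency Consistency level c in (0, 1] for
#'   [condition_support_module()] grouping (default 0.95).
#' @return A list of class `"screen_params"`.
#' @export
screen_params <- function(sign_mode = c("same-sign", "allow-opposite"),
                          min_bf = 0L, alpha = 0.01,
                          adjust = c("bonferroni", "none"),
                          n_permutations = 1000L, seed = 1L,
                          consistency = 0.95) {
  sign_mode <- match.arg(sign_mode)
  adjust <- match.arg(adjust)
  min_bf <- as.integer(min_bf)
  if (is.na(min_bf) || min_bf < 0L) stop("min_bf must be a non-negative integer")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (consistency <= 0 || consistency > 1) stop("consistency must lie in (0, 1]")
  structure(list(sign_mode = sign_mode, min_bf = min_bf, alpha = alpha,
                 adjust = adjust, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), consistency = consistency),
            class = "screen_params")
}

#' BF matching score of two level vectors
#'
#' Counts the conditions in which `a` and `b` hold identical non-zero levels
#' (same-sign mode); under `"allow-opposite"`, conditions with exactly
#' opposite non-zero levels also count, and the sign reports the majority
#' match type. The score is symmetric, `bf_score(a, a)` equals the number of
#' non-zero entries of `a`, and `0 <= bf <= length(a)`.
#'
#' @param a,b Integer level vectors of equal length (levels in `{-r..r}`).
#' @param sign_mode See [screen_params()].
#' @return A list with `bf` (integer), `support` (condition names, or
#'   indices if unnamed) and `sign` (+1 or -1).
#' @export
bf_score <- function(a, b, sign_mode = c("same-sign", "allow-opposite")) {
  sign_mode <- match.arg(sign_mode)
  if (length(a) != length(b)) stop("level vectors differ in length")
  same <- which(a != 0L & a == b)
  if (sign_mode == "same-sign") {
    support <- same
    sgn <- 1L
  } else {
    opp <- which(a != 0L & b != 0L & a == -b)
    support <- sort(c(same, opp))
    sgn <- if (length(opp) > length(same)) -1L else 1L
  }
  ids <- if (!is.null(names(a))) names(a)[support] else support
  list(bf = length(support), support = ids, sign = sgn)
}

# Counts of each level -r..r in a vector, named by level.
level_counts <- function(v) {
  r <- max(1L, max(abs(v)))
  levels <- seq.int(-r, r)
  counts <- vapply(levels, function(k) sum(v == k), integer(1L))
  names(counts) <- as.character(levels)
  counts
}

#' Exact null distribution of the BF score
#'
#' Under the permutation null (condition labels of one gene permuted
#' uniformly), the BF score depends on the two genes' level counts only.
#' This enumerates all joint placements of the non-zero levels of `b` into
#' the level classes of `a` -- a contingency table with fixed margins -- and
#' returns the exact probability mass function of BF.
#'
#' @param counts_a,counts_b Named integer vectors of level counts as
#'   produced by tabulating each vector (names are the levels, e.g.
#'   `c("-1" = 6, "0" = 81, "1" = 6)`).
#' @param n Number of conditions; must equal `sum(counts_a)` and
#'   `sum(counts_b)`.
#' @param sign_mode See [screen_params()].
#' @return Named numeric vector: `P(BF = k)` for `k = 0..max attainable`.
#' @export
bf_null_distribution <- function(counts_a, counts_b, n,
                                 sign_mode = c("same-sign", "allow-opposite")) {
  sign_mode <- match.arg(sign_mode)
  if (sum(counts_a) != n || sum(counts_b) != n)
    stop("level counts must sum to the number of conditions")
  lev_a <- as.integer(names(counts_a))
  lev_b <- as.integer(names(counts_b))
  nz_a <- which(lev_a != 0L & counts_a > 0L)
  nz_b <- which(lev_b != 0L & counts_b > 0L)
  a_nz <- counts_a[nz_a]; la <- lev_a[nz_a]
  b_nz <- counts_b[nz_b]; lb <- lev_b[nz_b]
  R <- length(a_nz); C <- length(b_nz)
  max_bf <- as.integer(min(sum(a_nz), sum(b_nz)))
  pmf <- numeric(max_bf + 1L)
  if (R == 0L || C == 0L) {
    pmf[1L] <- 1
    names(pmf) <- 0:max_bf
    return(pmf)
  }
  # does cell (i, j) contribute to BF?
  contrib <- outer(la, lb, function(x, y) {
    if (sign_mode == "same-sign") x == y else x == y | x == -y
  })
  a0 <- n - sum(a_nz)  # size of a's zero class
  base_lp <- sum(lgamma(counts_a + 1)) + sum(lgamma(counts_b + 1)) - lgamma(n + 1)
  M <- matrix(0L, R, C)
  recurse <- function(cell, used_row, used_col) {
    if (cell > R * C) {
      # remaining b non-zeros fall into a's zero class
      rest_b <- b_nz - used_col
      t00 <- a0 - sum(rest_b)
      if (t00 < 0L) return()
      rest_a <- a_nz - used_row
      lp <- base_lp - sum(lgamma(M + 1)) - sum(lgamma(rest_a + 1)) -
        sum(lgamma(rest_b + 1)) - lgamma(t00 + 1)
      bf <- sum(M[contrib])
      pmf[bf + 1L] <<- pmf[bf + 1L] + exp(lp)
      return()
    }
    i <- (cell - 1L) %/% C + 1L
    j <- (cell - 1L) %% C + 1L
    top <- min(a_nz[i] - used_row[i], b_nz[j] - used_col[j])
    for (v in 0:top) {
      M[i, j] <<- v
      used_row[i] <- used_row[i] + v
      used_col[j] <- used_col[j] + v
      recurse(cell + 1L, used_row, used_col)
      used_row[i] <- used_row[i] - v
      used_col[j] <- used_col[j] - v
      M[i, j] <<- 0L
    }
  }
  recurse(1L, integer(R), integer(C))
  names(pmf) <- 0:max_bf
  pmf / sum(pmf)
}

#' Exact null tail probability of the BF score
#'
#' `P(BF >= bf)` under the fixed-margins permutation null; the exact
#' counterpart of [bf_null_pvalue()].
#'
#' @param bf Observed BF value.
#' @param a,b Integer level vectors of equal length.
#' @param sign_mode See [screen_params()].
#' @return A probability in \[0, 1\].
#' @export
bf_null_tail <- function(bf, a, b, sign_mode = c("same-sign", "allow-opposite")) {
  sign_mode <- match.arg(sign_mode)
  if (length(a) != length(b)) stop("level vectors differ in length")
  exact_tail(bf, level_counts(a), level_counts(b), length(a), sign_mode)
}

#' Expected BF score under the permutation null
#'
#' Closed form: `E[BF] = sum_k n_k(a) * n_k(b) / n` over non-zero levels k
#' (same-sign mode); under `"allow-opposite"` the cross terms
#' `n_k(a) * n_-k(b) / n` are added.
#'
#' @inheritParams bf_null_distribution
#' @return Expected BF (numeric scalar).
#' @export
bf_null_expectation <- function(counts_a, counts_b, n,
                                sign_mode = c("same-sign", "allow-opposite")) {
  sign_mode <- match.arg(sign_mode)
  lev_a <- as.integer(names(counts_a))
  lev_b <- as.integer(names(counts_b))
  e <- 0
  for (i in seq_along(lev_a)) {
    if (lev_a[i] == 0L) next
    j <- match(lev_a[i], lev_b)
    if (!is.na(j)) e <- e + counts_a[[i]] * counts_b[[j]] / n
    if (sign_mode == "allow-opposite") {
      jo <- match(-lev_a[i], lev_b)
      if (!is.na(jo)) e <- e + counts_a[[i]] * counts_b[[jo]] / n
    }
  }
  e
}

#' Permutation p-value for a BF score
#'
#' Permutes the condition labels of `b` `n_permutations` times and reports
#' the add-one-smoothed fraction of permutations whose BF is at least the
#' observed value: `p = (1 + #{BF* >= bf}) / (1 + n_permutations)`.
#' Deterministic for a fixed seed.
#'
#' @param bf Observed BF value for `(a, b)`.
#' @param a,b Integer level vectors.
#' @param n_permutations Number of permutations (>= 1; below 100 a warning
#'   is issued since the estimate is then very coarse).
#' @param seed Integer seed for the permutation stream.
#' @param sign_mode See [screen_params()].
#' @return A p-value in (0, 1\].
#' @seealso [bf_null_distribution()] for the exact tail this estimates.
#' @export
bf_null_pvalue <- function(bf, a, b, n_permutations = 1000L, seed = 1L,
                           sign_mode = c("same-sign", "allow-opposite")) {
  sign_mode <- match.arg(sign_mode)
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L)
    stop("n_permutations must be a positive integer")
  if (n_permutations < 100L)
    warning("fewer than 100 permutations give a very coarse p-value")
  if (length(a) != length(b)) stop("level vectors differ in length")
  n <- length(a)
  opp <- sign_mode == "allow-opposite"
  count <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_permutations)) {
      bp <- b[sample.int(n)]
      s <- sum(a != 0L & a == bp)
      if (opp) s <- s + sum(a != 0L & bp != 0L & a == -bp)
      if (s >= bf) hits <- hits + 1L
    }
    hits
  })
  (1 + count) / (1 + n_permutations)
}

# Exact conditional p-value P(BF >= bf | margins), cached per margin pair.
exact_tail <- function(bf, counts_a, counts_b, n, sign_mode, cache = NULL) {
  key <- paste(paste(names(counts_a), counts_a, sep = ":", collapse = ","),
               paste(names(counts_b), counts_b, sep = ":", collapse = ","),
               sign_mode, sep = "|")
  pmf <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]]
  else {
    p <- bf_null_distribution(counts_a, counts_b, n, sign_mode)
    if (!is.null(cache)) cache[[key]] <- p
    p
  }
  if (bf <= 0L) return(1)
  if (bf > length(pmf) - 1L) return(0)
  sum(pmf[(bf + 1L):length(pmf)])
}

#' Screen bait genes for co-expressed partners
#'
#' Scores every (bait, other-gene) pair on the discretized matrix with
#' [bf_score()] and calls an edge when the score clears `min_bf` and its
#' exact conditional null p-value clears the (optionally
#' Bonferroni-adjusted) significance level. Baits absent from the matrix are
#' reported with a warning and skipped; if none remain this is an error.
#'
#' @param d Integer level matrix from [discretize_matrix()].
#' @param baits Character vector of bait gene IDs (see [read_bait_set()]).
#' @param params A [screen_params()] object.
#' @return Data frame of edges, sorted by bait (input order) then descending
#'   BF then partner ID: columns `bait`, `partner`, `bf`, `sign`, `pvalue`
#'   (exact conditional null) and `support` (comma-joined condition IDs).
#'   The number of conditions is attached as attribute `"n_conditions"` and
#'   the parameters as `"params"`.
#' @export
screen_baits <- function(d, baits, params = screen_params()) {
  stopifnot(is.matrix(d))
  baits <- as.character(baits)
  present <- baits[baits %in% rownames(d)]
  absent <- setdiff(baits, present)
  if (length(absent) > 0L)
    warning("bait(s) absent from the matrix, skipped: ",
            paste(absent, collapse = ", "))
  if (length(present) == 0L) stop("no bait gene is present in the matrix")
  n <- ncol(d)
  genes <- rownames(d)
  opp <- params$sign_mode == "allow-opposite"
  n_candidates <- nrow(d) - 1L
  alpha_eff <- if (params$adjust == "bonferroni")
    params$alpha / n_candidates else params$alpha
  cache <- new.env(parent = emptyenv())
  out <- vector("list", length(present))
  for (bi in seq_along(present)) {
    bait <- present[bi]
    a <- d[bait, ]
    ca <- level_counts(a)
    others <- setdiff(genes, bait)
    # vectorized BF over all candidate rows
    sub <- d[others, , drop = FALSE]
    eq <- sub == matrix(a, nrow = length(others), ncol = n, byrow = TRUE)
    nz <- matrix(a != 0L, nrow = length(others), ncol = n, byrow = TRUE)
    bf_same <- rowSums(eq & nz)
    if (opp) {
      eqo <- sub == matrix(-a, nrow = length(others), ncol = n, byrow = TRUE)
      bf_opp <- rowSums(eqo & nz & sub != 0L)
      bf_all <- bf_same + bf_opp
    } else {
      bf_all <- bf_same
    }
    keep <- which(bf_all >= max(1L, params$min_bf))
    rows <- list()
    for (g in keep) {
      b <- sub[g, ]
      p <- exact_tail(bf_all[g], ca, level_counts(b), n, params$sign_mode, cache)
      if (p <= alpha_eff) {
        sc <- bf_score(a, b, params$sign_mode)
        rows[[length(rows) + 1L]] <- data.frame(
          bait = bait, partner = others[g], bf = as.integer(bf_all[g]),
          sign = sc$sign, pvalue = p,
          support = paste(sc$support, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) > 0L) {
      tab <- do.call(rbind, rows)
      tab <- tab[order(-tab$bf, tab$partner), , drop = FALSE]
      out[[bi]] <- tab
    }
  }
  edges <- do.call(rbind, out)
  if (is.null(edges))
    edges <- data.frame(bait = character(), partner = character(),
                        bf = integer(), sign = integer(), pvalue = double(),
                        support = character(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(edges, n_conditions = n, params = params)
}

#' Group one bait's partners by shared supporting conditions
#'
#' Makes the "to-be-identified" condition subset explicit: starting from the
#' highest-BF edge, genes whose support overlaps the current condition set
#' in at least a fraction `consistency` of its size are added and the
#' condition set shrinks to the intersection; exhausted, the next ungrouped
#' highest-BF edge seeds a new group. Ties are broken by descending BF then
#' lexicographic partner ID.
#'
#' @param edges Edge table from [screen_baits()] restricted to one bait.
#' @param consistency Required overlap fraction c in (0, 1] (default 0.95).
#' @return List of groups, each a list with `genes` (character) and
#'   `conditions` (character): the genes co-expressed with the bait over the
#'   shared condition subset.
#' @export
condition_support_module <- function(edges, consistency = 0.95) {
  if (nrow(edges) == 0L) stop("at least one edge is required")
  if (length(unique(edges$bait)) != 1L)
    stop("edges must belong to a single bait")
  edges <- edges[order(-edges$bf, edges$partner), , drop = FALSE]
  supports <- strsplit(edges$support, ",", fixed = TRUE)
  remaining <- seq_len(nrow(edges))
  groups <- list()
  while (length(remaining) > 0L) {
    seed <- remaining[1L]
    conds <- supports[[seed]]
    genes <- edges$partner[seed]
    remaining <- remaining[-1L]
    repeat {
      added <- FALSE
      for (i in remaining) {
        ov <- intersect(supports[[i]], conds)
        if (length(ov) >= consistency * length(conds)) {
          genes <- c(genes, edges$partner[i])
          conds <- ov
          remaining <- setdiff(remaining, i)
          added <- TRUE
          break
        }
      }
      if (!added) break
    }
    groups[[length(groups) + 1L]] <- list(genes = genes, conditions = conds)
  }
  groups
}

#' Pearson correlation of two expression profiles
#'
#' The global-correlation comparator: the standard product-moment
#' correlation over all conditions.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_score <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  if (length(x) < 3L) stop("at least 3 conditions are required")
  ok <- is.finite(x) & is.finite(y)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("undefined correlation: a profile has zero variance")
  stats::cor(x[ok], y[ok])
}

#' Score every gene against one bait by both methods
#'
#' Computes, for each other gene on the matrix, the BF score with its exact
#' null p-value and the global Pearson correlation -- the head-to-head table
#' used to contrast subset-aware and global co-expression detection.
#'
#' @param m Numeric expression matrix.
#' @param bait Bait gene ID (must be a row of `m`).
#' @param dparams A [discretization_params()] object.
#' @param sparams A [screen_params()] object.
#' @return Data frame with one row per other gene: `gene`, `bf`, `bf_p`,
#'   `pcc`. The bait itself is excluded.
#' @export
compare_methods <- function(m, bait, dparams = discretization_params(),
                            sparams = screen_params()) {
  validate_expression_matrix(m)
  if (!bait %in% rownames(m)) stop("bait '", bait, "' is not on the matrix")
  d <- discretize_matrix(m, dparams)
  if (!bait %in% rownames(d)) stop("bait '", bait, "' was dropped by the missing-value filter")
  a <- d[bait, ]
  n <- ncol(d)
  ca <- level_counts(a)
  cache <- new.env(parent = emptyenv())
  others <- setdiff(rownames(d), bait)
  bf <- integer(length(others)); bf_p <- double(length(others))
  pcc <- double(length(others))
  for (i in seq_along(others)) {
    b <- d[others[i], ]
    sc <- bf_score(a, b, sparams$sign_mode)
    bf[i] <- sc$bf
    bf_p[i] <- exact_tail(sc$bf, ca, level_counts(b), n, sparams$sign_mode, cache)
    pcc[i] <- tryCatch(pearson_score(m[bait, ], m[others[i], ]),
                       error = function(e) NA_real_)
  }
  data.frame(gene = others, bf = bf, bf_p = bf_p, pcc = pcc,
             stringsAsFactors = FALSE)
}
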