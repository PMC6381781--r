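# Independent oracles and fixture builders shared across the suite. Every
# oracle here is deliberately naive (loops, explicit enumeration, closed
# forms) so it cannot share a defect with the implementation it checks.

# Position-by-position BF count.
brute_bf <- function(a, b, sign_mode = "same-sign") {
  bf <- 0L
  for (i in seq_along(a)) {
    if (a[i] != 0L && a[i] == b[i]) bf <- bf + 1L
    else if (sign_mode == "allow-opposite" && a[i] != 0L && b[i] != 0L &&
             a[i] == -b[i]) bf <- bf + 1L
  }
  bf
}

# Random level vector with the given level frequencies.
random_levels <- function(n, f = c("-1" = 0.06, "0" = 0.88, "1" = 0.06)) {
  sample(as.integer(names(f)), n, replace = TRUE, prob = f)
}

# All permutations of 1..n (n small): the exhaustive permutation null.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in 0:(n - 1L)) out[[length(out) + 1L]] <- append(p, n, after = k)
  }
  out
}

# Hypergeometric upper tail by explicit summation of binomial coefficients.
hyper_tail <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Step-up BH computed from the definition (sort, cummin from the largest).
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Tabulate level counts -r..r by name (oracle-side twin of the package's
# internal tabulation).
level_counts_public <- function(v) {
  r <- max(1, max(abs(v)))
  ks <- seq.int(-r, r)
  structure(vapply(ks, function(k) sum(v == k), integer(1L)),
            names = as.character(ks))
}

# Minimal valid edge table.
make_edges <- function(bait, partner, bf = 5L, sign = 1L, pvalue = 1e-4,
                       support = "c001,c002") {
  data.frame(bait = bait, partner = partner, bf = as.integer(bf),
             sign = as.integer(sign), pvalue = pvalue, support = support,
             stringsAsFactors = FALSE)
}

# Expression fixture with named dims.
make_matrix <- function(values, genes, conditions) {
  matrix(values, nrow = length(genes), ncol = length(conditions),
         dimnames = list(genes, conditions))
}

# 12-column BLAST tabular line.
blast_line <- function(q, s, pident, len, evalue, bits) {
  paste(q, s, pident, len, 0L, 0L, 1L, len, 1L, len,
        format(evalue, scientific = TRUE), bits, sep = "\t")
}
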