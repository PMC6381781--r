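# Synthetic expression matrices with planted co-expression modules. Each
# module is a bait plus partner genes that share a single latent activity
# profile over a chosen condition subset (a planted bicluster): outside the
# subset the genes are independent noise, so the planted signal is exactly
# the "correlated under some to-be-identified conditions" structure the BF
# screen targets and a global correlation dilutes.

#' Specification of a synthetic expression data set
#'
#' Defaults mirror the screening study conditions this generator emulates: a
#' switchgrass-sized compendium of 93 samples, 14 bait genes each with a
#' handful of true partners, co-expression confined to a quarter of the
#' conditions, and a planted effect twice the noise standard deviation.
#'
#' @param n_genes Total number of genes (default 500).
#' @param n_conditions Number of conditions (default 93).
#' @param n_modules Number of planted modules, one bait each (default 14).
#' @param partners_per_module True partners per bait (default 5).
#' @param subset_fraction Fraction of conditions a module spans (default
#'   0.25).
#' @param effect_size Scale of the shared module signal in expression units;
#'   per condition the planted shift is `effect_size * activity`, with the
#'   latent activity standard normal across the module's conditions. Default
#'   `2 * noise_sd`.
#' @param noise_sd Standard deviation of the independent Gaussian noise on
#'   every cell (default 0.5, a typical residual spread for RMA-normalized
#'   log2 intensities).
#' @param baseline_mean,baseline_sd Per-gene mean expression is drawn from
#'   `N(baseline_mean, baseline_sd)` (defaults 8 and 1.5, the bulk of an RMA
#'   log2 scale).
#' @param coherent_sign +1 or -1: sign of the partners' loading on the
#'   module activity relative to the bait (default +1, coordinated
#'   regulation).
#' @param modules Optional explicit module list overriding the automatic
#'   layout; each element a list with `bait_id`, `partner_ids`,
#'   `condition_subset` (condition IDs or a fraction), `effect_size`,
#'   `coherent_sign`.
#' @param seed Integer seed; the same spec and seed always generate the same
#'   matrix.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_genes = 500L, n_conditions = 93L,
                           n_modules = 14L, partners_per_module = 5L,
                           subset_fraction = 0.25, effect_size = NULL,
                           noise_sd = 0.5, baseline_mean = 8,
                           baseline_sd = 1.5, coherent_sign = 1L,
                           modules = NULL, seed = 1L) {
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (is.null(effect_size)) effect_size <- 2 * noise_sd
  if (effect_size < 0) stop("effect_size must be non-negative")
  if (subset_fraction <= 0 || subset_fraction > 1)
    stop("subset_fraction must lie in (0, 1]")
  if (!coherent_sign %in% c(-1L, 1L)) stop("coherent_sign must be +1 or -1")
  if (is.null(modules) &&
      n_modules * (1L + partners_per_module) > n_genes)
    stop("modules need more genes than n_genes provides")
  structure(list(n_genes = as.integer(n_genes),
                 n_conditions = as.integer(n_conditions),
                 n_modules = as.integer(n_modules),
                 partners_per_module = as.integer(partners_per_module),
                 subset_fraction = subset_fraction,
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 coherent_sign = as.integer(coherent_sign),
                 modules = modules, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic expression matrix with planted modules
#'
#' Baseline cells are independent Gaussian noise around per-gene means. For
#' each module, a latent activity `z_c ~ N(0, 1)` is drawn once per subset
#' condition and added as `effect_size * sign * z_c` to the bait and every
#' partner on exactly those conditions. Identical spec and seed give an
#' identical matrix.
#'
#' @param spec A [synthetic_spec()] object.
#' @return A list with `matrix` (numeric gene-by-condition matrix), `truth`
#'   (data frame of every planted (bait, partner) pair with its condition
#'   subset) and `modules` (the realized module list).
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_conditions
  cond_ids <- sprintf("c%03d", seq_len(n))
  with_seed(spec$seed, {
    modules <- spec$modules
    if (is.null(modules)) {
      subset_size <- max(1L, round(spec$subset_fraction * n))
      modules <- lapply(seq_len(spec$n_modules), function(i) {
        list(bait_id = sprintf("bait%02d", i),
             partner_ids = sprintf("bait%02d_p%d", i,
                                   seq_len(spec$partners_per_module)),
             condition_subset = sort(sample(cond_ids, subset_size)),
             effect_size = spec$effect_size,
             coherent_sign = spec$coherent_sign)
      })
    } else {
      modules <- lapply(modules, function(mod) {
        cs <- mod$condition_subset
        if (is.numeric(cs) && length(cs) == 1L && cs <= 1) {
          mod$condition_subset <- sort(sample(cond_ids, max(1L, round(cs * n))))
        } else if (is.numeric(cs)) {
          if (any(cs < 1 | cs > n)) stop("condition subset index out of range")
          mod$condition_subset <- cond_ids[cs]
        } else {
          if (!all(cs %in% cond_ids))
            stop("condition subset names unknown; conditions are ",
                 cond_ids[1L], "..", cond_ids[n])
        }
        if (length(mod$condition_subset) > n)
          stop("condition subset larger than n_conditions")
        if (is.null(mod$effect_size)) mod$effect_size <- spec$effect_size
        if (is.null(mod$coherent_sign)) mod$coherent_sign <- spec$coherent_sign
        if (mod$bait_id %in% mod$partner_ids)
          stop("module bait must not be listed among its partners")
        mod
      })
    }
    planted_ids <- unlist(lapply(modules, function(m) c(m$bait_id, m$partner_ids)))
    if (anyDuplicated(vapply(modules, `[[`, "", "bait_id")))
      stop("module bait IDs must be distinct")
    n_background <- spec$n_genes - length(unique(planted_ids))
    if (n_background < 0L) stop("modules need more genes than n_genes provides")
    gene_ids <- c(unique(planted_ids), sprintf("gene%04d", seq_len(n_background)))
    mu <- stats::rnorm(length(gene_ids), spec$baseline_mean, spec$baseline_sd)
    m <- matrix(stats::rnorm(length(gene_ids) * n, mean = 0, sd = spec$noise_sd),
                nrow = length(gene_ids), ncol = n,
                dimnames = list(gene_ids, cond_ids))
    m <- m + mu
    truth <- list()
    for (mod in modules) {
      cs <- mod$condition_subset
      z <- stats::rnorm(length(cs))
      shift <- mod$effect_size * z
      members <- c(mod$bait_id, mod$partner_ids)
      loading <- c(1, rep(mod$coherent_sign, length(mod$partner_ids)))
      for (i in seq_along(members))
        m[members[i], cs] <- m[members[i], cs] + loading[i] * shift
      truth[[length(truth) + 1L]] <- data.frame(
        bait = mod$bait_id, partner = mod$partner_ids,
        conditions = paste(cs, collapse = ","),
        effect_size = mod$effect_size, sign = mod$coherent_sign,
        stringsAsFactors = FALSE)
    }
    list(matrix = m, truth = do.call(rbind, truth), modules = modules)
  })
}

#' Generate independent null level-vector pairs
#'
#' Draws pairs of independent discretized profiles with i.i.d. levels at the
#' given frequencies -- the calibration null for the BF score. Under this
#' null the expected BF of a pair is `n * sum(f_k^2)` over non-zero levels.
#'
#' @param n_pairs Number of pairs.
#' @param n_conditions Length of each vector.
#' @param level_frequencies Named numeric vector of level frequencies
#'   summing to 1; names are the integer levels (default
#'   `c("-1" = 0.06, "0" = 0.88, "1" = 0.06)`).
#' @param seed Integer seed.
#' @return A list with integer matrices `a` and `b` (`n_pairs` rows).
#' @export
generate_null_pairs <- function(n_pairs, n_conditions,
                                level_frequencies = c("-1" = 0.06, "0" = 0.88,
                                                      "1" = 0.06),
                                seed = 1L) {
  if (abs(sum(level_frequencies) - 1) > 1e-8)
    stop("level frequencies must sum to 1")
  levels <- as.integer(names(level_frequencies))
  with_seed(seed, {
    draw <- function() matrix(sample(levels, n_pairs * n_conditions,
                                     replace = TRUE, prob = level_frequencies),
                              nrow = n_pairs)
    list(a = draw(), b = draw())
  })
}
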