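---
title: "Bait-seeded qualitative co-expression screening: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bait-seeded qualitative co-expression screening: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baitnet)
```

## The problem

Transcription factors that drive a pathway tend to be transcribed together
with the pathway's structural genes, so screening a compendium of expression
profiles for genes correlated with a handful of well-characterized *bait*
genes (for example the monolignol-pathway enzymes PAL, 4CL, CCR, F5H, COMT,
CAD in a grass such as switchgrass) is a standard way to nominate candidate
regulators. The catch is that biologically meaningful co-expression is often
confined to a *subset* of the sampled conditions -- the tissues and
treatments in which the pathway is actually active. A global Pearson
correlation averages over all samples and dilutes such signals; a
biclustering view, in which a pair of genes may agree only over some
to-be-identified subset of conditions, does not.

`baitnet` implements that view as a screening tool: a qualitative
discretization of each gene's profile, a pairwise matching score (the **BF
value**) counting the conditions on which two genes agree in their extreme
states, an exact null for calling edges, and the downstream bookkeeping a
screening study needs (network assembly and extension, cross-species homolog
overlay, functional-bin enrichment, intersection with differential-expression
lists, and a Pearson comparator).

## Discretization

For each gene the `n` conditions are ranked by expression value. With
quantile fraction `q` (default 0.06) and rank depth `r` (default 1), the
`ceiling(q * n)` lowest conditions receive level `-1` (with `r > 1`, the `r`
bottom blocks receive `-r..-1`, most extreme block first), the top blocks
mirror this with positive levels, and every other condition is level 0.
Defaults follow the published defaults of the qualitative biclustering
algorithm this score derives from, which were tuned for microarray-style
(approximately Gaussian, log-scale) expression data.

Properties that matter, and that the test suite checks:

* only ranks enter, so any strictly increasing transform of a profile leaves
  its levels unchanged -- the screen is insensitive to the scale of
  normalized data;
* permuting conditions permutes levels identically;
* each non-zero level holds at most `ceiling(q * n)` conditions, with
  equality when the profile has no ties at a block boundary.

Numerical corner cases are fixed by convention: ties at a block boundary are
broken by condition order (stable sort), a constant profile has no extremes
and is all zeros, missing values are excluded from ranking and score level 0,
and genes missing more than `max_missing` (default 20%) of their conditions
are dropped from matrix discretization with a warning. A missing observation
supports no co-expression evidence, so these conventions only ever remove
evidence, never invent it.

## The BF score and its null

For two level vectors the BF value is the number of conditions holding
identical non-zero levels (`sign_mode = "same-sign"`, the default);
`"allow-opposite"` additionally counts exactly opposite levels, for
repressor-style anticorrelation, and reports the majority match type as the
edge sign. The score is symmetric, bounded by the sample count, and
`bf_score(a, a)` equals the number of non-zero entries of `a` -- with the
defaults on a 93-sample compendium, at most `2 * ceiling(0.06 * 93) = 12`.
The set of agreeing conditions (the *support*) is reported with every edge,
and `condition_support_module()` groups one bait's partners by greedily
intersecting supports (consistency level `c`, default 0.95), making the
"to-be-identified" condition subset of each group explicit.

Under the null hypothesis that two profiles are unrelated, the natural
reference distribution is obtained by permuting one gene's condition labels.
Conditioned on the two genes' level counts, this null depends on the counts
alone, and the distribution of BF can be enumerated exactly as a
fixed-margins contingency problem (`bf_null_distribution()`); its mean has
the closed form `sum_k n_k(a) n_k(b) / n` over non-zero levels.
`bf_null_pvalue()` is the Monte-Carlo counterpart the same null estimated by
explicit permutation, with add-one smoothing; the suite checks the two
routes against each other and against exhaustive permutation at small `n`.

`screen_baits()` calls an edge when `bf >= min_bf` (default 0) and the exact
null tail probability clears the significance level `alpha` (default 0.01).
Because a bait is screened against *every* other gene on the matrix, the
default applies a Bonferroni correction across the candidates of each bait
(`adjust = "bonferroni"`); `adjust = "none"` tests each pair at raw `alpha`
and will admit roughly `alpha * n_genes` false partners per bait, which is
rarely what a screening study wants. The published studies this design
follows do not print their exact thresholding rule, so the calling rule here
is the package's own, chosen to control the per-bait false-positive burden,
and is recorded in every output's provenance.

Two consequences of BF being an integer statistic are worth knowing. First,
its null mass at the default margins is concentrated on 0--3, so a valid
test can only reject at the achievable tail probabilities; the realized
size of a level-0.05 test is below 0.05 (about 0.034 at margins
`(6, 81, 6)` with `n = 93`, and smaller once level counts vary around their
expectation). Second, deep tails (needed after multiplicity adjustment) are
resolved exactly by the enumerated null where a 1000-permutation estimate
cannot go below `1/1001`.

## The synthetic benchmark

`generate_matrix()` plants known structure so that every stage can be tested
against ground truth. Baseline cells are independent Gaussian noise
(`noise_sd`, default 0.5 -- a typical residual spread of RMA-normalized log2
intensities) around per-gene means drawn from `N(8, 1.5)`. Each module is a
bait plus `partners_per_module` partners sharing a single latent activity
`z_c ~ N(0, 1)` over the module's condition subset, added as
`effect_size * sign * z_c`; outside the subset the genes are independent.
This single-factor planted bicluster is the standard generative model in the
biclustering literature; a flat shift was rejected because it produces no
within-subset covariation -- the extreme conditions of two flatly shifted
genes are then chosen by noise, and their expected agreement is only the
hypergeometric baseline.

The default spec mirrors the screening-study conditions the package is
benchmarked under: 500 genes by 93 conditions, 14 baits with 5 partners
each, subset fraction 0.25, and `effect_size = 2 * noise_sd`. These sizes
are also what `scripts/acceptance.R` and the acceptance tests use.

What the generator does *not* emulate: probe-level artifacts, batch and
array effects, heavy-tailed or gene-specific outlier conditions, overlapping
modules sharing genes, and correlated baseline structure among background
genes. Passing the planted-recovery checks therefore demonstrates that the
chain of discretization, scoring and calling behaves as designed under a
clean condition-subset signal -- not that real compendia are this benign.

### Operating characteristics at the default benchmark

The default operating point is deliberately hard, and two honest properties
of it deserve emphasis rather than concealment:

* With `q = 0.06` and `n = 93` a pair can agree on at most 12 conditions,
  and an effect of twice the noise makes the within-subset ranking only
  partially reproducible between genes, so planted pairs realize BF values
  around the exact-null tail where sensitivity and false-positive control
  trade off sharply. The Bonferroni default keeps called edges almost free
  of false positives at the price of sensitivity near one half; the
  unadjusted rule recovers most planted pairs but pays with a large false
  fraction. `scripts/acceptance.R` recomputes both sides of this trade-off.
* At subset fraction 0.25 and effect `2 * noise_sd`, a planted pair's
  *global* correlation is around `f * b^2 / (f * b^2 + s^2) ~ 0.5`, far
  above the null spread `1/sqrt(n)`, so the Pearson comparator also ranks
  planted partners at the top: the subset advantage of the qualitative
  score over global correlation emerges at smaller subset fractions or
  weaker effects, not at this operating point. `compare_methods()` lets the
  user map the regime boundary directly.

## Downstream modules

**Networks.** `build_network()` assembles edges into an annotated graph
(species, TF family, bait flag); `tf_only` restricts partners to annotated
TFs, the restriction used when counting candidate regulators.
`extend_network()` screens additional baits (for example validated
secondary-wall TFs) under identical parameters and unions the result;
bait-bait edges are flagged and stored once, canonically oriented, which
makes extension idempotent and order-independent. Exports cover Cytoscape
SIF plus attribute tables, lossless edge/node TSV, and GraphML via igraph.

**Orthology.** `map_homologs()` consumes standard 12-column BLAST tabular
output. No thresholds are published for the comparison this reproduces, so
the defaults are common practice (`max_evalue = 1e-10`, best hit per query,
ties by bitscore then subject ID) and are recorded in the map; the
many-to-one shape of a cross-species TF comparison is what best-hit mode
produces structurally. Reciprocal-best mode is available but not the
default. `overlay_networks()` reports, per homolog pair, the Jaccard
overlap of bait neighborhoods under a user-supplied bait correspondence;
pairs at or above `min_jaccard` (default 0.5) are labelled conserved, and
network genes without homologs are the species-specific "triangles".

**Enrichment.** `fisher_enrichment()` tests over-representation only (the
one-sided hypergeometric tail), BH-adjusts across tested bins, and flags
significance at FDR 0.1 by default. The background defaults to the genes on
the expression matrix; genes in several bins count once per bin, and no
bin-overlap correction is attempted. Depletion is deliberately out of
scope.

**DE intersection.** `intersect_with_de()` intersects a bait's neighborhood
with any number of DE gene lists (produced upstream by an RNA-seq pipeline;
this package does not call differential expression) and reports BF and
per-list direction for the survivors.

## Determinism and provenance

Every randomized step is governed by one user seed: the generator and the
pipeline restore the caller's RNG state, permutation streams are derived
deterministically, and `run_pipeline()` writes a provenance YAML (full
configuration plus MD5 digests of all inputs) and a summary JSON next to its
outputs. Re-running a config reproduces every output byte for byte, which
the suite asserts.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
1000 random pairs for the score oracle, 500 random 93-condition profiles
for the discretization properties, 10^4 and 2 x 10^3 null pairs for
calibration, ten replicates of the 500 x 93 planted benchmark for recovery
and the method contrast, full enumeration of all hypergeometric tables with
`N <= 12`, and 500 null replicates for the FDR check. These sizes keep each
check well inside interactive runtimes while leaving the Monte-Carlo bands
(three standard errors) meaningful.

## Known limitations

* The BF score is blind to within-subset effect direction ordering beyond
  the `2r` qualitative levels; it detects agreement of extremes, not shape.
* The exact null conditions on level counts; if a user feeds hand-made
  level matrices with pathological margins, the discrete achievable p-values
  can be very coarse.
* Probe-to-gene ambiguity is handled by reporting per-probe edges and an
  optional max-BF collapse (`collapse_probe_edges()`); no sequence-level
  resolution is attempted.
* Homology is whatever BLAST tabular input asserts; the package does not
  align sequences or infer orthogroups.
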