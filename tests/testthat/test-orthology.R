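# 10-query hit fixture with a brute-force filter/argmin oracle.
hits_fixture <- function() {
  set.seed(17)
  rows <- list()
  for (q in paste0("Pv", sprintf("%02d", 1:10))) {
    for (s in sample(paste0("At", 1:6), sample(2:4, 1))) {
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = q, sseqid = s, pident = round(runif(1, 30, 95), 1),
        length = 200L, mismatch = 0L, gapopen = 0L, qstart = 1L,
        qend = 200L, sstart = 1L, send = 200L,
        evalue = 10^-sample(5:60, 1), bitscore = round(runif(1, 50, 400)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

best_hit_oracle <- function(hits, genes_a, genes_b, max_e, min_id) {
  keep <- hits[hits$qseqid %in% genes_a & hits$sseqid %in% genes_b &
                 hits$evalue <= max_e & hits$pident >= min_id, ]
  do.call(rbind, lapply(split(keep, keep$qseqid), function(h) {
    h <- h[h$evalue == min(h$evalue), ]
    h <- h[h$bitscore == max(h$bitscore), ]
    h[order(h$sseqid), ][1, ]
  }))
}

test_that("best-hit selection matches the brute-force argmin oracle", {
  hits <- hits_fixture()
  genes_a <- unique(hits$qseqid)
  genes_b <- unique(hits$sseqid)
  for (max_e in c(1e-10, 1e-30)) {
    map <- map_homologs(hits, genes_a, genes_b, max_evalue = max_e)
    want <- best_hit_oracle(hits, genes_a, genes_b, max_e, 0)
    expect_equal(nrow(map$pairs), nrow(want))
    expect_setequal(paste(map$pairs$gene_a, map$pairs$gene_b),
                    paste(want$qseqid, want$sseqid))
  }

  # explicit tie-break: lower evalue wins regardless of identity
  two <- rbind(
    data.frame(qseqid = "q", sseqid = "s_weak", pident = 90, length = 100L,
               mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
               sstart = 1L, send = 100L, evalue = 1e-10, bitscore = 100),
    data.frame(qseqid = "q", sseqid = "s_strong", pident = 50, length = 100L,
               mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
               sstart = 1L, send = 100L, evalue = 1e-50, bitscore = 300))
  m2 <- map_homologs(two, "q", c("s_weak", "s_strong"))
  expect_equal(m2$pairs$gene_b, "s_strong")

  expect_equal(nrow(map_homologs(two[0, ], "q", "s")$pairs), 0L)
})

test_that("threshold tightening never adds pairs; all-pass/reciprocal modes", {
  hits <- hits_fixture()
  genes_a <- unique(hits$qseqid); genes_b <- unique(hits$sseqid)
  thresholds <- c(1e-5, 1e-10, 1e-20, 1e-40)
  sizes_all <- sizes_best <- integer(0)
  prev <- NULL
  for (e in thresholds) {
    ap <- map_homologs(hits, genes_a, genes_b, max_evalue = e, mode = "all-pass")
    sizes_all <- c(sizes_all, nrow(ap$pairs))
    sizes_best <- c(sizes_best,
                    nrow(map_homologs(hits, genes_a, genes_b, max_evalue = e)$pairs))
    if (!is.null(prev))
      expect_true(all(paste(ap$pairs$gene_a, ap$pairs$gene_b) %in% prev))
    prev <- paste(ap$pairs$gene_a, ap$pairs$gene_b)
  }
  expect_true(all(diff(sizes_all) <= 0))
  expect_true(all(diff(sizes_best) <= 0))

  # identity threshold is monotone too
  n_lo <- nrow(map_homologs(hits, genes_a, genes_b, 1e-5, 40, "all-pass")$pairs)
  n_hi <- nrow(map_homologs(hits, genes_a, genes_b, 1e-5, 80, "all-pass")$pairs)
  expect_lte(n_hi, n_lo)

  # reciprocal-best is one-to-one and a subset of best-hit
  rb <- map_homologs(hits, genes_a, genes_b, 1e-5, 0, "reciprocal-best")
  bh <- map_homologs(hits, genes_a, genes_b, 1e-5, 0, "best-hit")
  expect_equal(anyDuplicated(rb$pairs$gene_b), 0L)
  expect_true(all(paste(rb$pairs$gene_a, rb$pairs$gene_b) %in%
                    paste(bh$pairs$gene_a, bh$pairs$gene_b)))

  s <- summary(bh)
  expect_equal(s$n_genes_a, length(unique(bh$pairs$gene_a)))
  expect_equal(s$n_genes_b, length(unique(bh$pairs$gene_b)))
  expect_gte(s$n_genes_a, s$n_genes_b * 0L)  # distinct counts are defined
})

make_two_nets <- function(edges_a, edges_b) {
  list(a = build_network(edges_a), b = build_network(edges_b))
}

test_that("network overlay computes Jaccard overlap under bait correspondence", {
  bait_map <- data.frame(bait_a = c("A1", "A2", "A3"),
                         bait_b = c("B1", "B2", "B3"),
                         stringsAsFactors = FALSE)
  nets <- make_two_nets(
    make_edges(bait = c("A1", "A2", "A3", "A1"),
               partner = c("ga", "ga", "ga", "gx")),
    make_edges(bait = c("B1", "B2", "B3"), partner = c("gb", "gb", "gb")))
  map <- structure(list(pairs = data.frame(gene_a = "ga", gene_b = "gb",
                                           pident = 80, evalue = 1e-40,
                                           bitscore = 200,
                                           stringsAsFactors = FALSE),
                        thresholds = list(), mode = "best-hit"),
                   class = "ortholog_map")
  ov <- overlay_networks(nets$a, nets$b, map, bait_map)
  pair_row <- ov[!is.na(ov$gene_a) & ov$gene_a == "ga" & !is.na(ov$gene_b), ]
  expect_equal(pair_row$jaccard, 1)
  expect_equal(pair_row$label, "conserved")
  # gx has no homolog: species-specific "triangle"
  expect_true("species-specific" %in% ov$label[is.na(ov$gene_b)])
  expect_error(overlay_networks(nets$a, nets$b, map, NULL), "bait correspondence")

  # brute-force Jaccard oracle on a random two-network fixture
  set.seed(23)
  ea <- make_edges(bait = sample(bait_map$bait_a, 40, TRUE),
                   partner = sample(paste0("ga", 1:8), 40, TRUE))
  ea <- ea[!duplicated(paste(ea$bait, ea$partner)), ]
  eb <- make_edges(bait = sample(bait_map$bait_b, 40, TRUE),
                   partner = sample(paste0("gb", 1:8), 40, TRUE))
  eb <- eb[!duplicated(paste(eb$bait, eb$partner)), ]
  netsR <- make_two_nets(ea, eb)
  pairs <- data.frame(gene_a = paste0("ga", 1:8), gene_b = paste0("gb", 1:8),
                      pident = 70, evalue = 1e-30, bitscore = 100,
                      stringsAsFactors = FALSE)
  mapR <- structure(list(pairs = pairs, thresholds = list(), mode = "best-hit"),
                    class = "ortholog_map")
  ovR <- overlay_networks(netsR$a, netsR$b, mapR, bait_map, min_jaccard = 0.5)
  for (i in seq_len(8)) {
    na_ <- ea$bait[ea$partner == pairs$gene_a[i]]
    nb_ <- bait_map$bait_a[match(eb$bait[eb$partner == pairs$gene_b[i]],
                                 bait_map$bait_b)]
    u <- union(na_, nb_)
    want <- if (length(u) == 0) 0 else length(intersect(na_, nb_)) / length(u)
    row <- ovR[!is.na(ovR$gene_a) & ovR$gene_a == pairs$gene_a[i] &
                 !is.na(ovR$gene_b), ]
    if (nrow(row) == 1L) expect_equal(row$jaccard, want)
  }

  # symmetry: swapping the networks with the map transposed swaps the sides
  mapT <- mapR
  mapT$pairs <- data.frame(gene_a = pairs$gene_b, gene_b = pairs$gene_a,
                           pident = 70, evalue = 1e-30, bitscore = 100,
                           stringsAsFactors = FALSE)
  bait_mapT <- data.frame(bait_a = bait_map$bait_b, bait_b = bait_map$bait_a)
  ovT <- overlay_networks(netsR$b, netsR$a, mapT, bait_mapT, min_jaccard = 0.5)
  both <- merge(ovR[!is.na(ovR$gene_a) & !is.na(ovR$gene_b), ],
                ovT[!is.na(ovT$gene_a) & !is.na(ovT$gene_b), ],
                by.x = c("gene_a", "gene_b"), by.y = c("gene_b", "gene_a"))
  expect_gt(nrow(both), 0L)
  expect_equal(both$jaccard.x, both$jaccard.y)
})
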