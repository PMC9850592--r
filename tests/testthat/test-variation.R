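test_that("SV vs boundary classification follows the ABA/PBA/NBA definitions", {
  boundaries <- data.frame(chrom = "chr1", start = 125e3, end = 150e3)
  tads <- data.frame(chrom = "chr1", start = c(0, 150e3), end = c(125e3, 500e3))
  sv <- data.frame(chrom = "chr1",
                   start = c(100e3, 130e3, 200e3, 600e3),
                   end = c(200e3, 200e3, 300e3, 700e3))
  got <- classify_sv_vs_boundary(sv, boundaries, tads)
  expect_identical(got$boundary_class, c("ABA", "PBA", "NBA", "none"))
  # order invariance
  got2 <- classify_sv_vs_boundary(sv[4:1, ], boundaries, tads)
  expect_identical(got2$boundary_class, rev(got$boundary_class))
})

test_that("bootstrap enrichment matches exhaustive placement on a toy genome", {
  # one 5-bp segment on a 20-bp genome; 3 point SVs
  segments <- data.frame(chrom = "c", start = 2, end = 7)
  sv <- data.frame(chrom = "c", start = c(1, 9, 15), end = c(2, 10, 16))
  lens <- c(c = 20)
  res <- sv_compartment_enrichment(sv, segments, lens, n_boot = 4000, seed = 9)
  # exhaustive: placements s = 0..15, count SVs overlapping [s, s+5)
  exact <- mean(sapply(0:15, function(s) {
    sum(sv$start < s + 5 & sv$end > s)
  }))
  expect_lt(abs(res$null_mean - exact), 0.1)
  expect_identical(res$observed, sum(sv$start < 7 & sv$end > 2))
  expect_error(
    sv_compartment_enrichment(sv, data.frame(chrom = "c", start = 0, end = 30),
                              lens, n_boot = 10),
    "longer than")
})

test_that("planted enrichment gives strongly positive z", {
  set.seed(4)
  segments <- data.frame(chrom = "c", start = c(0, 5e5), end = c(1e5, 6e5))
  sv <- data.frame(chrom = "c",
                   start = c(runif(20, 0, 0.9e5), runif(20, 5e5, 5.9e5)))
  sv$end <- sv$start + 1e3
  res <- sv_compartment_enrichment(sv, segments, c(c = 1e6),
                                   n_boot = 500, seed = 2)
  expect_gt(res$z, 3)
  expect_lt(res$p_empirical, 0.01)
})

test_that("effect/contribution identities hold and Fisher P equals the
           hypergeometric tail", {
  lab <- c(rep("specific", 10), rep("common", 9))
  pres <- cbind("ABA-PAV" = c(rep(TRUE, 8), rep(FALSE, 2),
                              rep(TRUE, 3), rep(FALSE, 6)))
  res <- sv_effect_contribution(lab, pres)
  # 2x2 table (8,2 / 3,6): one-sided P from the hypergeometric tail
  p_oracle <- sum(stats::dhyper(8:10, 11, 8, 10))
  expect_equal(res$p_fisher, p_oracle, tolerance = 1e-12)
  expect_equal(res$contribution_pct, 100 * 8 / 10)
  expect_equal(res$effect_pct, 100 * 8 / 11)
  # identity: contribution x #specific = effect x #(with SV) = #(specific & SV)
  expect_equal(res$contribution_pct / 100 * 10, 8)
  expect_equal(res$effect_pct / 100 * res$n_with_sv, 8)
  # degenerate cases: all specific carry it, no SV anywhere
  res2 <- sv_effect_contribution(lab, cbind(x = c(rep(TRUE, 10), rep(FALSE, 9))))
  expect_equal(res2$contribution_pct, 100)
  expect_equal(res2$effect_pct, 100)
  res3 <- sv_effect_contribution(lab, cbind(x = rep(FALSE, 19)))
  expect_equal(res3$contribution_pct, 0)
  expect_true(is.na(res3$effect_pct))
})

test_that("feature tracks: GC over non-N bases, TSS dedup, merged repeats", {
  seq <- paste0(strrep("G", 100), strrep("A", 80), strrep("N", 20))
  ft <- feature_tracks(200, 100, tss = c(5, 5, 150), seq = seq,
                       repeats = data.frame(start = c(10, 30, 120),
                                            end = c(40, 60, 130)))
  expect_equal(ft$gc, c(1, 0))  # N bases excluded from the second window
  expect_equal(ft$tss_count, c(1, 1))  # duplicated TSS collapsed
  # overlapping repeats merged: [10,60) covers 50 of 100
  expect_equal(ft$repeat_frac, c(0.5, 0.1))
  # base-counting oracle for merged coverage
  covered <- logical(200)
  for (k in 1:3) covered[(c(10, 30, 120)[k] + 1):c(40, 60, 130)[k]] <- TRUE
  expect_equal(ft$repeat_frac, c(mean(covered[1:100]), mean(covered[101:200])))
  # partial final window flagged
  ft2 <- feature_tracks(250, 100)
  expect_identical(ft2$partial, c(FALSE, FALSE, TRUE))
})

test_that("repeat metaprofile assigns fragments by midpoint with the right-open
           tie rule and matches a brute-force oracle", {
  # fragment [90, 110): midpoint 100 sits exactly on the bin edge at the
  # anchor -> assigned to the right-open bin starting at offset 0
  anchors <- 100
  rp <- data.frame(start = 90, end = 110)
  prof <- repeat_metaprofile(anchors, rp, flank = 50, bin = 50,
                             chrom_length = 1000)
  expect_equal(prof$n_fragments, c(0, 1))
  # fragments planted only at anchors peak at offset 0
  anchors2 <- c(300, 600)
  rp2 <- data.frame(start = anchors2 + 2, end = anchors2 + 20)
  prof2 <- repeat_metaprofile(anchors2, rp2, flank = 100, bin = 25,
                              chrom_length = 1000)
  expect_equal(which.max(prof2$coverage_pct), which(prof2$offset == 0))
  # brute-force oracle on random fragments
  set.seed(8)
  rp3 <- data.frame(start = sort(runif(40, 0, 900)))
  rp3$end <- rp3$start + runif(40, 5, 60)
  anchors3 <- c(200, 500, 800)
  prof3 <- repeat_metaprofile(anchors3, rp3, flank = 100, bin = 50,
                              chrom_length = 1000)
  for (r in seq_len(nrow(prof3))) {
    ws <- anchors3 + prof3$offset[r]
    cnt <- 0
    for (w in ws) {
      mid <- floor((rp3$start + rp3$end) / 2)
      cnt <- cnt + sum(mid >= w & mid < w + 50)
    }
    expect_equal(prof3$n_fragments[r], cnt)
  }
})

test_that("metaprofile truncates flanks at chromosome ends", {
  prof <- repeat_metaprofile(30, data.frame(start = 1, end = 5),
                             flank = 100, bin = 50, chrom_length = 1000)
  expect_equal(prof$n_anchors, c(0, 0, 1, 1))  # left flank off-chromosome
})

test_that("DEG density profile is linear and peaks at planted classes", {
  bounds <- data.frame(position = c(1e5, 5e5), class = c("specific", "common"))
  degs <- data.frame(accession = "q1", tss = c(95e3, 98e3, 105e3))
  prof <- deg_density_profile(bounds, degs, flank = 50e3, bin = 25e3)
  spec <- prof[prof$class == "specific", ]
  comm <- prof[prof$class == "common", ]
  expect_gt(sum(spec$mean_degs), sum(comm$mean_degs))
  # doubling DEGs doubles the profile
  prof2 <- deg_density_profile(bounds, rbind(degs, degs), flank = 50e3,
                               bin = 25e3)
  expect_equal(prof2$mean_degs, 2 * prof$mean_degs)
  # no DEGs -> zero profile
  prof0 <- deg_density_profile(bounds,
                               data.frame(accession = character(0),
                                          tss = numeric(0)),
                               flank = 50e3, bin = 25e3)
  expect_true(all(prof0$mean_degs == 0))
})

test_that("nonVariation genes have zero overlap under the half-open convention", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      start = c(100, 500, 900), end = c(200, 600, 950))
  variants <- data.frame(chrom = "chr1", start = c(150, 600), end = c(151, 601))
  got <- nonvariation_genes(genes, variants)
  # g2's variant starts exactly at its (exclusive) end -> no overlap
  expect_identical(got$nonvariation, c(FALSE, TRUE, TRUE))
  # brute-force oracle on random inputs
  set.seed(12)
  genes2 <- data.frame(gene_id = sprintf("g%d", 1:30), chrom = "chr1",
                       start = sort(sample(1e4, 30)))
  genes2$end <- genes2$start + sample(50:500, 30, replace = TRUE)
  vars2 <- data.frame(chrom = "chr1", start = sample(1e4, 50))
  vars2$end <- vars2$start + sample(c(1, 10, 100), 50, replace = TRUE)
  got2 <- nonvariation_genes(genes2, vars2)
  for (k in 1:30) {
    ov <- any(vars2$start < genes2$end[k] & vars2$end > genes2$start[k])
    expect_identical(got2$nonvariation[k], !ov)
  }
})

# Direct per-site Weir-Cockerham oracle (allele-count form).
fst_site_oracle <- function(n1, x1, n2, x2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pbar <- (x1 + x2) / (n1 + n2)
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 + n2 - 2)
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2))
  (msp - msg) / (msp + (nc - 1) * msg)
}

test_that("windowed F_ST matches the per-site estimator oracle and bounds", {
  # identical frequencies -> ~0; fixed difference -> 1
  lens <- c(chr1 = 50e3)
  sites_eq <- data.frame(chrom = "chr1", pos = seq(1000, 24000, by = 4000),
                         n1 = 40, x1 = 20, n2 = 40, x2 = 20)
  res_eq <- windowed_fst(sites_eq, lens, min_sites = 3)
  # the Weir-Cockerham estimator is unbiased around 0, slightly negative
  # at identical frequencies (finite-sample correction)
  expect_lt(abs(res_eq$windows$fst[1]), 0.05)
  expect_lte(res_eq$windows$fst[1], 0)
  sites_fix <- data.frame(chrom = "chr1", pos = seq(1000, 24000, by = 4000),
                          n1 = 40, x1 = 40, n2 = 40, x2 = 0)
  res_fix <- windowed_fst(sites_fix, lens, min_sites = 3)
  expect_equal(res_fix$windows$fst[1], 1)
  # random counts: window value equals ratio-of-sums of the per-site oracle
  set.seed(3)
  pos <- sort(sample(25e3, 12))
  x1 <- rbinom(12, 30, 0.3); x2 <- rbinom(12, 50, 0.7)
  sites <- data.frame(chrom = "chr1", pos = pos, n1 = 30, x1 = x1,
                      n2 = 50, x2 = x2)
  res <- windowed_fst(sites, lens, min_sites = 3)
  comp <- t(mapply(pan3d:::wc_site_components, 30, x1, 50, x2))
  poly <- !is.na(comp[, 1])
  expect_equal(res$windows$fst[1], sum(comp[poly, 1]) / sum(comp[poly, 2]))
  # per-site value equals the direct-formula oracle at polymorphic sites
  for (k in which(poly)) {
    expect_equal(unname(comp[k, 1] / comp[k, 2]),
                 fst_site_oracle(30, x1[k], 50, x2[k]), tolerance = 1e-12)
  }
  expect_error(windowed_fst(data.frame(chrom = "c", pos = 1, n1 = 1, x1 = 0,
                                       n2 = 10, x2 = 1), c(c = 100)),
               "allele count")
})

test_that("monomorphic windows are excluded and selected regions merge", {
  lens <- c(chr1 = 100e3)
  mono <- data.frame(chrom = "chr1", pos = seq(1000, 24000, by = 3000),
                     n1 = 20, x1 = 0, n2 = 20, x2 = 0)
  res <- windowed_fst(mono, lens, min_sites = 3)
  expect_true(is.na(res$windows$fst[1]))
  expect_equal(res$windows$n_sites[1], 0)
})
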