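test_that("generators are deterministic for a fixed seed", {
  r1 <- simulate_reference(list(n_chrom = 1, chrom_length = 5e6), seed = 1)
  r2 <- simulate_reference(list(n_chrom = 1, chrom_length = 5e6), seed = 1)
  expect_identical(r1, r2)
  p1 <- suppressMessages(simulate_accession_panel(r1, 3, seed = 7))
  p2 <- suppressMessages(simulate_accession_panel(r1, 3, seed = 7))
  expect_identical(lapply(p1$accessions, `[[`, "svs"),
                   lapply(p2$accessions, `[[`, "svs"))
  # byte-identical COO output for a fixed seed
  lab <- rep(c("A", "B"), each = 10)
  m1 <- simulate_contact_matrix(lab, rep(1:2, each = 10), 25e3, seed = 3)
  m2 <- simulate_contact_matrix(lab, rep(1:2, each = 10), 25e3, seed = 3)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_contacts(m1, f1); write_contacts(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("reference model invariants hold", {
  ref <- simulate_reference(list(n_chrom = 2, chrom_length = 8e6), seed = 11)
  for (ch in names(ref$chrom_lengths)) {
    tads <- ref$tads[[ch]]
    # TADs tile the chromosome without overlap
    expect_equal(tads$start[1], 0)
    expect_equal(tads$end[nrow(tads)], ref$chrom_lengths[[ch]])
    expect_equal(tads$start[-1], tads$end[-nrow(tads)])
    expect_true(all(tads$end > tads$start))
    # labels cover all bins; GC within [0, 1]
    expect_equal(length(ref$comp_labels[[ch]]),
                 ref$chrom_lengths[[ch]] / ref$comp_bin)
    expect_true(all(ref$comp_labels[[ch]] %in% c("A", "B")))
    expect_true(all(ref$gc[[ch]] >= 0 & ref$gc[[ch]] <= 1))
    # intervals within bounds
    expect_true(all(ref$repeats[[ch]]$start >= 0))
    expect_true(all(ref$repeats[[ch]]$end <= ref$chrom_lengths[[ch]]))
    expect_true(all(ref$repeats[[ch]]$subtype %in% pan3d:::REPEAT_SUBTYPES))
  }
  expect_error(simulate_reference(list(chrom_length = -5)), "non-positive")
  expect_error(simulate_contact_matrix("A", 1, 25e3, alpha = -1), "positive")
})

test_that("TSS density margins behave as configured (null and default)", {
  ref <- simulate_reference(list(n_chrom = 1, chrom_length = 5e7), seed = 2)
  lab <- ref$comp_labels$chr1
  dens <- gene_density_track(ref, "chr1")
  p_default <- stats::wilcox.test(dens[lab == "A"], dens[lab == "B"],
                                  alternative = "greater")$p.value
  expect_lt(p_default, 1e-6)
  ref0 <- simulate_reference(list(n_chrom = 1, chrom_length = 5e7,
                                  tss_a = 5, tss_b = 5), seed = 2)
  dens0 <- gene_density_track(ref0, "chr1")
  lab0 <- ref0$comp_labels$chr1
  p_null <- stats::wilcox.test(dens0[lab0 == "A"], dens0[lab0 == "B"])$p.value
  expect_gt(p_null, 0.01)
})

test_that("no-structure contact matrix has flat observed/expected", {
  lab <- rep(c("A", "B"), each = 15)
  m <- simulate_contact_matrix(lab, rep(1:3, each = 10), 25e3,
                               comp_factor = 1, tad_factor = 1, noise = "none")
  oe <- observed_expected(m)
  expect_lt(max(abs(oe - 1), na.rm = TRUE), 1e-6)
})

test_that("within-TAD counts exceed between-TAD counts at matched distance", {
  lab <- rep("A", 60)
  tad <- rep(1:3, each = 20)
  m <- simulate_contact_matrix(lab, tad, 25e3, comp_factor = 1,
                               tad_factor = 5, seed = 9)
  d <- abs(outer(1:60, 1:60, "-"))
  same <- outer(tad, tad, "==")
  sel <- d == 5
  expect_gt(mean(m$counts[sel & same]), mean(m$counts[sel & !same]))
})

test_that("a single-accession panel with zero SV rates is the identity", {
  ref <- simulate_reference(list(n_chrom = 2, chrom_length = 5e6), seed = 3)
  panel <- simulate_accession_panel(ref, 1, seed = 3)
  acc <- panel$accessions$ref
  expect_equal(nrow(acc$svs), 0)
  expect_equal(acc$chrom_lengths, ref$chrom_lengths)
  for (ch in names(ref$chrom_lengths)) {
    seg <- acc$map[acc$map$ref_chrom == ch, ]
    expect_equal(min(seg$ref_start), 0)
    expect_equal(max(seg$ref_end), ref$chrom_lengths[[ch]])
    expect_equal(seg$ref_start, seg$query_start)
    expect_equal(seg$ref_end, seg$query_end)
    expect_true(all(seg$strand == "+"))
  }
})

test_that("planted ABA-PAVs delete their boundaries from the accession truth", {
  panel <- shared_panel()
  found_any <- FALSE
  for (a in setdiff(names(panel$accessions), "ref")) {
    acc <- panel$accessions[[a]]
    aba <- acc$svs[acc$svs$planted == "ABA", , drop = FALSE]
    for (r in seq_len(nrow(aba))) {
      ch <- aba$chrom[r]
      ref_j <- panel$reference$tads[[ch]]$start[-1]
      covered <- ref_j[aba$start[r] <= ref_j - 25e3 &
                         aba$end[r] >= ref_j + 50e3]
      covered <- ref_j[vapply(ref_j, function(p)
        aba$start[r] <= p && aba$end[r] >= p + 25e3, logical(1))]
      if (!length(covered)) next
      found_any <- TRUE
      # absent from the accession's merged TAD partition
      expect_false(any(covered %in% acc$tads_ref[[ch]]$start[-1]))
      expect_true(all(covered %in%
                        acc$truth$lost_boundaries$pos[
                          acc$truth$lost_boundaries$chrom == ch]))
    }
  }
  expect_true(found_any)
})

test_that("coordinate maps round-trip fully mapped intervals", {
  panel <- shared_panel()
  for (a in c("q01", "q03")) {
    map <- panel$accessions[[a]]$map
    set.seed(42)
    # sample intervals inside single mapped segments (fully mapped)
    seg <- map[map$ref_end - map$ref_start > 2e4, ]
    seg <- seg[sample(nrow(seg), min(20, nrow(seg))), ]
    for (r in seq_len(nrow(seg))) {
      s <- seg$ref_start[r] + 1e3
      e <- s + 1e4
      f <- liftover_interval(map, seg$ref_chrom[r], s, e, from = "ref")
      expect_true(f$ok)
      back <- liftover_interval(map, f$chrom, f$start, f$end, from = "query")
      expect_true(back$ok)
      expect_equal(c(back$start, back$end), c(s, e))
    }
    # applying the edit list reproduces derived lengths exactly
    acc <- panel$accessions[[a]]
    svs <- acc$svs
    for (ch in names(panel$reference$chrom_lengths)) {
      expected <- panel$reference$chrom_lengths[[ch]]
      expected <- expected -
        sum((svs$end - svs$start)[svs$type == "PAV" & svs$chrom == ch]) +
        sum((svs$end - svs$start)[svs$type == "CNV" & svs$chrom == ch])
      tr_out <- svs$type == "TRANS" & svs$chrom == ch
      tr_in <- svs$type == "TRANS" & !is.na(svs$chrom2) & svs$chrom2 == ch
      expected <- expected -
        sum((svs$end - svs$start)[tr_out]) +
        sum((svs$end2 - svs$start2)[tr_out]) -
        sum((svs$end2 - svs$start2)[tr_in]) +
        sum((svs$end - svs$start)[tr_in])
      expect_equal(acc$chrom_lengths[[ch]], expected)
    }
    # map segments non-overlapping on both genomes
    for (side in list(c("ref_chrom", "ref_start", "ref_end"),
                      c("query_chrom", "query_start", "query_end"))) {
      for (ch in unique(map[[side[1]]])) {
        mm <- map[map[[side[1]]] == ch, ]
        o <- order(mm[[side[2]]])
        expect_true(all(mm[[side[2]]][o][-1] >= mm[[side[3]]][o][-nrow(mm)]))
      }
    }
  }
})

test_that("expression generator plants A > B and boundary-loss DEG shifts", {
  panel <- shared_panel()
  ex <- simulate_expression(panel, seed = 4)
  a_med <- stats::median(ex$fpkm[ex$genes$label == "A", "ref"])
  b_med <- stats::median(ex$fpkm[ex$genes$label == "B", "ref"])
  expect_gt(a_med, 2 * b_med)
  # planted shift factor 4 -> planted gene/accession pairs are DEGs
  if (nrow(ex$planted)) {
    hits <- merge(ex$planted, ex$degs, by = c("gene_id", "accession"))
    expect_gt(nrow(hits) / nrow(ex$planted), 0.9)
  }
  # shift factor 1 -> no planted DEGs
  ex0 <- simulate_expression(panel, config = list(shift_factor = 1), seed = 4)
  expect_equal(nrow(ex0$planted), 0)
  # equal A/B means -> no significant expression difference
  ex_eq <- simulate_expression(panel,
                               config = list(fpkm_meanlog_a = log(8),
                                             fpkm_meanlog_b = log(8)),
                               seed = 4)
  a_m <- stats::median(ex_eq$fpkm[ex_eq$genes$label == "A", "ref"])
  b_m <- stats::median(ex_eq$fpkm[ex_eq$genes$label == "B", "ref"])
  expect_gt(a_m / b_m, 0.85)
  expect_lt(a_m / b_m, 1.18)
})

test_that("top-5% F_ST scan recovers planted selected windows", {
  gt <- simulate_genotypes(c(chr1 = 1e7, chr2 = 1e7), seed = 6)
  res <- windowed_fst(gt$sites, c(chr1 = 1e7, chr2 = 1e7))
  sel <- res$selected
  hit <- vapply(seq_len(nrow(gt$selected)), function(r) {
    any(sel$chrom == gt$selected$chrom[r] &
          sel$start < gt$selected$end[r] & sel$end > gt$selected$start[r])
  }, logical(1))
  expect_gte(mean(hit), 0.8)
  # divergence ~0 everywhere -> near-zero F_ST
  gt0 <- simulate_genotypes(c(chr1 = 2e6),
                            config = list(fst_selected = 1e-4,
                                          fst_neutral = 1e-4), seed = 6)
  res0 <- windowed_fst(gt0$sites, c(chr1 = 2e6))
  expect_lt(stats::median(res0$windows$fst, na.rm = TRUE), 0.05)
})

test_that("panel writer emits the declared plain-text formats", {
  panel <- shared_panel()
  dir <- withr::local_tempdir()
  write_panel(panel, dir)
  expect_true(file.exists(file.path(dir, "reference_tss.gff3")))
  expect_true(file.exists(file.path(dir, "q01_svs.tsv")))
  expect_true(file.exists(file.path(dir, "q01_map.tsv")))
  gff <- readLines(file.path(dir, "reference_tss.gff3"))
  expect_identical(gff[1], "##gff-version 3")
  map_back <- utils::read.table(file.path(dir, "q01_map.tsv"), header = TRUE)
  expect_equal(nrow(map_back), nrow(panel$accessions$q01$map))
})
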