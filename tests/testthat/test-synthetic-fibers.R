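# Generator contracts: layout arithmetic, determinism, planted truth
# consistency, and the degenerate-rate identity that underpins every
# downstream truth-recovery test.

test_that("simulate_genome places genes and CREs per the layout", {
  cfg <- sim_config(n_genes = 1L, gene_length = 2000L, seed = 7L)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$genes), 1L)
  expect_equal(g$genes$end - g$genes$start, 2000L)
  expect_equal(g$genes$tss, g$genes$start)  # plus strand: TSS at body start
  expect_equal(nchar(g$reference[["chrS"]]), cfg$genome_length)
  # CREs inside the 9 kb regression window upstream of the TSS
  win <- gene_windows(g$genes[1], upstream_bp = 9000L)$upstream
  expect_true(all(g$cres$start >= win[1] & g$cres$end <= win[2]))
  # TATA box 25-35 bp upstream
  expect_equal(g$tata$start, g$genes$tss - 35L)
  expect_equal(g$tata$end, g$genes$tss - 25L)
})

test_that("simulate_genome rejects layouts that cannot fit", {
  expect_error(simulate_genome(sim_config(genome_length = 20000L,
                                          n_genes = 3L)),
               "overlap")
})

test_that("identical config and seed give byte-identical datasets", {
  cfg <- sim_config(n_genes = 1L, n_fibers_per_gene = 6L, seed = 7L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$reference, b$reference)
  expect_identical(a$fibers, b$fibers)
  expect_identical(a$truth_footprints, b$truth_footprints)
  expect_identical(a$proseq, b$proseq)
})

test_that("state-specific planting obeys the stated rules", {
  cfg <- sim_config(n_genes = 1L, seed = 9L)
  g <- simulate_genome(cfg)
  gene <- g$genes[1]; gcres <- g$cres
  win <- gene_windows(gene)
  set.seed(42)
  off <- simulate_fiber(gene, gcres, "off", cfg, g$reference, "f_off")
  expect_equal(nrow(off$footprints[class == "polII"]), 0L)
  expect_true(all(off$footprints$class %in% c("nucleosome", "TF")))

  hb <- simulate_fiber(gene, gcres, "hyperburst", cfg, g$reference, "f_hb")
  nuc <- hb$footprints[class == "nucleosome"]
  occ <- iv_overlap_bp(win$hyperburst[1], win$hyperburst[2], nuc$start, nuc$end) /
    (win$hyperburst[2] - win$hyperburst[1])
  expect_lt(occ, 0.5)  # < 50% nucleosome occupancy of the first 1.5 kb

  refr <- simulate_fiber(gene, gcres, "refractory", cfg, g$reference, "f_r")
  expect_equal(nrow(refr$footprints[class %in% c("polII", "PIC")]), 0L)

  expect_error(simulate_fiber(gene, gcres, "nonsense", cfg, g$reference),
               "unknown transcription state")
})

test_that("degenerate rates make methylation equal the accessibility mask", {
  cfg <- sim_config(n_genes = 1L, n_fibers_per_gene = 2L,
                    meth_rate_accessible = 1, meth_rate_inaccessible = 0,
                    seed = 5L)
  ds <- simulate_dataset(cfg)
  for (i in seq_len(nrow(ds$fibers))) {
    f <- ds$fibers[i]
    fp <- ds$truth_footprints[fiber_id == f$fiber_id]
    seq <- get_sequence(ds$reference, f$chrom, f$start, f$end)
    bases <- strsplit(seq, "")[[1]]
    at <- which(bases %in% c("A", "T")) - 1L   # 0-based offsets
    inacc <- rep(FALSE, f$end - f$start)
    for (k in seq_len(nrow(fp)))
      inacc[(fp$start[k] - f$start + 1L):(fp$end[k] - f$start)] <- TRUE
    expected <- at[!inacc[at + 1L]]
    expect_identical(sort(f$meth[[1]]), sort(expected))
  }
})

test_that("planted footprints are disjoint and conserve fiber coverage", {
  ds <- fx_dataset()
  for (fid in ds$fibers$fiber_id) {
    f <- ds$fibers[fiber_id == fid]
    fp <- ds$truth_footprints[fiber_id == fid][order(start)]
    expect_true(all(fp$start >= f$start & fp$end <= f$end))
    expect_true(all(head(fp$end, -1) <= tail(fp$start, -1)))
    gaps <- iv_complement(fp[, .(start, end)], f$start, f$end)
    expect_equal(sum(fp$end - fp$start) + sum(gaps$end - gaps$start),
                 f$end - f$start)
  }
})

test_that("truth states are recovered by the state rules at degenerate rates", {
  cl <- fx_classified_degenerate()
  ds <- cl$ds
  gene <- ds$genes[1]
  calls <- assign_states(ds$fibers, gene, cl$classified, cl$access)
  truth <- ds$fibers[, .(fiber_id, true_state)]
  m <- merge(calls, truth, by = "fiber_id")
  # "off" guarantees transcriptional silence; promoter closure is left to
  # random nucleosome phasing, so accessible_promoter is not asserted
  expect_true(all(m[true_state == "off",
                    !paused & !elongating & !terminating &
                      n_polII == 0L & burst_class == "none"]))
  expect_true(all(m[true_state == "poised", paused & !elongating]))
  expect_true(all(m[true_state == "elongating", elongating]))
  expect_true(all(m[true_state == "hyperburst", burst_class == "active"]))
  expect_true(all(m[true_state == "refractory",
                    burst_class == "refractory" & accessible_promoter]))
  expect_true(all(m[true_state == "terminating", terminating]))
})

test_that("simulate_proseq counts planted Pol II coverage exactly", {
  genome <- list(reference = c(chrX = strrep("ACGT", 100)))
  fp <- data.table(fiber_id = c("a", "b", "c", "d"), chrom = "chrX",
                   start = c(100L, 120L, 130L, 10L),
                   end = c(150L, 170L, 180L, 60L),
                   class = c("polII", "polII", "polII", "nucleosome"))
  tr <- simulate_proseq(genome, fp)
  expect_equal(tr$chrX[135], 3)   # position 134 (0-based) under 3 footprints
  expect_equal(tr$chrX[105], 1)
  expect_equal(tr$chrX[30], 0)    # nucleosome does not contribute
  expect_equal(sum(tr$chrX), sum((fp$end - fp$start)[fp$class == "polII"]))
  none <- simulate_proseq(genome, fp[class == "nucleosome"])
  expect_true(all(none$chrX == 0))
})

test_that("simulate_fluorescence honors the mixture contract", {
  expect_error(simulate_fluorescence(sd = 0), "sd")
  expect_error(simulate_fluorescence(mu_off = 5, mu_on = 1), "mu_on")
  off_only <- simulate_fluorescence(n_cells = 10L, n_timepoints = 20L,
                                    active_fraction = 0, mu_off = 0,
                                    mu_on = 10, sd = 1, seed = 3L)
  expect_true(all(off_only$truth_active == 0L))
  expect_lt(max(abs(off_only$value)), 6)
  a <- simulate_fluorescence(n_cells = 5L, n_timepoints = 7L, seed = 11L)
  b <- simulate_fluorescence(n_cells = 5L, n_timepoints = 7L, seed = 11L)
  expect_identical(a, b)
})
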