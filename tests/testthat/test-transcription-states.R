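# Convoy detection (with brute-force closure oracle), state flags, burst
# classes, kinetics, the fluorescence GMM, and decile concordance.

test_that("convoy chaining follows the 100 bp edge-to-edge rule", {
  body <- c(0L, 5000L)
  two <- data.table(start = c(0L, 140L), end = c(50L, 190L))   # gap 90
  cv <- detect_convoys(two, body)
  expect_length(cv, 1L)
  expect_equal(cv[[1]]$size, 2L)
  expect_equal(cv[[1]]$center_spacings, 140)
  # boundary: gap exactly 100 chains, 101 splits
  expect_length(detect_convoys(data.table(start = c(0L, 150L),
                                          end = c(50L, 200L)), body), 1L)
  expect_length(detect_convoys(data.table(start = c(0L, 151L),
                                          end = c(50L, 201L)), body), 0L)
  # 14 footprints of 50 bp with 10 bp gaps form one convoy of 14
  s <- seq(0L, by = 60L, length.out = 14L)
  cv14 <- detect_convoys(data.table(start = s, end = s + 50L), body)
  expect_length(cv14, 1L)
  expect_equal(cv14[[1]]$size, 14L)
  # singletons are not convoys
  expect_length(detect_convoys(data.table(start = 0L, end = 50L), body), 0L)
})

test_that("convoy chaining equals the transitive-closure oracle", {
  set.seed(88)
  for (trial in 1:200) {
    n <- sample(0:12, 1)
    starts <- sort(sample.int(3000L, n))
    widths <- sample(40:60, n, replace = TRUE)
    ends <- starts + widths
    # drop overlapping intervals (footprints on one fiber are disjoint)
    keep <- c(TRUE, tail(starts, -1) >= head(ends, -1))[seq_len(n)]
    starts <- starts[keep]; ends <- ends[keep]
    got <- detect_convoys(data.table(start = starts, end = ends),
                          c(0L, 4000L))
    want <- convoy_closure_oracle(starts, ends)
    expect_equal(length(got), length(want))
    got_sets <- lapply(got, function(cv) sort(cv$members$start))
    want_sets <- lapply(want, function(g) sort(starts[g]))
    expect_setequal(lapply(got_sets, paste, collapse = ","),
                    lapply(want_sets, paste, collapse = ","))
  }
})

test_that("planted center-to-center spacing is recovered from convoys", {
  ds <- fx(key = "ds_spacing", {
    simulate_dataset(sim_config(
      n_genes = 1L, n_fibers_per_gene = 150L,
      p_state = c(off = 0, poised = 0, elongating = 1, hyperburst = 0,
                  refractory = 0, terminating = 0),
      convoy_size_range = c(4L, 6L), seed = 303L))
  })
  gene <- ds$genes[1]
  body <- gene_windows(gene)$body
  planted <- ds$truth_footprints[class == "polII"]
  spacings <- c()
  for (fid in unique(planted$fiber_id)) {
    cv <- detect_convoys(planted[fiber_id == fid], body)
    spacings <- c(spacings, unlist(lapply(cv, `[[`, "center_spacings")))
  }
  expect_gt(length(spacings), 400)
  # planted sizes 41..60 (mean 50.5) + gaps 5..15 (mean 10) = 60.5 expected
  expect_lt(abs(mean(spacings) - 60.5), 2)
})

mk_state_fixture <- function(footprints, fiber_span = c(0L, 15000L),
                             gene = NULL) {
  if (is.null(gene))
    gene <- data.table(gene_id = "g", chrom = "c", start = 11000L,
                       end = 13000L, strand = "+", tss = 11000L)
  fiber <- data.table(fiber_id = "f1", chrom = "c", start = fiber_span[1],
                      end = fiber_span[2], gene_id = "g", strand = "+")
  fp <- copy(footprints)[, `:=`(fiber_id = "f1", chrom = "c")]
  acc <- accessible_regions(fiber[1], fp)
  list(fiber = fiber, gene = gene, fp = fp, acc = acc)
}

test_that("state flags follow the quoted definitions", {
  # accessible promoter: >= 100 bp accessible around TSS, no Pol II in gene
  fx1 <- mk_state_fixture(data.table(
    start = c(10000L, 11200L), end = c(10850L, 11500L),
    class = "nucleosome"))
  s1 <- assign_state(fx1$fiber[1], fx1$gene, fx1$fp, fx1$acc)
  expect_true(s1$accessible_promoter)
  expect_false(s1$paused)

  # paused: one 50 bp footprint just downstream of the TSS, nothing else
  fx2 <- mk_state_fixture(data.table(
    start = 11010L, end = 11060L, class = "polII"))
  s2 <- assign_state(fx2$fiber[1], fx2$gene, fx2$fp, fx2$acc)
  expect_true(s2$paused)
  expect_false(s2$elongating)
  expect_false(s2$accessible_promoter)  # the Pol II overlaps the gene

  # elongating: Pol II mid-body
  fx3 <- mk_state_fixture(data.table(
    start = 12000L, end = 12050L, class = "polII"))
  s3 <- assign_state(fx3$fiber[1], fx3$gene, fx3$fp, fx3$acc)
  expect_true(s3$elongating)
  expect_false(s3$paused)

  # hyperburst flag: body >= 50% accessible (no nucleosomes at all here)
  expect_true(s3$hyperburst)
  fx4 <- mk_state_fixture(data.table(
    start = seq(11000L, 12800L, by = 180L),
    end = seq(11000L, 12800L, by = 180L) + 147L, class = "nucleosome"))
  s4 <- assign_state(fx4$fiber[1], fx4$gene, fx4$fp, fx4$acc)
  expect_false(s4$hyperburst)

  # terminating: Pol II within 500 bp after the gene end
  fx5 <- mk_state_fixture(data.table(
    start = 13100L, end = 13150L, class = "polII"))
  s5 <- assign_state(fx5$fiber[1], fx5$gene, fx5$fp, fx5$acc)
  expect_true(s5$terminating)
  expect_false(s5$elongating)

  # fiber not spanning the termination window: flag undefined
  fx6 <- mk_state_fixture(data.table(start = 12000L, end = 12050L,
                                     class = "polII"),
                          fiber_span = c(0L, 13200L))
  s6 <- assign_state(fx6$fiber[1], fx6$gene, fx6$fp, fx6$acc)
  expect_true(is.na(s6$terminating))
})

test_that("burst classes follow eviction and convoy criteria", {
  call <- function(ev, nconv) data.table(
    fiber_id = "f", nucleosome_eviction_fraction = ev, n_convoys = nconv)
  expect_equal(classify_burst(call(0.7, 2L)), "active")
  expect_equal(classify_burst(call(0.7, 0L)), "refractory")
  expect_equal(classify_burst(call(0.3, 5L)), "none")
  expect_equal(classify_burst(call(0.5, 1L)), "active")  # boundary inclusive
})

test_that("active/refractory/none partition all fibers exactly", {
  cl <- fx_classified_degenerate()
  ds <- cl$ds
  calls <- assign_states(ds$fibers, ds$genes[1], cl$classified, cl$access)
  expect_equal(nrow(calls), nrow(ds$fibers))
  expect_true(all(calls$burst_class %in% c("active", "refractory", "none")))
  expect_equal(sum(calls$burst_class == "active") +
                 sum(calls$burst_class == "refractory") +
                 sum(calls$burst_class == "none"), nrow(ds$fibers))
  expect_true(all(calls[burst_class == "refractory", n_convoys] == 0L))
  expect_true(all(calls[burst_class == "active", n_convoys] >= 1L))
})

test_that("kinetics computes on-rate and amplitude with stable bootstrap", {
  gene <- data.table(gene_id = "g", chrom = "c", start = 11000L,
                     end = 13000L, strand = "+", tss = 11000L)
  sc <- data.table(fiber_id = paste0("f", 1:10), gene_id = "g",
                   n_convoys = c(1L, 2L, rep(0L, 8L)),
                   n_polII = c(0L, 0L, 4L, rep(0L, 7L)),
                   nucleosome_eviction_fraction = runif(10))
  k <- kinetics(gene, sc, data.table(fiber_id = character(),
                                     chrom = character(), start = integer(),
                                     end = integer(), class = character()),
                n_boot = 100L, seed = 9L)
  expect_equal(k$summary$on_rate, 0.2)
  expect_equal(k$summary$amplitude, 0.4)  # mean of {0,0,4,0,...}
  # amplitude for counts {0,0,4} is 4/3
  k2 <- kinetics(gene, sc[1:3][, n_convoys := 0L][, n_polII := c(0L, 0L, 4L)],
                 data.table(fiber_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            class = character()),
                 n_boot = 100L, seed = 9L)
  expect_equal(k2$summary$amplitude, 4 / 3)
  # on-rate is invariant under fiber reordering
  empty_fp <- data.table(fiber_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         class = character())
  k3 <- kinetics(gene, sc[sample.int(10)], empty_fp, n_boot = 100L, seed = 9L)
  expect_equal(k3$summary$on_rate, k$summary$on_rate)
  expect_equal(k3$summary$amplitude, k$summary$amplitude)
  # identical input + seed reproduces the bootstrap CI exactly
  k4 <- kinetics(gene, sc, empty_fp, n_boot = 100L, seed = 9L)
  expect_equal(k4$summary$on_rate_lo, k$summary$on_rate_lo)
  expect_equal(k4$summary$on_rate_hi, k$summary$on_rate_hi)
})

test_that("gmm_on_rate recovers a planted active fraction", {
  tr <- simulate_fluorescence(n_cells = 200L, n_timepoints = 50L,
                              active_fraction = 0.16, mu_off = 0, mu_on = 10,
                              sd = 1, seed = 21L)
  fit <- gmm_on_rate(tr)
  expect_lt(abs(fit$active_fraction - mean(tr$truth_active)), 0.01)
  expect_gt(fit$threshold, 2)
  expect_lt(fit$threshold, 9)
  expect_error(gmm_on_rate(rep(1, 100)), "distinct")
  expect_error(gmm_on_rate(c(rep(0, 500), rep(1e-12, 500))), "collapse")
})

test_that("decile concordance bins genes by stable rank", {
  sig <- 1:20
  occ <- sig + 0.5
  d <- decile_concordance(sig, occ)
  expect_equal(nrow(d), 10L)
  expect_equal(d$n, rep(2L, 10L))
  expect_true(all(diff(d$mean_occupancy) > 0))
  # constant signal: stable order, equal bin sizes
  d2 <- decile_concordance(rep(1, 30), 1:30)
  expect_equal(d2$mean_occupancy, vapply(split(1:30, rep(1:10, each = 3)),
                                         mean, numeric(1)),
               ignore_attr = TRUE)
  expect_error(decile_concordance(1:5, 1:5), "at least")
})

test_that("correlated signal and occupancy give concordant deciles", {
  set.seed(12)
  n <- 200
  sig <- rnorm(n)
  occ <- 0.9 * sig + sqrt(1 - 0.81) * rnorm(n)
  d <- decile_concordance(sig, occ)
  expect_gt(cor(d$mean_signal, d$mean_occupancy, method = "spearman"), 0.8)
})
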