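# HMM module: emission table construction, Viterbi decoding against the
# exhaustive-enumeration oracle, posterior normalization, and Baum-Welch
# training recovery.

test_that("build_emission_table computes smoothed frequencies", {
  acc <- data.frame(context = "AAATAAA", methylated = 90, total = 100)
  inacc <- data.frame(context = "AAATAAA", methylated = 5, total = 100)
  tab <- build_emission_table(acc, inacc, pseudocount = 0)
  expect_equal(unname(tab$p_acc["AAATAAA"]), 0.9)
  expect_equal(unname(tab$p_inacc["AAATAAA"]), 0.05)
  # smoothing limit: 0/0 counts with pseudocount 1 -> 1/2
  tab2 <- build_emission_table(
    data.frame(context = "CCCACCC", methylated = 0, total = 0),
    data.frame(context = "CCCACCC", methylated = 0, total = 0),
    pseudocount = 1)
  expect_equal(unname(tab2$p_acc["CCCACCC"]), 0.5)
  expect_error(build_emission_table(data.frame(), inacc), "empty control")
})

test_that("emission table matches a counting oracle on mixed contexts", {
  set.seed(14)
  ctx <- unique(replicate(10, paste(sample(c("A", "C", "G", "T"), 7,
                                           replace = TRUE), collapse = "")))
  tot <- sample(20:200, length(ctx))
  met <- vapply(tot, function(t) sample.int(t, 1), integer(1))
  pc <- 1.0
  tab <- build_emission_table(
    data.frame(context = ctx, methylated = met, total = tot),
    data.frame(context = ctx, methylated = tot - met, total = tot),
    pseudocount = pc)
  expect_equal(unname(tab$p_acc[ctx]), (met + pc) / (tot + 2 * pc))
  expect_equal(unname(tab$p_inacc[ctx]), (tot - met + pc) / (tot + 2 * pc))
})

test_that("7-mer fallback hierarchy resolves unseen contexts", {
  acc <- data.frame(context = c("AAATAAA", "CCCACCC"),
                    methylated = c(90, 50), total = c(100, 100))
  inacc <- data.frame(context = c("AAATAAA", "CCCACCC"),
                      methylated = c(5, 5), total = c(100, 100))
  tab <- build_emission_table(acc, inacc, pseudocount = 0)
  r <- emission_rates(tab, contexts = c("AAATAAA", "GGGTGGG", NA),
                      centers = c("T", "T", "A"))
  expect_equal(r$p_acc[1], 0.9)
  expect_equal(r$p_acc[2], 0.9)  # center-base fallback: only T-centered seen
  expect_equal(r$n_fallback, 2L)
})

test_that("Viterbi equals exhaustive path enumeration (oracle)", {
  set.seed(31)
  for (trial in 1:60) {
    L <- sample(2:10, 1)
    par <- random_hmm_params()
    emis <- random_emissions(L)
    fast <- hmm_viterbi_cpp(emis, par$log_pi, par$log_T)
    slow <- viterbi_enumerate(emis, par$log_pi, par$log_T)
    score <- function(path) {
      lp <- par$log_pi[path[1] + 1] + emis[1, path[1] + 1]
      if (L > 1) for (t in 2:L)
        lp <- lp + par$log_T[path[t - 1] + 1, path[t] + 1] + emis[t, path[t] + 1]
      lp
    }
    expect_equal(score(fast), slow$logprob, tolerance = 1e-10)
  }
})

test_that("degenerate emissions reproduce the mask's runs exactly", {
  ref <- c(chr1 = strrep("AT", 50))   # every position informative
  mask <- rep(c(TRUE, FALSE, TRUE), c(30, 40, 30))  # accessible/footprint/acc
  meth <- which(mask) - 1L
  fiber <- data.table(fiber_id = "f1", chrom = "chr1", start = 0L, end = 100L,
                      strand = "+", meth = list(as.integer(meth)))
  params <- hmm_params(emissions = flat_emission_table(1, 0))
  seg <- decode_fiber(fiber[1], ref, params)
  expect_equal(seg$state, c("accessible", "inaccessible", "accessible"))
  expect_equal(seg$start, c(0L, 30L, 70L))
  expect_equal(seg$end, c(30L, 70L, 100L))
  fp <- footprints_from_path(seg)
  expect_equal(nrow(fp$footprints), 1L)
  expect_equal(fp$footprints$start, 30L)
  expect_equal(fp$footprints$end, 70L)
})

test_that("dominant emissions give a single accessible segment", {
  ref <- c(chr1 = strrep("A", 200))
  fiber <- data.table(fiber_id = "f1", chrom = "chr1", start = 0L, end = 200L,
                      strand = "+", meth = list(0:199))
  params <- hmm_params(trans = matrix(c(.99, .01, .01, .99), 2, byrow = TRUE),
                       emissions = flat_emission_table(0.9, 0.01))
  seg <- decode_fiber(fiber[1], ref, params)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$state, "accessible")
})

test_that("fibers with no informative position fall back to the prior", {
  ref <- c(chr1 = strrep("GC", 50))
  fiber <- data.table(fiber_id = "f1", chrom = "chr1", start = 0L, end = 100L,
                      strand = "+", meth = list(integer(0)))
  params <- hmm_params(start = c(0.9, 0.1))
  seg <- decode_fiber(fiber[1], ref, params)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$state, "accessible")
  expect_true(attr(seg, "no_informative_positions"))
})

test_that("footprints_from_path splits runs correctly", {
  seg <- data.table(fiber_id = "f", chrom = "c", strand = "+",
                    start = c(0L, 3L, 6L), end = c(3L, 6L, 7L),
                    state = c("accessible", "inaccessible", "accessible"))
  fp <- footprints_from_path(seg)
  expect_equal(fp$footprints$start, 3L)
  expect_equal(fp$footprints$end, 6L)
  all_acc <- seg[state == "accessible"]
  expect_equal(nrow(footprints_from_path(all_acc)$footprints), 0L)
})

test_that("forward-backward posteriors are normalized", {
  set.seed(77)
  for (trial in 1:20) {
    L <- sample(5:200, 1)
    par <- random_hmm_params()
    emis <- random_emissions(L)
    fb <- hmm_forward_backward_cpp(emis, par$log_pi, par$log_T)
    expect_lt(max(abs(rowSums(fb$gamma) - 1)), 1e-9)
  }
})

test_that("training recovers transitions from observable-state fibers", {
  # degenerate emissions make the hidden state observable, so EM should
  # land on the empirical transition frequencies of the generating chain
  set.seed(55)
  T_true <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  ref <- c(chr1 = strrep("AT", 300))
  fibers <- rbindlist(lapply(1:200, function(i) {
    s <- integer(600); s[1] <- rbinom(1, 1, 0.5)
    for (t in 2:600) s[t] <- rbinom(1, 1, T_true[s[t - 1] + 1, 2])
    meth <- which(s == 0L) - 1L   # state 0 = accessible = methylated
    data.table(fiber_id = paste0("f", i), chrom = "chr1", start = 0L,
               end = 600L, strand = "+", meth = list(as.integer(meth)))
  }))
  em <- flat_emission_table(1 - 1e-9, 1e-9)
  fit <- train_hmm(fibers, ref, em, n_restarts = 2L, seed = 4L,
                   max_iter = 30L)
  expect_lt(max(abs(fit$trans - T_true)), 0.02)
  # log-likelihood non-decreasing across EM iterations
  trace <- attr(fit, "loglik_trace")
  expect_true(all(diff(trace) > -1e-6))
  # fixed seed reproduces the fit exactly
  fit2 <- train_hmm(fibers, ref, em, n_restarts = 2L, seed = 4L,
                    max_iter = 30L)
  expect_equal(fit$trans, fit2$trans)
  expect_equal(fit$start, fit2$start)
})

test_that("training on an all-methylated fiber favors accessible runs", {
  ref <- c(chr1 = strrep("A", 300))
  fibers <- data.table(fiber_id = "f1", chrom = "chr1", start = 0L,
                       end = 300L, strand = "+", meth = list(0:299))
  em <- flat_emission_table(0.9, 0.05)
  fit <- suppressWarnings(train_hmm(fibers, ref, em, n_restarts = 3L,
                                    seed = 2L, max_iter = 50L))
  expect_gt(fit$trans["accessible", "accessible"], 0.9)
})
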