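# Regression module: AUC oracle equivalence, separable/null behavior,
# dropout delta-AUC, synergy algebra and the constructed OR-gate
# cooperativity case.

test_that("rank-based AUC equals the pairwise-counting oracle", {
  set.seed(17)
  for (trial in 1:25) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(roc_auc(s, y), auc_pair_oracle(s, y), tolerance = 1e-9)
  }
})

test_that("average precision matches a direct computation", {
  s <- c(0.9, 0.8, 0.7, 0.6)
  y <- c(1, 0, 1, 0)
  # precision at the two positives: 1/1 and 2/3
  expect_equal(average_precision(s, y), mean(c(1, 2 / 3)))
})

test_that("stratified folds keep both classes in every fold", {
  set.seed(3)
  y <- rep(c(0L, 1L), c(40, 12))
  f <- stratified_folds(y, 5L)
  expect_equal(attr(f, "K"), 5L)
  for (k in 1:5) expect_equal(sort(unique(y[f == k])), c(0L, 1L))
  expect_error(stratified_folds(rep(c(0L, 1L), c(50, 1)), 5L), "at least 2")
})

test_that("a perfectly separating feature yields OOF AUC 1", {
  set.seed(5)
  n <- 200
  x1 <- rbinom(n, 1, 0.5)
  X <- cbind(cre1 = x1, cre2 = rbinom(n, 1, 0.5))
  fe <- fit_and_evaluate(X, x1, K = 5L, n_permutations = 10L, seed = 2L)
  expect_equal(fe$eval$auc, 1.0)
  expect_gt(fe$model$coefficients["cre1"], 0)
})

test_that("label-independent features give chance-level AUC", {
  set.seed(6)
  n <- 500
  X <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.5)
  fe <- fit_and_evaluate(X, y, K = 5L, n_permutations = 20L, seed = 3L)
  expect_gt(fe$eval$auc, 0.4)
  expect_lt(fe$eval$auc, 0.6)
  expect_lt(abs(fe$eval$delta_auc), 3 * max(sd(fe$eval$null_aucs), 0.02))
})

test_that("evaluation is deterministic under a fixed seed", {
  set.seed(9)
  n <- 120
  X <- cbind(a = rbinom(n, 1, 0.4), b = rbinom(n, 1, 0.6))
  y <- as.integer(runif(n) < 0.3 + 0.4 * X[, "a"])
  a <- fit_and_evaluate(X, y, K = 4L, n_permutations = 8L, seed = 77L)
  b <- fit_and_evaluate(X, y, K = 4L, n_permutations = 8L, seed = 77L)
  expect_identical(a$eval$auc, b$eval$auc)
  expect_identical(a$eval$null_aucs, b$eval$null_aucs)
})

test_that("dropout isolates the informative feature", {
  set.seed(11)
  n <- 400
  x1 <- rbinom(n, 1, 0.5)
  X <- cbind(sig = x1, n1 = rbinom(n, 1, 0.5), n2 = rbinom(n, 1, 0.5))
  fe <- fit_and_evaluate(X, x1, K = 5L, n_permutations = 0L, seed = 4L)
  dr <- dropout_analysis(X, x1, fe$eval$fold, fe$eval$auc)
  expect_gt(dr["sig"], 0.4)       # ~ AUC 1.0 -> ~0.5 without the feature
  expect_lt(abs(dr["n1"]), 0.1)
  expect_lt(abs(dr["n2"]), 0.1)
})

test_that("duplicated predictors make singleton dropouts redundant", {
  set.seed(13)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  X <- cbind(d1 = y, d2 = y, noise = rbinom(n, 1, 0.5))
  fe <- fit_and_evaluate(X, y, K = 5L, n_permutations = 0L, seed = 5L)
  dr <- dropout_analysis(X, y, fe$eval$fold, fe$eval$auc)
  expect_lt(abs(dr["d1"]), 0.05)
  expect_lt(abs(dr["d2"]), 0.05)
})

test_that("single-feature models drop to the empty-model convention", {
  set.seed(15)
  n <- 100
  x <- rbinom(n, 1, 0.5)
  X <- cbind(only = x)
  fe <- fit_and_evaluate(X, x, K = 5L, n_permutations = 0L, seed = 6L)
  dr <- dropout_analysis(X, x, fe$eval$fold, fe$eval$auc)
  expect_equal(unname(dr["only"]), fe$eval$auc - 0.5)
})

test_that("synergy algebra: singleton synergy is exactly zero", {
  set.seed(19)
  n <- 200
  X <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5))
  y <- as.integer(runif(n) < 0.2 + 0.5 * X[, "a"])
  fe <- fit_and_evaluate(X, y, K = 5L, n_permutations = 0L, seed = 7L)
  dr <- dropout_analysis(X, y, fe$eval$fold, fe$eval$auc)
  s <- synergy(X, y, "a", dr, fe$eval$fold, fe$eval$auc)
  expect_identical(s$synergy, 0)
  expect_error(synergy(X, y, c("a", "zzz"), dr, fe$eval$fold, fe$eval$auc),
               "absent")
})

test_that("an OR-gate pair shows negative (cooperative) synergy", {
  set.seed(23)
  n <- 1000
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  y <- as.integer(x1 | x2)
  X <- cbind(x1 = x1, x2 = x2, noise = rbinom(n, 1, 0.5))
  fe <- fit_and_evaluate(X, y, K = 5L, n_permutations = 0L, seed = 8L)
  dr <- dropout_analysis(X, y, fe$eval$fold, fe$eval$auc)
  s <- synergy(X, y, c("x1", "x2"), dr, fe$eval$fold, fe$eval$auc)
  expect_lt(s$synergy, 0)
  # additive case: pairing the signal with noise is approximately inert
  y1 <- x1
  fe1 <- fit_and_evaluate(X, y1, K = 5L, n_permutations = 0L, seed = 9L)
  dr1 <- dropout_analysis(X, y1, fe1$eval$fold, fe1$eval$auc)
  s1 <- synergy(X, y1, c("x1", "noise"), dr1, fe1$eval$fold, fe1$eval$auc)
  expect_lt(abs(s1$synergy), 0.06)
})

test_that("coefficient signs track a planted logistic model", {
  set.seed(29)
  n <- 2000
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  eta <- -1.5 + 2.5 * x1 - 1.5 * x2
  y <- as.integer(runif(n) < 1 / (1 + exp(-eta)))
  X <- cbind(up = x1, down = x2, noise = rbinom(n, 1, 0.5))
  fe <- fit_and_evaluate(X, y, K = 5L, n_permutations = 0L, seed = 10L)
  co <- fe$model$coefficients
  expect_gt(co["up"], 0)
  expect_lt(co["down"], 0)
  expect_gt(abs(co["up"]), abs(co["noise"]))
})

test_that("build_feature_matrix restricts to the 9 kb window and drops NAs", {
  gene <- data.table(gene_id = "g", chrom = "c", start = 20000L,
                     end = 22000L, strand = "+", tss = 20000L)
  peaks <- data.table(start = c(10500L, 12000L, 19000L),
                      end = c(10700L, 12200L, 19200L),
                      label = c("far", "U2", "U1"))
  M <- matrix(c(1L, 0L, 1L,
                0L, 1L, NA,
                1L, 1L, 0L), 3, 3, byrow = TRUE,
              dimnames = list(paste0("f", 1:3),
                              c("far", "U2", "U1")))
  sc <- data.table(fiber_id = paste0("f", 1:3),
                   accessible_promoter = c(TRUE, TRUE, FALSE),
                   paused = c(NA, NA, NA), elongating = c(TRUE, TRUE, FALSE),
                   hyperburst = c(FALSE, FALSE, FALSE),
                   terminating = c(TRUE, FALSE, NA))
  fm <- build_feature_matrix(sc, M, peaks, gene)
  # the 10.5 kb peak is outside the 9 kb window: 2 features remain
  expect_equal(colnames(fm$X), c("U2", "U1"))
  expect_true("hyperburst" %in% fm$skipped)   # single class
  expect_true("paused" %in% fm$skipped)       # all NA
  # f2 carries an NA feature and is dropped row-wise
  expect_equal(fm$responses$accessible_promoter$y, c(1L, 0L))
  expect_equal(unname(fm$responses$accessible_promoter$rows), c(1L, 3L))
})
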