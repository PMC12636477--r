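# Per-gene, per-state modeling of fiber transcription state from CRE
# accessibility: L1-penalized logistic regression (glmnet backend,
# lambda = 1/(C*n) with C = 1.0, inverse-frequency balanced class weights,
# iteration cap 500), stratified K-fold cross-validation with pooled
# out-of-fold predictions, a 50-shuffle permutation null for delta-AUC,
# per-feature dropout delta-AUC, and subset-removal synergy. Fold
# assignments are computed once per gene x state and reused across the
# full, dropout, and subset models so that delta-AUC isolates feature
# removal rather than fold noise.

#' Area under the ROC curve from scores and binary labels
#'
#' Rank-statistic (Mann-Whitney) form with midrank tie handling.
#'
#' @param scores numeric prediction scores
#' @param labels 0/1 (or logical) labels
#' @return AUC in [0, 1]; NA if one class is absent
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (area under the precision-recall curve, step form)
#'
#' @inheritParams roc_auc
#' @return AP in [0, 1]; NA if no positives
#' @export
average_precision <- function(scores, labels) {
  y <- as.integer(labels)[order(-scores)]
  n1 <- sum(y == 1L)
  if (n1 == 0L) return(NA_real_)
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y == 1L]) / n1
}

#' Stratified K-fold assignments
#'
#' Shuffles within each class and deals rows round-robin into folds, so
#' every fold holds both classes whenever the minority class has at least K
#' members. K is lowered to the largest feasible value when it does not.
#'
#' @param y 0/1 labels
#' @param K requested fold count
#' @return integer fold vector (1..K used), with attribute `K`
#' @export
stratified_folds <- function(y, K = 5L) {
  y <- as.integer(y)
  K <- min(K, min(table(y)))
  if (K < 2L) stop("need at least 2 members of each class for cross-validation")
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(K), length(idx))
  }
  structure(fold, K = K)
}

# L1 logistic fit with balanced class weights; returns a predict closure.
# A lone feature is padded with a zero column (glmnet needs >= 2 columns);
# an empty feature set yields the 0.5-probability null model.
#' @keywords internal
fit_l1_logistic <- function(X, y, C = 1.0, max_iter = 500L, tol = 1e-4) {
  y <- as.integer(y)
  if (is.null(dim(X)) || ncol(X) == 0L) {
    return(list(predict = function(newX) rep(0.5, nrow(newX)),
                beta = numeric(0), intercept = 0, empty = TRUE))
  }
  n <- nrow(X)
  tab <- table(factor(y, levels = c(0L, 1L)))
  w <- n / (2 * as.numeric(tab[as.character(y)]))
  Xf <- X
  padded <- FALSE
  if (ncol(Xf) == 1L) { Xf <- cbind(Xf, 0); padded <- TRUE }
  # all-constant predictors (possible on tiny CV folds): intercept-only
  # model, all coefficients zero by the L1 limit
  if (all(apply(X, 2L, function(col) length(unique(col)) <= 1L))) {
    p <- sum(w * y) / sum(w)   # balanced weights make this 0.5
    return(list(predict = function(newX) rep(p, nrow(newX)),
                beta = rep(0, ncol(X)), intercept = stats::qlogis(p),
                empty = FALSE))
  }
  # glmnet warns about small class counts on every tiny CV fold; the fold
  # builder already guards degenerate splits, so silence that chatter
  fit <- suppressWarnings(
    glmnet::glmnet(Xf, y, family = "binomial", alpha = 1,
                   lambda = 1 / (C * n), weights = w,
                   standardize = FALSE, maxit = max_iter * 100L,
                   thresh = tol * 1e-3))
  beta <- as.numeric(fit$beta)
  if (padded) beta <- beta[1L]
  b0 <- as.numeric(fit$a0)
  list(predict = function(newX) {
    eta <- b0 + as.numeric(as.matrix(newX) %*% beta)
    1 / (1 + exp(-eta))
  }, beta = beta, intercept = b0, empty = FALSE)
}

# pooled out-of-fold probabilities for a fixed fold assignment
#' @keywords internal
cv_oof <- function(X, y, fold, C = 1.0) {
  oof <- rep(NA_real_, length(y))
  for (k in seq_len(attr(fold, "K") %||% max(fold))) {
    tr <- fold != k
    # degenerate training split (a class absent or singleton): skip fold
    if (length(unique(y[tr])) < 2L || min(table(y[tr])) < 2L) next
    m <- fit_l1_logistic(X[tr, , drop = FALSE], y[tr], C = C)
    oof[!tr] <- m$predict(X[!tr, , drop = FALSE])
  }
  oof
}

#' Build the per-gene feature matrix and response vectors
#'
#' Predictors are CRE accessibility indicators within the upstream
#' regression window; responses are the five transcription-state flags.
#' Rows with an undefined flag are dropped per response; responses with
#' fewer than two classes are skipped (logged via attribute).
#'
#' @param state_calls StateCall table for one gene
#' @param access_matrix fibers x CRE 0/1 matrix (rownames fiber_id) from
#'   [cre_access_matrix()]
#' @param peaks peak table matching the matrix columns
#' @param gene one-row gene
#' @param window_bp regression feature window upstream of the TSS (default
#'   9000)
#' @return list with `X` (matrix), `responses` (named list of data.frames
#'   with y and row index), `skipped` (character)
#' @export
build_feature_matrix <- function(state_calls, access_matrix, peaks, gene,
                                 window_bp = 9000L) {
  win <- gene_windows(gene, upstream_bp = window_bp)$upstream
  keep <- peaks$start < win[2] & peaks$end > win[1]
  X_all <- access_matrix[, keep, drop = FALSE]
  sc <- as.data.table(state_calls)
  idx <- match(sc$fiber_id, rownames(X_all))
  X_all <- X_all[idx, , drop = FALSE]
  flags <- c("accessible_promoter", "paused", "elongating", "hyperburst",
             "terminating")
  responses <- list(); skipped <- character()
  for (fl in flags) {
    yv <- sc[[fl]]
    ok <- !is.na(yv) & rowSums(is.na(X_all)) == 0L
    y <- as.integer(yv[ok])
    if (length(unique(y)) < 2L) { skipped <- c(skipped, fl); next }
    responses[[fl]] <- list(y = y, rows = which(ok))
  }
  list(X = X_all, responses = responses, skipped = skipped)
}

#' Fit and cross-validate one gene x state model
#'
#' @param X binary feature matrix (reads x CREs)
#' @param y 0/1 response
#' @param K requested folds (default 5; lowered if infeasible)
#' @param n_permutations label shuffles for the null (default 50)
#' @param seed RNG seed controlling fold shuffling and permutations
#' @param C inverse regularization strength (default 1.0)
#' @return list with `model` (coefficients from an all-rows fit) and `eval`
#'   (auc, ap, null_aucs, delta_auc, per-feature single AUCs, fold vector)
#' @export
fit_and_evaluate <- function(X, y, K = 5L, n_permutations = 50L, seed = 1L,
                             C = 1.0) {
  y <- as.integer(y)
  stopifnot(length(unique(y)) == 2L)
  set.seed(seed)
  fold <- stratified_folds(y, K)
  oof <- cv_oof(X, y, fold, C = C)
  auc <- roc_auc(oof, y)
  ap <- average_precision(oof, y)
  single <- vapply(seq_len(ncol(X)), function(j)
    roc_auc(cv_oof(X[, j, drop = FALSE], y, fold, C = C), y), numeric(1))
  names(single) <- colnames(X)
  null_aucs <- vapply(seq_len(n_permutations), function(p) {
    yp <- sample(y)
    fp <- stratified_folds(yp, K)  # re-stratified: folds depend on labels
    roc_auc(cv_oof(X, yp, fp, C = C), yp)
  }, numeric(1))
  full <- fit_l1_logistic(X, y, C = C)
  list(
    model = list(intercept = full$intercept,
                 coefficients = setNames(full$beta, colnames(X)),
                 C = C, class_weight = "balanced", max_iter = 500L,
                 seed = seed),
    eval = list(auc = auc, ap = ap, K = attr(fold, "K"), fold = fold,
                null_aucs = null_aucs,
                delta_auc = if (n_permutations > 0)
                  auc - mean(null_aucs) else NA_real_,
                single_feature_auc = single, oof = oof)
  )
}

#' Per-feature dropout delta-AUC
#'
#' Refits the cross-validated model without each feature in turn, reusing
#' the full model's fold assignments; `delta_auc_j = auc_full -
#' auc_dropout_j`. Removing the last feature leaves the empty model, whose
#' AUC is 0.5 by convention.
#'
#' @param X,y as in [fit_and_evaluate()]
#' @param fold fold assignment from the full model evaluation
#' @param auc_full full-model out-of-fold AUC
#' @param features columns to drop (default all)
#' @param C inverse regularization strength
#' @return named numeric vector of delta-AUC per dropped feature
#' @export
dropout_analysis <- function(X, y, fold, auc_full,
                             features = colnames(X), C = 1.0) {
  out <- vapply(features, function(j) {
    keep <- setdiff(colnames(X), j)
    auc_wo <- if (length(keep) == 0L) 0.5 else
      roc_auc(cv_oof(X[, keep, drop = FALSE], y, fold, C = C), y)
    auc_full - auc_wo
  }, numeric(1))
  setNames(out, features)
}

#' Synergy of a feature subset
#'
#' `Synergy(S) = sum_i delta_auc_i - delta_auc_S` where `delta_auc_S` is the
#' AUC drop after removing all of S at once (same folds throughout).
#' Negative values indicate cooperative (super-additive) contributions.
#'
#' @param X,y feature matrix and response
#' @param S character vector of feature names, |S| in 1..4
#' @param singleton_dropouts named delta-AUC vector from
#'   [dropout_analysis()] covering all of S
#' @param fold fold assignment shared with the full model
#' @param auc_full full-model out-of-fold AUC
#' @param n_permutations label shuffles for the synergy null (0 = skip)
#' @param C inverse regularization strength
#' @return list: subset, k, synergy, delta_auc_S, null_synergies
#' @export
synergy <- function(X, y, S, singleton_dropouts, fold, auc_full,
                    n_permutations = 0L, C = 1.0) {
  if (!all(S %in% colnames(X)))
    stop("subset S contains features absent from the model: ",
         paste(setdiff(S, colnames(X)), collapse = ", "))
  if (!all(S %in% names(singleton_dropouts)))
    stop("singleton dropout delta-AUCs missing for some of S")
  drop_S_auc <- function(Xm, yv, fv, full_auc) {
    keep <- setdiff(colnames(Xm), S)
    auc_wo <- if (length(keep) == 0L) 0.5 else
      roc_auc(cv_oof(Xm[, keep, drop = FALSE], yv, fv, C = C), yv)
    full_auc - auc_wo
  }
  delta_S <- drop_S_auc(X, y, fold, auc_full)
  syn <- sum(singleton_dropouts[S]) - delta_S
  null_syn <- numeric(0)
  if (n_permutations > 0L) {
    null_syn <- vapply(seq_len(n_permutations), function(p) {
      yp <- sample(as.integer(y))
      fp <- stratified_folds(yp, attr(fold, "K") %||% max(fold))
      full_p <- roc_auc(cv_oof(X, yp, fp, C = C), yp)
      singles_p <- vapply(S, function(j) {
        keep <- setdiff(colnames(X), j)
        auc_wo <- if (length(keep) == 0L) 0.5 else
          roc_auc(cv_oof(X[, keep, drop = FALSE], yp, fp, C = C), yp)
        full_p - auc_wo
      }, numeric(1))
      sum(singles_p) - drop_S_auc(X, yp, fp, full_p)
    }, numeric(1))
  }
  list(subset = S, k = length(S), synergy = syn, delta_auc_S = delta_S,
       null_synergies = null_syn)
}

#' Full regression analysis for one gene
#'
#' Runs [fit_and_evaluate()], [dropout_analysis()] and pairwise [synergy()]
#' for every state flag with two observed classes.
#'
#' @param state_calls StateCall table for the gene
#' @param access_matrix fibers x CRE matrix
#' @param peaks peak table
#' @param gene one-row gene
#' @param K,n_permutations,seed,C as in [fit_and_evaluate()]
#' @param synergy_k subset sizes for synergy (default 2)
#' @param window_bp regression window (default 9000)
#' @return list per state: model, eval, dropout, synergies
#' @export
regress_gene <- function(state_calls, access_matrix, peaks, gene, K = 5L,
                         n_permutations = 50L, seed = 1L, C = 1.0,
                         synergy_k = 2L, window_bp = 9000L) {
  fm <- build_feature_matrix(state_calls, access_matrix, peaks, gene,
                             window_bp = window_bp)
  out <- list()
  for (fl in names(fm$responses)) {
    resp <- fm$responses[[fl]]
    X <- fm$X[resp$rows, , drop = FALSE]
    if (min(table(resp$y)) < 2L) next
    fe <- fit_and_evaluate(X, resp$y, K = K, n_permutations = n_permutations,
                           seed = seed, C = C)
    dr <- dropout_analysis(X, resp$y, fe$eval$fold, fe$eval$auc, C = C)
    syns <- list()
    if (ncol(X) >= 2L && length(synergy_k) > 0L) {
      for (k in synergy_k) {
        if (k > ncol(X) || k < 2L) next
        subsets <- utils::combn(colnames(X), k, simplify = FALSE)
        for (S in subsets)
          syns[[paste(S, collapse = "+")]] <-
            synergy(X, resp$y, S, dr, fe$eval$fold, fe$eval$auc, C = C)
      }
    }
    out[[fl]] <- list(model = fe$model, eval = fe$eval, dropout = dr,
                      synergies = syns, skipped = fm$skipped)
  }
  out
}
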