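# Independent brute-force oracles and cached fixtures shared across test
# files. Oracles deliberately re-derive quantities by enumeration or naive
# counting, never by calling the code paths they check.

library(data.table)

# ---- fixture cache (built once per test run) --------------------------------

.fx_cache <- new.env(parent = emptyenv())

fx <- function(key, expr) {
  if (!exists(key, envir = .fx_cache)) assign(key, expr, envir = .fx_cache)
  get(key, envir = .fx_cache)
}

# small default-world dataset (stochastic rates)
fx_dataset <- function() fx("ds_default", {
  simulate_dataset(sim_config(n_genes = 1L, n_fibers_per_gene = 40L,
                              seed = 101L))
})

# degenerate-rate dataset: methylation equals the accessibility mask exactly
fx_dataset_degenerate <- function() fx("ds_degenerate", {
  simulate_dataset(sim_config(n_genes = 1L, n_fibers_per_gene = 40L,
                              meth_rate_accessible = 1,
                              meth_rate_inaccessible = 0, seed = 202L))
})

# decoded + classified view of the degenerate dataset
fx_classified_degenerate <- function() fx("cl_degenerate", {
  ds <- fx_dataset_degenerate()
  params <- hmm_params(emissions = ds$emissions)
  segs <- decode_fibers(ds$fibers, ds$reference, params)
  fp <- footprints_from_path(segs)
  cl <- classify_footprints(fp$footprints, ds$proseq, ds$tata, ds$tss_sites)
  list(ds = ds, segments = segs, footprints = fp, classified = cl,
       access = accessible_regions_all(ds$fibers, cl))
})

# ---- HMM oracle: exhaustive path enumeration --------------------------------

# enumerate all 2^L state paths; returns the max-probability path (0-based
# states, 1 = inaccessible) under log-space scoring
viterbi_enumerate <- function(emis_log, log_pi, log_T) {
  L <- nrow(emis_log)
  best <- NULL; best_lp <- -Inf
  for (mask in 0:(2^L - 1)) {
    path <- as.integer(intToBits(mask)[1:L])
    lp <- log_pi[path[1] + 1] + emis_log[1, path[1] + 1]
    if (L > 1) for (t in 2:L) {
      lp <- lp + log_T[path[t - 1] + 1, path[t] + 1] + emis_log[t, path[t] + 1]
    }
    if (lp > best_lp + 1e-12) { best_lp <- lp; best <- path }
  }
  list(path = best, logprob = best_lp)
}

# random strictly-positive HMM parameterization
random_hmm_params <- function() {
  pi0 <- runif(1, 0.05, 0.95)
  t11 <- runif(1, 0.05, 0.95); t22 <- runif(1, 0.05, 0.95)
  list(log_pi = log(c(pi0, 1 - pi0)),
       log_T = log(matrix(c(t11, 1 - t11, 1 - t22, t22), 2, 2, byrow = TRUE)))
}

# emission log-matrix for a random observation sequence
random_emissions <- function(L) {
  p_acc <- runif(1, 0.55, 0.95); p_inacc <- runif(1, 0.02, 0.45)
  obs <- runif(L) < 0.5
  emis <- cbind(ifelse(obs, log(p_acc), log1p(-p_acc)),
                ifelse(obs, log(p_inacc), log1p(-p_inacc)))
  # sprinkle uninformative positions
  uninf <- runif(L) < 0.2
  emis[uninf, ] <- 0
  emis
}

# ---- convoy oracle: transitive closure over pairwise gaps -------------------

convoy_closure_oracle <- function(starts, ends, max_gap = 100) {
  n <- length(starts)
  if (n == 0) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    gap <- max(starts[j] - ends[i], starts[i] - ends[j], 0)
    # overlap counts as gap 0
    if (max(starts[i], starts[j]) < min(ends[i], ends[j])) gap <- 0
    adj[i, j] <- gap <= max_gap
  }
  # transitive closure (Floyd-Warshall style)
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (adj[i, k] && adj[k, j]) adj[i, j] <- TRUE
  diag(adj) <- TRUE
  comp <- rep(0L, n); cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[adj[i, ] | adj[, i]] <- cid
      comp[i] <- cid
    }
  }
  groups <- split(seq_len(n), comp)
  Filter(function(g) length(g) >= 2, groups)
}

# ---- AUC oracle: O(n^2) pair counting ---------------------------------------

auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# ---- motif scan oracle: per-offset rescoring --------------------------------

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

scan_oracle <- function(sequence, pwms, threshold) {
  n <- nchar(sequence)
  best <- rep(-Inf, n)
  score_window <- function(sub, M) {
    ri <- match(strsplit(sub, "")[[1]], rownames(M))
    if (anyNA(ri)) return(-Inf)
    sum(M[cbind(ri, seq_along(ri))])
  }
  for (M in pwms) {
    w <- ncol(M)
    if (n < w) next
    for (i in seq_len(n - w + 1)) {
      sub <- substr(sequence, i, i + w - 1)
      sc <- max(score_window(sub, M), score_window(revcomp_chr(sub), M))
      if (sc > best[i]) best[i] <- sc
    }
  }
  which(is.finite(best) & best >= threshold)
}

# ---- trajectory oracle via igraph simple paths ------------------------------

routes_oracle <- function(nodes, initial, peak, terminals,
                          require_peak = TRUE) {
  skip_if_not_installed("igraph")
  combos <- nodes$combo
  n <- length(combos)
  hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  edges <- c()
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (hd(combos[i], combos[j]) == 1) edges <- c(edges, i, j)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  out <- list()
  for (term in intersect(terminals, combos)) {
    ps <- igraph::all_simple_paths(g, from = match(initial, combos),
                                   to = match(term, combos))
    for (p in ps) {
      route <- combos[as.integer(p)]
      # terminals absorbing: no terminal may appear before the end
      if (any(route[-length(route)] %in% terminals)) next
      if (require_peak && !peak %in% route) next
      out[[length(out) + 1L]] <- route
    }
  }
  out
}
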