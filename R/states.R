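# Per-fiber transcription-state calling: Pol II convoy detection, the five
# regression state flags, hyperburst/active/refractory burst classes, and
# burst-kinetics summaries (on-rate, amplitude, flank occupancy).

#' Detect Pol II convoys on one fiber
#'
#' Convoys are groups of two or more Pol II footprints within the gene body
#' whose consecutive members are separated by at most `max_gap` bp. Gaps are
#' measured edge-to-edge by default; center-to-center mode is available.
#' Singletons are not convoys.
#'
#' @param polII data.table of Pol II-class footprints on one fiber
#'   (start, end)
#' @param gene_body `c(start, end)` of the gene body
#' @param max_gap chaining threshold in bp (default 100)
#' @param gap_mode "edge" (default) or "center"
#' @return list of convoys; each is a list with `members` (data.table),
#'   `size`, `span`, `center_spacings`
#' @export
detect_convoys <- function(polII, gene_body, max_gap = 100L,
                           gap_mode = c("edge", "center")) {
  gap_mode <- match.arg(gap_mode)
  m <- as.data.table(polII)[start < gene_body[2] & end > gene_body[1]]
  if (nrow(m) < 2L) return(list())
  m <- m[order(start)]
  gaps <- if (gap_mode == "edge") {
    tail(m$start, -1L) - head(m$end, -1L)
  } else {
    (tail(m$start, -1L) + tail(m$end, -1L)) / 2 -
      (head(m$start, -1L) + head(m$end, -1L)) / 2
  }
  grp <- cumsum(c(0L, as.integer(gaps > max_gap)))
  out <- list()
  for (g in unique(grp)) {
    mem <- m[grp == g]
    if (nrow(mem) < 2L) next
    centers <- (mem$start + mem$end) / 2
    out[[length(out) + 1L]] <- list(
      members = mem, size = nrow(mem),
      span = max(mem$end) - min(mem$start),
      center_spacings = diff(centers))
  }
  out
}

#' Assign per-fiber transcription-state flags
#'
#' Five flags are evaluated independently:
#' \itemize{
#' \item accessible_promoter: at least 100 bp of accessibility within the
#'   promoter window (TSS +/- 100 bp), with no Pol II footprint overlapping
#'   the gene body
#' \item paused: footprints overlapping the first 50 bp downstream of the
#'   TSS have mean size 40-60 bp, with no Pol II footprints elsewhere
#' \item elongating: at least one Pol II footprint in the gene body beyond
#'   the pause window
#' \item hyperburst: at least 50 percent of the gene body covered by
#'   accessible regions
#' \item terminating: at least one Pol II footprint in the 500 bp past the
#'   annotated gene end
#' }
#' Flags over windows the fiber does not fully span are NA (excluded from
#' downstream denominators).
#'
#' @param fiber one-row fiber
#' @param gene one-row gene (with tss, strand)
#' @param classified classified footprints for this fiber
#' @param accessible accessible regions for this fiber
#' @param max_gap convoy chaining threshold
#' @return one-row data.table StateCall
#' @export
assign_state <- function(fiber, gene, classified, accessible,
                         max_gap = 100L) {
  win <- gene_windows(gene)
  fp <- classified[fiber_id == fiber$fiber_id]
  acc <- accessible[fiber_id == fiber$fiber_id]
  pol <- fp[class == "polII"]
  spans <- function(w) fiber$start <= w[1] && fiber$end >= w[2]
  acc_bp <- function(w) iv_overlap_bp(w[1], w[2], acc$start, acc$end)
  n_pol_in <- function(w) sum(pol$start < w[2] & pol$end > w[1])

  body <- win$body
  accessible_promoter <- if (!spans(win$promoter) || !spans(body)) NA else
    acc_bp(win$promoter) >= 100L && n_pol_in(body) == 0L

  paused <- if (!spans(win$pause)) NA else {
    inpause <- fp[start < win$pause[2] & end > win$pause[1]]
    if (nrow(inpause) == 0L) FALSE else {
      msize <- mean(inpause$end - inpause$start)
      other_pol <- pol[!(start < win$pause[2] & end > win$pause[1])]
      msize >= 40 && msize <= 60 && nrow(other_pol) == 0L
    }
  }

  # "elongating" excludes the paused molecule: Pol II in the body beyond the
  # pause window
  elongating <- if (!spans(body)) NA else {
    body_pol <- pol[start < body[2] & end > body[1]]
    nrow(body_pol[!(start < win$pause[2] & end > win$pause[1])]) > 0L
  }

  hyperburst <- if (!spans(body)) NA else
    acc_bp(body) / (body[2] - body[1]) >= 0.5

  terminating <- if (!spans(win$termination)) NA else
    n_pol_in(win$termination) > 0L

  hb_win <- win$hyperburst
  nuc <- fp[class == "nucleosome"]
  eviction <- if (!spans(hb_win)) NA_real_ else
    1 - iv_overlap_bp(hb_win[1], hb_win[2], nuc$start, nuc$end) /
      (hb_win[2] - hb_win[1])
  convoys <- detect_convoys(pol, body, max_gap = max_gap)
  # Pol II count over the gene: body through termination window
  lo <- min(body[1], win$termination[1]); hi <- max(body[2], win$termination[2])
  n_polII <- sum(pol$start < hi & pol$end > lo)

  data.table(fiber_id = fiber$fiber_id, gene_id = gene$gene_id,
             accessible_promoter = accessible_promoter, paused = paused,
             elongating = elongating, hyperburst = hyperburst,
             terminating = terminating,
             nucleosome_eviction_fraction = eviction,
             n_polII = as.integer(n_polII),
             n_convoys = length(convoys))
}

#' Hyperburst/active/refractory burst classification
#'
#' Active: nucleosome eviction of at least 50 percent over the first
#' `min(1500, body length)` bp of the gene body and at least one convoy.
#' Refractory: same eviction but zero convoys. Otherwise: none.
#'
#' @param state_call one-row StateCall from [assign_state()]
#' @return "active", "refractory" or "none"
#' @export
classify_burst <- function(state_call) {
  ev <- state_call$nucleosome_eviction_fraction
  if (is.na(ev) || ev < 0.5) return("none")
  if (state_call$n_convoys >= 1L) "active" else "refractory"
}

#' State calls for every fiber of a gene
#'
#' @param fibers fiber data.table (with gene_id)
#' @param gene one-row gene
#' @param classified classified footprints (all fibers)
#' @param accessible accessible regions (all fibers)
#' @param max_gap convoy threshold
#' @return StateCall data.table with `burst_class` column
#' @export
assign_states <- function(fibers, gene, classified, accessible,
                          max_gap = 100L) {
  rows <- fibers[gene_id == gene$gene_id]
  calls <- rbindlist(lapply(seq_len(nrow(rows)), function(i)
    assign_state(rows[i], gene, classified, accessible, max_gap)))
  calls[, burst_class := vapply(seq_len(.N), function(i)
    classify_burst(calls[i]), character(1))]
  calls[]
}

#' Burst-kinetics summary for one gene
#'
#' On-rate is the fraction of fibers with at least one convoy; amplitude is
#' the mean Pol II count per fiber. Both are reported overall and per
#' nucleosome-eviction bin, with percentile bootstrap confidence intervals
#' (resampling unit = fiber) and two-sided Mann-Whitney rank-sum p-values
#' for adjacent-bin amplitude contrasts. Flank occupancy is the fraction of
#' the 300 bp upstream/downstream of each convoy covered by nucleosome
#' footprints, excluding the promoter window.
#'
#' @param gene one-row gene
#' @param state_calls StateCall table for this gene
#' @param classified classified footprints
#' @param eviction_bins breaks over [0,1] for eviction binning
#' @param n_boot bootstrap replicates (default 1000)
#' @param seed RNG seed for the bootstrap
#' @param max_gap convoy threshold
#' @return list: `summary` (one-row data.table), `by_bin`, `flanks`
#' @export
kinetics <- function(gene, state_calls, classified,
                     eviction_bins = c(0, 0.25, 0.5, 0.75, 1),
                     n_boot = 1000L, seed = 1L, max_gap = 100L) {
  sc <- as.data.table(state_calls)
  stopifnot(nrow(sc) >= 1L)
  set.seed(seed)
  boot_ci <- function(x, stat) {
    if (length(x) == 0L) return(c(NA_real_, NA_real_))
    reps <- vapply(seq_len(n_boot), function(b)
      stat(x[sample.int(length(x), replace = TRUE)]), numeric(1))
    unname(quantile(reps, c(0.025, 0.975), na.rm = TRUE))
  }
  on_rate <- mean(sc$n_convoys >= 1L)
  amplitude <- mean(sc$n_polII)
  ci_on <- boot_ci(as.integer(sc$n_convoys >= 1L), mean)
  ci_amp <- boot_ci(sc$n_polII, mean)
  degenerate <- length(unique(sc$n_convoys >= 1L)) == 1L

  bin <- cut(sc$nucleosome_eviction_fraction, eviction_bins,
             include.lowest = TRUE)
  dtb <- data.table(eviction_bin = bin, conv = sc$n_convoys >= 1L,
                    npol = sc$n_polII)
  by_bin <- dtb[!is.na(eviction_bin),
                .(n = .N, on_rate = mean(conv), amplitude = mean(npol)),
                by = eviction_bin][order(eviction_bin)]
  if (nrow(by_bin) > 1L) {
    pvals <- rep(NA_real_, nrow(by_bin))
    for (i in 2:nrow(by_bin)) {
      a <- dtb[eviction_bin == by_bin$eviction_bin[i - 1L], npol]
      b <- dtb[eviction_bin == by_bin$eviction_bin[i], npol]
      if (length(a) && length(b))
        pvals[i] <- suppressWarnings(
          wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    }
    by_bin[, p_vs_prev_bin := pvals]
  }

  flanks <- convoy_flank_occupancy(gene, sc, classified, max_gap = max_gap)
  fl_ci_up <- boot_ci(flanks$upstream_occupancy, function(v) mean(v, na.rm = TRUE))
  fl_ci_dn <- boot_ci(flanks$downstream_occupancy, function(v) mean(v, na.rm = TRUE))

  list(summary = data.table(
    gene_id = gene$gene_id, n_fibers = nrow(sc),
    on_rate = on_rate, on_rate_lo = ci_on[1], on_rate_hi = ci_on[2],
    amplitude = amplitude, amplitude_lo = ci_amp[1], amplitude_hi = ci_amp[2],
    flank_up_occ = mean(flanks$upstream_occupancy, na.rm = TRUE),
    flank_up_lo = fl_ci_up[1], flank_up_hi = fl_ci_up[2],
    flank_down_occ = mean(flanks$downstream_occupancy, na.rm = TRUE),
    flank_down_lo = fl_ci_dn[1], flank_down_hi = fl_ci_dn[2],
    degenerate_ci = degenerate),
    by_bin = by_bin, flanks = flanks)
}

# nucleosome occupancy of the 300 bp flanks around each fiber's convoys,
# promoter window excluded
#' @keywords internal
convoy_flank_occupancy <- function(gene, state_calls, classified,
                                   flank_bp = 300L, max_gap = 100L) {
  win <- gene_windows(gene)
  res <- list()
  for (fid in state_calls[n_convoys >= 1L, fiber_id]) {
    fp <- classified[fiber_id == fid]
    conv <- detect_convoys(fp[class == "polII"], win$body, max_gap = max_gap)
    nuc <- fp[class == "nucleosome"]
    for (cv in conv) {
      lo <- min(cv$members$start); hi <- max(cv$members$end)
      occ <- function(w1, w2) {
        # clip out the promoter window
        segs <- iv_complement(data.table(start = win$promoter[1],
                                         end = win$promoter[2]), w1, w2)
        tot <- sum(segs$end - segs$start)
        if (tot == 0L) return(NA_real_)
        sum(vapply(seq_len(nrow(segs)), function(k)
          iv_overlap_bp(segs$start[k], segs$end[k], nuc$start, nuc$end),
          numeric(1))) / tot
      }
      res[[length(res) + 1L]] <- data.table(
        fiber_id = fid,
        upstream_occupancy = occ(lo - flank_bp, lo),
        downstream_occupancy = occ(hi, hi + flank_bp))
    }
  }
  if (length(res) == 0L)
    return(data.table(fiber_id = character(), upstream_occupancy = numeric(),
                      downstream_occupancy = numeric()))
  rbindlist(res)
}

#' Gaussian-mixture threshold and active fraction from fluorescence traces
#'
#' Fits a two-component 1-D Gaussian mixture by EM, finds the smallest
#' observed value whose posterior probability of the high-mean component is
#' at least `confidence`, and reports the fraction of measurements at or
#' above that threshold.
#'
#' @param values numeric vector of background-normalized measurements, or a
#'   data.frame with a `value` column
#' @param confidence posterior confidence for the active call (default 0.99)
#' @param max_iter,tol EM controls
#' @return list: threshold, active_fraction, means, sds, weights, loglik
#' @export
gmm_on_rate <- function(values, confidence = 0.99, max_iter = 500L,
                        tol = 1e-10) {
  if (is.data.frame(values)) values <- values$value
  x <- as.numeric(values)
  if (length(unique(x)) < 2L)
    stop("need at least 2 distinct values to fit a mixture")
  mu <- unname(quantile(x, c(0.25, 0.75)))
  sg <- rep(max(sd(x) / 2, 1e-6), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sg[1])
    d2 <- w[2] * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    ll <- sum(log(tot))
    w <- c(mean(1 - r2), mean(r2))
    if (any(w < 1e-9))
      stop("mixture component collapsed to zero weight; ",
           "data do not support two components")
    mu <- c(sum((1 - r2) * x) / sum(1 - r2), sum(r2 * x) / sum(r2))
    sg <- sqrt(c(sum((1 - r2) * (x - mu[1])^2) / sum(1 - r2),
                 sum(r2 * (x - mu[2])^2) / sum(r2)))
    sg <- pmax(sg, 1e-9)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (abs(mu[1] - mu[2]) < 1e-6 * max(sd(x), 1e-12))
    stop("mixture components collapsed to equal means; ",
         "no threshold separates active from inactive")
  hi <- which.max(mu)
  post_hi <- w[hi] * dnorm(x, mu[hi], sg[hi]) /
    (w[1] * dnorm(x, mu[1], sg[1]) + w[2] * dnorm(x, mu[2], sg[2]))
  cand <- x[post_hi >= confidence]
  if (length(cand) == 0L)
    stop("no observed value reaches the requested posterior confidence")
  threshold <- min(cand)
  list(threshold = threshold, active_fraction = mean(x >= threshold),
       means = mu, sds = sg, weights = w, loglik = ll)
}

#' Decile concordance between an external signal and fiber occupancy
#'
#' Genes are ranked by the external track signal (stable ties), cut into 10
#' equal-count bins, and fiber footprint occupancy is pooled per bin.
#'
#' @param gene_scores named numeric vector: external signal per gene
#' @param gene_occupancy named numeric vector: mean fiber occupancy per gene
#' @param n_bins number of bins (default 10)
#' @return data.table: decile, n, mean_signal, mean_occupancy
#' @export
decile_concordance <- function(gene_scores, gene_occupancy, n_bins = 10L) {
  stopifnot(length(gene_scores) == length(gene_occupancy))
  if (length(gene_scores) < n_bins)
    stop("need at least ", n_bins, " genes for ", n_bins, " bins")
  ord <- order(gene_scores)  # stable for ties
  n <- length(ord)
  edges <- round(seq(0, n, length.out = n_bins + 1))
  bin <- rep(seq_len(n_bins), times = diff(edges))
  rbindlist(lapply(seq_len(n_bins), function(b) {
    idx <- ord[bin == b]
    data.table(decile = b, n = length(idx),
               mean_signal = mean(gene_scores[idx]),
               mean_occupancy = mean(gene_occupancy[idx]))
  }))
}
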