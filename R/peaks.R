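# Candidate-CRE discovery from aggregate per-bp accessibility. The upstream
# machine-learned FIRE score is deliberately not re-implemented: the
# aggregate trace here is the per-position accessibility frequency across
# fibers, and the published peak-calling stage (minimum width 20 bp, minimum
# height one fifth of the window maximum, sub-100 bp peaks expanded to
# 100 bp, overlapping peaks merged) operates on it unchanged. Because raw
# accessibility frequency carries a linker-level baseline that FIRE scores
# do not, the pipeline applies an optional median-baseline correction and
# light smoothing before peak calling (see the methods vignette).

#' Aggregate accessibility trace over a window
#'
#' `trace[p] = (# fibers accessible at p) / (# fibers covering p)`.
#' Positions covered by no fiber are NA (masked).
#'
#' @param fibers fiber data.table (spans)
#' @param accessible accessible-region data.table for those fibers
#' @param chrom chromosome of the window
#' @param window `c(start, end)` half-open genomic window
#' @return numeric vector of length `window[2] - window[1]`
#' @export
aggregate_trace <- function(fibers, accessible, chrom, window) {
  w1 <- window[1]; w2 <- window[2]
  L <- w2 - w1
  stopifnot(L > 0)
  add_cov <- function(cov, s, e) {
    s <- pmax(s, w1) - w1; e <- pmin(e, w2) - w1
    keep <- e > s
    s <- s[keep]; e <- e[keep]
    d <- numeric(L + 1L)
    for (i in seq_along(s)) {
      d[s[i] + 1L] <- d[s[i] + 1L] + 1
      d[e[i] + 1L] <- d[e[i] + 1L] - 1
    }
    cov + cumsum(d)[seq_len(L)]
  }
  fb <- fibers[fibers$chrom == chrom]
  cov <- add_cov(numeric(L), fb$start, fb$end)
  acc <- accessible[accessible$chrom == chrom]
  nacc <- add_cov(numeric(L), acc$start, acc$end)
  if (all(cov == 0))
    stop("no fiber covers any position of the requested window")
  out <- nacc / cov
  out[cov == 0] <- NA_real_
  out
}

#' Call accessibility peaks on a trace
#'
#' Peaks are maximal runs of the (optionally baseline-corrected and
#' smoothed) trace at or above one fifth of the window maximum
#' (`height_frac`), at least `min_width` bp wide. Each peak narrower than
#' `expand_to` bp is expanded symmetrically around its summit to
#' `expand_to` bp (clipped at the window edges) and overlapping peaks are
#' merged.
#'
#' @param trace numeric trace (NA = masked)
#' @param window `c(start, end)` genomic coordinates of the trace
#' @param min_width minimum peak width before expansion (default 20)
#' @param height_frac minimum height as a fraction of the window maximum
#'   (default 0.2)
#' @param expand_to minimum reported peak width (default 100)
#' @param smooth_bp running-mean half-window; 0 disables smoothing
#' @param baseline "none" (default) or "median" (subtract the window median
#'   and floor at zero before thresholding)
#' @return data.table: start, end, summit, height (pre-expansion summit
#'   height)
#' @export
call_peaks <- function(trace, window = c(0L, length(trace)),
                       min_width = 20L, height_frac = 0.2,
                       expand_to = 100L, smooth_bp = 0L,
                       baseline = c("none", "median")) {
  baseline <- match.arg(baseline)
  tr <- trace
  tr[is.na(tr)] <- 0
  if (baseline == "median") tr <- pmax(tr - stats::median(tr), 0)
  if (smooth_bp > 0L) {
    k <- 2L * smooth_bp + 1L
    tr <- as.numeric(stats::filter(tr, rep(1 / k, k), sides = 2))
    tr[is.na(tr)] <- 0
  }
  mx <- max(tr)
  if (mx <= 0)
    return(data.table(start = integer(), end = integer(),
                      summit = integer(), height = numeric()))
  thr <- mx * height_frac
  above <- tr >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- c(0L, head(ends, -1L))
  runs <- data.table(start = starts[r$values], end = ends[r$values])
  runs <- runs[end - start >= min_width]
  if (nrow(runs) == 0L)
    return(data.table(start = integer(), end = integer(),
                      summit = integer(), height = numeric()))
  w1 <- window[1]; L <- length(tr)
  peaks <- runs[, {
    seg <- tr[(start + 1L):end]
    smt <- start + which(seg == max(seg))
    smt <- as.integer(round(mean(smt))) - 1L  # center of summit plateau
    .(summit = smt, height = max(seg))
  }, by = .(start, end)]
  # symmetric summit-centered expansion, clipped at window edges
  narrow <- peaks$end - peaks$start < expand_to
  if (any(narrow)) {
    es <- pmax(0L, peaks$summit[narrow] - expand_to %/% 2L)
    ee <- pmin(L, es + expand_to)
    es <- pmax(0L, ee - expand_to)  # re-anchor when clipped at the right edge
    peaks[narrow, `:=`(start = es, end = ee)]
  }
  merged <- iv_merge(peaks[, .(start, end)])
  merged[, `:=`(summit = NA_integer_, height = NA_real_)]
  for (i in seq_len(nrow(merged))) {
    cand <- peaks[start < merged$end[i] & end > merged$start[i]]
    best <- cand[which.max(height)]
    merged[i, `:=`(summit = best$summit, height = best$height)]
  }
  merged[, `:=`(start = as.integer(start + w1), end = as.integer(end + w1),
                summit = as.integer(summit + w1))]
  merged[]
}

#' Discover CRE peaks upstream of a gene
#'
#' @param fibers fiber table
#' @param accessible accessible regions
#' @param gene one-row gene
#' @param window_bp upstream window size (default 10000, the discovery
#'   window; the regression module restricts features to 9 kb)
#' @param ... passed to [call_peaks()]
#' @return CRE peak data.table with gene_id and labels U1, U2, ... ordered
#'   by distance from the TSS
#' @export
discover_cres <- function(fibers, accessible, gene, window_bp = 10000L, ...) {
  win <- gene_windows(gene, upstream_bp = window_bp)$upstream
  tr <- aggregate_trace(fibers[gene_id == gene$gene_id], accessible,
                        gene$chrom, win)
  pk <- call_peaks(tr, window = win, ...)
  if (nrow(pk) == 0L) {
    pk[, `:=`(gene_id = character(), label = character())]
    return(pk)
  }
  pk[, gene_id := gene$gene_id]
  # label by distance from the TSS, U1 = closest upstream element
  d <- if (identical(gene$strand, "-")) pk$start - gene$tss else gene$tss - pk$end
  pk[order(d), label := paste0("U", seq_len(.N))]
  pk[]
}

#' Per-read CRE accessibility call
#'
#' TRUE when at least `threshold` of the peak's bp lie inside the fiber's
#' accessible regions; NA when the fiber does not span the peak.
#'
#' @param fiber one-row fiber
#' @param accessible accessible regions for this fiber
#' @param peak one-row peak (start, end)
#' @param threshold accessible fraction cutoff (default 0.5, boundary
#'   inclusive)
#' @return logical or NA
#' @export
read_cre_accessibility <- function(fiber, accessible, peak, threshold = 0.5) {
  if (fiber$start > peak$start || fiber$end < peak$end) return(NA)
  acc <- accessible[fiber_id == fiber$fiber_id]
  frac <- iv_overlap_bp(peak$start, peak$end, acc$start, acc$end) /
    (peak$end - peak$start)
  frac >= threshold
}

#' Per-read CRE accessibility matrix
#'
#' @param fibers fiber table
#' @param accessible accessible regions for all fibers
#' @param peaks peak table (uses `label` or row index as column names)
#' @param threshold see [read_cre_accessibility()]
#' @return integer matrix fibers x peaks (0/1, NA where not spanning), with
#'   fiber_id rownames
#' @export
cre_access_matrix <- function(fibers, accessible, peaks, threshold = 0.5) {
  labels <- if ("label" %in% names(peaks)) peaks$label else
    paste0("peak", seq_len(nrow(peaks)))
  M <- matrix(NA_integer_, nrow(fibers), nrow(peaks),
              dimnames = list(fibers$fiber_id, labels))
  for (j in seq_len(nrow(peaks))) {
    pk <- peaks[j]
    for (i in seq_len(nrow(fibers))) {
      v <- read_cre_accessibility(fibers[i], accessible, pk, threshold)
      M[i, j] <- if (is.na(v)) NA_integer_ else as.integer(v)
    }
  }
  M
}
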