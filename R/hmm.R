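# Two-hidden-state (accessible / inaccessible) HMM over single fibers.
# State 1 = accessible, state 2 = inaccessible, everywhere. The chain runs
# over every bp of the fiber; non-A/T positions carry no methylation call and
# contribute emission probability 1 in both states, so segment coordinates
# stay in genomic bp. All arithmetic is in log space (fibers are ~20 kb;
# linear space underflows).

.hmm_states <- c("accessible", "inaccessible")

#' Construct HMM parameters
#'
#' @param start length-2 start probabilities (accessible, inaccessible)
#' @param trans 2x2 transition matrix, rows = from-state
#' @param emissions an `emission_table`
#' @return an `hmm_params` object
#' @export
hmm_params <- function(start = c(0.5, 0.5),
                       trans = matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2,
                                      byrow = TRUE),
                       emissions = flat_emission_table()) {
  start <- as.numeric(start)
  trans <- matrix(as.numeric(trans), 2, 2)
  if (abs(sum(start) - 1) > 1e-8) stop("start probabilities must sum to 1")
  if (any(abs(rowSums(trans) - 1) > 1e-8)) stop("transition rows must sum to 1")
  if (any(start <= 0) || any(trans <= 0))
    stop("start and transition probabilities must be strictly positive")
  dimnames(trans) <- list(.hmm_states, .hmm_states)
  names(start) <- .hmm_states
  structure(list(start = start, trans = trans, emissions = emissions),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("hmm_params: 2-state accessible/inaccessible\n")
  cat("start:", sprintf("%.4f", x$start), "\n")
  cat("transitions:\n"); print(round(x$trans, 4))
  cat("emissions:", x$emissions$type, "\n")
  invisible(x)
}

# L x 2 log-emission matrix for one fiber. `sequence` is the fiber's
# reference sequence; `meth_offsets` are fiber-relative 0-based offsets of
# methylated positions.
#' @keywords internal
fiber_emission_loglik <- function(sequence, meth_offsets, tab) {
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(bases)
  emis <- matrix(0, L, 2L)
  info <- which(bases == "A" | bases == "T")
  if (length(info) == 0L) return(structure(emis, informative = 0L))
  contexts <- rep(NA_character_, length(info))
  if (tab$type == "context") {
    inner <- info >= 4L & info <= L - 3L
    if (any(inner))
      contexts[inner] <- substring(sequence, info[inner] - 3L, info[inner] + 3L)
  }
  rates <- emission_rates(tab, contexts, bases[info])
  meth <- logical(L)
  meth[meth_offsets + 1L] <- TRUE
  m <- meth[info]
  emis[info, 1L] <- ifelse(m, log(rates$p_acc), log1p(-rates$p_acc))
  emis[info, 2L] <- ifelse(m, log(rates$p_inacc), log1p(-rates$p_inacc))
  structure(emis, informative = length(info))
}

#' Decode one fiber into accessible/inaccessible segments
#'
#' Runs maximum-a-posteriori (Viterbi) decoding, or per-position posterior
#' decoding, of the fiber's methylation calls and returns the hidden-state
#' path as maximal segments that tile the fiber span.
#'
#' @param fiber one-row list/data.table with `chrom`, `start`, `end`,
#'   `fiber_id`, `strand`, and `meth` (integer vector of fiber-relative
#'   methylated offsets; a list column element)
#' @param reference named character vector or DNAStringSet
#' @param params `hmm_params`
#' @param decoder "viterbi" (default) or "posterior"
#' @return data.table of segments: fiber_id, chrom, start, end, strand, state
#' @export
decode_fiber <- function(fiber, reference, params,
                         decoder = c("viterbi", "posterior")) {
  decoder <- match.arg(decoder)
  stopifnot(inherits(params, "hmm_params"))
  meth <- fiber$meth
  if (is.list(meth)) meth <- meth[[1]]
  seq <- get_sequence(reference, fiber$chrom, fiber$start, fiber$end)
  emis <- fiber_emission_loglik(seq, as.integer(meth), params$emissions)
  L <- nrow(emis)
  flagged <- FALSE
  if (attr(emis, "informative") == 0L) {
    # no A/T position: fall back to the prior-dominant state over the span
    path <- rep.int(which.max(params$start) - 1L, L)
    flagged <- TRUE
  } else if (decoder == "viterbi") {
    path <- hmm_viterbi_cpp(emis, log(params$start), log(params$trans))
  } else {
    fb <- hmm_forward_backward_cpp(emis, log(params$start), log(params$trans))
    path <- as.integer(fb$gamma[, 2L] > fb$gamma[, 1L])
  }
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- c(0L, head(ends, -1L))
  seg <- data.table(
    fiber_id = fiber$fiber_id, chrom = fiber$chrom,
    start = as.integer(fiber$start + starts),
    end = as.integer(fiber$start + ends),
    strand = fiber$strand %||% "+",
    state = .hmm_states[r$values + 1L]
  )
  setattr(seg, "no_informative_positions", flagged)
  seg
}

#' Decode a fiber table
#'
#' @param fibers data.table of fibers (list column `meth`)
#' @inheritParams decode_fiber
#' @return rbound segment data.table
#' @export
decode_fibers <- function(fibers, reference, params,
                          decoder = c("viterbi", "posterior")) {
  decoder <- match.arg(decoder)
  segs <- lapply(seq_len(nrow(fibers)), function(i)
    decode_fiber(fibers[i], reference, params, decoder))
  rbindlist(segs)
}

#' Extract footprints (inaccessible runs) from a decoded path
#'
#' @param segments segment data.table from [decode_fiber()]
#' @return list with `footprints` (maximal inaccessible intervals) and
#'   `accessible` (accessible gaps), both data.tables
#' @export
footprints_from_path <- function(segments) {
  list(footprints = segments[state == "inaccessible"][, !"state"],
       accessible = segments[state == "accessible"][, !"state"])
}

#' Posterior state probabilities for one fiber
#'
#' @inheritParams decode_fiber
#' @return list with `gamma` (L x 2 posterior matrix), `loglik`
#' @export
fiber_posteriors <- function(fiber, reference, params) {
  meth <- fiber$meth
  if (is.list(meth)) meth <- meth[[1]]
  seq <- get_sequence(reference, fiber$chrom, fiber$start, fiber$end)
  emis <- fiber_emission_loglik(seq, as.integer(meth), params$emissions)
  fb <- hmm_forward_backward_cpp(emis, log(params$start), log(params$trans))
  list(gamma = fb$gamma, loglik = fb$loglik)
}

#' Train start/transition probabilities by Baum-Welch EM
#'
#' Emissions are held fixed (they come from control datasets); only the
#' 2x2 transition matrix and the start distribution are re-estimated.
#' Each restart is initialized from flat Dirichlet draws (all concentration
#' parameters 1) and the highest-likelihood restart is returned.
#'
#' @param fibers fiber data.table
#' @param reference reference sequences
#' @param emissions `emission_table` (held fixed)
#' @param n_restarts number of EM restarts
#' @param seed RNG seed for restart initialization
#' @param max_iter EM iteration cap per restart
#' @param tol convergence tolerance on log-likelihood improvement
#' @return `hmm_params` with attributes `loglik`, `loglik_trace`, `converged`
#' @export
train_hmm <- function(fibers, reference, emissions, n_restarts = 3L,
                      seed = 1L, max_iter = 100L, tol = 1e-4) {
  stopifnot(nrow(fibers) >= 1L)
  emis_list <- lapply(seq_len(nrow(fibers)), function(i) {
    f <- fibers[i]
    meth <- f$meth
    if (is.list(meth)) meth <- meth[[1]]
    fiber_emission_loglik(get_sequence(reference, f$chrom, f$start, f$end),
                          as.integer(meth), emissions)
  })
  n_inf <- sum(vapply(emis_list, attr, 1L, "informative"))
  if (n_inf < 2L) stop("training needs at least 2 informative positions")
  set.seed(seed)
  rdirichlet1 <- function(k) { g <- stats::rgamma(k, 1); g / sum(g) }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    start <- rdirichlet1(2L)
    trans <- rbind(rdirichlet1(2L), rdirichlet1(2L))
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      lp <- log(start); lt <- log(trans)
      xi <- matrix(0, 2, 2); g1 <- c(0, 0); ll <- 0
      for (emis in emis_list) {
        fb <- hmm_forward_backward_cpp(emis, lp, lt)
        xi <- xi + fb$xi
        g1 <- g1 + fb$gamma[1L, ]
        ll <- ll + fb$loglik
      }
      trace <- c(trace, ll)
      # floor keeps probabilities strictly positive per the params contract
      start <- pmax(g1 / sum(g1), 1e-12); start <- start / sum(start)
      trans <- pmax(xi / pmax(rowSums(xi), .Machine$double.xmin), 1e-12)
      trans <- trans / rowSums(trans)
      if (it > 1L && trace[it] - trace[it - 1L] < tol) { converged <- TRUE; break }
    }
    if (is.null(best) || tail(trace, 1L) > attr(best, "loglik")) {
      best <- hmm_params(start, trans, emissions)
      setattr(best, "loglik", tail(trace, 1L))
      setattr(best, "loglik_trace", trace)
      setattr(best, "converged", converged)
    }
  }
  if (!attr(best, "converged"))
    warning("EM did not converge within max_iter; returning best iterate")
  best
}
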