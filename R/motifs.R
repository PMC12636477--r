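# Log-odds PWM scanning of CRE sequences with single-fiber footprint
# filtering. Position frequency matrices are normalized with a pseudocount
# of 0.8 against a background distribution (uniform by default) and
# converted to log2-odds weights; sequences are scanned base by base on
# both strands, per-position scores are combined across a factor's motif
# variants by maximum, hits at log-odds >= 2.0 are retained, and hits are
# further filtered to those overlapping a TF-class footprint on at least 5
# percent of spanning fibers.

.dna_bases <- c("A", "C", "G", "T")

#' Log-odds PWM from a position frequency matrix
#'
#' `pwm[b, j] = log2(((count[b, j] + pc) / (colsum_j + 4 pc)) / background[b])`
#'
#' @param pfm 4 x L numeric count matrix, rownames A, C, G, T
#' @param pseudocount additive count (default 0.8)
#' @param background length-4 base distribution (default uniform)
#' @param name transcription-factor name carried on the result
#' @return a `pwm` object (matrix with attributes name, background)
#' @export
pwm_from_pfm <- function(pfm, pseudocount = 0.8,
                         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                         name = "motif") {
  pfm <- as.matrix(pfm)
  if (ncol(pfm) == 0L) stop("position frequency matrix has zero columns")
  if (is.null(rownames(pfm))) rownames(pfm) <- .dna_bases
  pfm <- pfm[.dna_bases, , drop = FALSE]
  if (any(pfm < 0)) stop("PFM counts must be non-negative")
  probs <- sweep(pfm + pseudocount, 2, colSums(pfm) + 4 * pseudocount, "/")
  if (any(probs == 0))
    stop("zero probability after smoothing (pseudocount 0 with a zero count?)")
  lw <- log2(sweep(probs, 1, background, "/"))
  structure(lw, class = c("pwm", "matrix"), name = name,
            background = background)
}

# reverse-complement a PWM: complement rows, reverse columns
#' @keywords internal
pwm_revcomp <- function(pwm) {
  rc <- pwm[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(rc) <- .dna_bases
  rc
}

# per-offset forward scores of one weight matrix over an encoded sequence;
# windows containing N score -Inf
#' @keywords internal
scan_scores_one <- function(codes, mat) {
  w <- ncol(mat); n <- length(codes)
  if (n < w) return(numeric(0))
  s <- numeric(n - w + 1L)
  bad <- logical(n - w + 1L)
  for (j in seq_len(w)) {
    cj <- codes[j:(n - w + j)]
    v <- mat[cbind(cj, j)]
    nas <- is.na(cj)
    if (any(nas)) { v[nas] <- 0; bad <- bad | nas }
    s <- s + v
  }
  s[bad] <- -Inf
  s
}

#' Scan a sequence with a transcription factor's motif variants
#'
#' Both strands are scanned at every offset; the per-position score is the
#' maximum over variants and strands of motifs starting at that position.
#'
#' @param sequence character scalar over A/C/G/T/N
#' @param pwms list of `pwm` objects (the factor's motif variants)
#' @param threshold log-odds hit threshold (default 2.0)
#' @param tf factor name attached to hits
#' @param origin genomic coordinate of sequence position 0 (for hit
#'   coordinates)
#' @return a `motif_profile`: list with `scores` (per-offset max), `hits`
#'   (data.table: start, end, strand, score, tf), `tf`, `origin`,
#'   `seq_length`
#' @export
scan_sequence <- function(sequence, pwms, threshold = 2.0, tf = "motif",
                          origin = 0L) {
  sequence <- toupper(sequence)
  codes <- match(strsplit(sequence, "", fixed = TRUE)[[1]], .dna_bases)
  n <- length(codes)
  scores <- rep(-Inf, n)
  best_strand <- rep(NA_character_, n)
  best_width <- rep(NA_integer_, n)
  for (pwm in pwms) {
    w <- ncol(pwm)
    if (n < w) next
    for (strand in c("+", "-")) {
      mat <- if (strand == "+") pwm else pwm_revcomp(pwm)
      sc <- scan_scores_one(codes, mat)
      off <- seq_along(sc)
      upd <- sc > scores[off]
      scores[off][upd] <- sc[upd]
      best_strand[off][upd] <- strand
      best_width[off][upd] <- w
    }
  }
  hit_idx <- which(is.finite(scores) & scores >= threshold)
  hits <- data.table(
    start = as.integer(origin + hit_idx - 1L),
    end = as.integer(origin + hit_idx - 1L + best_width[hit_idx]),
    strand = best_strand[hit_idx],
    score = scores[hit_idx], tf = tf)
  structure(list(scores = scores, hits = hits, tf = tf,
                 origin = as.integer(origin), seq_length = n),
            class = "motif_profile")
}

#' Filter motif hits by single-fiber TF footprint support
#'
#' A hit survives iff at least `min_fraction` of the fibers spanning it
#' carry a TF-class footprint overlapping the hit interval.
#'
#' @param profile `motif_profile` from [scan_sequence()]
#' @param fibers fiber table (spans, genomic coordinates)
#' @param tf_footprints TF-class classified footprints
#' @param min_fraction support threshold (default 0.05, boundary inclusive)
#' @return the profile with `hits` filtered and a `support` column added
#' @export
footprint_filter <- function(profile, fibers, tf_footprints,
                             min_fraction = 0.05) {
  hits <- copy(profile$hits)
  if (nrow(hits) == 0L) return(profile)
  support <- numeric(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    spanning <- fibers[start <= hits$start[i] & end >= hits$end[i], fiber_id]
    if (length(spanning) == 0L) { support[i] <- NA_real_; next }
    with_fp <- tf_footprints[fiber_id %in% spanning &
                               start < hits$end[i] & end > hits$start[i],
                             uniqueN(fiber_id)]
    support[i] <- with_fp / length(spanning)
  }
  if (anyNA(support))
    warning("some hits had no spanning fibers; they were removed")
  hits[, support := support]
  out <- profile
  out$hits <- hits[!is.na(support) & support >= min_fraction]
  out
}

#' Per-CRE motif enrichment and activator/repressor balance
#'
#' Sums retained hit intensities per CRE per factor, then computes
#' `balance = min(act, rep) / max(act, rep)` per CRE (0/0 defined as 0).
#'
#' @param profiles list of (filtered) `motif_profile`s, one per factor
#' @param cres CRE table (cre_id, start, end); must lie inside the scanned
#'   region
#' @param activator_set,repressor_set disjoint character vectors of factor
#'   names
#' @return list: `enrichment` (CRE x factor matrix of summed intensities),
#'   `balance` (data.table: cre_id, activator_sum, repressor_sum, balance)
#' @export
cre_enrichment_and_balance <- function(profiles, cres, activator_set,
                                       repressor_set) {
  if (length(intersect(activator_set, repressor_set)) > 0L)
    stop("activator and repressor sets must be disjoint")
  tfs <- vapply(profiles, function(p) p$tf, character(1))
  scanned <- range(vapply(profiles, function(p)
    c(p$origin, p$origin + p$seq_length), numeric(2)))
  if (any(cres$start < scanned[1]) || any(cres$end > scanned[2]))
    stop("CRE outside the scanned region")
  E <- matrix(0, nrow(cres), length(profiles),
              dimnames = list(cres$cre_id, tfs))
  for (k in seq_along(profiles)) {
    h <- profiles[[k]]$hits
    for (i in seq_len(nrow(cres)))
      E[i, k] <- sum(h[start < cres$end[i] & end > cres$start[i], score])
  }
  act <- rowSums(E[, tfs %in% activator_set, drop = FALSE])
  rep_ <- rowSums(E[, tfs %in% repressor_set, drop = FALSE])
  bal <- ifelse(act == 0 & rep_ == 0, 0,
                pmin(act, rep_) / pmax(act, rep_))
  list(enrichment = E,
       balance = data.table(cre_id = cres$cre_id, activator_sum = act,
                            repressor_sum = rep_, balance = bal))
}

#' Read position frequency matrices in JASPAR text format
#'
#' Parses the line-oriented JASPAR format:
#' \preformatted{>MA0001.1 name
#' A  [ 1 2 3 ]
#' C  [ 0 1 0 ]
#' ...}
#' Bracket-free whitespace-separated rows are accepted too.
#'
#' @param path file path
#' @return named list of 4 x L count matrices (names = "id name" header)
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  out <- list(); cur <- NULL; rows <- list()
  flush <- function() {
    if (is.null(cur) || length(rows) == 0L) return()
    m <- do.call(rbind, rows[.dna_bases])
    out[[cur]] <<- m
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    if (startsWith(ln, ">")) {
      flush()
      cur <- sub("^>\\s*", "", ln)
      rows <- list()
    } else {
      base <- substr(ln, 1, 1)
      if (!base %in% .dna_bases) next
      nums <- gsub("[^0-9. -]", " ", substring(ln, 2))
      vals <- as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
      rows[[base]] <- vals
    }
  }
  flush()
  out
}
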