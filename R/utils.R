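#' @useDynLib fiberburst, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats rbinom rgeom runif rnorm dnorm quantile wilcox.test sd
#'   setNames aggregate var
#' @importFrom utils head tail modifyList
NULL

# All genomic intervals in this package are 0-based half-open [start, end),
# BED convention. `start`/`end` columns are integers in genome coordinates
# unless a function documents fiber-relative offsets.

.state_levels <- c("off", "poised", "elongating", "hyperburst",
                   "refractory", "terminating")

.fp_classes <- c("nucleosome", "polII", "PIC", "TF", "unclassified")

#' Width of half-open intervals
#' @keywords internal
iv_width <- function(start, end) end - start

#' Overlap width between one interval and a set of intervals
#'
#' @param s,e scalar query interval (half-open)
#' @param starts,ends vectors of intervals
#' @return total overlapping bp (intervals assumed disjoint)
#' @keywords internal
iv_overlap_bp <- function(s, e, starts, ends) {
  if (length(starts) == 0L) return(0L)
  sum(pmax(0L, pmin(e, ends) - pmax(s, starts)))
}

#' Merge overlapping or touching half-open intervals
#' @param dt data.table with start, end
#' @return data.table with merged start, end, sorted
#' @keywords internal
iv_merge <- function(dt) {
  if (nrow(dt) == 0L) return(data.table(start = integer(), end = integer()))
  dt <- dt[order(start, end)]
  s <- dt$start; e <- dt$end
  out_s <- s[1]; out_e <- e[1]
  res_s <- integer(); res_e <- integer()
  if (nrow(dt) > 1L) {
    for (i in 2:nrow(dt)) {
      if (s[i] <= out_e) {
        out_e <- max(out_e, e[i])
      } else {
        res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
        out_s <- s[i]; out_e <- e[i]
      }
    }
  }
  res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
  data.table(start = as.integer(res_s), end = as.integer(res_e))
}

#' Complement of intervals within a span
#' @param dt data.table with start, end (will be merged first)
#' @param span_start,span_end enclosing half-open interval
#' @keywords internal
iv_complement <- function(dt, span_start, span_end) {
  m <- iv_merge(dt[end > span_start & start < span_end])
  if (nrow(m) == 0L)
    return(data.table(start = as.integer(span_start), end = as.integer(span_end)))
  m[start < span_start, start := as.integer(span_start)]
  m[end > span_end, end := as.integer(span_end)]
  starts <- c(span_start, m$end)
  ends <- c(m$start, span_end)
  keep <- ends > starts
  data.table(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' Strand-aware windows for a gene model
#'
#' Computes the canonical assessment windows used throughout the pipeline:
#' promoter (centered on the TSS), pause window (first 50 bp downstream of the
#' TSS), gene body, termination window (500 bp past the annotated gene end),
#' hyperburst window (first `min(1500, body length)` bp of the body), and the
#' upstream regulatory window.
#'
#' @param gene one-row list/data.table with chrom, start, end, strand, tss
#' @param promoter_halfwidth bp on each side of the TSS for the promoter window
#' @param upstream_bp size of the upstream regulatory window
#' @param hyperburst_bp cap on the hyperburst assessment window
#' @return named list of `c(start, end)` integer pairs
#' @export
gene_windows <- function(gene, promoter_halfwidth = 100L,
                         upstream_bp = 9000L, hyperburst_bp = 1500L) {
  tss <- as.integer(gene$tss)
  plus <- !identical(gene$strand, "-")
  body <- if (plus) c(gene$start, gene$end) else c(gene$start, gene$end)
  body <- as.integer(body)
  body_len <- body[2] - body[1]
  hb_len <- min(hyperburst_bp, body_len)
  if (plus) {
    list(
      promoter    = c(tss - promoter_halfwidth, tss + promoter_halfwidth),
      pause       = c(tss, tss + 50L),
      body        = body,
      termination = c(body[2], body[2] + 500L),
      hyperburst  = c(tss, tss + hb_len),
      upstream    = c(tss - upstream_bp, tss)
    )
  } else {
    list(
      promoter    = c(tss - promoter_halfwidth, tss + promoter_halfwidth),
      pause       = c(tss - 50L, tss),
      body        = body,
      termination = c(body[1] - 500L, body[1]),
      hyperburst  = c(tss - hb_len, tss),
      upstream    = c(tss, tss + upstream_bp)
    )
  }
}

# Deterministic FNV-1a hash of a serialized object; used to stamp parameter
# provenance into output file headers without an external digest dependency.
#' @keywords internal
param_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
fb_log <- function(..., verbose = getOption("fiberburst.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[fiberburst] ", ...)
  invisible(NULL)
}

#' Extract a subsequence from a reference
#'
#' @param reference named character vector or `Biostrings::DNAStringSet`
#' @param chrom sequence name
#' @param start,end 0-based half-open coordinates
#' @return uppercase character scalar
#' @export
get_sequence <- function(reference, chrom, start, end) {
  if (methods::is(reference, "DNAStringSet")) {
    as.character(Biostrings::subseq(reference[[chrom]], start + 1L, end))
  } else {
    toupper(substr(reference[[chrom]], start + 1L, end))
  }
}
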