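# Readers and writers for the pipeline's plain-text formats. All genomic
# records use 0-based half-open BED conventions with the strand column
# always populated. Stochastic outputs carry a comment header line with the
# seed and a parameter hash for provenance.

#' @keywords internal
provenance_header <- function(seed = NULL, params = NULL) {
  if (is.null(seed) && is.null(params)) return(character(0))
  sprintf("# fiberburst seed=%s params=%s",
          if (is.null(seed)) "NA" else format(seed),
          if (is.null(params)) "NA" else param_hash(params))
}

#' @keywords internal
write_tsv <- function(dt, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  # fixed-notation, locale-independent formatting
  out <- capture_tsv(dt)
  writeLines(out, con)
  invisible(path)
}

#' @keywords internal
capture_tsv <- function(dt) {
  dt <- as.data.table(dt)
  cols <- vapply(dt, function(col) {
    if (is.numeric(col) && !is.integer(col))
      formatC(col, format = "g", digits = 15)
    else as.character(col)
  }, FUN.VALUE = character(nrow(dt)))
  if (nrow(dt) == 1L) cols <- matrix(cols, nrow = 1L)
  c(paste(names(dt), collapse = "\t"),
    apply(cols, 1L, paste, collapse = "\t"))
}

#' Write the per-read methylation table
#'
#' Columns: fiber_id, chrom, start, end, strand, gene_id, true_state (if
#' present), meth_offsets (comma-separated ascending fiber-relative 0-based
#' offsets of methylated positions).
#'
#' @param fibers fiber data.table with `meth` list column
#' @param path output path
#' @param seed,params provenance for the header comment
#' @export
write_fiber_table <- function(fibers, path, seed = NULL, params = NULL) {
  dt <- copy(as.data.table(fibers))
  dt[, meth_offsets := vapply(meth, function(v)
    paste(sort(as.integer(v)), collapse = ","), character(1))]
  dt[, meth := NULL]
  write_tsv(dt, path, provenance_header(seed, params))
}

#' Read and validate a per-read methylation table
#'
#' @param path TSV in the [write_fiber_table()] dialect
#' @return fiber data.table with `meth` list column
#' @export
read_fiber_table <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  dt <- fread(text = paste(lines[!is_comment], collapse = "\n"), sep = "\t",
              header = TRUE, colClasses = list(
                character = c("fiber_id", "chrom", "strand", "meth_offsets")))
  req <- c("fiber_id", "chrom", "start", "end", "strand", "meth_offsets")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("fiber table lacks required columns: ", paste(miss, collapse = ", "))
  n_header <- 1L + sum(is_comment)
  errs <- character(0)
  meth <- vector("list", nrow(dt))
  for (i in seq_len(nrow(dt))) {
    line <- i + n_header
    if (is.na(dt$start[i]) || is.na(dt$end[i]) || dt$end[i] <= dt$start[i]) {
      errs <- c(errs, sprintf("line %d: end <= start", line)); next
    }
    off <- dt$meth_offsets[i]
    v <- if (is.na(off) || off == "") integer(0) else
      as.integer(strsplit(off, ",", fixed = TRUE)[[1]])
    L <- dt$end[i] - dt$start[i]
    if (anyNA(v)) {
      errs <- c(errs, sprintf("line %d: non-numeric methylation offset", line))
    } else if (length(v) && (min(v) < 0L || max(v) >= L)) {
      errs <- c(errs, sprintf("line %d: offset out of range [0, %d)", line, L))
    } else if (is.unsorted(v)) {
      errs <- c(errs, sprintf("line %d: offsets not ascending", line))
    }
    meth[[i]] <- v
  }
  if (length(errs)) stop("malformed fiber table:\n", paste(errs, collapse = "\n"))
  dt[, meth := meth]
  dt[, meth_offsets := NULL]
  dt[]
}

#' Write intervals as BED6
#'
#' @param dt data.table with chrom, start, end; optional name, score, strand
#' @param path output path
#' @param name_col,score_col column names to map into BED name/score
#' @param seed,params provenance header
#' @export
write_bed <- function(dt, path, name_col = NULL, score_col = NULL,
                      seed = NULL, params = NULL) {
  dt <- as.data.table(dt)
  bed <- data.table(
    chrom = dt$chrom, start = dt$start, end = dt$end,
    name = if (!is.null(name_col)) as.character(dt[[name_col]]) else ".",
    score = if (!is.null(score_col))
      pmin(1000L, pmax(0L, as.integer(round(dt[[score_col]])))) else 0L,
    strand = dt$strand %||% "+")
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- provenance_header(seed, params)
  if (length(hdr)) writeLines(hdr, con)
  if (nrow(bed))
    writeLines(do.call(paste, c(bed, sep = "\t")), con)
  invisible(path)
}

#' Read a BED3+/BED6 file
#' @param path file path
#' @return data.table: chrom, start, end (+ name, score, strand if present)
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  dt <- fread(text = paste(lines, collapse = "\n"), sep = "\t", header = FALSE)
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  setnames(dt, nm[seq_len(min(ncol(dt), 6L))])
  dt
}

#' Write a coverage track as bedGraph (per-bp values, run-length compressed)
#'
#' @param track named list of numeric vectors
#' @param path output path
#' @param seed,params provenance header
#' @export
write_bedgraph <- function(track, path, seed = NULL, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- provenance_header(seed, params)
  if (length(hdr)) writeLines(hdr, con)
  for (ch in names(track)) {
    v <- track[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths); starts <- c(0L, head(ends, -1L))
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                       formatC(r$values[keep], format = "g", digits = 15)), con)
  }
  invisible(path)
}

#' Read a bedGraph into a coverage track
#' @param path file path
#' @param lengths named integer vector of sequence lengths
#' @return named list of numeric vectors
#' @export
read_bedgraph <- function(path, lengths) {
  track <- lapply(lengths, numeric)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  dt <- fread(text = paste(lines, collapse = "\n"), sep = "\t", header = FALSE,
              col.names = c("chrom", "start", "end", "value"))
  for (i in seq_len(nrow(dt))) {
    ch <- dt$chrom[i]
    track[[ch]][(dt$start[i] + 1L):dt$end[i]] <- dt$value[i]
  }
  track
}

#' Write reference sequences as FASTA
#' @param reference named character vector
#' @param path output path
#' @export
write_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), path)
  invisible(path)
}

#' Read a FASTA reference into a named character vector
#' @param path file path
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
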