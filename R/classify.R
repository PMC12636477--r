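# Footprint classification by size and overlap rules:
#   PIC: 20-40 bp overlapping a TATA box, or 60-80 bp overlapping the TSS
#   Pol II: 40-60 bp overlapping nonzero PRO-seq signal
#   TF: < 90 bp with no PRO-seq overlap
#   nucleosome: > 90 bp, unless the 90-200 bp TF-rescue rule applies
# Rule precedence is PIC > Pol II > TF > nucleosome so 60 bp promoter
# footprints at the TSS are not double-counted as Pol II. Sizes at exactly
# 90 bp fall through all rules and stay unclassified.

# cumulative count of PRO-seq-positive positions, per chromosome, for O(1)
# interval overlap queries
#' @keywords internal
proseq_positive_cumsum <- function(proseq, min_signal = 0) {
  lapply(proseq, function(v) cumsum(v > min_signal))
}

#' @keywords internal
has_positive_overlap <- function(cs, chrom, start, end) {
  v <- cs[[chrom]]
  if (is.null(v)) return(rep(FALSE, length(start)))
  lo <- ifelse(start <= 0L, 0, v[pmax(start, 1L)])
  (v[pmin(end, length(v))] - lo) > 0
}

#' @keywords internal
overlaps_any <- function(start, end, ref_start, ref_end) {
  if (length(ref_start) == 0L) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i)
    any(ref_start < end[i] & ref_end > start[i]), logical(1))
}

#' Transcription-factor rescue of merged sub-nucleosomal footprints
#'
#' A 90-200 bp footprint is re-called as a transcription factor when enough
#' reads carry sub-90 bp footprints whose boundaries align exactly with the
#' large footprint's boundaries -- evidence that it is a merged cluster of TF
#' footprints rather than a nucleosome.
#'
#' @param fp one-row footprint (start, end, fiber_id)
#' @param all_footprints decoded footprints from the whole fiber cohort
#' @param min_reads support threshold per end (default 50)
#' @param mode "independent" (default): each end independently needs
#'   `min_reads` supporting reads; "joint": the same read must support both
#'   ends
#' @return list(rescued = logical, n_start, n_end)
#' @export
tf_rescue <- function(fp, all_footprints, min_reads = 50L,
                      mode = c("independent", "joint")) {
  mode <- match.arg(mode)
  w <- fp$end - fp$start
  if (w <= 90L || w >= 200L)
    return(list(rescued = FALSE, n_start = 0L, n_end = 0L))
  sub <- all_footprints[(end - start) < 90L & chrom == fp$chrom &
                          fiber_id != fp$fiber_id]
  if (mode == "independent") {
    n_start <- uniqueN(sub[start == fp$start, fiber_id])
    n_end <- uniqueN(sub[end == fp$end, fiber_id])
    list(rescued = n_start >= min_reads && n_end >= min_reads,
         n_start = n_start, n_end = n_end)
  } else {
    both <- intersect(sub[start == fp$start, fiber_id],
                      sub[end == fp$end, fiber_id])
    list(rescued = length(both) >= min_reads,
         n_start = length(both), n_end = length(both))
  }
}

#' Classify decoded footprints
#'
#' @param footprints data.table: fiber_id, chrom, start, end (strand optional)
#' @param proseq coverage track (named list of numeric vectors) or NULL;
#'   without it Pol II calls are disabled with a warning
#' @param tata data.table of TATA-box intervals (chrom, start, end)
#' @param tss_sites data.table of TSS intervals (chrom, start, end)
#' @param rescue_min_reads TF-rescue support threshold
#' @param proseq_min_signal coverage strictly above this counts as signal
#' @param rescue_mode see [tf_rescue()]
#' @return the input with `class` and `evidence` columns added
#' @export
classify_footprints <- function(footprints, proseq, tata, tss_sites,
                                rescue_min_reads = 50L, proseq_min_signal = 0,
                                rescue_mode = "independent") {
  fp <- copy(as.data.table(footprints))
  if (nrow(fp) == 0L) {
    fp[, `:=`(class = character(), evidence = character())]
    return(fp)
  }
  w <- fp$end - fp$start
  if (is.null(proseq)) {
    warning("no PRO-seq track supplied; Pol II calls disabled")
    pro_hit <- rep(FALSE, nrow(fp))
  } else {
    cs <- proseq_positive_cumsum(proseq, proseq_min_signal)
    pro_hit <- logical(nrow(fp))
    for (ch in unique(fp$chrom)) {
      i <- which(fp$chrom == ch)
      pro_hit[i] <- has_positive_overlap(cs, ch, fp$start[i], fp$end[i])
    }
  }
  tata_hit <- logical(nrow(fp)); tss_hit <- logical(nrow(fp))
  for (ch in unique(fp$chrom)) {
    i <- which(fp$chrom == ch)
    if (!is.null(tata) && nrow(tata))
      tata_hit[i] <- overlaps_any(fp$start[i], fp$end[i],
                                  tata[chrom == ch, start], tata[chrom == ch, end])
    if (!is.null(tss_sites) && nrow(tss_sites))
      tss_hit[i] <- overlaps_any(fp$start[i], fp$end[i],
                                 tss_sites[chrom == ch, start],
                                 tss_sites[chrom == ch, end])
  }
  cls <- rep("unclassified", nrow(fp))
  ev <- rep("", nrow(fp))
  is_pic <- (w >= 20L & w <= 40L & tata_hit) | (w >= 60L & w <= 80L & tss_hit)
  cls[is_pic] <- "PIC"
  ev[is_pic] <- ifelse((w >= 20L & w <= 40L & tata_hit)[is_pic],
                       "20-40bp+TATA", "60-80bp+TSS")
  is_pol <- !is_pic & w >= 40L & w <= 60L & pro_hit
  cls[is_pol] <- "polII"; ev[is_pol] <- "40-60bp+PROseq"
  is_tf <- cls == "unclassified" & w < 90L & !pro_hit
  cls[is_tf] <- "TF"; ev[is_tf] <- "<90bp,no-PROseq"
  # nucleosome rule with TF rescue for 90-200 bp merged footprints.
  # Rescue support is counted once per distinct (chrom, boundary) over
  # sub-90 bp footprints, one count per read.
  is_big <- cls == "unclassified" & w > 90L
  if (any(is_big)) {
    sub <- fp[(end - start) < 90L, .(fiber_id, chrom, start, end)]
    start_support <- sub[, .(n = uniqueN(fiber_id)), by = .(chrom, start)]
    end_support <- sub[, .(n = uniqueN(fiber_id)), by = .(chrom, end)]
    setkey(start_support, chrom, start); setkey(end_support, chrom, end)
    for (i in which(is_big)) {
      if (w[i] < 200L) {
        ns <- start_support[.(fp$chrom[i], fp$start[i]), n]
        ne <- end_support[.(fp$chrom[i], fp$end[i]), n]
        ns <- if (is.na(ns)) 0L else ns
        ne <- if (is.na(ne)) 0L else ne
        # own read contributes only its sub-90 footprints, which a >90 bp
        # candidate is not, so no self-support correction is needed
        hit <- if (rescue_mode == "independent")
          ns >= rescue_min_reads && ne >= rescue_min_reads
        else {
          both <- intersect(
            fp[chrom == fp$chrom[i] & (end - start) < 90L & start == fp$start[i],
               fiber_id],
            fp[chrom == fp$chrom[i] & (end - start) < 90L & end == fp$end[i],
               fiber_id])
          length(both) >= rescue_min_reads
        }
        if (hit) {
          cls[i] <- "TF"
          ev[i] <- sprintf("TF-rescue:n=%d/%d", ns, ne)
          next
        }
      }
      cls[i] <- "nucleosome"; ev[i] <- ">90bp"
    }
  }
  fp[, `:=`(class = cls, evidence = ev)]
  fp
}

#' Per-fiber accessible regions
#'
#' The complement of nucleosome-class footprints within the fiber span;
#' TF, Pol II and PIC footprints do not interrupt accessibility.
#'
#' @param fiber one-row fiber (fiber_id, chrom, start, end)
#' @param classified classified footprints for this fiber
#' @return data.table of accessible intervals with fiber_id, chrom
#' @export
accessible_regions <- function(fiber, classified) {
  nuc <- classified[fiber_id == fiber$fiber_id & class == "nucleosome",
                    .(start, end)]
  out <- iv_complement(nuc, fiber$start, fiber$end)
  out[, `:=`(fiber_id = fiber$fiber_id, chrom = fiber$chrom)]
  setcolorder(out, c("fiber_id", "chrom", "start", "end"))
  out[]
}

#' Accessible regions for every fiber in a table
#' @param fibers fiber data.table
#' @param classified classified footprint data.table
#' @return rbound accessible-region data.table
#' @export
accessible_regions_all <- function(fibers, classified) {
  rbindlist(lapply(seq_len(nrow(fibers)), function(i)
    accessible_regions(fibers[i], classified)))
}
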