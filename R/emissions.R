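# Sequence-context-conditioned emission probabilities for the two-state
# footprint HMM. Methylation is informative only at A/T positions (adenine
# methyltransferase chemistry); each informative position is conditioned on
# its 7-mer context (center base +/- 3 bp) with a fallback hierarchy
# 7-mer -> center base -> global rate when a context was never observed in
# the controls.

#' Build a context-conditioned emission table from control counts
#'
#' Controls supply, per 7-mer context, counts of methylated and total
#' observations for the fully accessible control (dechromatinized DNA) and
#' the fully inaccessible control (untreated chromatin). Probabilities are
#' smoothed as `(methylated + pseudocount) / (total + 2 * pseudocount)`.
#'
#' @param accessible_control data.frame with columns `context` (7-mer),
#'   `methylated`, `total`
#' @param inaccessible_control same layout for the inaccessible control
#' @param pseudocount additive smoothing count (default 1)
#' @return an `emission_table` object
#' @export
build_emission_table <- function(accessible_control, inaccessible_control,
                                 pseudocount = 1.0) {
  for (ctl in list(accessible_control, inaccessible_control)) {
    if (is.null(ctl) || nrow(as.data.frame(ctl)) == 0L)
      stop("empty control dataset; emission table needs counts for both states")
    stopifnot(all(c("context", "methylated", "total") %in% names(ctl)))
  }
  acc <- as.data.table(accessible_control)
  inacc <- as.data.table(inaccessible_control)
  smooth <- function(m, t) (m + pseudocount) / (t + 2 * pseudocount)
  rate_map <- function(dt) {
    dt <- dt[, .(methylated = sum(methylated), total = sum(total)), by = context]
    setNames(smooth(dt$methylated, dt$total), dt$context)
  }
  center_map <- function(dt) {
    dt <- copy(dt)[, center := substr(context, 4L, 4L)]
    dt <- dt[, .(methylated = sum(methylated), total = sum(total)), by = center]
    setNames(smooth(dt$methylated, dt$total), dt$center)
  }
  global_rate <- function(dt) smooth(sum(dt$methylated), sum(dt$total))
  tab <- structure(list(
    type = "context",
    p_acc = rate_map(acc), p_inacc = rate_map(inacc),
    center_acc = center_map(acc), center_inacc = center_map(inacc),
    global_acc = global_rate(acc), global_inacc = global_rate(inacc),
    pseudocount = pseudocount
  ), class = "emission_table")
  validate_emission_table(tab)
  tab
}

#' Flat (context-independent) emission table
#'
#' @param p_acc P(methylated | accessible)
#' @param p_inacc P(methylated | inaccessible)
#' @return an `emission_table` object
#' @export
flat_emission_table <- function(p_acc = 0.8, p_inacc = 0.05) {
  structure(list(type = "flat", p_acc = p_acc, p_inacc = p_inacc),
            class = "emission_table")
}

#' @keywords internal
validate_emission_table <- function(tab) {
  probs <- c(tab$p_acc, tab$p_inacc, tab$global_acc, tab$global_inacc)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("emission probabilities must lie in [0, 1]")
  invisible(tab)
}

#' Look up emission rates for a set of positions
#'
#' Degenerate rates (exactly 0 or 1) are honored as stated so that
#' mask-recovery identities hold exactly; smoothing is the table builder's
#' job, not the lookup's.
#'
#' @param tab emission_table
#' @param contexts character vector of 7-mers (NA where unavailable, e.g.
#'   fiber edges)
#' @param centers character vector of center bases ("A"/"T")
#' @return list with numeric vectors `p_acc`, `p_inacc` and the count of
#'   fallback lookups in `n_fallback`
#' @export
emission_rates <- function(tab, contexts, centers) {
  stopifnot(inherits(tab, "emission_table"))
  n <- length(centers)
  if (tab$type == "flat") {
    return(list(p_acc = rep(tab$p_acc, n), p_inacc = rep(tab$p_inacc, n),
                n_fallback = 0L))
  }
  p_acc <- unname(tab$p_acc[contexts])
  p_inacc <- unname(tab$p_inacc[contexts])
  miss <- is.na(p_acc) | is.na(p_inacc)
  n_fb <- sum(miss)
  if (n_fb > 0L) {
    ca <- unname(tab$center_acc[centers[miss]])
    ci <- unname(tab$center_inacc[centers[miss]])
    ca[is.na(ca)] <- tab$global_acc
    ci[is.na(ci)] <- tab$global_inacc
    p_acc[miss] <- ca
    p_inacc[miss] <- ci
    fb_log(sprintf("emission lookup: %d/%d positions used fallback rates",
                   n_fb, n))
  }
  list(p_acc = p_acc, p_inacc = p_inacc, n_fallback = n_fb)
}
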