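# Regulatory trajectory over binary CRE-accessibility combinations: fibers
# spanning the tracked region are tabulated into combination nodes, rare
# combinations are filtered, and routes are enumerated over the graph whose
# edges connect combinations differing in exactly one element. Routes run
# from a designated initial state through the peak state to a terminal
# state, never revisit a node, and are ranked by summed read support.

#' @keywords internal
combo_key <- function(m) apply(m, 1L, paste, collapse = "")

#' Tabulate accessibility combinations
#'
#' @param access binary matrix (reads x elements; colnames = element names)
#'   with no NA rows (non-spanning reads are excluded upstream)
#' @param min_support_fraction combinations on fewer than this fraction of
#'   reads are discarded (default 0.01)
#' @param min_support_count optional absolute floor; the effective threshold
#'   is `max(min_support_fraction * total, min_support_count)`
#' @return data.table: combo (e.g. "10110"), count, plus one 0/1 column per
#'   element; attribute `total` = total reads tabulated
#' @export
tabulate_combos <- function(access, min_support_fraction = 0.01,
                            min_support_count = 0L) {
  m <- as.matrix(access)
  if (nrow(m) == 0L) stop("no reads to tabulate")
  if (anyNA(m)) stop("access matrix has NA entries; drop non-spanning reads first")
  storage.mode(m) <- "integer"
  keys <- combo_key(m)
  counts <- table(keys)
  thr <- max(min_support_fraction * nrow(m), min_support_count)
  keep <- counts[counts >= thr]
  if (length(keep) == 0L)
    return(structure(data.table(combo = character(), count = integer()),
                     total = nrow(m)))
  out <- data.table(combo = names(keep), count = as.integer(keep))
  bits <- do.call(rbind, strsplit(out$combo, "", fixed = TRUE))
  bits <- matrix(as.integer(bits), nrow = nrow(out))
  colnames(bits) <- colnames(m) %||% paste0("e", seq_len(ncol(m)))
  out <- cbind(out, as.data.table(bits))
  setorder(out, -count, combo)
  setattr(out, "total", nrow(m))
  out[]
}

#' @keywords internal
hamming1 <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]]) == 1L
}

#' Enumerate regulatory routes
#'
#' Depth-first enumeration of all simple paths from `initial` to any of
#' `terminals` over the Hamming-distance-1 graph of retained combination
#' nodes, constrained (by default) to pass through `peak`. Terminals are
#' absorbing. Routes are ranked by summed read support over their nodes,
#' ties broken by shorter route, then lexicographically.
#'
#' @param nodes data.table from [tabulate_combos()] (combo, count)
#' @param initial,peak character combos (e.g. "10000", "11111")
#' @param terminals character vector of terminal combos
#' @param require_peak if FALSE the peak-passage constraint is dropped
#' @param support "sum" (default) or "min" of node counts along the route
#' @return data.table: rank, support, length, route (">"-joined combos)
#' @export
enumerate_routes <- function(nodes, initial, peak, terminals,
                             require_peak = TRUE,
                             support = c("sum", "min")) {
  support <- match.arg(support)
  combos <- nodes$combo
  counts <- setNames(nodes$count, combos)
  for (anchor in c(initial = initial, peak = if (require_peak) peak,
                   setNames(terminals, rep("terminal", length(terminals))))) {
    if (!anchor %in% combos)
      stop("anchor state ", anchor, " is absent from the filtered nodes")
  }
  n <- length(combos)
  adj <- lapply(seq_len(n), function(i)
    which(vapply(seq_len(n), function(j)
      i != j && hamming1(combos[i], combos[j]), logical(1))))
  idx <- setNames(seq_len(n), combos)
  routes <- list()
  visited <- rep(FALSE, n)
  dfs <- function(v, path) {
    visited[v] <<- TRUE
    if (combos[v] %in% terminals && length(path) > 1L) {
      if (!require_peak || peak %in% combos[path])
        routes[[length(routes) + 1L]] <<- combos[path]
      # terminals are absorbing: do not extend past them
    } else {
      for (u in adj[[v]]) if (!visited[u]) dfs(u, c(path, u))
    }
    visited[v] <<- FALSE
  }
  dfs(idx[[initial]], idx[[initial]])
  if (length(routes) == 0L) {
    fb_log("no route from ", initial, " to any terminal")
    return(data.table(rank = integer(), support = integer(),
                      length = integer(), route = character()))
  }
  supp <- vapply(routes, function(r)
    if (support == "sum") sum(counts[r]) else min(counts[r]), numeric(1))
  len <- lengths(routes)
  key <- vapply(routes, paste, character(1), collapse = ">")
  ord <- order(-supp, len, key)
  data.table(rank = seq_along(ord), support = supp[ord],
             length = len[ord], route = key[ord])
}

#' Assign fibers to the stages of a route
#'
#' @param route character vector of combos, or one row of the
#'   [enumerate_routes()] table
#' @param access binary matrix (reads x elements, rownames = fiber ids)
#' @param state_calls optional StateCall table for per-stage aggregates
#' @return list: `stages` (fiber_id, combo, stage; stage NA = off-route),
#'   `summary` (per-node fiber counts and optional aggregates)
#' @export
annotate_stages <- function(route, access, state_calls = NULL) {
  if (is.data.frame(route)) route <- strsplit(route$route[1], ">", fixed = TRUE)[[1]]
  keys <- combo_key(as.matrix(access))
  stage <- match(keys, route)
  stages <- data.table(fiber_id = rownames(access) %||% seq_along(keys),
                       combo = keys, stage = stage)
  grouped <- copy(stages)
  grouped[is.na(stage), combo := "off-route"]
  summary <- grouped[, .(n = .N), by = .(stage, combo)][order(stage)]
  if (!is.null(state_calls)) {
    sc <- as.data.table(state_calls)
    joined <- merge(stages, sc, by = "fiber_id")
    agg <- joined[, .(mean_polII = mean(n_polII),
                      hyperburst_fraction = mean(burst_class == "active" |
                                                   burst_class == "refractory")),
                  by = stage]
    summary <- merge(summary, agg, by = "stage", all.x = TRUE)
  }
  list(stages = stages, summary = summary[])
}
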