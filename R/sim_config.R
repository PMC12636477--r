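# Configuration for the synthetic fiber generator. Defaults encode the
# generative assumptions the downstream stages are specified against:
# 147 bp nucleosomes, ~40 bp linkers (Drosophila nucleosome repeat length
# ~187 bp), 40-60 bp Pol II footprints whose convoy center-to-center spacing
# averages ~60 bp, hyperburst eviction of the first 1.5 kb of gene body, and
# CRE accessibility probabilities that co-vary with transcription state.

#' Default cis-regulatory element layout
#'
#' Three upstream elements with per-state accessibility probabilities.
#' Columns: `label`, `offset` (bp from TSS, negative = upstream), `width`,
#' and one `p_<state>` column per transcription state.
#'
#' @export
default_cre_layout <- function() {
  data.table(
    label = c("E1", "E2", "E3"),
    offset = c(-6000L, -3000L, -800L),
    width = c(200L, 200L, 200L),
    p_off = c(0.10, 0.10, 0.10),
    p_poised = c(0.50, 0.50, 0.50),
    p_elongating = c(0.60, 0.60, 0.60),
    p_hyperburst = c(0.95, 0.95, 0.95),
    p_refractory = c(0.95, 0.95, 0.95),
    p_terminating = c(0.60, 0.60, 0.60)
  )
}

#' Build and validate a simulation configuration
#'
#' @param genome_length total reference length (bp)
#' @param n_genes number of genes to place
#' @param gene_length gene body length (bp)
#' @param n_fibers_per_gene fibers simulated per gene
#' @param nucleosome_size planted nucleosome footprint size (bp, default 147)
#' @param linker_mean mean linker length (bp); linkers are truncated-geometric
#'   with minimum `linker_min`
#' @param linker_min minimum linker length (bp)
#' @param polII_size_range inclusive bp range of Pol II footprint sizes
#' @param convoy_gap_range inclusive bp range of edge-to-edge gaps between
#'   convoy members
#' @param convoy_size_range inclusive range of Pol II count per convoy
#' @param p_state named probability vector over the six transcription states
#' @param cre_layout data.frame as in [default_cre_layout()]
#' @param meth_rate_accessible P(methylated | accessible) at A/T positions
#' @param meth_rate_inaccessible P(methylated | footprinted)
#' @param context_emissions if TRUE, per-7-mer heterogeneous rates are derived
#'   deterministically around the flat rates
#' @param fiber_pad_up bp of fiber upstream of the TSS (covers the 10 kb
#'   CRE discovery window and the 9 kb regression window)
#' @param fiber_pad_down bp of fiber past the gene end (covers the 500 bp
#'   termination window)
#' @param tf_in_cre_prob probability an accessible CRE carries a planted TF
#'   footprint
#' @param tf_size_range inclusive bp range of planted TF footprints
#' @param proseq_noise uniform per-bp noise added to the PRO-seq track
#' @param strands "+" (default), "-" or "random" gene strands
#' @param seed integer; fully determines the generator output
#' @return a validated `sim_config` object
#' @export
sim_config <- function(genome_length = 150000L,
                       n_genes = 2L,
                       gene_length = 2000L,
                       n_fibers_per_gene = 60L,
                       nucleosome_size = 147L,
                       linker_mean = 40,
                       linker_min = 5L,
                       polII_size_range = c(41L, 60L),
                       convoy_gap_range = c(5L, 15L),
                       convoy_size_range = c(2L, 5L),
                       p_state = c(off = 0.35, poised = 0.15,
                                   elongating = 0.20, hyperburst = 0.10,
                                   refractory = 0.10, terminating = 0.10),
                       cre_layout = default_cre_layout(),
                       meth_rate_accessible = 0.8,
                       meth_rate_inaccessible = 0.05,
                       context_emissions = FALSE,
                       fiber_pad_up = 10500L,
                       fiber_pad_down = 600L,
                       tf_in_cre_prob = 0.7,
                       tf_size_range = c(20L, 35L),
                       proseq_noise = 0,
                       strands = "+",
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  with(cfg, {
    if (abs(sum(p_state) - 1) > 1e-8)
      stop("p_state must sum to 1")
    if (any(p_state < 0 | p_state > 1))
      stop("p_state entries must be probabilities")
    if (!setequal(names(p_state), .state_levels))
      stop("p_state must be named over: ", paste(.state_levels, collapse = ", "))
    if (nucleosome_size <= 90)
      stop("nucleosome_size must exceed 90 bp (the nucleosome size rule)")
    if (polII_size_range[1] <= 40 || polII_size_range[2] > 60)
      stop("polII_size_range must lie within (40, 60] to match the Pol II size rule")
    if (linker_mean < linker_min) stop("linker_mean must be >= linker_min")
    probs <- unlist(cre_layout[, grep("^p_", names(cre_layout)), with = FALSE])
    if (any(probs < 0 | probs > 1)) stop("cre_layout probabilities must be in [0,1]")
    if (meth_rate_accessible < 0 || meth_rate_accessible > 1 ||
        meth_rate_inaccessible < 0 || meth_rate_inaccessible > 1)
      stop("methylation rates must be in [0,1]")
    if (!strands %in% c("+", "-", "random")) stop("strands must be +, - or random")
  })
  cfg$p_state <- cfg$p_state[.state_levels]
  cfg
}

#' Emission table implied by a simulation configuration
#'
#' Flat configurations give a context-independent table; with
#' `context_emissions = TRUE` each A/T-centered 7-mer gets a deterministic
#' logit-scale perturbation of the flat rates, so the context machinery is
#' exercised without changing the marginal rates much.
#'
#' @param config `sim_config`
#' @return an `emission_table`
#' @export
sim_emission_table <- function(config) {
  if (!config$context_emissions)
    return(flat_emission_table(config$meth_rate_accessible,
                               config$meth_rate_inaccessible))
  flanks <- do.call(expand.grid, c(rep(list(c("A", "C", "G", "T")), 6),
                                   stringsAsFactors = FALSE))
  ctx <- c(paste0(do.call(paste0, flanks[, 1:3]), "A",
                  do.call(paste0, flanks[, 4:6])),
           paste0(do.call(paste0, flanks[, 1:3]), "T",
                  do.call(paste0, flanks[, 4:6])))
  z <- vapply(ctx, function(s) {
    h <- as.integer(charToRaw(s))
    (sum(h * seq_along(h)) %% 101) / 101 - 0.5  # deterministic in [-0.5, 0.5)
  }, numeric(1))
  jitter_rate <- function(p) stats::plogis(stats::qlogis(p) + z)
  structure(list(
    type = "context",
    p_acc = setNames(jitter_rate(config$meth_rate_accessible), ctx),
    p_inacc = setNames(jitter_rate(config$meth_rate_inaccessible), ctx),
    center_acc = c(A = config$meth_rate_accessible, T = config$meth_rate_accessible),
    center_inacc = c(A = config$meth_rate_inaccessible, T = config$meth_rate_inaccessible),
    global_acc = config$meth_rate_accessible,
    global_inacc = config$meth_rate_inaccessible,
    pseudocount = 0
  ), class = "emission_table")
}
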