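# Synthetic fiber generator. Every fiber is built in TSS-relative
# "along-strand" coordinates u (u = 0 at the TSS, increasing into the gene
# body), planted as non-overlapping footprints plus forced-accessible
# intervals, then mapped to genomic coordinates. Methylation calls are drawn
# per A/T position conditional on the planted accessibility mask, so at
# degenerate rates (1/0) the calls equal the mask exactly and every
# downstream stage can be checked against planted truth.

# map an along-strand half-open interval to genomic coordinates
#' @keywords internal
map_u <- function(gene, u1, u2) {
  if (identical(gene$strand, "-")) {
    c(as.integer(gene$tss - u2), as.integer(gene$tss - u1))
  } else {
    c(as.integer(gene$tss + u1), as.integer(gene$tss + u2))
  }
}

#' Simulate a reference genome with gene and CRE annotations
#'
#' Genes are placed on non-overlapping slots, each slot holding the upstream
#' regulatory window, the gene body, and the downstream termination pad.
#' CREs are placed per the configured layout upstream of each TSS; a TATA
#' box is annotated 25-35 bp upstream of each TSS.
#'
#' @param config a [sim_config()] object
#' @return list with `reference` (named character vector), `genes`, `cres`,
#'   `tata`, `tss_sites` (data.tables, BED-convention coordinates)
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  slot <- config$fiber_pad_up + config$gene_length + config$fiber_pad_down
  need <- config$n_genes * (slot + 100L)
  if (config$genome_length < need)
    stop(sprintf(paste0("layout overflow: %d genes with %d bp slots need ",
                        ">= %d bp but genome_length = %d; genes would overlap"),
                 config$n_genes, slot, need, config$genome_length))
  set.seed(config$seed)
  seq_chr <- paste(sample(c("A", "C", "G", "T"), config$genome_length,
                          replace = TRUE), collapse = "")
  genes <- vector("list", config$n_genes)
  cres <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    slot0 <- (g - 1L) * (slot + 100L) + 50L
    strand <- switch(config$strands, "random" = sample(c("+", "-"), 1L),
                     config$strands)
    if (strand == "+") {
      tss <- slot0 + config$fiber_pad_up
      gstart <- tss; gend <- tss + config$gene_length
    } else {
      tss <- slot0 + config$fiber_pad_down + config$gene_length
      gstart <- tss - config$gene_length; gend <- tss
    }
    gene_id <- sprintf("gene%02d", g)
    genes[[g]] <- data.table(gene_id = gene_id, chrom = "chrS",
                             start = as.integer(gstart), end = as.integer(gend),
                             strand = strand, tss = as.integer(tss))
    lay <- as.data.table(config$cre_layout)
    iv <- t(vapply(seq_len(nrow(lay)), function(i)
      map_u(genes[[g]], lay$offset[i], lay$offset[i] + lay$width[i]),
      integer(2)))
    cres[[g]] <- data.table(cre_id = paste0(gene_id, "_", lay$label),
                            gene_id = gene_id, chrom = "chrS",
                            start = iv[, 1], end = iv[, 2], strand = strand,
                            label = lay$label)
  }
  genes <- rbindlist(genes)
  cres <- rbindlist(cres)
  tata <- genes[, {
    iv <- map_u(.SD, -35L, -25L)
    .(chrom = chrom, start = iv[1], end = iv[2], gene_id = gene_id,
      strand = strand)
  }, by = seq_len(nrow(genes))][, !"seq_len"]
  tss_sites <- genes[, .(chrom, start = tss, end = tss + 1L, gene_id, strand)]
  list(reference = c(chrS = seq_chr), genes = genes, cres = cres,
       tata = tata, tss_sites = tss_sites)
}

# truncated-geometric linker sampler (minimum linker_min, mean linker_mean)
#' @keywords internal
sample_linker <- function(n, config) {
  extra <- config$linker_mean - config$linker_min
  p <- 1 / (extra + 1)
  config$linker_min + rgeom(n, p)
}

# tile free intervals (data.table start/end, along-strand u) with nucleosomes
#' @keywords internal
tile_nucleosomes <- function(free, config) {
  out_s <- integer(0); out_e <- integer(0)
  nsz <- config$nucleosome_size
  for (i in seq_len(nrow(free))) {
    pos <- free$start[i]
    # leading linker so nucleosome phase varies fiber to fiber
    pos <- pos + sample_linker(1L, config)
    while (pos + nsz <= free$end[i]) {
      out_s <- c(out_s, pos); out_e <- c(out_e, pos + nsz)
      pos <- pos + nsz + sample_linker(1L, config)
    }
  }
  data.table(start = as.integer(out_s), end = as.integer(out_e),
             class = rep("nucleosome", length(out_s)))
}

#' Simulate one fiber for a gene in a given transcription state
#'
#' Plants state-specific footprints (PIC, paused/elongating Pol II convoys,
#' TF footprints inside accessible CREs), evicts nucleosomes where the state
#' requires it, tiles the rest with nucleosomes, and draws methylation calls
#' at A/T positions from the accessible/inaccessible rates.
#'
#' @param gene one-row gene data.table (with `tss`)
#' @param cres CRE annotation rows for this gene
#' @param state one of off, poised, elongating, hyperburst, refractory,
#'   terminating
#' @param config `sim_config`
#' @param reference named character vector of sequences
#' @param fiber_id identifier for the new fiber
#' @param emissions emission table used to draw methylation calls
#' @return list with `fiber` (one-row data.table, `meth` list column),
#'   `footprints` (planted truth), `cre_access` (per-CRE 0/1)
#' @export
simulate_fiber <- function(gene, cres, state, config, reference,
                           fiber_id = "fiber1",
                           emissions = sim_emission_table(config)) {
  if (!state %in% .state_levels)
    stop("unknown transcription state: ", state)
  lay <- as.data.table(config$cre_layout)
  if (nrow(lay) != nrow(cres))
    stop("configuration error: cre_layout does not match the gene's CREs")
  glen <- gene$end - gene$start
  span_u <- c(-config$fiber_pad_up, glen + config$fiber_pad_down)
  open <- list()   # forced-accessible intervals, along-strand
  fps <- list()    # planted footprints: start, end, class (along-strand)

  # CRE accessibility draws
  pcol <- paste0("p_", state)
  if (!pcol %in% names(lay))
    stop("configuration error: cre_layout lacks column ", pcol,
         " for state ", state)
  cre_acc <- rbinom(nrow(lay), 1L, lay[[pcol]])
  for (i in seq_len(nrow(lay))) {
    if (cre_acc[i] == 1L) {
      u1 <- lay$offset[i]; u2 <- u1 + lay$width[i]
      if (runif(1) < config$tf_in_cre_prob) {
        w <- sample(config$tf_size_range[1]:config$tf_size_range[2], 1L)
        ts <- u1 + sample.int(lay$width[i] - w, 1L) - 1L
        fps[[length(fps) + 1L]] <- data.table(start = ts, end = ts + w,
                                              class = "TF")
        open[[length(open) + 1L]] <- data.table(start = c(u1, ts + w),
                                                end = c(ts, u2))
      } else {
        open[[length(open) + 1L]] <- data.table(start = u1, end = u2)
      }
    }
  }

  hb_len <- min(1500L, glen)
  transcribed <- state %in% c("poised", "elongating", "hyperburst", "terminating")
  if (state != "off") {
    # open promoter; PIC occupies part of it for transcribing states
    if (transcribed) {
      fps[[length(fps) + 1L]] <- data.table(start = -40L, end = -10L,
                                            class = "PIC")
      open[[length(open) + 1L]] <- data.table(start = c(-150L, -10L),
                                              end = c(-40L, 0L))
    } else {
      open[[length(open) + 1L]] <- data.table(start = -150L, end = 0L)
    }
  }
  if (state %in% c("hyperburst", "refractory")) {
    open[[length(open) + 1L]] <- data.table(start = 0L, end = hb_len)
  }

  plant_convoy <- function(u0) {
    k <- sample(config$convoy_size_range[1]:config$convoy_size_range[2], 1L)
    sizes <- sample(config$polII_size_range[1]:config$polII_size_range[2], k,
                    replace = TRUE)
    gaps <- sample(config$convoy_gap_range[1]:config$convoy_gap_range[2],
                   max(k - 1L, 0L), replace = TRUE)
    s <- u0 + c(0L, cumsum(sizes[-k] + gaps))
    data.table(start = as.integer(s), end = as.integer(s + sizes),
               class = "polII")
  }
  max_convoy_span <- config$convoy_size_range[2] *
    (config$polII_size_range[2] + config$convoy_gap_range[2])
  if (state == "poised") {
    fps[[length(fps) + 1L]] <- data.table(start = 2L, end = 52L, class = "polII")
  } else if (state == "elongating") {
    u0 <- sample(seq.int(200L, max(201L, glen - max_convoy_span - 50L)), 1L)
    fps[[length(fps) + 1L]] <- plant_convoy(u0)
  } else if (state == "hyperburst") {
    c1 <- plant_convoy(100L)
    u0 <- max(c1$end) + 150L
    fps[[length(fps) + 1L]] <- c1
    if (u0 + max_convoy_span < hb_len - 50L)
      fps[[length(fps) + 1L]] <- plant_convoy(u0)
  } else if (state == "terminating") {
    u0 <- sample(seq.int(200L, max(201L, glen - max_convoy_span - 50L)), 1L)
    fps[[length(fps) + 1L]] <- plant_convoy(u0)
    fps[[length(fps) + 1L]] <- data.table(start = glen + 20L, end = glen + 70L,
                                          class = "polII")
  }

  fps <- if (length(fps)) rbindlist(fps) else
    data.table(start = integer(), end = integer(), class = character())
  open <- if (length(open)) rbindlist(open) else
    data.table(start = integer(), end = integer())
  open <- open[end > start]

  # nucleosome tiling of everything not forced open or already footprinted
  blocked <- rbind(open[, .(start, end)], fps[, .(start, end)])
  free <- iv_complement(blocked, span_u[1], span_u[2])
  nucs <- tile_nucleosomes(free, config)
  fps <- rbind(fps, nucs)[order(start)]
  stopifnot(all(fps$start >= span_u[1]), all(fps$end <= span_u[2]),
            all(head(fps$end, -1L) <= tail(fps$start, -1L)))

  # map to genomic coordinates
  span_g <- map_u(gene, span_u[1], span_u[2])
  iv <- t(vapply(seq_len(nrow(fps)),
                 function(i) map_u(gene, fps$start[i], fps$end[i]),
                 integer(2)))
  fp_g <- data.table(fiber_id = fiber_id, chrom = gene$chrom,
                     start = if (nrow(fps)) iv[, 1] else integer(),
                     end = if (nrow(fps)) iv[, 2] else integer(),
                     class = fps$class)[order(start)]

  # methylation draws over the accessibility mask
  seqs <- get_sequence(reference, gene$chrom, span_g[1], span_g[2])
  bases <- strsplit(seqs, "", fixed = TRUE)[[1]]
  L <- length(bases)
  info <- which(bases == "A" | bases == "T")
  inaccessible <- rep(FALSE, L)
  for (i in seq_len(nrow(fp_g)))
    inaccessible[(fp_g$start[i] - span_g[1] + 1L):(fp_g$end[i] - span_g[1])] <- TRUE
  ctx <- rep(NA_character_, length(info))
  if (emissions$type == "context") {
    inner <- info >= 4L & info <= L - 3L
    ctx[inner] <- substring(seqs, info[inner] - 3L, info[inner] + 3L)
  }
  rates <- emission_rates(emissions, ctx, bases[info])
  p <- ifelse(inaccessible[info], rates$p_inacc, rates$p_acc)
  meth <- info[runif(length(info)) < p] - 1L  # 0-based fiber-relative offsets

  fiber <- data.table(fiber_id = fiber_id, chrom = gene$chrom,
                      start = span_g[1], end = span_g[2],
                      strand = gene$strand, gene_id = gene$gene_id,
                      true_state = state, meth = list(as.integer(meth)))
  cre_dt <- data.table(fiber_id = fiber_id, cre_id = cres$cre_id,
                       accessible = as.integer(cre_acc))
  list(fiber = fiber, footprints = fp_g, cre_access = cre_dt)
}

#' Simulate a full dataset: genome, fibers, truth, PRO-seq track
#'
#' @param config `sim_config`; `config$seed` fully determines the output
#' @return list with `reference`, `genes`, `cres`, `tata`, `tss_sites`,
#'   `fibers`, `truth_footprints`, `truth_cre`, `proseq`, `emissions`,
#'   `config`
#' @export
simulate_dataset <- function(config = sim_config()) {
  genome <- simulate_genome(config)   # seeds the RNG with config$seed
  emissions <- sim_emission_table(config)
  fibers <- list(); fps <- list(); cre <- list()
  n <- 0L
  for (g in seq_len(nrow(genome$genes))) {
    gene <- genome$genes[g]
    gcres <- genome$cres[gene_id == gene$gene_id]
    states <- sample(.state_levels, config$n_fibers_per_gene, replace = TRUE,
                     prob = config$p_state)
    for (j in seq_len(config$n_fibers_per_gene)) {
      n <- n + 1L
      sim <- simulate_fiber(gene, gcres, states[j], config, genome$reference,
                            fiber_id = sprintf("f%05d", n),
                            emissions = emissions)
      fibers[[n]] <- sim$fiber; fps[[n]] <- sim$footprints
      cre[[n]] <- sim$cre_access
    }
  }
  fibers <- rbindlist(fibers)
  truth_footprints <- rbindlist(fps)
  proseq <- simulate_proseq(genome, truth_footprints, noise = config$proseq_noise)
  list(reference = genome$reference, genes = genome$genes, cres = genome$cres,
       tata = genome$tata, tss_sites = genome$tss_sites, fibers = fibers,
       truth_footprints = truth_footprints, truth_cre = rbindlist(cre),
       proseq = proseq, emissions = emissions, config = config)
}

#' Simulate a PRO-seq-like coverage track from planted Pol II footprints
#'
#' Per-bp counts equal the number of planted Pol II footprints covering each
#' position, plus optional uniform noise.
#'
#' @param genome output of [simulate_genome()] (for sequence lengths)
#' @param truth_footprints planted footprint table
#' @param noise nonnegative uniform noise ceiling added per bp
#' @return a coverage track: named list of numeric vectors (one per sequence)
#' @export
simulate_proseq <- function(genome, truth_footprints, noise = 0) {
  track <- lapply(genome$reference, function(s) numeric(nchar(s)))
  pol <- truth_footprints[class == "polII"]
  for (i in seq_len(nrow(pol))) {
    ch <- pol$chrom[i]
    idx <- (pol$start[i] + 1L):pol$end[i]
    track[[ch]][idx] <- track[[ch]][idx] + 1
  }
  if (noise > 0)
    track <- lapply(track, function(v) v + runif(length(v), 0, noise))
  track
}

#' Simulate two-population fluorescence traces
#'
#' Each measurement is drawn from a two-component Gaussian mixture; truth
#' labels are retained for recovery tests.
#'
#' @param n_cells,n_timepoints trace dimensions
#' @param active_fraction mixture weight of the high-mean (active) component
#' @param mu_off,mu_on component means (mu_on > mu_off)
#' @param sd shared component standard deviation (> 0)
#' @param seed RNG seed
#' @return data.table: cell_id, timepoint, value, truth_active
#' @export
simulate_fluorescence <- function(n_cells = 1541L, n_timepoints = 181L,
                                  active_fraction = 0.16, mu_off = 0,
                                  mu_on = 10, sd = 1, seed = 1L) {
  if (sd <= 0) stop("sd must be positive")
  if (mu_on <= mu_off) stop("mu_on must exceed mu_off")
  if (active_fraction < 0 || active_fraction > 1)
    stop("active_fraction must be in [0,1]")
  set.seed(seed)
  n <- n_cells * n_timepoints
  active <- runif(n) < active_fraction
  value <- rnorm(n, ifelse(active, mu_on, mu_off), sd)
  data.table(cell_id = rep(sprintf("cell%04d", seq_len(n_cells)),
                           each = n_timepoints),
             timepoint = rep(seq_len(n_timepoints) - 1L, n_cells),
             value = value, truth_active = as.integer(active))
}
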