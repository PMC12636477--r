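# Pipeline configuration and the end-to-end driver: simulate -> footprints
# -> classify -> states -> peaks -> regress -> trajectory -> motifs. Each
# stage reads/writes plain-text files under the configured output
# directory; identical config + seed reproduce the outputs byte for byte.

#' Default pipeline configuration
#'
#' Stage parameter blocks mirror the module function arguments. Unknown
#' keys are rejected at validation.
#'
#' @return nested list of defaults
#' @export
default_pipeline_config <- function() {
  list(
    out_dir = "fiberburst_out",
    seed = 1L,
    log_level = "info",
    simulate = list(enabled = TRUE, config = list()),
    footprints = list(pseudocount = 1.0, decoder = "viterbi",
                      self_transition = 0.95),
    classify = list(rescue_min_reads = 50L, proseq_min_signal = 0,
                    rescue_mode = "independent"),
    states = list(max_gap = 100L, bootstrap_reps = 1000L,
                  eviction_bins = c(0, 0.25, 0.5, 0.75, 1)),
    peaks = list(window = 10000L, min_width = 20L, height_frac = 0.2,
                 access_threshold = 0.5, smooth_bp = 12L,
                 baseline = "median"),
    regress = list(k_folds = 5L, n_perm = 50L, synergy_k = 2L,
                   window = 9000L, C = 1.0),
    trajectory = list(min_support = 0.01, require_peak = TRUE),
    motifs = list(threshold = 2.0, pseudocount = 0.8,
                  min_footprint_frac = 0.05,
                  pfm_file = NULL,
                  activators = c("bcd", "cad", "dl", "vfl"),
                  repressors = c("hb", "Kr", "run", "odd"))
  )
}

#' Load and validate a pipeline configuration
#'
#' @param config named list of overrides, or a path to a JSON file of them
#' @return validated config list
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (blk in names(config)) {
    if (is.list(defaults[[blk]]) && !is.null(names(defaults[[blk]]))) {
      bad <- setdiff(names(config[[blk]]),
                     c(names(defaults[[blk]]), if (blk == "simulate") "config"))
      if (length(bad))
        stop("unknown keys in '", blk, "': ", paste(bad, collapse = ", "))
    }
  }
  cfg <- modifyList(defaults, config)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @keywords internal
stage_log <- function(cfg, stage, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible(NULL))
  message(sprintf("[fiberburst:%s] %s", stage, paste0(...)))
}

#' Run the full pipeline
#'
#' @param config see [pipeline_config()]
#' @param stop_after optional stage name ("simulate", "footprints",
#'   "classify", "states", "peaks", "regress", "trajectory", "motifs");
#'   earlier stages always run since each stage consumes its predecessors
#' @return invisibly, a list of key in-memory results; writes all stage
#'   outputs plus a `run_summary.json` and a provenance copy of the config
#'   under `out_dir`
#' @export
run_pipeline <- function(config = list(), stop_after = NULL) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = cfg$seed, stages = list())
  jsonlite::write_json(cfg, file.path(cfg$out_dir, "config_used.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  finish <- function(value) {
    jsonlite::write_json(summary, file.path(cfg$out_dir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(value)
  }
  run_stage <- function(name, fun) {
    stage_log(cfg, name, "starting")
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline halted at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE))
    summary$stages[[name]] <<- res$counts
    stage_log(cfg, name, "done")
    res$value
  }

  # --- simulate ------------------------------------------------------------
  sim <- run_stage("simulate", function() {
    sc <- do.call(sim_config, modifyList(cfg$simulate$config,
                                         list(seed = cfg$seed)))
    ds <- simulate_dataset(sc)
    write_fasta(ds$reference, file.path(cfg$out_dir, "reference.fa"))
    write_bed(ds$genes[, .(chrom, start, end, name = gene_id, strand)],
              file.path(cfg$out_dir, "genes.bed"), name_col = "name",
              seed = cfg$seed, params = sc)
    write_bed(ds$cres[, .(chrom, start, end, name = cre_id, strand)],
              file.path(cfg$out_dir, "cres_truth.bed"), name_col = "name",
              seed = cfg$seed, params = sc)
    write_bed(ds$tata[, .(chrom, start, end, name = gene_id, strand)],
              file.path(cfg$out_dir, "tata.bed"), name_col = "name",
              seed = cfg$seed, params = sc)
    write_bed(ds$tss_sites[, .(chrom, start, end, name = gene_id, strand)],
              file.path(cfg$out_dir, "tss.bed"), name_col = "name",
              seed = cfg$seed, params = sc)
    write_fiber_table(ds$fibers, file.path(cfg$out_dir, "fibers.tsv"),
                      seed = cfg$seed, params = sc)
    write_tsv(ds$truth_footprints,
              file.path(cfg$out_dir, "truth_footprints.tsv"),
              provenance_header(cfg$seed, sc))
    write_tsv(ds$truth_cre, file.path(cfg$out_dir, "truth_cre.tsv"),
              provenance_header(cfg$seed, sc))
    write_bedgraph(ds$proseq, file.path(cfg$out_dir, "proseq.bedgraph"),
                   seed = cfg$seed, params = sc)
    list(value = ds, counts = list(n_fibers = nrow(ds$fibers),
                                   n_genes = nrow(ds$genes)))
  })

  if (identical(stop_after, "simulate")) return(finish(list(sim = sim, config = cfg)))

  # --- footprints ----------------------------------------------------------
  decoded <- run_stage("footprints", function() {
    p <- cfg$footprints$self_transition
    params <- hmm_params(trans = matrix(c(p, 1 - p, 1 - p, p), 2, 2,
                                        byrow = TRUE),
                         emissions = sim$emissions)
    segs <- decode_fibers(sim$fibers, sim$reference, params,
                          decoder = cfg$footprints$decoder)
    fp <- footprints_from_path(segs)
    write_tsv(segs, file.path(cfg$out_dir, "segments.tsv"),
              provenance_header(cfg$seed, cfg$footprints))
    fpb <- copy(fp$footprints)[, score := pmin(1000L, end - start)]
    write_bed(fpb, file.path(cfg$out_dir, "footprints.bed"),
              name_col = "fiber_id", score_col = "score",
              seed = cfg$seed, params = cfg$footprints)
    list(value = fp, counts = list(n_footprints = nrow(fp$footprints)))
  })

  if (identical(stop_after, "footprints")) return(finish(list(decoded = decoded, config = cfg)))

  # --- classify ------------------------------------------------------------
  classified <- run_stage("classify", function() {
    cl <- classify_footprints(decoded$footprints, sim$proseq, sim$tata,
                              sim$tss_sites,
                              rescue_min_reads = cfg$classify$rescue_min_reads,
                              proseq_min_signal = cfg$classify$proseq_min_signal,
                              rescue_mode = cfg$classify$rescue_mode)
    write_tsv(cl, file.path(cfg$out_dir, "classified_footprints.tsv"),
              provenance_header(cfg$seed, cfg$classify))
    list(value = cl, counts = as.list(table(cl$class)))
  })

  if (identical(stop_after, "classify")) return(finish(list(classified = classified, config = cfg)))

  access <- accessible_regions_all(sim$fibers, classified)

  # --- states --------------------------------------------------------------
  states <- run_stage("states", function() {
    calls <- list(); kin <- list()
    for (g in seq_len(nrow(sim$genes))) {
      gene <- sim$genes[g]
      sc <- assign_states(sim$fibers, gene, classified, access,
                          max_gap = cfg$states$max_gap)
      calls[[g]] <- sc
      kin[[g]] <- kinetics(gene, sc, classified,
                           eviction_bins = cfg$states$eviction_bins,
                           n_boot = cfg$states$bootstrap_reps,
                           seed = cfg$seed,
                           max_gap = cfg$states$max_gap)$summary
    }
    calls <- rbindlist(calls); kin <- rbindlist(kin)
    # convoy spans as BED (name = fiber, score = convoy size)
    conv_rows <- list()
    for (g in seq_len(nrow(sim$genes))) {
      gene <- sim$genes[g]
      body <- gene_windows(gene)$body
      for (fid in calls[gene_id == gene$gene_id & n_convoys >= 1L, fiber_id]) {
        cvs <- detect_convoys(classified[fiber_id == fid & class == "polII"],
                              body, max_gap = cfg$states$max_gap)
        for (cv in cvs)
          conv_rows[[length(conv_rows) + 1L]] <- data.table(
            chrom = gene$chrom, start = min(cv$members$start),
            end = max(cv$members$end), name = fid, score = cv$size,
            strand = gene$strand)
      }
    }
    conv_dt <- if (length(conv_rows)) rbindlist(conv_rows) else
      data.table(chrom = character(), start = integer(), end = integer(),
                 name = character(), score = integer(), strand = character())
    write_bed(conv_dt, file.path(cfg$out_dir, "convoys.bed"),
              name_col = "name", score_col = "score",
              seed = cfg$seed, params = cfg$states)
    write_tsv(calls, file.path(cfg$out_dir, "state_calls.tsv"),
              provenance_header(cfg$seed, cfg$states))
    write_tsv(kin, file.path(cfg$out_dir, "kinetics.tsv"),
              provenance_header(cfg$seed, cfg$states))
    list(value = calls, counts = list(n_calls = nrow(calls)))
  })

  if (identical(stop_after, "states")) return(finish(list(states = states, config = cfg)))

  # --- peaks ---------------------------------------------------------------
  peaks <- run_stage("peaks", function() {
    pk <- rbindlist(lapply(seq_len(nrow(sim$genes)), function(g)
      discover_cres(sim$fibers, access, sim$genes[g],
                    window_bp = cfg$peaks$window,
                    min_width = cfg$peaks$min_width,
                    height_frac = cfg$peaks$height_frac,
                    smooth_bp = cfg$peaks$smooth_bp,
                    baseline = cfg$peaks$baseline)), fill = TRUE)
    pk[, chrom := sim$genes$chrom[1]]
    pk[, score := as.integer(round(height * 1000))]
    pk[, strand := "+"]
    write_bed(pk, file.path(cfg$out_dir, "peaks.bed"), name_col = "label",
              score_col = "score", seed = cfg$seed, params = cfg$peaks)
    list(value = pk, counts = list(n_peaks = nrow(pk)))
  })

  if (identical(stop_after, "peaks")) return(finish(list(peaks = peaks, config = cfg)))

  matrices <- lapply(seq_len(nrow(sim$genes)), function(g) {
    gene <- sim$genes[g]
    gp <- peaks[gene_id == gene$gene_id]
    if (nrow(gp) == 0L) return(NULL)
    cre_access_matrix(sim$fibers[gene_id == gene$gene_id], access, gp,
                      threshold = cfg$peaks$access_threshold)
  })
  names(matrices) <- sim$genes$gene_id
  for (gid in names(matrices)) {
    M <- matrices[[gid]]
    if (is.null(M)) next
    dt <- data.table(fiber_id = rownames(M))
    for (cn in colnames(M)) dt[[cn]] <- M[, cn]
    write_tsv(dt, file.path(cfg$out_dir, paste0("cre_matrix_", gid, ".tsv")),
              provenance_header(cfg$seed, cfg$peaks))
  }

  # --- regress -------------------------------------------------------------
  regression <- run_stage("regress", function() {
    rows <- list(); coef_rows <- list(); drop_rows <- list()
    syn_rows <- list(); n_models <- 0L
    for (g in seq_len(nrow(sim$genes))) {
      gene <- sim$genes[g]
      M <- matrices[[gene$gene_id]]
      if (is.null(M) || ncol(M) < 1L) next
      sc <- states[gene_id == gene$gene_id]
      res <- regress_gene(sc, M, peaks[gene_id == gene$gene_id], gene,
                          K = cfg$regress$k_folds,
                          n_permutations = cfg$regress$n_perm,
                          seed = cfg$seed, C = cfg$regress$C,
                          synergy_k = cfg$regress$synergy_k,
                          window_bp = cfg$regress$window)
      for (fl in names(res)) {
        n_models <- n_models + 1L
        ev <- res[[fl]]$eval
        rows[[length(rows) + 1L]] <- data.table(
          gene_id = gene$gene_id, state = fl, auc = ev$auc, ap = ev$ap,
          delta_auc = ev$delta_auc, null_mean = mean(ev$null_aucs),
          null_sd = sd(ev$null_aucs), K = ev$K)
        co <- res[[fl]]$model$coefficients
        coef_rows[[length(coef_rows) + 1L]] <- data.table(
          gene_id = gene$gene_id, state = fl, feature = names(co),
          coefficient = unname(co))
        dr <- res[[fl]]$dropout
        drop_rows[[length(drop_rows) + 1L]] <- data.table(
          gene_id = gene$gene_id, state = fl, feature = names(dr),
          delta_auc = unname(dr))
        for (sy in res[[fl]]$synergies)
          syn_rows[[length(syn_rows) + 1L]] <- data.table(
            gene_id = gene$gene_id, state = fl,
            subset = paste(sy$subset, collapse = "+"), k = sy$k,
            synergy = sy$synergy, delta_auc_S = sy$delta_auc_S)
      }
    }
    ev_dt <- if (length(rows)) rbindlist(rows) else
      data.table(gene_id = character(), state = character())
    bind_or_empty <- function(lst, proto) if (length(lst)) rbindlist(lst) else proto
    write_tsv(ev_dt, file.path(cfg$out_dir, "regression_eval.tsv"),
              provenance_header(cfg$seed, cfg$regress))
    write_tsv(bind_or_empty(coef_rows,
                            data.table(gene_id = character(), state = character(),
                                       feature = character(), coefficient = numeric())),
              file.path(cfg$out_dir, "regression_coefficients.tsv"),
              provenance_header(cfg$seed, cfg$regress))
    write_tsv(bind_or_empty(drop_rows,
                            data.table(gene_id = character(), state = character(),
                                       feature = character(), delta_auc = numeric())),
              file.path(cfg$out_dir, "regression_dropout.tsv"),
              provenance_header(cfg$seed, cfg$regress))
    write_tsv(bind_or_empty(syn_rows,
                            data.table(gene_id = character(), state = character(),
                                       subset = character(), k = integer(),
                                       synergy = numeric(), delta_auc_S = numeric())),
              file.path(cfg$out_dir, "regression_synergy.tsv"),
              provenance_header(cfg$seed, cfg$regress))
    list(value = ev_dt, counts = list(n_models = n_models))
  })

  if (identical(stop_after, "regress")) return(finish(list(regression = regression, config = cfg)))

  # --- trajectory ----------------------------------------------------------
  trajectory <- run_stage("trajectory", function() {
    results <- list()
    for (gid in names(matrices)) {
      M <- matrices[[gid]]
      if (is.null(M) || ncol(M) < 2L) next
      M <- M[rowSums(is.na(M)) == 0L, , drop = FALSE]
      if (nrow(M) == 0L) next
      # order elements promoter-proximal first (U1 = closest to the TSS)
      ord <- order(colnames(M))
      M <- M[, ord, drop = FALSE]
      nodes <- tabulate_combos(M, min_support_fraction = cfg$trajectory$min_support)
      k <- ncol(M)
      initial <- paste(c(1L, rep(0L, k - 1L)), collapse = "")
      peak_state <- paste(rep(1L, k), collapse = "")
      terminals <- paste(c(rep(0L, k - 1L), 1L), collapse = "")
      routes <- tryCatch(
        enumerate_routes(nodes, initial, peak_state, terminals,
                         require_peak = cfg$trajectory$require_peak),
        error = function(e) {
          stage_log(cfg, "trajectory", gid, ": ", conditionMessage(e))
          data.table(rank = integer(), support = integer(),
                     length = integer(), route = character())
        })
      write_tsv(nodes[, .(combo, count)],
                file.path(cfg$out_dir, paste0("trajectory_nodes_", gid, ".tsv")),
                provenance_header(cfg$seed, cfg$trajectory))
      write_tsv(routes,
                file.path(cfg$out_dir, paste0("trajectory_routes_", gid, ".tsv")),
                provenance_header(cfg$seed, cfg$trajectory))
      if (nrow(routes)) {
        st <- annotate_stages(routes[1], M, states[gene_id == gid])
        write_tsv(st$stages,
                  file.path(cfg$out_dir, paste0("trajectory_stages_", gid, ".tsv")),
                  provenance_header(cfg$seed, cfg$trajectory))
      }
      results[[gid]] <- list(nodes = nodes, routes = routes)
    }
    list(value = results,
         counts = list(n_genes_with_routes =
                         sum(vapply(results, function(r) nrow(r$routes) > 0,
                                    logical(1)))))
  })

  if (identical(stop_after, "trajectory")) return(finish(list(trajectory = trajectory, config = cfg)))

  # --- motifs --------------------------------------------------------------
  motifs <- run_stage("motifs", function() {
    pfm_file <- cfg$motifs$pfm_file %||%
      system.file("extdata", "motifs_synthetic.jaspar", package = "fiberburst")
    pfms <- read_jaspar_pfm(pfm_file)
    tf_names <- sub("^\\S+\\s+", "", names(pfms))
    tf_fp <- classified[class == "TF"]
    all_hits <- list(); bal <- list(); enr <- list()
    for (g in seq_len(nrow(sim$genes))) {
      gene <- sim$genes[g]
      win <- gene_windows(gene, upstream_bp = cfg$peaks$window)$upstream
      seqs <- get_sequence(sim$reference, gene$chrom, win[1], win[2])
      profiles <- lapply(unique(tf_names), function(tf) {
        pw <- lapply(which(tf_names == tf), function(i)
          pwm_from_pfm(pfms[[i]], pseudocount = cfg$motifs$pseudocount,
                       name = tf))
        pr <- scan_sequence(seqs, pw, threshold = cfg$motifs$threshold,
                            tf = tf, origin = win[1])
        footprint_filter(pr, sim$fibers[gene_id == gene$gene_id], tf_fp,
                         min_fraction = cfg$motifs$min_footprint_frac)
      })
      gcre <- peaks[gene_id == gene$gene_id & start >= win[1] & end <= win[2]]
      if (nrow(gcre)) {
        gcre_in <- data.table(cre_id = paste0(gene$gene_id, "_", gcre$label),
                              start = gcre$start, end = gcre$end)
        eb <- cre_enrichment_and_balance(profiles, gcre_in,
                                         cfg$motifs$activators,
                                         cfg$motifs$repressors)
        bal[[length(bal) + 1L]] <- eb$balance
        em <- as.data.table(eb$enrichment, keep.rownames = "cre_id")
        enr[[length(enr) + 1L]] <- em
      }
      all_hits[[length(all_hits) + 1L]] <-
        rbindlist(lapply(profiles, function(p) p$hits), fill = TRUE)
    }
    hits <- rbindlist(all_hits, fill = TRUE)
    if (nrow(hits)) {
      hits[, `:=`(chrom = sim$genes$chrom[1],
                  score100 = as.integer(round(score * 100)))]
      write_bed(hits, file.path(cfg$out_dir, "motif_hits.bed"),
                name_col = "tf", score_col = "score100",
                seed = cfg$seed, params = cfg$motifs)
    } else {
      write_bed(data.table(chrom = character(), start = integer(),
                           end = integer(), strand = character()),
                file.path(cfg$out_dir, "motif_hits.bed"),
                seed = cfg$seed, params = cfg$motifs)
    }
    baldt <- if (length(bal)) rbindlist(bal) else
      data.table(cre_id = character(), balance = numeric())
    write_tsv(baldt, file.path(cfg$out_dir, "motif_balance.tsv"),
              provenance_header(cfg$seed, cfg$motifs))
    enrdt <- if (length(enr)) rbindlist(enr, fill = TRUE) else
      data.table(cre_id = character())
    write_tsv(enrdt, file.path(cfg$out_dir, "motif_enrichment.tsv"),
              provenance_header(cfg$seed, cfg$motifs))
    list(value = list(hits = hits, balance = baldt),
         counts = list(n_hits = nrow(hits)))
  })

  finish(NULL)
  invisible(list(sim = sim, decoded = decoded, classified = classified,
                 access = access, states = states, peaks = peaks,
                 matrices = matrices, regression = regression,
                 trajectory = trajectory, motifs = motifs, config = cfg))
}
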