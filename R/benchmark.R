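#' End-to-end local-vs-swarm benchmark on synthetic collections
#'
#' Runs the full study at desk scale: for each seed, generates a 4-study
#' synthetic collection (2 rare cell types, one type absent from one study,
#' planted low-quality cells), preprocesses every study once, executes the
#' Local_1 / Local_2 / Local_3 / Swarm_3 experiment grid, and collects the
#' comparison quantities: per-setting mean weighted F1, the paired
#' swarm-vs-local gap, the Mann-Whitney comparison of the two F1 samples,
#' the regression of per-class F1 on the rarity index (pooled over the local
#' runs, as in the 28-run design), and the planted-QC removal rate.
#'
#' Default problem sizes (500 cells/study, 500 genes, 8 types, top-200 HVGs,
#' 20 epochs, sync interval 5) are chosen so a multi-seed run completes in
#' minutes on one CPU while keeping the qualitative structure of the
#' full-scale study; see the package vignette for the rationale.
#'
#' @param seeds Integer vector of simulation seeds (one grid per seed).
#' @param n_cells Cells per study.
#' @param n_genes Genes per study.
#' @param n_types Cell types.
#' @param n_hvg Per-study HVG count.
#' @param epochs Training epochs.
#' @param sync_interval Swarm sync interval in lockstep rounds.
#' @param hidden_sizes MLP hidden widths.
#' @param level Annotation level for the grid.
#' @param verbose Print progress lines.
#' @return A `swarm_benchmark` list; see the fields of the printed summary.
#' @export
swarm_benchmark <- function(seeds = 1:3,
                            n_cells = 500, n_genes = 500, n_types = 8,
                            n_hvg = 200, epochs = 20, sync_interval = 5,
                            hidden_sizes = c(128L, 32L),
                            level = "cell_type", verbose = FALSE) {
  settings <- c("Local_1", "Local_2", "Local_3", "Swarm_3")
  agg_all <- list()
  pc_all <- list()
  rarity_all <- list()
  qc_planted <- 0L
  qc_removed <- 0L

  for (seed in seeds) {
    if (verbose) message("seed ", seed, ": generating collection")
    cfg <- collection_config(
      n_studies = 4, cells_per_study = rep(n_cells, 4),
      n_genes = n_genes, n_types = n_types,
      seed = derive_seed(seed, "collection")
    )
    coll <- generate_collection(cfg)
    prep <- preprocess_collection(coll, qc_config(), n_hvg = n_hvg)

    removed <- unlist(lapply(prep, function(p) p$qc_report$cell_id))
    planted <- coll$truth$cell_id[coll$truth$planted_lowq]
    qc_planted <- qc_planted + length(planted)
    qc_removed <- qc_removed + sum(planted %in% removed)

    hp <- mlp_hyperparams(hidden_sizes = hidden_sizes, epochs = epochs,
                          seed = derive_seed(seed, "grid"))
    cfg_sw <- swarm_config(sync_interval_batches = sync_interval)
    if (verbose) message("seed ", seed, ": running grid")
    res <- run_grid(prep, settings = settings, hp = hp, cfg = cfg_sw,
                    level = level)
    sm <- summarize_grid(res)
    sm$aggregate$seed <- seed
    sm$per_class$seed <- seed
    agg_all[[length(agg_all) + 1L]] <- sm$aggregate
    pc_all[[length(pc_all) + 1L]] <- sm$per_class
    rarity_all[[as.character(seed)]] <-
      rarity_index(collection_labels(coll, level))
  }

  aggregate <- do.call(rbind, agg_all)
  per_class <- do.call(rbind, pc_all)

  mean_f1 <- vapply(settings, function(s) {
    mean(aggregate$weighted_f1[aggregate$setting == s])
  }, numeric(1))

  ## paired swarm-vs-local gap: same seed and test study
  l3 <- aggregate[aggregate$setting == "Local_3", ]
  sw <- aggregate[aggregate$setting == "Swarm_3", ]
  key <- function(d) paste(d$seed, d$test_study)
  gap <- abs(sw$weighted_f1[match(key(l3), key(sw))] - l3$weighted_f1)

  mw <- compare_settings(sw$weighted_f1, l3$weighted_f1)

  ## rarity regression, pooled over the 28 local runs per seed:
  ## per-class F1 averaged over runs, one point per (class, test study)
  local_pc <- per_class[per_class$setting %in% c("Local_1", "Local_2", "Local_3") &
                          per_class$support > 0, ]
  pts <- stats::aggregate(f1 ~ class + test_study + seed, data = local_pc, FUN = mean)
  pts$rarity <- vapply(seq_len(nrow(pts)), function(i) {
    rarity_all[[as.character(pts$seed[i])]][[pts$class[i]]]
  }, numeric(1))
  rarity_fit <- fit_rarity_regression(pts$rarity, pts$f1)

  structure(list(
    seeds = seeds, level = level,
    aggregate = aggregate, per_class = per_class,
    mean_weighted_f1 = mean_f1,
    swarm_local_gap = mean(gap),
    swarm_local_gaps = gap,
    mann_whitney = mw,
    rarity_points = pts,
    rarity_regression = rarity_fit,
    qc_removal_rate = qc_removed / max(1L, qc_planted),
    n_planted = qc_planted
  ), class = "swarm_benchmark")
}

#' @export
print.swarm_benchmark <- function(x, ...) {
  cat(sprintf("<swarm_benchmark> %d seed(s), level %s\n", length(x$seeds), x$level))
  for (s in names(x$mean_weighted_f1)) {
    cat(sprintf("  mean weighted F1 %-8s %.3f\n", s, x$mean_weighted_f1[[s]]))
  }
  cat(sprintf("  |F1(Swarm_3) - F1(Local_3)| (paired mean): %.4f\n", x$swarm_local_gap))
  cat(sprintf("  Mann-Whitney Swarm vs Local_3: U = %.1f, p = %.3f\n",
              x$mann_whitney$statistic, x$mann_whitney$p_value))
  print(x$rarity_regression)
  cat(sprintf("  planted low-quality cells removed by QC: %.1f%% of %d\n",
              100 * x$qc_removal_rate, x$n_planted))
  invisible(x)
}
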