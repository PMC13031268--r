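#' Enumerate the experiment grid
#'
#' For each choice of test study, all size-`k` subsets of the remaining
#' studies form the training set, where `k` is 1, 2 or 3 for
#' `Local_1`/`Local_2`/`Local_3` and 3 for `Swarm_3`. With `n` studies a
#' setting with `k` training studies yields `n * choose(n - 1, k)` designs;
#' for 4 studies that is 12, 12 and 4 (28 in total over the three local
#' settings). Order is deterministic (lexicographic in test study, then
#' training subset).
#'
#' @param study_ids Character vector of at least two study ids.
#' @param setting One of `"Local_1"`, `"Local_2"`, `"Local_3"`, `"Swarm_3"`.
#' @param level Annotation level, `"cell_type"` or `"cell_subtype"`.
#' @return A list of `experiment_design` objects.
#' @export
enumerate_designs <- function(study_ids,
                              setting = c("Local_1", "Local_2", "Local_3", "Swarm_3"),
                              level = c("cell_type", "cell_subtype")) {
  setting <- match.arg(setting)
  level <- match.arg(level)
  study_ids <- sort(as.character(study_ids))
  if (length(study_ids) < 2) stop("need at least two studies", call. = FALSE)
  k <- setting_train_size(setting)
  if (k >= length(study_ids)) {
    stop(sprintf("%s needs %d training studies but only %d studies exist",
                 setting, k, length(study_ids)), call. = FALSE)
  }
  designs <- list()
  for (test in study_ids) {
    rest <- setdiff(study_ids, test)
    combos <- utils::combn(rest, k, simplify = FALSE)
    for (tr in combos) {
      designs[[length(designs) + 1L]] <- structure(list(
        setting = setting, train_studies = tr, test_study = test,
        level = level
      ), class = "experiment_design")
    }
  }
  designs
}

setting_train_size <- function(setting) {
  switch(setting, Local_1 = 1L, Local_2 = 2L, Local_3 = 3L, Swarm_3 = 3L,
         stop("unknown setting: ", setting, call. = FALSE))
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<design> %s: train {%s} -> test %s (%s)\n", x$setting,
              paste(x$train_studies, collapse = ", "), x$test_study, x$level))
  invisible(x)
}

design_key <- function(design) {
  paste(design$setting, design$level, design$test_study,
        paste(design$train_studies, collapse = "+"), sep = "__")
}

#' Assemble peer-ready training data for a design
#'
#' Builds the shared feature space from the training studies' HVG lists
#' (union over training studies only by default, preventing test-set feature
#' leakage; set `include_test = TRUE` to mirror a union over all studies),
#' then projects each training study onto it.
#'
#' @param design An `experiment_design`.
#' @param prep Output of [preprocess_collection()].
#' @param include_test Include the test study's HVGs in the union.
#' @return List with `fs`, `train` (list of `peer_id`/`x`/`y`), `test_x`,
#'   `test_y`.
#' @export
prepare_design_data <- function(design, prep, include_test = FALSE) {
  lab_of <- function(p) {
    if (design$level == "cell_type") p$study$labels_type else p$study$labels_subtype
  }
  hvg_ids <- if (include_test) {
    unique(c(design$train_studies, design$test_study))
  } else design$train_studies
  fs <- union_feature_space(lapply(stats::setNames(hvg_ids, hvg_ids),
                                   function(s) prep[[s]]$hvgs))
  train <- lapply(design$train_studies, function(s) {
    list(peer_id = s, x = project_to_features(prep[[s]]$norm, fs),
         y = lab_of(prep[[s]]))
  })
  te <- prep[[design$test_study]]
  list(fs = fs, train = train,
       test_x = project_to_features(te$norm, fs), test_y = lab_of(te))
}

#' Run one experiment of the grid
#'
#' Trains via the pooled local fit or the swarm simulation according to the
#' design's setting, predicts the projected test study, and returns aligned
#' true/predicted labels. The class vocabulary is the sorted union of labels
#' over the whole collection; test cells whose true label never occurs in
#' the training data are marked non-evaluable (excluded from metrics and
#' counted in the coverage report). The run's seed is derived by hashing the
#' global seed with the design, so adding designs never perturbs others.
#'
#' @param design An `experiment_design`.
#' @param prep Output of [preprocess_collection()] covering all named
#'   studies.
#' @param hp An [mlp_hyperparams()]; its `seed` acts as the global grid seed.
#' @param cfg A [swarm_config()] (used for `Swarm_3` designs).
#' @param class_labels Shared vocabulary; defaults to the union over `prep`.
#' @param include_test Passed to [prepare_design_data()].
#' @return An `experiment_result` with fields `design`, `truth`, `predicted`,
#'   `evaluable`, `coverage`, `model_checksum`, `wall_time`.
#' @export
run_design <- function(design, prep, hp = mlp_hyperparams(),
                       cfg = swarm_config(), class_labels = NULL,
                       include_test = FALSE) {
  missing <- setdiff(c(design$train_studies, design$test_study), names(prep))
  if (length(missing)) {
    stop("studies missing from preprocessed collection: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(class_labels)) {
    class_labels <- sort(unique(unlist(lapply(prep, function(p) {
      if (design$level == "cell_type") p$study$labels_type else p$study$labels_subtype
    }))))
  }
  t0 <- proc.time()[["elapsed"]]
  dat <- prepare_design_data(design, prep, include_test)
  hp_run <- hp
  hp_run$seed <- derive_seed(hp$seed, design_key(design))

  train_labels <- unique(unlist(lapply(dat$train, `[[`, "y")))
  if (!any(dat$test_y %in% train_labels)) {
    stop("no test label overlaps the training vocabulary for design ",
         design_key(design), call. = FALSE)
  }
  fit <- if (design$setting == "Swarm_3") {
    run_swarm(dat$train, cfg, hp_run, class_labels = class_labels)
  } else {
    fit_local(dat$train, fs = NULL, hp = hp_run, class_labels = class_labels)
  }
  pred <- predict(fit, dat$test_x)
  evaluable <- dat$test_y %in% train_labels
  structure(list(
    design = design,
    cell_ids = prep[[design$test_study]]$study$cell_ids,
    truth = dat$test_y,
    predicted = pred,
    evaluable = evaluable,
    coverage = mean(evaluable),
    class_labels = class_labels,
    model_checksum = param_checksum(fit$params),
    n_sync_events = nrow(fit$sync_log),
    wall_time = proc.time()[["elapsed"]] - t0
  ), class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  print(x$design)
  cat(sprintf("  %d test cells (%.1f%% evaluable), wall time %.1fs\n",
              length(x$truth), 100 * x$coverage, x$wall_time))
  invisible(x)
}

#' Run the full experiment grid
#'
#' Maps [run_design()] over [enumerate_designs()] for every requested
#' setting. Per-design failures are caught and logged without aborting the
#' grid. When `out_dir` is given, each result is persisted as
#' `<design key>.rds` and completed designs are skipped on re-runs, making
#' long grids resumable.
#'
#' @param prep Output of [preprocess_collection()].
#' @param settings Character vector of settings to run.
#' @param hp,cfg,include_test As in [run_design()].
#' @param level Annotation level for every design.
#' @param out_dir Optional directory for resumable per-design result files.
#' @return A named list of `experiment_result` (or `try-error` for failed
#'   designs), keyed by design.
#' @export
run_grid <- function(prep, settings = c("Local_1", "Local_2", "Local_3"),
                     hp = mlp_hyperparams(), cfg = swarm_config(),
                     level = "cell_type", out_dir = NULL,
                     include_test = FALSE) {
  class_labels <- sort(unique(unlist(lapply(prep, function(p) {
    if (level == "cell_type") p$study$labels_type else p$study$labels_subtype
  }))))
  results <- list()
  for (setting in settings) {
    for (design in enumerate_designs(names(prep), setting, level)) {
      key <- design_key(design)
      if (!is.null(out_dir)) {
        f <- file.path(out_dir, paste0(key, ".rds"))
        if (file.exists(f)) {
          results[[key]] <- readRDS(f)
          next
        }
      }
      res <- tryCatch(
        run_design(design, prep, hp, cfg, class_labels, include_test),
        error = function(e) {
          warning(sprintf("design %s failed: %s", key, conditionMessage(e)),
                  call. = FALSE)
          structure(list(message = conditionMessage(e), design = design),
                    class = "design_failure")
        })
      if (!is.null(out_dir) && !inherits(res, "design_failure")) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(res, file.path(out_dir, paste0(key, ".rds")))
      }
      results[[key]] <- res
    }
  }
  results
}
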