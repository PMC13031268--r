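#' Per-class and aggregate F1 report
#'
#' Computes per-class precision, recall and F1 (0 substituted when a
#' denominator is 0), the support-weighted, macro (over classes with nonzero
#' support) and micro F1 aggregates, and the row-normalized confusion
#' matrix. Micro F1 is `TP / (TP + (FP + FN) / 2)` over globally pooled
#' counts, which for single-label classification equals overall accuracy.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param class_vocabulary Ordered class vocabulary containing every label.
#' @param coverage Optional fraction of test cells that were evaluable.
#' @return An `evaluation_report`: list with `per_class` (data frame),
#'   `weighted_f1`, `macro_f1`, `micro_f1`, `confusion`, `coverage`.
#' @export
f1_report <- function(true_labels, predicted_labels, class_vocabulary = NULL,
                      coverage = NA_real_) {
  if (length(true_labels) == 0 ||
      length(true_labels) != length(predicted_labels)) {
    stop("label vectors must be non-empty and of equal length", call. = FALSE)
  }
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (is.null(class_vocabulary)) {
    class_vocabulary <- sort(unique(c(true_labels, predicted_labels)))
  }
  if (!all(true_labels %in% class_vocabulary) ||
      !all(predicted_labels %in% class_vocabulary)) {
    stop("labels outside the class vocabulary", call. = FALSE)
  }
  tf <- factor(true_labels, levels = class_vocabulary)
  pf <- factor(predicted_labels, levels = class_vocabulary)
  tab <- table(true = tf, predicted = pf)
  tp <- diag(tab)
  support <- rowSums(tab)
  pred_n <- colSums(tab)
  fp <- pred_n - tp
  fn <- support - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  per_class <- data.frame(
    class = class_vocabulary, precision = as.numeric(prec),
    recall = as.numeric(rec), f1 = as.numeric(f1),
    support = as.numeric(support), row.names = NULL, stringsAsFactors = FALSE
  )
  has_support <- support > 0
  conf <- matrix(0, nrow(tab), ncol(tab), dimnames = dimnames(tab))
  conf[has_support, ] <- tab[has_support, , drop = FALSE] / support[has_support]
  tp_tot <- sum(tp)
  structure(list(
    per_class = per_class,
    weighted_f1 = sum(support * f1) / sum(support),
    macro_f1 = mean(f1[has_support]),
    micro_f1 = tp_tot / (tp_tot + (sum(fp) + sum(fn)) / 2),
    confusion = conf,
    coverage = coverage
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> weighted F1 %.3f, macro %.3f, micro %.3f (%d classes)\n",
              x$weighted_f1, x$macro_f1, x$micro_f1, nrow(x$per_class)))
  invisible(x)
}

#' Cell-type rarity index
#'
#' For class `c` with within-study proportion `p[c, s]`, the index is the
#' mean over studies of `1 - p[c, s]`: it lies in `[0, 1]` and is higher for
#' rarer classes. A class absent from every study gets index 1 and is
#' flagged in the `absent_everywhere` attribute. A companion binary Gini
#' impurity `mean(2 p (1 - p))` is available via `flavor = "gini_binary"`
#' for comparison; note it is not monotone in rarity.
#'
#' @param label_tables List of per-study label vectors.
#' @param class_vocabulary Classes to score; defaults to the union observed.
#' @param flavor `"one_minus_prevalence"` (default) or `"gini_binary"`.
#' @return Named numeric vector of rarity indices.
#' @export
rarity_index <- function(label_tables, class_vocabulary = NULL,
                         flavor = c("one_minus_prevalence", "gini_binary")) {
  flavor <- match.arg(flavor)
  if (length(label_tables) < 1) stop("need at least one study", call. = FALSE)
  if (is.null(class_vocabulary)) {
    class_vocabulary <- sort(unique(unlist(label_tables)))
  }
  P <- vapply(label_tables, function(lab) {
    tab <- table(factor(as.character(lab), levels = class_vocabulary))
    as.numeric(tab) / length(lab)
  }, numeric(length(class_vocabulary)))
  P <- matrix(P, nrow = length(class_vocabulary))
  idx <- if (flavor == "one_minus_prevalence") {
    rowMeans(1 - P)
  } else {
    rowMeans(2 * P * (1 - P))
  }
  names(idx) <- class_vocabulary
  attr(idx, "absent_everywhere") <- class_vocabulary[rowSums(P) == 0]
  idx
}

#' Regress per-class F1 on rarity
#'
#' Ordinary least squares of F1 on the rarity index, via [stats::lm()]. The
#' slope p-value is the two-sided t-test with `n - 2` degrees of freedom and
#' the adjusted R-squared is `1 - (1 - R2)(n - 1)/(n - 2)`.
#'
#' @param x Rarity values (at least 3, finite, non-constant).
#' @param y Per-class F1 values.
#' @return A `rarity_regression` list: `intercept`, `slope`,
#'   `slope_p_value`, `adjusted_r2`, `n_points`.
#' @export
fit_rarity_regression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need at least 3 paired points", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("values must be finite", call. = FALSE)
  }
  if (stats::var(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    slope_p_value = unname(s$coefficients[2, 4]),
    adjusted_r2 = s$adj.r.squared,
    n_points = length(x)
  ), class = "rarity_regression")
}

#' @export
print.rarity_regression <- function(x, ...) {
  cat(sprintf("<rarity_regression> F1 = %.3f %+.3f * rarity (p = %.3g, adj. R2 = %.3f, n = %d)\n",
              x$intercept, x$slope, x$slope_p_value, x$adjusted_r2, x$n_points))
  invisible(x)
}

#' Mann-Whitney comparison of two F1 samples
#'
#' Two-sided Mann-Whitney U test via [stats::wilcox.test()]: the exact
#' enumeration p-value is used for small tie-free samples
#' (`n_a + n_b <= 12`), the tie-corrected normal approximation otherwise.
#'
#' @param f1_sample_a,f1_sample_b Non-empty numeric samples.
#' @return List with `statistic` (the U of the first sample) and `p_value`.
#' @export
compare_settings <- function(f1_sample_a, f1_sample_b) {
  if (length(f1_sample_a) == 0 || length(f1_sample_b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  no_ties <- !anyDuplicated(c(f1_sample_a, f1_sample_b))
  exact <- no_ties && (length(f1_sample_a) + length(f1_sample_b) <= 12)
  wt <- suppressWarnings(
    stats::wilcox.test(f1_sample_a, f1_sample_b, alternative = "two.sided",
                       exact = exact, correct = !exact)
  )
  list(statistic = unname(wt$statistic), p_value = min(1, wt$p.value))
}

#' Long-format summary of an experiment grid
#'
#' One row per (setting, level, test study, class) with the class F1 and
#' support, plus one aggregate row per experiment with the weighted, macro
#' and micro F1 and the coverage. Metrics are computed on evaluable test
#' cells only (cells whose true label occurred in the training data).
#'
#' @param results List of `experiment_result` objects (failures are
#'   skipped).
#' @return List with data frames `per_class` and `aggregate`.
#' @export
summarize_grid <- function(results) {
  results <- Filter(function(r) inherits(r, "experiment_result"), results)
  if (length(results) < 1) stop("no successful results to summarize", call. = FALSE)
  per_class <- list()
  aggregate <- list()
  for (r in results) {
    keep <- r$evaluable
    rep <- f1_report(r$truth[keep], r$predicted[keep], r$class_labels,
                     coverage = r$coverage)
    d <- r$design
    pc <- rep$per_class
    pc$setting <- d$setting; pc$level <- d$level; pc$test_study <- d$test_study
    pc$train_studies <- paste(d$train_studies, collapse = "+")
    per_class[[length(per_class) + 1L]] <- pc
    aggregate[[length(aggregate) + 1L]] <- data.frame(
      setting = d$setting, level = d$level, test_study = d$test_study,
      train_studies = paste(d$train_studies, collapse = "+"),
      weighted_f1 = rep$weighted_f1, macro_f1 = rep$macro_f1,
      micro_f1 = rep$micro_f1, coverage = r$coverage,
      stringsAsFactors = FALSE
    )
  }
  list(per_class = do.call(rbind, per_class),
       aggregate = do.call(rbind, aggregate))
}
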