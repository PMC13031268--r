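#' Quality-control configuration
#'
#' @param n_mads Outlier margin in median-absolute-deviation units (unscaled
#'   MAD, no normal-consistency factor). Default 5.
#' @param mito_max_pct Maximum allowed percentage of counts on mitochondrial
#'   (`MT-`) genes; the rule is strict (`>`), so a cell at exactly the
#'   threshold is retained. Default 8.
#' @param top_k_genes Number of largest counts entering the
#'   "percentage of counts in top genes" metric. Default 20.
#' @return A `qc_config` list.
#' @export
qc_config <- function(n_mads = 5, mito_max_pct = 8, top_k_genes = 20) {
  stopifnot_scalar_num(n_mads, "n_mads", 0, strict = TRUE)
  stopifnot_scalar_num(mito_max_pct, "mito_max_pct", 0, strict = TRUE)
  stopifnot_scalar_num(top_k_genes, "top_k_genes", 0, strict = TRUE)
  structure(list(n_mads = n_mads, mito_max_pct = mito_max_pct,
                 top_k_genes = as.integer(top_k_genes)),
            class = "qc_config")
}

#' Per-cell quality-control metrics
#'
#' Computes the four standard QC metrics: `log1p_total_counts`,
#' `log1p_n_genes_by_counts`, `pct_counts_top20` (percentage of counts in the
#' `top_k` most expressed genes of the cell) and `pct_mito` (percentage of
#' counts on `MT-` genes). Cells with zero total counts get 0 for both
#' percentage metrics and are force-flagged by [qc_filter()].
#'
#' @param dataset A `swarm_study`.
#' @param top_k Number of top genes for the concentration metric.
#' @return A data frame with one row per cell.
#' @export
compute_qc_metrics <- function(dataset, top_k = 20) {
  counts <- dataset$counts
  if (ncol(counts) < 1) stop("dataset has no genes", call. = FALSE)
  total <- Matrix::rowSums(counts)
  ngene <- Matrix::rowSums(counts > 0)
  mito <- grepl("^MT-", dataset$gene_ids)
  mito_sum <- if (any(mito)) Matrix::rowSums(counts[, mito, drop = FALSE]) else
    rep(0, nrow(counts))
  k <- min(top_k, ncol(counts))
  dense <- as.matrix(counts)
  top_sum <- apply(dense, 1L, function(r) {
    sum(sort.int(r, decreasing = TRUE, method = "quick")[seq_len(k)])
  })
  pct <- function(num) ifelse(total > 0, 100 * num / total, 0)
  data.frame(
    cell_id = dataset$cell_ids,
    log1p_total_counts = log1p(total),
    log1p_n_genes_by_counts = log1p(ngene),
    pct_counts_top20 = pct(top_sum),
    pct_mito = pct(mito_sum),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Two-sided MAD outlier mask
#'
#' Flags values lying more than `n_mads` unscaled median absolute deviations
#' from the median: `|x - median(x)| > n_mads * median(|x - median(x)|)`.
#' When the MAD is zero only values differing from the median are flagged;
#' an infinite margin flags nothing.
#'
#' @param values Numeric vector (non-empty).
#' @param n_mads Margin in MAD units.
#' @return A logical mask the length of `values`.
#' @export
mad_outlier_mask <- function(values, n_mads = 5) {
  if (length(values) == 0) stop("'values' must be non-empty", call. = FALSE)
  if (!is.finite(n_mads)) return(rep(FALSE, length(values)))
  med <- stats::median(values)
  dev <- abs(values - med)
  dev > n_mads * stats::median(dev)
}

#' Per-study QC filtering
#'
#' Removes a cell iff it is a MAD outlier on any of the four QC metrics, or
#' its mitochondrial percentage strictly exceeds `qc$mito_max_pct`, or it has
#' zero total counts. Filtering is per study and is intended to run exactly
#' once per study: the MAD margins are data-dependent, so re-running on
#' already-filtered output may remove further cells.
#'
#' @param dataset A `swarm_study`.
#' @param qc A [qc_config()].
#' @return A list with `dataset` (the filtered study), `report` (data frame
#'   of removed cells and the rule(s) that fired) and `metrics` (the full QC
#'   metric table).
#' @export
qc_filter <- function(dataset, qc = qc_config()) {
  m <- compute_qc_metrics(dataset, top_k = qc$top_k_genes)
  metric_cols <- c("log1p_total_counts", "log1p_n_genes_by_counts",
                   "pct_counts_top20", "pct_mito")
  fired <- matrix(FALSE, nrow(m), length(metric_cols) + 2L,
                  dimnames = list(NULL, c(paste0("mad_", metric_cols),
                                          "mito_gt_max", "zero_counts")))
  for (j in seq_along(metric_cols)) {
    fired[, j] <- mad_outlier_mask(m[[metric_cols[j]]], qc$n_mads)
  }
  fired[, "mito_gt_max"] <- m$pct_mito > qc$mito_max_pct
  fired[, "zero_counts"] <- m$log1p_total_counts == 0
  remove <- rowSums(fired) > 0
  if (all(remove)) {
    stop(sprintf("QC removed every cell of study '%s'", dataset$study_id),
         call. = FALSE)
  }
  report <- data.frame(
    cell_id = m$cell_id[remove],
    rules = apply(fired[remove, , drop = FALSE], 1L,
                  function(r) paste(colnames(fired)[r], collapse = ";")),
    row.names = NULL, stringsAsFactors = FALSE
  )
  keep <- which(!remove)
  filtered <- new_swarm_study(
    study_id = dataset$study_id,
    counts = dataset$counts[keep, , drop = FALSE],
    gene_ids = dataset$gene_ids,
    cell_ids = dataset$cell_ids[keep],
    labels_type = dataset$labels_type[keep],
    labels_subtype = if (is.null(dataset$labels_subtype)) NULL else
      dataset$labels_subtype[keep]
  )
  list(dataset = filtered, report = report, metrics = m)
}

#' Library-size normalization with log1p scaling
#'
#' Scales each cell to `target_sum` total counts, then applies `log(1 + x)`.
#' All-zero cells map to all-zero rows; the zero pattern is preserved.
#'
#' @param counts Cells x genes non-negative matrix (sparse or dense).
#' @param target_sum Per-cell total after scaling (default 10,000).
#' @return A sparse `dgCMatrix` of normalized, log-transformed values with
#'   the input dimnames.
#' @export
normalize_counts <- function(counts, target_sum = 1e4) {
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  rs <- Matrix::rowSums(m)
  sf <- ifelse(rs > 0, target_sum / rs, 0)
  out <- Matrix::Diagonal(x = sf) %*% m
  out <- methods::as(out, "CsparseMatrix")
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(m)
  out
}

#' Highly variable gene selection (bin-normalized dispersion)
#'
#' On the study's normalized log1p matrix (or raw counts when
#' `use_normalized = FALSE`), computes per-gene mean and dispersion
#' (variance / mean), bins genes into 20 equal-frequency bins by mean,
#' z-scores the dispersions within each bin (bins with fewer than two genes
#' fall back to the raw dispersion), and returns the `n_top` genes by
#' normalized dispersion, ties broken lexicographically by gene id. The
#' result is invariant to cell- and gene-order permutations of the input.
#'
#' @param dataset A `swarm_study` (assumed already QC-filtered).
#' @param n_top Number of genes to select (default 2000).
#' @param use_normalized Compute dispersions on the normalized log1p matrix
#'   (default) or on raw counts.
#' @param n_bins Number of mean-expression bins (default 20).
#' @return Character vector of `n_top` gene ids.
#' @export
select_hvgs <- function(dataset, n_top = 2000, use_normalized = TRUE,
                        n_bins = 20) {
  if (n_top > length(dataset$gene_ids)) {
    stop("n_top exceeds the number of genes", call. = FALSE)
  }
  X <- if (use_normalized) normalize_counts(dataset$counts) else dataset$counts
  n <- nrow(X)
  mu <- Matrix::colMeans(X)
  ex2 <- Matrix::colMeans(X^2)
  v <- if (n > 1) (ex2 - mu^2) * n / (n - 1) else rep(0, length(mu))
  disp <- ifelse(mu > 0, v / mu, 0)

  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(br) > 2) {
    cut(mu, breaks = br, include.lowest = TRUE)
  } else factor(rep(1L, length(mu)))
  z <- disp
  for (b in levels(bin)) {
    idx <- which(bin == b)
    if (length(idx) < 2) next  # fallback: raw dispersion
    s <- stats::sd(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - mean(disp[idx])) / s
  }
  ord <- order(-z, dataset$gene_ids)
  dataset$gene_ids[ord][seq_len(n_top)]
}

#' Union feature space over per-study HVG lists
#'
#' The shared feature set is the sorted set-union of the per-study highly
#' variable gene lists; the operation is commutative and associative in its
#' inputs.
#'
#' @param hvg_lists Named list mapping study id to a character vector of
#'   gene ids.
#' @return An object of class `feature_space` with `gene_ids` (sorted union)
#'   and `per_study_hvgs`.
#' @export
union_feature_space <- function(hvg_lists) {
  if (length(hvg_lists) < 1) stop("need at least one HVG list", call. = FALSE)
  structure(list(
    gene_ids = sort(unique(unlist(hvg_lists, use.names = FALSE))),
    per_study_hvgs = hvg_lists
  ), class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space> %d genes (union of %d lists of sizes %s)\n",
              length(x$gene_ids), length(x$per_study_hvgs),
              paste(lengths(x$per_study_hvgs), collapse = ", ")))
  invisible(x)
}

#' Project a normalized matrix onto a shared feature space
#'
#' Reorders columns to `fs$gene_ids`, zero-filling genes the study lacks.
#'
#' @param x Cells x genes matrix with gene ids as column names (typically
#'   the output of [normalize_counts()]).
#' @param fs A [union_feature_space()] result.
#' @return A dense matrix of shape `n_cells x length(fs$gene_ids)`.
#' @export
project_to_features <- function(x, fs) {
  out <- matrix(0, nrow(x), length(fs$gene_ids),
                dimnames = list(rownames(x), fs$gene_ids))
  idx <- match(fs$gene_ids, colnames(x))
  present <- which(!is.na(idx))
  if (length(present)) {
    out[, present] <- as.matrix(x[, idx[present], drop = FALSE])
  }
  out
}

#' Preprocess every study of a collection
#'
#' Runs the per-study pipeline once per study: QC filtering, 10,000-count
#' log1p normalization and per-study HVG selection. No batch correction is
#' performed at any point; each study is processed independently.
#'
#' @param collection A `cell_collection` or list of `swarm_study` objects.
#' @param qc A [qc_config()].
#' @param n_hvg Number of HVGs per study.
#' @param use_normalized Passed to [select_hvgs()].
#' @return A named list (by study id) of lists with elements `study`
#'   (filtered), `norm` (normalized matrix), `hvgs`, `qc_report`.
#' @export
preprocess_collection <- function(collection, qc = qc_config(), n_hvg = 2000,
                                  use_normalized = TRUE) {
  studies <- if (inherits(collection, "cell_collection")) collection$studies else collection
  out <- lapply(studies, function(st) {
    f <- qc_filter(st, qc)
    norm <- normalize_counts(f$dataset$counts)
    hvgs <- select_hvgs(f$dataset, n_top = min(n_hvg, length(st$gene_ids)),
                        use_normalized = use_normalized)
    list(study = f$dataset, norm = norm, hvgs = hvgs, qc_report = f$report)
  })
  names(out) <- vapply(studies, function(x) x$study_id, character(1))
  out
}

#' Generic metadata row filter
#'
#' Keeps the cells of a study for which `predicate` returns `TRUE` on a
#' cell-metadata table (e.g. suspension type or tissue filters applied before
#' QC).
#'
#' @param dataset A `swarm_study`.
#' @param metadata Data frame with one row per cell, aligned with
#'   `dataset$cell_ids`.
#' @param predicate Function mapping the metadata table to a logical vector.
#' @return The filtered `swarm_study`.
#' @export
filter_cells_by_metadata <- function(dataset, metadata, predicate) {
  stopifnot(nrow(metadata) == length(dataset$cell_ids))
  keep <- which(isTRUE_vec(predicate(metadata)))
  new_swarm_study(
    study_id = dataset$study_id,
    counts = dataset$counts[keep, , drop = FALSE],
    gene_ids = dataset$gene_ids,
    cell_ids = dataset$cell_ids[keep],
    labels_type = dataset$labels_type[keep],
    labels_subtype = if (is.null(dataset$labels_subtype)) NULL else
      dataset$labels_subtype[keep]
  )
}

isTRUE_vec <- function(x) !is.na(x) & x
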