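#' Configuration for a synthetic multi-study single-cell collection
#'
#' Describes the statistical structure of a simulated collection of
#' single-cell RNA-seq studies: per-study cell-type composition (including
#' types absent from some studies), marker-driven expression profiles with a
#' two-level type/subtype hierarchy, per-study multiplicative batch effects,
#' log-normal library sizes, negative-binomial over-dispersion, a designated
#' mitochondrial gene subset, and a fraction of planted low-quality cells that
#' downstream quality control is expected to remove.
#'
#' Counts are drawn as `NegBin(mean = L_i * q_g, size = nb_dispersion)` where
#' `q` is the cell's normalized expression profile perturbed by the study's
#' batch factors and `L_i` is the cell's library size, so
#' `Var = mu + mu^2 / nb_dispersion`.
#'
#' @param n_studies Number of studies (peers) in the collection.
#' @param cells_per_study Integer vector of length `n_studies`.
#' @param n_genes Number of genes.
#' @param n_types Number of (coarse) cell types.
#' @param n_subtypes_per_type Subtypes nested in each type; subtypes perturb
#'   their parent profile on a private marker set with half the fold change.
#' @param type_prevalence `n_studies x n_types` matrix of per-study type
#'   probabilities; each row must sum to 1. Zero entries encode cell types
#'   missing from a study. Defaults to [default_type_prevalence()].
#' @param marker_genes_per_type Marker genes private to each type.
#' @param marker_log_fold_change Natural-log fold change applied to marker
#'   genes of a type (subtype markers get half of it).
#' @param batch_sigma Standard deviation of the per-study, per-gene log-normal
#'   batch factor; 0 disables batch effects.
#' @param libsize_log_mean,libsize_log_sd Log-normal library-size parameters.
#' @param nb_dispersion Negative-binomial inverse-dispersion (`size`); larger
#'   values mean less over-dispersion.
#' @param mito_gene_fraction Fraction of genes designated mitochondrial and
#'   renamed with an `MT-` prefix.
#' @param baseline_mito_fraction Expected fraction of a healthy cell's counts
#'   carried by mitochondrial genes.
#' @param lowq_cell_fraction Fraction of cells per study corrupted to violate
#'   quality control (inflated mitochondrial fraction, or library size far
#'   outside the study distribution). These are flagged in the returned truth
#'   table.
#' @param seed Integer seed; the whole collection is a deterministic function
#'   of the configuration.
#' @return An object of class `collection_config`.
#' @seealso [generate_collection()]
#' @export
collection_config <- function(n_studies = 4,
                              cells_per_study = rep(500L, n_studies),
                              n_genes = 500,
                              n_types = 8,
                              n_subtypes_per_type = 2,
                              type_prevalence = default_type_prevalence(n_studies, n_types),
                              marker_genes_per_type = 10,
                              marker_log_fold_change = 2,
                              batch_sigma = 0.2,
                              libsize_log_mean = log(3000),
                              libsize_log_sd = 0.3,
                              nb_dispersion = 2,
                              mito_gene_fraction = 0.05,
                              baseline_mito_fraction = 0.04,
                              lowq_cell_fraction = 0.05,
                              seed = 1L) {
  stopifnot_scalar_num(n_studies, "n_studies", 1, strict = FALSE)
  stopifnot_scalar_num(n_genes, "n_genes", 0, strict = TRUE)
  stopifnot_scalar_num(n_types, "n_types", 0, strict = TRUE)
  stopifnot_scalar_num(n_subtypes_per_type, "n_subtypes_per_type", 0, strict = TRUE)
  stopifnot_scalar_num(marker_genes_per_type, "marker_genes_per_type", 0, strict = TRUE)
  stopifnot_scalar_num(marker_log_fold_change, "marker_log_fold_change", 0, strict = TRUE)
  stopifnot_scalar_num(batch_sigma, "batch_sigma", 0)
  stopifnot_scalar_num(nb_dispersion, "nb_dispersion", 0, strict = TRUE)
  if (length(cells_per_study) != n_studies || any(cells_per_study <= 0)) {
    stop("'cells_per_study' must hold one positive count per study", call. = FALSE)
  }
  type_prevalence <- as.matrix(type_prevalence)
  if (!all(dim(type_prevalence) == c(n_studies, n_types))) {
    stop("'type_prevalence' must be an n_studies x n_types matrix", call. = FALSE)
  }
  if (any(type_prevalence < 0) ||
      any(abs(rowSums(type_prevalence) - 1) > 1e-9)) {
    stop("each row of 'type_prevalence' must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (mito_gene_fraction <= 0 || mito_gene_fraction >= 1 ||
      baseline_mito_fraction <= 0 || baseline_mito_fraction >= 1) {
    stop("mito fractions must lie strictly in (0, 1)", call. = FALSE)
  }
  if (lowq_cell_fraction < 0 || lowq_cell_fraction >= 1) {
    stop("'lowq_cell_fraction' must lie in [0, 1)", call. = FALSE)
  }
  n_mito <- max(1L, round(mito_gene_fraction * n_genes))
  needed <- n_types * marker_genes_per_type +
    n_types * n_subtypes_per_type * ceiling(marker_genes_per_type / 2)
  if (needed > n_genes - n_mito) {
    stop("not enough non-mitochondrial genes for disjoint marker sets",
         call. = FALSE)
  }
  structure(list(
    n_studies = as.integer(n_studies),
    cells_per_study = as.integer(cells_per_study),
    n_genes = as.integer(n_genes),
    n_types = as.integer(n_types),
    n_subtypes_per_type = as.integer(n_subtypes_per_type),
    type_prevalence = type_prevalence,
    marker_genes_per_type = as.integer(marker_genes_per_type),
    marker_log_fold_change = marker_log_fold_change,
    batch_sigma = batch_sigma,
    libsize_log_mean = libsize_log_mean,
    libsize_log_sd = libsize_log_sd,
    nb_dispersion = nb_dispersion,
    mito_gene_fraction = mito_gene_fraction,
    baseline_mito_fraction = baseline_mito_fraction,
    lowq_cell_fraction = lowq_cell_fraction,
    seed = as.integer(seed)
  ), class = "collection_config")
}

#' Default per-study cell-type composition
#'
#' A deterministic prevalence matrix with a dominant type, mid-frequency
#' types and (for six or more types) two rare types; each study tilts the
#' shared base composition differently, and when there are at least two
#' studies and two types the rarest type is absent from the second study,
#' emulating cell types that some centers never observed.
#'
#' @param n_studies,n_types Dimensions of the matrix.
#' @return An `n_studies x n_types` matrix whose rows sum to 1.
#' @export
default_type_prevalence <- function(n_studies, n_types) {
  n_rare <- if (n_types >= 6) 2L else if (n_types >= 4) 1L else 0L
  n_common <- n_types - n_rare
  w <- c(seq(3, 1, length.out = n_common),
         if (n_rare > 0) c(0.15, 0.10)[seq_len(n_rare)])
  prev <- matrix(0, n_studies, n_types)
  for (s in seq_len(n_studies)) {
    tilt <- 1 + 0.25 * sin(2.3 * s + 1.7 * seq_len(n_types))
    prev[s, ] <- pmax(w * tilt, 0.01)
  }
  if (n_studies >= 2 && n_types >= 2) prev[2, n_types] <- 0
  prev / rowSums(prev)
}

#' Generate a synthetic multi-study single-cell collection
#'
#' Simulates every study of a collection from a shared set of cell-type and
#' subtype expression profiles, applying study-specific batch factors and
#' library sizes, and planting a configurable fraction of low-quality cells
#' (high mitochondrial load or aberrant library size). The result is fully
#' deterministic given the configuration, including its seed.
#'
#' @param config A [collection_config()].
#' @return An object of class `cell_collection`: a list with elements
#'   `studies` (list of `swarm_study` objects), `truth` (data frame flagging
#'   planted low-quality cells and their corruption mode), `profiles` (the
#'   per-study expected expression profiles per subtype, after batch effects)
#'   and `config`.
#' @examples
#' cfg <- collection_config(n_studies = 2, cells_per_study = c(60, 60),
#'                          n_genes = 120, n_types = 3, seed = 42)
#' coll <- generate_collection(cfg)
#' sapply(coll$studies, function(s) nrow(s$counts))
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "collection_config"))
  with_seed(config$seed, generate_collection_impl(config))
}

generate_collection_impl <- function(cfg) {
  G <- cfg$n_genes
  K <- cfg$n_types
  S <- cfg$n_subtypes_per_type
  n_mito <- max(1L, round(cfg$mito_gene_fraction * G))
  gene_ids <- sprintf("G%05d", seq_len(G))
  mito_idx <- seq.int(G - n_mito + 1L, G)
  gene_ids[mito_idx] <- paste0("MT-", gene_ids[mito_idx])
  nonmito_idx <- setdiff(seq_len(G), mito_idx)

  ## shared baseline expression, heavy-tailed across genes
  base <- stats::rgamma(G, shape = 0.6, rate = 0.6) + 1e-4

  ## disjoint marker blocks: first type markers, then subtype markers
  m_type <- cfg$marker_genes_per_type
  m_sub <- ceiling(m_type / 2)
  cursor <- 0L
  take <- function(n) {
    idx <- nonmito_idx[cursor + seq_len(n)]
    cursor <<- cursor + n
    idx
  }
  type_markers <- lapply(seq_len(K), function(k) take(m_type))
  sub_markers <- lapply(seq_len(K), function(k)
    lapply(seq_len(S), function(j) take(m_sub)))

  ## profile per (type, subtype), normalized with the mito mass pinned
  profile_of <- function(k, j) {
    p <- base
    p[type_markers[[k]]] <- p[type_markers[[k]]] * exp(cfg$marker_log_fold_change)
    p[sub_markers[[k]][[j]]] <- p[sub_markers[[k]][[j]]] *
      exp(cfg$marker_log_fold_change / 2)
    p
  }
  pin_mito <- function(p, mito_frac) {
    p[nonmito_idx] <- p[nonmito_idx] / sum(p[nonmito_idx]) * (1 - mito_frac)
    p[mito_idx] <- p[mito_idx] / sum(p[mito_idx]) * mito_frac
    p
  }
  profs <- vector("list", K * S)  # indexed (k-1)*S + j
  for (k in seq_len(K)) for (j in seq_len(S)) {
    profs[[(k - 1L) * S + j]] <- profile_of(k, j)
  }

  type_names <- sprintf("CT%02d", seq_len(K))
  subtype_names <- as.vector(t(outer(type_names, sprintf("S%d", seq_len(S)),
                                     paste, sep = ".")))

  studies <- vector("list", cfg$n_studies)
  truth_list <- vector("list", cfg$n_studies)
  profiles_out <- vector("list", cfg$n_studies)

  for (s in seq_len(cfg$n_studies)) {
    n <- cfg$cells_per_study[s]
    sid <- sprintf("S%d", s)
    b <- if (cfg$batch_sigma > 0) {
      stats::rlnorm(G, 0, cfg$batch_sigma)
    } else rep(1, G)

    ## expected per-profile composition in this study (batch-perturbed,
    ## renormalized so library size keeps its meaning)
    q <- lapply(profs, function(p) {
      v <- pin_mito(p * b, cfg$baseline_mito_fraction)
      v / sum(v)
    })
    q_low_mito <- lapply(profs, function(p) {
      v <- pin_mito(p * b, 0.30)  # corrupted cells: 30% mitochondrial mass
      v / sum(v)
    })

    types <- sample.int(K, n, replace = TRUE, prob = cfg$type_prevalence[s, ])
    subs <- sample.int(S, n, replace = TRUE)
    prof_idx <- (types - 1L) * S + subs
    L <- stats::rlnorm(n, cfg$libsize_log_mean, cfg$libsize_log_sd)

    n_low <- round(cfg$lowq_cell_fraction * n)
    low_idx <- if (n_low > 0) sort(sample.int(n, n_low)) else integer(0)
    mode <- rep("none", n)
    if (n_low > 0) {
      half <- seq_along(low_idx) %% 2L == 1L
      mode[low_idx[half]] <- "mito"
      lib_cells <- low_idx[!half]
      updown <- seq_along(lib_cells) %% 2L == 1L
      mode[lib_cells[updown]] <- "libsize_high"
      mode[lib_cells[!updown]] <- "libsize_low"
    }
    L[mode == "libsize_high"] <- L[mode == "libsize_high"] * 25
    L[mode == "libsize_low"] <- L[mode == "libsize_low"] / 25

    mu <- matrix(0, n, G)
    for (i in seq_len(n)) {
      qq <- if (mode[i] == "mito") q_low_mito[[prof_idx[i]]] else q[[prof_idx[i]]]
      mu[i, ] <- L[i] * qq
    }
    counts <- matrix(stats::rnbinom(n * G, size = cfg$nb_dispersion,
                                    mu = as.vector(mu)),
                     nrow = n, ncol = G)
    cell_ids <- sprintf("%s_C%04d", sid, seq_len(n))
    cm <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
    dimnames(cm) <- list(cell_ids, gene_ids)

    studies[[s]] <- new_swarm_study(
      study_id = sid,
      counts = cm,
      gene_ids = gene_ids,
      cell_ids = cell_ids,
      labels_type = type_names[types],
      labels_subtype = subtype_names[prof_idx]
    )
    truth_list[[s]] <- data.frame(
      study_id = sid, cell_id = cell_ids,
      planted_lowq = mode != "none", mode = mode,
      stringsAsFactors = FALSE
    )
    qs <- do.call(rbind, q)
    dimnames(qs) <- list(subtype_names, gene_ids)
    profiles_out[[s]] <- qs
  }
  names(studies) <- vapply(studies, function(x) x$study_id, character(1))
  names(profiles_out) <- names(studies)

  structure(list(
    studies = studies,
    truth = do.call(rbind, truth_list),
    profiles = profiles_out,
    config = cfg
  ), class = "cell_collection")
}

## StudyDataset --------------------------------------------------------------

#' Construct a single-study dataset
#'
#' A `swarm_study` bundles one peer's private data: a cells x genes sparse
#' count matrix, gene and cell identifiers, and per-cell labels at one or two
#' annotation levels. Mitochondrial genes are identified by the `MT-` prefix.
#'
#' @param study_id Study identifier.
#' @param counts Cells x genes matrix of non-negative integers (dense or
#'   sparse).
#' @param gene_ids,cell_ids Unique identifier vectors matching the matrix
#'   dimensions.
#' @param labels_type Per-cell cell-type labels.
#' @param labels_subtype Optional per-cell subtype labels.
#' @return A validated object of class `swarm_study`.
#' @export
new_swarm_study <- function(study_id, counts, gene_ids, cell_ids,
                            labels_type, labels_subtype = NULL) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  x <- structure(list(
    study_id = as.character(study_id),
    counts = counts,
    gene_ids = as.character(gene_ids),
    cell_ids = as.character(cell_ids),
    labels_type = as.character(labels_type),
    labels_subtype = if (is.null(labels_subtype)) NULL else as.character(labels_subtype)
  ), class = "swarm_study")
  validate_swarm_study(x)
}

validate_swarm_study <- function(x) {
  if (anyDuplicated(x$gene_ids)) stop("duplicate gene_ids", call. = FALSE)
  if (anyDuplicated(x$cell_ids)) stop("duplicate cell_ids", call. = FALSE)
  if (!all(dim(x$counts) == c(length(x$cell_ids), length(x$gene_ids)))) {
    stop("counts shape does not match cell_ids x gene_ids", call. = FALSE)
  }
  v <- x$counts@x
  if (length(v) && (any(v < 0) || any(v != round(v)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (length(x$labels_type) != length(x$cell_ids)) {
    stop("labels_type must align 1:1 with cell_ids", call. = FALSE)
  }
  if (!is.null(x$labels_subtype) &&
      length(x$labels_subtype) != length(x$cell_ids)) {
    stop("labels_subtype must align 1:1 with cell_ids", call. = FALSE)
  }
  x
}

#' @export
print.swarm_study <- function(x, ...) {
  cat(sprintf("<swarm_study> %s: %d cells x %d genes, %d cell types%s\n",
              x$study_id, nrow(x$counts), ncol(x$counts),
              length(unique(x$labels_type)),
              if (is.null(x$labels_subtype)) ""
              else sprintf(", %d subtypes", length(unique(x$labels_subtype)))))
  invisible(x)
}

#' @export
print.cell_collection <- function(x, ...) {
  cat(sprintf("<cell_collection> %d studies, %d genes, %d cell types; %d planted low-quality cells\n",
              length(x$studies), x$config$n_genes, x$config$n_types,
              sum(x$truth$planted_lowq)))
  for (s in x$studies) print(s)
  invisible(x)
}

# Per-study label vectors at the requested annotation level.
collection_labels <- function(collection, level = c("cell_type", "cell_subtype")) {
  level <- match.arg(level)
  lapply(collection$studies, function(s) {
    if (level == "cell_type") s$labels_type else s$labels_subtype
  })
}

# Sorted label vocabulary over the whole collection.
collection_vocabulary <- function(collection, level = "cell_type") {
  sort(unique(unlist(collection_labels(collection, level))))
}
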