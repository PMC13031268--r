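test_that("generation is deterministic and respects the configuration", {
  cfg <- collection_config(n_studies = 2, cells_per_study = c(50L, 70L),
                           n_genes = 120, n_types = 3, seed = 7)
  a <- generate_collection(cfg)
  b <- generate_collection(cfg)
  expect_identical(lapply(a$studies, `[[`, "counts"),
                   lapply(b$studies, `[[`, "counts"))
  expect_identical(a$truth, b$truth)
  expect_equal(vapply(a$studies, function(s) nrow(s$counts), numeric(1)),
               c(S1 = 50, S2 = 70))
  expect_true(all(grepl("^MT-", a$studies$S1$gene_ids[
    grepl("^MT-", a$studies$S1$gene_ids)])))
  expect_gt(sum(grepl("^MT-", a$studies$S1$gene_ids)), 0)
})

test_that("nothing is planted when lowq_cell_fraction is zero", {
  coll <- tiny_collection()
  expect_identical(sum(coll$truth$planted_lowq), 0L)
})

test_that("zero batch variance yields identical expected profiles across studies", {
  cfg <- collection_config(n_studies = 2, cells_per_study = c(40L, 40L),
                           n_genes = 120, n_types = 3, batch_sigma = 0,
                           lowq_cell_fraction = 0, seed = 9)
  coll <- generate_collection(cfg)
  expect_equal(coll$profiles$S1, coll$profiles$S2)
  # realized counts still differ by sampling
  expect_false(identical(coll$studies$S1$counts[1:20, ],
                         coll$studies$S2$counts[1:20, ]))
})

test_that("counts follow the stated negative-binomial mean/variance relation", {
  # homogeneous config: one type, fixed library size, no batch effect, so all
  # cells share one expected profile and moments can be checked per gene
  cfg <- collection_config(
    n_studies = 1, cells_per_study = 3000L, n_genes = 200, n_types = 1,
    n_subtypes_per_type = 1, type_prevalence = matrix(1, 1, 1),
    batch_sigma = 0, libsize_log_sd = 0, libsize_log_mean = log(2000),
    nb_dispersion = 2, lowq_cell_fraction = 0, seed = 3
  )
  coll <- generate_collection(cfg)
  m <- as.matrix(coll$studies$S1$counts)
  mu_hat <- colMeans(m)
  v_hat <- apply(m, 2, var)
  expressed <- mu_hat > 1
  expect_gt(sum(expressed), 20)
  # oracle: NB moment formula Var = mu + mu^2 / theta
  v_expected <- mu_hat + mu_hat^2 / 2
  ratio <- v_hat[expressed] / v_expected[expressed]
  expect_true(all(ratio > 0.6 & ratio < 1.6))
  expect_lt(abs(median(ratio) - 1), 0.15)
})

test_that("marker genes are over-dispersed at the documented example scale", {
  cfg <- collection_config(n_studies = 4, cells_per_study = rep(500L, 4),
                           n_genes = 1000, n_types = 8, nb_dispersion = 2,
                           seed = 7)
  coll <- generate_collection(cfg)
  m <- as.matrix(coll$studies$S1$counts)
  mu_hat <- colMeans(m)
  v_hat <- apply(m, 2, var)
  hi <- mu_hat > 0.5
  expect_true(all(v_hat[hi] > mu_hat[hi]))
})

test_that("invalid configurations are rejected", {
  expect_error(collection_config(n_genes = 0), "n_genes")
  expect_error(collection_config(n_studies = 2, cells_per_study = c(10L, 0L)),
               "cells_per_study")
  expect_error(
    collection_config(n_studies = 2, cells_per_study = c(10L, 10L),
                      n_types = 2, type_prevalence = matrix(c(0.5, 0.6,
                                                             0.5, 0.5), 2, 2)),
    "sum to 1")
  expect_error(collection_config(lowq_cell_fraction = 1), "lowq")
})

test_that("planted low-quality cells violate the QC rules they target", {
  cfg <- collection_config(n_studies = 2, cells_per_study = c(250L, 250L),
                           n_genes = 200, n_types = 3,
                           lowq_cell_fraction = 0.06, seed = 13)
  coll <- generate_collection(cfg)
  planted <- coll$truth$cell_id[coll$truth$planted_lowq]
  expect_gt(length(planted), 10)
  removed <- unlist(lapply(coll$studies, function(s) {
    qc_filter(s)$report$cell_id
  }))
  expect_gte(mean(planted %in% removed), 0.9)
})

test_that("marker structure makes classes separable by nearest centroid", {
  cfg <- collection_config(n_studies = 2, cells_per_study = c(150L, 150L),
                           n_genes = 200, n_types = 4,
                           marker_log_fold_change = 2, batch_sigma = 0.3,
                           lowq_cell_fraction = 0, seed = 17)
  coll <- generate_collection(cfg)
  x <- do.call(rbind, lapply(coll$studies, function(s)
    as.matrix(normalize_counts(s$counts))))
  y <- unlist(lapply(coll$studies, `[[`, "labels_type"))
  centroids <- do.call(rbind, lapply(split(seq_along(y), y), function(i)
    colMeans(x[i, , drop = FALSE])))
  d2 <- outer(rowSums(x^2), rowSums(centroids^2), "+") - 2 * x %*% t(centroids)
  pred <- rownames(centroids)[apply(d2, 1, which.min)]
  expect_gte(mean(pred == y), 0.8)
})

test_that("collections round-trip through MTX + TSV on disk", {
  coll <- tiny_collection()
  dir <- withr::local_tempdir()
  write_collection(coll, dir)
  back <- read_collection(dir)
  expect_identical(names(back), names(coll$studies))
  for (sid in names(back)) {
    expect_equal(as.matrix(back[[sid]]$counts),
                 as.matrix(coll$studies[[sid]]$counts),
                 ignore_attr = TRUE)
    expect_identical(back[[sid]]$gene_ids, coll$studies[[sid]]$gene_ids)
    expect_identical(back[[sid]]$cell_ids, coll$studies[[sid]]$cell_ids)
    expect_identical(back[[sid]]$labels_type, coll$studies[[sid]]$labels_type)
    expect_identical(back[[sid]]$labels_subtype,
                     coll$studies[[sid]]$labels_subtype)
  }
  expect_identical(attr(back, "truth")$planted_lowq, coll$truth$planted_lowq)
})

test_that("a dataset with an all-zero cell survives the round trip", {
  counts <- rbind(c(0L, 0L, 0L, 0L), c(1L, 0L, 2L, 0L), c(5L, 1L, 0L, 3L))
  st <- study_from_counts(counts, c("A", "B", "C", "D"),
                          labels = c("x", "y", "y"), id = "Z1")
  dir <- withr::local_tempdir()
  write_collection(list(st), dir)
  back <- read_collection(dir)
  expect_equal(as.matrix(back$Z1$counts), counts, ignore_attr = TRUE)
  expect_equal(Matrix::rowSums(back$Z1$counts)[1], 0, ignore_attr = TRUE)
})

test_that("malformed MTX files raise parse errors naming the file", {
  st <- study_from_counts(rbind(c(1L, 2L), c(0L, 3L)), c("A", "B"),
                          labels = c("x", "y"), id = "Z2")
  dir <- withr::local_tempdir()
  write_collection(list(st), dir)
  mtx <- file.path(dir, "Z2", "matrix.mtx")
  lines <- readLines(mtx)
  writeLines(lines[-length(lines)], mtx)  # drop one entry: nnz now wrong
  expect_error(read_collection(dir), "matrix.mtx")

  # mismatched sidecar: extra gene line
  writeLines(lines, mtx)
  cat("EXTRA\n", file = file.path(dir, "Z2", "genes.tsv"), append = TRUE)
  expect_error(read_collection(dir), "genes.tsv")
})
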