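test_that("QC metrics match their definitions on hand-built cells", {
  st <- study_from_counts(rbind(c(10L, 0L, 0L), c(2L, 8L, 0L)),
                          c("A", "MT-B", "C"), labels = c("x", "x"))
  m <- compute_qc_metrics(st)
  expect_equal(m$log1p_total_counts, log1p(c(10, 10)))
  expect_equal(m$log1p_n_genes_by_counts, log1p(c(1, 2)))
  expect_equal(m$pct_mito, c(0, 80))
})

test_that("top-k concentration metric equals a brute-force sort oracle", {
  set.seed(42)
  counts <- matrix(rpois(8 * 30, 3), nrow = 8)
  st <- study_from_counts(counts, sprintf("g%02d", 1:30),
                          labels = rep("x", 8))
  m <- compute_qc_metrics(st, top_k = 20)
  oracle <- apply(counts, 1, function(r) {
    100 * sum(rev(sort(r))[1:20]) / sum(r)
  })
  expect_equal(m$pct_counts_top20, oracle)
})

test_that("zero-count cells get zero percentage metrics", {
  st <- study_from_counts(rbind(c(0L, 0L), c(3L, 1L)), c("A", "MT-B"),
                          labels = c("x", "x"))
  m <- compute_qc_metrics(st)
  expect_equal(m$pct_mito[1], 0)
  expect_equal(m$pct_counts_top20[1], 0)
  expect_equal(m$log1p_total_counts[1], 0)
})

test_that("MAD outlier mask follows the unscaled-MAD definition", {
  # oracle by hand: median 3, MAD = median(|x-3|) = 1, margin 5 => only 100
  expect_identical(mad_outlier_mask(c(1, 2, 3, 4, 100), 5),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(mad_outlier_mask(rep(7, 10), 5)))
  expect_false(any(mad_outlier_mask(c(1, 2, 3, 4, 100), Inf)))
  # zero MAD: any deviation from the median is flagged
  expect_identical(mad_outlier_mask(c(5, 5, 5, 5, 6), 5),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_error(mad_outlier_mask(numeric(0)), "non-empty")
})

test_that("the mitochondrial rule is strictly greater-than 8 percent", {
  # ten cells at exactly 8% mito, one at 9%: only the 9% cell is removed
  base <- rbind(matrix(rep(c(92L, 8L), 10), ncol = 2, byrow = TRUE),
                c(91L, 9L))
  st <- study_from_counts(base, c("A", "MT-B"), labels = rep("x", 11))
  res <- qc_filter(st, qc_config())
  expect_identical(res$report$cell_id, st$cell_ids[11])
  expect_true(all(grepl("mito", res$report$rules)))
  expect_equal(nrow(res$dataset$counts), 10)
})

test_that("a clean tight dataset yields an empty removal report", {
  # high, homogeneous counts: every metric's spread is far inside 5 MADs
  set.seed(8)
  counts <- matrix(rpois(40 * 100, 50), nrow = 40)
  st <- study_from_counts(counts, sprintf("g%03d", 1:100),
                          labels = rep("x", 40))
  res <- qc_filter(st)
  expect_equal(nrow(res$report), 0)
  expect_equal(nrow(res$dataset$counts), 40)
})

test_that("removing every cell is an explicit error naming the study", {
  st <- study_from_counts(matrix(0L, 3, 4), c("A", "B", "C", "D"),
                          labels = rep("x", 3), id = "EMPTY")
  expect_error(qc_filter(st), "EMPTY")
})

test_that("preprocess_collection applies QC in a single pass per study", {
  coll <- grid_collection()
  prep <- grid_prep()
  once <- qc_filter(coll$studies$S1)
  expect_identical(prep$S1$study$cell_ids, once$dataset$cell_ids)
})

test_that("normalization scales cells to 10,000 counts then log1p", {
  x <- normalize_counts(rbind(c(1, 1, 2), c(0, 0, 0)))
  expect_equal(as.numeric(x[1, ]), log1p(c(2500, 2500, 5000)))
  expect_equal(as.numeric(x[2, ]), c(0, 0, 0))
  set.seed(1)
  m <- matrix(rpois(200, 2), nrow = 10)
  n <- normalize_counts(m)
  sums <- Matrix::rowSums(expm1(as.matrix(n)))
  expect_equal(sums[rowSums(m) > 0], rep(1e4, sum(rowSums(m) > 0)),
               tolerance = 1e-6, ignore_attr = TRUE)
  # zero pattern preserved and transform monotone in ranks
  expect_identical(as.matrix(n) == 0, m == 0, ignore_attr = TRUE)
  r <- m[3, ]
  expect_identical(order(as.numeric(n[3, ])), order(r))
})

test_that("HVG selection returns all genes when n_top equals n_genes", {
  st <- tiny_collection()$studies$S1
  hv <- select_hvgs(st, n_top = length(st$gene_ids))
  expect_setequal(hv, st$gene_ids)
  expect_error(select_hvgs(st, n_top = length(st$gene_ids) + 1), "n_top")
})

test_that("a single planted variable gene is always selected", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 80
    counts <- matrix(rpois(n * 200, 5), nrow = n)
    # gene 7 differs strongly between two balanced groups, all others i.i.d.
    counts[, 7] <- c(rpois(n / 2, 1), rpois(n / 2, 40))
    st <- study_from_counts(counts, sprintf("g%03d", 1:200),
                            labels = rep(c("a", "b"), each = n / 2))
    expect_true("g007" %in% select_hvgs(st, n_top = 1))
  }
})

test_that("HVG selection is deterministic and permutation invariant", {
  st <- tiny_collection()$studies$S1
  hv <- select_hvgs(st, n_top = 30)
  expect_identical(hv, select_hvgs(st, n_top = 30))

  set.seed(99)
  cp <- sample(nrow(st$counts))
  gp <- sample(ncol(st$counts))
  st_perm <- new_swarm_study(
    study_id = st$study_id, counts = st$counts[cp, gp],
    gene_ids = st$gene_ids[gp], cell_ids = st$cell_ids[cp],
    labels_type = st$labels_type[cp]
  )
  expect_identical(sort(select_hvgs(st_perm, n_top = 30)), sort(hv))
})

test_that("union feature space has set-union semantics and is order-insensitive", {
  l1 <- sprintf("g%03d", 1:100)
  expect_length(union_feature_space(list(a = l1, b = l1, c = l1))$gene_ids, 100)
  l2 <- sprintf("h%03d", 1:100)
  fs <- union_feature_space(list(a = l1, b = l2))
  expect_length(fs$gene_ids, 200)
  expect_true(all(c(l1, l2) %in% fs$gene_ids))
  # commutative and associative in its inputs
  expect_identical(fs$gene_ids,
                   union_feature_space(list(b = l2, a = l1))$gene_ids)
  l3 <- sprintf("g%03d", 50:150)
  expect_identical(
    union_feature_space(list(a = l1, b = l2, c = l3))$gene_ids,
    union_feature_space(list(c = l3, b = l2, a = l1))$gene_ids)
  expect_error(union_feature_space(list()), "at least one")
})

test_that("feature projection zero-fills and is a section of restriction", {
  st <- tiny_collection()$studies$S1
  norm <- normalize_counts(st$counts)
  fs_own <- union_feature_space(list(s = st$gene_ids))
  proj <- project_to_features(norm, fs_own)
  expect_equal(proj, as.matrix(norm)[, fs_own$gene_ids], ignore_attr = TRUE)

  fs_extra <- union_feature_space(list(s = c(st$gene_ids[1:10], "ABSENT-1")))
  proj2 <- project_to_features(norm, fs_extra)
  expect_equal(unname(proj2[, "ABSENT-1"]), rep(0, nrow(norm)))
  # restriction back to original genes recovers the original columns
  common <- intersect(fs_extra$gene_ids, st$gene_ids)
  expect_equal(proj2[, common], as.matrix(norm)[, common], ignore_attr = TRUE)
})
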