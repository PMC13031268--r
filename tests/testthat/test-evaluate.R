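# Brute-force contingency oracle: per-class counts via explicit comparisons.
oracle_f1 <- function(truth, pred, vocab) {
  per <- lapply(vocab, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(f1 = f1, support = sum(truth == cl), tp = tp, fp = fp, fn = fn)
  })
  m <- do.call(rbind, per)
  list(
    f1 = m[, "f1"], support = m[, "support"],
    weighted = sum(m[, "f1"] * m[, "support"]) / sum(m[, "support"]),
    macro = mean(m[m[, "support"] > 0, "f1"]),
    micro = sum(m[, "tp"]) / (sum(m[, "tp"]) + (sum(m[, "fp"]) + sum(m[, "fn"])) / 2)
  )
}

test_that("perfect predictions give unit F1 and an identity confusion matrix", {
  y <- rep(c("a", "b", "c"), times = c(5, 3, 2))
  rep_ <- f1_report(y, y, c("a", "b", "c"))
  expect_equal(rep_$per_class$f1, rep(1, 3))
  expect_equal(rep_$weighted_f1, 1)
  expect_equal(rep_$macro_f1, 1)
  expect_equal(rep_$micro_f1, 1)
  expect_equal(rep_$confusion, diag(3), ignore_attr = TRUE)
})

test_that("the four-cell worked example matches the precision/recall formulas", {
  rep_ <- f1_report(c("A", "A", "B", "B"), c("A", "B", "B", "B"), c("A", "B"))
  expect_equal(rep_$per_class$f1, c(2 / 3, 0.8))
  expect_equal(rep_$macro_f1, 11 / 15)
  expect_equal(rep_$weighted_f1, 11 / 15)
  expect_equal(rep_$micro_f1, 0.75)
})

test_that("f1_report agrees with the contingency oracle on random instances", {
  set.seed(123)
  for (i in 1:200) {
    k <- sample(2:6, 1)
    n <- sample(5:50, 1)
    vocab <- sprintf("c%d", seq_len(k))
    truth <- sample(vocab, n, replace = TRUE)
    pred <- sample(vocab, n, replace = TRUE)
    rep_ <- f1_report(truth, pred, vocab)
    orc <- oracle_f1(truth, pred, vocab)
    expect_equal(rep_$per_class$f1, unname(orc$f1))
    expect_equal(rep_$weighted_f1, orc$weighted)
    expect_equal(rep_$macro_f1, orc$macro)
    expect_equal(rep_$micro_f1, orc$micro)
    # micro F1 equals accuracy for single-label classification
    expect_equal(rep_$micro_f1, mean(truth == pred))
    # weighted F1 within the per-class range; confusion rows sum to 1
    sup <- rep_$per_class$support > 0
    expect_gte(rep_$weighted_f1, min(rep_$per_class$f1[sup]) - 1e-12)
    expect_lte(rep_$weighted_f1, max(rep_$per_class$f1[sup]) + 1e-12)
    expect_equal(unname(rowSums(rep_$confusion)[sup]), rep(1, sum(sup)),
                 tolerance = 1e-9)
  }
})

test_that("f1_report rejects degenerate inputs", {
  expect_error(f1_report(character(0), character(0)), "non-empty")
  expect_error(f1_report(c("a", "b"), c("a")), "equal length")
  expect_error(f1_report("a", "z", class_vocabulary = c("a", "b")),
               "vocabulary")
})

test_that("the rarity index is one minus mean prevalence, higher for rarer", {
  expect_equal(as.numeric(rarity_index(list(rep("a", 10), rep("a", 5)))), 0)
  ri <- rarity_index(list(c(rep("a", 1), rep("b", 9)),
                          c(rep("a", 3), rep("b", 7))))
  expect_equal(unname(ri["a"]), 0.8)  # proportions 0.1 and 0.3
  expect_equal(unname(ri["b"]), mean(1 - c(0.9, 0.7)))
  # monotone: increasing any prevalence weakly decreases the index
  ri2 <- rarity_index(list(c(rep("a", 2), rep("b", 8)),
                           c(rep("a", 3), rep("b", 7))))
  expect_lt(ri2["a"], ri["a"])
  # absent class: index 1 and flagged
  ri3 <- rarity_index(list(rep("a", 4)), class_vocabulary = c("a", "ghost"))
  expect_equal(unname(ri3["ghost"]), 1)
  expect_identical(attr(ri3, "absent_everywhere"), "ghost")
})

test_that("the rarity regression matches a normal-equations oracle", {
  expect_error(fit_rarity_regression(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(fit_rarity_regression(c(1, 2), c(1, 2)), "3 paired")

  r <- suppressWarnings(fit_rarity_regression(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(r$intercept, 0, tolerance = 1e-10)
  expect_equal(r$slope, 1, tolerance = 1e-10)
  expect_lt(r$slope_p_value, 1e-8)

  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:15, 1)
    x <- rnorm(n)
    y <- 0.3 - 0.8 * x + rnorm(n, sd = 0.5)
    fit <- fit_rarity_regression(x, y)
    # oracle: closed-form normal equations and t-test, computed longhand
    sxx <- sum((x - mean(x))^2)
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    a <- mean(y) - b * mean(x)
    res <- y - a - b * x
    se_b <- sqrt(sum(res^2) / (n - 2) / sxx)
    p <- 2 * pt(-abs(b / se_b), df = n - 2)
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
    expect_equal(fit$intercept, a, tolerance = 1e-10)
    expect_equal(fit$slope, b, tolerance = 1e-10)
    expect_equal(fit$slope_p_value, p, tolerance = 1e-10)
    expect_equal(fit$adjusted_r2, adj, tolerance = 1e-10)
    expect_equal(fit$n_points, n)
  }
})

test_that("the Mann-Whitney comparison uses exact small-sample p-values", {
  cmp <- compare_settings(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$statistic, 0)
  # oracle: enumerate all C(6,3) = 20 assignments of ranks to group A
  ranks <- 1:6
  combos <- combn(6, 3)
  u_of <- function(idx) sum(rank(ranks)[idx]) - 3 * 4 / 2
  u_all <- apply(combos, 2, u_of)
  u_obs <- u_of(1:3)
  p_exact <- mean(pmin(u_all, 9 - u_all) <= min(u_obs, 9 - u_obs))
  expect_equal(p_exact, 0.1)
  expect_equal(cmp$p_value, 0.1)

  same <- compare_settings(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  # two-sided p is symmetric in the sample order
  a <- runif(8); b <- runif(5)
  expect_equal(compare_settings(a, b)$p_value, compare_settings(b, a)$p_value)
  expect_error(compare_settings(numeric(0), 1), "non-empty")
})

test_that("grid summaries aggregate per-experiment reports faithfully", {
  prep <- grid_prep()
  d <- enumerate_designs(names(prep), "Local_1")[[1]]
  r <- run_design(d, prep, tiny_hp())
  s1 <- summarize_grid(list(r))
  direct <- f1_report(r$truth[r$evaluable], r$predicted[r$evaluable],
                      r$class_labels)
  expect_equal(s1$aggregate$weighted_f1, direct$weighted_f1)
  expect_equal(s1$aggregate$macro_f1, direct$macro_f1)
  expect_equal(nrow(s1$aggregate), 1)
  # duplicated result: identical means, doubled run count
  s2 <- summarize_grid(list(r, r))
  expect_equal(nrow(s2$aggregate), 2)
  expect_equal(mean(s2$aggregate$weighted_f1), s1$aggregate$weighted_f1)
})
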