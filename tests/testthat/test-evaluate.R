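test_that("confusion counts follow the four-cell definitions", {
  cc <- confusion_counts(c(1L, 1L, -1L, -1L), c(1L, 1L, -1L, -1L))
  expect_equal(unclass(cc)[c("tp", "fn", "tn", "fp")],
               list(tp = 2L, fn = 0L, tn = 2L, fp = 0L))
  cc2 <- confusion_counts(c(1L, -1L), c(1L, 1L))
  expect_equal(cc2$tp, 1L); expect_equal(cc2$fp, 1L)
  expect_equal(cc2$tn, 0L); expect_equal(cc2$fn, 0L)
  # totals decompose: tp + fn = positives, tn + fp = negatives
  set.seed(41)
  yt <- sample(c(1L, -1L), 50, replace = TRUE)
  yp <- sample(c(1L, -1L), 50, replace = TRUE)
  cc3 <- confusion_counts(yt, yp)
  expect_equal(cc3$tp + cc3$fn, sum(yt == 1L))
  expect_equal(cc3$tn + cc3$fp, sum(yt == -1L))

  expect_error(confusion_counts(integer(), integer()), "empty")
  expect_error(confusion_counts(c(1L, 0L), c(1L, 1L)), "labels")
  expect_error(confusion_counts(c(1L), c(1L, -1L)), "length")
})

test_that("metric formulas reproduce hand-evaluated tables", {
  perfect <- classification_metrics(
    structure(list(tp = 60, fn = 0, tn = 60, fp = 0),
              class = "confusion_counts"))
  expect_equal(unname(perfect), c(1, 1, 1, 1))

  inverted <- classification_metrics(
    structure(list(tp = 0, fn = 60, tn = 0, fp = 60),
              class = "confusion_counts"))
  expect_equal(inverted[["mcc"]], -1)

  # tp=50, fn=10, tn=40, fp=20 worked by hand from the four formulas:
  # sens = 50/60, spec = 40/60, acc = 90/120,
  # mcc = (40*50 - 20*10)/sqrt(60*70*50*60) = 1800/sqrt(12,600,000)
  m <- classification_metrics(
    structure(list(tp = 50, fn = 10, tn = 40, fp = 20),
              class = "confusion_counts"))
  expect_equal(m[["sensitivity"]], 50 / 60, tolerance = 1e-12)
  expect_equal(m[["specificity"]], 40 / 60, tolerance = 1e-12)
  expect_equal(m[["accuracy"]], 0.75, tolerance = 1e-12)
  expect_equal(m[["mcc"]], 1800 / sqrt(60 * 70 * 50 * 60), tolerance = 1e-12)
  expect_equal(round(unname(m), 4), c(0.8333, 0.6667, 0.75, 0.5071))

  # degenerate denominators: MCC falls back to 0, absent class rate is NA
  z <- classification_metrics(
    structure(list(tp = 5, fn = 0, tn = 0, fp = 0),
              class = "confusion_counts"))
  expect_equal(z[["mcc"]], 0)
  expect_true(is.na(z[["specificity"]]))

  # accuracy identity and MCC bounds on random tables
  set.seed(42)
  for (i in 1:50) {
    cc <- structure(as.list(setNames(sample(0:30, 4, replace = TRUE),
                                     c("tp", "fn", "tn", "fp"))),
                    class = "confusion_counts")
    mm <- classification_metrics(cc)
    expect_equal(mm[["accuracy"]],
                 (cc$tp + cc$tn) / max(1, cc$tp + cc$tn + cc$fp + cc$fn))
    expect_gte(mm[["mcc"]], -1); expect_lte(mm[["mcc"]], 1)
  }
})

test_that("AUC spans its closed-form extremes and the chance level", {
  y <- c(rep(1L, 5), rep(-1L, 5))
  expect_equal(roc_auc(y, c(6:10, 1:5))$auc, 1)
  expect_equal(roc_auc(y, c(1:5, 6:10))$auc, 0)
  set.seed(43)
  y2 <- sample(c(1L, -1L), 2000, replace = TRUE)
  expect_equal(roc_auc(y2, rnorm(2000))$auc, 0.5, tolerance = 0.05)
  expect_error(roc_auc(rep(1L, 5), rnorm(5)), "both classes")
})

test_that("AUC equals the brute-force pairwise Mann-Whitney statistic", {
  set.seed(44)
  for (i in 1:10) {
    n <- 80
    y <- c(rep(1L, 30), rep(-1L, 50))
    s <- rnorm(n) + 0.8 * (y == 1L)
    if (i %% 2 == 0) s <- round(s, 1)       # force ties
    pos <- s[y == 1L]; neg <- s[y == -1L]
    brute <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(roc_auc(y, s)$auc, brute, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(45)
  y <- c(rep(1L, 40), rep(-1L, 60))
  s <- rnorm(100) + (y == 1L)
  ours <- roc_auc(y, s)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("cross-validation partitions are stratified, disjoint and exhaustive", {
  d <- gaussian_dataset(60, 60, sep = 3, seed = 51)
  cv <- cross_validate(d, n_folds = 6, seed = 7)
  expect_equal(cv$n_folds, 6)
  expect_equal(nrow(cv$per_fold), 6)
  fold <- succpred:::with_seed(7, succpred:::stratified_folds(d$y, 6))
  expect_equal(as.integer(table(fold)), rep(20L, 6))      # equal sizes
  for (f in 1:6) expect_true(all(c(1L, -1L) %in% d$y[fold == f]))
})

test_that("cross-validation is deterministic and accurate on separated classes", {
  d <- gaussian_dataset(60, 60, sep = 5, seed = 52)
  for (nf in c(6, 8, 10)) {
    cv <- cross_validate(d, n_folds = nf, seed = 9, params = list(gamma = 0.1))
    expect_gt(cv$means[["accuracy"]], 0.95)
  }
  cv1 <- cross_validate(d, n_folds = 6, seed = 9)
  cv2 <- cross_validate(d, n_folds = 6, seed = 9)
  expect_identical(cv1$per_fold, cv2$per_fold)

  expect_error(cross_validate(d, n_folds = 1), ">= 2")
  small <- gaussian_dataset(3, 40, seed = 53)
  expect_error(cross_validate(small, n_folds = 6), "fewer samples")
})

test_that("balancing can be restricted to training folds", {
  d <- gaussian_dataset(30, 150, sep = 0.8, seed = 54)
  cv <- cross_validate(d, n_folds = 3, seed = 2, balance_within_folds = TRUE,
                       balance_params = list(k_start = 5, k_max = 200))
  expect_equal(nrow(cv$per_fold), 3)
  expect_true(all(is.finite(cv$per_fold$accuracy)))
})
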