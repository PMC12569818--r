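test_that("compute_metrics matches hand-evaluated cases", {
  perfect <- compute_metrics(data.frame(y = c(1, 2, 3), p = c(1, 2, 3)), y, p)
  expect_equal(unlist(perfect[, c("mae", "rmse", "pearson", "spearman")]),
               c(mae = 0, rmse = 0, pearson = 1, spearman = 1))

  # rank formula with a single swapped pair: 1 - 6*2 / (4*15) = 0.8
  m <- compute_metrics(data.frame(y = 1:4, p = c(1, 3, 2, 4)), y, p)
  expect_equal(m$spearman, 0.8)

  m2 <- compute_metrics(data.frame(y = c(1, 2), p = c(2, 4)), y, p)
  expect_equal(m2$mae, 1.5)
  expect_equal(m2$rmse, sqrt(2.5))

  expect_error(compute_metrics(data.frame(y = 1, p = 1), y, p), "at least 2")
  expect_error(compute_metrics(data.frame(y = c(1, NA), p = c(1, 2)), y, p),
               "finite")
})

test_that("zero-variance input flags correlations as undefined", {
  m <- compute_metrics(data.frame(y = c(1, 1, 1), p = c(1, 2, 3)), y, p)
  expect_true(m$degenerate)
  expect_true(is.na(m$pearson) && is.na(m$spearman))
  expect_equal(m$mae, 1)
})

test_that("metrics agree with the brute-force formulas on random data", {
  set.seed(42)
  worst <- 0
  for (i in 1:200) {
    n <- sample(5:40, 1)
    y <- rnorm(n)
    yhat <- if (i %% 3 == 0) round(rnorm(n)) else rnorm(n)  # ties every 3rd
    if (sd(y) == 0 || sd(yhat) == 0) next
    m <- compute_metrics(data.frame(y = y, p = yhat), y, p)
    b <- brute_metrics(y, yhat)
    worst <- max(worst, abs(c(m$mae, m$rmse, m$pearson, m$spearman) - b))
  }
  expect_lt(worst, 1e-12)
})

test_that("correlations are invariant to affine / monotone transforms", {
  set.seed(7)
  y <- rnorm(30)
  yhat <- y + rnorm(30, sd = 0.5)
  m0 <- compute_metrics(data.frame(y = y, p = yhat), y, p)
  m_aff <- compute_metrics(data.frame(y = y, p = 3 * yhat + 2), y, p)
  expect_equal(m_aff$pearson, m0$pearson, tolerance = 1e-12)
  expect_equal(m_aff$spearman, m0$spearman, tolerance = 1e-12)
  m_mono <- compute_metrics(data.frame(y = y, p = exp(yhat)), y, p)
  expect_equal(m_mono$spearman, m0$spearman, tolerance = 1e-12)
})

test_that("fold-change threshold reproduces RT ln(fold)", {
  expect_equal(round(threshold_from_fold_change(10, 298), 2), 1.36)
  expect_equal(threshold_from_fold_change(100, 298),
               2 * threshold_from_fold_change(10, 298), tolerance = 1e-12)
  expect_lt(threshold_from_fold_change(1 + 1e-9), 1e-8)  # -> 0 as fold -> 1
  # strictly increasing in both arguments
  expect_gt(threshold_from_fold_change(11), threshold_from_fold_change(10))
  expect_gt(threshold_from_fold_change(10, 310),
            threshold_from_fold_change(10, 298))
  expect_error(threshold_from_fold_change(1), "greater than 1")
  expect_error(threshold_from_fold_change(10, -5), "positive")
})

test_that("resistance classification counts the 2x2 table correctly", {
  perfect <- classify_resistance(
    data.frame(y = c(2, 1, 0.5, 3), p = c(2, 1, 0.5, 3)), y, p
  )
  expect_equal(perfect$accuracy, 1)
  expect_equal(sum(perfect$confusion[cbind(c("R", "S"), c("S", "R"))]), 0)
  expect_equal(glance(perfect)$auc, 1)  # truth scores separate perfectly

  # truth (2.0, 1.0), preds (1.5, 1.4): one true positive, one false positive
  cr <- classify_resistance(data.frame(y = c(2, 1), p = c(1.5, 1.4)), y, p)
  expect_equal(cr$confusion["R", "R"], 1L)
  expect_equal(cr$confusion["S", "R"], 1L)
  expect_equal(cr$confusion["R", "S"] + cr$confusion["S", "S"], 0L)
  expect_equal(cr$accuracy, 0.5)

  # single-class truth: AUC undefined, accuracy still reported
  onecls <- classify_resistance(data.frame(y = c(0, 0.5), p = c(0, 2)), y, p)
  expect_true(is.na(onecls$auc))
  expect_equal(onecls$accuracy, 0.5)

  # boundary flag: ddg exactly at threshold flips class under "gt"
  at <- data.frame(y = c(1.36, 0), p = c(1.36, 0))
  expect_equal(classify_resistance(at, y, p)$confusion["R", "R"], 1L)
  expect_equal(classify_resistance(at, y, p, boundary = "gt")$confusion["R", "R"], 0L)
})

test_that("rank-based AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:10) {
    y <- rnorm(40, mean = 1)
    score <- 0.5 * y + rnorm(40)
    cr <- classify_resistance(data.frame(y = y, p = score), y, p,
                              threshold = 1.0)
    ref <- pROC::auc(pROC::roc(response = y >= 1.0, predictor = score,
                               quiet = TRUE, direction = "<"))
    expect_equal(glance(cr)$auc, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("location stratification uses the stated bin edges", {
  d <- data.frame(y = rnorm(6), p = rnorm(6),
                  distance = c(3, 8, 20, 7.999, 15.0, 15.0001))
  s <- stratify_by_location(d, y, p)
  expect_equal(s$n[s$location == "pocket"], 2L)        # 3, 7.999
  expect_equal(s$n[s$location == "intermediate"], 2L)  # 8, 15.0 inclusive
  expect_equal(s$n[s$location == "distal"], 2L)        # 20, 15.0001

  # all distal: other bins reported with n = 0 and undefined metrics
  d2 <- data.frame(y = rnorm(5), p = rnorm(5), distance = rep(50, 5))
  s2 <- stratify_by_location(d2, y, p)
  expect_equal(s2$n[s2$location == "distal"], 5L)
  expect_true(all(is.na(s2$pearson[s2$location != "distal"])))

  # missing distances are excluded and counted
  d3 <- data.frame(y = rnorm(4), p = rnorm(4), distance = c(1, 2, NA, NA))
  s3 <- stratify_by_location(d3, y, p)
  expect_equal(attr(s3, "n_excluded"), 2L)
  expect_equal(sum(s3$n), 2L)
})
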