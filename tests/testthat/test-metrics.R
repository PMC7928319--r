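# Overlap metrics, ROC/AUC, fold aggregation and the two-sample test.

test_that("confusion counts are exact pixel tallies", {
  truth <- matrix(0, 10, 10); truth[1:2, 1:5] <- 1
  expect_equal(unclass(confusion_counts(truth, truth))[c("TP", "FP", "FN", "TN")],
               list(TP = 10, FP = 0, FN = 0, TN = 90))
  none <- matrix(0, 10, 10)
  cc <- confusion_counts(none, truth)
  expect_equal(cc$TP, 0); expect_equal(cc$FN, 10)

  set.seed(40)
  for (i in 1:5) {
    p <- matrix(rbinom(256, 1, 0.4), 16, 16)
    t <- matrix(rbinom(256, 1, 0.4), 16, 16)
    expect_equal(unclass(confusion_counts(p, t))[c("TP", "FP", "FN", "TN")],
                 loop_confusion(p, t))
  }

  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("IoU, Dice and precision follow their defining ratios", {
  cc <- structure(list(TP = 6, FP = 2, FN = 2, TN = 90),
                  class = "confusion_counts")
  expect_equal(iou(cc), 0.6)
  expect_equal(dice(cc), 0.75)
  expect_equal(precision(cc), 0.75)

  perfect <- structure(list(TP = 50, FP = 0, FN = 0, TN = 50),
                       class = "confusion_counts")
  expect_equal(c(iou(perfect), dice(perfect), precision(perfect)), c(1, 1, 1))

  miss <- structure(list(TP = 0, FP = 3, FN = 4, TN = 93),
                    class = "confusion_counts")
  expect_equal(c(iou(miss), dice(miss)), c(0, 0))

  # both-empty convention
  empty <- structure(list(TP = 0, FP = 0, FN = 0, TN = 100),
                     class = "confusion_counts")
  expect_equal(c(iou(empty), dice(empty), precision(empty)), c(1, 1, 1))
})

test_that("the Dice-IoU identity holds on random confusion tables", {
  set.seed(41)
  for (i in 1:50) {
    cc <- structure(as.list(stats::setNames(rpois(4, 20), c("TP", "FP", "FN", "TN"))),
                    class = "confusion_counts")
    expect_equal(dice(cc), 2 * iou(cc) / (1 + iou(cc)))
  }
})

test_that("metrics are invariant to simultaneous spatial permutation", {
  set.seed(42)
  p <- matrix(rbinom(144, 1, 0.3), 12, 12)
  t <- matrix(rbinom(144, 1, 0.3), 12, 12)
  perm <- sample(144)
  c1 <- confusion_counts(p, t)
  c2 <- confusion_counts(matrix(p[perm], 12, 12), matrix(t[perm], 12, 12))
  expect_equal(c(iou(c1), dice(c1), precision(c1)),
               c(iou(c2), dice(c2), precision(c2)))
})

test_that("AUC matches hand-computed separations and handles ties by midrank", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 0, 1, 0)), 1.0)
  # frozen from the pairwise oracle: positives {0.9, 0.2}, negatives {0.4, 0.6}
  expect_equal(pairwise_auc(c(0.9, 0.4, 0.2, 0.6), c(1, 0, 1, 0)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.2, 0.6), c(1, 0, 1, 0)), 0.5)
  # constant scorer is uninformative
  expect_equal(roc_auc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  # ties: pairs (0.5 vs 0.5 -> 1/2) and (0.5 > 0.2) give 0.75
  expect_equal(roc_auc(c(0.5, 0.5, 0.2), c(1, 0, 0)), 0.75)

  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "single class")

  set.seed(43)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    s <- round(runif(n), 2)             # coarse grid to force ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), pairwise_auc(s, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(44)
  s <- runif(300); y <- rbinom(300, 1, 0.5)
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("ROC points trace a monotone curve from (0,0) to (1,1)", {
  set.seed(45)
  pts <- roc_points(runif(100), rbinom(100, 1, 0.5))
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("the two-sample t test is the classical pooled-variance form", {
  r <- two_sample_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  shifted <- two_sample_t_test(c(1, 2, 3), c(1001, 1002, 1003))
  expect_lt(shifted$p, 1e-8)

  # textbook hand computation through the pooled-variance formula
  a <- c(0.60, 0.62, 0.61); b <- c(0.70, 0.71, 0.69)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  r <- two_sample_t_test(a, b)
  expect_equal(r$t, t_hand)
  expect_equal(r$p, p_hand)
  expect_equal(r$df, 4)

  expect_error(two_sample_t_test(c(1), c(1, 2)), "at least 2")
  expect_error(two_sample_t_test(c(1, 1), c(1, 1)), "constant")
})

test_that("fold aggregation reports mean and sample SD", {
  r <- aggregate_folds(0.7)
  expect_equal(r$mean, 0.7); expect_equal(r$sd, 0)
  r <- aggregate_folds(c(0.6, 0.8))
  expect_equal(r$mean, 0.7)
  expect_equal(r$sd, sqrt(0.02))
  expect_equal(aggregate_folds(rep(0.5, 5))$sd, 0)
  expect_error(aggregate_folds(numeric(0)), "no values")
  expect_match(format(aggregate_folds(c(0.6, 0.8))), "0.700")
})

test_that("metric tables and ROC points round-trip through CSV and JSON", {
  tab <- data.frame(name = c("unet", "msunet"), mean_iou = c(0.61, 0.72),
                    sd_iou = c(0.03, 0.01))
  fc <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_metric_table(tab, fc)
  write_metric_table(tab, fj)
  back <- utils::read.csv(fc)
  expect_equal(back$mean_iou, tab$mean_iou)
  backj <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(backj$name, tab$name)
  expect_error(write_metric_table(tab, tempfile(fileext = ".xlsx")),
               "unsupported")

  pts <- roc_points(c(0.9, 0.3, 0.6), c(1, 0, 1))
  fr <- tempfile(fileext = ".csv")
  write_roc_points(pts, fr)
  expect_equal(utils::read.csv(fr)$tpr, pts$tpr)
  unlink(c(fc, fj, fr))
})
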