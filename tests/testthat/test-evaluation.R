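test_that("confusion counts match direct tallies", {
  lab <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)
  cc <- confusion_counts(lab, pred)
  expect_equal(cc[c("tp", "fn", "tn", "fp")],
               list(tp = 3, fn = 2, tn = 4, fp = 1))
  perfect <- confusion_counts(lab, lab)
  expect_equal(perfect$fp + perfect$fn, 0)
  inverted <- confusion_counts(lab, 1 - lab)
  expect_equal(inverted$tp + inverted$tn, 0)
  expect_error(confusion_counts(c(1, 2), c(0, 1)), class = "mmdda_config_error")
})

test_that("metric formulas from confusion counts", {
  cc <- confusion_counts(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                         c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1))
  m <- classification_metrics(cc)
  expect_equal(m$acc, 0.70)
  expect_equal(m$sen, 0.60)
  expect_equal(m$spe, 0.80)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6), tolerance = 1e-10)
  perfect <- classification_metrics(confusion_counts(c(1, 0), c(1, 0)))
  expect_equal(unlist(perfect), c(acc = 1, sen = 1, spe = 1, f1 = 1))
  # undefined metrics are reported as missing, never coerced to 0
  no_pos <- classification_metrics(confusion_counts(c(0, 0), c(0, 1)))
  expect_true(is.na(no_pos$sen))
  expect_false(is.na(no_pos$spe))
})

test_that("rank AUC on hand-scored examples", {
  expect_equal(rank_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.1)), 1.0)
  expect_equal(rank_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2)), 0.75)
  # ties count one half
  expect_equal(rank_auc(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_error(rank_auc(c(1, 1), c(0.2, 0.3)), class = "mmdda_config_error")
})

test_that("random scores give chance-level AUC", {
  set.seed(50)
  aucs <- replicate(500, rank_auc(rep(c(0, 1), each = 10), rnorm(20)))
  # se of the mean is ~0.006, so a 0.05 band is a ~3 sigma check
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
})

test_that("rank AUC equals the trapezoidal ROC integral", {
  trapezoid_auc <- function(labels, scores) {
    # independent oracle: sweep every threshold, integrate TPR over FPR
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
    tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t), 0)
    fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), 0)
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)      # coarse grid to exercise ties
    expect_equal(rank_auc(labels, scores), trapezoid_auc(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("reports satisfy the accuracy decomposition identity", {
  set.seed(52)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- runif(n)
    r <- metric_report(labels, scores)
    P <- r$confusion$tp + r$confusion$fn
    N <- r$confusion$tn + r$confusion$fp
    expect_equal(r$acc, (r$sen * P + r$spe * N) / (P + N))
    expect_equal(r$n, n)
  }
})

test_that("head sweep rejects counts that do not divide E", {
  cfg <- tiny_config()   # channels end at 4, so E = 8
  expect_error(head_sweep(list(), c(2, 3), cfg), "do not divide")
})
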