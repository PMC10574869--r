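random_classes <- function(n) sample(foot_classes, n, replace = TRUE)

test_that("confusion_summary equals the per-item tally oracle", {
  set.seed(21)
  for (i in 1:5) {
    pred <- random_classes(60); truth <- random_classes(60)
    cs <- confusion_summary(pred, truth)
    for (cl in foot_classes) {
      o <- tally_oracle(pred, truth, cl)
      r <- cs[cs$class == cl, ]
      expect_equal(c(tp = r$tp, fp = r$fp, fn = r$fn, tn = r$tn), o)
      expect_equal(r$tp + r$fp + r$fn + r$tn, 60)
    }
    expect_equal(sum(cs$tp), sum(pred == truth))
  }

  p <- random_classes(10)
  perfect <- confusion_summary(p, p)
  expect_true(all(perfect$fp == 0) && all(perfect$fn == 0))

  allnorm <- confusion_summary(rep("normal", 12),
                               c(rep("normal", 5), rep("mild", 4),
                                 rep("moderate", 3)))
  expect_equal(allnorm$fp[allnorm$class == "normal"], 7)
  expect_error(confusion_summary("normal", c("mild", "mild")),
               class = "flatfootr_error_input")
})

test_that("metric formulas: direct arithmetic and identities", {
  cs <- tibble::tibble(class = "normal", tp = 9, fp = 1, fn = 0, tn = 10,
                       n_total = 20)
  m <- class_metrics(cs)
  expect_equal(m$precision, 90)
  expect_equal(m$recall, 100)
  expect_equal(m$specificity, 10 / 11 * 100)
  expect_equal(m$accuracy, 95)
  expect_equal(m$error_rate, 5)

  set.seed(33)
  for (i in 1:100) {
    counts <- as.list(sample(0:20, 4, replace = TRUE))
    names(counts) <- c("tp", "fp", "fn", "tn")
    if (sum(unlist(counts)) == 0) next
    cs <- tibble::tibble(class = "mild", !!!counts,
                         n_total = sum(unlist(counts)))
    m <- class_metrics(cs)
    # complementary formulas
    expect_equal(m$accuracy + m$error_rate, 100)
    # harmonic-mean fixed point and bounds
    if (!is.na(m$precision) && !is.na(m$recall)) {
      if (m$precision == m$recall && m$precision > 0) {
        expect_equal(m$f_score, m$precision)
      }
      if (!is.na(m$f_score)) {
        expect_lte(m$f_score, max(m$precision, m$recall) + 1e-12)
        expect_gte(m$f_score, min(m$precision, m$recall) - 1e-12)
      }
    }
    # against the plain formulas
    if (counts$tp + counts$fp > 0) {
      expect_equal(m$precision,
                   counts$tp / (counts$tp + counts$fp) * 100)
    } else {
      expect_true(is.na(m$precision))
    }
  }
})

test_that("zero-denominator metrics surface as the undefined marker", {
  cs <- tibble::tibble(class = "moderate", tp = 0, fp = 0, fn = 0,
                       tn = 15, n_total = 15)
  m <- class_metrics(cs)
  expect_true(is.na(m$precision))
  expect_true(is.na(m$recall))
  expect_true(is.na(m$f_score))
  expect_equal(m$accuracy, 100)
})

test_that("overall accuracy averages the three per-angle accuracies", {
  truth <- rep(foot_classes, each = 10)
  perfect <- list(cia = truth, ma = truth, aa = truth)
  expect_equal(overall_accuracy(perfect, truth), 100)

  # known per-angle accuracies 90 / 80 / 70 -> mean 80
  flip <- function(v, k) {
    v[seq_len(k)] <- ifelse(v[seq_len(k)] == "normal", "mild", "normal")
    v
  }
  preds <- list(cia = flip(truth, 3), ma = flip(truth, 6),
                aa = flip(truth, 9))
  expect_equal(overall_accuracy(preds, truth), 80)

  set.seed(12)
  preds2 <- list(cia = random_classes(30), ma = random_classes(30),
                 aa = random_classes(30))
  manual <- mean(vapply(preds2, function(p) mean(p == truth) * 100, 1))
  expect_equal(overall_accuracy(preds2, truth), manual)
  expect_error(overall_accuracy(preds2[1:2], truth),
               class = "flatfootr_error_input")
})

test_that("per-angle error rates follow the one-vs-rest formula", {
  truth <- rep(foot_classes, each = 8)
  perfect <- list(cia = truth, ma = truth, aa = truth)
  expect_equal(unname(per_angle_error_rates(perfect, truth, "mild")),
               c(0, 0, 0))

  wrong_mild <- ifelse(truth == "mild", "moderate", truth)
  preds <- list(cia = truth, ma = truth, aa = wrong_mild)
  er <- per_angle_error_rates(preds, truth, "mild")
  o <- tally_oracle(wrong_mild, truth, "mild")
  expect_equal(er[["aa"]], (o["fn"] + o["fp"]) / 24 * 100,
               ignore_attr = TRUE)
  expect_equal(er[["cia"]], 0)
  set.seed(2)
  rnd <- list(cia = random_classes(24), ma = random_classes(24),
              aa = random_classes(24))
  for (ft in foot_classes) {
    er <- per_angle_error_rates(rnd, truth, ft)
    expect_true(all(er >= 0 & er <= 100))
  }
})

test_that("k-fold splits partition indices with near-equal sizes", {
  folds <- kfold_split(100, 10, seed = 7)
  expect_length(folds, 10)
  expect_true(all(lengths(folds) == 10))
  expect_setequal(unlist(folds), 1:100)

  folds2 <- kfold_split(23, 5, seed = 7)
  expect_setequal(unlist(folds2), 1:23)
  expect_lte(diff(range(lengths(folds2))), 1)
  expect_equal(sum(vapply(folds2, length, 1L)), 23)
  # pairwise disjoint
  expect_equal(anyDuplicated(unlist(folds2)), 0)
  # train/test pairs complement each other
  pairs <- attr(folds2, "pairs")
  for (p in pairs) expect_setequal(c(p$train, p$test), 1:23)

  expect_identical(kfold_split(40, 10, seed = 3),
                   kfold_split(40, 10, seed = 3))
  expect_false(identical(folds, kfold_split(100, 10, seed = 8)))
  expect_error(kfold_split(5, 10), class = "flatfootr_error_input")
})
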