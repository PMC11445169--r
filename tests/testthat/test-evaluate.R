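test_that("score_predictions satisfies the confusion-matrix identities", {
  # all correct
  rep0 <- score_predictions(c(0, 1, 2, 2), c(0, 1, 2, 2))
  expect_equal(rep0$per_class_accuracy, c(100, 100, 100))
  expect_equal(sum(rep0$confusion) - sum(diag(rep0$confusion)), 0)
  # degenerate predictor: always Empty on balanced truth
  rep1 <- score_predictions(rep(0, 30), rep(0:2, each = 10))
  expect_equal(rep1$per_class_accuracy, c(100, 0, 0))
  expect_equal(rep1$overall_accuracy, 100 / 3, tolerance = 1e-10)
  # hand-counted toy contingency: 10 pairs, two planted errors
  truth <- c(0, 0, 0, 0, 1, 1, 1, 2, 2, 2)
  preds <- c(0, 0, 0, 0, 0, 1, 1, 1, 2, 2)  # Single->Empty, Multiple->Single
  rep2 <- score_predictions(preds, truth)
  expect_equal(rep2$overall_accuracy, 80)
  expect_equal(unname(rep2$confusion),
               matrix(c(4, 0, 0, 1, 2, 0, 0, 1, 2), 3, byrow = TRUE))
  expect_equal(rep2$n_per_class, c(4, 3, 3))
  # type invariants on a random instance
  set.seed(2)
  t <- sample(0:2, 60, replace = TRUE); p <- sample(0:2, 60, replace = TRUE)
  r <- score_predictions(p, t)
  expect_equal(rowSums(r$confusion), r$n_per_class, ignore_attr = TRUE)
  expect_equal(r$per_class_accuracy,
               100 * diag(r$confusion) / r$n_per_class, ignore_attr = TRUE)
  expect_equal(r$overall_accuracy, 100 * sum(diag(r$confusion)) / 60)
  # permutation invariance
  o <- sample(60)
  r2 <- score_predictions(p[o], t[o])
  expect_equal(r2$confusion, r$confusion)
})

test_that("score_predictions aligns by file and reports mismatches", {
  preds <- data.frame(file = c("a", "b", "c"), label = c(0, 1, 2))
  truth <- data.frame(file = c("c", "a", "b"), label = c(2, 0, 1))
  r <- score_predictions(preds, truth)
  expect_equal(r$overall_accuracy, 100)
  truth2 <- data.frame(file = c("a", "b", "zzz"), label = c(0, 1, 2))
  expect_error(score_predictions(preds, truth2), "zzz")
})

test_that("retention curves are monotone and leave empty subsets undefined", {
  preds <- data.frame(label = c(0, 1, 2), confidence = c(60, 80, 95))
  truth <- c(1, 1, 2)  # the only error sits at confidence 60
  curve <- retention_accuracy(preds, truth, c(0, 75, 90, 99))
  expect_equal(curve$retained_fraction, c(1, 2 / 3, 1 / 3, 0))
  expect_true(all(diff(curve$retained_fraction) <= 0))
  expect_equal(curve$accuracy[1], 100 * 2 / 3, tolerance = 1e-10)
  expect_equal(curve$accuracy[2], 100)      # error filtered out
  expect_true(is.na(curve$accuracy[4]))     # empty subset: NA, never 0
  # threshold 0 reproduces overall accuracy on any random prediction set
  set.seed(5)
  p2 <- data.frame(label = sample(0:2, 50, TRUE), confidence = runif(50, 34, 100))
  t2 <- sample(0:2, 50, TRUE)
  c2 <- retention_accuracy(p2, t2, seq(0, 100, by = 10))
  expect_equal(c2$accuracy[1], score_predictions(p2$label, t2)$overall_accuracy)
  expect_true(all(diff(c2$retained_fraction) <= 0))
})

test_that("filter_by_confidence is a superlevel-set filter", {
  set.seed(6)
  preds <- data.frame(label = sample(0:2, 40, TRUE),
                      confidence = c(runif(39, 34, 99.9), 100))
  f0 <- filter_by_confidence(preds, 0)
  expect_equal(f0$retention_fraction, 1)
  f100 <- filter_by_confidence(preds, 100)
  expect_true(all(f100$retained$confidence == 100))
  expect_equal(nrow(f100$retained), 1L)
  fr <- vapply(c(0, 25, 50, 75, 90, 100),
               function(th) filter_by_confidence(preds, th)$retention_fraction,
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("Welch's t-test matches hand computation and stats::t.test", {
  same <- welch_t_test(c(4, 5, 6), c(4, 5, 6))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  a <- c(1, 2, 3); b <- a + 10
  w <- welch_t_test(a, b)
  expect_equal(w$t, -10 / sqrt(1 / 3 + 1 / 3), tolerance = 1e-12)
  expect_equal(abs(w$t), 12.247, tolerance = 1e-4)
  # swapping the samples negates t and leaves p unchanged
  w2 <- welch_t_test(b, a)
  expect_equal(w2$t, -w$t)
  expect_equal(w2$p, w$p)
  # cross-check against the reference implementation on random data
  set.seed(8)
  x <- rnorm(10, 90, 3); y <- rnorm(12, 85, 5)
  ref <- stats::t.test(x, y)
  mine <- welch_t_test(x, y)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  # both variances zero with equal means: t = 0, p = 1 by contract
  z <- welch_t_test(c(2, 2), c(2, 2))
  expect_equal(z$p, 1)
})

test_that("the paired t-test matches the reference implementation", {
  set.seed(9)
  x <- rnorm(6, 90, 4); y <- x + rnorm(6, 2, 1)
  ref <- stats::t.test(x, y, paired = TRUE)
  mine <- paired_t_test(x, y)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
})
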