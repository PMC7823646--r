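test_that("one-vs-rest counts match direct enumeration", {
  cc <- oneVsRestCounts(c("A", "A", "B"), c("A", "A", "B"), "A")
  expect_equal(cc, list(TP = 2L, FP = 0L, FN = 0L, TN = 1L),
               ignore_attr = TRUE)
  cc <- oneVsRestCounts(rep("A", 4), rep("B", 4), "A")
  expect_equal(cc$TP, 0L)
  expect_equal(cc$FN, 4L)
  set.seed(19)
  yt <- sample(letters[1:5], 500, replace = TRUE)
  yp <- sample(letters[1:5], 500, replace = TRUE)
  for (target in letters[1:5]) {
    cc <- oneVsRestCounts(yt, yp, target)
    tp <- fp <- fn <- tn <- 0L
    for (i in 1:500) {
      if (yt[i] == target && yp[i] == target) tp <- tp + 1L
      else if (yt[i] != target && yp[i] == target) fp <- fp + 1L
      else if (yt[i] == target && yp[i] != target) fn <- fn + 1L
      else tn <- tn + 1L
    }
    expect_equal(cc, list(TP = tp, FP = fp, FN = fn, TN = tn),
                 ignore_attr = TRUE)
    expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 500L)
  }
  expect_error(oneVsRestCounts(1:3, 1:4, 1), "lengths differ")
})

test_that("precision, recall and F1 follow the formulas with 0/0 -> 0", {
  expect_equal(precisionScore(list(TP = 9, FP = 1)), 0.9)
  expect_equal(recallScore(list(TP = 9, FN = 3)), 0.75)
  expect_equal(precisionScore(list(TP = 0, FP = 0)), 0)
  expect_equal(recallScore(list(TP = 0, FN = 0)), 0)
  expect_equal(f1Score(precision = 0, recall = 0), 0)
  expect_equal(f1Score(precision = 0.67, recall = 0.45),
               2 * 0.67 * 0.45 / (0.67 + 0.45))
  # harmonic mean lies between min and max of precision and recall
  set.seed(23)
  for (i in 1:50) {
    p <- runif(1); r <- runif(1)
    f <- f1Score(precision = p, recall = r)
    expect_gte(f, min(p, r) - 1e-12)
    expect_lte(f, max(p, r) + 1e-12)
  }
})

test_that("accuracy and Hamming loss satisfy the one-hot identity", {
  expect_equal(accuracyScore(1:5, 1:5), 1)
  expect_equal(accuracyScore(1:4, 5:8), 0)
  expect_equal(accuracyScore(c(rep(1, 976), rep(2, 24)), rep(1, 1000)), 0.976)
  onehot <- function(y, n) {
    m <- matrix(0L, length(y), n); m[cbind(seq_along(y), y)] <- 1L; m
  }
  # perfect prediction
  y <- sample.int(7, 100, replace = TRUE)
  expect_equal(hammingLoss(onehot(y, 7), onehot(y, 7)), 0)
  # identity 2 (1 - accuracy) / N on random single-label data
  set.seed(31)
  for (n in c(7L, 8L)) {
    yt <- sample.int(n, 400, replace = TRUE)
    yp <- sample.int(n, 400, replace = TRUE)
    expect_equal(hammingLoss(onehot(yt, n), onehot(yp, n)),
                 2 * (1 - accuracyScore(yt, yp)) / n, tolerance = 1e-12)
  }
  expect_error(hammingLoss(onehot(1:3, 4), matrix(1, 3, 4)), "one-hot")
})

test_that("Kruskal-Wallis matches the hand-ranked statistic and handles ties", {
  kw <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-9)  # 3.857
  expect_equal(kw$df, 1L)
  expect_equal(kruskalWallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0)
  expect_equal(kruskalWallis(list(rep(2, 4), rep(2, 5)))$H, 0)
  # invariance under monotone transformation
  set.seed(5)
  g1 <- runif(12); g2 <- runif(15) + 0.2
  expect_equal(kruskalWallis(list(g1, g2))$H,
               kruskalWallis(list(exp(g1), exp(g2)))$H, tolerance = 1e-12)
  expect_error(kruskalWallis(list(1:3)), "two groups")
})

test_that("metricsReport aggregates counts micro-consistently", {
  set.seed(41)
  yt <- sample.int(8, 300, replace = TRUE)
  yp <- ifelse(runif(300) < 0.8, yt, sample.int(8, 300, replace = TRUE))
  rep8 <- metricsReport(yt, yp, bodyParts(), "knn", "S")
  # summed one-vs-rest TP over classes equals the correct predictions
  tps <- vapply(1:8, function(i) oneVsRestCounts(yt, yp, i)$TP, integer(1))
  expect_equal(sum(tps), sum(yt == yp))
  expect_equal(rep8@accuracy, mean(yt == yp))
  expect_equal(rep8@hammingLoss, 2 * (1 - rep8@accuracy) / 8)
  expect_true(all(rep8@perClass$f1 >= 0 & rep8@perClass$f1 <= 1))
})

test_that("report comparison groups metrics and degenerates to H = 0", {
  set.seed(43)
  yt <- sample.int(8, 200, replace = TRUE)
  r1 <- metricsReport(yt, yt, bodyParts(), "knn", "S")
  r2 <- metricsReport(yt, yt, bodyParts(), "nn", "S")
  kw <- compareReports(list(r1, r2), by = "method")
  expect_equal(kw$precision$H, 0)
  expect_equal(kw$precision$df, 1L)
  # three position groups -> df = 2
  r3 <- metricsReport(yt, yt, bodyParts(), "knn", "N")
  yt7 <- sample.int(7, 200, replace = TRUE)
  r4 <- metricsReport(yt7, yt7, bodyParts()[1:7], "knn", "U")
  kw3 <- compareReports(list(r1, r3, r4), by = "position")
  expect_equal(kw3$recall$df, 2L)
  expect_error(compareReports(list(r1), by = "method"), "two distinct")
  # fully separated constant shift: closed-form two-group rank H
  ra <- r1; rb <- r2
  ra@perClass$precision <- seq(0.1, 0.45, length.out = 8)
  rb@perClass$precision <- seq(0.1, 0.45, length.out = 8) + 0.5
  kw2 <- compareReports(list(ra, rb), by = "method")
  n <- 16; R1 <- sum(1:8); R2 <- sum(9:16)
  H <- 12 / (n * (n + 1)) * (R1^2 / 8 + R2^2 / 8) - 3 * (n + 1)
  expect_equal(kw2$precision$H, H, tolerance = 1e-9)
})
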