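test_that("confusion matrices count true x predicted pairs", {
  # true NM, NM, AT; predicted NM, AT, AT
  cm <- confusion(c("NM", "AT", "AT"), c("NM", "NM", "AT"),
                  classes = c("NM", "AT"))
  expect_equal(cm["NM", "NM"], 1L)
  expect_equal(cm["NM", "AT"], 1L)
  expect_equal(cm["AT", "AT"], 1L)
  expect_equal(sum(cm), 3L)
  # perfect predictions give a diagonal matrix
  perfect <- confusion(c("NM", "AT"), c("NM", "AT"), c("NM", "AT"))
  expect_true(all(perfect[row(perfect) != col(perfect)] == 0))
  expect_error(confusion("NM", "XX", c("NM", "AT")), "outside")
  expect_error(confusion(c("NM", "AT"), "NM", c("NM", "AT")), "equal length")
})

test_that("row-normalized confusion rows sum to 1 (empty rows stay 0)", {
  cm <- confusion(c("NM", "NM", "NM"), c("NM", "NM", "AT"),
                  classes = c("NM", "AT", "CTM"))
  nc <- normalize_confusion(cm)
  expect_equal(unname(rowSums(nc)), c(1, 1, 0))
})

test_that("metrics follow the harmonic-mean F1 formula", {
  # P = 0.8, R = 0.6 for class A: TP=12, FP=3, FN=8
  cm <- matrix(c(12, 3, 8, 27), 2, 2,
               dimnames = list(true = c("A", "B"), predicted = c("A", "B")))
  ev <- metrics(cm)
  expect_equal(unname(ev$precision["A"]), 0.8)
  expect_equal(unname(ev$recall["A"]), 0.6)
  expect_equal(unname(ev$f1["A"]), 0.6857, tolerance = 1e-4)
  # P = R implies F1 = P
  cm2 <- matrix(c(5, 5, 5, 5), 2, 2,
                dimnames = list(true = c("A", "B"),
                                predicted = c("A", "B")))
  ev2 <- metrics(cm2)
  expect_equal(unname(ev2$f1), unname(ev2$precision))
  # diagonal matrix: accuracy 1, macro-F1 1
  ev3 <- metrics(confusion(c("A", "B"), c("A", "B"), c("A", "B")))
  expect_equal(ev3$accuracy, 1)
  expect_equal(ev3$macro_f1, 1)
  # all-wrong class: F1 = 0, not NaN
  cm4 <- matrix(c(0, 0, 10, 10), 2, 2,
                dimnames = list(true = c("A", "B"),
                                predicted = c("A", "B")))
  expect_equal(unname(metrics(cm4)$f1["A"]), 0)
})

test_that("metrics agree with a brute-force per-record recount", {
  # independent oracle: recompute every metric by direct enumeration over
  # the raw prediction/label pairs
  brute <- function(preds, labels, classes) {
    acc <- mean(preds == labels)
    f1s <- vapply(classes, function(k) {
      tp <- sum(preds == k & labels == k)
      p <- if (sum(preds == k) == 0) 0 else tp / sum(preds == k)
      r <- if (sum(labels == k) == 0) 0 else tp / sum(labels == k)
      if (p + r == 0) 0 else 2 * p * r / (p + r)
    }, numeric(1))
    list(acc = acc, macro = mean(f1s))
  }
  set.seed(42)
  classes <- c("A", "B", "C", "D")
  for (i in 1:1000) {
    n <- sample(2:30, 1)
    labels <- sample(classes, n, replace = TRUE)
    preds <- ifelse(runif(n) < 0.6, labels, sample(classes, n, TRUE))
    ev <- metrics(confusion(preds, labels, classes))
    bf <- brute(preds, labels, classes)
    expect_equal(ev$accuracy, bf$acc)
    expect_equal(ev$macro_f1, bf$macro)
  }
})

test_that("macro-F1 tracks accuracy on balanced, uniform test sets", {
  # class-balanced truth with the same error rate in every class
  set.seed(7)
  classes <- morph_classes()
  labels <- rep(classes, each = 200)
  preds <- ifelse(runif(length(labels)) < 0.8, labels,
                  sample(classes, length(labels), TRUE))
  ev <- metrics(confusion(preds, labels, classes))
  expect_lt(abs(ev$macro_f1 - ev$accuracy), 0.02)
})

test_that("all-correct records give a degenerate unit CI", {
  rec <- make_records(3, 2, 20, 1, seed = 1)
  rec$correct <- 1
  ci <- hier_bootstrap(rec, B = 200, seed = 5)
  expect_equal(ci$point, 1)
  expect_equal(ci$lower, 1)
  expect_equal(ci$upper, 1)
  expect_error(hier_bootstrap(rec[0, ], B = 10), "empty")
  expect_error(hier_bootstrap(rec, B = 0), "B must be")
})

test_that("single bull and ejaculate reduces to a flat image bootstrap", {
  rec <- make_records(1, 1, 400, 0.8, seed = 2)
  ci <- hier_bootstrap(rec, B = 2000, seed = 3)
  # independent flat-bootstrap oracle over images
  set.seed(3)
  flat <- replicate(2000, mean(sample(rec$correct, nrow(rec),
                                      replace = TRUE)))
  qs <- quantile(flat, c(0.025, 0.975), names = FALSE)
  expect_equal(ci$point, mean(rec$correct))
  expect_lt(abs(ci$lower - qs[1]), 0.01)
  expect_lt(abs(ci$upper - qs[2]), 0.01)
})

test_that("CI width shrinks with images only when bulls do not dominate", {
  # no bull effects: more images per ejaculate tightens the CI
  small <- hier_bootstrap(make_records(6, 2, 30, 0.8, seed = 4),
                          B = 600, seed = 1)
  big <- hier_bootstrap(make_records(6, 2, 600, 0.8, seed = 4),
                        B = 600, seed = 1)
  expect_lt(big$upper - big$lower, small$upper - small$lower)
  # dominant bull effects: width floor set by between-bull sampling
  smallb <- hier_bootstrap(make_records(6, 2, 30, 0.8, seed = 5,
                                        bull_sd = 0.12),
                           B = 600, seed = 1)
  bigb <- hier_bootstrap(make_records(6, 2, 600, 0.8, seed = 5,
                                      bull_sd = 0.12),
                         B = 600, seed = 1)
  expect_gt(bigb$upper - bigb$lower, 0.5 * (smallb$upper - smallb$lower))
})

test_that("identical record sets are never significantly different", {
  rec <- make_records(4, 2, 50, 0.8, seed = 6)
  sd0 <- significant_difference(rec, rec, paired = TRUE, B = 500, seed = 2)
  expect_equal(sd0$diff, 0)
  expect_false(sd0$is_significant)
  # the CI-excludes-zero rule
  expect_true(sd0$ci$lower <= 0 && sd0$ci$upper >= 0)
})

test_that("clear accuracy differences are detected as significant", {
  a <- make_records(6, 2, 200, 0.9, seed = 7)
  b <- make_records(6, 2, 200, 0.7, seed = 8)
  sd1 <- significant_difference(a, b, paired = FALSE, B = 800, seed = 3)
  expect_equal(sd1$diff, mean(a$correct) - mean(b$correct))
  expect_true(sd1$is_significant)
  expect_gt(sd1$ci$lower, 0)
  # paired mode demands aligned clusters
  expect_error(significant_difference(a, b[1:100, ], paired = TRUE, B = 10),
               "aligned")
})

test_that("generalization matrices expose cells and percentage-point gaps", {
  cells <- data.frame(
    train_domain = c("frozen", "frozen", "fresh", "fresh"),
    test_domain = c("frozen", "fresh", "frozen", "fresh"),
    accuracy = c(83.58, 68.75, 66.12, 76.39))
  m <- generalization_matrix(cells)
  expect_equal(gap(m, "frozen", "frozen", "fresh"), -14.83)
  expect_equal(gap(m, "fresh", "fresh", "frozen"), -10.27)
  expect_equal(gap(m, "fresh", "fresh", "fresh"), 0)
  expect_error(gap(m, "frozen", "frozen", "thawed"), "no cell")
  expect_error(generalization_matrix(rbind(cells, cells[1, ])), "duplicate")
})

test_that("generalization reports are pure functions of the run table", {
  cells <- data.frame(train_domain = "A", test_domain = c("A", "B"),
                      accuracy = c(90.123, 80.456),
                      lower = c(89.1, 79.2), upper = c(91.2, 81.9))
  m <- generalization_matrix(cells)
  r1 <- report_generalization(m)
  r2 <- report_generalization(m)
  expect_identical(r1, r2)
  expect_true(any(grepl("90.12 \\[89.1-91.2\\]", r1)))
})
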