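test_that("quota sampling returns exactly the quota per stratum", {
  man <- meta_manifest(n_per_stratum = 8)
  sel <- quota_sample(man, quota = 5, rng_seed = 1)
  expect_equal(nrow(sel), 5 * 10 * 3 * 2)
  counts <- table(sel$label, sel$breed, sel$condition)
  expect_true(all(counts == 5))
  # no duplicates, subset of input, order preserved
  expect_false(anyDuplicated(sel$image_id) > 0)
  expect_true(all(sel$image_id %in% man$image_id))
  expect_false(is.unsorted(match(sel$image_id, man$image_id)))
  expect_equal(nrow(quota_sample(man, quota = 0)), 0)
})

test_that("quota shortfall errors by default and names the stratum", {
  man <- meta_manifest(n_per_stratum = 3, breeds = "KW",
                       conditions = "fresh", classes = c("NM", "AT"))
  expect_error(quota_sample(man, quota = 5), "NM|AT")
  short <- quota_sample(man, quota = 5, allow_short = TRUE)
  expect_equal(nrow(short), 6) # all 3 rows of both strata
})

test_that("quota sampling is seed-deterministic but seed-sensitive", {
  man <- meta_manifest(n_per_stratum = 10)
  s1 <- quota_sample(man, quota = 4, rng_seed = 7)
  s2 <- quota_sample(man, quota = 4, rng_seed = 7)
  s3 <- quota_sample(man, quota = 4, rng_seed = 8)
  expect_identical(s1, s2)
  expect_false(identical(s1$image_id, s3$image_id))
})

test_that("stratified split partitions with per-stratum 80/10/10", {
  man <- meta_manifest(n_per_stratum = 10, breeds = "KW",
                       conditions = "fresh") # 10 classes x 10
  sp <- stratified_split(man, rng_seed = 3)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$val), 10)
  expect_equal(nrow(sp$test), 10)
  # partition: disjoint and exhaustive
  ids <- c(sp$train$image_id, sp$val$image_id, sp$test$image_id)
  expect_setequal(ids, man$image_id)
  expect_equal(anyDuplicated(ids), 0L)
  # per-stratum proportions
  expect_true(all(table(sp$train$label) == 8))
  expect_true(all(table(sp$val$label) == 1))
  # deterministic at fixed seed, different across seeds
  sp2 <- stratified_split(man, rng_seed = 3)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(man, rng_seed = 4)
  expect_false(identical(sp$test$image_id, sp3$test$image_id))
})

test_that("single-stratum 1000-row split yields 800/100/100", {
  man <- data.frame(image_id = sprintf("r%04d", 1:1000), label = "NM")
  sp <- stratified_split(man, rng_seed = 1)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 800L, val = 100L, test = 100L))
})

test_that("tiny strata are rejected", {
  man <- data.frame(image_id = c("a", "b"), label = "NM")
  expect_error(stratified_split(man), "too small")
})

test_that("LOBO folds hold out each breed exactly once", {
  man <- meta_manifest(n_per_stratum = 10)
  folds <- lobo_folds(man, rng_seed = 2)
  expect_length(folds, 3)
  expect_setequal(vapply(folds, `[[`, character(1), "held_out"),
                  c("KW", "SIM", "AUL"))
  f <- folds[["AUL"]]
  expect_false("AUL" %in% c(f$train$breed, f$val$breed))
  expect_true(all(f$test$breed == "AUL"))
  # validation is 20% of the non-held-out rows (up to rounding)
  n_rest <- nrow(f$train) + nrow(f$val)
  expect_equal(nrow(f$val) / n_rest, 0.2, tolerance = 0.01)
  # folds cover all rows
  expect_equal(nrow(f$train) + nrow(f$val) + nrow(f$test), nrow(man))
  expect_error(lobo_folds(man[man$breed == "KW", ]), ">= 2 levels")
})

test_that("fraction subsets are nested, stratified and end at the full set", {
  man <- meta_manifest(n_per_stratum = 10, breeds = "KW",
                       conditions = "fresh") # balanced 100 rows
  subs <- fraction_subsets(man, c(0.1, 0.2, 0.5, 1), rng_seed = 5)
  expect_identical(subs[["1"]], man)
  expect_equal(nrow(subs[["0.2"]]), 20)
  expect_true(all(table(subs[["0.2"]]$label) == 2)) # class-balanced
  for (pair in list(c("0.1", "0.2"), c("0.2", "0.5"), c("0.5", "1")))
    expect_true(all(subs[[pair[1]]]$image_id %in% subs[[pair[2]]]$image_id))
})

test_that("balanced batches equalize class exposure on imbalanced pools", {
  n <- 1000
  man <- data.frame(image_id = sprintf("r%04d", 1:n),
                    label = rep(c("NM", "CTM"), times = c(900, 100)),
                    breed = "KW",
                    bull_id = rep(sprintf("b%d", 1:3), length.out = n))
  bb <- balanced_batches(man, batch_size = 50, rng_seed = 4,
                         n_draws = 10000)
  draws <- unlist(bb$batches)
  expect_length(draws, 10000)
  freq <- mean(man$label[draws] == "CTM")
  expect_equal(freq, 0.5, tolerance = 0.02)
  expect_true(bb$replacement)
  # already-balanced pool stays balanced
  man2 <- man
  man2$label <- rep(c("NM", "CTM"), each = 500)
  bb2 <- balanced_batches(man2, batch_size = 50, rng_seed = 4,
                          n_draws = 10000)
  expect_equal(mean(man2$label[unlist(bb2$batches)] == "CTM"), 0.5,
               tolerance = 0.02)
})

test_that("caps bound distinct images per bull in the epoch pool", {
  n <- 600
  man <- data.frame(image_id = sprintf("r%04d", 1:n),
                    label = rep(c("NM", "AT"), length.out = n),
                    breed = "KW",
                    bull_id = rep(sprintf("b%d", 1:3), each = 200))
  bb <- balanced_batches(man, batch_size = 64, rng_seed = 9,
                         per_bull_cap = 100)
  per_bull <- table(man$bull_id[bb$pool])
  expect_true(all(per_bull <= 100))
  drawn_bulls <- table(man$bull_id[unique(unlist(bb$batches))])
  expect_true(all(drawn_bulls <= 100))
  expect_error(balanced_batches(man, per_bull_cap = 0), "caps")
})
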