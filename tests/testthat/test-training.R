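# Training uses small cached pools of rendered synthetic images; LP trains
# only the head, so most checks run in seconds.

two_class_data <- function(n_per_class = 200, noise_sd = 2, seed0 = 1000) {
  cached(paste("tc", n_per_class, noise_sd, seed0, sep = "_"), {
    dom <- domain_params(noise_sd = noise_sd)
    labs <- rep(c("NM", "CTM"), each = n_per_class)
    imgs <- lapply(seq_along(labs), function(i)
      generate_cell(labs[i], dom, rng_seed = seed0 + i)$image)
    x <- prepare_inputs(imgs)
    set.seed(99)
    idx <- sample(length(labs), round(0.8 * length(labs)))
    list(train = list(x = x[idx, , drop = FALSE], y = labs[idx]),
         val = list(x = x[-idx, , drop = FALSE], y = labs[-idx]))
  })
}

test_that("a single-class training set is fit perfectly", {
  d <- two_class_data()
  keep <- d$train$y == "NM"
  vkeep <- d$val$y == "NM"
  data <- list(train = list(x = d$train$x[keep, ], y = d$train$y[keep]),
               val = list(x = d$val$x[vkeep, ], y = d$val$y[vkeep]))
  # full-batch probe: the one-class optimum is reached through the bias
  cfg <- train_config("LP", max_epochs_lp = 30, patience = 30,
                      batch_size = 512, lr_lp = 1e-2,
                      classes = c("NM", "CTM"), seed = 1)
  m <- linear_probe(data, cfg)
  expect_equal(m$val_accuracy, 1)
  expect_true(all(predict(m, data$val$x)$labels == "NM"))
})

test_that("linear probing never touches the frozen backbone", {
  d <- two_class_data()
  cfg <- train_config("LP", max_epochs_lp = 5, classes = c("NM", "CTM"),
                      seed = 2)
  ref <- linear_probe(list(train = list(x = d$train$x[1:4, ],
                                        y = d$train$y[1:4]),
                           val = d$val), cfg)
  m <- linear_probe(d, cfg)
  expect_identical(backbone_checksum(m), backbone_checksum(ref))
  expect_identical(m$params$conv_w, ref$params$conv_w)
  expect_error(linear_probe(list(train = list(x = NULL, y = character()),
                                 val = d$val), cfg), "empty train")
})

test_that("well-separated classes are linearly probed to high accuracy", {
  d <- two_class_data() # low noise NM vs CTM, n = 400
  cfg <- train_config("LP", max_epochs_lp = 20, patience = 20,
                      classes = c("NM", "CTM"), seed = 3)
  m <- linear_probe(d, cfg)
  expect_gte(m$val_accuracy, 0.95)
  # independent oracle: the task is linearly separable in pixel space
  skip_if_not_installed("glmnet")
  fit <- glmnet::glmnet(d$train$x, factor(d$train$y), family = "binomial",
                        lambda = 0.01)
  oracle_acc <- mean(predict(fit, d$val$x, type = "class") == d$val$y)
  expect_gt(oracle_acc, 0.9)
})

test_that("zero fine-tuning epochs return the model unchanged", {
  d <- two_class_data()
  cfg <- train_config("LP_FT", max_epochs_lp = 5, max_epochs_ft = 0,
                      classes = c("NM", "CTM"), seed = 4)
  m <- linear_probe(d, cfg)
  expect_identical(fine_tune(m, d, cfg), m)
})

test_that("fine-tuning warns when the rate is not reduced", {
  d <- two_class_data()
  cfg <- train_config("LP_FT", max_epochs_lp = 2, max_epochs_ft = 1,
                      classes = c("NM", "CTM"), seed = 5, lr_ft = 1e-3)
  m <- linear_probe(d, cfg)
  expect_warning(fine_tune(m, d, cfg), "reduced")
})

test_that("fine-tuning decreases training loss and keeps the best val acc", {
  d <- two_class_data()
  cfg <- train_config("LP_FT", max_epochs_lp = 8, max_epochs_ft = 6,
                      patience = 6, classes = c("NM", "CTM"), seed = 6)
  mlp <- linear_probe(d, cfg)
  mft <- fine_tune(mlp, d, cfg)
  expect_gte(mft$val_accuracy, mlp$val_accuracy)
  ft_loss <- mft$log$train_loss[mft$log$phase == "ft"]
  sm <- stats::filter(ft_loss, rep(1 / 3, 3), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 0.02)) # smoothed trend non-increasing
})

test_that("prediction is a proper, batch-invariant probability model", {
  d <- two_class_data()
  cfg <- train_config("LP", max_epochs_lp = 5, classes = c("NM", "CTM"),
                      seed = 7)
  m <- linear_probe(d, cfg)
  pr <- predict(m, d$val$x)
  expect_equal(unname(rowSums(pr$probs)), rep(1, nrow(d$val$x)),
               tolerance = 1e-6)
  # duplicated input -> identical outputs
  x2 <- d$val$x[c(1, 1), , drop = FALSE]
  p2 <- predict(m, x2)$probs
  expect_identical(p2[1, ], p2[2, ])
  # batch-of-1 vs batch-of-64 agreement
  pa <- predict(m, d$val$x, batch_size = 1)$probs
  pb <- predict(m, d$val$x, batch_size = 64)$probs
  expect_lt(max(abs(pa - pb)), 1e-5)
  expect_error(predict(m, array(0, c(10, 10, 3))), "224 x 224 x 3")
  expect_error(predict(m, matrix(0, 2, 7)), "1024")
})

test_that("model inputs can be classified directly", {
  d <- two_class_data()
  cfg <- train_config("LP", max_epochs_lp = 5, classes = c("NM", "CTM"),
                      seed = 8)
  m <- linear_probe(d, cfg)
  img <- generate_cell("NM", domain_params(noise_sd = 2), 77)$image
  pr <- predict(m, to_model_input(img))
  expect_equal(dim(pr$probs), c(1L, 2L))
})

test_that("training is fully reproducible from config and seed", {
  d <- two_class_data()
  cfg <- train_config("LP_FT", max_epochs_lp = 4, max_epochs_ft = 2,
                      classes = c("NM", "CTM"), seed = 9)
  m1 <- train_classifier(d, cfg)
  m2 <- train_classifier(d, cfg)
  expect_identical(m1$best_epoch, m2$best_epoch)
  expect_equal(m1$params, m2$params, tolerance = 1e-12)
  p1 <- predict(m1, d$val$x)$probs
  p2 <- predict(m2, d$val$x)$probs
  expect_lt(max(abs(p1 - p2)), 1e-6)
})

test_that("unknown backbones and labels are rejected", {
  d <- two_class_data()
  cfg <- train_config("LP", backbone_id = "resnet-50",
                      classes = c("NM", "CTM"))
  expect_error(linear_probe(d, cfg), "not built in")
  cfg2 <- train_config("LP", max_epochs_lp = 1, classes = c("NM", "AT"))
  expect_error(linear_probe(d, cfg2), "outside the configured class list")
})
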