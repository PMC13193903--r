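doms <- default_domains()
dom <- doms[["KW.fresh"]]

test_that("generated defect sets round-trip to their class", {
  for (cls in morph_classes()) {
    for (seed in seq(0, 99, by = 4)) {
      g <- generate_cell(cls, dom, rng_seed = seed)
      expect_equal(assign_label(g$defects), cls)
    }
  }
})

test_that("normal cells have no defects and coiled tails carry their tag", {
  g <- generate_cell("NM", dom, rng_seed = 0)
  expect_length(g$defects$defects, 0)
  expect_false(g$defects$multiplet || g$defects$debris)
  g2 <- generate_cell("CTM", dom, rng_seed = 1)
  expect_true("coiled_tail_midpiece" %in% g2$defects$defects)
})

test_that("rendering is deterministic and 8-bit on the default canvas", {
  a <- generate_cell("AT", dom, rng_seed = 7)
  b <- generate_cell("AT", dom, rng_seed = 7)
  expect_identical(a$image, b$image)
  expect_identical(dim(a$image), c(96L, 96L))
  expect_true(all(a$image >= 0 & a$image <= 255))
  expect_true(is.integer(a$image))
  d <- generate_cell("AT", dom, rng_seed = 8)
  expect_false(identical(a$image, d$image))
  expect_error(generate_cell("XYZ", dom, rng_seed = 1), "unknown class")
})

test_that("proximal droplets render as bright blobs in the proximal half", {
  hits <- 0
  for (seed in 1:10) {
    g <- generate_cell("PCD", dom, rng_seed = seed)
    expect_lt(g$params[["droplet_position"]], 0.5)
    # brute-force bright-blob detection: largest connected component of
    # near-saturated pixels (stray noise pixels form tiny components)
    mask <- EBImage::bwlabel(g$image >= 248)
    sizes <- table(mask[mask > 0])
    if (length(sizes) == 0 || max(sizes) < 10) next # clipped at the edge
    blob <- as.integer(names(which.max(sizes)))
    bright <- which(mask == blob, arr.ind = TRUE)
    ctr <- colMeans(bright) # (y, x)
    p <- g$params
    d_neck <- sqrt((ctr[2] - p[["neck_x"]])^2 + (ctr[1] - p[["neck_y"]])^2)
    lm <- sqrt((p[["mid_end_x"]] - p[["neck_x"]])^2 +
                 (p[["mid_end_y"]] - p[["neck_y"]])^2)
    expect_lt(d_neck / lm, 0.5)
    hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("manifest counts follow the acquisition hierarchy", {
  h <- hierarchy_spec(n_bulls = 2, ejaculates_per_bull = c(fresh = 1),
                      files_per_ejaculate = 1, events_per_file = 30,
                      seed = 3)
  m <- generate_dataset(h, doms)
  expect_equal(nrow(m), 60)
  expect_setequal(unique(m$bull_id), c("bull01", "bull02"))
  h0 <- hierarchy_spec(n_bulls = 0)
  expect_equal(nrow(generate_dataset(h0, doms)), 0)
})

test_that("label frequencies follow the class mixture", {
  h <- hierarchy_spec(n_bulls = 1, ejaculates_per_bull = c(fresh = 1),
                      files_per_ejaculate = 1, events_per_file = 10000,
                      seed = 11)
  m <- generate_dataset(h, doms, include_params = FALSE)
  obs <- table(factor(m$label, morph_classes()))
  gof <- chisq.test(obs, p = default_class_mixture())
  expect_gt(gof$p.value, 0.01)
})

test_that("bull random effects induce intra-bull dependence", {
  h <- hierarchy_spec(n_bulls = 8, ejaculates_per_bull = c(fresh = 1),
                      files_per_ejaculate = 1, events_per_file = 150,
                      bull_effect_sd = 0.08, ejaculate_effect_sd = 0,
                      breed_of_bull = "KW", seed = 5)
  m <- generate_dataset(h, doms)
  # between-bull variance component must be visible against within-bull noise
  fit <- stats::aov(log(head_length_px) ~ bull_id, data = m)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  expect_lt(p, 0.01)
  h0 <- hierarchy_spec(n_bulls = 8, ejaculates_per_bull = c(fresh = 1),
                       files_per_ejaculate = 1, events_per_file = 150,
                       bull_effect_sd = 0, ejaculate_effect_sd = 0,
                       breed_of_bull = "KW", seed = 5)
  m0 <- generate_dataset(h0, doms)
  fit0 <- stats::aov(log(head_length_px) ~ bull_id, data = m0)
  p0 <- summary(fit0)[[1]][["Pr(>F)"]][1]
  expect_gt(p0, 0.01)
})

test_that("datasets are reproducible and rows carry stable per-image seeds", {
  h <- hierarchy_spec(n_bulls = 2, ejaculates_per_bull = c(fresh = 1),
                      files_per_ejaculate = 1, events_per_file = 20,
                      seed = 9)
  m1 <- generate_dataset(h, doms)
  m2 <- generate_dataset(h, doms)
  expect_identical(m1, m2)
  imgs1 <- render_images(m1[1:3, ], doms)
  imgs2 <- render_images(m1[1:3, ], doms)
  expect_identical(imgs1, imgs2)
})

test_that("generator config round-trips bit-exactly", {
  h <- hierarchy_spec(events_per_file = 123, bull_effect_sd = 1 / 3,
                      seed = 42)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(h, doms, path)
  back <- read_generator_config(path)
  expect_equal(back$hierarchy, h)
  expect_equal(back$domains, doms)
  expect_identical(back$hierarchy$bull_effect_sd, 1 / 3)
})

test_that("rendered PNGs read back to the rendered pixels", {
  h <- hierarchy_spec(n_bulls = 1, ejaculates_per_bull = c(fresh = 1),
                      files_per_ejaculate = 1, events_per_file = 2,
                      seed = 13)
  m <- generate_dataset(h, doms)
  dir <- withr::local_tempdir()
  m2 <- render_manifest(m, dir, doms)
  expect_true(all(file.exists(m2$path)))
  img <- render_images(m[1, , drop = FALSE], doms)[[1]]
  back <- read_cell_image(m2$path[1])
  expect_lt(max(abs(back - img)), 0.51) # 8-bit quantization only
})
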