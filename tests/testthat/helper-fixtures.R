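# Shared fixtures, built in code. Pools of rendered+featurized synthetic
# images are cached per test session (rendering is the slow step).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

# class-balanced single-domain pool: n_per_class images of every class,
# rendered under `domkey` and featurized
balanced_pool <- function(n_per_class, domkey = "KW.fresh", seed0 = 5000) {
  cached(paste("bp", n_per_class, domkey, seed0, sep = "_"), {
    doms <- default_domains()
    dom <- doms[[domkey]]
    labs <- rep(morph_classes(), each = n_per_class)
    imgs <- lapply(seq_along(labs), function(i)
      generate_cell(labs[i], dom, rng_seed = seed0 + i)$image)
    manifest <- data.frame(
      image_id = sprintf("fx_%s_%04d", domkey, seq_along(labs)),
      bull_id = sprintf("bull%02d", (seq_along(labs) - 1) %% 3 + 1),
      breed = dom$breed, condition = dom$condition, season = dom$season,
      ejaculate_id = sprintf("ej%02d", (seq_along(labs) - 1) %% 6 + 1),
      label = labs, stringsAsFactors = FALSE)
    structure(list(manifest = manifest,
                   x = prepare_inputs(imgs)), class = "ifc_pool")
  })
}

# small metadata-only labeled manifest with balanced strata
meta_manifest <- function(n_per_stratum = 10,
                          breeds = c("KW", "SIM", "AUL"),
                          conditions = c("fresh", "frozen"),
                          classes = morph_classes()) {
  g <- expand.grid(label = classes, breed = breeds, condition = conditions,
                   i = seq_len(n_per_stratum), stringsAsFactors = FALSE)
  g$bull_id <- paste0("bull_", g$breed, "_", (g$i - 1) %% 2 + 1)
  g$ejaculate_id <- paste0(g$bull_id, "_", g$condition, "_1")
  g$season <- ifelse(g$condition == "frozen", "summer", "spring")
  g$image_id <- sprintf("m%06d", seq_len(nrow(g)))
  g$i <- NULL
  g
}

# bernoulli records nested in bulls/ejaculates
make_records <- function(n_bulls, ej_per_bull, n_img, p, seed,
                         bull_sd = 0, ej_sd = 0) {
  set.seed(seed)
  rows <- list()
  for (b in seq_len(n_bulls)) {
    pb <- min(0.999, max(0.001, p + rnorm(1, 0, bull_sd)))
    for (e in seq_len(ej_per_bull)) {
      pe <- min(0.999, max(0.001, pb + rnorm(1, 0, ej_sd)))
      rows[[length(rows) + 1]] <- data.frame(
        bull_id = sprintf("b%02d", b),
        ejaculate_id = sprintf("b%02d_e%d", b, e),
        correct = rbinom(n_img, 1, pe))
    }
  }
  do.call(rbind, rows)
}
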