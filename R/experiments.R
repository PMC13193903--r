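# Experiment runners: LOBO learning curves over labeled-data fractions and
# cross-domain generalization matrices. All runners work on a "featurized
# pool" (manifest + stem-feature matrix) so that images are rendered and
# standardized exactly once per experiment.

#' Render and featurize a manifest into an experiment pool
#'
#' Renders every manifest row ([render_images()]), applies the model-input
#' standardization and the backbone stem ([prepare_inputs()]) and returns the
#' manifest together with the aligned feature matrix.
#'
#' @param manifest manifest rows (with parameter columns).
#' @param doms named list of [domain_params()].
#' @param policy optional training [augment_policy()] applied during
#'   featurization (use `NULL` for evaluation pools).
#' @param canvas rendered frame size.
#' @param rng_seed seed for augmentation draws (unused when `policy` is
#'   `NULL`; rendering uses the manifest's own per-image seeds).
#' @return an `ifc_pool`: `list(manifest =, x =)`.
#' @export
featurize_pool <- function(manifest, doms = default_domains(), policy = NULL,
                           canvas = c(96, 96), rng_seed = 1) {
  imgs <- render_images(manifest, doms, canvas)
  x <- prepare_inputs(imgs, policy = policy, rng_seed = rng_seed)
  structure(list(manifest = manifest, x = x), class = "ifc_pool")
}

# row indices of `sub` (a manifest subset) inside the pool
.pool_rows <- function(pool, sub) {
  i <- match(sub$image_id, pool$manifest$image_id)
  if (anyNA(i)) stop("manifest rows not found in pool")
  i
}

.pool_data <- function(pool, sub) {
  i <- .pool_rows(pool, sub)
  list(x = pool$x[i, , drop = FALSE], y = sub$label)
}

#' Evaluate a classifier on a manifest subset of a pool
#'
#' @param model an `ifcmorph_classifier`.
#' @param pool an `ifc_pool` from [featurize_pool()].
#' @param sub manifest subset to evaluate (default: the whole pool).
#' @return list with `result` (an `eval_result`) and `records` (per-image
#'   `data.frame`: `image_id`, `bull_id`, `ejaculate_id`, `true`,
#'   `predicted`, `correct`) ready for [hier_bootstrap()].
#' @export
evaluate_classifier <- function(model, pool, sub = pool$manifest) {
  d <- .pool_data(pool, sub)
  pr <- predict(model, d$x)
  cm <- confusion(pr$labels, d$y, model$classes)
  records <- data.frame(image_id = sub$image_id, bull_id = sub$bull_id,
                        ejaculate_id = sub$ejaculate_id, true = d$y,
                        predicted = pr$labels,
                        correct = as.integer(pr$labels == d$y),
                        stringsAsFactors = FALSE)
  list(result = metrics(cm), records = records)
}

#' Leave-one-group-out learning curve over labeled-data fractions
#'
#' For every LOBO fold, labeled-data fraction and seed: trains under the
#' configured regime on the fraction's (nested, class-stratified) subset of
#' the fold's training split, validates on the fold's fixed validation split
#' and tests on the held-out group. Within a fraction every seed sees the
#' same test split, so differences reflect training data volume.
#'
#' @param pool an `ifc_pool`.
#' @param cfg a [train_config()]; `cfg$seed` is replaced by the run seed.
#' @param fractions labeled-data fractions (default `c(0.1, 0.2, 0.5, 1)`).
#' @param group_key LOBO grouping column (default `"breed"`).
#' @param n_seeds independent training runs per cell (default 3).
#' @param rng_seed root seed for folds, subsets and run seeds.
#' @return `data.frame` with one row per (fold, fraction, seed): `model`,
#'   `regime`, `fraction`, `fold`, `seed`, `n_train`, `accuracy`, `macro_f1`.
#' @export
learning_curve <- function(pool, cfg = train_config(),
                           fractions = c(0.1, 0.2, 0.5, 1),
                           group_key = "breed", n_seeds = 3, rng_seed = 1) {
  folds <- lobo_folds(pool$manifest, group_key = group_key,
                      rng_seed = rng_seed)
  out <- list()
  for (fold in folds) {
    subsets <- fraction_subsets(fold$train, fractions,
                                rng_seed = seed_stream(rng_seed, 101))
    val <- .pool_data(pool, fold$val)
    for (fname in names(subsets)) {
      tr <- .pool_data(pool, subsets[[fname]])
      for (s in seq_len(n_seeds)) {
        run_cfg <- cfg
        run_cfg$seed <- seed_stream(rng_seed, 1000 + s)
        model <- train_classifier(list(train = tr, val = val), run_cfg)
        ev <- evaluate_classifier(model, pool, fold$test)
        out[[length(out) + 1]] <- data.frame(
          model = cfg$backbone_id, regime = cfg$regime,
          fraction = as.numeric(fname), fold = fold$held_out, seed = s,
          n_train = nrow(subsets[[fname]]),
          accuracy = ev$result$accuracy, macro_f1 = ev$result$macro_f1,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Summarize a learning curve
#'
#' Mean accuracy over seeds within each fold, then mean and SD across folds
#' per fraction.
#'
#' @param tbl output of [learning_curve()].
#' @return `data.frame` with `fraction`, `mean_accuracy`, `sd_across_folds`.
#' @export
summarize_learning_curve <- function(tbl) {
  per_fold <- stats::aggregate(accuracy ~ fraction + fold, tbl, mean)
  agg <- stats::aggregate(accuracy ~ fraction, per_fold,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  data.frame(fraction = agg$fraction,
             mean_accuracy = agg$accuracy[, "mean"],
             sd_across_folds = agg$accuracy[, "sd"])
}

#' Cross-domain generalization run
#'
#' Trains one model per level of `domain_key` (e.g. condition, or breed
#' within one condition) on that domain's stratified 80/10/10 train split,
#' with the per-class training budget equalized across domains (each class
#' truncated to the smallest per-class count over domains), then evaluates
#' every model on every domain's test split. Accuracies are averaged over
#' `n_seeds` runs; 95% CIs come from the hierarchical cluster bootstrap on
#' the pooled per-image records.
#'
#' @param pool an `ifc_pool`.
#' @param cfg a [train_config()].
#' @param domain_key manifest column defining the domains.
#' @param n_seeds training runs per domain (default 1).
#' @param rng_seed root seed.
#' @param B bootstrap resamples per cell (default 2000); `B = 0` skips CIs.
#' @return a [generalization_matrix()] with percent accuracies; the raw
#'   per-image records are attached as attribute `"records"`.
#' @export
generalization_run <- function(pool, cfg = train_config(),
                               domain_key = "condition", n_seeds = 1,
                               rng_seed = 1, B = 2000) {
  manifest <- pool$manifest
  domains <- unique(manifest[[domain_key]])
  if (length(domains) < 2) stop("need >= 2 domains")
  splits <- lapply(domains, function(d) {
    sub <- manifest[manifest[[domain_key]] == d, , drop = FALSE]
    if (nrow(sub) == 0) stop("domain ", d, " has no rows")
    stratified_split(sub, rng_seed = seed_stream(rng_seed, 7))
  })
  names(splits) <- domains
  # equal effective training budget: truncate per class to the smallest
  # per-class count across domains
  per_class <- sapply(splits, function(s) table(factor(s$train$label,
                                                       morph_classes())))
  cap <- apply(per_class, 1, min)
  all_records <- list()
  for (s in seq_len(n_seeds)) {
    for (d in domains) {
      tr_full <- splits[[d]]$train
      keep <- unlist(lapply(split(seq_len(nrow(tr_full)), tr_full$label),
                            function(idx) {
        k <- cap[[as.character(tr_full$label[idx[1]])]]
        if (length(idx) > k)
          with_seed(seed_stream(rng_seed, 50 + s), sample(idx, k))
        else idx
      }))
      tr <- tr_full[sort(keep), , drop = FALSE]
      run_cfg <- cfg
      run_cfg$seed <- seed_stream(rng_seed, 1000 + s)
      model <- train_classifier(list(train = .pool_data(pool, tr),
                                     val = .pool_data(pool, splits[[d]]$val)),
                                run_cfg)
      for (d2 in domains) {
        ev <- evaluate_classifier(model, pool, splits[[d2]]$test)
        rec <- ev$records
        rec$train_domain <- d
        rec$test_domain <- d2
        rec$seed <- s
        all_records[[length(all_records) + 1]] <- rec
      }
    }
  }
  records <- do.call(rbind, all_records)
  cells <- list()
  for (d in domains) for (d2 in domains) {
    rec <- records[records$train_domain == d & records$test_domain == d2, ]
    if (B > 0) {
      ci <- hier_bootstrap(rec, B = B, seed = seed_stream(rng_seed, 300))
      cells[[length(cells) + 1]] <- data.frame(
        train_domain = d, test_domain = d2, accuracy = 100 * ci$point,
        lower = 100 * ci$lower, upper = 100 * ci$upper, n = nrow(rec),
        stringsAsFactors = FALSE)
    } else {
      cells[[length(cells) + 1]] <- data.frame(
        train_domain = d, test_domain = d2,
        accuracy = 100 * mean(rec$correct), n = nrow(rec),
        stringsAsFactors = FALSE)
    }
  }
  m <- generalization_matrix(do.call(rbind, cells))
  attr(m, "records") <- records
  m
}
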