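# Stratified quota labeling, fixed splits, LOBO folds, nested fraction
# subsets and class-balanced batch schedules. All selections are
# deterministic at a fixed seed and never duplicate a row, except
# balanced_batches which samples with replacement by design (documented in
# its return value).

.stratum_key <- function(manifest, keys) {
  missing_keys <- setdiff(keys, names(manifest))
  if (length(missing_keys) > 0)
    stop("manifest lacks strata column(s): ",
         paste(missing_keys, collapse = ", "))
  interaction(manifest[keys], drop = FALSE, sep = "|", lex.order = TRUE)
}

#' Stratified quota sampling of a labeled pool
#'
#' Selects exactly `quota` rows uniformly at random within every stratum
#' (default strata: class x breed x condition), emulating a labeling campaign
#' that collects a fixed number of quality-labeled images per stratum.
#'
#' @param manifest labeled manifest `data.frame`.
#' @param quota rows to draw per stratum (default 200).
#' @param strata_keys stratifying columns (default
#'   `c("label", "breed", "condition")`).
#' @param allow_short if `FALSE` (default), a stratum smaller than the quota
#'   is an error naming the stratum; if `TRUE`, all of its rows are taken.
#' @param rng_seed integer seed.
#' @return manifest of selected rows (original order preserved).
#' @export
quota_sample <- function(manifest, quota = 200,
                         strata_keys = c("label", "breed", "condition"),
                         allow_short = FALSE, rng_seed = 1) {
  stopifnot(quota >= 0)
  if (quota == 0 || nrow(manifest) == 0)
    return(manifest[integer(0), , drop = FALSE])
  key <- .stratum_key(manifest, strata_keys)
  idx_by <- split(seq_len(nrow(manifest)), key, drop = FALSE)
  take <- with_seed(rng_seed, lapply(names(idx_by), function(k) {
    idx <- idx_by[[k]]
    if (length(idx) < quota) {
      if (!allow_short)
        stop("stratum '", k, "' has ", length(idx), " rows < quota ", quota)
      return(idx)
    }
    idx[sample.int(length(idx), quota)]
  }))
  sel <- sort(unlist(take))
  out <- manifest[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# largest-remainder apportionment of n into parts with the given fractions
.largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Fixed stratified train/validation/test split
#'
#' Partitions a manifest into train/val/test with per-stratum proportions
#' matching the requested fractions under largest-remainder rounding.
#' Deterministic at a fixed seed; the three parts are disjoint and exhaust
#' the input.
#'
#' @param manifest manifest `data.frame`.
#' @param fractions named numeric vector `c(train=, val=, test=)`, positive,
#'   summing to 1 (default 0.8/0.1/0.1).
#' @param stratify_keys stratifying columns (default `"label"`).
#' @param rng_seed integer seed.
#' @return list of manifests `train`, `val`, `test`.
#' @export
stratified_split <- function(manifest,
                             fractions = c(train = 0.8, val = 0.1, test = 0.1),
                             stratify_keys = "label", rng_seed = 1) {
  stopifnot(all(fractions > 0), abs(sum(fractions) - 1) < 1e-9,
            length(fractions) == 3)
  if (is.null(names(fractions))) names(fractions) <- c("train", "val", "test")
  key <- .stratum_key(manifest, stratify_keys)
  idx_by <- split(seq_len(nrow(manifest)), key, drop = TRUE)
  parts <- list(train = integer(), val = integer(), test = integer())
  with_seed(rng_seed, {
    for (k in names(idx_by)) {
      idx <- idx_by[[k]]
      counts <- .largest_remainder(length(idx), fractions)
      if (any(counts < 1))
        stop("stratum '", k, "' too small (", length(idx),
             " rows) to place >= 1 row in each part")
      perm <- idx[sample.int(length(idx))]
      bounds <- cumsum(counts)
      parts$train <- c(parts$train, perm[seq_len(bounds[1])])
      parts$val <- c(parts$val, perm[(bounds[1] + 1):bounds[2]])
      parts$test <- c(parts$test, perm[(bounds[2] + 1):bounds[3]])
    }
  })
  lapply(parts, function(i) {
    out <- manifest[sort(i), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Leave-one-group-out folds
#'
#' One fold per level of `group_key` (default: breed, i.e. LOBO). In each
#' fold the held-out group is the test set and the remaining rows are split
#' 80/20 into train/validation, stratified by class.
#'
#' @param manifest manifest `data.frame`.
#' @param group_key grouping column (default `"breed"`).
#' @param val_fraction fraction of non-held-out rows reserved for validation
#'   (default 0.2).
#' @param stratify_keys stratification for the train/val split.
#' @param rng_seed integer seed.
#' @return named list of folds, each `list(held_out=, train=, val=, test=)`.
#' @export
lobo_folds <- function(manifest, group_key = "breed", val_fraction = 0.2,
                       stratify_keys = "label", rng_seed = 1) {
  groups <- unique(manifest[[group_key]])
  if (length(groups) < 2)
    stop("need >= 2 levels of '", group_key, "' for leave-one-group-out")
  folds <- lapply(seq_along(groups), function(gi) {
    g <- groups[gi]
    test <- manifest[manifest[[group_key]] == g, , drop = FALSE]
    rest <- manifest[manifest[[group_key]] != g, , drop = FALSE]
    key <- .stratum_key(rest, stratify_keys)
    idx_by <- split(seq_len(nrow(rest)), key, drop = TRUE)
    val_idx <- with_seed(seed_stream(rng_seed, gi), unlist(lapply(idx_by,
      function(idx) {
        nv <- round(length(idx) * val_fraction)
        if (nv == 0) return(integer())
        idx[sample.int(length(idx), nv)]
      })))
    val <- rest[sort(val_idx), , drop = FALSE]
    train <- rest[setdiff(seq_len(nrow(rest)), val_idx), , drop = FALSE]
    rownames(test) <- rownames(train) <- rownames(val) <- NULL
    list(held_out = g, train = train, val = val, test = test)
  })
  names(folds) <- as.character(groups)
  folds
}

#' Nested labeled-data-fraction subsets
#'
#' Returns one training subset per fraction, stratified by class and nested
#' (the subset at a smaller fraction is contained in every larger one), so
#' that learning-curve differences reflect training data volume only.
#' `f = 1` returns the full set.
#'
#' @param train training manifest.
#' @param fractions numeric fractions in `(0, 1]`
#'   (default `c(0.1, 0.2, 0.5, 1)`).
#' @param stratify_keys stratifying columns (default `"label"`).
#' @param rng_seed integer seed.
#' @return named list mapping fraction (as character) to manifest.
#' @export
fraction_subsets <- function(train, fractions = c(0.1, 0.2, 0.5, 1),
                             stratify_keys = "label", rng_seed = 1) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  fractions <- sort(fractions)
  key <- .stratum_key(train, stratify_keys)
  idx_by <- split(seq_len(nrow(train)), key, drop = TRUE)
  # one permutation per stratum; subsets are prefixes, hence nested
  perms <- with_seed(rng_seed, lapply(idx_by, function(idx)
    idx[sample.int(length(idx))]))
  out <- lapply(fractions, function(f) {
    if (f == 1) {
      m <- train
    } else {
      sel <- unlist(lapply(perms, function(p)
        p[seq_len(round(length(p) * f))]))
      m <- train[sort(sel), , drop = FALSE]
      rownames(m) <- NULL
    }
    m
  })
  names(out) <- as.character(fractions)
  out
}

#' Class-balanced batch schedule with caps
#'
#' Builds one epoch of minibatch index sets over a training manifest with
#' uniform class exposure: each draw picks a class uniformly, then an image
#' uniformly within that class, with replacement (minority classes are
#' oversampled). Optional per-class / per-breed / per-bull caps limit how
#' many distinct images of a class, breed or bull enter the epoch's
#' effective pool.
#'
#' @param train training manifest with a `label` column.
#' @param batch_size rows per batch (>= 1).
#' @param rng_seed integer seed.
#' @param n_draws total draws in the epoch (default: `nrow(train)` rounded up
#'   to a full batch).
#' @param per_class_cap,per_breed_cap,per_bull_cap optional caps on distinct
#'   images per class / breed / bull in the epoch pool (`NULL` = uncapped).
#' @return list with `batches` (list of integer row-index vectors into
#'   `train`), `pool` (row indices of the effective pool) and `replacement =
#'   TRUE` (sampling policy marker).
#' @export
balanced_batches <- function(train, batch_size = 64, rng_seed = 1,
                             n_draws = NULL, per_class_cap = NULL,
                             per_breed_cap = NULL, per_bull_cap = NULL) {
  stopifnot(batch_size >= 1)
  if (nrow(train) == 0) stop("empty training manifest")
  for (cap in list(per_class_cap, per_breed_cap, per_bull_cap))
    if (!is.null(cap) && cap < 1) stop("caps must be >= 1 when set")

  pool <- seq_len(nrow(train))
  with_seed(rng_seed, {
    cap_by <- function(pool, col, cap) {
      if (is.null(cap)) return(pool)
      unlist(lapply(split(pool, train[[col]][pool]), function(idx) {
        if (length(idx) > cap) sample(idx, cap) else idx
      }), use.names = FALSE)
    }
    pool <- cap_by(pool, "label", per_class_cap)
    pool <- cap_by(pool, "breed", per_breed_cap)
    pool <- cap_by(pool, "bull_id", per_bull_cap)
    pool <- sort(pool)

    by_class <- split(pool, train$label[pool])
    by_class <- by_class[lengths(by_class) > 0]
    if (length(by_class) == 0) stop("no classes left in the effective pool")
    if (is.null(n_draws))
      n_draws <- ceiling(nrow(train) / batch_size) * batch_size
    cls_draw <- sample(names(by_class), n_draws, replace = TRUE)
    draws <- vapply(cls_draw, function(cl) {
      idx <- by_class[[cl]]
      idx[sample.int(length(idx), 1)]
    }, integer(1), USE.NAMES = FALSE)
    batches <- split(draws, ceiling(seq_along(draws) / batch_size))
    names(batches) <- NULL
    list(batches = batches, pool = pool, replacement = TRUE)
  })
}
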