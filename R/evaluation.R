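#' Confusion matrix
#'
#' Counts with rows = true labels and columns = predicted labels, over a
#' fixed class list.
#'
#' @param preds predicted class codes.
#' @param labels true class codes (same length).
#' @param classes ordered class list (default [morph_classes()]).
#' @return a `confusion_matrix`: integer K x K matrix with `dimnames`
#'   `list(true = classes, predicted = classes)`.
#' @export
confusion <- function(preds, labels, classes = morph_classes()) {
  if (length(preds) != length(labels))
    stop("preds and labels must have equal length")
  bad <- setdiff(unique(c(preds, labels)), classes)
  if (length(bad) > 0)
    stop("label(s) outside the class list: ", paste(bad, collapse = ", "))
  tt <- table(factor(labels, classes), factor(preds, classes))
  cm <- matrix(as.integer(tt), length(classes), length(classes),
               dimnames = list(true = classes, predicted = classes))
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Row-normalize a confusion matrix
#'
#' @param cm a [confusion()] matrix.
#' @return numeric matrix with rows summing to 1 (empty rows stay 0).
#' @export
normalize_confusion <- function(cm) {
  rs <- rowSums(cm)
  out <- unclass(cm) / ifelse(rs == 0, 1, rs)
  out
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, per-class precision/recall/F1 and macro-F1. F1 is the harmonic
#' mean `2 * P * R / (P + R)`, set to 0 when `P + R = 0`; the macro average
#' is the unweighted mean of per-class F1 over the full class list of the
#' matrix (classes absent from both truth and prediction contribute 0).
#'
#' @param cm a [confusion()] matrix.
#' @return an `eval_result` list: `accuracy`, `precision`, `recall`, `f1`
#'   (named per class), `macro_f1`, `confusion`, `n`.
#' @export
metrics <- function(cm) {
  n <- sum(cm)
  if (n < 1) stop("empty confusion matrix")
  tp <- diag(cm)
  colsum <- colSums(cm)
  rowsum <- rowSums(cm)
  precision <- ifelse(colsum == 0, 0, tp / colsum)
  recall <- ifelse(rowsum == 0, 0, tp / rowsum)
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  structure(list(accuracy = sum(tp) / n, precision = precision,
                 recall = recall, f1 = f1, macro_f1 = mean(f1),
                 confusion = cm, n = n),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result n=%d accuracy=%.4f macro_f1=%.4f>\n",
              x$n, x$accuracy, x$macro_f1))
  invisible(x)
}

#' Hierarchical cluster bootstrap confidence interval
#'
#' Percentile bootstrap CI for a mean correctness that respects the
#' bulls -> ejaculates -> images nesting: each resample draws bulls with
#' replacement (as many as observed), then ejaculates with replacement
#' within each drawn bull, then images with replacement within each drawn
#' ejaculate. This accounts for intra-bull dependence that a flat bootstrap
#' over images ignores.
#'
#' @param records `data.frame` with columns `bull_id`, `ejaculate_id` and
#'   `correct` (0/1 or logical).
#' @param B number of bootstrap resamples (default 5000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return a `bootstrap_ci` list: `point`, `lower`, `upper`, `level`, `B`,
#'   `seed`.
#' @export
hier_bootstrap <- function(records, B = 5000, level = 0.95, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  if (is.null(records) || nrow(records) == 0) stop("empty records")
  stopifnot(all(c("bull_id", "ejaculate_id", "correct") %in% names(records)))
  correct <- as.numeric(records$correct)
  bulls <- lapply(split(seq_len(nrow(records)), records$bull_id),
                  function(i) split(correct[i], records$ejaculate_id[i]))
  stats <- with_seed(seed, .hier_boot_stats(bulls, B))
  a <- (1 - level) / 2
  qs <- stats::quantile(stats, c(a, 1 - a), names = FALSE)
  structure(list(point = mean(correct), lower = qs[1], upper = qs[2],
                 level = level, B = B, seed = seed),
            class = "bootstrap_ci")
}

# one vector of resampled mean-correct statistics; assumes RNG scope is set
.hier_boot_stats <- function(bulls, B) {
  nb <- length(bulls)
  vapply(seq_len(B), function(r) {
    tot <- 0
    cnt <- 0
    for (b in sample.int(nb, nb, replace = TRUE)) {
      ejs <- bulls[[b]]
      ne <- length(ejs)
      for (e in sample.int(ne, ne, replace = TRUE)) {
        v <- ejs[[e]]
        n <- length(v)
        tot <- tot + sum(v[sample.int(n, n, replace = TRUE)])
        cnt <- cnt + n
      }
    }
    tot / cnt
  }, numeric(1))
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("<bootstrap_ci %.4f [%.4f, %.4f] level=%.2f B=%d>\n",
              x$point, x$lower, x$upper, x$level, x$B))
  invisible(x)
}

#' Bootstrap test for an accuracy difference
#'
#' Bootstrap distribution of the difference in mean correctness between two
#' record sets, with the hierarchical cluster resampling of
#' [hier_bootstrap()]. In paired mode the record sets must be aligned
#' (same images in the same order, e.g. two models evaluated on one test
#' set); each resample then draws one set of cluster/image indices and
#' applies it to both, capturing the correlation between the models'
#' errors. In unpaired mode the two sets are resampled independently.
#' The difference is significant when the CI excludes 0.
#'
#' @param a_records,b_records record `data.frame`s as in [hier_bootstrap()].
#' @param paired logical.
#' @param B,level,seed as in [hier_bootstrap()].
#' @return list with `diff` (observed `mean(a) - mean(b)`), `ci` (a
#'   `bootstrap_ci` for the difference) and `is_significant`.
#' @export
significant_difference <- function(a_records, b_records, paired = FALSE,
                                   B = 5000, level = 0.95, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  if (nrow(a_records) == 0 || nrow(b_records) == 0) stop("empty records")
  obs <- mean(as.numeric(a_records$correct)) -
    mean(as.numeric(b_records$correct))
  if (paired) {
    if (nrow(a_records) != nrow(b_records) ||
        !identical(a_records$bull_id, b_records$bull_id) ||
        !identical(a_records$ejaculate_id, b_records$ejaculate_id))
      stop("paired mode requires aligned record sets")
    d <- as.numeric(a_records$correct) - as.numeric(b_records$correct)
    bulls <- lapply(split(seq_len(nrow(a_records)), a_records$bull_id),
                    function(i) split(d[i], a_records$ejaculate_id[i]))
    stats <- with_seed(seed, .hier_boot_stats(bulls, B))
  } else {
    ca <- as.numeric(a_records$correct)
    cb <- as.numeric(b_records$correct)
    ba <- lapply(split(seq_len(nrow(a_records)), a_records$bull_id),
                 function(i) split(ca[i], a_records$ejaculate_id[i]))
    bb <- lapply(split(seq_len(nrow(b_records)), b_records$bull_id),
                 function(i) split(cb[i], b_records$ejaculate_id[i]))
    stats <- with_seed(seed, .hier_boot_stats(ba, B) -
                         .hier_boot_stats(bb, B))
  }
  a <- (1 - level) / 2
  qs <- stats::quantile(stats, c(a, 1 - a), names = FALSE)
  ci <- structure(list(point = obs, lower = qs[1], upper = qs[2],
                       level = level, B = B, seed = seed),
                  class = "bootstrap_ci")
  list(diff = obs, ci = ci, is_significant = ci$lower > 0 | ci$upper < 0)
}

#' Generalization matrix
#'
#' Container for train-domain x test-domain accuracies (in percent) with
#' optional confidence bounds.
#'
#' @param cells `data.frame` with columns `train_domain`, `test_domain`,
#'   `accuracy` (percent) and optionally `lower`, `upper`, `n`.
#' @return an object of class `generalization_matrix`.
#' @export
generalization_matrix <- function(cells) {
  stopifnot(all(c("train_domain", "test_domain", "accuracy") %in%
                  names(cells)))
  if (any(cells$accuracy < 0 | cells$accuracy > 100))
    stop("accuracies must be percentages in [0, 100]")
  if (anyDuplicated(cells[c("train_domain", "test_domain")]))
    stop("duplicate (train_domain, test_domain) cell")
  structure(list(cells = cells), class = "generalization_matrix")
}

.gm_cell <- function(m, train_domain, test_domain) {
  i <- which(m$cells$train_domain == train_domain &
               m$cells$test_domain == test_domain)
  if (length(i) != 1)
    stop("no cell for train=", train_domain, ", test=", test_domain)
  m$cells[i, ]
}

#' Accuracy gap between two test domains, in percentage points
#'
#' For a fixed training domain, the signed difference
#' `accuracy(train -> alt_test) - accuracy(train -> ref_test)` in percentage
#' points (negative when performance drops on the alternative test domain).
#'
#' @param m a [generalization_matrix()].
#' @param train_domain training domain label.
#' @param ref_test reference test domain (typically the in-domain cell).
#' @param alt_test alternative test domain.
#' @return signed gap in percentage points.
#' @export
gap <- function(m, train_domain, ref_test, alt_test) {
  stopifnot(inherits(m, "generalization_matrix"))
  .gm_cell(m, train_domain, alt_test)$accuracy -
    .gm_cell(m, train_domain, ref_test)$accuracy
}

#' Format a generalization matrix as a Markdown report
#'
#' A pure function of the matrix: the same input yields byte-identical text.
#' Accuracies are printed in percent with two decimals, with the 95% CI when
#' bounds are present.
#'
#' @param m a [generalization_matrix()].
#' @param title report heading.
#' @return character vector of report lines.
#' @export
report_generalization <- function(m, title = "Generalization analysis") {
  stopifnot(inherits(m, "generalization_matrix"))
  has_ci <- all(c("lower", "upper") %in% names(m$cells))
  lines <- c(paste("#", title), "",
             "| Train | Test | Accuracy (%) |",
             "|---|---|---|")
  for (i in seq_len(nrow(m$cells))) {
    r <- m$cells[i, ]
    acc <- if (has_ci && is.finite(r$lower))
      sprintf("%.2f [%.1f-%.1f]", r$accuracy, r$lower, r$upper)
    else sprintf("%.2f", r$accuracy)
    lines <- c(lines, sprintf("| %s | %s | %s |",
                              r$train_domain, r$test_domain, acc))
  }
  lines
}

#' @export
print.generalization_matrix <- function(x, ...) {
  cat(report_generalization(x), sep = "\n")
  invisible(x)
}
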