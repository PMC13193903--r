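# Morphology profiling of predicted pools and report formatting. MULTI and
# DEBRIS are dataset-hygiene categories: they are tallied and reported but
# excluded from the biological proportions.

#' Morphology profile from predicted labels
#'
#' Pure counting: per group, the proportion of each of the eight biological
#' morphology classes among biological predictions, with MULTI/DEBRIS counts
#' tallied separately (never silently dropped). Proportions are invariant to
#' record order.
#'
#' @param preds `data.frame` with a `predicted` column plus the grouping
#'   columns.
#' @param group_keys grouping columns (default `c("condition", "season")`).
#' @return `data.frame`: group keys, `n_biological`, `n_excluded`, and one
#'   `prop_<class>` column per biological class (rows sum to 1 when
#'   `n_biological > 0`).
#' @export
profile_predictions <- function(preds,
                                group_keys = c("condition", "season")) {
  stopifnot("predicted" %in% names(preds))
  missing_keys <- setdiff(group_keys, names(preds))
  if (length(missing_keys) > 0)
    stop("missing grouping column(s): ", paste(missing_keys, collapse = ", "))
  bio <- morph_classes(biological_only = TRUE)
  key <- interaction(preds[group_keys], drop = TRUE, sep = "|",
                     lex.order = TRUE)
  groups <- split(seq_len(nrow(preds)), key)
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    if (length(idx) == 0) {
      warning("empty group '", g, "' omitted")
      return(NULL)
    }
    lab <- preds$predicted[idx]
    is_bio <- lab %in% bio
    counts <- table(factor(lab[is_bio], bio))
    nb <- sum(is_bio)
    props <- if (nb > 0) as.numeric(counts) / nb else rep(NA_real_,
                                                          length(bio))
    out <- preds[idx[1], group_keys, drop = FALSE]
    out$n_biological <- nb
    out$n_excluded <- length(idx) - nb
    for (i in seq_along(bio)) out[[paste0("prop_", bio[i])]] <- props[i]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Profile an unlabeled pool with a trained classifier
#'
#' Predicts every record of the pool and reduces the predictions to
#' per-group morphology proportions via [profile_predictions()].
#'
#' @param model an `ifcmorph_classifier`.
#' @param pool an `ifc_pool` (see [featurize_pool()]).
#' @param group_keys grouping columns (default `c("condition", "season")`).
#' @return profile `data.frame` (see [profile_predictions()]).
#' @export
profile_pool <- function(model, pool, group_keys = c("condition", "season")) {
  pr <- predict(model, pool$x)
  preds <- pool$manifest
  preds$predicted <- pr$labels
  profile_predictions(preds, group_keys)
}

#' Format a morphology profile as Markdown
#'
#' Pure function of the profile table (byte-identical on rerun).
#'
#' @param profile output of [profile_predictions()].
#' @param title report heading.
#' @return character vector of report lines.
#' @export
report_profile <- function(profile, title = "Morphology profile") {
  bio <- morph_classes(biological_only = TRUE)
  keys <- setdiff(names(profile),
                  c("n_biological", "n_excluded", paste0("prop_", bio)))
  lines <- c(paste("#", title), "",
             paste0("| ", paste(c(keys, bio, "n", "excluded"),
                                collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(keys) + length(bio) + 2),
                               collapse = "|"), "|"))
  for (i in seq_len(nrow(profile))) {
    r <- profile[i, ]
    vals <- c(unlist(lapply(r[keys], as.character)),
              sprintf("%.1f%%", 100 * unlist(r[paste0("prop_", bio)])),
              as.character(r$n_biological), as.character(r$n_excluded))
    lines <- c(lines, paste0("| ", paste(vals, collapse = " | "), " |"))
  }
  lines
}

#' Write a provenance record for a run
#'
#' Records the config file's md5 hash, the root seed, package and R
#' versions, so that every artifact can be traced to a reproducible run.
#'
#' @param path output JSON path.
#' @param config_path config file used for the run (`NA` allowed).
#' @param seed root seed of the run.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config_path, seed) {
  hash <- if (!is.na(config_path) && file.exists(config_path))
    unname(tools::md5sum(config_path)) else NA_character_
  jsonlite::write_json(
    list(config = config_path, config_md5 = hash, seed = seed,
         package = "ifcmorph",
         package_version = as.character(utils::packageVersion("ifcmorph")),
         r_version = paste(R.version$major, R.version$minor, sep = ".")),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
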