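#' Generate a synthetic acquisition manifest
#'
#' Builds the full event-level manifest for an acquisition campaign described
#' by a [hierarchy_spec()]: one row per recorded single-cell event, nested as
#' bulls -> ejaculates -> files -> events. Class labels are drawn from the
#' matching domain's class mixture; morphometry parameters are drawn around
#' the domain means perturbed by multiplicative bull- and ejaculate-level
#' random effects, so that events within a bull are statistically dependent.
#' Images are not rendered here; use [render_manifest()] or
#' [render_images()] on (a subset of) the manifest.
#'
#' @param h a [hierarchy_spec()].
#' @param doms named list of [domain_params()], as from [default_domains()];
#'   matched to rows by `"<breed>.<condition>"`.
#' @param include_params if `FALSE`, skip per-event morphometry sampling and
#'   return metadata columns only (fast counting / design checks).
#' @return `data.frame` manifest with columns `image_id`, `bull_id`, `breed`,
#'   `condition`, `season`, `ejaculate_id`, `file_id`, `label`, `seed` and,
#'   when `include_params = TRUE`, one column per cell parameter.
#' @export
generate_dataset <- function(h, doms = default_domains(),
                             include_params = TRUE) {
  stopifnot(inherits(h, "hierarchy_spec"))
  if (h$n_bulls < 0 || h$files_per_ejaculate < 0 || h$events_per_file < 0 ||
      any(h$ejaculates_per_bull < 0))
    stop("hierarchy counts must be non-negative")

  # fresh ejaculates alternate spring/fall; frozen ejaculates are summer
  season_of <- function(condition, k) {
    if (condition == "frozen") "summer"
    else c("spring", "fall")[(k - 1L) %% 2L + 1L]
  }

  pieces <- list()
  counter <- 0
  with_seed(h$seed, {
    for (b in seq_len(h$n_bulls)) {
      breed <- h$breed_of_bull[b]
      bull_id <- sprintf("bull%02d", b)
      bull_eff <- stats::setNames(
        exp(stats::rnorm(length(.size_param_names), 0, h$bull_effect_sd)),
        .size_param_names)
      for (cond in names(h$ejaculates_per_bull)) {
        n_ej <- h$ejaculates_per_bull[[cond]]
        key <- paste(breed, cond, sep = ".")
        dom <- doms[[key]]
        if (is.null(dom) && n_ej > 0)
          stop("no domain_params supplied for ", key)
        for (e in seq_len(n_ej)) {
          ej_id <- sprintf("%s_%s%d", bull_id, cond, e)
          ej_eff <- stats::setNames(
            exp(stats::rnorm(length(.size_param_names), 0,
                             h$ejaculate_effect_sd)),
            .size_param_names)
          eff <- bull_eff * ej_eff
          for (f in seq_len(h$files_per_ejaculate)) {
            n <- h$events_per_file
            if (n == 0) next
            labels <- sample(morph_classes(), n, replace = TRUE,
                             prob = dom$class_mixture)
            df <- data.frame(
              image_id = sprintf("%s_f%d_%06d", ej_id, f, seq_len(n)),
              bull_id = bull_id, breed = breed, condition = cond,
              season = season_of(cond, e),
              ejaculate_id = ej_id, file_id = sprintf("%s_f%d", ej_id, f),
              label = labels,
              seed = seed_stream(h$seed, counter + seq_len(n) - 1),
              stringsAsFactors = FALSE)
            if (include_params)
              df <- cbind(df, .sample_param_block(labels, dom, eff))
            counter <- counter + n
            pieces[[length(pieces) + 1]] <- df
          }
        }
      }
    }
  })
  if (length(pieces) == 0) {
    out <- data.frame(image_id = character(), bull_id = character(),
                      breed = character(), condition = character(),
                      season = character(), ejaculate_id = character(),
                      file_id = character(), label = character(),
                      seed = integer(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# Vectorised per-event parameter sampling for one file's worth of labels.
# Mirrors sample_cell_params() but draws all events at once.
.sample_param_block <- function(labels, dom, effects) {
  n <- length(labels)
  p0 <- default_cell_params()
  shift <- dom$morphometry_shift
  curv_shift <- if (!is.null(shift) && "tail_curvature" %in% names(shift))
    shift[["tail_curvature"]] else 1
  if (!is.null(shift)) {
    sh <- shift[setdiff(names(shift), "tail_curvature")]
    p0[names(sh)] <- p0[names(sh)] * sh
  }
  p0[names(effects)] <- p0[names(effects)] * effects

  blk <- matrix(rep(p0, each = n), nrow = n,
                dimnames = list(NULL, names(p0)))
  for (nm in .size_param_names)
    blk[, nm] <- blk[, nm] * exp(stats::rnorm(n, 0, .cell_param_cv))
  blk[, "orientation"] <- stats::rnorm(n, 0, 12) +
    sample(c(0, 180), n, replace = TRUE)
  blk[, "tail_curvature"] <- abs(stats::rnorm(n, blk[, "tail_curvature"], 0.03))

  adj <- function(cls, col, lo, hi, mult = FALSE) {
    i <- which(labels == cls)
    if (length(i) == 0) return()
    draw <- stats::runif(length(i), lo, hi)
    blk[i, col] <<- if (mult) blk[i, col] * draw else draw
  }
  adj("TEH", "head_length_px", 1.4, 1.7, mult = TRUE)
  adj("TEH", "head_width_px", 0.55, 0.75, mult = TRUE)
  adj("IHS", "head_width_px", 1.35, 1.7, mult = TRUE)
  adj("AM", "midpiece_length_px", 1.3, 1.7, mult = TRUE)
  adj("AT", "tail_curvature", 0.55, 0.9)
  adj("CTM", "tail_curvature", 1.2, 1.8)
  adj("PCD", "droplet_position", 0.05, 0.30)
  adj("DCD", "droplet_position", 0.70, 0.95)
  blk[, "tail_curvature"] <- blk[, "tail_curvature"] * curv_shift
  as.data.frame(blk)
}

#' Render manifest rows to in-memory images
#'
#' Renders each manifest row with [generate_cell()] using the row's stored
#' per-event seed and morphometry parameters, under the domain matching the
#' row's breed and condition.
#'
#' @param manifest manifest rows (as from [generate_dataset()], with
#'   parameter columns).
#' @param doms named list of [domain_params()].
#' @param canvas frame size `c(height, width)` in pixels.
#' @return list of integer image matrices, one per row.
#' @export
render_images <- function(manifest, doms = default_domains(),
                          canvas = c(96, 96)) {
  pnames <- names(default_cell_params())
  has_params <- all(pnames %in% names(manifest))
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    dom <- doms[[paste(row$breed, row$condition, sep = ".")]]
    if (is.null(dom)) stop("no domain_params for row ", row$image_id)
    params <- if (has_params) unlist(row[pnames]) else NULL
    generate_cell(row$label, dom, rng_seed = row$seed, canvas = canvas,
                  params = params)$image
  })
}

#' Render manifest rows to PNG files
#'
#' As [render_images()], but writes each frame as an 8-bit grayscale PNG
#' under `dir` and returns the manifest with a `path` column added.
#'
#' @inheritParams render_images
#' @param dir output directory (created if missing).
#' @return the manifest with a `path` column.
#' @export
render_manifest <- function(manifest, dir, doms = default_domains(),
                            canvas = c(96, 96)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  imgs <- render_images(manifest, doms, canvas)
  paths <- file.path(dir, paste0(manifest$image_id, ".png"))
  for (i in seq_along(imgs))
    EBImage::writeImage(EBImage::Image(t(imgs[[i]]) / 255), paths[i])
  manifest$path <- paths
  manifest
}

#' Total a manifest by a grouping column
#'
#' Counts manifest rows per level of a metadata column and checks that the
#' per-level counts sum to the total row count.
#'
#' @param manifest a manifest `data.frame`.
#' @param by metadata column name (default `"condition"`).
#' @return list with `counts` (named integer vector) and `total`.
#' @export
manifest_totals <- function(manifest, by = "condition") {
  if (!by %in% names(manifest)) stop("no column '", by, "' in manifest")
  counts <- table(manifest[[by]])
  counts <- stats::setNames(as.integer(counts), names(counts))
  stopifnot(sum(counts) == nrow(manifest))
  list(counts = counts, total = nrow(manifest))
}

#' Read and write manifests as CSV
#'
#' @param manifest manifest `data.frame`.
#' @param path CSV file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` returns
#'   the manifest `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Save and restore a generator configuration
#'
#' Serializes a [hierarchy_spec()] plus domain list to YAML with 17
#' significant digits, so that a configuration round-trips bit-exactly.
#'
#' @param h a [hierarchy_spec()].
#' @param doms named list of [domain_params()].
#' @param path output file path (YAML).
#' @return `write_generator_config` returns `path` invisibly;
#'   `read_generator_config` returns `list(hierarchy =, domains =)`.
#' @export
write_generator_config <- function(h, doms, path) {
  hl <- unclass(h)
  hl$ejaculates_per_bull <- as.list(hl$ejaculates_per_bull)
  cfg <- list(hierarchy = hl,
              domains = lapply(doms, function(d) {
                dl <- unclass(d)
                dl$class_mixture <- as.list(dl$class_mixture)
                if (!is.null(dl$morphometry_shift))
                  dl$morphometry_shift <- as.list(dl$morphometry_shift)
                dl
              }))
  writeLines(yaml::as.yaml(cfg, precision = 17), path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  hl <- cfg$hierarchy
  h <- hierarchy_spec(
    n_bulls = hl$n_bulls,
    ejaculates_per_bull = unlist(hl$ejaculates_per_bull),
    files_per_ejaculate = hl$files_per_ejaculate,
    events_per_file = hl$events_per_file,
    bull_effect_sd = hl$bull_effect_sd,
    ejaculate_effect_sd = hl$ejaculate_effect_sd,
    breed_of_bull = hl$breed_of_bull,
    seed = hl$seed)
  doms <- lapply(cfg$domains, function(d) {
    domain_params(breed = d$breed, condition = d$condition,
                  season = d$season,
                  morphometry_shift = if (length(d$morphometry_shift))
                    unlist(d$morphometry_shift) else NULL,
                  illumination_gradient = d$illumination_gradient,
                  noise_sd = d$noise_sd,
                  class_mixture = unlist(d$class_mixture))
  })
  list(hierarchy = h, domains = doms)
}
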