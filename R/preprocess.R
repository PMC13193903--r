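# Image standardization and QC. Images are plain numeric matrices with
# rows = image rows (y) and columns = image columns (x), intensities on the
# 8-bit scale 0..255. EBImage (first dimension = x) backs all resampling ops;
# matrices are transposed at that boundary.

# fixed normalization constants, applied identically at train and test time
.norm_mean <- 0.5
.norm_sd <- 0.25

#' Read a grayscale cell image
#'
#' Reads a PNG/TIFF grayscale image into the package's matrix convention
#' (rows = y, intensities 0..255).
#'
#' @param path image file path.
#' @return numeric matrix.
#' @export
read_cell_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 3) img <- img[, , 1]
  t(img) * 255
}

#' Center-crop an image to a square
#'
#' Crops to S x S where S is the shorter edge; the crop window is centred,
#' with floor-based offsets when the trimmed margin is odd.
#'
#' @param img numeric image matrix.
#' @return square numeric matrix.
#' @export
center_crop_square <- function(img) {
  if (is.null(dim(img)) || any(dim(img) < 1) || length(img) == 0)
    stop("empty image")
  h <- nrow(img); w <- ncol(img)
  s <- min(h, w)
  top <- floor((h - s) / 2)
  left <- floor((w - s) / 2)
  img[(top + 1):(top + s), (left + 1):(left + s), drop = FALSE]
}

#' Quality-filter a manifest by image size
#'
#' Retains exactly the rows whose shorter image edge is at least
#' `min_short_edge` pixels (strict reading: an image whose shorter edge
#' equals the threshold is kept). Sizes are taken from `height`/`width`
#' manifest columns when present, otherwise read from the files in the
#' `path` column; an unreadable file is an error naming the row.
#'
#' @param manifest manifest `data.frame`.
#' @param min_short_edge threshold in pixels (default 50, the standard
#'   acquisition QC rule: frames below this scale are mostly debris).
#' @return list with `manifest` (kept rows, original order), `rejected_count`
#'   and `report` (a per-row QC report: `image_id`, `height`, `width`,
#'   `kept`, `reason`).
#' @export
qc_filter <- function(manifest, min_short_edge = 50) {
  if (nrow(manifest) == 0)
    return(list(manifest = manifest, rejected_count = 0L,
                report = data.frame(image_id = character(),
                                    height = integer(), width = integer(),
                                    kept = logical(), reason = character())))
  if (all(c("height", "width") %in% names(manifest))) {
    hh <- manifest$height; ww <- manifest$width
  } else {
    if (!"path" %in% names(manifest))
      stop("manifest needs height/width columns or a path column")
    dims <- lapply(seq_len(nrow(manifest)), function(i) {
      d <- tryCatch(dim(read_cell_image(manifest$path[i])),
                    error = function(e) NULL)
      if (is.null(d))
        stop("unreadable image for row ", manifest$image_id[i],
             " (", manifest$path[i], ")")
      d
    })
    hh <- vapply(dims, `[`, numeric(1), 1)
    ww <- vapply(dims, `[`, numeric(1), 2)
  }
  keep <- pmin(hh, ww) >= min_short_edge
  report <- data.frame(
    image_id = if ("image_id" %in% names(manifest)) manifest$image_id
               else as.character(seq_len(nrow(manifest))),
    height = as.integer(hh), width = as.integer(ww), kept = keep,
    reason = ifelse(keep, "",
                    sprintf("short edge %d < %d", as.integer(pmin(hh, ww)),
                            as.integer(min_short_edge))),
    stringsAsFactors = FALSE)
  out <- manifest[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(manifest = out, rejected_count = as.integer(sum(!keep)),
       report = report)
}

#' Convert a grayscale image to standardized model input
#'
#' Resizes to 224 x 224 (bilinear), replicates the single channel to three
#' identical channels, scales intensities to `[0, 1]` by dividing by 255 and
#' standardizes with the fixed constants mean 0.5, sd 0.25. The same
#' transform is applied at train and test time.
#'
#' @param img numeric image matrix (0..255).
#' @param size output spatial size (default 224).
#' @return numeric array `size x size x 3`, all channels identical.
#' @export
to_model_input <- function(img, size = 224L) {
  if (is.null(dim(img)) || any(dim(img) < 1)) stop("empty image")
  r <- EBImage::resize(EBImage::Image(img / 255), w = size, h = size)
  ch <- (EBImage::imageData(r) - .norm_mean) / .norm_sd
  array(ch, dim = c(size, size, 3))
}

#' Augmentation policy
#'
#' Training-only label-preserving augmentations: random horizontal flip,
#' small rotations, and a random resized crop retaining 80-100% of the area
#' with up to +/-10% translation.
#'
#' @param hflip_prob probability of a horizontal flip (default 0.5).
#' @param rot_deg_max maximum rotation magnitude in degrees (default 10;
#'   angles drawn uniformly on `[-rot_deg_max, rot_deg_max]`).
#' @param rrc_area_range retained-area interval of the random resized crop
#'   (default `c(0.8, 1)`).
#' @param translate_frac_max maximum crop-centre translation as a fraction of
#'   the image side (default 0.1).
#' @param enabled if `FALSE`, [augment()] is the identity.
#' @return an object of class `augment_policy`.
#' @export
augment_policy <- function(hflip_prob = 0.5, rot_deg_max = 10,
                           rrc_area_range = c(0.8, 1),
                           translate_frac_max = 0.1, enabled = TRUE) {
  stopifnot(hflip_prob >= 0, hflip_prob <= 1,
            rot_deg_max >= 0,
            length(rrc_area_range) == 2,
            rrc_area_range[1] > 0, rrc_area_range[2] <= 1,
            rrc_area_range[1] <= rrc_area_range[2],
            translate_frac_max >= 0)
  structure(list(hflip_prob = hflip_prob, rot_deg_max = rot_deg_max,
                 rrc_area_range = rrc_area_range,
                 translate_frac_max = translate_frac_max, enabled = enabled),
            class = "augment_policy")
}

#' Draw augmentation parameters from a policy
#'
#' @param policy an [augment_policy()].
#' @param n number of draws.
#' @param rng_seed integer seed.
#' @return `data.frame` with columns `flip`, `angle_deg`, `area`,
#'   `shift_x_frac`, `shift_y_frac`.
#' @export
sample_augment_params <- function(policy, n, rng_seed) {
  stopifnot(inherits(policy, "augment_policy"))
  with_seed(rng_seed, data.frame(
    flip = stats::runif(n) < policy$hflip_prob,
    angle_deg = stats::runif(n, -policy$rot_deg_max, policy$rot_deg_max),
    area = stats::runif(n, policy$rrc_area_range[1], policy$rrc_area_range[2]),
    shift_x_frac = stats::runif(n, -policy$translate_frac_max,
                                policy$translate_frac_max),
    shift_y_frac = stats::runif(n, -policy$translate_frac_max,
                                policy$translate_frac_max)))
}

# Apply one drawn augmentation to a single channel (matrix). Order is fixed:
# flip -> rotate -> random-resized-crop-with-translation. Out-of-frame pixels
# after rotation are filled with the border-median background estimate
# (avoids black corners alien to brightfield frames).
.apply_augment_channel <- function(ch, par) {
  h <- nrow(ch); w <- ncol(ch)
  if (par$flip) ch <- ch[, w:1, drop = FALSE]
  if (par$angle_deg != 0) {
    bgc <- stats::median(c(ch[1, ], ch[h, ], ch[, 1], ch[, w]))
    a <- par$angle_deg * pi / 180
    cx <- (h + 1) / 2; cy <- (w + 1) / 2 # EBImage coords of the transpose
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    off <- c(cx, cy) - c(cx, cy) %*% R
    m <- rbind(R, off)
    e <- EBImage::affine(EBImage::Image(ch), m, filter = "bilinear",
                         output.dim = c(h, w), bg.col = bgc,
                         antialias = FALSE)
    ch <- EBImage::imageData(e)
  }
  side <- sqrt(par$area)
  s <- max(1L, round(min(h, w) * side))
  cx0 <- (w - s) / 2 + par$shift_x_frac * w
  cy0 <- (h - s) / 2 + par$shift_y_frac * h
  left <- min(max(0L, round(cx0)), w - s)
  top <- min(max(0L, round(cy0)), h - s)
  crop <- ch[(top + 1):(top + s), (left + 1):(left + s), drop = FALSE]
  if (s != h || s != w)
    crop <- EBImage::imageData(EBImage::resize(EBImage::Image(crop),
                                               w = h, h = w))
  crop
}

#' Augment a model input
#'
#' Applies the policy's random horizontal flip, rotation and random resized
#' crop to a standardized model input. Deterministic given `rng_seed`;
#' label-preserving by construction; identity when the policy is disabled.
#'
#' @param x model input array (`S x S x 3`, see [to_model_input()]).
#' @param policy an [augment_policy()].
#' @param rng_seed integer seed.
#' @return augmented array with unchanged dimensions.
#' @export
augment <- function(x, policy, rng_seed) {
  stopifnot(inherits(policy, "augment_policy"), length(dim(x)) == 3)
  if (!policy$enabled) return(x)
  par <- sample_augment_params(policy, 1, rng_seed)
  ch <- .apply_augment_channel(x[, , 1], par[1, ])
  array(ch, dim = dim(x))
}
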