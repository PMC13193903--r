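#' Default morphometry parameter means
#'
#' Mean cell-geometry parameters, in pixels on the default 96x96 canvas
#' (roughly a 40x brightfield field of view around one spermatozoon).
#' Per-cell values are drawn around these means with modest lognormal
#' variation, then modified by class-specific defects, domain morphometry
#' shifts and bull/ejaculate random effects.
#'
#' @return named numeric vector of parameter means.
#' @export
default_cell_params <- function() {
  c(head_length_px = 22, head_width_px = 13,
    midpiece_length_px = 12, tail_length_px = 38,
    tail_curvature = 0.10, droplet_radius_px = 4,
    droplet_position = 0.5, orientation = 0,
    intensity_contrast = 1)
}

# Per-cell coefficient of variation of the lognormal size variation.
.cell_param_cv <- 0.06

# Names of the morphometry parameters that receive multiplicative shifts and
# bull/ejaculate random effects (positive length/size scales).
.size_param_names <- c("head_length_px", "head_width_px",
                       "midpiece_length_px", "tail_length_px")

#' Sample per-cell morphometry parameters
#'
#' Draws one cell's geometry for a given class under a domain. Class-specific
#' defects reshape the relevant parameters (e.g. an elongated head for TEH, a
#' strong tail bend for AT, a proximal droplet position for PCD). Must be
#' called inside an established RNG scope (see [generate_cell()]).
#'
#' @param cls class code from [morph_classes()].
#' @param dom a [domain_params()] object.
#' @param effects optional named multiplicative effects on the size
#'   parameters (bull/ejaculate random effects).
#' @return named numeric vector of cell parameters.
#' @keywords internal
sample_cell_params <- function(cls, dom, effects = NULL) {
  p <- default_cell_params()
  shift <- dom$morphometry_shift
  # the curvature shift multiplies the final (class-conditional) draw below
  curv_shift <- if (!is.null(shift) && "tail_curvature" %in% names(shift))
    shift[["tail_curvature"]] else 1
  if (!is.null(shift)) {
    sh <- shift[setdiff(names(shift), "tail_curvature")]
    p[names(sh)] <- p[names(sh)] * sh
  }
  if (!is.null(effects)) p[names(effects)] <- p[names(effects)] * effects
  p[.size_param_names] <- p[.size_param_names] *
    exp(stats::rnorm(length(.size_param_names), 0, .cell_param_cv))
  # cells flow roughly aligned with the instrument's flow axis; either end
  # may lead, with a modest angular wobble
  p["orientation"] <- stats::rnorm(1, 0, 12) + sample(c(0, 180), 1)
  p["tail_curvature"] <- abs(stats::rnorm(1, p["tail_curvature"], 0.03))
  # class-specific reshaping
  if (cls == "TEH") {
    p["head_length_px"] <- p["head_length_px"] * stats::runif(1, 1.4, 1.7)
    p["head_width_px"] <- p["head_width_px"] * stats::runif(1, 0.55, 0.75)
  } else if (cls == "IHS") {
    p["head_width_px"] <- p["head_width_px"] * stats::runif(1, 1.35, 1.7)
  } else if (cls == "AM") {
    p["midpiece_length_px"] <- p["midpiece_length_px"] * stats::runif(1, 1.3, 1.7)
  } else if (cls == "AT") {
    p["tail_curvature"] <- stats::runif(1, 0.55, 0.9)
  } else if (cls == "CTM") {
    p["tail_curvature"] <- stats::runif(1, 1.2, 1.8)
  } else if (cls == "PCD") {
    p["droplet_position"] <- stats::runif(1, 0.05, 0.30)
  } else if (cls == "DCD") {
    p["droplet_position"] <- stats::runif(1, 0.70, 0.95)
  }
  p["tail_curvature"] <- p["tail_curvature"] * curv_shift
  p
}

# -- low-level drawing helpers (96x96-ish numeric matrices, 0..255) ---------

.pixel_grid <- function(h, w) {
  list(x = matrix(rep(seq_len(w), each = h), h, w),
       y = matrix(rep(seq_len(h), times = w), h, w))
}

# filled rotated ellipse mask
.ellipse_mask <- function(grid, cx, cy, a, b, theta) {
  dx <- grid$x - cx; dy <- grid$y - cy
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  (u / a)^2 + (v / b)^2 <= 1
}

# stamp discs of given radius along a polyline (n x 2 matrix of x,y)
.stamp_path <- function(img, pts, radius, value) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(radius)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= radius^2 + 0.25, , drop = FALSE]
  xs <- round(rep(pts[, 1], each = nrow(off))) + off$dx
  ys <- round(rep(pts[, 2], each = nrow(off))) + off$dy
  keep <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
  img[cbind(ys[keep], xs[keep])] <- value
  img
}

# quadratic bezier points
.bezier <- function(p0, p1, p2, n = 80) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2])
}

# Draw one cell (head + midpiece + tail + optional droplet) onto img.
# Returns list(img, anchors) where anchors give head centre, neck (head/
# midpiece junction), midpiece end and droplet centre in pixel coordinates.
.draw_cell <- function(img, grid, p, defects, center, bg) {
  theta <- p[["orientation"]] * pi / 180
  u <- c(cos(theta), sin(theta))          # head axis direction
  contrast <- p[["intensity_contrast"]]
  a <- p[["head_length_px"]] / 2
  b <- p[["head_width_px"]] / 2
  lm <- p[["midpiece_length_px"]]
  lt <- p[["tail_length_px"]]

  # head centre placed so that head+midpiece straddle the given centre
  hc <- center + (lm / 2 + a * 0.6) * u
  neck <- hc - a * u                       # head/midpiece junction
  mid_end <- neck - lm * u

  head_in <- bg - 80 * contrast
  head_edge <- bg - 110 * contrast
  body_col <- bg - 70 * contrast
  tail_col <- bg - 55 * contrast

  m_out <- .ellipse_mask(grid, hc[1], hc[2], a, b, theta)
  m_core <- .ellipse_mask(grid, hc[1], hc[2], a * 0.72, b * 0.72, theta)
  img[m_out] <- head_edge
  img[m_core] <- head_in
  if ("irregular_head" %in% defects$defects) {
    # asymmetric lobe: secondary ellipse offset sideways off the head
    v <- c(-sin(theta), cos(theta))
    lc <- hc + b * 0.9 * v + stats::runif(1, -0.3, 0.3) * a * u
    img[.ellipse_mask(grid, lc[1], lc[2], a * 0.45, b * 0.6, theta)] <- head_edge
  }

  # midpiece: straight (or kinked when abnormal) thick segment
  mp_width <- if ("abnormal_midpiece" %in% defects$defects) 3.4 else 2.2
  if ("abnormal_midpiece" %in% defects$defects) {
    kink <- stats::runif(1, 20, 40) * pi / 180 * sample(c(-1, 1), 1)
    u2 <- c(cos(theta + kink), sin(theta + kink))
    half <- neck - (lm / 2) * u
    mid_end <- half - (lm / 2) * u2
    pts <- rbind(.seg_points(neck, half, 24), .seg_points(half, mid_end, 24))
  } else {
    pts <- .seg_points(neck, mid_end, 40)
  }
  img <- .stamp_path(img, pts, mp_width / 2 + 0.5, body_col)

  # tail: coiled spiral for CTM, otherwise a quadratic bend
  if ("coiled_tail_midpiece" %in% defects$defects) {
    turns <- stats::runif(1, 2, 3)
    r0 <- stats::runif(1, 6, 9)
    phi0 <- stats::runif(1, 0, 2 * pi)
    t <- seq(0, 1, length.out = 140)
    ctr <- mid_end - (r0 * 0.5) * u
    coil <- cbind(ctr[1] + r0 * (1 - 0.65 * t) * cos(phi0 + 2 * pi * turns * t),
                  ctr[2] + r0 * (1 - 0.65 * t) * sin(phi0 + 2 * pi * turns * t))
    img <- .stamp_path(img, coil, 1.1, tail_col)
  } else {
    curv <- p[["tail_curvature"]]
    bend_dir <- sample(c(-1, 1), 1)
    v <- c(-sin(theta), cos(theta)) * bend_dir
    p0 <- mid_end
    p2 <- mid_end - lt * (1 - 0.25 * curv) * u + lt * 0.55 * curv * v
    p1 <- mid_end - 0.5 * lt * u + lt * 0.9 * curv * v
    img <- .stamp_path(img, .bezier(p0, p1, p2, 110), 0.9, tail_col)
  }

  # cytoplasmic droplet: bright disc with a darker rim, along the midpiece
  droplet_ctr <- NULL
  if (any(c("proximal_droplet", "distal_droplet") %in% defects$defects)) {
    dp <- p[["droplet_position"]]
    droplet_ctr <- neck + dp * (mid_end - neck)
    rr <- p[["droplet_radius_px"]]
    img[.ellipse_mask(grid, droplet_ctr[1], droplet_ctr[2],
                      rr + 1.3, rr + 1.3, 0)] <- bg - 60 * contrast
    img[.ellipse_mask(grid, droplet_ctr[1], droplet_ctr[2], rr, rr, 0)] <- 254
  }

  list(img = img,
       anchors = list(head = hc, neck = neck, mid_end = mid_end,
                      droplet = droplet_ctr))
}

.seg_points <- function(p0, p1, n) {
  t <- seq(0, 1, length.out = n)
  cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]))
}

.draw_debris <- function(img, grid, bg, contrast) {
  n <- sample(1:4, 1)
  h <- nrow(img); w <- ncol(img)
  for (i in seq_len(n)) {
    cx <- stats::runif(1, w * 0.2, w * 0.8)
    cy <- stats::runif(1, h * 0.2, h * 0.8)
    aa <- stats::runif(1, 2, 6); bb <- stats::runif(1, 1.5, 5)
    th <- stats::runif(1, 0, pi)
    col <- bg - stats::runif(1, 30, 90) * contrast
    img[.ellipse_mask(grid, cx, cy, aa, bb, th)] <- col
  }
  img
}

#' Generate one synthetic single-cell brightfield image
#'
#' Renders a grayscale frame containing one cell of the requested morphology
#' class (or a multiplet / debris frame), together with the ground-truth
#' defect set. Rendering is a minimal geometric model: head as a filled
#' ellipse with edge darkening, midpiece as a thick segment, tail as a
#' quadratic spline (a spiral for coiled tails), cytoplasmic droplets as
#' bright discs, debris as small irregular blobs, multiplets as two
#' overlapping cells. The defect set always maps back to `cls` under
#' [assign_label()]; with probability 0.3 one additional lower-priority
#' co-defect is present and rendered, mimicking co-existing abnormalities.
#'
#' @param cls class code from [morph_classes()].
#' @param dom a [domain_params()] object.
#' @param rng_seed integer seed; output is deterministic given
#'   `(cls, dom, rng_seed)`.
#' @param canvas `c(height, width)` of the frame in pixels.
#' @param params optional pre-sampled parameter vector (as from
#'   [sample_cell_params()]); when supplied, only the defect draw, placement
#'   jitter and pixel noise are random.
#' @return list with elements `image` (integer matrix, 0..255), `defects`
#'   (a [defect_set()]), and `params` (named numeric vector including the
#'   anchor coordinates `head_x`/`head_y` (head centre), `neck_x`/`neck_y`
#'   (head-midpiece junction), `mid_end_x`/`mid_end_y` and,
#'   when a droplet is rendered, `droplet_x`, `droplet_y`).
#' @export
generate_cell <- function(cls, dom, rng_seed, canvas = c(96, 96),
                          params = NULL) {
  if (!cls %in% morph_classes()) stop("unknown class code: ", cls)
  stopifnot(inherits(dom, "domain_params"))
  with_seed(rng_seed, {
    h <- canvas[1]; w <- canvas[2]
    grid <- .pixel_grid(h, w)
    bg <- 235
    img <- matrix(bg, h, w)
    if (dom$illumination_gradient != 0) {
      ramp <- (grid$x - (w + 1) / 2) / w
      img <- img + dom$illumination_gradient * ramp
    }

    # ground-truth defect set (+ optional compatible co-defect)
    defects <- switch(cls,
      NM = defect_set(),
      MULTI = defect_set(multiplet = TRUE),
      DEBRIS = defect_set(debris = TRUE),
      defect_set(.class_primary_defect[[cls]]))
    if (!cls %in% c("NM", "MULTI", "DEBRIS") && stats::runif(1) < 0.3) {
      extra <- .compatible_codefects(cls)
      if (length(extra) > 0)
        defects <- defect_set(c(defects$defects, sample(extra, 1)))
    }

    if (is.null(params)) params <- sample_cell_params(cls, dom)
    contrast <- params[["intensity_contrast"]]

    anchors <- NULL
    if (cls == "DEBRIS") {
      img <- .draw_debris(img, grid, bg, contrast)
    } else if (cls == "MULTI") {
      ctr1 <- c(w / 2, h / 2) + stats::runif(2, -4, 4)
      d1 <- .draw_cell(img, grid, params, defect_set(), ctr1, bg)
      p2 <- sample_cell_params("NM", dom)
      off <- stats::runif(1, 10, 16) *
        c(cos(stats::runif(1, 0, 2 * pi)), sin(stats::runif(1, 0, 2 * pi)))
      d2 <- .draw_cell(img, grid, p2, defect_set(), ctr1 + off, bg)
      img <- pmin(d1$img, d2$img)
      anchors <- d1$anchors
    } else {
      ctr <- c(w / 2, h / 2) + stats::runif(2, -5, 5)
      dc <- .draw_cell(img, grid, params, defects, ctr, bg)
      img <- dc$img
      anchors <- dc$anchors
    }

    img <- img + stats::rnorm(h * w, 0, dom$noise_sd)
    img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), h, w)

    if (!is.null(anchors)) {
      params <- c(params, head_x = anchors$head[1], head_y = anchors$head[2],
                  neck_x = anchors$neck[1], neck_y = anchors$neck[2],
                  mid_end_x = anchors$mid_end[1],
                  mid_end_y = anchors$mid_end[2])
      if (!is.null(anchors$droplet))
        params <- c(params, droplet_x = anchors$droplet[1],
                    droplet_y = anchors$droplet[2])
    }
    list(image = img, defects = defects, params = params)
  })
}
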