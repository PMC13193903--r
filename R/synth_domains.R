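#' Default class mixture for a semen sample
#'
#' Probability of each of the ten categories among acquired single-cell
#' frames. The defaults are a realistic post-gating composition for bull
#' semen: a normal-morphology majority, head-shape anomalies and droplets as
#' the most common defects, and small residual fractions of multiplet and
#' debris frames that survive preliminary gating.
#'
#' @return named numeric vector over [morph_classes()], summing to 1.
#' @export
default_class_mixture <- function() {
  c(NM = 0.45, IHS = 0.10, TEH = 0.06, AM = 0.06, AT = 0.07,
    PCD = 0.05, DCD = 0.07, CTM = 0.06, MULTI = 0.04, DEBRIS = 0.04)
}

#' Domain parameters for one breed x condition cell population
#'
#' A domain bundles everything that differs between acquisition cohorts:
#' breed, preparation condition (fresh vs frozen-thawed), season, a
#' multiplicative shift on the morphometry means, an illumination gradient
#' across the frame, the additive image noise level, and the class mixture.
#'
#' @param breed breed label, one of `"KW"` (Kazakh Whitehead), `"SIM"`
#'   (Simmental), `"AUL"` (Auliekol).
#' @param condition `"fresh"` or `"frozen"`.
#' @param season `"spring"`, `"summer"` or `"fall"`.
#' @param morphometry_shift named numeric vector of multiplicative offsets
#'   applied to the [default_cell_params()] means (names must be a subset of
#'   the parameter names). `NULL` means no shift.
#' @param illumination_gradient peak-to-peak intensity slope across the frame
#'   in 8-bit counts (0 = flat illumination).
#' @param noise_sd standard deviation of the additive Gaussian pixel noise in
#'   8-bit counts; must be >= 0.
#' @param class_mixture named probability vector over [morph_classes()];
#'   must sum to 1 (tolerance 1e-9).
#' @return an object of class `domain_params`.
#' @export
domain_params <- function(breed = "KW", condition = "fresh",
                          season = "spring", morphometry_shift = NULL,
                          illumination_gradient = 0, noise_sd = 6,
                          class_mixture = default_class_mixture()) {
  breed <- match.arg(breed, c("KW", "SIM", "AUL"))
  condition <- match.arg(condition, c("fresh", "frozen"))
  season <- match.arg(season, c("spring", "summer", "fall"))
  stopifnot(noise_sd >= 0)
  cm <- class_mixture[morph_classes()]
  if (anyNA(cm))
    stop("class_mixture must name all of: ",
         paste(morph_classes(), collapse = ", "))
  if (abs(sum(cm) - 1) > 1e-9) stop("class_mixture must sum to 1")
  if (!is.null(morphometry_shift)) {
    bad <- setdiff(names(morphometry_shift), names(default_cell_params()))
    if (length(bad) > 0)
      stop("unknown morphometry_shift name(s): ", paste(bad, collapse = ", "))
  }
  structure(list(breed = breed, condition = condition, season = season,
                 morphometry_shift = morphometry_shift,
                 illumination_gradient = illumination_gradient,
                 noise_sd = noise_sd, class_mixture = cm),
            class = "domain_params")
}

# Built-in condition and breed shifts. Frozen-thawed material images noisier
# and at lower contrast than fresh (extender background, membrane damage),
# and cryodamage shifts the morphometry itself: more strongly bent/coiled
# tails across classes and mild osmotic head shrinkage. Breeds differ by
# ~10% in head and tail morphometry.
.condition_shift <- function(condition, base_noise = 6) {
  if (condition == "frozen")
    list(noise_sd = base_noise * 1.5,
         shift = c(intensity_contrast = 0.85, tail_curvature = 1.4,
                   head_length_px = 0.95, head_width_px = 0.95))
  else list(noise_sd = base_noise, shift = NULL)
}

.breed_shift <- function(breed) {
  switch(breed,
         KW  = NULL,
         SIM = c(head_length_px = 1.10, head_width_px = 1.10,
                 tail_length_px = 1.10),
         AUL = c(head_length_px = 0.90, head_width_px = 0.90,
                 tail_length_px = 0.90))
}

#' Default domain grid
#'
#' One [domain_params()] per breed x condition combination, with the built-in
#' condition shift (frozen: noise x1.5, contrast x0.85) and breed shifts
#' (+/-10% morphometry) applied. These defaults define the study conditions
#' for all synthetic-data experiments in the package.
#'
#' @param breeds breed labels to include.
#' @param conditions condition labels to include.
#' @param base_noise_sd fresh-condition noise level (8-bit counts).
#' @param class_mixture shared class mixture.
#' @return named list of `domain_params`, names `"<breed>.<condition>"`.
#' @export
default_domains <- function(breeds = c("KW", "SIM", "AUL"),
                            conditions = c("fresh", "frozen"),
                            base_noise_sd = 6,
                            class_mixture = default_class_mixture()) {
  merge_shift <- function(a, b) {
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    nm <- union(names(a), names(b))
    out <- rep(1, length(nm))
    names(out) <- nm
    out[names(a)] <- out[names(a)] * a
    out[names(b)] <- out[names(b)] * b
    out
  }
  doms <- list()
  for (b in breeds) for (cond in conditions) {
    cs <- .condition_shift(cond, base_noise_sd)
    shift <- merge_shift(.breed_shift(b), cs$shift)
    season <- if (cond == "frozen") "summer" else "spring"
    doms[[paste(b, cond, sep = ".")]] <-
      domain_params(breed = b, condition = cond, season = season,
                    morphometry_shift = shift, noise_sd = cs$noise_sd,
                    class_mixture = class_mixture)
  }
  doms
}

#' Acquisition hierarchy specification
#'
#' Describes the bulls -> ejaculates -> files -> events structure of an IFC
#' acquisition campaign. The default mirrors a six-bull design with two fresh
#' ejaculates (spring, fall) and one frozen ejaculate (summer) per bull, two
#' recorded files per sample and 50,000 events per file.
#'
#' @param n_bulls number of bulls.
#' @param ejaculates_per_bull named integer vector, count per condition.
#' @param files_per_ejaculate recorded files per ejaculate.
#' @param events_per_file single-cell events per file.
#' @param bull_effect_sd,ejaculate_effect_sd standard deviations (log scale)
#'   of the multiplicative bull- and ejaculate-level random effects on the
#'   morphometry means; they induce the intra-bull correlation structure the
#'   hierarchical bootstrap is designed for.
#' @param breed_of_bull breed label per bull (recycled/truncated to
#'   `n_bulls`); the default follows a 4 KW / 1 SIM / 1 AUL herd.
#' @param seed root seed for the whole dataset.
#' @return an object of class `hierarchy_spec`.
#' @export
hierarchy_spec <- function(n_bulls = 6,
                           ejaculates_per_bull = c(fresh = 2, frozen = 1),
                           files_per_ejaculate = 2,
                           events_per_file = 50000,
                           bull_effect_sd = 0.05,
                           ejaculate_effect_sd = 0.03,
                           breed_of_bull = NULL,
                           seed = 1) {
  stopifnot(n_bulls >= 0, files_per_ejaculate >= 0, events_per_file >= 0,
            all(ejaculates_per_bull >= 0), bull_effect_sd >= 0,
            ejaculate_effect_sd >= 0)
  if (is.null(names(ejaculates_per_bull)) ||
      !all(names(ejaculates_per_bull) %in% c("fresh", "frozen")))
    stop("ejaculates_per_bull must be named with conditions fresh/frozen")
  if (is.null(breed_of_bull))
    breed_of_bull <- c("KW", "KW", "KW", "KW", "SIM", "AUL")
  breed_of_bull <- rep_len(breed_of_bull, max(n_bulls, 1L))[seq_len(n_bulls)]
  structure(list(n_bulls = as.integer(n_bulls),
                 ejaculates_per_bull = ejaculates_per_bull,
                 files_per_ejaculate = as.integer(files_per_ejaculate),
                 events_per_file = as.integer(events_per_file),
                 bull_effect_sd = bull_effect_sd,
                 ejaculate_effect_sd = ejaculate_effect_sd,
                 breed_of_bull = breed_of_bull,
                 seed = as.integer(seed)),
            class = "hierarchy_spec")
}
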