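#' Morphology class codes
#'
#' The ten categories used throughout the pipeline: eight biological
#' morphology classes plus two residual categories retained for dataset
#' hygiene ("multiple" frames containing more than one cell, and debris).
#'
#' The biological classes are: NM (normal morphology), IHS (irregular head
#' shape), TEH (twisted or elongated head), AM (abnormal midpiece), AT
#' (abnormal tail), PCD (proximal cytoplasmic droplet), DCD (distal
#' cytoplasmic droplet) and CTM (coiled tail and midpiece).
#'
#' @param biological_only if `TRUE`, return only the eight biological
#'   classes, excluding `MULTI` and `DEBRIS`.
#' @return character vector of class codes, in the canonical order used for
#'   every classifier head and confusion matrix in the package.
#' @export
morph_classes <- function(biological_only = FALSE) {
  cls <- c("NM", "IHS", "TEH", "AM", "AT", "PCD", "DCD", "CTM",
           "MULTI", "DEBRIS")
  if (biological_only) cls[1:8] else cls
}

#' Atomic defect tags
#'
#' Tags for the single structural defects a cell can carry. A cell may carry
#' several at once; [assign_label()] reduces a set of tags to one class code.
#'
#' @return character vector of the seven recognised defect tags.
#' @export
defect_tags <- function() {
  c("irregular_head", "twisted_elongated_head", "abnormal_midpiece",
    "abnormal_tail", "coiled_tail_midpiece", "proximal_droplet",
    "distal_droplet")
}

#' Construct a defect set
#'
#' A defect set is the pre-precedence ground truth for a rendered cell: the
#' atomic defects present, plus flags for multiplet frames (more than one
#' cell) and debris. An empty defect set with both flags off denotes a
#' normal cell.
#'
#' @param defects character vector of tags from [defect_tags()].
#' @param multiplet logical; frame contains more than one cell.
#' @param debris logical; frame contains debris rather than a cell.
#' @return an object of class `defect_set`.
#' @export
defect_set <- function(defects = character(), multiplet = FALSE,
                       debris = FALSE) {
  defects <- unique(as.character(defects))
  bad <- setdiff(defects, defect_tags())
  if (length(bad) > 0)
    stop("unknown defect tag(s): ", paste(bad, collapse = ", "))
  stopifnot(is.logical(multiplet), length(multiplet) == 1L,
            is.logical(debris), length(debris) == 1L)
  structure(list(defects = defects, multiplet = multiplet, debris = debris),
            class = "defect_set")
}

#' @export
print.defect_set <- function(x, ...) {
  if (x$debris) cat("<defect_set: debris>\n")
  else if (x$multiplet) cat("<defect_set: multiplet>\n")
  else if (length(x$defects) == 0) cat("<defect_set: normal>\n")
  else cat("<defect_set:", paste(x$defects, collapse = " + "), ">\n")
  invisible(x)
}

# Total label priority. Annotation practice states two pairwise rules (CTM
# supersedes AT; TEH supersedes IHS); the remaining conflicts are resolved by
# one fixed, auditable order so that labelling is deterministic for any
# combination of co-existing abnormalities.
.label_priority <- c("DEBRIS", "MULTI", "CTM", "AT", "TEH", "IHS",
                     "AM", "PCD", "DCD", "NM")

.defect_to_class <- c(
  coiled_tail_midpiece  = "CTM",
  abnormal_tail         = "AT",
  twisted_elongated_head = "TEH",
  irregular_head        = "IHS",
  abnormal_midpiece     = "AM",
  proximal_droplet      = "PCD",
  distal_droplet        = "DCD"
)

#' Assign a single class label to a defect set
#'
#' Cells frequently carry several co-existing abnormalities; each image
#' nevertheless receives exactly one label. Precedence follows the fixed
#' total order `DEBRIS > MULTI > CTM > AT > TEH > IHS > AM > PCD > DCD > NM`:
#' the debris and multiplet flags dominate all structural defects, coiled
#' tail/midpiece supersedes a plain abnormal tail, and a twisted or elongated
#' head supersedes other head irregularities. An empty defect set is normal
#' morphology (`NM`).
#'
#' @param d a [defect_set()].
#' @return single class code (see [morph_classes()]).
#' @export
#' @examples
#' assign_label(defect_set(c("abnormal_tail", "coiled_tail_midpiece"))) # CTM
#' assign_label(defect_set())                                           # NM
assign_label <- function(d) {
  stopifnot(inherits(d, "defect_set"))
  if (d$debris) return("DEBRIS")
  if (d$multiplet) return("MULTI")
  if (length(d$defects) == 0) return("NM")
  classes <- unname(.defect_to_class[d$defects])
  classes[order(match(classes, .label_priority))][1]
}

# Defect sets implied by each class code; the primary defect comes first.
.class_primary_defect <- c(
  IHS = "irregular_head", TEH = "twisted_elongated_head",
  AM = "abnormal_midpiece", AT = "abnormal_tail",
  CTM = "coiled_tail_midpiece", PCD = "proximal_droplet",
  DCD = "distal_droplet"
)

# Tags that may co-occur with a primary defect without changing the label:
# exactly those mapping to classes of strictly lower priority.
.compatible_codefects <- function(cls) {
  if (cls %in% c("NM", "MULTI", "DEBRIS")) return(character())
  rank <- match(.defect_to_class, .label_priority)
  names(.defect_to_class)[rank > match(cls, .label_priority)]
}
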