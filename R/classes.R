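#' Tissue classes
#'
#' The pipeline works with exactly three mucosa classes, in a fixed order
#' that is used everywhere for tie-breaking and for confusion-matrix layout:
#' `abnormal` (code 0), `normal` (code 1) and `other` (code 2, i.e. non-tongue
#' or unannotated regions). `tongue_classes()` returns the canonical integer
#' codes as a named vector.
#'
#' @return named integer vector `c(abnormal = 0, normal = 1, other = 2)`.
#' @export
#' @examples
#' tongue_classes()
tongue_classes <- function() {
  c(abnormal = 0L, normal = 1L, other = 2L)
}

#' @rdname tongue_classes
#' @export
class_names <- function() {
  names(tongue_classes())
}

#' Convert between class names and integer codes
#'
#' @param x integer codes in `{0, 1, 2}` (for `class_name`) or class names
#'   (for `class_code`).
#' @return character names, or integer codes.
#' @export
class_name <- function(x) {
  stopifnot(all(x %in% 0:2))
  class_names()[x + 1L]
}

#' @rdname class_name
#' @export
class_code <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    stopifnot(all(x %in% 0:2))
    return(x)
  }
  codes <- tongue_classes()
  if (!all(x %in% names(codes))) {
    stop_validation("unknown class name(s): %s",
                    paste(setdiff(x, names(codes)), collapse = ", "))
  }
  unname(codes[x])
}

#' The ten recognised abnormality categories
#'
#' Closed vocabulary of abnormal or pathological change types used to tag
#' abnormal crop images: tongue coating, hairy tongue, fissures, papillary
#' atrophy, erosion, ulcer, lichenoid change, hyperkeratotic change,
#' papillary hypertrophy and artifacts (saliva bubbles, flash reflections).
#'
#' @return character vector of the ten category names.
#' @export
abnormality_tags <- function() {
  c("tongue_coating", "hairy_tongue", "fissures", "papillary_atrophy",
    "erosion", "ulcer", "lichenoid_change", "hyperkeratotic_change",
    "papillary_hypertrophy", "artifacts")
}
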