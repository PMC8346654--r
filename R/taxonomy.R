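#' Panel-type taxonomy
#'
#' A taxonomy is the closed, ordered set of panel-type classes used to encode
#' figures as Figure-words. The ordinal position of a class (1-based) is the
#' bit position it occupies in a Figure-word, so the taxonomy order is part of
#' the representation and must be stable across runs.
#'
#' @param classes Character vector of unique, non-empty class names, in the
#'   order that defines their bit positions.
#' @return An object of class `fw_taxonomy` with elements `classes` (the
#'   ordered names) and `positions` (named integer map class -> position).
#' @seealso [default_taxonomy()]
#' @export
#' @examples
#' tax <- fw_taxonomy(c("Histogram", "Gel/blot"))
#' tax$positions[["Gel/blot"]]
fw_taxonomy <- function(classes) {
  classes <- as.character(classes)
  if (length(classes) == 0L)
    stop("taxonomy must contain at least one class", call. = FALSE)
  if (any(is.na(classes)) || any(!nzchar(classes)))
    stop("taxonomy class names must be non-empty", call. = FALSE)
  if (anyDuplicated(classes))
    stop("taxonomy class names must be unique: duplicated '",
         classes[duplicated(classes)][1L], "'", call. = FALSE)
  structure(
    list(classes = classes,
         positions = stats::setNames(seq_along(classes), classes)),
    class = "fw_taxonomy"
  )
}

#' Default 11-class panel-type taxonomy
#'
#' The default image taxonomy used throughout the package: 11 panel-type
#' classes covering graphics (histogram, line chart, other diagram),
#' molecular-structure images (macromolecule sequence, 3D structure),
#' experimental images (fluorescence microscopy, gel/blot, plate, light
#' microscopy), a catch-all class, and the separation-residual class for
#' fragments produced by over-segmentation of compound figures.
#'
#' @return An `fw_taxonomy` with 11 classes.
#' @export
default_taxonomy <- function() {
  fw_taxonomy(c(
    "Histogram",
    "Line chart",
    "Other diagram",
    "Macromolecule sequence",
    "3D structure",
    "Fluorescence microscopy",
    "Gel/blot",
    "Plate",
    "Light microscopy",
    "Other",
    "Separation residual"
  ))
}

#' @export
print.fw_taxonomy <- function(x, ...) {
  cat("Panel-type taxonomy with", length(x$classes), "classes:\n")
  cat(paste0("  ", seq_along(x$classes), ". ", x$classes, collapse = "\n"), "\n")
  invisible(x)
}

#' Number of classes in a taxonomy
#' @param taxonomy An `fw_taxonomy`.
#' @return Integer K, the number of panel-type classes.
#' @export
taxonomy_size <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "fw_taxonomy"))
  length(taxonomy$classes)
}

assert_taxonomy <- function(taxonomy) {
  if (!inherits(taxonomy, "fw_taxonomy"))
    stop("expected an 'fw_taxonomy' object", call. = FALSE)
  invisible(taxonomy)
}
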