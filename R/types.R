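#' Grayscale slice constructor
#'
#' A slice is a numeric matrix (rows = image rows, columns = image columns)
#' carrying patient provenance. Intensities are arbitrary units; most of the
#' pipeline expects [0,1] after [normalize_slice()].
#'
#' @param pixels numeric matrix of finite intensities.
#' @param patient_id opaque patient identifier.
#' @param plane acquisition plane, one of `"transverse"`, `"coronal"`,
#'   `"sagittal"`, `"unknown"`.
#' @return a `grayscale_slice`: the matrix with provenance attributes.
#' @export
grayscale_slice <- function(pixels, patient_id = "unknown", plane = "unknown") {
  pixels <- as.matrix(pixels)
  if (length(pixels) < 1L) stop("slice must contain at least one pixel")
  if (!all(is.finite(pixels))) stop("slice intensities must be finite")
  plane <- match.arg(plane, c("transverse", "coronal", "sagittal", "unknown"))
  structure(pixels,
            patient_id = as.character(patient_id), plane = plane,
            class = c("grayscale_slice", "matrix", "array"))
}

#' Binary mask constructor
#'
#' @param pixels matrix over \{0,1\} (or logical), same shape as its slice.
#' @return a `binary_mask` integer matrix.
#' @export
binary_mask <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (is.logical(pixels)) pixels[] <- as.integer(pixels)
  if (!all(pixels %in% c(0, 1))) stop("mask values must be 0 or 1")
  storage.mode(pixels) <- "integer"
  structure(pixels, class = c("binary_mask", "matrix", "array"))
}

#' @export
print.grayscale_slice <- function(x, ...) {
  cat(sprintf("<grayscale_slice %dx%d patient=%s plane=%s range=[%.4g, %.4g]>\n",
              nrow(x), ncol(x), attr(x, "patient_id"), attr(x, "plane"),
              min(x), max(x)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %dx%d foreground=%d px>\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

# strip classes/attrs down to a plain numeric matrix
as_plain_matrix <- function(x) {
  m <- matrix(as.numeric(x), nrow(x), ncol(x))
  m
}

check_same_shape <- function(a, b, what = "slice and mask") {
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b)) {
    stop(sprintf("%s shapes differ: %dx%d vs %dx%d",
                 what, nrow(a), ncol(a), nrow(b), ncol(b)))
  }
  invisible(TRUE)
}

slice_attr <- function(x, which, default = "unknown") {
  v <- attr(x, which)
  if (is.null(v)) default else v
}

# rebuild a slice, preserving provenance from a template
reslice <- function(pixels, template) {
  grayscale_slice(pixels,
                  patient_id = slice_attr(template, "patient_id"),
                  plane      = slice_attr(template, "plane"))
}
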