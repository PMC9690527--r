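#' Preprocessing configuration
#'
#' Controls the binarize / fill / crop / normalize / resize pipeline applied
#' to every slice before it reaches the network.
#'
#' @param tie_to_foreground pixels exactly equal to the image mean map to
#'   foreground. The sign-based threshold is undefined at the mean, and
#'   sending ties to foreground keeps uniform regions inside the effective
#'   area instead of discarding them.
#' @param target_size integer `(h, w)` of the model input after resizing.
#' @param constant_image_value normalized value assigned to every pixel of a
#'   constant image, where min-max scaling is degenerate.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(tie_to_foreground = TRUE,
                              target_size = c(256L, 256L),
                              constant_image_value = 0) {
  target_size <- as.integer(target_size)
  if (length(target_size) != 2L || any(target_size < 1L))
    stop("target_size must be two positive integers (h, w)")
  structure(list(tie_to_foreground = isTRUE(tie_to_foreground),
                 target_size = target_size,
                 constant_image_value = as.numeric(constant_image_value)),
            class = "preprocess_config")
}

#' Mean-threshold binarization
#'
#' Each pixel maps to 1 when it exceeds the mean intensity of the whole
#' image, 0 when below. Pixels exactly at the mean follow
#' `cfg$tie_to_foreground`.
#'
#' @param slice a `grayscale_slice` or numeric matrix.
#' @param cfg a [preprocess_config()].
#' @return a [binary_mask()].
#' @export
binarize <- function(slice, cfg = preprocess_config()) {
  if (length(slice) < 1L) stop("cannot binarize an empty image")
  m <- as_plain_matrix(slice)
  mu <- mean(m)
  out <- if (cfg$tie_to_foreground) m >= mu else m > mu
  binary_mask(out)
}

#' Fill enclosed holes in a binary mask
#'
#' Background regions (0) not 4-connected to the image border are holes and
#' become foreground; border-connected background is preserved. Implemented
#' as an iterative flood fill from the border, vectorized over whole-image
#' shifts.
#'
#' @param mask a [binary_mask()].
#' @return a [binary_mask()] with holes filled.
#' @export
fill_holes <- function(mask) {
  m <- as_plain_matrix(mask) > 0
  h <- nrow(m); w <- ncol(m)
  bg <- !m
  reach <- matrix(FALSE, h, w)
  reach[1, ] <- bg[1, ]; reach[h, ] <- bg[h, ]
  reach[, 1] <- bg[, 1]; reach[, w] <- bg[, w]
  repeat {
    grown <- reach
    if (h > 1L) {
      grown[-1, ] <- grown[-1, ] | reach[-h, ]
      grown[-h, ] <- grown[-h, ] | reach[-1, ]
    }
    if (w > 1L) {
      grown[, -1] <- grown[, -1] | reach[, -w]
      grown[, -w] <- grown[, -w] | reach[, -1]
    }
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  binary_mask(m | (bg & !reach))
}

#' Effective region of a mask
#'
#' The smallest axis-aligned rectangle containing every foreground pixel.
#' Indices are 1-based and inclusive on both ends, following R convention.
#'
#' @param mask a [binary_mask()] with at least one foreground pixel.
#' @return a `bounding_box` list with `row_min`, `col_min`, `row_max`,
#'   `col_max`.
#' @export
effective_region <- function(mask) {
  m <- as_plain_matrix(mask) > 0
  if (!any(m)) stop("mask has no foreground: effective region undefined")
  idx <- which(m, arr.ind = TRUE)
  structure(list(row_min = min(idx[, 1L]), col_min = min(idx[, 2L]),
                 row_max = max(idx[, 1L]), col_max = max(idx[, 2L])),
            class = "bounding_box")
}

#' Min-max intensity normalization
#'
#' Rescales a slice to exactly span [0,1]:
#' `(p - p_min) / (p_max - p_min)`. A constant image (zero range) maps
#' uniformly to `cfg$constant_image_value`.
#'
#' @inheritParams binarize
#' @return a `grayscale_slice` with values in [0,1].
#' @export
normalize_slice <- function(slice, cfg = preprocess_config()) {
  if (length(slice) < 1L) stop("cannot normalize an empty image")
  m <- as_plain_matrix(slice)
  lo <- min(m); hi <- max(m)
  out <- if (hi > lo) (m - lo) / (hi - lo)
         else matrix(cfg$constant_image_value, nrow(m), ncol(m))
  reslice(out, slice)
}

crop_to_box <- function(m, box) {
  m[box$row_min:box$row_max, box$col_min:box$col_max, drop = FALSE]
}

#' Resize an image matrix
#'
#' @param m numeric matrix.
#' @param target integer `(h, w)`.
#' @param method `"bilinear"` for intensities, `"nearest"` for label masks.
#' @return resized matrix.
#' @export
resize_image <- function(m, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  m <- as_plain_matrix(m)
  if (nrow(m) == target[1L] && ncol(m) == target[2L]) return(m)
  filt <- if (method == "bilinear") "bilinear" else "none"
  out <- EBImage::resize(EBImage::Image(m), w = target[1L], h = target[2L],
                         filter = filt)
  matrix(EBImage::imageData(out), target[1L], target[2L])
}

#' Full preprocessing of one slice/mask pair
#'
#' Binarize the slice, fill holes, crop both slice and label mask to the
#' effective region (the box is applied to the label too so that the pair
#' stays aligned), normalize intensities, and resize to the model input
#' size. The image is resized bilinearly; the label with nearest-neighbor so
#' it stays strictly binary.
#'
#' @param slice a `grayscale_slice`.
#' @param mask the paired [binary_mask()] ground truth, or `NULL` for
#'   inference-only slices.
#' @param cfg a [preprocess_config()].
#' @return list with elements `image` (normalized, resized
#'   `grayscale_slice`), `mask` (resized `binary_mask` or `NULL`) and `box`
#'   (the effective-region `bounding_box` in original coordinates).
#' @export
preprocess_sample <- function(slice, mask = NULL, cfg = preprocess_config()) {
  if (!is.null(mask)) check_same_shape(slice, mask)
  fg <- fill_holes(binarize(slice, cfg))
  box <- effective_region(fg)
  img <- crop_to_box(as_plain_matrix(slice), box)
  img <- as_plain_matrix(normalize_slice(reslice(img, slice), cfg))
  img <- resize_image(img, cfg$target_size, "bilinear")
  out_mask <- NULL
  if (!is.null(mask)) {
    mm <- crop_to_box(as_plain_matrix(mask), box)
    out_mask <- binary_mask(resize_image(mm, cfg$target_size, "nearest"))
  }
  list(image = reslice(img, slice), mask = out_mask, box = box)
}
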