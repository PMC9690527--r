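#' Write a grayscale slice as PNG
#'
#' Values are clipped to [0,1] and quantized to 8 bits.
#' @param slice `grayscale_slice` or numeric matrix.
#' @param path output file.
#' @export
write_slice_png <- function(slice, path) {
  m <- pmin(pmax(as_plain_matrix(slice), 0), 1)
  EBImage::writeImage(EBImage::Image(t(m)), path)
  invisible(path)
}

#' Write a binary mask as a 0/255 PNG
#' @param mask a [binary_mask()].
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(as_plain_matrix(mask))), path)
  invisible(path)
}

#' Read a grayscale slice from PNG or TIFF
#'
#' Multi-channel images are collapsed to grayscale by channel averaging.
#' @param path image file.
#' @param patient_id,plane provenance to attach.
#' @return a `grayscale_slice` with intensities in [0,1].
#' @export
read_slice <- function(path, patient_id = "unknown", plane = "unknown") {
  im <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(im)) == 3L) im <- apply(im, c(1, 2), mean)
  grayscale_slice(t(im), patient_id = patient_id, plane = plane)
}

#' Read a binary mask from PNG
#'
#' Pixel values are mapped to \{0,1\} by thresholding at half intensity, so
#' both \{0,255\} and \{0,1\} encodings load correctly.
#' @param path mask file.
#' @return a [binary_mask()].
#' @export
read_mask <- function(path) {
  im <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(im)) == 3L) im <- im[, , 1L]
  binary_mask(t(im) > 0.5)
}

manifest_columns <- c("patient_id", "slice_path", "mask_path", "plane")

#' Read and validate a dataset manifest
#'
#' A manifest is a CSV with columns `patient_id`, `slice_path`,
#' `mask_path`, `plane`. Paths are interpreted relative to the manifest's
#' directory. Masks may be empty for inference-only rows.
#'
#' @param path CSV file.
#' @param check_paths verify that every referenced file exists.
#' @return data frame of class `dataset_manifest` with attribute `dir`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(manifest_columns, names(df))
  if (length(missing_cols))
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[manifest_columns]
  validate_manifest(df, dir = dirname(path), check_paths = check_paths)
}

validate_manifest <- function(df, dir = ".", check_paths = TRUE) {
  if (any(!nzchar(df$patient_id)))
    stop("manifest rows with empty patient_id: ",
         paste(which(!nzchar(df$patient_id)), collapse = ", "))
  dup <- duplicated(df$slice_path)
  if (any(dup))
    stop("duplicate slice_path in manifest rows: ",
         paste(which(dup), collapse = ", "))
  if (check_paths) {
    full <- file.path(dir, df$slice_path)
    bad <- !file.exists(full)
    if (any(bad))
      stop("missing slice files (rows ", paste(which(bad), collapse = ", "),
           "): ", paste(utils::head(full[bad], 3), collapse = ", "))
    has_mask <- nzchar(df$mask_path) & !is.na(df$mask_path)
    fullm <- file.path(dir, df$mask_path[has_mask])
    badm <- !file.exists(fullm)
    if (any(badm))
      stop("missing mask files: ", paste(utils::head(fullm[badm], 3),
                                         collapse = ", "))
  }
  structure(df, dir = dir, class = c("dataset_manifest", "data.frame"))
}

#' Write a dataset manifest CSV
#' @param df manifest data frame.
#' @param path output CSV.
#' @export
write_manifest <- function(df, path) {
  utils::write.csv(df[manifest_columns], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load manifest rows into memory as samples
#'
#' @param manifest a `dataset_manifest` (or path to one).
#' @return list of samples `(image, mask, patient_id, plane)`; `mask` is
#'   `NULL` where the manifest row has none.
#' @export
load_samples <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir <- attr(manifest, "dir") %||% "."
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    mask <- NULL
    if (nzchar(row$mask_path) && !is.na(row$mask_path))
      mask <- read_mask(file.path(dir, row$mask_path))
    list(image = read_slice(file.path(dir, row$slice_path),
                            patient_id = row$patient_id, plane = row$plane),
         mask = mask, patient_id = row$patient_id, plane = row$plane)
  })
}

omsas_default_config <- function() {
  list(
    seed = 17L,
    preprocess = list(tie_to_foreground = TRUE, target_size = c(256L, 256L),
                      constant_image_value = 0),
    augmentation = list(noise_sigma = 0.05, noise_fraction = 0.25),
    network = list(input_size = c(256L, 256L),
                   stage_widths = c(32L, 64L, 128L, 256L),
                   units_per_stage = 2L, condenser_ratio = 4L),
    training = list(learning_rate = 1e-4, epochs = 460L, batch_size = 8L),
    split = list(train_fraction = 0.7, k_folds = 10L),
    tversky = list(alpha = 0.25, beta = 0.75, epsilon = 1e-8)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", path, "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste(paste0(path, unknown), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      v <- user[[k]]
      if (!is.null(v) && mode(v) != mode(defaults[[k]]) &&
          !(is.numeric(v) && is.numeric(defaults[[k]])))
        stop("config key '", path, k, "' has wrong type")
      defaults[[k]] <- v
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML document and merges it over the package defaults (Tversky
#' alpha 0.25 / beta 0.75 / epsilon 1e-8, learning rate 1e-4, 460 epochs,
#' 7:3 patient split, 10 folds). Unknown keys are rejected rather than
#' silently ignored.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return nested configuration list of class `omsas_config`.
#' @export
load_config <- function(path = NULL) {
  user <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
  }
  cfg <- merge_config(omsas_default_config(), user)
  structure(cfg, class = "omsas_config")
}
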