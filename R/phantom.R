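#' Phantom generator parameters
#'
#' Describes an MRI-like 2-D phantom: a dark background, a bright elliptical
#' "limb" cross-section with smooth internal texture, and a single tumor
#' blob with an irregular boundary. Per-image global brightness offsets
#' emulate scanner-to-scanner brightness differences, which is what the
#' min-max normalization step is there to remove.
#'
#' @param image_size side length in pixels (square images).
#' @param limb_axes_range range of the ellipse semi-axes, px.
#' @param tumor_radius_range range of the tumor base radius, px.
#' @param tumor_irregularity boundary perturbation amplitude in [0,1);
#'   0 gives an exact circle.
#' @param tumor_contrast intensity offset of tumor relative to limb tissue
#'   (positive = bright lesion). Must be nonzero or the tumor is invisible.
#' @param brightness_jitter half-width of the uniform per-image global
#'   intensity offset.
#' @param texture_noise_sigma sd of smooth within-limb texture.
#' @param seed base RNG seed; together with the slice index it fully
#'   determines each phantom.
#' @param preset `"easy"` (high contrast, regular boundary) or `"hard"`
#'   (low contrast, strong jitter and irregularity); explicit arguments
#'   override preset values.
#' @return a `phantom_params` list.
#' @export
phantom_params <- function(image_size = 128L,
                           limb_axes_range = NULL,
                           tumor_radius_range = NULL,
                           tumor_irregularity = NULL,
                           tumor_contrast = NULL,
                           brightness_jitter = NULL,
                           texture_noise_sigma = NULL,
                           seed = 1L,
                           preset = c("easy", "hard")) {
  preset <- match.arg(preset)
  base <- if (preset == "easy") {
    list(tumor_irregularity = 0.15, tumor_contrast = 0.35,
         brightness_jitter = 0.10, texture_noise_sigma = 0.02)
  } else {
    list(tumor_irregularity = 0.40, tumor_contrast = 0.15,
         brightness_jitter = 0.25, texture_noise_sigma = 0.05)
  }
  image_size <- as.integer(image_size)
  if (is.null(limb_axes_range))
    limb_axes_range <- c(0.28, 0.42) * image_size
  if (is.null(tumor_radius_range))
    tumor_radius_range <- c(0.08, 0.16) * image_size
  p <- list(image_size = image_size,
            limb_axes_range = limb_axes_range,
            tumor_radius_range = tumor_radius_range,
            tumor_irregularity = tumor_irregularity %||% base$tumor_irregularity,
            tumor_contrast = tumor_contrast %||% base$tumor_contrast,
            brightness_jitter = brightness_jitter %||% base$brightness_jitter,
            texture_noise_sigma = texture_noise_sigma %||% base$texture_noise_sigma,
            seed = as.integer(seed), preset = preset)
  if (p$image_size < 16L) stop("image_size too small for a limb phantom")
  if (p$tumor_contrast == 0) stop("tumor_contrast must be nonzero")
  if (max(p$tumor_radius_range) * (1 + p$tumor_irregularity) >
      0.9 * min(p$limb_axes_range))
    stop("tumor does not fit inside the limb: shrink tumor_radius_range")
  structure(p, class = "phantom_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# seed derived from (base seed, index), kept within 32-bit integer range
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

#' Generate one phantom slice with its ground-truth mask
#'
#' The tumor boundary is a circle whose radius is modulated in polar angle
#' by a small sum of random low-order harmonics,
#' `r(theta) = r0 * (1 + a * sum_k w_k sin(k theta + phi_k))`, giving a
#' star-shaped (hence 4-connected) blob of controllable irregularity.
#'
#' @param params a [phantom_params()].
#' @param index slice index; `(seed, index)` determines the phantom
#'   bit-for-bit.
#' @param patient_id optional id stored on the slice.
#' @param geometry optional list overriding the randomly drawn geometry
#'   (used so slices of one synthetic patient share a tumor).
#' @return list `(image, mask, patient_id)`.
#' @export
generate_phantom <- function(params = phantom_params(), index = 1L,
                             patient_id = sprintf("P%04d", index),
                             geometry = NULL) {
  n <- params$image_size
  set.seed(derive_seed(params$seed, index))
  g <- geometry %||% draw_geometry(params)
  # small per-slice wobble when geometry is shared across a patient's slices
  if (!is.null(geometry)) {
    g$cx <- g$cx + stats::runif(1, -1.5, 1.5)
    g$cy <- g$cy + stats::runif(1, -1.5, 1.5)
    g$r0 <- g$r0 * stats::runif(1, 0.95, 1.05)
  }

  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  limb <- ((xs - g$ex)^2 / g$ax^2 + (ys - g$ey)^2 / g$ay^2) <= 1

  dx <- xs - g$cx; dy <- ys - g$cy
  theta <- atan2(dy, dx)
  rim <- g$r0 * (1 + params$tumor_irregularity *
                   (g$w1 * sin(theta + g$p1) +
                    g$w2 * sin(2 * theta + g$p2) +
                    g$w3 * sin(3 * theta + g$p3)))
  tumor <- (sqrt(dx^2 + dy^2) <= rim) & limb

  tex <- params$texture_noise_sigma *
    (sin(xs / g$tf1 + g$tp1) * cos(ys / g$tf2 + g$tp2) +
     0.5 * sin((xs + ys) / g$tf3 + g$tp3))
  img <- matrix(0.28, n, n)
  img[limb] <- 0.52 + tex[limb]
  img[tumor] <- img[tumor] + params$tumor_contrast
  img <- img + g$offset
  img <- img + matrix(stats::rnorm(n * n, 0, 0.004), n, n)  # sensor noise floor

  list(image = grayscale_slice(img, patient_id = patient_id,
                               plane = g$plane %||% "unknown"),
       mask = binary_mask(tumor),
       patient_id = patient_id)
}

draw_geometry <- function(params) {
  n <- params$image_size
  ax <- stats::runif(1, params$limb_axes_range[1], params$limb_axes_range[2])
  ay <- stats::runif(1, params$limb_axes_range[1], params$limb_axes_range[2])
  ex <- n / 2 + stats::runif(1, -0.05, 0.05) * n
  ey <- n / 2 + stats::runif(1, -0.05, 0.05) * n
  r0 <- stats::runif(1, params$tumor_radius_range[1], params$tumor_radius_range[2])
  # tumor center stays well inside the ellipse even after boundary wobble
  margin <- r0 * (1 + params$tumor_irregularity) + 2
  ang <- stats::runif(1, 0, 2 * pi)
  rad <- stats::runif(1, 0, 0.6)
  cx <- ex + rad * (ax - margin) * cos(ang)
  cy <- ey + rad * (ay - margin) * sin(ang)
  list(ax = ax, ay = ay, ex = ex, ey = ey, r0 = r0, cx = cx, cy = cy,
       w1 = stats::runif(1, 0.4, 1), w2 = stats::runif(1, 0.2, 0.8),
       w3 = stats::runif(1, 0.1, 0.5),
       p1 = stats::runif(1, 0, 2 * pi), p2 = stats::runif(1, 0, 2 * pi),
       p3 = stats::runif(1, 0, 2 * pi),
       tf1 = stats::runif(1, 6, 14), tf2 = stats::runif(1, 6, 14),
       tf3 = stats::runif(1, 10, 20),
       tp1 = stats::runif(1, 0, 2 * pi), tp2 = stats::runif(1, 0, 2 * pi),
       tp3 = stats::runif(1, 0, 2 * pi),
       offset = stats::runif(1, -params$brightness_jitter,
                             params$brightness_jitter))
}

#' Generate a phantom dataset on disk
#'
#' Writes slice and mask PNGs plus a CSV manifest. Slices of one synthetic
#' patient share their limb/tumor geometry up to a small per-slice wobble,
#' and the acquisition-plane label cycles transverse / coronal / sagittal.
#'
#' @param n_patients number of synthetic patients.
#' @param slices_per_patient slices written per patient.
#' @param params a [phantom_params()].
#' @param dir output directory (created if missing).
#' @return the manifest data frame (invisibly written to
#'   `file.path(dir, "manifest.csv")`).
#' @export
generate_dataset <- function(n_patients, slices_per_patient = 3L,
                             params = phantom_params(),
                             dir = tempfile("phantoms")) {
  stopifnot(n_patients >= 1L, slices_per_patient >= 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  planes <- c("transverse", "coronal", "sagittal")
  rows <- vector("list", n_patients * slices_per_patient)
  k <- 0L
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%04d", p)
    set.seed(derive_seed(params$seed, 1000000L + p))
    geo <- draw_geometry(params)
    for (s in seq_len(slices_per_patient)) {
      k <- k + 1L
      geo$plane <- planes[(s - 1L) %% 3L + 1L]
      ph <- generate_phantom(params, index = k, patient_id = pid,
                             geometry = geo)
      slice_file <- sprintf("%s_s%02d.png", pid, s)
      mask_file <- sprintf("%s_s%02d_mask.png", pid, s)
      write_slice_png(ph$image, file.path(dir, slice_file))
      write_mask_png(ph$mask, file.path(dir, mask_file))
      rows[[k]] <- data.frame(patient_id = pid, slice_path = slice_file,
                              mask_path = mask_file, plane = geo$plane,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}

#' Generate a list of phantoms in memory
#'
#' Convenience wrapper used by the training probes and tests: no files, one
#' phantom per index, each its own patient.
#'
#' @inheritParams generate_phantom
#' @param n number of phantoms.
#' @param params a [phantom_params()].
#' @return list of `(image, mask, patient_id)` samples.
#' @export
generate_phantom_set <- function(n, params = phantom_params()) {
  lapply(seq_len(n), function(i) generate_phantom(params, index = i))
}
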