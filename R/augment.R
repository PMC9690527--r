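#' Dihedral transform of the square
#'
#' One of the 8 symmetries of a square image: `rotation` quarter-turns
#' counterclockwise followed (optionally) by a horizontal flip. The 8
#' `(rotation, flip)` pairs form the dihedral group D4.
#'
#' @param rotation integer in 0..3, counterclockwise quarter-turns.
#' @param flip apply a horizontal (left-right) flip after rotating.
#' @return a `d4_transform`.
#' @export
d4_transform <- function(rotation = 0L, flip = FALSE) {
  rotation <- as.integer(rotation) %% 4L
  structure(list(rotation = rotation, flip = isTRUE(flip)),
            class = "d4_transform")
}

#' @export
format.d4_transform <- function(x, ...) {
  sprintf("rot%d%s", 90L * x$rotation, if (x$flip) "+hflip" else "")
}

#' @export
print.d4_transform <- function(x, ...) {
  cat("<d4_transform ", format(x), ">\n", sep = "")
  invisible(x)
}

#' The full dihedral orbit
#'
#' All 8 square symmetries in a fixed order: the four rotations (identity
#' first), then the four rotations followed by a horizontal flip.
#'
#' @return list of 8 [d4_transform()]s.
#' @export
d4_orbit <- function() {
  c(lapply(0:3, d4_transform, flip = FALSE),
    lapply(0:3, d4_transform, flip = TRUE))
}

rot90_ccw <- function(m) {
  tm <- t(m)
  tm[rev(seq_len(nrow(tm))), , drop = FALSE]
}

hflip <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

apply_to_matrix <- function(t, m) {
  k <- t$rotation
  while (k > 0L) { m <- rot90_ccw(m); k <- k - 1L }
  if (t$flip) m <- hflip(m)
  m
}

#' Apply a dihedral transform to a slice (and optionally its mask)
#'
#' Both members of a pair are transformed identically, so the mask stays
#' pixel-aligned and its foreground count is conserved.
#'
#' @param t a [d4_transform()].
#' @param slice `grayscale_slice` or numeric matrix.
#' @param mask optional paired [binary_mask()].
#' @return if `mask` is `NULL`, the transformed slice; otherwise a list
#'   `(image, mask)`.
#' @export
d4_apply <- function(t, slice, mask = NULL) {
  img <- apply_to_matrix(t, as_plain_matrix(slice))
  img <- if (inherits(slice, "grayscale_slice")) reslice(img, slice) else img
  if (is.null(mask)) return(img)
  check_same_shape(slice, mask)
  list(image = img, mask = binary_mask(apply_to_matrix(t, as_plain_matrix(mask))))
}

#' Inverse of a dihedral transform
#'
#' Pure rotations invert to the complementary rotation; every rotate-then-
#' flip element is an involution (its own inverse).
#'
#' @param t a [d4_transform()].
#' @return the `d4_transform` `s` with `s(t(x)) = x` for every image.
#' @export
d4_inverse <- function(t) {
  if (t$flip) d4_transform(t$rotation, TRUE)
  else d4_transform((4L - t$rotation) %% 4L, FALSE)
}

#' Compose two dihedral transforms
#'
#' `d4_compose(t2, t1)` is the transform "first `t1`, then `t2`". The group
#' is closed: the result is again one of the 8 orbit members.
#'
#' @param t2,t1 [d4_transform()]s.
#' @return their composition as a `d4_transform`.
#' @export
d4_compose <- function(t2, t1) {
  if (!t1$flip) d4_transform((t1$rotation + t2$rotation) %% 4L, t2$flip)
  else d4_transform((t1$rotation - t2$rotation) %% 4L, !t2$flip)
}

#' Augmentation configuration
#'
#' @param noise_sigma sd of additive Gaussian noise, as a fraction of the
#'   normalized [0,1] intensity range.
#' @param noise_fraction fraction of augmented images that receive noise.
#' @param seed RNG seed driving both the subset choice and the draws.
#' @return an `augmentation_config` list.
#' @export
augmentation_config <- function(noise_sigma = 0.05, noise_fraction = 0.25,
                                seed = 1L) {
  stopifnot(noise_sigma >= 0, noise_fraction >= 0, noise_fraction <= 1)
  structure(list(noise_sigma = noise_sigma, noise_fraction = noise_fraction,
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Add clipped Gaussian noise to a normalized slice
#'
#' @param slice normalized `grayscale_slice` (values in [0,1]).
#' @param cfg an [augmentation_config()]; `cfg$seed` makes the draw
#'   reproducible.
#' @return noisy slice, clipped back to [0,1].
#' @export
add_noise <- function(slice, cfg = augmentation_config()) {
  m <- as_plain_matrix(slice)
  if (cfg$noise_sigma > 0) {
    set.seed(cfg$seed)
    m <- m + matrix(stats::rnorm(length(m), 0, cfg$noise_sigma), nrow(m), ncol(m))
    m <- pmin(pmax(m, 0), 1)
  }
  if (inherits(slice, "grayscale_slice")) reslice(m, slice) else m
}

#' Expand a dataset by its dihedral orbit
#'
#' Every sample is replaced by its 8 distinct symmetry copies (so the output
#' holds exactly 8x the input count), after which a seeded random subset of
#' size `noise_fraction * count` receives additive Gaussian noise on the
#' image only — labels are never perturbed.
#'
#' @param samples list of samples, each a list with `image`, `mask` and
#'   optionally `patient_id`.
#' @param cfg an [augmentation_config()].
#' @return list of augmented samples; each carries its `transform` and a
#'   `noised` flag.
#' @export
augment_dataset <- function(samples, cfg = augmentation_config()) {
  orbit <- d4_orbit()
  out <- vector("list", 8L * length(samples))
  pos <- 0L
  for (s in samples) {
    for (t in orbit) {
      pos <- pos + 1L
      pr <- d4_apply(t, s$image, s$mask)
      out[[pos]] <- list(image = pr$image, mask = pr$mask,
                         patient_id = s$patient_id, transform = t,
                         noised = FALSE)
    }
  }
  n_noise <- round(cfg$noise_fraction * length(out))
  if (n_noise > 0L && cfg$noise_sigma > 0) {
    set.seed(cfg$seed)
    pick <- sample(length(out), n_noise)
    for (i in seq_along(pick)) {
      j <- pick[i]
      sub <- augmentation_config(cfg$noise_sigma, cfg$noise_fraction,
                                 seed = cfg$seed + i)
      out[[j]]$image <- add_noise(out[[j]]$image, sub)
      out[[j]]$noised <- TRUE
    }
  }
  out
}
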