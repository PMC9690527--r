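#' Single-pass prediction
#'
#' One forward pass; a pixel is tumor when its probability is at least
#' `threshold` (ties at the threshold go to tumor).
#'
#' @param model a built `acrnet`.
#' @param slice normalized `grayscale_slice` at the model input size.
#' @param threshold decision threshold (default 0.5).
#' @return a [binary_mask()].
#' @export
predict_single <- function(model, slice, threshold = 0.5) {
  prob <- acrnet_forward(model, slice)$prob
  binary_mask(prob >= threshold)
}

#' Fuse aligned binary predictions by per-pixel majority vote
#'
#' Given n re-aligned binary maps, a pixel is tumor when at least half the
#' copies call it tumor (`sum >= n/2`; exact ties go to tumor, consistent
#' with prioritizing recall). `literal_eq6 = TRUE` instead applies the
#' sign-based voting formula exactly as printed in the source description,
#' `1/2 - 1/2 * sign(sum - n/2)` — note that convention labels a pixel 1
#' when the copies vote *below* half, i.e., it inverts the majority; it is
#' exposed only for auditability.
#'
#' @param stack list of shape-matched binary masks/matrices, or a 3-D array
#'   with copies along the third axis.
#' @param literal_eq6 use the printed sign convention instead of the
#'   majority-vote reading.
#' @return a [binary_mask()].
#' @export
compound_decision <- function(stack, literal_eq6 = FALSE) {
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  n <- length(stack)
  if (n < 1L) stop("empty prediction stack")
  for (m in stack) check_same_shape(stack[[1]], m, "vote-stack copies")
  sigma <- Reduce(`+`, lapply(stack, as_plain_matrix))
  if (literal_eq6) {
    out <- 0.5 - 0.5 * sign(sigma - n / 2)
    out[sigma == n / 2] <- 1  # sign() is 0 at a tie; resolve ties to tumor
  } else {
    out <- sigma >= n / 2
  }
  binary_mask(out > 0)
}

#' Compound (test-time-augmentation) prediction
#'
#' Predicts on all 8 dihedral copies of the slice, inverse-transforms each
#' binary prediction back to the original frame, and fuses them with the
#' per-pixel majority vote of [compound_decision()]. Averaging the 8
#' probability maps before thresholding is available via
#' `mode = "mean"`.
#'
#' @inheritParams predict_single
#' @param mode `"vote"` (binarize each copy, then majority) or `"mean"`
#'   (average probabilities, then threshold).
#' @param transforms the symmetry copies to use; default the full 8-element
#'   orbit. A single identity transform reduces to [predict_single()].
#' @param literal_eq6 passed to [compound_decision()].
#' @return a [binary_mask()].
#' @export
predict_compound <- function(model, slice, threshold = 0.5,
                             mode = c("vote", "mean"),
                             transforms = d4_orbit(),
                             literal_eq6 = FALSE) {
  mode <- match.arg(mode)
  m <- as_plain_matrix(slice)
  probs <- lapply(transforms, function(t) {
    p <- acrnet_forward(model, apply_to_matrix(t, m))$prob
    apply_to_matrix(d4_inverse(t), p)
  })
  if (mode == "mean") {
    avg <- Reduce(`+`, probs) / length(probs)
    return(binary_mask(avg >= threshold))
  }
  compound_decision(lapply(probs, function(p) binary_mask(p >= threshold)),
                    literal_eq6 = literal_eq6)
}

#' Attention-map overlay
#'
#' Extracts the channel-mean attention gate of the requested encoder
#' stage's condenser, upsamples it to the input size, and renders it as a
#' heat overlay on the grayscale slice: the brighter/warmer the area, the
#' more the stage's attention concentrates there.
#'
#' @param model a built `acrnet`.
#' @param slice normalized input slice.
#' @param stage_index encoder stage whose condenser gate to visualize.
#' @param alpha blend weight of the heat layer over the grayscale image.
#' @param out optional PNG path.
#' @return an `(h, w, 3)` RGB array in [0,1], invisibly written to `out`
#'   when given.
#' @export
attention_overlay <- function(model, slice, stage_index = 1L, alpha = 0.45,
                              out = NULL) {
  S <- length(model$config$stage_widths)
  if (stage_index < 1L || stage_index > S)
    stop("stage_index must be in 1..", S)
  fw <- acrnet_forward(model, slice, keep_gates = TRUE)
  gate <- fw$gates[[stage_index]]
  m <- as_plain_matrix(slice)
  gate_up <- resize_image(gate, c(nrow(m), ncol(m)), "bilinear")
  rng <- range(gate_up)
  heat01 <- if (diff(rng) > 0) (gate_up - rng[1]) / diff(rng)
            else matrix(0.5, nrow(m), ncol(m))
  pal <- grDevices::hcl.colors(256, "Inferno")
  rgb_mat <- grDevices::col2rgb(pal[pmin(255L, floor(heat01 * 255)) + 1L]) / 255
  base <- pmin(pmax(m, 0), 1)
  overlay <- array(0, c(nrow(m), ncol(m), 3L))
  for (ch in 1:3) {
    heat_ch <- matrix(rgb_mat[ch, ], nrow(m), ncol(m))
    overlay[, , ch] <- (1 - alpha) * base + alpha * heat_ch
  }
  if (!is.null(out)) {
    EBImage::writeImage(EBImage::Image(aperm(overlay, c(2, 1, 3)),
                                       colormode = "Color"), out)
  }
  invisible(overlay)
}
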