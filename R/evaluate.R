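#' Pixelwise confusion counts
#'
#' Tumor is the positive class: TP counts pixels predicted and labeled
#' tumor, TN pixels predicted and labeled normal, FP normal tissue called
#' tumor, FN tumor missed.
#'
#' @param pred,truth shape-matched [binary_mask()]s.
#' @return a `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(pred, truth) {
  check_same_shape(pred, truth, "prediction and truth")
  p <- as_plain_matrix(pred) > 0
  t <- as_plain_matrix(truth) > 0
  structure(list(TP = sum(p & t), TN = sum(!p & !t),
                 FP = sum(p & !t), FN = sum(!p & t)),
            class = "confusion_counts")
}

# ratio with the degenerate-case rule: 0/0 -> 1 when the comparison is
# between two empty sets (perfect agreement), else 0
safe_ratio <- function(num, den, both_empty) {
  if (den > 0) return(num / den)
  if (both_empty) 1 else 0
}

#' Segmentation metric panel
#'
#' Computes the confusion-matrix panel with tumor as the positive class:
#' accuracy, precision, two recalls, F1, IoU and DSC. `recall_paper` is the
#' negative-class ratio TN/(TN+FN) as printed in the source panel this
#' package reproduces; `recall_standard` is the usual sensitivity
#' TP/(TP+FN). `f1` is the harmonic mean of precision and `recall_paper`
#' (matching the panel); `f1_standard` uses `recall_standard`. Degenerate
#' 0/0 ratios score 1 when both masks are empty (perfect agreement) and 0
#' when only one side is empty.
#'
#' @param counts a [confusion()] result, or a prediction mask when `truth`
#'   is given.
#' @param truth optional truth mask (then `counts` is the prediction).
#' @return a `metrics_report` list; `dsc` and `iou` satisfy
#'   `dsc == 2 * iou / (1 + iou)`.
#' @export
metrics <- function(counts, truth = NULL) {
  if (!is.null(truth)) counts <- confusion(counts, truth)
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  pred_area <- TP + FP; real_area <- TP + FN
  both_empty <- pred_area == 0 && real_area == 0

  accuracy <- (TP + TN) / total
  precision <- safe_ratio(TP, TP + FP, both_empty)
  recall_paper <- safe_ratio(TN, TN + FN, TN == 0 && FN == 0 && FP == 0 && TP == total)
  recall_standard <- safe_ratio(TP, TP + FN, both_empty)
  f1 <- safe_ratio(2 * precision * recall_paper, precision + recall_paper,
                   both_empty)
  f1_standard <- safe_ratio(2 * precision * recall_standard,
                            precision + recall_standard, both_empty)
  iou <- safe_ratio(TP, TP + FP + FN, both_empty)
  dsc <- safe_ratio(2 * TP, 2 * TP + FP + FN, both_empty)

  structure(list(accuracy = accuracy, precision = precision,
                 recall_paper = recall_paper,
                 recall_standard = recall_standard,
                 f1 = f1, f1_standard = f1_standard,
                 iou = iou, dsc = dsc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("segmentation metrics:\n")
  for (k in names(x)) cat(sprintf("  %-16s %.4f\n", k, x[[k]]))
  invisible(x)
}

#' Single-epoch training time
#'
#' Arithmetic mean of per-epoch wall times, in seconds. Hardware-dependent;
#' reported, never compared against published values.
#'
#' @param epoch_times numeric vector of per-epoch seconds.
#' @return mean seconds.
#' @export
sett <- function(epoch_times) {
  if (length(epoch_times) < 1L) stop("sett needs at least one epoch time")
  mean(epoch_times)
}

#' Evaluate a model over a manifest
#'
#' Runs the model on every labeled slice and tabulates the per-slice metric
#' panel plus an unweighted mean row (macro averaging across slices).
#'
#' @param model a built ACRNet.
#' @param manifest a `dataset_manifest` or path to one; rows must have
#'   masks.
#' @param cfg [preprocess_config()] matched to the model input size.
#' @param tta use compound (8-copy majority vote) prediction; otherwise a
#'   single forward pass.
#' @param out optional CSV path for the table.
#' @return data frame: one row per slice plus a final `"mean"` row.
#' @export
evaluate_dataset <- function(model, manifest,
                             cfg = preprocess_config(target_size = model$config$input_size),
                             tta = TRUE, out = NULL) {
  samples <- if (is.list(manifest) && !is.data.frame(manifest)) manifest
             else load_samples(manifest)
  if (!length(samples)) stop("no samples to evaluate")
  rows <- lapply(samples, function(s) {
    if (is.null(s$mask)) stop("evaluate_dataset requires masks for all rows")
    pp <- preprocess_sample(s$image, s$mask, cfg)
    pred <- if (tta) predict_compound(model, pp$image)
            else predict_single(model, pp$image)
    met <- metrics(pred, pp$mask)
    data.frame(patient_id = s$patient_id %||% "unknown",
               as.data.frame(unclass(met)), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  mean_row <- tab[1, ]
  mean_row$patient_id <- "mean"
  for (k in setdiff(names(tab), "patient_id")) mean_row[[k]] <- mean(tab[[k]])
  tab <- rbind(tab, mean_row)
  rownames(tab) <- NULL
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  tab
}
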