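#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-4).
#' @param epochs passes over the training set (default 460; probes use far
#'   fewer).
#' @param batch_size samples per gradient step.
#' @param seed RNG seed driving shuffling (weights are seeded by the
#'   architecture config).
#' @param checkpoint_dir directory for the best-model checkpoint, or
#'   `NULL` to keep it in memory only.
#' @param log_path optional CSV path for the epoch log.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 460L, batch_size = 8L,
                         seed = 17L, checkpoint_dir = NULL, log_path = NULL) {
  stopifnot(learning_rate > 0, epochs >= 1L, batch_size >= 1L)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir, log_path = log_path),
            class = "train_config")
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L, b1 = 0.9, b2 = 0.999, eps = 1e-8)
}

adam_step <- function(state, flat, grads, lr) {
  state$t <- state$t + 1L
  b1 <- state$b1; b2 <- state$b2
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, flat = flat)
}

sample_loss_grad <- function(model, sample, params) {
  fw <- acrnet_forward(model, sample$image, keep_cache = TRUE)
  truth <- as_plain_matrix(sample$mask)
  loss <- tversky_loss(fw$prob, truth, params)
  dprob <- tversky_loss_grad(fw$prob, truth, params)
  grads <- acrnet_backward(model, fw$cache, dprob)
  list(loss = loss, grads = grads)
}

#' Mean DSC of a model over labeled samples
#'
#' @param model an `acrnet`.
#' @param samples list of `(image, mask)` samples at the model input size.
#' @param tta fuse the 8 dihedral copies by majority vote before scoring.
#' @return mean per-slice Dice similarity coefficient.
#' @export
validation_dsc <- function(model, samples, tta = FALSE) {
  if (!length(samples)) return(NA_real_)
  mean(vapply(samples, function(s) {
    pred <- if (tta) predict_compound(model, s$image)
            else predict_single(model, s$image)
    metrics(pred, s$mask)$dsc
  }, numeric(1)))
}

#' Train an ACRNet with Tversky loss
#'
#' Mini-batch Adam at the configured learning rate. Each epoch logs the
#' mean training loss, validation DSC and wall time; the weights achieving
#' the best validation DSC are kept (and written to
#' `cfg$checkpoint_dir/best.rds` when a directory is given). Fully seeded:
#' identical seeds give identical runs on CPU.
#'
#' @param model a built `acrnet`.
#' @param train_samples list of `(image, mask)` samples at model input
#'   size, intensities normalized to [0,1].
#' @param val_samples held-out samples for checkpoint selection (may be
#'   empty; then the final weights are kept).
#' @param cfg a [train_config()].
#' @param params a [tversky_params()].
#' @param verbose print one line per epoch.
#' @return list with `model` (best weights), `log` (data frame: epoch,
#'   loss, val_dsc, seconds) and `sett_seconds` (mean epoch wall time).
#' @export
train_acrnet <- function(model, train_samples, val_samples = list(),
                         cfg = train_config(), params = tversky_params(),
                         verbose = FALSE) {
  n <- length(train_samples)
  if (n < 1L) stop("empty training set")
  flat <- flatten_params(model)
  opt <- adam_init(flat)
  best_dsc <- -Inf
  best_flat <- flat
  log_rows <- vector("list", cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    set.seed(cfg$seed + epoch)
    order_idx <- sample(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- order_idx[start:min(start + cfg$batch_size - 1L, n)]
      acc <- NULL
      batch_loss <- 0
      for (i in idx) {
        sg <- sample_loss_grad(model, train_samples[[i]], params)
        if (!is.finite(sg$loss))
          stop(sprintf("non-finite loss at epoch %d, sample %d: %g",
                       epoch, i, sg$loss))
        batch_loss <- batch_loss + sg$loss
        if (is.null(acc)) acc <- sg$grads
        else for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + sg$grads[[nm]]
      }
      k <- length(idx)
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / k
      st <- adam_step(opt, flat, acc, cfg$learning_rate)
      opt <- st$state; flat <- st$flat
      model <- assign_params(model, flat)
      losses <- c(losses, batch_loss / k)
    }
    vdsc <- validation_dsc(model, val_samples)
    secs <- proc.time()[["elapsed"]] - t0
    log_rows[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses),
                                    val_dsc = vdsc, seconds = secs)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val_dsc %s  %.1fs",
                      epoch, mean(losses),
                      ifelse(is.na(vdsc), "NA", sprintf("%.4f", vdsc)), secs))
    if (!is.na(vdsc) && vdsc > best_dsc) {
      best_dsc <- vdsc
      best_flat <- flat
    }
  }
  if (!length(val_samples)) best_flat <- flat
  model <- assign_params(model, best_flat)
  log <- do.call(rbind, log_rows)
  if (!is.null(cfg$log_path)) {
    dir.create(dirname(cfg$log_path), recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(log, cfg$log_path, row.names = FALSE)
  }
  if (!is.null(cfg$checkpoint_dir)) {
    dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    acrnet_save(model, file.path(cfg$checkpoint_dir, "best.rds"))
  }
  list(model = model, log = log, sett_seconds = sett(log$seconds))
}
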