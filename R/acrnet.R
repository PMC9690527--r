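#' ACRNet architecture configuration
#'
#' Describes the encoder-decoder: a stem that lifts the grayscale input to
#' the first stage width, then per stage a stack of depthwise-separable
#' residual units followed by one attention condenser, with 2x max-pool
#' between stages; the decoder mirrors the encoder with nearest-neighbor
#' upsampling, skip concatenation and reservation blocks to merge channels;
#' the head is a 1x1 convolution with a sigmoid, giving per-pixel tumor
#' probabilities.
#'
#' @param input_size integer `(h, w)`; both must be divisible by
#'   `2^(n_stages - 1)`.
#' @param stage_widths channel count per encoder stage (>= 2 stages).
#' @param units_per_stage residual units per stage.
#' @param condenser_ratio channel-bottleneck ratio of the attention
#'   condensers; larger ratio means a narrower (cheaper) embedding.
#' @param seed RNG seed for weight initialization.
#' @return an `acrnet_config` list.
#' @export
acrnet_config <- function(input_size = c(256L, 256L),
                          stage_widths = c(32L, 64L, 128L, 256L),
                          units_per_stage = 2L,
                          condenser_ratio = 4L,
                          seed = 17L) {
  input_size <- as.integer(input_size)
  stage_widths <- as.integer(stage_widths)
  if (length(stage_widths) < 2L) stop("need at least 2 stages")
  if (any(stage_widths < 1L)) stop("stage widths must be positive")
  down <- 2L^(length(stage_widths) - 1L)
  if (any(input_size %% down != 0L))
    stop("input_size must be divisible by ", down,
         " for ", length(stage_widths), " stages")
  structure(list(input_size = input_size, stage_widths = stage_widths,
                 units_per_stage = as.integer(units_per_stage),
                 condenser_ratio = as.integer(condenser_ratio),
                 seed = as.integer(seed)),
            class = "acrnet_config")
}

#' A small configuration for probes and tests
#'
#' Three stages of widths 8/16/32 with one residual unit each at 64x64
#' input: a few tens of thousands of parameters, trainable on a CPU in
#' minutes.
#' @param seed RNG seed.
#' @return an `acrnet_config`.
#' @export
acrnet_tiny_config <- function(seed = 17L) {
  acrnet_config(input_size = c(64L, 64L), stage_widths = c(8L, 16L, 32L),
                units_per_stage = 1L, condenser_ratio = 4L, seed = seed)
}

#' Build an ACRNet model
#'
#' Instantiates every block with seeded He-uniform convolution weights,
#' unit layer-norm scales and zero offsets.
#'
#' @param config an [acrnet_config()].
#' @return an `acrnet` model object (a module tree plus its config).
#' @export
build_acrnet <- function(config = acrnet_config()) {
  stopifnot(inherits(config, "acrnet_config"))
  set.seed(config$seed)
  widths <- config$stage_widths
  S <- length(widths)
  mods <- list(stem = nn_reservation(1L, widths[1L]))
  for (s in seq_len(S)) {
    units <- lapply(seq_len(config$units_per_stage),
                    function(i) nn_residual(widths[s]))
    stage <- do.call(nn_seq, c(units, list(nn_condenser(widths[s],
                                                        config$condenser_ratio))))
    mods[[paste0("enc", s)]] <- stage
    if (s < S)
      mods[[paste0("trans", s)]] <- nn_reservation(widths[s], widths[s + 1L])
  }
  for (s in rev(seq_len(S - 1L))) {
    units <- lapply(seq_len(config$units_per_stage),
                    function(i) nn_residual(widths[s]))
    merge <- nn_reservation(widths[s + 1L] + widths[s], widths[s])
    mods[[paste0("dec", s)]] <- do.call(nn_seq, c(list(merge), units))
  }
  mods$head <- nn_pw(widths[1L], 1L)
  structure(list(type = "acrnet", config = config, mods = mods),
            class = "acrnet")
}

#' @export
print.acrnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<acrnet %dx%d input, stages [%s], %d unit(s)/stage, ratio %d, %s parameters>\n",
    cfg$input_size[1], cfg$input_size[2],
    paste(cfg$stage_widths, collapse = ", "),
    cfg$units_per_stage, cfg$condenser_ratio,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

slice_to_tensor <- function(slice) {
  m <- as_plain_matrix(slice)
  array(m, c(nrow(m), ncol(m), 1L))
}

#' Forward pass
#'
#' @param model a built `acrnet`.
#' @param x input: a normalized `grayscale_slice`, matrix, or `(h, w, 1)`
#'   array at the configured input size.
#' @param keep_cache keep every layer cache (needed for backprop).
#' @param keep_gates collect each encoder condenser's channel-mean
#'   attention gate (for attention maps).
#' @return list with `prob` (h x w matrix of tumor probabilities) and,
#'   when requested, `cache` and `gates`.
#' @export
acrnet_forward <- function(model, x, keep_cache = FALSE, keep_gates = FALSE) {
  if (!is.array(x) || length(dim(x)) != 3L) x <- slice_to_tensor(x)
  d <- dim(x)
  if (!all(d[1:2] == model$config$input_size))
    stop(sprintf("input is %dx%d but model expects %dx%d",
                 d[1], d[2], model$config$input_size[1],
                 model$config$input_size[2]))
  S <- length(model$config$stage_widths)
  cache <- list()
  st <- nn_forward(model$mods$stem, x)
  cache$stem <- st$cache
  h <- st$y
  skips <- vector("list", S)
  gates <- if (keep_gates) vector("list", S) else NULL
  cache$pool <- vector("list", S)
  for (s in seq_len(S)) {
    st <- nn_forward(model$mods[[paste0("enc", s)]], h)
    cache[[paste0("enc", s)]] <- st$cache
    skips[[s]] <- st$y
    if (keep_gates) {
      cond_cache <- st$cache[[length(st$cache)]]
      G <- cond_cache$G
      gates[[s]] <- apply(G, c(1, 2), mean)
    }
    if (s < S) {
      pl <- pool2_fwd(st$y)
      cache$pool[[s]] <- pl
      st2 <- nn_forward(model$mods[[paste0("trans", s)]], pl$y)
      cache[[paste0("trans", s)]] <- st2$cache
      h <- st2$y
    }
  }
  dcur <- skips[[S]]
  cache$cat_dims <- vector("list", S)
  for (s in rev(seq_len(S - 1L))) {
    up <- up2_fwd(dcur)
    cat_in <- array(c(up, skips[[s]]),
                    c(dim(up)[1], dim(up)[2], dim(up)[3] + dim(skips[[s]])[3]))
    cache$cat_dims[[s]] <- c(dim(up)[3], dim(skips[[s]])[3])
    st <- nn_forward(model$mods[[paste0("dec", s)]], cat_in)
    cache[[paste0("dec", s)]] <- st$cache
    dcur <- st$y
  }
  st <- nn_forward(model$mods$head, dcur)
  cache$head <- st$cache
  prob <- 1 / (1 + exp(-st$y))
  out <- list(prob = matrix(prob, d[1], d[2]))
  if (keep_cache) { cache$prob <- prob; out$cache <- cache }
  if (keep_gates) out$gates <- gates
  out
}

# backward pass from d(loss)/d(prob); returns flat named gradient list
acrnet_backward <- function(model, cache, dprob) {
  S <- length(model$config$stage_widths)
  prob <- cache$prob
  dlogit <- array(dprob, dim(prob)) * prob * (1 - prob)
  gr <- list()
  st <- nn_backward(model$mods$head, cache$head, dlogit)
  gr <- c(gr, flatten_grads(st$grads, "head/"))
  dcur <- st$dx
  dskips <- vector("list", S)
  for (s in seq_len(S - 1L)) {
    st <- nn_backward(model$mods[[paste0("dec", s)]],
                      cache[[paste0("dec", s)]], dcur)
    gr <- c(gr, flatten_grads(st$grads, paste0("dec", s, "/")))
    dims <- cache$cat_dims[[s]]
    dcat <- st$dx
    dup <- dcat[, , seq_len(dims[1]), drop = FALSE]
    dskips[[s]] <- dcat[, , dims[1] + seq_len(dims[2]), drop = FALSE]
    dcur <- up2_bwd(dup)
  }
  dskips[[S]] <- dcur
  denc_out <- dskips[[S]]
  for (s in rev(seq_len(S))) {
    if (s < S) {
      st <- nn_backward(model$mods[[paste0("trans", s)]],
                        cache[[paste0("trans", s)]], denc_out)
      gr <- c(gr, flatten_grads(st$grads, paste0("trans", s, "/")))
      denc_out <- pool2_bwd(cache$pool[[s]], st$dx) + dskips[[s]]
    }
    st <- nn_backward(model$mods[[paste0("enc", s)]],
                      cache[[paste0("enc", s)]], denc_out)
    gr <- c(gr, flatten_grads(st$grads, paste0("enc", s, "/")))
    denc_out <- st$dx
  }
  st <- nn_backward(model$mods$stem, cache$stem, denc_out)
  gr <- c(gr, flatten_grads(st$grads, "stem/"))
  gr
}

#' Count trainable parameters
#'
#' @param model an `acrnet` (or any module).
#' @return integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(flatten_params(model), length, integer(1)))
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the architecture configuration, so loading
#' rebuilds the module tree and restores the weights.
#' @param model an `acrnet`.
#' @param path checkpoint file.
#' @export
acrnet_save <- function(model, path) {
  saveRDS(list(config = model$config, params = flatten_params(model)), path)
  invisible(path)
}

#' @rdname acrnet_save
#' @export
acrnet_load <- function(path) {
  ck <- readRDS(path)
  model <- build_acrnet(ck$config)
  model <- assign_params(model, ck$params)
  class(model) <- "acrnet"
  model
}

# ---- attention primitives (exported for direct use and audit) ----------

#' Channel squeeze: spatial mean per channel
#'
#' @param M a `(h, w, c)` feature array.
#' @return numeric vector `z` of length `c`, the mean activation of each
#'   channel.
#' @export
channel_squeeze <- function(M) {
  d <- dim(M)
  .colMeans(matrix(M, d[1] * d[2], d[3]), d[1] * d[2], d[3])
}

#' Channel excitation: bottleneck gating weights
#'
#' `e = sigmoid(W_rho %*% relu(W_sigma %*% z))`; every gate lies strictly
#' in (0,1).
#'
#' @param z per-channel summary vector.
#' @param W_sigma bottleneck matrix (`c_r` x `c`).
#' @param W_rho expansion matrix (`c` x `c_r`).
#' @return gate vector `e` of length `c`.
#' @export
channel_excite <- function(z, W_sigma, W_rho) {
  W_sigma <- as.matrix(W_sigma); W_rho <- as.matrix(W_rho)
  if (ncol(W_sigma) != length(z))
    stop("W_sigma has ", ncol(W_sigma), " columns but z has length ", length(z))
  if (ncol(W_rho) != nrow(W_sigma))
    stop("W_rho columns must match W_sigma rows")
  hidden <- pmax(as.numeric(W_sigma %*% z), 0)
  as.numeric(1 / (1 + exp(-(W_rho %*% hidden))))
}

#' Apply per-channel attention gates
#'
#' Scales every channel of `M` by its gate: `M'[ , , c] = e[c] * M[ , , c]`.
#'
#' @param M `(h, w, c)` feature array.
#' @param e gate vector of length `c`.
#' @return gated array of the same shape.
#' @export
apply_attention <- function(M, e) {
  d <- dim(M)
  if (length(e) != d[3]) stop("gate length must equal channel count")
  M * rep(e, each = d[1] * d[2])
}

#' Run one attention condenser as a standalone operation
#'
#' Builds a seeded condenser for the input's channel count and applies it:
#' condense (2x spatial max-pool plus channel reduction to
#' `floor(c / ratio)`), embed, expand, and gate. Output shape equals input
#' shape.
#'
#' @param M `(h, w, c)` feature array with even `h`, `w`.
#' @param ratio channel bottleneck ratio.
#' @param seed RNG seed for the block weights.
#' @return gated array, same shape as `M`.
#' @export
attention_condenser <- function(M, ratio = 4L, seed = 1L) {
  d <- dim(M)
  set.seed(seed)
  mod <- nn_condenser(d[3], ratio)
  nn_forward(mod, M)$y
}

#' Apply a freshly initialized reservation block
#'
#' 1x1 convolution + layer normalization + ReLU: changes only the channel
#' count. Exposed mainly for audits of shape and parameter-count behavior.
#'
#' @param x `(h, w, c)` feature array.
#' @param out_channels output channel count.
#' @param seed RNG seed for the weights.
#' @return `(h, w, out_channels)` array, elementwise nonnegative.
#' @export
reservation_block <- function(x, out_channels, seed = 1L) {
  set.seed(seed)
  nn_forward(nn_reservation(dim(x)[3], out_channels), x)$y
}

#' Apply a freshly initialized retracting block
#'
#' Depthwise 3x3 convolution (one kernel per input channel) followed by a
#' pointwise 1x1 convolution to `out_channels`; spatial size is preserved.
#'
#' @inheritParams reservation_block
#' @return `(h, w, out_channels)` array.
#' @export
retracting_block <- function(x, out_channels, seed = 1L) {
  set.seed(seed)
  nn_forward(nn_retracting(dim(x)[3], out_channels), x)$y
}

#' Apply a freshly initialized residual unit
#'
#' Two retracting blocks with layer normalization, skip-added to the input
#' before the final ReLU; input and output shapes match.
#'
#' @param x `(h, w, c)` feature array.
#' @param seed RNG seed for the weights.
#' @return array of the same shape as `x`.
#' @export
residual_unit <- function(x, seed = 1L) {
  set.seed(seed)
  nn_forward(nn_residual(dim(x)[3]), x)$y
}
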