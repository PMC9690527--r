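# Minimal CNN engine: explicit forward/backward passes over (h, w, c)
# arrays, vectorized so the heavy lifting lands in BLAS. Every module is a
# list with a `type`, optional `params` (named numeric arrays) and optional
# `mods` (named submodules); gradients come back in a tree of the same
# shape, and flatten/assign walkers map that tree to the flat parameter
# vectors the optimizer works on.

LN_EPS <- 1e-5

as_hw_c <- function(x, c_axis) matrix(x, length(x) %/% c_axis, c_axis)

he_uniform <- function(n, fan_in) {
  l <- sqrt(6 / fan_in)
  stats::runif(n, -l, l)
}

nn_pw <- function(c_in, c_out) {
  list(type = "pw", c_in = c_in, c_out = c_out,
       params = list(W = matrix(he_uniform(c_in * c_out, c_in), c_in, c_out),
                     b = numeric(c_out)))
}

nn_dw <- function(c) {
  list(type = "dw", c = c,
       params = list(K = array(he_uniform(9 * c, 9), c(3, 3, c)),
                     b = numeric(c)))
}

nn_ln <- function(c) {
  list(type = "ln", c = c,
       params = list(g = rep(1, c), b = numeric(c)))
}

nn_relu <- function() list(type = "relu")
nn_sigmoid <- function() list(type = "sigmoid")

nn_seq <- function(...) {
  mods <- list(...)
  names(mods) <- sprintf("m%d", seq_along(mods))
  list(type = "seq", mods = mods)
}

# 1x1 conv + layer norm (over channels, per position) + ReLU:
# changes channel count only.
nn_reservation <- function(c_in, c_out) {
  m <- nn_seq(nn_pw(c_in, c_out), nn_ln(c_out), nn_relu())
  m$type <- "seq"; m$label <- "reservation"
  m
}

# depthwise 3x3 then pointwise 1x1: a parameter-sparse feature extractor.
nn_retracting <- function(c_in, c_out) {
  m <- nn_seq(nn_dw(c_in), nn_pw(c_in, c_out))
  m$label <- "retracting"
  m
}

# residual unit: two retracting blocks with normalization, skip-added to
# the input before the final activation.
nn_residual <- function(c) {
  body <- nn_seq(nn_dw(c), nn_pw(c, c), nn_ln(c), nn_relu(),
                 nn_dw(c), nn_pw(c, c), nn_ln(c))
  list(type = "residual", c = c, mods = list(body = body))
}

# attention condenser: spatially condensed, channel-reduced embedding of
# the activation pattern, expanded back and squashed to a per-pixel,
# per-channel gate in (0,1) that multiplies the input.
nn_condenser <- function(c, ratio = 4L) {
  cr <- max(1L, c %/% ratio)
  list(type = "condenser", c = c, cr = cr, ratio = ratio,
       mods = list(reduce = nn_pw(c, cr),
                   embed_dw = nn_dw(cr),
                   embed_pw = nn_pw(cr, cr),
                   expand = nn_pw(cr, c)))
}

# ---- primitive array ops (hot kernels live in src/omsas_ops.cpp) ------

pool2_fwd <- function(x) {
  d <- dim(x)
  .pool2_fwd_cpp(x, d[1], d[2], d[3])
}

pool2_bwd <- function(cache, dy) {
  .pool2_bwd_cpp(dy, cache$idx, cache$in_dim)
}

up2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

up2_bwd <- function(dy) {
  d <- dim(dy)
  ri <- seq(1L, d[1], 2L); ci <- seq(1L, d[2], 2L)
  dy[ri, ci, , drop = FALSE] + dy[ri + 1L, ci, , drop = FALSE] +
    dy[ri, ci + 1L, , drop = FALSE] + dy[ri + 1L, ci + 1L, , drop = FALSE]
}

# ---- module forward/backward ------------------------------------------

nn_forward <- function(mod, x) {
  switch(mod$type,
    pw = {
      d <- dim(x); hw <- d[1] * d[2]
      X2 <- matrix(x, hw, d[3])
      Y2 <- X2 %*% mod$params$W + rep(mod$params$b, each = hw)
      list(y = array(Y2, c(d[1], d[2], mod$c_out)), cache = list(X2 = X2, d = d))
    },
    dw = {
      d <- dim(x)
      y <- .dw_fwd_cpp(x, mod$params$K, mod$params$b, d[1], d[2], d[3])
      list(y = y, cache = list(x = x, d = d))
    },
    ln = {
      d <- dim(x); hw <- d[1] * d[2]; cc <- d[3]
      st <- .ln_fwd_cpp(x, mod$params$g, mod$params$b, hw, cc, LN_EPS)
      list(y = array(st$y, d),
           cache = list(xhat = st$xhat, inv = st$inv, d = d))
    },
    relu = list(y = pmax(x, 0), cache = list(mask = x > 0)),
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(y = y, cache = list(y = y))
    },
    seq = {
      caches <- vector("list", length(mod$mods))
      for (i in seq_along(mod$mods)) {
        st <- nn_forward(mod$mods[[i]], x)
        x <- st$y; caches[[i]] <- st$cache
      }
      list(y = x, cache = caches)
    },
    residual = {
      st <- nn_forward(mod$mods$body, x)
      s <- st$y + x
      list(y = pmax(s, 0), cache = list(body = st$cache, mask = s > 0))
    },
    condenser = {
      pl <- pool2_fwd(x)
      s1 <- nn_forward(mod$mods$reduce, pl$y)
      r1 <- pmax(s1$y, 0)
      s2 <- nn_forward(mod$mods$embed_dw, r1)
      s3 <- nn_forward(mod$mods$embed_pw, s2$y)
      r2 <- pmax(s3$y, 0)
      s4 <- nn_forward(mod$mods$expand, r2)
      u <- up2_fwd(s4$y)
      G <- 1 / (1 + exp(-u))
      list(y = x * G,
           cache = list(pool = pl, c1 = s1$cache, m1 = s1$y > 0,
                        c2 = s2$cache, c3 = s3$cache, m2 = s3$y > 0,
                        c4 = s4$cache, G = G, x = x))
    },
    stop("unknown module type: ", mod$type)
  )
}

nn_backward <- function(mod, cache, dy) {
  switch(mod$type,
    pw = {
      d <- cache$d; hw <- d[1] * d[2]
      dY2 <- matrix(dy, hw, mod$c_out)
      dW <- crossprod(cache$X2, dY2)
      db <- .colSums(dY2, hw, mod$c_out)
      dX2 <- tcrossprod(dY2, mod$params$W)
      list(dx = array(dX2, c(d[1], d[2], mod$c_in)),
           grads = list(params = list(W = dW, b = db)))
    },
    dw = {
      d <- cache$d
      st <- .dw_bwd_cpp(cache$x, mod$params$K, dy, d[1], d[2], d[3])
      list(dx = st$dx, grads = list(params = list(K = st$dK, b = st$db)))
    },
    ln = {
      d <- cache$d; hw <- d[1] * d[2]; cc <- d[3]
      st <- .ln_bwd_cpp(dy, cache$xhat, cache$inv, mod$params$g, hw, cc)
      list(dx = array(st$dx, d),
           grads = list(params = list(g = st$dg, b = st$db)))
    },
    relu = list(dx = dy * cache$mask, grads = NULL),
    sigmoid = list(dx = dy * cache$y * (1 - cache$y), grads = NULL),
    seq = {
      n <- length(mod$mods)
      gr <- vector("list", n); names(gr) <- names(mod$mods)
      for (i in rev(seq_len(n))) {
        st <- nn_backward(mod$mods[[i]], cache[[i]], dy)
        dy <- st$dx; gr[[i]] <- st$grads
      }
      list(dx = dy, grads = list(mods = gr))
    },
    residual = {
      dpre <- dy * cache$mask
      st <- nn_backward(mod$mods$body, cache$body, dpre)
      list(dx = st$dx + dpre, grads = list(mods = list(body = st$grads)))
    },
    condenser = {
      G <- cache$G
      dG <- dy * cache$x
      dx_direct <- dy * G
      du <- dG * G * (1 - G)
      da4 <- up2_bwd(du)
      s4 <- nn_backward(mod$mods$expand, cache$c4, da4)
      dr2 <- s4$dx * cache$m2
      s3 <- nn_backward(mod$mods$embed_pw, cache$c3, dr2)
      s2 <- nn_backward(mod$mods$embed_dw, cache$c2, s3$dx)
      dr1 <- s2$dx * cache$m1
      s1 <- nn_backward(mod$mods$reduce, cache$c1, dr1)
      dx_pool <- pool2_bwd(cache$pool, s1$dx)
      list(dx = dx_direct + dx_pool,
           grads = list(mods = list(reduce = s1$grads, embed_dw = s2$grads,
                                    embed_pw = s3$grads, expand = s4$grads)))
    },
    stop("unknown module type: ", mod$type)
  )
}

# ---- parameter tree walkers -------------------------------------------

flatten_params <- function(mod, prefix = "") {
  out <- list()
  if (!is.null(mod$params))
    for (nm in names(mod$params))
      out[[paste0(prefix, nm)]] <- mod$params[[nm]]
  if (!is.null(mod$mods))
    for (nm in names(mod$mods))
      out <- c(out, flatten_params(mod$mods[[nm]], paste0(prefix, nm, "/")))
  out
}

flatten_grads <- function(gr, prefix = "") {
  out <- list()
  if (is.null(gr)) return(out)
  if (!is.null(gr$params))
    for (nm in names(gr$params))
      out[[paste0(prefix, nm)]] <- gr$params[[nm]]
  if (!is.null(gr$mods))
    for (nm in names(gr$mods))
      out <- c(out, flatten_grads(gr$mods[[nm]], paste0(prefix, nm, "/")))
  out
}

assign_params <- function(mod, flat, prefix = "") {
  if (!is.null(mod$params))
    for (nm in names(mod$params)) {
      key <- paste0(prefix, nm)
      if (!is.null(flat[[key]])) {
        v <- mod$params[[nm]]
        v[] <- flat[[key]]
        mod$params[[nm]] <- v
      }
    }
  if (!is.null(mod$mods))
    for (nm in names(mod$mods))
      mod$mods[[nm]] <- assign_params(mod$mods[[nm]], flat,
                                      paste0(prefix, nm, "/"))
  mod
}
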