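test_that("channel_squeeze is the spatial mean per channel", {
  M <- array(0, c(2, 2, 3))
  M[, , 1] <- 5
  M[, , 2] <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]]
  M[, , 3] <- -1
  expect_equal(channel_squeeze(M), c(5, 2.5, -1))
  one <- array(c(7, 9), c(1, 1, 2))
  expect_equal(channel_squeeze(one), c(7, 9))
})

test_that("channel_excite applies relu then sigmoid through the bottleneck", {
  # 1-channel hand example: sigmoid(relu(2 * 3) * 1) = sigmoid(6)
  e <- channel_excite(3, W_sigma = matrix(2), W_rho = matrix(1))
  expect_equal(e, 1 / (1 + exp(-6)))
  # all-zero weights: sigmoid(0) = 0.5 on every channel
  e0 <- channel_excite(rnorm(4), matrix(0, 2, 4), matrix(0, 4, 2))
  expect_equal(e0, rep(0.5, 4))
  # gates are strictly inside (0,1)
  set.seed(18)
  e1 <- channel_excite(rnorm(6), matrix(rnorm(18), 3, 6),
                       matrix(rnorm(18), 6, 3))
  expect_true(all(e1 > 0 & e1 < 1))
  expect_error(channel_excite(rnorm(5), matrix(0, 2, 4), matrix(0, 4, 2)),
               "columns")
})

test_that("apply_attention scales channels and never amplifies", {
  set.seed(20)
  M <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  expect_equal(apply_attention(M, rep(1, 5)), M)
  expect_equal(apply_attention(M, rep(0, 5)), M * 0)
  e <- c(0.5, 0.2, 0.9, 0.1, 0.7)
  out <- apply_attention(M, e)
  expect_equal(out[, , 1], 0.5 * M[, , 1])
  expect_true(all(abs(out) <= abs(M) + 1e-15))
})

test_that("attention condenser preserves shape and only attenuates", {
  set.seed(22)
  for (cc in c(3L, 8L)) {
    M <- array(rnorm(8 * 8 * cc), c(8, 8, cc))
    out <- attention_condenser(M, ratio = 4L, seed = 1L)
    expect_equal(dim(out), dim(M))
    expect_true(all(abs(out) <= abs(M) + 1e-12))  # gates in (0,1)
  }
})

test_that("condenser parameter count shrinks monotonically as ratio doubles", {
  counts <- vapply(c(1L, 2L, 4L, 8L, 16L), function(r) {
    sum(vapply(omsas:::flatten_params(omsas:::nn_condenser(64L, r)),
               length, integer(1)))
  }, integer(1))
  expect_true(all(diff(counts) < 0))
})

test_that("reservation and retracting blocks meet their shape and count contracts", {
  set.seed(24)
  x <- array(rnorm(32 * 32 * 8), c(32, 32, 8))
  y <- reservation_block(x, 16L)
  expect_equal(dim(y), c(32, 32, 16))
  expect_gte(min(y), 0)  # post-ReLU
  # parameter audit: conv W + conv b + layernorm scale + offset
  res <- omsas:::nn_reservation(8L, 16L)
  expect_equal(sum(lengths(omsas:::flatten_params(res))),
               8 * 16 + 16 + 2 * 16)

  x16 <- array(rnorm(32 * 32 * 16), c(32, 32, 16))
  y2 <- retracting_block(x16, 32L)
  expect_equal(dim(y2), c(32, 32, 32))
  # depthwise 9 weights/channel + bias, pointwise 16x32 + bias
  ret <- omsas:::nn_retracting(16L, 32L)
  expect_equal(sum(lengths(omsas:::flatten_params(ret))),
               (9 * 16 + 16) + (16 * 32 + 32))
  # vs a full 3x3 convolution: 9 * 16 * 32 = 4608 weights
  expect_lt(9 * 16 + 16 * 32, 9 * 16 * 32)
})

test_that("residual unit preserves shape and passes gradient to its input", {
  set.seed(26)
  x <- array(rnorm(16 * 16 * 6), c(16, 16, 6))
  y <- residual_unit(x, seed = 2)
  expect_equal(dim(y), dim(x))
  # gradient probe through the skip path
  mod <- omsas:::nn_residual(6L)
  fw <- omsas:::nn_forward(mod, x)
  bw <- omsas:::nn_backward(mod, fw$cache, array(1, dim(x)))
  expect_gt(sum(abs(bw$dx)), 0)
  expect_true(all(is.finite(bw$dx)))
})

test_that("built networks map (h,w) inputs to probabilities of the same shape", {
  model <- micro_model()
  set.seed(28)
  x <- matrix(runif(256), 16, 16)
  out <- acrnet_forward(model, x)
  expect_equal(dim(out$prob), c(16L, 16L))
  expect_true(all(out$prob > 0 & out$prob < 1))
  # deterministic forward
  expect_identical(out$prob, acrnet_forward(model, x)$prob)
  expect_error(acrnet_forward(model, matrix(0, 8, 8)), "expects")
  expect_error(acrnet_config(stage_widths = 8L), "at least 2 stages")
})

test_that("parameter count equals the closed-form per-block audit", {
  widths <- c(8L, 16L, 32L); units <- 1L; ratio <- 4L
  model <- build_acrnet(acrnet_config(input_size = c(64L, 64L),
                                      stage_widths = widths,
                                      units_per_stage = units,
                                      condenser_ratio = ratio, seed = 1))
  reservation_n <- function(ci, co) ci * co + co + 2 * co
  residual_n <- function(c) 2 * ((9 * c + c) + (c * c + c)) + 2 * (2 * c)
  condenser_n <- function(c, r) {
    cr <- max(1, c %/% r)
    (c * cr + cr) + (9 * cr + cr) + (cr * cr + cr) + (cr * c + c)
  }
  S <- length(widths)
  expected <- reservation_n(1, widths[1])                      # stem
  for (s in seq_len(S)) {
    expected <- expected + units * residual_n(widths[s]) +
      condenser_n(widths[s], ratio)
    if (s < S) expected <- expected + reservation_n(widths[s], widths[s + 1])
  }
  for (s in seq_len(S - 1)) {
    expected <- expected + reservation_n(widths[s + 1] + widths[s], widths[s]) +
      units * residual_n(widths[s])
  }
  expected <- expected + widths[1] * 1 + 1                     # head
  expect_equal(count_parameters(model), expected)
})

test_that("the default configuration stays within the parameter budget", {
  model <- build_acrnet(acrnet_config())
  n_m <- count_parameters(model) / 1e6
  expect_lte(n_m, 6.91)
})

test_that("model backward matches finite differences end to end", {
  model <- micro_model(seed = 11)
  set.seed(32)
  x <- matrix(runif(256), 16, 16)
  truth <- matrix(0L, 16, 16); truth[5:11, 6:12] <- 1L
  fw <- acrnet_forward(model, x, keep_cache = TRUE)
  gr <- omsas:::acrnet_backward(model, fw$cache,
                                omsas:::tversky_loss_grad(fw$prob, truth))
  flat <- omsas:::flatten_params(model)
  loss_of <- function(fl) {
    m2 <- omsas:::assign_params(model, fl)
    tversky_loss(acrnet_forward(m2, x)$prob, truth)
  }
  set.seed(33)
  for (k in 1:6) {
    nm <- sample(names(flat), 1)
    i <- sample(length(flat[[nm]]), 1)
    eps <- 1e-5
    fp <- flat; fp[[nm]][i] <- fp[[nm]][i] + eps
    fm <- flat; fm[[nm]][i] <- fm[[nm]][i] - eps
    num <- (loss_of(fp) - loss_of(fm)) / (2 * eps)
    expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
  }
})
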