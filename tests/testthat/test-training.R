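test_that("tversky index reproduces the worked 4-pixel example", {
  # R = [1,1,0,0], Q = [1,0,1,0]: TP=1, FP=1, FN=1
  # T = 1 / (1 + 0.25*1 + 0.75*1 + eps) = 0.5
  r <- c(1, 1, 0, 0); q <- c(1, 0, 1, 0)
  expect_equal(tversky_index(r, q, tversky_params(0.25, 0.75)), 0.5,
               tolerance = 1e-7)
  expect_equal(tversky_index(q, q), 1, tolerance = 1e-6)
  expect_equal(tversky_index(rep(1, 10), rep(0, 10)), 0)
  expect_equal(tversky_loss(rep(1, 4), rep(0, 4)), 1)
  expect_error(tversky_index(1:3 / 3, 1:4 %% 2), "differ")
})

test_that("tversky at alpha=beta=0.5 equals Dice on random binary pairs", {
  set.seed(12)
  half <- tversky_params(0.5, 0.5, 1e-12)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    r <- as.numeric(runif(n) < 0.5)
    q <- as.numeric(runif(n) < 0.5)
    tp <- sum(r * q); fp <- sum(r * (1 - q)); fn <- sum(q * (1 - r))
    dice <- if (2 * tp + fp + fn == 0) NA else 2 * tp / (2 * tp + fp + fn)
    t <- tversky_index(r, q, half)
    if (is.na(dice)) expect_lt(t, 1e-6)  # eps only
    else expect_equal(t, dice, tolerance = 1e-9)
  }
})

test_that("tversky index is in [0,1] and degrades with each FP or FN pixel", {
  set.seed(14)
  p <- tversky_params()
  for (i in 1:50) {
    n <- 30
    r <- as.numeric(runif(n) < 0.5); q <- as.numeric(runif(n) < 0.5)
    t0 <- tversky_index(r, q, p)
    expect_gte(t0, 0); expect_lte(t0, 1)
    # append one FP pixel (pred 1, truth 0) and one FN pixel
    t_fp <- tversky_index(c(r, 1), c(q, 0), p)
    t_fn <- tversky_index(c(r, 0), c(q, 1), p)
    expect_lte(t_fp, t0 + 1e-12)
    expect_lte(t_fn, t0 + 1e-12)
  }
})

test_that("tversky loss gradient matches finite differences", {
  set.seed(16)
  r <- runif(25); q <- as.numeric(runif(25) < 0.4)
  g <- tversky_loss_grad(r, q)
  eps <- 1e-6
  for (i in sample(25, 6)) {
    rp <- r; rp[i] <- rp[i] + eps
    rm <- r; rm[i] <- rm[i] - eps
    num <- (tversky_loss(rp, q) - tversky_loss(rm, q)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("patient splits are disjoint, exhaustive, and 210 -> 147/63", {
  ids210 <- sprintf("P%03d", 1:210)
  for (seed in c(1, 7, 99)) {
    sp <- split_patients(ids210, 0.7, seed)
    expect_length(sp$train, 147L)
    expect_length(sp$test, 63L)
    expect_setequal(c(sp$train, sp$test), ids210)
    expect_length(intersect(sp$train, sp$test), 0L)
  }
  sp10 <- split_patients(sprintf("q%d", 1:10), 0.7, 3)
  expect_length(sp10$train, 7L)
  expect_length(sp10$test, 3L)
  expect_error(split_patients("only-one"), "at least 2")
})

test_that("k folds are balanced, seeded, and cover every id", {
  ids <- sprintf("P%03d", 1:147)
  f <- kfold_patients(ids, 10, seed = 2)
  expect_length(f, 10L)
  sizes <- lengths(f)
  expect_true(all(sizes %in% c(14L, 15L)))
  expect_setequal(unlist(f), ids)
  expect_identical(f, kfold_patients(ids, 10, seed = 2))
  # leave-one-out at k = n
  loo <- kfold_patients(sprintf("x%d", 1:5), 5, seed = 1)
  expect_true(all(lengths(loo) == 1L))
  expect_error(kfold_patients(sprintf("x%d", 1:5), 6), "fewer patients")
})

test_that("training on a few easy phantoms drives the loss down, deterministically", {
  train_set <- make_probe_set(8, seed = 77, size = 32)
  model <- build_acrnet(acrnet_config(input_size = c(32L, 32L),
                                      stage_widths = c(12L, 24L),
                                      units_per_stage = 1L, seed = 5))
  # 8 samples x 25 epochs at batch size 1 = 200 gradient steps; the hot
  # learning rate is what lets so few steps overfit this tiny set
  cfg <- train_config(learning_rate = 1e-2, epochs = 25, batch_size = 1,
                      seed = 5)
  fit <- train_acrnet(model, train_set, list(), cfg)
  expect_lt(utils::tail(fit$log$loss, 1), 0.1)
  expect_equal(nrow(fit$log), 25L)
  expect_true(all(is.finite(fit$log$loss)))

  # epoch-0 determinism: identical seeds give identical first-epoch loss
  m2 <- build_acrnet(acrnet_config(input_size = c(32L, 32L),
                                   stage_widths = c(12L, 24L),
                                   units_per_stage = 1L, seed = 5))
  cfg1 <- train_config(learning_rate = 1e-2, epochs = 1, batch_size = 4,
                       seed = 5)
  f1 <- train_acrnet(m2, train_set, list(), cfg1)
  m3 <- build_acrnet(acrnet_config(input_size = c(32L, 32L),
                                   stage_widths = c(12L, 24L),
                                   units_per_stage = 1L, seed = 5))
  f2 <- train_acrnet(m3, train_set, list(), cfg1)
  expect_identical(f1$log$loss, f2$log$loss)
})

test_that("checkpoints round-trip through save/load with identical predictions", {
  model <- micro_model(seed = 8)
  set.seed(30)
  x <- grayscale_slice(matrix(runif(256), 16, 16))
  p1 <- acrnet_forward(model, x)$prob
  path <- withr::local_tempfile(fileext = ".rds")
  acrnet_save(model, path)
  reloaded <- acrnet_load(path)
  expect_identical(acrnet_forward(reloaded, x)$prob, p1)
  expect_equal(count_parameters(reloaded), count_parameters(model))
})
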