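test_that("predict_single thresholds probabilities with ties to tumor", {
  model <- micro_model()
  set.seed(34)
  x <- matrix(runif(256), 16, 16)
  prob <- acrnet_forward(model, x)$prob
  mask <- predict_single(model, x)
  expect_equal(unclass(mask), matrix(as.integer(prob >= 0.5), 16, 16),
               ignore_attr = TRUE)
  # extreme thresholds behave like constant maps
  expect_true(all(predict_single(model, x, threshold = 0) == 1L))
  expect_true(all(predict_single(model, x, threshold = 1.0001) == 0L))
})

test_that("compound_decision is an exact per-pixel majority with ties to tumor", {
  mk <- function(v) binary_mask(matrix(v, 1, 1))
  vote <- function(ones, n) {
    stack <- c(replicate(ones, mk(1), simplify = FALSE),
               replicate(n - ones, mk(0), simplify = FALSE))
    as.integer(compound_decision(stack)[1, 1])
  }
  expect_equal(vote(8, 8), 1L)  # unanimous tumor
  expect_equal(vote(0, 8), 0L)  # unanimous background
  expect_equal(vote(5, 8), 1L)
  expect_equal(vote(3, 8), 0L)
  expect_equal(vote(4, 8), 1L)  # exact tie goes to tumor
  expect_error(compound_decision(list()), "empty")
})

test_that("compound_decision matches a brute-force majority oracle on random stacks", {
  set.seed(36)
  for (rep in 1:1000) {
    n <- sample(1:8, 1)
    stack <- replicate(n, random_mask(4, 4), simplify = FALSE)
    got <- compound_decision(stack)
    # oracle: per-pixel loop over copies
    expected <- matrix(0L, 4, 4)
    for (j in 1:4) for (k in 1:4) {
      s <- sum(vapply(stack, function(m) unclass(m)[j, k], integer(1)))
      expected[j, k] <- as.integer(s >= n / 2)
    }
    expect_equal(unclass(got), expected, ignore_attr = TRUE)
  }
})

test_that("the literal sign-convention vote inverts the majority off ties", {
  set.seed(38)
  stack <- replicate(5, random_mask(6, 6), simplify = FALSE)
  maj <- unclass(compound_decision(stack))
  lit <- unclass(compound_decision(stack, literal_eq6 = TRUE))
  sigma <- Reduce(`+`, lapply(stack, unclass))
  off_tie <- sigma != 5 / 2
  expect_true(all(lit[off_tie] == 1L - maj[off_tie]))
})

test_that("flipping every copy flips the decision except at exact ties", {
  set.seed(40)
  for (rep in 1:50) {
    n <- sample(c(3, 5, 7), 1)  # odd: no ties possible
    stack <- replicate(n, random_mask(3, 3), simplify = FALSE)
    flipped <- lapply(stack, function(m) binary_mask(1L - unclass(m)))
    expect_equal(unclass(compound_decision(flipped)),
                 1L - unclass(compound_decision(stack)), ignore_attr = TRUE)
  }
})

test_that("predict_compound is order-invariant and reduces to predict_single at n=1", {
  model <- micro_model()
  set.seed(42)
  x <- grayscale_slice(matrix(runif(256), 16, 16))
  full <- predict_compound(model, x)
  shuffled <- predict_compound(model, x, transforms = rev(d4_orbit()))
  expect_identical(unclass(full), unclass(shuffled))
  single <- predict_compound(model, x, transforms = list(d4_transform(0, FALSE)))
  expect_identical(unclass(single), unclass(predict_single(model, x)))
})

test_that("predict_compound is equivariant under every dihedral transform", {
  model <- micro_model(seed = 19)
  pp <- phantom_params(image_size = 16, seed = 55)
  ph <- generate_phantom(pp, 1)
  x <- as.matrix(normalize_slice(ph$image))
  base <- predict_compound(model, x)
  for (t in d4_orbit()) {
    lhs <- predict_compound(model, d4_apply(t, x))
    rhs <- d4_apply(t, unclass(base))
    expect_equal(unclass(lhs), rhs, ignore_attr = TRUE,
                 label = paste("equivariance under", format(t)))
  }
})

test_that("probability-mean fusion agrees with voting on confident maps", {
  model <- micro_model()
  set.seed(44)
  x <- matrix(runif(256), 16, 16)
  v <- predict_compound(model, x, mode = "vote")
  m <- predict_compound(model, x, mode = "mean")
  expect_true(mean(unclass(v) == unclass(m)) > 0.8)
})

test_that("attention overlays have RGB shape and track gate brightness", {
  model <- micro_model()
  set.seed(46)
  x <- grayscale_slice(matrix(runif(256), 16, 16))
  ov <- attention_overlay(model, x, stage_index = 1)
  expect_equal(dim(ov), c(16L, 16L, 3L))
  expect_true(all(ov >= 0 & ov <= 1.0001))
  expect_error(attention_overlay(model, x, stage_index = 9), "stage_index")

  # monotone brightness: with the heat layer alone (alpha = 1), overlay
  # luminance rank order follows the gate rank order (up to palette
  # quantization). Stage 2: its wider bottleneck keeps the gates varying.
  ov1 <- attention_overlay(model, x, stage_index = 2, alpha = 1)
  fw <- acrnet_forward(model, x, keep_gates = TRUE)
  gate <- resize_image(fw$gates[[2]], c(16L, 16L), "bilinear")
  expect_gt(stats::sd(gate), 0)
  lum <- 0.2126 * ov1[, , 1] + 0.7152 * ov1[, , 2] + 0.0722 * ov1[, , 3]
  expect_gt(stats::cor(as.vector(gate), as.vector(lum), method = "spearman"),
            0.9)
})
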