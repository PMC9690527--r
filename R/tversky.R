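#' Tversky loss parameters
#'
#' `alpha` weights false positives, `beta` false negatives; raising `beta`
#' pushes training toward high recall, the priority in tumor detection
#' where a miss is worse than a false alarm. Defaults alpha = 0.25,
#' beta = 0.75, epsilon = 1e-8.
#'
#' @param alpha FP penalty weight (>= 0).
#' @param beta FN penalty weight (>= 0).
#' @param epsilon stabilizer against 0/0 (> 0).
#' @return a `tversky_params` list.
#' @export
tversky_params <- function(alpha = 0.25, beta = 0.75, epsilon = 1e-8) {
  stopifnot(alpha >= 0, beta >= 0, epsilon > 0)
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon),
            class = "tversky_params")
}

#' Tversky index
#'
#' `T = sum(RQ) / (sum(RQ) + alpha * sum(R(1-Q)) + beta * sum(Q(1-R)) + eps)`
#' where `R` are predicted probabilities and `Q` binary truth. At
#' `alpha = beta = 0.5` this is exactly the Dice coefficient.
#'
#' @param pred probabilities in [0,1], any shape.
#' @param truth binary labels, same shape.
#' @param params a [tversky_params()].
#' @return scalar in [0,1].
#' @export
tversky_index <- function(pred, truth, params = tversky_params()) {
  if (length(pred) != length(truth))
    stop("pred and truth sizes differ: ", length(pred), " vs ", length(truth))
  r <- as.numeric(pred); q <- as.numeric(truth)
  tp <- sum(r * q)
  fp <- sum(r * (1 - q))
  fn <- sum(q * (1 - r))
  tp / (tp + params$alpha * fp + params$beta * fn + params$epsilon)
}

#' Tversky loss
#'
#' `1 - tversky_index`: 0 for a perfect prediction, 1 for a disjoint one;
#' differentiable in the predicted probabilities.
#'
#' @inheritParams tversky_index
#' @return scalar loss.
#' @export
tversky_loss <- function(pred, truth, params = tversky_params()) {
  1 - tversky_index(pred, truth, params)
}

# gradient of the loss w.r.t. each predicted probability.
# T = N/D with N = sum(rq), D = N + a*sum(r(1-q)) + b*sum(q(1-r)) + eps;
# dN/dr_i = q_i, dD/dr_i = q_i + a(1-q_i) - b q_i.
tversky_loss_grad <- function(pred, truth, params = tversky_params()) {
  r <- as.numeric(pred); q <- as.numeric(truth)
  N <- sum(r * q)
  D <- N + params$alpha * sum(r * (1 - q)) + params$beta * sum(q * (1 - r)) +
    params$epsilon
  dN <- q
  dD <- q + params$alpha * (1 - q) - params$beta * q
  dT <- (dN * D - N * dD) / D^2
  g <- -dT
  if (!is.null(dim(pred))) dim(g) <- dim(pred)
  g
}

#' Patient-level train/test split
#'
#' Shuffles patient ids with a seeded RNG and assigns the first
#' `round(train_fraction * n)` to training. Splitting at patient level
#' guarantees no patient contributes slices to both sides.
#'
#' @param patient_ids character vector of unique patient ids (>= 2).
#' @param train_fraction fraction of patients in training (default 0.7, the
#'   7:3 split).
#' @param seed RNG seed.
#' @return list `(train, test)` of id vectors; disjoint, exhaustive.
#' @export
split_patients <- function(patient_ids, train_fraction = 0.7, seed = 1L) {
  ids <- unique(as.character(patient_ids))
  if (length(ids) < 2L) stop("need at least 2 patients to split")
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  ids <- sample(ids)
  n_train <- round(train_fraction * length(ids))
  n_train <- min(max(n_train, 1L), length(ids) - 1L)
  list(train = ids[seq_len(n_train)], test = ids[-seq_len(n_train)])
}

#' Balanced k folds of patient ids
#'
#' @param patient_ids character vector (length >= k).
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return list of `k` disjoint id vectors whose sizes differ by at most 1.
#' @export
kfold_patients <- function(patient_ids, k = 10L, seed = 1L) {
  ids <- unique(as.character(patient_ids))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (length(ids) < k) stop("fewer patients (", length(ids), ") than folds (", k, ")")
  set.seed(seed)
  ids <- sample(ids)
  fold_of <- rep(seq_len(k), length.out = length(ids))
  split(ids, fold_of)
}
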