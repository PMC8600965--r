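#' Classifier settings for the likelihood-ratio model
#'
#' The Donsker-Varadhan representation of the KL divergence is optimised by
#' the pointwise log-likelihood ratio, which is estimated here by a small
#' multi-layer perceptron trained with binary cross-entropy to distinguish
#' joint samples (label 1) from permuted samples (label 0). Predicted
#' probabilities are clipped into `[prob_clip, 1 - prob_clip]` so the
#' plug-in KL estimate stays finite.
#'
#' Defaults favour a compact, strongly regularised network: at the sample
#' sizes typical for windowed neural recordings (a few thousand windows) a
#' large classifier overfits the permuted class, which inflates the
#' log-mean-ratio term of the KL plug-in and destabilises the estimate.
#'
#' @param hidden_layers integer vector of hidden-layer widths.
#' @param max_epochs maximum training epochs (full passes, mini-batched
#'   Adam); training usually stops earlier via the validation criterion.
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param l2 L2 weight penalty.
#' @param prob_clip clipping bound for predicted probabilities, in (0, 0.5).
#' @param val_fraction fraction of the training rows held out to monitor
#'   the loss for early stopping (0 disables; the weights from the
#'   best-validation epoch are kept).
#' @param patience epochs without validation improvement before stopping.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(hidden_layers = 16, max_epochs = 100,
                            batch_size = 512, learning_rate = 0.01,
                            l2 = 1e-4, prob_clip = 1e-3,
                            val_fraction = 0.2, patience = 10) {
  if (prob_clip <= 0 || prob_clip >= 0.5) stop("'prob_clip' must be in (0, 0.5)")
  if (any(hidden_layers < 1)) stop("'hidden_layers' must be positive widths")
  if (val_fraction < 0 || val_fraction >= 1) stop("'val_fraction' must be in [0, 1)")
  structure(
    list(hidden_layers = as.integer(hidden_layers),
         max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, l2 = l2, prob_clip = prob_clip,
         val_fraction = val_fraction, patience = as.integer(patience)),
    class = "classifier_spec"
  )
}

#' Estimator configuration for bootstrap-averaged information estimates
#'
#' @param bootstrap_iters number of bootstrap iterations `B`; each iteration
#'   draws a fresh 2/3 train / 1/3 test split and a fresh permutation of the
#'   source block, fits the ratio classifier, and evaluates the KL plug-in
#'   on the held-out third. The reported value is the mean across iterations.
#' @param train_fraction proportion of rows used for training.
#' @param classifier a [classifier_spec].
#' @param seed integer master seed; per-iteration seeds are derived from it.
#' @return An object of class `estimator_config`. All information values are
#'   in nats (natural logarithm).
#' @export
estimator_config <- function(bootstrap_iters = 10, train_fraction = 2 / 3,
                             classifier = classifier_spec(), seed = 1L) {
  if (bootstrap_iters < 1) stop("'bootstrap_iters' must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("'train_fraction' must be in (0, 1)")
  }
  stopifnot(inherits(classifier, "classifier_spec"))
  structure(
    list(bootstrap_iters = as.integer(bootstrap_iters),
         train_fraction = train_fraction,
         classifier = classifier, seed = as.integer(seed)),
    class = "estimator_config"
  )
}

#' Fit the likelihood-ratio classifier
#'
#' Trains the binary classifier distinguishing samples of the dependent
#' distribution (label 1) from samples of the independence surrogate
#' (label 0). Features are standardised with the training-set moments; the
#' returned model exposes the pointwise likelihood ratio
#' `L(x) = P(label = 1 | x) / (1 - P(label = 1 | x))` through
#' [predict_ratio()].
#'
#' @param train_p matrix of training samples from the joint distribution.
#' @param train_q matrix of training samples from the permuted surrogate.
#' @param spec a [classifier_spec].
#' @param seed integer seed; training is fully reproducible.
#' @return An object of class `ratio_model`.
#' @export
fit_ratio_model <- function(train_p, train_q, spec = classifier_spec(),
                            seed = 1L) {
  train_p <- as.matrix(train_p)
  train_q <- as.matrix(train_q)
  if (nrow(train_p) == 0 || nrow(train_q) == 0) stop("empty training set")
  if (ncol(train_p) != ncol(train_q)) stop("dimensionality mismatch between sample sets")
  X <- rbind(train_p, train_q)
  y <- c(rep(1, nrow(train_p)), rep(0, nrow(train_q)))
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  fit <- cpp_mlp_train(Xs, y, spec$hidden_layers, spec$max_epochs,
                       spec$batch_size, spec$learning_rate, spec$l2,
                       as.integer(seed), spec$val_fraction, spec$patience)
  structure(
    list(fit = fit, center = center, scale = scale,
         prob_clip = spec$prob_clip, d = ncol(X)),
    class = "ratio_model"
  )
}

#' Pointwise likelihood ratio of a fitted classifier
#'
#' @param model a `ratio_model` from [fit_ratio_model()].
#' @param x matrix of points to evaluate.
#' @return Vector of likelihood-ratio values `L(x)`, finite by the
#'   probability-clipping contract.
#' @export
predict_ratio <- function(model, x) {
  stopifnot(inherits(model, "ratio_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$d) stop("dimensionality mismatch")
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  p <- as.numeric(cpp_mlp_predict(model$fit, xs))
  p <- pmin(pmax(p, model$prob_clip), 1 - model$prob_clip)
  p / (1 - p)
}

#' Donsker-Varadhan plug-in estimate of the KL divergence
#'
#' Evaluates `mean(log L(x_p)) - log(mean(L(x_q)))` over held-out samples,
#' the plug-in form of the Donsker-Varadhan representation with the
#' classifier's likelihood ratio substituted for the optimal function.
#'
#' @param test_p held-out samples from the joint distribution.
#' @param test_q held-out samples from the permuted surrogate.
#' @param model a `ratio_model`.
#' @return KL divergence estimate in nats.
#' @export
estimate_kl <- function(test_p, test_q, model) {
  test_p <- as.matrix(test_p)
  test_q <- as.matrix(test_q)
  if (nrow(test_p) == 0 || nrow(test_q) == 0) stop("empty test set")
  Lp <- predict_ratio(model, test_p)
  Lq <- predict_ratio(model, test_q)
  mean(log(Lp)) - log(mean(Lq))
}

# One bootstrap iteration on a joint matrix: fresh permutation of the
# A-block, fresh train/test split, fit, plug-in KL on the held-out rows.
kl_iteration <- function(joint, block_index, cfg, it_seed) {
  n <- nrow(joint)
  shuffled <- permute_block(joint, block_index, it_seed)
  n_train <- max(1L, floor(cfg$train_fraction * n))
  tr <- withr::with_seed(derive_seed(it_seed, 1L), sample.int(n, n_train))
  model <- fit_ratio_model(joint[tr, , drop = FALSE],
                           shuffled[tr, , drop = FALSE],
                           cfg$classifier, derive_seed(it_seed, 2L))
  list(value = estimate_kl(joint[-tr, , drop = FALSE],
                           shuffled[-tr, , drop = FALSE], model),
       n_test = n - n_train)
}

#' Bootstrap-averaged mutual information between two sample blocks
#'
#' Estimates `I(A; B)` from paired samples via the classifier-based KL
#' plug-in: each bootstrap iteration re-permutes the A-block, splits rows
#' into training and test sets, fits the ratio classifier and evaluates the
#' Donsker-Varadhan estimate on the test rows; the iteration values are
#' averaged. Negative values are reported as-is at this layer (flooring is a
#' graph-level policy), preserving estimator diagnostics.
#'
#' @param pair a `sample_pair` list (e.g. one element of
#'   [build_mi_problems()]), with fields `joint` and `block_index`.
#' @param cfg an [estimator_config].
#' @return An object of class `mi_estimate`: list with `value` (nats, the
#'   mean), `per_iteration` (length-B trace) and `n_samples_test`.
#' @export
estimate_mi <- function(pair, cfg = estimator_config()) {
  joint <- as.matrix(pair$joint)
  if (nrow(joint) < 3) stop("need at least 3 samples")
  B <- cfg$bootstrap_iters
  vals <- numeric(B)
  n_test <- 0L
  for (b in seq_len(B)) {
    it <- kl_iteration(joint, pair$block_index, cfg, derive_seed(cfg$seed, b))
    vals[b] <- it$value
    n_test <- it$n_test
  }
  structure(
    list(value = mean(vals), per_iteration = vals, n_samples_test = n_test),
    class = "mi_estimate"
  )
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("<mi_estimate> %.4f nats (B = %d, sd = %.4f)\n",
              x$value, length(x$per_iteration), stats::sd(x$per_iteration)))
  invisible(x)
}

#' Bootstrap-averaged conditional mutual information
#'
#' Estimates `I(A; B | Z) = I(A; B, Z) - I(A; Z)` as a difference of two
#' classifier-based MI estimates. Both terms share the bootstrap schedule:
#' at every iteration the same derived seed drives the permutation and the
#' train/test split of both problems, so correlated estimation bias largely
#' cancels in the difference.
#'
#' The block that gets permuted is chosen as the lower-dimensional of `A`
#' and `B` (by the symmetry of MI and the chain rule the value is
#' unchanged): permuting e.g. a one-dimensional current-value block keeps
#' both MI terms bounded by that variable's own information content, which
#' keeps the classifier problems in the low-divergence regime where the
#' plug-in is accurate even when the conditioning block is wide and
#' internally dependent.
#'
#' @param A,B,Z row-aligned sample matrices; `Z` may have zero columns, in
#'   which case the estimate reduces to `I(A; B)`.
#' @param cfg an [estimator_config].
#' @return An `mi_estimate`; `per_iteration` holds the per-iteration
#'   differences, so its mean is the reported value.
#' @export
estimate_cmi <- function(A, B, Z = NULL, cfg = estimator_config()) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (is.null(Z)) Z <- matrix(numeric(0), nrow(A), 0)
  Z <- as.matrix(Z)
  if (nrow(B) != nrow(A) || (ncol(Z) > 0 && nrow(Z) != nrow(A))) {
    stop("A, B, Z must be row-aligned")
  }
  if (nrow(A) < 3) stop("need at least 3 samples")
  if (ncol(B) < ncol(A)) {  # permute the smaller block (see above)
    tmp <- A
    A <- B
    B <- tmp
  }
  block <- seq_len(ncol(A))
  joint1 <- cbind(A, B, Z)
  has_z <- ncol(Z) > 0
  joint2 <- if (has_z) cbind(A, Z) else NULL
  B_iter <- cfg$bootstrap_iters
  vals <- numeric(B_iter)
  n_test <- 0L
  for (b in seq_len(B_iter)) {
    it_seed <- derive_seed(cfg$seed, b)
    it1 <- kl_iteration(joint1, block, cfg, it_seed)
    v2 <- 0
    if (has_z) v2 <- kl_iteration(joint2, block, cfg, it_seed)$value
    vals[b] <- it1$value - v2
    n_test <- it1$n_test
  }
  structure(
    list(value = mean(vals), per_iteration = vals, n_samples_test = n_test),
    class = "mi_estimate"
  )
}
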