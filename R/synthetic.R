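#' Ground-truth network specification
#'
#' Describes a generative network shared by the simulators and the analytic
#' oracles: a set of directed edges with signed coupling weights `beta` and
#' integer lags, plus a per-node noise weight `alpha` fixed by the
#' constraint `sum(|beta| incoming) + alpha = 1` (nodes without incoming
#' edges have `alpha = 1`).
#'
#' @param n_nodes number of nodes `R`.
#' @param edges data frame with columns `from`, `to`, `beta` (signed),
#'   and optionally `lag` (samples, default 1).
#' @param source_dist marginal of source/isolated nodes: `"gaussian"` or
#'   `"uniform"`.
#' @param interaction `"linear"` or `"squared"` coupling of past values.
#' @param noise_sd standard deviation of the additive Gaussian noise term of
#'   nodes with incoming edges (scalar or per-node vector).
#' @return An object of class `network_spec` with derived `alpha` vector.
#' @export
network_spec <- function(n_nodes, edges, source_dist = c("gaussian", "uniform"),
                         interaction = c("linear", "squared"), noise_sd = 1) {
  source_dist <- match.arg(source_dist)
  interaction <- match.arg(interaction)
  edges <- as.data.frame(edges)
  if (!all(c("from", "to", "beta") %in% names(edges))) {
    stop("'edges' needs columns from, to, beta")
  }
  if (is.null(edges$lag)) edges$lag <- 1L
  edges$lag <- as.integer(edges$lag)
  if (any(edges$lag < 1)) stop("edge lags must be >= 1")
  if (any(edges$from == edges$to)) stop("self-edges are not allowed")
  if (any(edges$from < 1 | edges$from > n_nodes |
          edges$to < 1 | edges$to > n_nodes)) stop("edge endpoints out of range")
  alpha <- rep(1, n_nodes)
  for (k in seq_len(n_nodes)) {
    bsum <- sum(abs(edges$beta[edges$to == k]))
    if (bsum > 0) {
      alpha[k] <- 1 - bsum
      if (alpha[k] <= 0) stop(sprintf("node %d: sum(|beta|) >= 1 violates the weight constraint", k))
    }
  }
  noise_sd <- rep_len(noise_sd, n_nodes)
  structure(
    list(n_nodes = as.integer(n_nodes), edges = edges, alpha = alpha,
         source_dist = source_dist, interaction = interaction,
         noise_sd = noise_sd),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d nodes, %d edges (%s, %s sources)\n",
              x$n_nodes, nrow(x$edges), x$interaction, x$source_dist))
  invisible(x)
}

#' Default 11-node benchmark topology
#'
#' The shipped ground truth used throughout the package's benchmarks:
#' an extended path 6 -> 1 -> 4 -> 11, a sink \{6, 8, 9\} -> 2, a multipath
#' 6 -> \{3, 5\} -> 10, and isolated node 7. Path and multipath couplings
#' have `|beta| = 0.45`, sink couplings `|beta| = 0.25`; edges 6 -> 1 and
#' 5 -> 10 are inhibitory (negative beta), the rest excitatory. All lags
#' are 1 sample.
#'
#' @param interaction `"linear"` (Gaussian sources, unit noise) or
#'   `"squared"` (uniform sources, noise sd 0.5).
#' @return A [network_spec] with 10 true directed edges.
#' @export
default_network_spec <- function(interaction = c("linear", "squared")) {
  interaction <- match.arg(interaction)
  edges <- data.frame(
    from = c(6, 6, 6, 1, 4, 3, 5, 6, 8, 9),
    to   = c(1, 3, 5, 4, 11, 10, 10, 2, 2, 2),
    beta = c(-0.45, 0.45, 0.45, 0.45, 0.45, 0.45, -0.45, 0.25, 0.25, 0.25),
    lag  = 1L
  )
  if (interaction == "linear") {
    network_spec(11, edges, source_dist = "gaussian", interaction = "linear",
                 noise_sd = 1)
  } else {
    network_spec(11, edges, source_dist = "uniform", interaction = "squared",
                 noise_sd = 0.5)
  }
}

#' Bivariate Gaussian benchmark pair
#'
#' Generates two channels where `(X_{i-1}, Y_i)` is jointly Gaussian with
#' zero mean, unit variances and correlation `rho`, independent across
#' non-overlapping windows of length 2. The directed information of this
#' model is `-0.5 * log(1 - rho^2)` nats. Optional independent standard
#' Gaussian nuisance channels can be appended for conditioning-scaling
#' studies.
#'
#' @param rho correlation, `|rho| < 1`.
#' @param N number of windows (samples of the joint distribution); the
#'   returned series has `2 * N` time samples.
#' @param seed integer seed.
#' @param d_nuisance number of independent nuisance channels to append.
#' @return A continuous [ts_set] with channels `X`, `Y` (and `Z1`, ...).
#' @export
gen_gaussian_pair <- function(rho, N, seed = 1L, d_nuisance = 0) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  T_len <- 2L * as.integer(N)
  withr::with_seed(as.integer(seed), {
    x <- stats::rnorm(T_len)
    y <- stats::rnorm(T_len)
    y[2:T_len] <- rho * x[1:(T_len - 1)] + sqrt(1 - rho^2) * y[2:T_len]
    vals <- cbind(X = x, Y = y)
    if (d_nuisance > 0) {
      Zm <- matrix(stats::rnorm(T_len * d_nuisance), T_len, d_nuisance)
      colnames(Zm) <- paste0("Z", seq_len(d_nuisance))
      vals <- cbind(vals, Zm)
    }
    ts_set(vals, dt = 1, kind = "continuous")
  })
}

#' Binary symmetric channel benchmark pair
#'
#' `X` is i.i.d. Bernoulli(`bern_p`) and `Y_i` equals `X_{i-1}` flipped
#' with probability `p_flip`. Optional independent Bernoulli(0.5) nuisance
#' channels can be appended.
#'
#' @param p_flip bit-flip probability in `[0, 0.5]`.
#' @param bern_p source Bernoulli rate.
#' @param N number of windows; the series has `2 * N` time samples.
#' @param seed integer seed.
#' @param d_nuisance number of independent binary nuisance channels.
#' @return A binary [ts_set] with channels `X`, `Y` (and `Z1`, ...).
#' @export
gen_bsc <- function(p_flip, bern_p = 0.3, N = 2500, seed = 1L, d_nuisance = 0) {
  if (p_flip < 0 || p_flip > 0.5) stop("'p_flip' must be in [0, 0.5]")
  T_len <- 2L * as.integer(N)
  withr::with_seed(as.integer(seed), {
    x <- stats::rbinom(T_len, 1, bern_p)
    flip <- stats::rbinom(T_len, 1, p_flip)
    y <- stats::rbinom(T_len, 1, bern_p)  # first sample has no parent
    y[2:T_len] <- xor(x[1:(T_len - 1)], flip[2:T_len]) * 1L
    vals <- cbind(X = x, Y = y)
    if (d_nuisance > 0) {
      Zm <- matrix(stats::rbinom(T_len * d_nuisance, 1, 0.5), T_len, d_nuisance)
      colnames(Zm) <- paste0("Z", seq_len(d_nuisance))
      vals <- cbind(vals, Zm)
    }
    ts_set(vals, dt = 1, kind = "binary")
  })
}

simulate_network <- function(spec, N, seed, burn_in = 100L) {
  R <- spec$n_nodes
  max_lag <- max(c(1L, spec$edges$lag))
  T_tot <- as.integer(N) + burn_in + max_lag
  has_parent <- seq_len(R) %in% spec$edges$to
  withr::with_seed(as.integer(seed), {
    x <- matrix(0, T_tot, R)
    for (k in seq_len(R)) {
      if (has_parent[k]) {
        x[, k] <- spec$alpha[k] * stats::rnorm(T_tot, sd = spec$noise_sd[k])
      } else if (spec$source_dist == "uniform") {
        x[, k] <- stats::runif(T_tot)
      } else {
        x[, k] <- stats::rnorm(T_tot)
      }
    }
    for (i in (max_lag + 1):T_tot) {
      for (e in seq_len(nrow(spec$edges))) {
        j <- spec$edges$from[e]
        k <- spec$edges$to[e]
        v <- x[i - spec$edges$lag[e], j]
        if (spec$interaction == "squared") v <- v^2
        x[i, k] <- x[i, k] + spec$edges$beta[e] * v
      }
    }
    out <- x[(burn_in + max_lag + 1):T_tot, , drop = FALSE]
    colnames(out) <- paste0("n", seq_len(R))
    ts_set(out, dt = 1, kind = "continuous")
  })
}

#' Simulate a linear-Gaussian autoregressive network
#'
#' Each node with incoming edges follows
#' `x_i^(k) = sum_j beta^(j,k) x_{i-lag}^(j) + alpha^(k) z_i^(k)` with
#' standard Gaussian noise `z`; source and isolated nodes are white
#' standard Gaussian. An initial burn-in segment is discarded.
#'
#' @param spec a linear [network_spec] (default [default_network_spec()]).
#' @param N number of retained time samples.
#' @param seed integer seed.
#' @return A continuous [ts_set] with `N` rows.
#' @export
gen_gaussian_network <- function(spec = default_network_spec("linear"),
                                 N = 1e4, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  if (spec$interaction != "linear" || spec$source_dist != "gaussian") {
    stop("spec must be linear with Gaussian sources")
  }
  simulate_network(spec, N, seed)
}

#' Simulate the nonlinear (squared-interaction) network
#'
#' Same topology and couplings as the linear network, but source and
#' isolated nodes are Uniform(0, 1) and targets couple to the *square* of
#' parent past values: `x_i^(k) = sum_j beta^(j,k) (x_{i-lag}^(j))^2 +
#' alpha^(k) z_i^(k)` with Gaussian noise of variance 0.25, which keeps the
#' noise comparable to the small squared inputs.
#'
#' @param spec a squared-interaction [network_spec].
#' @param N number of retained time samples.
#' @param seed integer seed.
#' @return A continuous [ts_set].
#' @export
gen_nonlinear_network <- function(spec = default_network_spec("squared"),
                                  N = 1e4, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  if (spec$interaction != "squared") stop("spec must have squared interaction")
  simulate_network(spec, N, seed)
}

#' Three-node sign-masking demonstration
#'
#' Generates the canonical masking scenario used to motivate partial (as
#' opposed to pairwise) sign inference: `W` excites `Y` and `X` inhibits
#' `Y`, both with a 0.125 s delay, while `X` is strongly correlated with
#' `W` so the inhibition is masked in any pairwise analysis. A periodic dip
#' in `X` (continuous case) or intermittent dropout of `X` (spiking case)
#' carries the only trace of the inhibition; without it the inhibitory sign
#' would be unidentifiable.
#'
#' The continuous variant uses 1 Hz sinusoids sampled at 400 Hz
#' (`Y(t) = W(t - 0.125) - X(t - 0.125)`, delay = 50 samples) with a narrow
#' negative Gaussian dip in `X` at each cycle peak. The spiking variant
#' uses 25 ms bins (delay = 5 bins): `W` and `X` fire in a shared burst
#' phase of each 1 s cycle, `X` drops out every third cycle, and `Y` spikes
#' through a logistic rate driven by `+W` and `-X` at the delay.
#'
#' @param kind `"continuous"` or `"spikes"`.
#' @param N number of time samples (bins for the spiking variant).
#' @param seed integer seed.
#' @param dip include the per-cycle dip in continuous `X` (default TRUE).
#' @param dropout include the intermittent dropout of spiking `X`
#'   (default TRUE). Disabling either reproduces the degenerate mode in
#'   which the inhibitory sign is unidentifiable.
#' @return A [ts_set] with channels `X`, `W`, `Y`; `dt` is 1/400 s
#'   (continuous) or 0.025 s (spikes). Attribute `delay_samples` records
#'   the ground-truth delay.
#' @export
gen_three_node_demo <- function(kind = c("continuous", "spikes"), N = 4000,
                                seed = 1L, dip = TRUE, dropout = TRUE) {
  kind <- match.arg(kind)
  N <- as.integer(N)
  if (kind == "continuous") {
    dt <- 1 / 400
    delay <- 50L  # 0.125 s
    tt <- (seq_len(N) - 1) * dt
    w <- sin(2 * pi * tt)
    dipsig <- rep(0, N)
    if (dip) {
      # narrow Gaussian dip at each peak of the sinusoid (t = 0.25 + n)
      phase <- (tt - 0.25) %% 1
      phase <- pmin(phase, 1 - phase)
      dipsig <- 0.4 * exp(-phase^2 / (2 * 0.02^2))
    }
    x <- 0.5 * sin(2 * pi * tt) - dipsig
    shift <- function(v, s) c(v[(N - s + 1):N], v[1:(N - s)])  # periodic, period 1 s
    y <- shift(w, delay) - shift(x, delay)
    out <- withr::with_seed(as.integer(seed), {
      eps <- matrix(stats::rnorm(3 * N, sd = 0.01), N, 3)
      cbind(X = x, W = w, Y = y) + eps
    })
    res <- ts_set(out, dt = dt, kind = "continuous")
  } else {
    dt <- 0.025
    delay <- 5L  # 0.125 s
    period <- 40L  # 1 s cycles
    cycle <- ((seq_len(N) - 1) %/% period) + 1L
    in_burst <- ((seq_len(N) - 1) %% period) < 8L
    res <- withr::with_seed(as.integer(seed), {
      w <- stats::rbinom(N, 1, ifelse(in_burst, 0.7, 0.02))
      x_active <- if (dropout) cycle %% 3L != 0L else rep(TRUE, N)
      x <- stats::rbinom(N, 1, ifelse(in_burst & x_active, 0.7, 0.02))
      lagged <- function(v, s) c(rep(0L, s), v[1:(N - s)])
      eta <- -2.5 + 4 * lagged(w, delay) - 2.5 * lagged(x, delay)
      y <- stats::rbinom(N, 1, stats::plogis(eta))
      ts_set(cbind(X = x, W = w, Y = y), dt = dt, kind = "binary")
    })
  }
  attr(res, "delay_samples") <- delay
  res
}

#' Probabilistic spiking-network surrogate
#'
#' Discrete-time logistic-Bernoulli spiking dynamics on a [network_spec]
#' topology: each unit's spike probability per bin is a logistic function
#' of a baseline plus signed weighted sums of presynaptic spikes `lag` bins
#' earlier. This is a lightweight statistical surrogate for conductance-
#' based simulations; only the binned binary statistics matter to the
#' estimator.
#'
#' @param spec a [network_spec]; `beta` values are scaled by
#'   `weight_scale` into logistic weights.
#' @param T_sec simulated duration in seconds.
#' @param bin_width bin width in seconds.
#' @param seed integer seed.
#' @param baseline logit of the spontaneous per-bin spike probability.
#' @param weight_scale multiplier from `beta` to logistic weight.
#' @return A data frame with columns `unit`, `time` (spike table, one spike
#'   at each active bin centre), with the generating `network_spec` in
#'   attribute `spec` and the binary bin matrix in attribute `bins`.
#' @export
gen_spiking_network <- function(spec = default_network_spec("linear"),
                                T_sec = 300, bin_width = 0.035, seed = 1L,
                                baseline = -1.4, weight_scale = 12) {
  stopifnot(inherits(spec, "network_spec"))
  n_bins <- floor(T_sec / bin_width)
  R <- spec$n_nodes
  max_lag <- max(spec$edges$lag)
  withr::with_seed(as.integer(seed), {
    s <- matrix(0L, n_bins, R)
    for (i in seq_len(n_bins)) {
      eta <- rep(baseline, R)
      for (e in seq_len(nrow(spec$edges))) {
        lg <- spec$edges$lag[e]
        if (i > lg) {
          eta[spec$edges$to[e]] <- eta[spec$edges$to[e]] +
            weight_scale * spec$edges$beta[e] * s[i - lg, spec$edges$from[e]]
        }
      }
      s[i, ] <- stats::rbinom(R, 1, stats::plogis(eta))
    }
    idx <- which(s == 1L, arr.ind = TRUE)
    out <- data.frame(unit = idx[, 2], time = (idx[, 1] - 0.5) * bin_width)
    out <- out[order(out$time, out$unit), ]
    rownames(out) <- NULL
    attr(out, "spec") <- spec
    attr(out, "bins") <- s
    out
  })
}
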