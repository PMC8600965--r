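test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(gen_gaussian_pair(0.6, 100, seed = 9)$values,
                   gen_gaussian_pair(0.6, 100, seed = 9)$values)
  expect_identical(gen_bsc(0.1, 0.3, 100, seed = 9)$values,
                   gen_bsc(0.1, 0.3, 100, seed = 9)$values)
  expect_identical(gen_gaussian_network(N = 200, seed = 9)$values,
                   gen_gaussian_network(N = 200, seed = 9)$values)
  expect_identical(gen_three_node_demo("spikes", 500, seed = 9)$values,
                   gen_three_node_demo("spikes", 500, seed = 9)$values)
  expect_identical(gen_spiking_network(T_sec = 20, seed = 9),
                   gen_spiking_network(T_sec = 20, seed = 9))
})

test_that("network spec enforces the coupling-weight constraint", {
  spec <- default_network_spec("linear")
  expect_equal(nrow(spec$edges), 10)
  for (k in unique(spec$edges$to)) {
    expect_equal(sum(abs(spec$edges$beta[spec$edges$to == k])) + spec$alpha[k], 1)
  }
  expect_equal(spec$alpha[7], 1)  # isolated node
  expect_error(network_spec(2, data.frame(from = 1, to = 2, beta = 1.2)),
               "constraint")
  expect_error(network_spec(2, data.frame(from = 1, to = 1, beta = 0.5)),
               "self-edges")
})

test_that("gaussian pair matches its nominal correlation and window structure", {
  s <- gen_gaussian_pair(0.6, 1e5, seed = 1)
  x <- s$values[, "X"]
  y <- s$values[, "Y"]
  T_len <- length(x)
  lagged <- cor(x[seq(1, T_len - 1, by = 2)], y[seq(2, T_len, by = 2)])
  expect_equal(lagged, 0.6, tolerance = 0.01)
  s0 <- gen_gaussian_pair(0, 2e4, seed = 2)
  expect_lt(abs(cor(s0$values[-nrow(s0$values), 1], s0$values[-1, 2])), 0.02)
})

test_that("binary symmetric channel flips with the nominal probability", {
  s <- gen_bsc(0, 0.3, 5000, seed = 3)
  x <- s$values[, 1]
  y <- s$values[, 2]
  expect_true(all(y[-1] == x[-length(x)]))  # p_flip = 0: perfect copy
  s2 <- gen_bsc(0.1, 0.3, 5e4, seed = 4)
  flips <- mean(s2$values[-1, 2] != s2$values[-nrow(s2$values), 1])
  expect_equal(flips, 0.1, tolerance = 0.01)
  expect_equal(mean(s2$values[, 1]), 0.3, tolerance = 0.01)
})

test_that("nonlinear network sources are uniform and targets non-Gaussian", {
  s <- gen_nonlinear_network(N = 5000, seed = 5)
  for (src in c(6, 7, 8, 9)) {
    ks <- suppressWarnings(ks.test(s$values[, src], "punif"))
    expect_gt(ks$p.value, 0.001)
  }
  # node 10 mixes two (anti-)correlated squared inputs over a tiny noise
  # floor, making its marginal strongly leptokurtic
  x10 <- s$values[, 10]
  kurt <- mean((x10 - mean(x10))^4) / stats::sd(x10)^4
  expect_gt(abs(kurt - 3), 0.5)
})

test_that("zero-coupling specs degenerate to independent noise", {
  spec <- network_spec(3, data.frame(from = 1, to = 2, beta = 1e-9))
  s <- gen_gaussian_network(spec, N = 4000, seed = 6)
  cm <- cor(s$values)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.06)

  sp0 <- gen_spiking_network(spec, T_sec = 60, bin_width = 0.02, seed = 7,
                             baseline = -1.4)
  bins <- attr(sp0, "bins")
  expect_equal(colMeans(bins), rep(plogis(-1.4), 3), tolerance = 0.03)
})

test_that("spiking surrogate expresses imposed couplings in the correlogram", {
  spec <- network_spec(2, data.frame(from = 1, to = 2, beta = 0.45))
  sp <- gen_spiking_network(spec, T_sec = 120, bin_width = 0.02, seed = 8)
  b <- attr(sp, "bins")
  n <- nrow(b)
  pos <- cor(b[-n, 1], b[-1, 2])
  expect_gt(pos, 0.2)  # excitatory peak at the imposed lag
  specn <- network_spec(2, data.frame(from = 1, to = 2, beta = -0.45))
  bn <- attr(gen_spiking_network(specn, T_sec = 120, bin_width = 0.02, seed = 8), "bins")
  expect_lt(cor(bn[-n, 1], bn[-1, 2]), -0.1)  # inhibitory trough
})

test_that("analytic oracles reproduce hand-derived values and orderings", {
  expect_equal(analytic_pair_di(0.6), -0.5 * log(1 - 0.36))
  # exact enumeration: Hb(0.34) - Hb(0.1)
  hb <- function(p) -p * log(p) - (1 - p) * log(1 - p)
  expect_equal(analytic_bsc_di(0.1, 0.3), hb(0.34) - hb(0.1), tolerance = 1e-12)
  expect_equal(analytic_bsc_di(0.5, 0.3), 0, tolerance = 1e-12)

  spec <- network_spec(2, data.frame(from = 1, to = 2, beta = 0.6))
  expect_equal(analytic_network_gdi(spec, 1, 2), 0.5 * log(1 + 0.36 / 0.16))
  # conditioning can only raise the value of a sink edge: Eq-21-type <= Eq-20-type
  sink <- default_network_spec("linear")
  for (e in which(sink$edges$to == 2)) {
    j <- sink$edges$from[e]
    expect_lte(analytic_network_di(sink, j, 2), analytic_network_gdi(sink, j, 2))
  }
  expect_error(analytic_network_di(sink, 2, 6), "no edge")
})

test_that("discrete plug-in MI matches direct enumeration on a known table", {
  a <- c(0, 0, 1, 1, 0, 1, 0, 1)
  b <- c(0, 0, 1, 1, 0, 1, 1, 0)
  # joint: p(0,0)=3/8, p(0,1)=1/8, p(1,0)=1/8, p(1,1)=3/8, uniform marginals
  expected <- 2 * (3 / 8) * log((3 / 8) / 0.25) + 2 * (1 / 8) * log((1 / 8) / 0.25)
  expect_equal(discrete_mi(a, b), expected)
  expect_equal(discrete_mi(a, a), log(2))
  expect_equal(discrete_cmi(a, b, b), 0)
})
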