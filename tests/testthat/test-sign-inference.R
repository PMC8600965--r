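test_that("time-lagged correlation recovers constructed lags and signs", {
  withr::with_seed(1, {
    x <- rnorm(300)
    y <- c(rep(0, 4), x[1:296])  # y is x delayed by 4 samples
  })
  expect_equal(tlc(x, y, -4), 1, tolerance = 1e-6)
  expect_equal(tlc(x, -x, 0), -1)
  z <- withr::with_seed(2, rnorm(300))
  expect_lt(abs(tlc(x, z, -3)), 0.15)
  expect_error(tlc(x, rep(1, 300), 0), "constant")
  expect_error(tlc(x[1:5], y[1:5], -4), "overlap")
})

test_that("partial correlation with empty conditioning equals the TLC", {
  s <- ts_set(withr::with_seed(3, matrix(rnorm(900), 300, 3)),
              channel_names = c("a", "b", "c"))
  expect_equal(tlpc(s, "a", "b", -2),
               tlc(s$values[, 1], s$values[, 2], -2))
})

test_that("recursive and regression-residual TLPC agree to 1e-8", {
  s <- ts_set(withr::with_seed(4, matrix(rnorm(1600), 400, 4)))
  for (tau in c(-1, -3, -6)) {
    expect_equal(tlpc(s, 1, 2, tau, 3),
                 tlpc_recursive(s, 1, 2, tau, 3), tolerance = 1e-8)
    expect_equal(tlpc(s, 1, 2, tau, c(3, 4)),
                 tlpc_recursive(s, 1, 2, tau, c(3, 4)), tolerance = 1e-8)
  }
})

test_that("all coefficients lie within the correlation bounds", {
  s <- ts_set(withr::with_seed(5, matrix(rnorm(1200), 300, 4)))
  for (tau in -(1:10)) {
    v <- tlpc(s, 2, 3, tau, c(1, 4))
    expect_true(abs(v) <= 1 + 1e-9)
  }
})

test_that("collinear conditioning channels raise a rank error", {
  base <- withr::with_seed(6, matrix(rnorm(300), 100, 3))
  s <- ts_set(cbind(base, base[, 3]))
  expect_error(tlpc(s, 1, 2, -1, c(3, 4)), "collinear")
})

test_that("sign inference finds the lag of a pure excitatory copy", {
  withr::with_seed(7, {
    x <- rnorm(400)
    y <- c(rep(0, 3), x[1:397]) + rnorm(400, sd = 0.05)
  })
  s <- ts_set(cbind(X = x, Y = y))
  out <- infer_sign(s, "X", "Y", lag_range = -(1:8))
  expect_equal(out$sign, 1)
  expect_equal(out$tau_star, -3)
  expect_error(infer_sign(s, "X", "Y", lag_range = 0:3), "negative")
})

test_that("masking demos: TLC mislabels the inhibitory edge, TLPC corrects it", {
  cont <- gen_three_node_demo("continuous", N = 4000, seed = 1)
  lags <- -(1:60)
  expect_equal(infer_sign(cont, "X", "Y", "W", lags)$sign, -1)
  expect_equal(infer_sign(cont, "X", "Y", integer(0), lags)$sign, 1)
  expect_equal(infer_sign(cont, "W", "Y", "X", lags)$sign, 1)
  expect_equal(infer_sign(cont, "W", "Y", integer(0), lags)$sign, 1)

  disc <- gen_three_node_demo("spikes", N = 8000, seed = 2)
  lags2 <- -(1:15)
  expect_equal(infer_sign(disc, "X", "Y", "W", lags2)$sign, -1)
  expect_equal(infer_sign(disc, "X", "Y", integer(0), lags2)$sign, 1)
  expect_equal(infer_sign(disc, "W", "Y", "X", lags2)$sign, 1)
})
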