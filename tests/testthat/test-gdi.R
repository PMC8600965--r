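test_that("conditioning-set selection thresholds incoming DI to the target", {
  m <- matrix(0, 5, 5)
  m[1, 4] <- 0.005
  m[2, 4] <- 0.02
  m[5, 4] <- 0.3
  expect_equal(select_conditioning_set(m, j = 3, k = 4, theta = 0.01), c(2, 5))
  expect_equal(select_conditioning_set(matrix(0, 4, 4), 1, 2, 0.01), integer(0))
  expect_equal(select_conditioning_set(m, 3, 4, 0), c(1, 2, 5))
  expect_error(select_conditioning_set(m[, 1:3], 1, 2), "square")
})

test_that("normalization rescales into [0, 1] and flags out-of-range noise", {
  expect_equal(normalize_di(0, 0.5), 0)
  expect_equal(normalize_di(0.5, 0.5), 1)
  expect_equal(normalize_di(0.25, 0.5), 0.5)
  expect_warning(v <- normalize_di(-0.05, 0.5), "clipped")
  expect_equal(v, 0)
  expect_warning(v2 <- normalize_di(0.7, 0.5), "clipped")
  expect_equal(v2, 1)
  expect_error(normalize_di(0.1, 0), "positive")
})

test_that("target entropy matches the closed form for i.i.d. binary channels", {
  p <- 0.3
  y <- withr::with_seed(10, rbinom(2e4, 1, p))
  s <- ts_set(cbind(A = y, B = withr::with_seed(11, rbinom(2e4, 1, 0.5))))
  hb <- function(p) -p * log(p) - (1 - p) * log(1 - p)
  expect_equal(target_entropy(s, "A", M = 3), hb(p), tolerance = 0.01)
  expect_error(target_entropy(ts_set(matrix(rnorm(20), 10, 2)), 1), "binary")
})

test_that("a noiseless binary copy channel attains DI = ln 2 and normalized 1", {
  s <- copy_channel_series(6000, seed = 12)
  est <- estimate_di(s, "X", "Y", fast_graph_cfg(M = 1, seed = 3, B = 5))
  expect_equal(est$value, log(2), tolerance = 0.06)
  expect_equal(suppressWarnings(normalize_di(est$value, target_entropy(s, "Y", 1))),
               1, tolerance = 0.06)
})

test_that("GDI with empty conditioning equals DI bit-for-bit under equal seeds", {
  s <- gen_gaussian_pair(0.5, 400, seed = 13)
  cfg <- fast_graph_cfg(M = 1, seed = 4, B = 2)
  a <- estimate_di(s, "X", "Y", cfg, seed = 99)
  b <- estimate_gdi(s, "X", "Y", integer(0), cfg, seed = 99)
  expect_identical(a$per_iteration, b$per_iteration)
})

test_that("independent channels produce a near-empty graph", {
  s <- ts_set(withr::with_seed(14, matrix(rnorm(1200), 600, 2)))
  g <- build_graph(s, fast_graph_cfg(M = 1, seed = 5, B = 3))
  expect_s3_class(g, "di_graph")
  expect_equal(nrow(g$edges), 2)
  expect_true(all(abs(g$edges$raw_gdi_nats) < 0.06))
})

test_that("graphical mode with an impossible threshold reduces to pairwise DI", {
  s <- gen_bsc(0.2, 0.4, 600, seed = 15)
  cfg <- fast_graph_cfg(M = 1, seed = 6, B = 2,
                        conditioning_policy = "di-thresholded", di_threshold = 10)
  g <- build_graph(s, cfg)
  expect_identical(g$edges$raw_gdi_nats, g$edges$raw_di_nats)
})

test_that("bin-width averaging pools magnitudes and resolves signs", {
  spec <- network_spec(3, data.frame(from = c(1, 2), to = c(2, 3),
                                     beta = c(0.45, -0.45)))
  sp <- gen_spiking_network(spec, T_sec = 80, bin_width = 0.02, seed = 16)
  cfg <- fast_graph_cfg(M = 2, seed = 7, B = 2,
                        conditioning_policy = "di-thresholded",
                        bin_widths = c(0.02, 0.03))
  g <- average_over_bin_widths(sp, cfg)
  pw <- attr(g, "per_width")
  expect_equal(length(pw), 2)
  i12 <- which(g$edges$source == "1" & g$edges$target == "2")
  manual <- mean(c(pw[[1]]$edges$normalized[i12], pw[[2]]$edges$normalized[i12]))
  expect_equal(g$edges$normalized[i12], manual)
  expect_true(all(g$edges$normalized >= 0 & g$edges$normalized <= 1, na.rm = TRUE))
  expect_error(average_over_bin_widths(sp, fast_graph_cfg(M = 2, bin_widths = 0.02)),
               "2 bin widths")
})
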