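test_that("configuration objects validate their fields", {
  expect_error(classifier_spec(prob_clip = 0.7), "prob_clip")
  expect_error(classifier_spec(hidden_layers = 0), "hidden_layers")
  expect_error(estimator_config(bootstrap_iters = 0), "bootstrap_iters")
  expect_error(estimator_config(train_fraction = 1), "train_fraction")
})

test_that("ratio model: chance-level data gives L near 1, training is seeded", {
  set.seed(3)
  p <- matrix(rnorm(600), ncol = 2)
  q <- matrix(rnorm(600), ncol = 2)  # same distribution -> chance
  m <- fit_ratio_model(p, q, classifier_spec(8, 40), seed = 7)
  L <- predict_ratio(m, matrix(rnorm(200), ncol = 2))
  expect_true(all(is.finite(L)))
  expect_lt(abs(mean(log(L))), 0.35)

  m2 <- fit_ratio_model(p, q, classifier_spec(8, 40), seed = 7)
  expect_identical(predict_ratio(m, p), predict_ratio(m2, p))

  expect_error(fit_ratio_model(p, q[, 1, drop = FALSE]), "mismatch")
  expect_error(predict_ratio(m, p[, 1, drop = FALSE]), "mismatch")
})

test_that("likelihood ratios are clipped to finite extremes on separable data", {
  p <- matrix(rnorm(400, mean = 10), ncol = 1)
  q <- matrix(rnorm(400, mean = -10), ncol = 1)
  spec <- classifier_spec(8, 60, prob_clip = 1e-3)
  m <- fit_ratio_model(p, q, spec, seed = 1)
  L <- predict_ratio(m, rbind(p, q))
  expect_true(all(L <= (1 - 1e-3) / 1e-3 + 1e-9))
  expect_true(all(L >= 1e-3 / (1 - 1e-3) - 1e-12))
})

test_that("KL plug-in matches the closed form for a Gaussian mean shift", {
  # KL(N(0,1) || N(1,1)) = 1/2 nat
  withr::with_seed(11, {
    p <- matrix(rnorm(5000), ncol = 1)
    q <- matrix(rnorm(5000, mean = 1), ncol = 1)
  })
  tr <- 1:3300
  m <- fit_ratio_model(p[tr, , drop = FALSE], q[tr, , drop = FALSE],
                       classifier_spec(16, 100), seed = 5)
  kl <- estimate_kl(p[-tr, , drop = FALSE], q[-tr, , drop = FALSE], m)
  expect_equal(kl, 0.5, tolerance = 0.15)
  expect_error(estimate_kl(p[0, , drop = FALSE], q, m), "empty")
})

test_that("MI estimates: independence near zero, Gaussian pair near closed form", {
  s <- gen_gaussian_pair(0.6, 1500, seed = 21)
  pr <- build_mi_problems(s, embedding_config(1, target = 2, source = 1))
  est <- estimate_mi(pr$mi1, fast_estimator(seed = 2, B = 5))
  expect_s3_class(est, "mi_estimate")
  expect_equal(est$value, mean(est$per_iteration))
  expect_equal(length(est$per_iteration), 5)
  expect_lt(abs(est$value - (-0.5 * log(1 - 0.36))), 0.07)

  ind <- withr::with_seed(4, cbind(rnorm(1200), rnorm(1200)))
  est0 <- estimate_mi(list(joint = ind, block_index = 1),
                      fast_estimator(seed = 3, B = 5))
  expect_lt(abs(est0$value), 0.04)
  expect_error(estimate_mi(list(joint = ind[1:2, ], block_index = 1)), "3 samples")
})

test_that("CMI reduces to MI with empty conditioning and vanishes on Markov chains", {
  withr::with_seed(8, {
    A <- rbinom(4000, 1, 0.5)
    Z <- ifelse(rbinom(4000, 1, 0.85) == 1, A, 1 - A)
    B <- ifelse(rbinom(4000, 1, 0.85) == 1, Z, 1 - Z)
  })
  cfg <- fast_estimator(seed = 5, B = 5)
  cmi <- estimate_cmi(matrix(A), matrix(B), matrix(Z), cfg)
  mi <- estimate_cmi(matrix(A), matrix(B), NULL, cfg)
  # A -> Z -> B: conditional independence given Z, but marginal dependence
  expect_lt(abs(cmi$value), 0.04)
  expect_gt(mi$value, 0.1)
  # against the exact plug-in oracle
  expect_equal(cmi$value, discrete_cmi(A, B, Z), tolerance = 0.04)
  expect_equal(mi$value, discrete_mi(A, B), tolerance = 0.05)
  expect_error(estimate_cmi(matrix(A), matrix(B[1:10])), "row-aligned")
})

test_that("MI estimator is unbiased near zero over repeated independent runs", {
  vals <- vapply(1:20, function(r) {
    joint <- withr::with_seed(100 + r, cbind(rnorm(600), rnorm(600)))
    estimate_mi(list(joint = joint, block_index = 1),
                fast_estimator(seed = 200 + r, B = 2))$value
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.02)
})
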