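test_that("embedding config enforces its invariants", {
  expect_error(embedding_config(0, 1, 2), "M")
  expect_error(embedding_config(1, 1, 1), "differ")
  expect_error(embedding_config(1, 1, 2, conditioning = 2), "exclude")
  cfg <- embedding_config(3, target = 2, source = 1, conditioning = 3:4)
  expect_equal(cfg$M, 3L)
})

test_that("windowed MI problems have the documented shapes", {
  # R = 2, T = 8, M = 1: 4 non-overlapping windows; MI1 has A = 1 col,
  # B = 2 cols (target current + target past); MI2 drops the current value
  s <- ts_set(matrix(rnorm(16), 8, 2))
  pr <- build_mi_problems(s, embedding_config(1, target = 2, source = 1))
  expect_equal(pr$mi1$n_windows, 4)
  expect_equal(ncol(pr$mi1$joint), 3)
  expect_equal(ncol(pr$mi2$joint), 2)
  expect_equal(pr$mi1$block_index, 1)

  # R = 11, M = 3, conditioning on all 9 others: 34 columns in MI1
  s11 <- ts_set(matrix(rnorm(11 * 80), 80, 11))
  pr11 <- build_mi_problems(
    s11, embedding_config(3, target = 2, source = 1, conditioning = 3:11))
  expect_equal(ncol(pr11$mi1$joint), 34)
  expect_equal(ncol(pr11$mi2$joint), 33)

  # T = 11, M = 3 -> only 2 windows: allowed but flagged
  s2 <- ts_set(matrix(rnorm(22), 11, 2))
  expect_warning(
    pr2 <- build_mi_problems(s2, embedding_config(3, target = 2, source = 1)),
    "noisy")
  expect_equal(pr2$mi1$n_windows, 2)

  # T < 2 (M + 1) -> insufficient data
  s3 <- ts_set(matrix(rnorm(14), 7, 2))
  expect_error(build_mi_problems(s3, embedding_config(3, 2, 1)), "insufficient")
})

test_that("windows are non-overlapping, anchored at the start, remainder dropped", {
  x <- matrix(seq_len(20), 10, 2)  # channel 1: 1..10
  s <- ts_set(x)
  emb <- gdinfer:::embed_windows(s, 2)
  expect_equal(emb$n_windows, 3)  # floor(10 / 3)
  expect_equal(emb$past[[1]], matrix(c(1, 4, 7, 2, 5, 8), 3))
  expect_equal(emb$current[, 1], c(3, 6, 9))  # sample 10 discarded
})

test_that("permutation preserves block marginals exactly and is seeded", {
  m <- cbind(A = 1:6, B = rnorm(6))
  out <- permute_block(m, 1, seed = 5)
  expect_equal(sort(out[, 1]), 1:6)       # multiset preserved
  expect_identical(out[, 2], m[, 2])      # B-block untouched
  expect_identical(out, permute_block(m, 1, seed = 5))  # determinism
  expect_false(identical(out[, 1], m[, 1]) &&
               identical(permute_block(m, 1, 6)[, 1], out[, 1]))

  same <- matrix(1, 4, 2)
  expect_identical(permute_block(same, 1, 1), same)  # degenerate rows
  expect_error(permute_block(m[1, , drop = FALSE], 1, 1), "2 rows")
})

test_that("binary input stays binary through embedding", {
  s <- copy_channel_series(40)
  pr <- build_mi_problems(s, embedding_config(1, target = 2, source = 1))
  expect_true(all(pr$mi1$joint %in% c(0, 1)))
  expect_true(all(pr$mi1$shuffled %in% c(0, 1)))
})
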