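# Shared test helpers: small estimator settings keep unit tests fast;
# acceptance-scale settings live in test-acceptance.R.

fast_estimator <- function(seed = 1L, B = 3) {
  estimator_config(bootstrap_iters = B, seed = seed,
                   classifier = classifier_spec(hidden_layers = 8,
                                                max_epochs = 40,
                                                patience = 5))
}

fast_graph_cfg <- function(M = 1, seed = 1L, B = 3, ...) {
  graph_config(M = M, estimator = fast_estimator(seed, B), ...)
}

# deterministic binary copy channel: y_i = x_{i-1}
copy_channel_series <- function(T_len, seed = 1L) {
  withr::with_seed(seed, {
    x <- stats::rbinom(T_len, 1, 0.5)
    y <- c(0L, x[-T_len])
    ts_set(cbind(X = x, Y = y), kind = "binary")
  })
}

true_edge_keys <- function(spec) paste(spec$edges$from, spec$edges$to)
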