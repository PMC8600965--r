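#' Graph-estimation configuration
#'
#' Collects every tunable of a connectivity-graph run: the memory length,
#' the estimator settings, pairwise versus graphical mode, the
#' conditioning-set policy, normalization and flooring behaviour, the bin
#' widths for spike data, and the lag range scanned by sign inference.
#'
#' @param M memory length in samples (past window per channel).
#' @param estimator an [estimator_config].
#' @param mode `"graphical"` (condition on other nodes) or `"pairwise"`.
#' @param conditioning_policy `"all-others"` conditions every edge on all
#'   remaining channels; `"di-thresholded"` conditions only on channels
#'   whose incoming pairwise DI to the target reaches `di_threshold`
#'   (normalized units for binary data, nats otherwise).
#' @param di_threshold significance threshold `theta` (default 0.01).
#' @param normalize scale DI/GDI by the target's conditional entropy so
#'   values lie in `[0, 1]`; defaults to TRUE for binary series and FALSE
#'   for continuous ones (where values are reported in nats).
#' @param floor_negative floor negative magnitudes at 0 in graph weights
#'   (raw values are retained in the edge record).
#' @param bin_widths vector of bin widths in seconds for
#'   [average_over_bin_widths()].
#' @param sign_lag_range negative lags scanned for sign inference;
#'   default `-(1:(5 * M))`.
#' @return An object of class `graph_config`.
#' @export
graph_config <- function(M = 3, estimator = estimator_config(),
                         mode = c("graphical", "pairwise"),
                         conditioning_policy = c("all-others", "di-thresholded"),
                         di_threshold = 0.01, normalize = NULL,
                         floor_negative = TRUE, bin_widths = NULL,
                         sign_lag_range = NULL) {
  mode <- match.arg(mode)
  conditioning_policy <- match.arg(conditioning_policy)
  if (di_threshold < 0) stop("'di_threshold' must be >= 0")
  if (!is.null(bin_widths)) {
    if (any(bin_widths <= 0) || anyDuplicated(bin_widths)) {
      stop("'bin_widths' must be positive and distinct")
    }
  }
  if (is.null(sign_lag_range)) sign_lag_range <- -(1:(5 * M))
  stopifnot(inherits(estimator, "estimator_config"))
  structure(
    list(M = as.integer(M), estimator = estimator, mode = mode,
         conditioning_policy = conditioning_policy,
         di_threshold = di_threshold, normalize = normalize,
         floor_negative = floor_negative, bin_widths = bin_widths,
         sign_lag_range = as.integer(sign_lag_range)),
    class = "graph_config"
  )
}

edge_estimator_cfg <- function(cfg, seed) {
  est <- cfg$estimator
  est$seed <- as.integer(seed)
  est
}

#' Pairwise directed information between two channels
#'
#' DI is the mutual information between the `M` past values of the source
#' and the current value of the target, conditioned on the target's own
#' past: estimated here as a classifier-based CMI with `A` = source past,
#' `B` = target current and `Z` = target past.
#'
#' @param series a [ts_set].
#' @param j,k source and target channels (index or name).
#' @param cfg a [graph_config].
#' @param seed optional seed overriding `cfg$estimator$seed`.
#' @return An `mi_estimate` (raw DI, nats).
#' @export
estimate_di <- function(series, j, k, cfg = graph_config(), seed = NULL) {
  estimate_gdi(series, j, k, conditioning = integer(0), cfg = cfg, seed = seed)
}

#' Graphical directed information between two channels
#'
#' DI from `j` to `k` additionally conditioned on the pasts of the given
#' channels, so the estimate expresses direct (conditional) influence:
#' classifier-based CMI with `A` = source past, `B` = target current and
#' `Z` = pasts of the target and of every conditioning channel. With an
#' empty conditioning set this equals [estimate_di()].
#'
#' @param series a [ts_set].
#' @param j,k source and target channels.
#' @param conditioning channels conditioned on (excluding `j`, `k`).
#' @param cfg a [graph_config].
#' @param seed optional seed overriding `cfg$estimator$seed`.
#' @return An `mi_estimate` (raw GDI, nats).
#' @export
estimate_gdi <- function(series, j, k, conditioning = integer(0),
                         cfg = graph_config(), seed = NULL) {
  stopifnot(inherits(series, "ts_set"), inherits(cfg, "graph_config"))
  j <- resolve_channel(series, j)
  k <- resolve_channel(series, k)
  if (j == k) stop("source and target must differ")
  cset <- if (length(conditioning)) resolve_channel(series, conditioning) else integer(0)
  if (j %in% cset || k %in% cset) stop("conditioning set must exclude j and k")
  emb <- embed_windows(series, cfg$M)
  A <- emb$past[[j]]
  B <- emb$current[, k, drop = FALSE]
  Z <- do.call(cbind, c(list(emb$past[[k]]), emb$past[cset]))
  est <- edge_estimator_cfg(cfg, if (is.null(seed)) cfg$estimator$seed else seed)
  estimate_cmi(A, B, Z, est)
}

#' Select the conditioning set for an edge from pairwise DI
#'
#' Keeps the channels whose incoming (normalized) pairwise DI to the target
#' reaches the threshold `theta`, excluding source and target. This keeps
#' the dimensionality of the conditional estimate low when sample sizes are
#' modest.
#'
#' @param pairwise_di square matrix of pairwise DI values, entry `[r, k]`
#'   holding DI from `r` to `k` (diagonal ignored).
#' @param j,k source and target indices of the edge under analysis.
#' @param theta threshold.
#' @return Integer vector of selected channel indices.
#' @export
select_conditioning_set <- function(pairwise_di, j, k, theta = 0.01) {
  pairwise_di <- as.matrix(pairwise_di)
  if (nrow(pairwise_di) != ncol(pairwise_di)) stop("'pairwise_di' must be square")
  cand <- setdiff(seq_len(ncol(pairwise_di)), c(j, k))
  cand[!is.na(pairwise_di[cand, k]) & pairwise_di[cand, k] >= theta]
}

#' Normalize a DI value by the target's information content
#'
#' Rescales raw DI/GDI (nats) by the target node's conditional entropy so
#' incoming information is expressed relative to the target's own
#' information and lies in `[0, 1]`. Values pushed outside the range by
#' estimator noise are clipped with a warning.
#'
#' @param raw raw DI/GDI in nats (vectorised).
#' @param target_entropy positive entropy in nats, e.g. [target_entropy()].
#' @return Normalized, unitless value(s) in `[0, 1]`.
#' @export
normalize_di <- function(raw, target_entropy) {
  if (!is.finite(target_entropy) || target_entropy <= 0) {
    stop("'target_entropy' must be positive (degenerate constant channel?)")
  }
  out <- raw / target_entropy
  bad <- !is.na(out) & (out < 0 | out > 1)
  if (any(bad)) {
    warning(sprintf("%d normalized value(s) outside [0, 1] clipped", sum(bad)))
    out <- pmin(pmax(out, 0), 1)
  }
  out
}

#' Conditional entropy of a binary channel given its own past
#'
#' Plug-in estimate of `H(Y_i | Y_{i-M}, ..., Y_{i-1})` in nats from the
#' empirical frequencies of the `2^M` past patterns over all sliding
#' positions; the denominator used to normalize DI/GDI for spike data.
#'
#' @param series a binary [ts_set].
#' @param k target channel.
#' @param M memory length in samples.
#' @return Conditional entropy in nats.
#' @export
target_entropy <- function(series, k, M = 3) {
  stopifnot(inherits(series, "ts_set"))
  if (series$kind != "binary") stop("target_entropy is defined for binary series")
  k <- resolve_channel(series, k)
  y <- series$values[, k]
  T_len <- length(y)
  if (T_len < M + 1) stop("series shorter than M + 1")
  i <- (M + 1):T_len
  past <- vapply(seq_len(M), function(m) y[i - m], numeric(length(i)))
  key <- as.vector(matrix(past, ncol = M) %*% 2^(seq_len(M) - 1))
  tab <- table(key, y[i])
  n <- length(i)
  h <- 0
  for (r in seq_len(nrow(tab))) {
    pr <- sum(tab[r, ]) / n
    cond <- tab[r, ] / sum(tab[r, ])
    cond <- cond[cond > 0]
    h <- h + pr * (-sum(cond * log(cond)))
  }
  h
}

#' Estimate a signed connectivity graph
#'
#' Runs the full edge-by-edge analysis over all ordered channel pairs:
#' pairwise DI for every pair, then (in graphical mode) conditioning-set
#' selection and GDI, sign inference via time-lagged (partial) correlation,
#' and assembly of signed edge weights `w = S x magnitude`. For binary
#' series values are normalized by the target's conditional entropy; with
#' `floor_negative` negative magnitudes are floored at zero in the weight
#' (the raw estimate is kept in the edge record). Per-edge estimates use
#' seeds derived from the master seed, so results do not depend on
#' evaluation order.
#'
#' @param series a [ts_set] with at least 2 channels.
#' @param cfg a [graph_config].
#' @return An object of class `di_graph`: list with `nodes`, `edges` (data
#'   frame with columns source, target, raw_di_nats, raw_gdi_nats,
#'   normalized, sign, weight, tau_star_samples) and the resolved `config`.
#' @export
build_graph <- function(series, cfg = graph_config()) {
  stopifnot(inherits(series, "ts_set"), inherits(cfg, "graph_config"))
  R <- ncol(series$values)
  if (R < 2) stop("need at least 2 channels")
  normalize <- if (is.null(cfg$normalize)) series$kind == "binary" else cfg$normalize
  if (normalize && series$kind != "binary") {
    stop("normalization requires a binary series")
  }
  master <- cfg$estimator$seed
  ent <- if (normalize) {
    vapply(seq_len(R), function(k) target_entropy(series, k, cfg$M), numeric(1))
  } else rep(NA_real_, R)

  pairs <- expand.grid(source = seq_len(R), target = seq_len(R))
  pairs <- pairs[pairs$source != pairs$target, ]

  # pairwise DI matrix
  di_mat <- matrix(NA_real_, R, R)
  for (p in seq_len(nrow(pairs))) {
    j <- pairs$source[p]; k <- pairs$target[p]
    est <- tryCatch(
      estimate_di(series, j, k, cfg, seed = derive_seed(master, j, k, 1L)),
      error = function(e) {
        warning(sprintf("DI %d->%d failed: %s", j, k, conditionMessage(e)))
        NULL
      })
    di_mat[j, k] <- if (is.null(est)) NA_real_ else est$value
  }
  di_for_threshold <- di_mat
  if (normalize) {
    for (k in seq_len(R)) {
      di_for_threshold[, k] <- suppressWarnings(
        ifelse(is.na(di_mat[, k]), NA, pmin(pmax(di_mat[, k] / ent[k], 0), 1)))
    }
  }

  edges <- data.frame(
    source = character(0), target = character(0), raw_di_nats = numeric(0),
    raw_gdi_nats = numeric(0), normalized = numeric(0), sign = numeric(0),
    weight = numeric(0), tau_star_samples = integer(0),
    stringsAsFactors = FALSE
  )
  for (p in seq_len(nrow(pairs))) {
    j <- pairs$source[p]; k <- pairs$target[p]
    raw_di <- di_mat[j, k]
    raw_gdi <- NA_real_
    cset <- integer(0)
    if (cfg$mode == "graphical") {
      cset <- if (cfg$conditioning_policy == "all-others") {
        setdiff(seq_len(R), c(j, k))
      } else {
        select_conditioning_set(di_for_threshold, j, k, cfg$di_threshold)
      }
      if (length(cset) == 0) {
        raw_gdi <- raw_di  # GDI degenerates to DI with empty conditioning
      } else {
        est <- tryCatch(
          estimate_gdi(series, j, k, cset, cfg, seed = derive_seed(master, j, k, 1L)),
          error = function(e) {
            warning(sprintf("GDI %d->%d failed: %s", j, k, conditionMessage(e)))
            NULL
          })
        raw_gdi <- if (is.null(est)) NA_real_ else est$value
      }
    }
    mag_raw <- if (cfg$mode == "graphical") raw_gdi else raw_di
    norm_val <- NA_real_
    if (normalize && !is.na(mag_raw)) {
      norm_val <- suppressWarnings(normalize_di(mag_raw, ent[k]))
      if (norm_val < cfg$di_threshold) norm_val <- 0
    }
    mag <- if (normalize) norm_val else mag_raw
    if (!is.na(mag) && cfg$floor_negative) mag <- max(mag, 0)
    sign_cond <- if (cfg$mode == "graphical") cset else integer(0)
    sg <- tryCatch(
      infer_sign(series, j, k, sign_cond, cfg$sign_lag_range),
      error = function(e) list(sign = NA_real_, tau_star = NA_integer_))
    w <- if (is.na(mag)) NA_real_ else if (is.na(sg$sign)) mag else sg$sign * mag
    edges <- rbind(edges, data.frame(
      source = series$channel_names[j], target = series$channel_names[k],
      raw_di_nats = raw_di, raw_gdi_nats = raw_gdi, normalized = norm_val,
      sign = sg$sign, weight = w, tau_star_samples = sg$tau_star,
      stringsAsFactors = FALSE
    ))
  }
  rownames(edges) <- NULL
  structure(
    list(nodes = series$channel_names, edges = edges, config = cfg),
    class = "di_graph"
  )
}

#' @export
print.di_graph <- function(x, ...) {
  cat(sprintf("<di_graph> %d nodes, %d evaluated edges (%s mode)\n",
              length(x$nodes), nrow(x$edges), x$config$mode))
  top <- x$edges[order(-abs(x$edges$weight)), ]
  print(utils::head(top, 10), row.names = FALSE)
  invisible(x)
}

#' Bin-width-averaged connectivity graph for spike data
#'
#' Repeats the binning + graph estimation at several bin widths and
#' averages: per width, spike times are binned, DI/GDI are estimated and
#' normalized, values below the threshold are set to zero, and the edge
#' sign is inferred; the final magnitude is the mean of the per-width
#' normalized values and the final sign is the sign of the mean of the
#' per-width signs over widths with non-zero estimates (a zero mean leaves
#' the sign undetermined and the weight unsigned).
#'
#' @param spikes spike table (unit, time in seconds), see
#'   [bin_spike_trains()].
#' @param cfg a [graph_config] whose `bin_widths` holds at least 2 widths.
#' @param t_start,t_end analysis interval; defaults to the spike range.
#' @return A `di_graph` whose edge magnitudes are bin-width averages; the
#'   per-width graphs are attached as attribute `per_width`.
#' @export
average_over_bin_widths <- function(spikes, cfg, t_start = NULL, t_end = NULL) {
  stopifnot(inherits(cfg, "graph_config"))
  widths <- cfg$bin_widths
  if (is.null(widths) || length(widths) < 2) stop("need at least 2 bin widths")
  spikes <- as.data.frame(spikes)
  if (is.null(t_start)) t_start <- 0
  if (is.null(t_end)) t_end <- max(spikes[[2]])
  units <- unique(as.character(spikes[[1]]))
  per_width <- list()
  for (w in widths) {
    series <- bin_spike_trains(spikes, w, t_start, t_end, units = units)
    if (floor(nrow(series$values) / (cfg$M + 1)) < 2) {
      warning(sprintf("bin width %g s yields < 2 windows; skipped", w))
      next
    }
    g <- build_graph(series, cfg)
    per_width[[as.character(w)]] <- g
  }
  if (length(per_width) == 0) stop("no usable bin width")
  base <- per_width[[1]]$edges[, c("source", "target")]
  mags <- sapply(per_width, function(g) g$edges$normalized)
  signs <- sapply(per_width, function(g) g$edges$sign)
  mags <- matrix(mags, nrow = nrow(base))
  signs <- matrix(signs, nrow = nrow(base))
  avg_mag <- rowMeans(mags, na.rm = TRUE)
  final_sign <- numeric(nrow(base))
  for (i in seq_len(nrow(base))) {
    contributing <- which(!is.na(mags[i, ]) & mags[i, ] > 0 & !is.na(signs[i, ]))
    if (length(contributing) == 0) {
      final_sign[i] <- NA_real_
    } else {
      m <- mean(signs[i, contributing])
      final_sign[i] <- if (m == 0) NA_real_ else sign(m)
    }
  }
  edges <- data.frame(
    source = base$source, target = base$target,
    raw_di_nats = rowMeans(sapply(per_width, function(g) g$edges$raw_di_nats),
                           na.rm = TRUE),
    raw_gdi_nats = rowMeans(sapply(per_width, function(g) g$edges$raw_gdi_nats),
                            na.rm = TRUE),
    normalized = avg_mag,
    sign = final_sign,
    weight = ifelse(is.na(final_sign), avg_mag, final_sign * avg_mag),
    tau_star_samples = per_width[[1]]$edges$tau_star_samples,
    stringsAsFactors = FALSE
  )
  structure(
    list(nodes = per_width[[1]]$nodes, edges = edges, config = cfg),
    class = "di_graph", per_width = per_width
  )
}
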