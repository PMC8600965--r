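#' Embedding configuration
#'
#' Describes one directed-information problem on a [ts_set]: the memory
#' length `M` (number of past samples per channel), the source channel, the
#' target channel and an optional conditioning set.
#'
#' @param M memory length in samples, at least 1.
#' @param target index (or name) of the target channel.
#' @param source index (or name) of the source channel.
#' @param conditioning indices/names of channels conditioned on; must not
#'   contain source or target. May be empty (pairwise case).
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(M, target, source, conditioning = integer(0)) {
  if (M < 1) stop("'M' must be >= 1")
  if (length(source) != 1 || length(target) != 1) {
    stop("'source' and 'target' must be single channels")
  }
  if (identical(source, target)) stop("'source' and 'target' must differ")
  if (source %in% conditioning || target %in% conditioning) {
    stop("'conditioning' must exclude source and target")
  }
  structure(
    list(M = as.integer(M), target = target, source = source,
         conditioning = conditioning),
    class = "embedding_config"
  )
}

resolve_channel <- function(series, ch) {
  if (is.character(ch)) {
    i <- match(ch, series$channel_names)
    if (any(is.na(i))) stop("unknown channel: ", paste(ch[is.na(i)], collapse = ", "))
    return(i)
  }
  ch <- as.integer(ch)
  if (any(ch < 1 | ch > ncol(series$values))) stop("channel index out of range")
  ch
}

# Cut the series into non-overlapping windows of length M+1 anchored at the
# first sample (trailing remainder discarded). Returns, per channel, the M
# "past" values (first M of each window) and the "current" value (last).
embed_windows <- function(series, M) {
  x <- series$values
  T_len <- nrow(x)
  wlen <- M + 1L
  n_win <- floor(T_len / wlen)
  if (n_win < 2) {
    stop("insufficient data: fewer than 2 non-overlapping windows of length M+1")
  }
  starts <- (seq_len(n_win) - 1L) * wlen
  past <- lapply(seq_len(ncol(x)), function(r) {
    cols <- vapply(seq_len(M), function(m) x[starts + m, r], numeric(n_win))
    matrix(cols, nrow = n_win)
  })
  current <- x[starts + wlen, , drop = FALSE]
  list(past = past, current = current, n_windows = n_win)
}

#' Build the paired mutual-information problems for one directed edge
#'
#' Directed information from a source to a target, conditioned on a set of
#' other channels, is a difference of two mutual-information terms. This
#' function embeds the series into non-overlapping windows of length `M + 1`
#' and assembles the sample blocks of both terms: the A-block holds the `M`
#' past values of the source; the B-block of the first problem holds the
#' current value of the target followed by the pasts of the target and of
#' every conditioning channel; the second problem drops the target's current
#' value. Independence surrogates are produced by [permute_block()].
#'
#' @param series a [ts_set].
#' @param cfg an [embedding_config].
#' @param seed integer seed for the canonical permutation.
#' @return A list with elements `mi1` and `mi2`, each a `sample_pair` list
#'   with fields `joint`, `shuffled`, `block_index` (columns of the A-block)
#'   and `n_windows`.
#' @export
build_mi_problems <- function(series, cfg, seed = 1L) {
  stopifnot(inherits(series, "ts_set"), inherits(cfg, "embedding_config"))
  j <- resolve_channel(series, cfg$source)
  k <- resolve_channel(series, cfg$target)
  z <- if (length(cfg$conditioning)) resolve_channel(series, cfg$conditioning) else integer(0)
  if (j %in% z || k %in% z) stop("conditioning set must exclude source and target")
  M <- cfg$M
  if (nrow(series$values) < 2 * (M + 1)) {
    stop("insufficient data: T < 2 * (M + 1)")
  }
  emb <- embed_windows(series, M)
  if (emb$n_windows < 50) {
    warning(sprintf("only %d windows available; estimates will be noisy", emb$n_windows))
  }
  A <- emb$past[[j]]
  B2 <- do.call(cbind, c(list(emb$past[[k]]), emb$past[z]))
  B1 <- cbind(emb$current[, k], B2)
  make_pair <- function(A, B, seed) {
    joint <- cbind(A, B)
    block <- seq_len(ncol(A))
    list(joint = joint,
         shuffled = permute_block(joint, block, seed),
         block_index = block,
         n_windows = nrow(joint))
  }
  list(mi1 = make_pair(A, B1, seed), mi2 = make_pair(A, B2, seed))
}

#' Permute the source block of a joint sample matrix
#'
#' Draws samples from the independence surrogate distribution by applying a
#' uniformly random row permutation to the A-block columns only, leaving the
#' remaining columns untouched. Each column's empirical distribution is
#' preserved exactly; only the association between blocks is destroyed.
#'
#' @param samples numeric matrix of joint samples (rows = windows).
#' @param block_index columns forming the A-block.
#' @param seed integer seed; the same seed yields the same permutation.
#' @return Matrix of the same shape as `samples`.
#' @export
permute_block <- function(samples, block_index, seed) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < 2) stop("need at least 2 rows to permute")
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  out <- samples
  out[, block_index] <- samples[perm, block_index, drop = FALSE]
  out
}

# Deterministic substream derivation: keeps every derived seed a positive
# 32-bit integer so nested set.seed() calls are valid.
derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (i in ids) {
    s <- (s * 48271 + as.double(i) + 1) %% 2147483647
  }
  as.integer(s %% 2147483646) + 1L
}
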