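#' Multichannel time-series container
#'
#' Bundles a numeric matrix of uniformly sampled channels (rows = time,
#' columns = channels) with its sampling interval and a kind flag
#' distinguishing continuous-valued recordings from binary binned spike
#' trains. All estimation entry points of the package accept this container.
#'
#' @param values numeric matrix, `T x R` (time by channel).
#' @param dt sampling interval in seconds (metadata only; all lags are
#'   handled internally in samples). Defaults to 1.
#' @param channel_names optional character vector of channel identifiers;
#'   defaults to column names or `"ch1"`, `"ch2"`, ...
#' @param kind `"continuous"` or `"binary"`. If missing it is auto-detected:
#'   a matrix whose values all lie in \{0, 1\} is taken as binary.
#' @return An object of class `ts_set` with elements `values`, `dt`,
#'   `channel_names`, `kind`.
#' @examples
#' x <- ts_set(matrix(rnorm(40), 20, 2), dt = 0.01)
#' x$kind
#' @export
ts_set <- function(values, dt = 1, channel_names = NULL, kind = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (any(!is.finite(values))) stop("'values' contains non-finite entries")
  if (dt <= 0) stop("'dt' must be positive")
  if (is.null(channel_names)) {
    channel_names <- colnames(values)
    if (is.null(channel_names)) {
      channel_names <- paste0("ch", seq_len(ncol(values)))
    }
  }
  if (length(channel_names) != ncol(values)) {
    stop("length of 'channel_names' must match the number of channels")
  }
  is_binary <- all(values %in% c(0, 1))
  if (is.null(kind)) {
    kind <- if (is_binary) "binary" else "continuous"
  }
  kind <- match.arg(kind, c("continuous", "binary"))
  if (kind == "binary" && !is_binary) {
    stop("kind = 'binary' but values are not all in {0, 1}")
  }
  colnames(values) <- channel_names
  structure(
    list(values = values, dt = dt, channel_names = channel_names, kind = kind),
    class = "ts_set"
  )
}

#' @export
print.ts_set <- function(x, ...) {
  cat(sprintf(
    "<ts_set> %d samples x %d channels (%s, dt = %g s)\n",
    nrow(x$values), ncol(x$values), x$kind, x$dt
  ))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ts_set <- function(x) dim(x$values)

#' Bin spike times into a binary time-series set
#'
#' Converts a table of (unit, spike time) events into binary binned spike
#' trains: a bin takes value 1 when at least one spike of the unit falls in
#' it, 0 otherwise. Bins are half-open `[left, right)`, so a spike exactly on
#' an edge belongs to the later bin; multiple spikes in one bin clip to 1.
#'
#' @param spikes data frame (or matrix) whose first column is a unit
#'   identifier and second column a spike time in seconds.
#' @param bin_width bin width in seconds (e.g. 0.035 for 35 ms).
#' @param t_start,t_end analysis interval in seconds; spikes outside
#'   `[t_start, t_end)` are dropped (a message reports how many).
#' @param units optional vector fixing the channel set and order; unknown
#'   unit ids in `spikes` otherwise create channels in order of appearance.
#' @return A binary [ts_set] with `floor((t_end - t_start) / bin_width)`
#'   bins per unit and `dt = bin_width`.
#' @examples
#' sp <- data.frame(unit = 1, time = c(0.010, 0.012, 0.090))
#' bin_spike_trains(sp, 0.035, 0, 0.105)$values
#' @export
bin_spike_trains <- function(spikes, bin_width, t_start, t_end, units = NULL) {
  if (bin_width <= 0) stop("'bin_width' must be positive")
  if (t_end <= t_start) stop("'t_end' must exceed 't_start'")
  spikes <- as.data.frame(spikes)
  if (ncol(spikes) < 2) stop("'spikes' needs (unit, time) columns")
  unit <- spikes[[1]]
  time <- as.numeric(spikes[[2]])
  n_bins <- floor((t_end - t_start) / bin_width + 1e-9)
  if (n_bins < 1) stop("interval shorter than one bin")
  keep <- time >= t_start & time < t_start + n_bins * bin_width
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("bin_spike_trains: dropped %d spike(s) outside the binned interval", n_drop))
  }
  unit <- unit[keep]
  time <- time[keep]
  if (is.null(units)) units <- unique(c(unit))
  units <- as.character(units)
  mat <- matrix(0, nrow = n_bins, ncol = length(units),
                dimnames = list(NULL, units))
  if (length(time) > 0) {
    b <- floor((time - t_start) / bin_width) + 1L
    j <- match(as.character(unit), units)
    ok <- !is.na(j)
    mat[cbind(b[ok], j[ok])] <- 1
  }
  ts_set(mat, dt = bin_width, channel_names = units, kind = "binary")
}
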