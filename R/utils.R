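# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Frame indices covered by a half-open time window
#'
#' Maps a half-open window `[t0, t1)` in seconds onto 1-based frame indices of
#' a stream sampled at `rate` Hz whose first frame is at t = 0. Window edges
#' are frame-snapped: a frame at exactly `t0` is included, a frame at exactly
#' `t1` is excluded.
#'
#' @param t0,t1 window start and end in seconds, `t0 < t1`.
#' @param rate sampling rate in Hz.
#' @param n_frames optional stream length; when given, the window must fit.
#' @return integer vector of frame indices.
#' @export
frame_window <- function(t0, t1, rate, n_frames = NULL) {
  stopifnot(is.finite(t0), is.finite(t1), t0 < t1, rate > 0)
  i0 <- floor(t0 * rate + 1e-9) + 1L
  i1 <- ceiling(t1 * rate - 1e-9)
  if (i0 < 1L) stop("window starts before the stream (t0 = ", t0, ")")
  if (!is.null(n_frames) && i1 > n_frames) {
    stop(sprintf("window [%g, %g) s needs %d frames but stream has %d",
                 t0, t1, i1, n_frames))
  }
  seq.int(i0, i1)
}

# Deterministic per-trial substream seed derived from (session seed, index).
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, index, salt = 0L) {
  as.integer((abs(seed) * 1000003 + index * 7919 + salt * 104729) %% 2147483647)
}

# Euclidean distance between rows of an n x 2 matrix and a point c(x, y).
dist_to_point <- function(xy, p) {
  sqrt((xy[, 1L] - p[1L])^2 + (xy[, 2L] - p[2L])^2)
}

# Run-length encode a logical vector into episodes (start, end indices of
# TRUE runs); NA treated as FALSE.
true_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}
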