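#' Zero-phase low-pass Butterworth filtering
#'
#' Applies a second-order (by default) Butterworth low-pass filter forward
#' and backward (zero net phase; the magnitude response is applied twice, so
#' the gain at the cutoff is 0.5).  Edges are handled by odd reflection
#' padding so that constant signals pass through unchanged and edge
#' transients decay inside the padding, which is trimmed off.
#'
#' @param x Numeric vector (or matrix: columns filtered independently), no
#'   NaN/NA (gap-fill first, see [fill_marker_gaps()]).
#' @param rate Sampling rate, Hz.
#' @param config List with `cutoff` (Hz, default 5), `order` (default 2).
#' @return Filtered series, same dimensions as `x`.
#' @export
lowpass_zero_phase <- function(x, rate, config = list()) {
  cutoff <- config$cutoff %||% 5
  order <- config$order %||% 2
  if (!(cutoff > 0 && cutoff < rate / 2)) {
    stop("cutoff must lie in (0, Nyquist) = (0, ", rate / 2, ") Hz", call. = FALSE)
  }
  if (anyNA(x)) {
    stop("series contains missing samples; gap-fill before filtering",
         call. = FALSE)
  }
  if (is.matrix(x)) {
    return(apply(x, 2, lowpass_zero_phase, rate = rate, config = config))
  }
  n <- length(x)
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  pad <- min(n - 1L, max(3L * order, ceiling(3 * rate / cutoff)))
  if (pad < 1L) return(x)
  # remove the endpoint-connecting trend (a zero-phase low-pass preserves
  # it), filter the remainder with odd-reflection padding so transients
  # decay inside the trimmed-off edges, and restore the trend
  trend <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1)
  xr <- x - trend
  head_ext <- 2 * xr[1] - xr[seq(pad + 1L, 2L)]
  tail_ext <- 2 * xr[n] - xr[seq(n - 1L, n - pad)]
  xe <- c(head_ext, xr, tail_ext)
  yf <- signal::filter(bf, xe)
  yb <- rev(signal::filter(bf, rev(yf)))
  yb[seq(pad + 1L, pad + n)] + trend
}

#' Linear gap filling of missing marker samples
#'
#' Fills runs of `NA` by linear interpolation when the gap is at most
#' `max_gap_s` seconds; longer gaps are left missing and reported.
#'
#' @param x Numeric vector with possible `NA` runs.
#' @param rate Sampling rate, Hz.
#' @param max_gap_s Longest gap to fill, s (default 0.1).
#' @return List with `x` (filled series) and `unfilled` (logical mask of
#'   samples still missing).
#' @export
fill_marker_gaps <- function(x, rate, max_gap_s = 0.1) {
  if (!anyNA(x)) return(list(x = x, unfilled = rep(FALSE, length(x))))
  n <- length(x)
  idx <- which(!is.na(x))
  if (length(idx) < 2L) return(list(x = x, unfilled = is.na(x)))
  filled <- stats::approx(idx, x[idx], xout = seq_len(n), rule = 1)$y
  runs <- rle(is.na(x))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  unfilled <- rep(FALSE, n)
  max_len <- max_gap_s * rate
  for (i in seq_along(runs$lengths)) {
    if (runs$values[i] && runs$lengths[i] > max_len) {
      unfilled[starts[i]:ends[i]] <- TRUE
    }
  }
  filled[unfilled] <- NA_real_
  filled[is.na(filled) & !unfilled] <- NA_real_
  unfilled <- unfilled | is.na(filled)
  list(x = filled, unfilled = unfilled)
}
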