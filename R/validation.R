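#' Detect stance and swing from vertical ground reaction force
#'
#' Stance is where the vertical GRF exceeds `threshold`.  The series is
#' assumed to cover one gait cycle, heel-strike to heel-strike, and is
#' normalized to 0-100% cycle.
#'
#' @param fz Vertical GRF series, N.
#' @param threshold Stance threshold, N (default 20).
#' @return List with `stance_mask` (logical per frame), `stance_pct`
#'   (c(start, end) in % cycle), `pct` (per-frame % cycle).
#' @export
detect_gait_events <- function(fz, threshold = 20) {
  n <- length(fz)
  mask <- fz > threshold
  if (!any(mask)) {
    stop("vertical GRF never crosses the stance threshold (", threshold,
         " N); no gait events detectable", call. = FALSE)
  }
  pct <- seq(0, 100, length.out = n)
  idx <- which(mask)
  list(stance_mask = mask,
       stance_pct = c(pct[idx[1]], pct[idx[length(idx)]]),
       pct = pct)
}

# Resample a series (vector or columns of a matrix) onto the 101-point
# 0-100% cycle grid by monotone cubic interpolation.
resample_cycle <- function(x, n_out = 101L) {
  if (is.matrix(x)) return(apply(x, 2, resample_cycle, n_out = n_out))
  n <- length(x)
  if (n == n_out) return(x)
  s_in <- seq(0, 1, length.out = n)
  fn <- stats::splinefun(s_in, x, method = "monoH.FC")
  fn(seq(0, 1, length.out = n_out))
}

#' RMSE validation report for predicted vs measured hip contact force
#'
#' Resamples both series to a 101-point gait-cycle grid (monotone cubic) and
#' computes the root mean square error per femur-frame component (AP/ML/PD),
#' for the total force magnitude (`sqrt(AP^2+ML^2+PD^2)` per frame), and for
#' the total split into stance and swing.  Locates the two stance peaks of
#' the magnitude (largest local maximum in the 0-30% window = first /
#' loading peak; in 30-60% = second / terminal peak) and their errors.
#'
#' @param predicted,measured Frames x 3 matrices of AP/ML/PD components
#'   (BW).
#' @param events Gait events from [detect_gait_events()] (computed on the
#'   same cycle).
#' @param peak_windows List with `first` and `second` % windows (defaults
#'   `c(0, 30)` and `c(30, 60)`).
#' @return Object of class `validation_report`.
#' @export
rmse_report <- function(predicted, measured, events = NULL,
                        peak_windows = list(first = c(0, 30),
                                            second = c(30, 60))) {
  predicted <- as.matrix(predicted)
  measured <- as.matrix(measured)
  if (ncol(predicted) != 3L || ncol(measured) != 3L) {
    stop("HCF series must have 3 components (AP, ML, PD)", call. = FALSE)
  }
  pr <- resample_cycle(predicted)
  ms <- resample_cycle(measured)
  if (!all(dim(pr) == dim(ms))) {
    stop("predicted and measured series sizes differ after resampling",
         call. = FALSE)
  }
  pct <- seq(0, 100, length.out = nrow(pr))
  tot_p <- sqrt(rowSums(pr^2))
  tot_m <- sqrt(rowSums(ms^2))
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  comp <- vapply(1:3, function(j) rmse(pr[, j], ms[, j]), 0)
  names(comp) <- c("AP", "ML", "PD")

  stance_mask <- if (is.null(events)) rep(TRUE, length(pct)) else
    pct >= events$stance_pct[1] & pct <= events$stance_pct[2]

  peak_in <- function(x, win) {
    sel <- which(pct >= win[1] & pct <= win[2])
    if (length(sel) < 3L) return(NA_real_)
    xx <- x[sel]
    loc <- which(diff(sign(diff(xx))) < 0) + 1L
    if (length(loc) == 0L) loc <- which.max(xx)
    max(xx[loc])
  }
  peaks <- list(
    first_pred = peak_in(tot_p, peak_windows$first),
    first_meas = peak_in(tot_m, peak_windows$first),
    second_pred = peak_in(tot_p, peak_windows$second),
    second_meas = peak_in(tot_m, peak_windows$second))
  peaks$first_error <- peaks$first_pred - peaks$first_meas
  peaks$second_error <- peaks$second_pred - peaks$second_meas

  structure(list(
    rmse_total = rmse(tot_p, tot_m),
    rmse_component = comp,
    rmse_stance = rmse(tot_p[stance_mask], tot_m[stance_mask]),
    rmse_swing = if (all(stance_mask)) NA_real_ else
      rmse(tot_p[!stance_mask], tot_m[!stance_mask]),
    peaks = peaks,
    error_series = data.frame(pct_gc = pct, total_error_BW = tot_p - tot_m,
                              AP_error_BW = pr[, 1] - ms[, 1],
                              ML_error_BW = pr[, 2] - ms[, 2],
                              PD_error_BW = pr[, 3] - ms[, 3])),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  RMSE total: %.3f BW (stance %.3f, swing %s)\n",
              x$rmse_total, x$rmse_stance,
              if (is.na(x$rmse_swing)) "-" else sprintf("%.3f", x$rmse_swing)))
  cat(sprintf("  RMSE components AP/ML/PD: %.3f / %.3f / %.3f BW\n",
              x$rmse_component[1], x$rmse_component[2], x$rmse_component[3]))
  cat(sprintf("  peaks: first %.2f vs %.2f BW, second %.2f vs %.2f BW\n",
              x$peaks$first_pred, x$peaks$first_meas,
              x$peaks$second_pred, x$peaks$second_meas))
  invisible(x)
}

#' On-off intervals of a predicted muscle activation series
#'
#' Thresholds the activation over the gait cycle and debounces: on and off
#' runs shorter than `debounce_pct` of the cycle are merged into their
#' neighbours.
#'
#' @param activation Activation series over the cycle (any uniform grid).
#' @param on_threshold Absolute threshold; if `NULL` (default) uses
#'   `rel_threshold` times the cycle maximum.
#' @param rel_threshold Relative threshold (default 0.1).
#' @param debounce_pct Minimum on/off run length, % cycle (default 3).
#' @return Matrix with columns `on_pct`, `off_pct` (possibly 0 rows).
#' @export
activation_onoff <- function(activation, on_threshold = NULL,
                             rel_threshold = 0.1, debounce_pct = 3) {
  n <- length(activation)
  thr <- on_threshold %||% (rel_threshold * max(activation))
  if (max(activation) <= 0 || thr <= 0) {
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("on_pct", "off_pct"))))
  }
  mask <- activation > thr
  min_run <- max(1L, round(debounce_pct / 100 * n))
  runs <- rle(mask)
  for (i in seq_along(runs$lengths)) {
    if (runs$lengths[i] < min_run && i > 1L && i < length(runs$lengths)) {
      runs$values[i] <- !runs$values[i]
    }
  }
  mask <- inverse.rle(runs)
  runs <- rle(mask)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  pct <- seq(0, 100, length.out = n)
  keep <- which(runs$values)
  out <- cbind(on_pct = pct[starts[keep]], off_pct = pct[ends[keep]])
  out[out[, 2] > out[, 1], , drop = FALSE]
}

#' Compare predicted on-off intervals with reference EMG windows
#'
#' Each reference window (e.g. transcribed published EMG on-off timing) is
#' matched with the predicted interval overlapping it most; onset and offset
#' errors (% cycle, predicted minus reference) and the Jaccard overlap are
#' reported.
#'
#' @param intervals Predicted intervals from [activation_onoff()].
#' @param reference Matrix/data.frame with columns `on_pct`, `off_pct`.
#' @return Data frame: one row per reference window with `onset_error_pct`,
#'   `offset_error_pct`, `jaccard` (`NA` when unmatched).
#' @export
compare_timing <- function(intervals, reference) {
  reference <- as.matrix(reference)
  out <- data.frame(ref_on = reference[, 1], ref_off = reference[, 2],
                    onset_error_pct = NA_real_, offset_error_pct = NA_real_,
                    jaccard = NA_real_)
  if (nrow(intervals) == 0L || nrow(reference) == 0L) return(out)
  for (i in seq_len(nrow(reference))) {
    r <- reference[i, ]
    ov <- pmax(0, pmin(intervals[, 2], r[2]) - pmax(intervals[, 1], r[1]))
    j <- which.max(ov)
    if (ov[j] <= 0) next
    un <- max(intervals[j, 2], r[2]) - min(intervals[j, 1], r[1])
    out$onset_error_pct[i] <- intervals[j, 1] - r[1]
    out$offset_error_pct[i] <- intervals[j, 2] - r[2]
    out$jaccard[i] <- ov[j] / un
  }
  out
}
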