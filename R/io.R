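#' Write marker trajectories to a TRC file
#'
#' Standard tab-separated TRC layout (header with rates/counts/units, then
#' `Frame#`, `Time` and X/Y/Z triplets per marker), coordinates in meters.
#'
#' @param markers Named list: marker -> frames x 3 matrix (m).
#' @param rate Sampling rate, Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(markers, rate, path) {
  nms <- names(markers)
  nfr <- nrow(markers[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("PathFileType", "4", "(X/Y/Z)", basename(path),
                   sep = "\t"), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(paste(rate, rate, nfr, length(nms), "m", rate, 1, nfr,
                   sep = "\t"), con)
  writeLines(paste(c("Frame#", "Time",
                     unlist(lapply(nms, function(n) c(n, "", "")))),
                   collapse = "\t"), con)
  writeLines(paste(c("", "", unlist(lapply(seq_along(nms), function(i)
    paste0(c("X", "Y", "Z"), i)))), collapse = "\t"), con)
  writeLines("", con)
  times <- (seq_len(nfr) - 1L) / rate
  for (k in seq_len(nfr)) {
    vals <- unlist(lapply(markers, function(m) m[k, ]))
    writeLines(paste(c(k, format(times[k], digits = 10),
                       format(vals, digits = 10, trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read marker trajectories from a TRC file
#'
#' @param path TRC file path.
#' @return List with `markers` (named list of frames x 3 matrices, m) and
#'   `rate` (Hz).  Millimeter files are converted to meters.
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  meta <- strsplit(lines[3], "\t")[[1]]
  rate <- as.numeric(meta[1])
  units <- meta[5]
  hdr <- strsplit(lines[4], "\t")[[1]]
  nms <- hdr[-(1:2)]
  nms <- nms[nms != ""]
  data_lines <- lines[-(1:6)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  vals <- do.call(rbind, lapply(strsplit(data_lines, "\t"), function(x)
    as.numeric(x)))
  conv <- if (identical(tolower(units), "mm")) 1e-3 else 1
  markers <- list()
  for (i in seq_along(nms)) {
    cols <- 2L + (i - 1L) * 3L + (1:3)
    markers[[nms[i]]] <- vals[, cols, drop = FALSE] * conv
  }
  list(markers = markers, rate = rate)
}

#' Write ground reaction force records to CSV
#'
#' Long-per-frame wide-column layout: `time_s`, then per plate
#' `<plate>_fx/fy/fz` (N), `<plate>_copx/copy/copz` (m),
#' `<plate>_mx/my/mz` (N m).
#'
#' @param grf Per-plate list (`segment`, `force`, `cop`, `moment`).
#' @param time Frame times, s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grf_csv <- function(grf, time, path) {
  df <- data.frame(time_s = time)
  for (i in seq_along(grf)) {
    pl <- grf[[i]]
    tag <- pl$segment
    for (j in 1:3) {
      df[[paste0(tag, "_f", c("x", "y", "z")[j])]] <- pl$force[, j]
      df[[paste0(tag, "_cop", c("x", "y", "z")[j])]] <- pl$cop[, j]
      df[[paste0(tag, "_m", c("x", "y", "z")[j])]] <- pl$moment[, j]
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read ground reaction force records from CSV
#'
#' Inverse of [write_grf_csv()].
#'
#' @param path CSV path.
#' @return List with `grf` (per-plate list) and `time`.
#' @export
read_grf_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  time <- df$time_s
  tags <- unique(sub("_f[xyz]$", "",
                     grep("_f[xyz]$", names(df), value = TRUE)))
  grf <- lapply(tags, function(tag) {
    list(segment = tag,
         force = as.matrix(df[paste0(tag, "_f", c("x", "y", "z"))]),
         cop = as.matrix(df[paste0(tag, "_cop", c("x", "y", "z"))]),
         moment = as.matrix(df[paste0(tag, "_m", c("x", "y", "z"))]))
  })
  list(grf = grf, time = time)
}

#' Read a measured hip contact force series from CSV
#'
#' Expects columns `time_s` (or none) and the femur-frame components
#' `AP_BW`, `ML_BW`, `PD_BW` (instrumented-implant style export, body-weight
#' normalized).
#'
#' @param path CSV path.
#' @return Frames x 3 matrix (AP/ML/PD, BW), attribute `time_s` if present.
#' @export
read_hcf_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("AP_BW", "ML_BW", "PD_BW")
  if (!all(need %in% names(df))) {
    stop("measured HCF CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- as.matrix(df[need])
  colnames(out) <- c("AP", "ML", "PD")
  if ("time_s" %in% names(df)) attr(out, "time_s") <- df$time_s
  out
}

#' Assemble a gait trial from TRC + GRF CSV files
#'
#' @param trc_path Marker TRC file.
#' @param grf_path GRF CSV file (see [write_grf_csv()]).
#' @param hcf_path Optional measured HCF CSV (see [read_hcf_csv()]).
#' @return A `gait_trial` list usable with [run_pipeline()].
#' @export
read_trial <- function(trc_path, grf_path, hcf_path = NULL) {
  trc <- read_trc(trc_path)
  grf <- read_grf_csv(grf_path)
  structure(list(time = grf$time, rate = trc$rate, markers = trc$markers,
                 grf = grf$grf,
                 measured_hcf = if (!is.null(hcf_path)) read_hcf_csv(hcf_path),
                 truth = NULL),
            class = "gait_trial")
}
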