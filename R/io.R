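# Readers and writers for the session's on-disk formats: pose CSV in the
# common pose-estimation export dialect (two header rows: bodypart,
# coordinate), event-log CSV, ground-truth JSON, and multi-page TIFF movies
# with a JSON metadata sidecar.

#' Write pose tracks as CSV
#'
#' Layout mirrors common markerless-pose exports: a `frame` column followed
#' by x / y / likelihood triplets per bodypart, with two header rows naming
#' the bodypart and the coordinate.
#'
#' @param tracks a `pose_tracks`.
#' @param path output file.
#' @export
write_pose_csv <- function(tracks, path) {
  kps <- names(tracks$keypoints)
  header1 <- c("frame", rep(kps, each = 3L))
  header2 <- c("frame", rep(c("x", "y", "likelihood"), times = length(kps)))
  cols <- lapply(tracks$keypoints, function(kp) {
    cbind(kp$x, kp$y, kp$confidence)
  })
  mat <- do.call(cbind, cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(header1, collapse = ","),
               paste(header2, collapse = ",")), con)
  utils::write.table(cbind(seq_len(nrow(mat)) - 1L, mat), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read pose tracks from CSV
#'
#' @param path file written by [write_pose_csv()] (or any export in the
#'   same two-header-row dialect).
#' @param rate sampling rate in Hz (not stored in the CSV; default 60).
#' @return a `pose_tracks`.
#' @export
read_pose_csv <- function(path, rate = 60) {
  header <- readLines(path, n = 2L)
  h1 <- strsplit(header[1L], ",", fixed = TRUE)[[1L]]
  h2 <- strsplit(header[2L], ",", fixed = TRUE)[[1L]]
  dat <- utils::read.csv(path, skip = 2L, header = FALSE)
  kps <- unique(h1[-1L])
  keypoints <- lapply(kps, function(kp) {
    cidx <- which(h1 == kp)
    stats::setNames(
      lapply(cidx, function(j) dat[[j]]),
      ifelse(h2[cidx] == "likelihood", "confidence", h2[cidx])
    )
  })
  names(keypoints) <- kps
  pose_tracks(keypoints, rate = rate)
}

#' Write / read a session event log
#'
#' @param log event-log data.frame (see [generate_session()]).
#' @param path CSV file.
#' @export
write_event_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  utils::read.csv(path)
}

#' Write / read simulator ground truth as JSON
#'
#' @param ground_truth ground-truth data.frame from [generate_session()].
#' @param path JSON file.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, dataframe = "rows", digits = NA,
                       na = "null", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a strobed stack as multi-page TIFF plus JSON sidecar
#'
#' Frames are stored as 16-bit grayscale pages holding the raw 12-bit
#' values losslessly; the sidecar records frame rate, channel order, bit
#' depth and pixel size.
#'
#' @param stack a `strobed_stack`.
#' @param path TIFF file; the sidecar is written next to it as
#'   `<path>.json`.
#' @export
write_strobed_tiff <- function(stack, path) {
  pages <- lapply(seq_len(nrow(stack$frames)), function(i) {
    matrix(stack$frames[i, ] / 65535, stack$h, stack$w)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(combined_rate_hz = stack$combined_rate,
         channel_order = stack$channel_order,
         bit_depth = 12L,
         pixel_size_um = stack$pixel_size_um,
         height = stack$h, width = stack$w,
         n_frames = nrow(stack$frames)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_strobed_tiff
#' @export
read_strobed_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- do.call(rbind, lapply(pages, function(p) as.vector(round(p * 65535))))
  strobed_stack(frames, h = meta$height, w = meta$width,
                combined_rate = meta$combined_rate_hz,
                channel_order = meta$channel_order,
                pixel_size_um = meta$pixel_size_um)
}
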