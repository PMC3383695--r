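#' Read a space-time image from disk
#'
#' Reads line-scan data from a single-page grayscale TIFF (rows = time,
#' columns = space) or from a delimited numeric text file (comma, tab or
#' whitespace separated, same orientation).
#'
#' @param path Path to the file.
#' @param calibration A \code{\link{scan_calibration}} to attach.
#' @param deinterlace If \code{TRUE} and the calibration declares
#'   bidirectional scanning, every second row (0-based odd rows) is flipped
#'   left-right so all scans share one orientation. The data are assumed to be
#'   otherwise resampled to a common pixel grid upstream.
#'
#' @return A \code{\link{line_scan_series}}.
#' @seealso \code{\link{write_spacetime}}
#' @export
read_spacetime <- function(path, calibration, deinterlace = FALSE) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  m <- if (is_tiff_file(path)) read_spacetime_tiff(path) else read_spacetime_text(path)
  if (!is.matrix(m)) stop(sprintf("'%s': data are not a 2-D matrix", path))
  if (nrow(m) < 2L) stop(sprintf("'%s': need at least 2 line-scans", path))
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("'%s': non-finite value at row %d, column %d",
                 path, bad[1L], bad[2L]))
  }
  if (deinterlace && calibration$scan_direction == "bidirectional") {
    odd <- seq(2L, nrow(m), by = 2L)  # 0-based odd rows
    m[odd, ] <- m[odd, ncol(m):1L, drop = FALSE]
  }
  line_scan_series(m, calibration)
}

is_tiff_file <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) return(TRUE)
  magic <- readBin(path, "raw", n = 4L)
  length(magic) == 4L &&
    (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
     identical(magic[1:2], as.raw(c(0x4d, 0x4d))))
}

read_spacetime_tiff <- function(path) {
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) stop(sprintf("cannot read '%s' as TIFF: %s",
                                                  path, conditionMessage(e))))
  if (is.list(img)) stop(sprintf("'%s': multi-page TIFF not supported", path))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] == 1L) img <- img[, , 1L] else
      stop(sprintf("'%s': expected a grayscale (single-channel) TIFF", path))
  }
  storage.mode(img) <- "double"
  img
}

read_spacetime_text <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  df <- tryCatch(utils::read.table(path, header = FALSE, sep = sep),
                 error = function(e) stop(sprintf("cannot parse '%s': %s",
                                                 path, conditionMessage(e))))
  if (!all(vapply(df, is.numeric, TRUE))) {
    stop(sprintf("'%s': non-numeric cells in delimited input", path))
  }
  unname(as.matrix(df))
}

#' Write a space-time image to disk
#'
#' The TIFF writer stores 16-bit grayscale. Integer data already in
#' \code{[0, 65535]} round-trip exactly through
#' \code{\link{read_spacetime}}; anything else is affinely rescaled to the
#' full 16-bit range (the analysis pipeline is invariant to affine intensity
#' maps, so this is harmless for velocimetry). Text output (\code{.csv},
#' \code{.tsv} or anything else) writes the values verbatim.
#'
#' @param series A \code{\link{line_scan_series}} (or bare numeric matrix).
#' @param path Destination; format chosen by extension.
#' @return Invisibly, \code{path}.
#' @export
write_spacetime <- function(series, path) {
  m <- if (inherits(series, "line_scan_series")) series$data else series
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (all(m >= 0 & m <= 65535) && all(m == round(m))) {
      tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
    } else {
      rng <- range(m)
      scaled <- if (rng[2L] > rng[1L]) (m - rng[1L]) / (rng[2L] - rng[1L]) else m * 0
      tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
    }
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    utils::write.table(m, path, sep = sep, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a velocity trace as delimited text
#'
#' One header row (\code{time_s, velocity_mm_s, peak_quality, outlier_flag})
#' and one row per velocity point. Values survive a write/read round trip to
#' at least 6 significant digits.
#'
#' @param trace A non-empty \code{\link{velocity_trace}}.
#' @param path Destination CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_velocity_trace <- function(trace, path) {
  if (!inherits(trace, "velocity_trace")) stop("trace must be a velocity_trace")
  if (nrow(trace) == 0L) stop("cannot write an empty velocity trace")
  df <- data.frame(time_s = format_sig(trace$time_s),
                   velocity_mm_s = format_sig(trace$velocity_mm_s),
                   peak_quality = format_sig(trace$peak_quality),
                   outlier_flag = as.integer(trace$outlier_flag))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write velocity trace to '%s'", path))
  invisible(path)
}

format_sig <- function(x, digits = 10L) {
  out <- formatC(x, digits = digits, format = "g")
  out[!is.finite(x) & !is.na(x)] <- as.character(x[!is.finite(x) & !is.na(x)])
  out[is.na(x)] <- "NA"
  out
}

#' Read a velocity trace written by \code{\link{write_velocity_trace}}
#'
#' @param path CSV path with columns \code{time_s, velocity_mm_s,
#'   peak_quality, outlier_flag}.
#' @return A \code{\link{velocity_trace}} (with \code{shift_px} set to
#'   \code{NA}: the file format does not carry the pixel shift).
#' @export
read_velocity_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "velocity_mm_s", "peak_quality", "outlier_flag")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s' is not a velocity trace file (missing columns: %s)",
                 path, paste(setdiff(need, names(df)), collapse = ", ")))
  }
  velocity_trace(df$time_s, df$velocity_mm_s,
                 peak_quality = df$peak_quality,
                 outlier_flag = as.logical(df$outlier_flag))
}
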