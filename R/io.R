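#' Read and write intensity traces as CSV
#'
#' The on-disk format has columns `time_s`, `intensity`, `channel`.
#'
#' @param path File path.
#' @return `read_intensity_csv()` returns a tibble with those columns
#'   and, when the grid is uniform, a `frame_interval` attribute.
#' @export
read_intensity_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "intensity")
  if (!all(need %in% names(df))) {
    abort("CSV must have columns time_s, intensity (and optional channel).",
          class = "curvesense_format_error")
  }
  if (is.null(df$channel)) df$channel <- 0L
  out <- tibble::as_tibble(df[, c("time_s", "intensity", "channel")])
  t0 <- sort(unique(out$time_s))
  dt <- diff(t0)
  if (length(dt) > 0 && max(abs(dt - dt[1])) <= 1e-9 * max(dt[1], 1)) {
    attr(out, "frame_interval") <- dt[1]
  }
  out
}

#' @rdname read_intensity_csv
#' @param traces A tibble with `time_s`, `intensity` and optionally
#'   `channel`.
#' @export
write_intensity_csv <- function(traces, path) {
  df <- as.data.frame(traces)
  if (is.null(df$channel)) df$channel <- 0L
  utils::write.csv(df[, c("time_s", "intensity", "channel")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read and write images and movies as (multi-page) TIFF
#'
#' Images are stored as 16-bit unsigned integer TIFF, the standard
#' container for photon-count microscopy data: values are rounded to
#' integers and must lie in \[0, 65535\]. A movie or multi-channel stack
#' becomes one page per frame.
#'
#' @param path File path.
#' @return `read_image_tiff()` returns a matrix for a single page or a
#'   `[rows, cols, pages]` array for a multi-page file, in counts.
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) == 1L) return(pages[[1]])
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  arr
}

#' @rdname read_image_tiff
#' @param img A matrix, a `[rows, cols, pages]` array, or a list of
#'   matrices.
#' @export
write_image_tiff <- function(img, path) {
  pages <- if (is.list(img)) {
    img
  } else if (length(dim(img)) == 3) {
    purrr::map(seq_len(dim(img)[3]), function(i) img[, , i])
  } else {
    list(unclass(img))
  }
  rng <- range(unlist(purrr::map(pages, range)))
  if (rng[1] < 0 || rng[2] > 65535) {
    abort("image values must lie in [0, 65535] for 16-bit TIFF export.",
          class = "curvesense_format_error")
  }
  pages <- purrr::map(pages, function(p) round(p) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Write a ground-truth sidecar for a simulated dataset
#'
#' Stores the generating parameters (and any geometry table) as JSON next
#' to the exported images/traces, so downstream recovery can be checked
#' against exact truth.
#'
#' @param x A simulated object (`nanobar_field`, or any trace/alignment
#'   with a `ground_truth` attribute) or a bare params list.
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(x, path) {
  payload <- if (inherits(x, "nanobar_field")) {
    list(params = unclass(x$params), geometry = x$geometry)
  } else if (!is.null(attr(x, "ground_truth"))) {
    gt <- attr(x, "ground_truth")
    list(params = unclass(gt))
  } else {
    list(params = unclass(x))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
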