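#' Extract a region-of-interest intensity trace from a movie
#'
#' Averages pixel intensities over a square region of interest in every
#' frame of an image time series, the standard readout for wave-phase
#' analysis (a ~2 x 2 um square inside the cell). No background
#' subtraction is applied at this stage.
#'
#' @param movie Numeric array `[rows, cols, frames]` with at least 8
#'   frames.
#' @param center ROI centre, `c(row, col)` in 0-based pixel-centre
#'   coordinates.
#' @param side_px ROI side length in pixels.
#' @param frame_interval Frame interval in seconds.
#' @param channel Optional channel label stored on the trace.
#' @return A tibble with columns `time_s`, `intensity`, `channel` and a
#'   `frame_interval` attribute.
#' @export
extract_roi_trace <- function(movie, center, side_px, frame_interval,
                              channel = 0L) {
  stopifnot(length(dim(movie)) == 3)
  if (dim(movie)[3] < 8L) {
    abort("movie must have at least 8 frames.",
          class = "curvesense_invalid_parameters")
  }
  half <- (side_px - 1) / 2
  r0 <- round(center[1] - half); r1 <- round(center[1] + half)
  c0 <- round(center[2] - half); c1 <- round(center[2] + half)
  if (r0 < 0 || c0 < 0 || r1 > dim(movie)[1] - 1 ||
      c1 > dim(movie)[2] - 1) {
    abort("ROI extends outside the image bounds.",
          class = "curvesense_geometry_error")
  }
  vals <- apply(movie[(r0:r1) + 1, (c0:c1) + 1, , drop = FALSE],
                3, mean)
  n <- length(vals)
  new_tibble_trace(time_s = (seq_len(n) - 1) * frame_interval,
                   intensity = vals, channel = channel,
                   frame_interval = frame_interval)
}

trace_interval <- function(trace) {
  fi <- attr(trace, "frame_interval")
  if (!is.null(fi)) return(fi)
  dt <- diff(trace$time_s)
  if (length(dt) == 0L) {
    abort("trace too short.", class = "curvesense_invalid_parameters")
  }
  if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt[1]), 1)) {
    abort("trace times must be uniformly spaced.",
          class = "curvesense_invalid_parameters")
  }
  dt[1]
}

#' Remove slow baseline drift from a trace
#'
#' Subtracts a centred moving average of span `window` seconds. At the
#' trace edges the window shrinks symmetrically, so no samples are
#' dropped. Detrending stabilises the cross-correlation of short drifting
#' traces; it attenuates oscillations only mildly when the window matches
#' the oscillation period (a one-period moving average of a sinusoid
#' leaves the sinusoid nearly intact while removing trends).
#'
#' @param trace A tibble with `time_s` and `intensity` (one channel).
#' @param window Moving-average span in seconds (default 25 s, one typical
#'   wave period). Must cover at least 2 frames.
#' @return A tibble like `trace` with detrended `intensity`.
#' @export
detrend_trace <- function(trace, window = 25) {
  dt <- trace_interval(trace)
  if (window < 2 * dt) {
    abort("`window` must span at least two frames.",
          class = "curvesense_invalid_parameters")
  }
  half <- max(1L, round(window / (2 * dt)))
  out <- trace
  out$intensity <- trace$intensity -
    moving_average_shrink(trace$intensity, half)
  attr(out, "frame_interval") <- dt
  out
}

#' Inter-channel phase shift by normalized cross-correlation
#'
#' Computes the Pearson-normalized cross-correlation between two traces on
#' the same sampling grid, over every integer lag within `max_lag`. Each
#' lag correlates only the overlapping segment, which avoids the
#' wrap-around artefacts of circular (FFT) correlation on short drifting
#' traces. The lag of the maximum is returned; with `subsample = TRUE` a
#' parabola through the peak and its two neighbours refines the lag below
#' the frame interval. Ties on the maximum correlation are broken towards
#' the smaller absolute lag.
#'
#' Sign convention: a positive lag means the first trace peaks *after* the
#' second (trace `a` lags trace `b`).
#'
#' @param a,b Tibbles with `time_s` and `intensity`, identical grids.
#' @param max_lag Maximum |lag| scanned, in seconds. Must be below half
#'   the trace duration; defaults to a quarter of the duration. For
#'   periodic signals choose `max_lag` below half a period so the global
#'   peak is unambiguous.
#' @param detrend Detrend both traces first (default `TRUE`, window
#'   `detrend_window`). The correlation of raw drifting traces is
#'   dominated by the shared trend; this choice is reversible.
#' @param detrend_window Detrending span in seconds.
#' @param smooth_window Matched low-pass span in seconds (0 = off, the
#'   default). At sampling much faster than the signal bandwidth the
#'   per-sample noise floor makes adjacent correlation lags
#'   indistinguishable; a centred moving average well below the pulse
#'   width (e.g. a quarter of it), applied identically to both traces,
#'   suppresses that floor without biasing the delay.
#' @param subsample Refine the peak below the frame interval by 3-point
#'   parabolic interpolation.
#' @return A list of class `phase_shift`: `lag` (seconds),
#'   `peak_correlation`, `interpolated`, `frame_interval`, and
#'   `correlation_curve`, a tibble of `lag_s` and `correlation` over the
#'   scanned grid.
#' @examples
#' tr <- simulate_wave_traces(wave_params(phase_offsets = c(0, 5),
#'   noise_sd = 0.1, seed = 4))
#' a <- dplyr::filter(tr, channel == 1)
#' b <- dplyr::filter(tr, channel == 0)
#' xcorr_lag(a, b, max_lag = 10)$lag  # ~ +5 s: channel 1 lags channel 0
#' @export
xcorr_lag <- function(a, b, max_lag = NULL, detrend = TRUE,
                      detrend_window = 25, smooth_window = 0,
                      subsample = FALSE) {
  dt <- trace_interval(a)
  dtb <- trace_interval(b)
  if (nrow(a) != nrow(b) || abs(dt - dtb) > 1e-9 * dt ||
      max(abs(a$time_s - b$time_s)) > 1e-9 * max(dt, 1)) {
    abort("traces must share the same sampling grid.",
          class = "curvesense_grid_error")
  }
  n <- nrow(a)
  duration <- (n - 1) * dt
  if (is.null(max_lag)) max_lag <- duration / 4
  if (max_lag >= duration / 2) {
    abort("`max_lag` must be below half the trace duration.",
          class = "curvesense_invalid_parameters")
  }
  if (detrend) {
    a <- detrend_trace(a, detrend_window)
    b <- detrend_trace(b, detrend_window)
  }
  x <- a$intensity; y <- b$intensity
  if (smooth_window > 0) {
    half_sm <- max(1L, round(smooth_window / (2 * dt)))
    x <- moving_average_shrink(x, half_sm)
    y <- moving_average_shrink(y, half_sm)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero-variance trace: correlation undefined.",
          class = "curvesense_degenerate_signal")
  }
  kmax <- floor(max_lag / dt + 1e-9)
  lags <- -kmax:kmax
  r <- vapply(lags, function(k) {
    if (k >= 0) {
      xa <- x[(k + 1):n]; yb <- y[1:(n - k)]
    } else {
      xa <- x[1:(n + k)]; yb <- y[(1 - k):n]
    }
    if (sd(xa) == 0 || sd(yb) == 0) return(NA_real_)
    cor(xa, yb)
  }, numeric(1))
  best <- which(r >= max(r, na.rm = TRUE) - 1e-12)
  best <- best[which.min(abs(lags[best]))]
  lag <- lags[best] * dt
  peak <- r[best]
  interpolated <- FALSE
  if (subsample && best > 1L && best < length(lags) &&
      all(is.finite(r[(best - 1):(best + 1)]))) {
    pp <- parabolic_peak(r[best - 1], r[best], r[best + 1])
    lag <- lag + pp$offset * dt
    peak <- min(pp$value, 1)
    interpolated <- TRUE
  }
  structure(list(lag = lag, peak_correlation = peak,
                 interpolated = interpolated, frame_interval = dt,
                 correlation_curve = tibble::tibble(lag_s = lags * dt,
                                                    correlation = r)),
            class = "phase_shift")
}

#' @export
print.phase_shift <- function(x, ...) {
  cat(sprintf("<phase_shift> lag %.3f s (r = %.3f%s)\n", x$lag,
              x$peak_correlation,
              if (x$interpolated) ", sub-frame" else ""))
  invisible(x)
}

#' Phase shift by reference-peak alignment
#'
#' An estimator of the inter-channel shift independent of
#' [xcorr_lag()]: peaks are detected on the detrended reference trace,
#' windows around each reference peak are extracted from both traces and
#' averaged on the relative-time grid, and the location of the follower's
#' mean-profile maximum (parabolically refined) estimates the shift.
#'
#' @param reference,follower Tibbles with `time_s` and `intensity` on the
#'   same grid.
#' @param min_prominence Peak prominence threshold as a fraction of the
#'   detrended reference's amplitude range (default 0.3).
#' @param half_window Half-width of the extracted window, seconds.
#' @param detrend_window Detrending span in seconds.
#' @return A list of class `aligned_profile`: `profile` (tibble of
#'   `rel_time_s`, `reference_mean`, `follower_mean`), `n_peaks`, and
#'   `follower_shift`, the follower peak location in seconds.
#' @export
align_peaks <- function(reference, follower, min_prominence = 0.3,
                        half_window = 12, detrend_window = 25) {
  dt <- trace_interval(reference)
  ref_d <- detrend_trace(reference, detrend_window)
  fol_d <- detrend_trace(follower, detrend_window)
  rng <- diff(range(ref_d$intensity))
  peaks <- find_peaks(ref_d$intensity, min_prominence * rng)
  hw <- round(half_window / dt)
  n <- nrow(ref_d)
  peaks <- peaks[peaks - hw >= 1 & peaks + hw <= n]
  if (length(peaks) < 3L) {
    abort("fewer than 3 usable peaks in the reference trace.",
          class = "curvesense_insufficient_peaks")
  }
  win <- -hw:hw
  ref_mat <- vapply(peaks, function(p) ref_d$intensity[p + win],
                    numeric(length(win)))
  fol_mat <- vapply(peaks, function(p) fol_d$intensity[p + win],
                    numeric(length(win)))
  ref_mean <- rowMeans(ref_mat)
  fol_mean <- rowMeans(fol_mat)
  imax <- which.max(fol_mean)
  shift <- win[imax] * dt
  if (imax > 1L && imax < length(win)) {
    shift <- shift + parabolic_peak(fol_mean[imax - 1], fol_mean[imax],
                                    fol_mean[imax + 1])$offset * dt
  }
  structure(list(profile = tibble::tibble(rel_time_s = win * dt,
                                          reference_mean = ref_mean,
                                          follower_mean = fol_mean),
                 n_peaks = length(peaks),
                 follower_shift = shift),
            class = "aligned_profile")
}

#' @export
print.aligned_profile <- function(x, ...) {
  cat(sprintf("<aligned_profile> %d peaks, follower shift %+.3f s\n",
              x$n_peaks, x$follower_shift))
  invisible(x)
}

#' Summarize a set of phase-shift estimates
#'
#' @param shifts A list of `phase_shift` objects, or a numeric vector of
#'   lags in seconds.
#' @return A one-row tibble: `mean_lag_s`, `sem_lag_s` (NA for n = 1),
#'   `n`.
#' @export
summarize_phase <- function(shifts) {
  lags <- if (is.numeric(shifts)) shifts else {
    vapply(shifts, function(s) s$lag, numeric(1))
  }
  if (length(lags) == 0L) {
    abort("no phase shifts supplied.",
          class = "curvesense_invalid_parameters")
  }
  tibble::tibble(mean_lag_s = mean(lags), sem_lag_s = sem(lags),
                 n = length(lags))
}
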