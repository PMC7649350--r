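#' Parameters for simulated cortical-wave intensity traces
#'
#' Describes an oscillatory protein-recruitment signal as seen in a small
#' region of interest on the cell cortex: a periodic waveform (raised-cosine
#' pulse train by default, mimicking transient protein puncta whose lifetime
#' is much shorter than the oscillation period, or a pure sinusoid for
#' closed-form checks), sampled uniformly, with per-channel phase offsets,
#' additive Gaussian noise, and a slow linear baseline drift.
#'
#' @param period Oscillation period in seconds. Cortical waves of BAR-domain
#'   proteins cycle every 20-30 s; the default is 25 s.
#' @param amplitude Peak signal amplitude in arbitrary fluorescence units.
#' @param phase_offsets Numeric vector of per-channel delays in seconds,
#'   relative to channel 0. Channel k is channel 0 delayed by
#'   `phase_offsets[k]` (positive = peaks later).
#' @param frame_interval Sampling interval in seconds.
#' @param duration Total trace duration in seconds; must be at least three
#'   periods so a cross-correlation sees several repeats.
#' @param noise_sd Gaussian noise standard deviation, as a fraction of
#'   `amplitude`.
#' @param baseline_drift Linear drift slope, as a fraction of `amplitude`
#'   per period.
#' @param waveform `"pulse"` for a raised-cosine pulse train (default) or
#'   `"sinusoid"`.
#' @param pulse_width Width of each raised-cosine pulse in seconds (the
#'   protein's dwell time per cycle, about 8 s); must be shorter than the
#'   period. Ignored for the sinusoid.
#' @param seed Integer seed; all random draws for one dataset flow from it.
#'
#' @return A validated `wave_params` list.
#' @seealso [simulate_wave_traces()]
#' @export
wave_params <- function(period = 25, amplitude = 100,
                        phase_offsets = c(0, 1),
                        frame_interval = 1, duration = 150,
                        noise_sd = 0.05, baseline_drift = 0,
                        waveform = c("pulse", "sinusoid"),
                        pulse_width = 8, seed = 1L) {
  waveform <- match.arg(waveform)
  stop_if_not_scalar_pos(period, "period")
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  stop_if_not_scalar_pos(duration, "duration")
  stop_if_not_scalar_pos(amplitude, "amplitude")
  if (duration < 3 * period) {
    abort("`duration` must be at least 3 periods.",
          class = "curvesense_invalid_parameters")
  }
  if (waveform == "pulse" && pulse_width >= period) {
    abort("`pulse_width` must be smaller than `period`.",
          class = "curvesense_invalid_parameters")
  }
  if (!is.numeric(phase_offsets) || length(phase_offsets) < 1L) {
    abort("`phase_offsets` must be a numeric vector (one entry per channel).",
          class = "curvesense_invalid_parameters")
  }
  structure(list(period = period, amplitude = amplitude,
                 phase_offsets = phase_offsets,
                 frame_interval = frame_interval, duration = duration,
                 noise_sd = noise_sd, baseline_drift = baseline_drift,
                 waveform = waveform, pulse_width = pulse_width,
                 seed = as.integer(seed)),
            class = "wave_params")
}

wave_profile <- function(t, params) {
  if (params$waveform == "sinusoid") {
    params$amplitude * 0.5 * (1 + sin(2 * pi * t / params$period))
  } else {
    u <- t %% params$period
    ifelse(u < params$pulse_width,
           params$amplitude * 0.5 *
             (1 - cos(2 * pi * u / params$pulse_width)),
           0)
  }
}

#' Simulate multi-channel wave traces with known phase offsets
#'
#' Generates one intensity trace per entry of `phase_offsets`, all on the
#' same sampling grid. Channel k is the noiseless base waveform delayed by
#' `phase_offsets[k]` seconds, with baseline drift and Gaussian noise added
#' independently per channel. With a fixed seed the output is bit-identical
#' across runs.
#'
#' @param params A [wave_params()] object.
#' @return A tibble with columns `time_s`, `intensity`, `channel`
#'   (0-based integer) and attributes `frame_interval` and `ground_truth`
#'   (the generating parameters).
#' @examples
#' tr <- simulate_wave_traces(wave_params(phase_offsets = c(0, 5),
#'                                        noise_sd = 0, seed = 2))
#' @export
simulate_wave_traces <- function(params) {
  stopifnot(inherits(params, "wave_params"))
  t <- seq(0, params$duration, by = params$frame_interval)
  local_seed(params$seed)
  drift_per_s <- params$baseline_drift * params$amplitude / params$period
  pieces <- purrr::imap(params$phase_offsets, function(off, k) {
    clean <- wave_profile(t - off, params) + drift_per_s * t
    noisy <- clean + rnorm(length(t), 0,
                           params$noise_sd * params$amplitude)
    tibble::tibble(time_s = t, intensity = noisy, channel = k - 1L)
  })
  out <- dplyr::bind_rows(pieces)
  attr(out, "frame_interval") <- params$frame_interval
  attr(out, "ground_truth") <- params
  out
}

#' Extract one channel from a multi-channel trace tibble
#'
#' Filters `channel == k` and preserves the `frame_interval` attribute.
#'
#' @param traces Tibble with `time_s`, `intensity`, `channel`.
#' @param k Channel index.
#' @return A single-channel trace tibble.
#' @export
trace_channel <- function(traces, k) {
  out <- dplyr::filter(traces, .data$channel == k)
  if (nrow(out) == 0L) {
    abort(sprintf("no channel %s in traces.", k),
          class = "curvesense_invalid_parameters")
  }
  attr(out, "frame_interval") <- attr(traces, "frame_interval")
  out
}

#' Render simulated wave traces as a movie
#'
#' Builds a small image time series whose pixels inside a central square
#' follow the given channel's trace (plus independent pixel noise), so the
#' region-of-interest extraction step can be exercised end to end.
#'
#' @param trace A single-channel tibble with `time_s` and `intensity`.
#' @param nx,ny Image dimensions in pixels.
#' @param roi_half Half-side of the bright central square, in pixels.
#' @param pixel_noise_sd Per-pixel Gaussian noise SD in intensity units.
#' @param seed Integer seed.
#' @return A numeric array `[ny, nx, n_frames]`.
#' @export
trace_to_movie <- function(trace, nx = 24, ny = 24, roi_half = 5,
                           pixel_noise_sd = 0, seed = 1L) {
  n <- nrow(trace)
  local_seed(seed)
  arr <- array(0, dim = c(ny, nx, n))
  cy <- floor(ny / 2); cx <- floor(nx / 2)
  rows <- (cy - roi_half):(cy + roi_half) + 1L
  cols <- (cx - roi_half):(cx + roi_half) + 1L
  for (i in seq_len(n)) {
    frame <- matrix(0, ny, nx)
    frame[rows, cols] <- trace$intensity[i]
    if (pixel_noise_sd > 0) {
      frame <- frame + matrix(rnorm(ny * nx, 0, pixel_noise_sd), ny, nx)
    }
    arr[, , i] <- frame
  }
  arr
}

## seed the RNG for the calling function only, restoring the caller's state
local_seed <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(NULL)
}
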