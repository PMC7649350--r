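#' Parameters for a simulated FRAP trace
#'
#' Single-exponential fluorescence recovery after photobleaching: the
#' normalized intensity sits at 1 before the bleach, drops instantaneously
#' to `1 - bleach_depth`, and recovers as
#' \deqn{I(t) = (1 - d) + d \cdot m \cdot (1 - 2^{-t/t_{1/2}})}
#' where `d` is the bleach depth, `m` the mobile fraction and `t` the time
#' since the bleach. Gaussian noise is added on top.
#'
#' @param t_half Recovery half-time in seconds.
#' @param mobile_fraction Fraction of the bleached signal that exchanges,
#'   in \[0, 1\]. Zero gives the "no detectable recovery" regime.
#' @param bleach_depth Fractional intensity loss at the bleach, in \[0, 1\].
#' @param pre_bleach_frames Number of frames acquired before the bleach.
#' @param frame_interval Sampling interval in seconds (default 2 s).
#' @param duration Post-bleach observation window in seconds (default
#'   120 s, a 2-minute experiment).
#' @param noise_sd Gaussian noise SD as a fraction of the pre-bleach
#'   intensity.
#' @param seed Integer seed.
#' @return A validated `frap_params` list.
#' @export
frap_params <- function(t_half = 9, mobile_fraction = 1,
                        bleach_depth = 0.8, pre_bleach_frames = 5L,
                        frame_interval = 2, duration = 120,
                        noise_sd = 0.02, seed = 1L) {
  stop_if_not_scalar_pos(t_half, "t_half")
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  stop_if_not_scalar_pos(duration, "duration")
  if (mobile_fraction < 0 || mobile_fraction > 1) {
    abort("`mobile_fraction` must lie in [0, 1].",
          class = "curvesense_invalid_parameters")
  }
  if (bleach_depth < 0 || bleach_depth > 1) {
    abort("`bleach_depth` must lie in [0, 1].",
          class = "curvesense_invalid_parameters")
  }
  if (pre_bleach_frames < 1L) {
    abort("`pre_bleach_frames` must be at least 1.",
          class = "curvesense_invalid_parameters")
  }
  structure(list(t_half = t_half, mobile_fraction = mobile_fraction,
                 bleach_depth = bleach_depth,
                 pre_bleach_frames = as.integer(pre_bleach_frames),
                 frame_interval = frame_interval, duration = duration,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "frap_params")
}

#' Simulate a FRAP recovery trace
#'
#' @param params A [frap_params()] object.
#' @return A tibble with columns `time_s`, `intensity` and attributes
#'   `bleach_index` (1-based index of the first post-bleach frame) and
#'   `ground_truth`. The noiseless trace is monotonically non-decreasing
#'   after the bleach.
#' @examples
#' fr <- simulate_frap_trace(frap_params(t_half = 35, seed = 7))
#' @export
simulate_frap_trace <- function(params) {
  stopifnot(inherits(params, "frap_params"))
  pre_t <- seq_len(params$pre_bleach_frames) * params$frame_interval
  post_t <- seq(0, params$duration, by = params$frame_interval)
  t <- c(pre_t - params$frame_interval, max(pre_t) + post_t)
  n_pre <- params$pre_bleach_frames
  d <- params$bleach_depth
  clean <- c(rep(1, n_pre),
             (1 - d) + d * params$mobile_fraction *
               (1 - 2^(-post_t / params$t_half)))
  local_seed(params$seed)
  noisy <- clean + rnorm(length(clean), 0, params$noise_sd)
  out <- tibble::tibble(time_s = t, intensity = noisy)
  attr(out, "bleach_index") <- n_pre + 1L
  attr(out, "ground_truth") <- params
  out
}
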