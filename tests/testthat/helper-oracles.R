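## Independent oracles used across the suite. These deliberately use
## plain loops and direct formulas, not the package's vectorized paths.

## brute-force normalized cross-correlation: explicit loop over integer
## lags, Pearson r on the overlapping segment only
bf_xcorr <- function(x, y, kmax) {
  lags <- -kmax:kmax
  n <- length(x)
  r <- numeric(length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    if (k >= 0) {
      xs <- x[(k + 1):n]; ys <- y[1:(n - k)]
    } else {
      xs <- x[1:(n + k)]; ys <- y[(1 - k):n]
    }
    r[i] <- suppressWarnings(stats::cor(xs, ys))
  }
  list(lags = lags, r = r)
}

## brute-force lag scan: lag (in samples) maximizing bf correlation,
## smaller |lag| on ties
bf_best_lag <- function(x, y, kmax) {
  bf <- bf_xcorr(x, y, kmax)
  best <- which(bf$r >= max(bf$r, na.rm = TRUE) - 1e-12)
  bf$lags[best[which.min(abs(bf$lags[best]))]]
}

## brute-force Mann-Whitney U for sample a: pairwise wins + half-ties
bf_u_stat <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) {
    u <- u + (x > y) + 0.5 * (x == y)
  }
  u
}

## exact two-sided Mann-Whitney p by full enumeration of group labelings
## (no ties assumed); feasible for small n only
bf_u_pvalue <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  obs <- bf_u_stat(a, b)
  mu <- na * length(b) / 2
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(idx) {
    bf_u_stat(pooled[idx], pooled[-idx])
  })
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

## two-channel wave pair on a shared grid, returning each channel with
## its frame_interval attribute intact
wave_pair <- function(offset, frame_interval, noise_sd, seed,
                      duration = 150, period = 25, ...) {
  tr <- simulate_wave_traces(wave_params(
    phase_offsets = c(0, offset), frame_interval = frame_interval,
    noise_sd = noise_sd, duration = duration, period = period,
    seed = seed, ...))
  list(ref = trace_channel(tr, 0), lagged = trace_channel(tr, 1))
}

## small single-width nanobar field for fast tests
small_field <- function(enrichment = 1.4, n_bars = 8, width = 300,
                        seed = 1, noise_model = "poisson", ...) {
  simulate_nanobar_field(nanobar_field_params(
    widths = width, bars_per_width = n_bars,
    end_enrichment = enrichment, noise_model = noise_model,
    seed = seed, ...))
}
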