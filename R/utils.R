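## internal numerical helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name),
          class = "curvesense_invalid_parameters")
  }
  invisible(x)
}

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  sd(x) / sqrt(length(x))
}

## centred moving average whose window shrinks symmetrically at the edges,
## so the filtered value at index i always averages i +/- k usable points
moving_average_shrink <- function(x, half_width) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(half_width, i - 1L, n - i)
    out[i] <- (cs[i + k + 1L] - cs[i - k]) / (2L * k + 1L)
  }
  out
}

## 3-point parabolic interpolation around a discrete maximum; returns the
## sub-sample offset in [-0.5, 0.5] and the interpolated peak value
parabolic_peak <- function(y_m1, y_0, y_p1) {
  denom <- y_m1 - 2 * y_0 + y_p1
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) {
    return(list(offset = 0, value = y_0))
  }
  offset <- 0.5 * (y_m1 - y_p1) / denom
  offset <- max(-0.5, min(0.5, offset))
  value <- y_0 - 0.25 * (y_m1 - y_p1) * offset
  list(offset = offset, value = value)
}

## local maxima with topographic prominence (standard water-level walk):
## a peak's prominence is its height minus the highest minimum separating
## it from a higher peak (or from the trace edge)
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(idx) == 0L) return(integer(0))
  prom <- vapply(idx, function(i) {
    h <- x[i]
    left_min <- h
    j <- i
    while (j > 1L) {
      j <- j - 1L
      if (x[j] > h) break
      left_min <- min(left_min, x[j])
    }
    if (j == 1L && x[1L] <= h) left_min <- min(left_min, x[1L])
    right_min <- h
    j <- i
    while (j < n) {
      j <- j + 1L
      if (x[j] > h) break
      right_min <- min(right_min, x[j])
    }
    if (j == n && x[n] <= h) right_min <- min(right_min, x[n])
    h - min(max(left_min, right_min), h)
  }, numeric(1))
  idx[prom >= min_prominence]
}

## circular 2-D Gaussian convolution via FFT; conserves the image sum exactly
## (the kernel is normalised and the convolution is cyclic)
gaussian_blur_fft <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  gx <- gaussian_kernel_1d(nr, sigma_px)
  gy <- gaussian_kernel_1d(nc, sigma_px)
  kern <- outer(gx, gy)
  kern <- kern / sum(kern)
  re <- fft(fft(img) * fft(kern), inverse = TRUE) / (nr * nc)
  Re(re)
}

gaussian_kernel_1d <- function(n, sigma) {
  ## centred at index 1 with wrap-around, as FFT convolution expects
  d <- c(0:(n %/% 2), -(ceiling(n / 2) - 1):-1)
  if (n == 1L) d <- 0
  exp(-d^2 / (2 * sigma^2))
}

## bilinear sample of matrix `img` at (row, col) positions given in 0-based
## pixel-centre coordinates; positions outside the image return `fill`
bilinear_sample <- function(img, r, c, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- function(ri, ci) {
    ok <- ri >= 0 & ri <= nr - 1 & ci >= 0 & ci <= nc - 1
    out <- rep(fill, length(ri))
    out[ok] <- img[cbind(ri[ok] + 1, ci[ok] + 1)]
    out
  }
  v00 <- val(r0, c0); v01 <- val(r0, c0 + 1)
  v10 <- val(r0 + 1, c0); v11 <- val(r0 + 1, c0 + 1)
  ## treat out-of-range neighbours as nearest in-range value
  v01 <- ifelse(is.na(v01), v00, v01)
  v10 <- ifelse(is.na(v10), v00, v10)
  v11 <- ifelse(is.na(v11), v01, v11)
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

new_tibble_trace <- function(time_s, intensity, channel, frame_interval) {
  out <- tibble::tibble(time_s = time_s, intensity = intensity,
                        channel = channel)
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("intensity_trace", class(out))
  out
}
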