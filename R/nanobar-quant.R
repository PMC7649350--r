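## FFT cross-correlation of an image with a small centred template:
## out[p] = sum_q T[q] * img[p + q - centre]; cyclic at the borders
fft_correlate <- function(img, tmpl) {
  nr <- nrow(img); nc <- ncol(img)
  tr <- nrow(tmpl); tc <- ncol(tmpl)
  ci <- (tr + 1) %/% 2; cj <- (tc + 1) %/% 2
  K <- matrix(0, nr, nc)
  ri <- ((seq_len(tr) - ci) %% nr) + 1
  cjx <- ((seq_len(tc) - cj) %% nc) + 1
  K[ri, cjx] <- tmpl
  Re(fft(fft(img) * Conj(fft(K)), inverse = TRUE)) / (nr * nc)
}

## bar appearance model for matched filtering: unit interior plus a
## brighter one-pixel wall outline, blurred to the expected PSF
stadium_template <- function(width_nm, length_nm, pixel_size,
                             psf_sigma = 150, wall_weight = 5) {
  half_seg <- (length_nm - width_nm) / 2
  ext <- ceiling((length_nm / 2 + pixel_size) / pixel_size)
  ax <- (-ext:ext) * pixel_size
  drm <- matrix(ax, length(ax), length(ax))
  dcm <- t(drm)
  d <- segment_distance(drm, dcm, 0, half_seg)
  tmpl <- (d <= width_nm / 2) * 1 +
    (abs(d - width_nm / 2) <= pixel_size / 2) * wall_weight
  gaussian_blur_fft(tmpl, max(psf_sigma / pixel_size, 0.5))
}

rotate_template <- function(tmpl, orientation) {
  if (abs(orientation) < 1e-12) return(tmpl)
  n <- nrow(tmpl)
  ctr <- (n - 1) / 2
  idx <- seq_len(n) - 1
  drm <- matrix(idx - ctr, n, n)
  dcm <- t(drm)
  co <- cos(orientation); si <- sin(orientation)
  src_r <- ctr + drm * co - dcm * si
  src_c <- ctr + drm * si + dcm * co
  matrix(bilinear_sample(tmpl, as.vector(src_r), as.vector(src_c),
                         fill = 0), n, n)
}

#' Detect nanobars in a lipid-channel image by matched filtering
#'
#' Cross-correlates the image with a stadium-shaped bar template at the
#' expected orientation (normalized cross-correlation, so the score is
#' insensitive to local gain and offset), picks correlation maxima above
#' `threshold` separated by at least half a pitch, and refines each centre
#' to sub-pixel precision with a parabolic fit through the correlation
#' peak. Bars whose footprint touches the image border are discarded.
#'
#' @param lipid_image Numeric matrix, lipid (membrane) channel.
#' @param expected Named list with `width`, `length`, `pitch` (nm) and
#'   optionally `orientation` (radians, default 0 = long axis vertical).
#' @param pixel_size Pixel size in nm/pixel.
#' @param threshold Minimum normalized correlation for a detection
#'   (default 0.75; true bars typically score above 0.95 while
#'   between-bar sidelobes stay near 0.7).
#' @param psf_sigma Expected PSF sigma in nm used to blur the template.
#' @return A tibble of geometries (`bar`, `row`, `col` 0-based pixel
#'   centres, `orientation`, `width_nm`, `length_nm`, `pixel_size`);
#'   empty, with a warning, when nothing scores above threshold.
#' @export
detect_nanobars <- function(lipid_image, expected, pixel_size,
                            threshold = 0.75, psf_sigma = 150) {
  orientation <- expected$orientation %||% 0
  tmpl <- rotate_template(
    stadium_template(expected$width, expected$length, pixel_size,
                     psf_sigma = psf_sigma),
    orientation)
  t0 <- tmpl - mean(tmpl)
  denom_t <- sqrt(sum(t0^2))
  nt <- length(tmpl)
  nr <- nrow(lipid_image); nc <- ncol(lipid_image)
  num <- fft_correlate(lipid_image, t0)
  ones <- matrix(1, nrow(tmpl), ncol(tmpl))
  s1 <- fft_correlate(lipid_image, ones)
  s2 <- fft_correlate(lipid_image^2, ones)
  var_local <- pmax(s2 - s1^2 / nt, 0)
  r <- num / (sqrt(var_local) * denom_t)
  r[var_local <= 1e-9 * max(var_local)] <- 0

  min_sep <- 0.6 * expected$pitch / pixel_size
  border <- (expected$length / 2 + expected$width) / pixel_size
  ## strict 3x3 local maxima above threshold
  is_max <- r >= threshold
  sh <- function(m, dr, dc) {
    out <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (r >= sh(r, dr, dc))
  }
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    warn("no nanobar candidates above threshold.")
    return(empty_geometry())
  }
  ord <- order(r[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(kept) > 0 &&
        any((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2 < min_sep^2)) {
      next
    }
    kept <- rbind(kept, p)
  }
  ## sub-pixel refinement and border filtering
  geo <- purrr::map_dfr(seq_len(nrow(kept)), function(i) {
    ri <- kept[i, 1]; ci <- kept[i, 2]
    row <- ri - 1; col <- ci - 1
    if (ri > 1 && ri < nr) {
      row <- row + parabolic_peak(r[ri - 1, ci], r[ri, ci],
                                  r[ri + 1, ci])$offset
    }
    if (ci > 1 && ci < nc) {
      col <- col + parabolic_peak(r[ri, ci - 1], r[ri, ci],
                                  r[ri, ci + 1])$offset
    }
    tibble::tibble(row = row, col = col, score = r[ri, ci])
  })
  geo <- dplyr::filter(geo,
                       .data$row >= border, .data$row <= nr - 1 - border,
                       .data$col >= border, .data$col <= nc - 1 - border)
  if (nrow(geo) == 0L) {
    warn("all nanobar candidates touch the image border.")
    return(empty_geometry())
  }
  geo <- dplyr::arrange(geo, .data$col, .data$row)
  tibble::tibble(bar = seq_len(nrow(geo)), row = geo$row, col = geo$col,
                 orientation = orientation, width_nm = expected$width,
                 length_nm = expected$length, pixel_size = pixel_size,
                 score = geo$score)
}

empty_geometry <- function() {
  tibble::tibble(bar = integer(0), row = numeric(0), col = numeric(0),
                 orientation = numeric(0), width_nm = numeric(0),
                 length_nm = numeric(0), pixel_size = numeric(0),
                 score = numeric(0))
}

#' Crop, rotate and background-subtract individual nanobars
#'
#' Each bar is resampled (bilinear interpolation, rotation and sub-pixel
#' shift applied in a single mapping) onto a canonical upright grid — long
#' axis vertical, bar centre at the grid centre — and the local background,
#' the median intensity in an annulus 2-4 bar widths from the bar axis, is
#' subtracted.
#'
#' @param image Numeric matrix (one channel).
#' @param geometries Geometry tibble as returned by [detect_nanobars()] or
#'   carried by a simulated field; all rows must share one nominal width.
#' @param margin_nm Margin added around the bar footprint in the crop
#'   (default one bar width).
#' @param background `"annulus"` (default) or `"none"`.
#' @param annulus_nm Inner and outer annulus radii in nm measured from the
#'   bar axis; defaults to `c(2, 4) * width`.
#' @return An object of class `bar_crops`: a 3-D array
#'   `[rows, cols, bar]` of registered background-subtracted crops, with
#'   `width_nm`, `length_nm`, `pixel_size` and per-bar `background`
#'   attributes.
#' @export
register_bars <- function(image, geometries, margin_nm = NULL,
                          background = c("annulus", "none"),
                          annulus_nm = NULL) {
  background <- match.arg(background)
  if (nrow(geometries) == 0L) {
    abort("no geometries supplied.",
          class = "curvesense_invalid_parameters")
  }
  w <- unique(geometries$width_nm)
  if (length(w) != 1L) {
    abort("all bars must share one nominal width; got several.",
          class = "curvesense_mixed_widths")
  }
  len <- geometries$length_nm[1]
  px <- geometries$pixel_size[1]
  margin_nm <- margin_nm %||% w
  half_al <- ceiling((len / 2 + margin_nm) / px)
  half_ac <- ceiling((w / 2 + margin_nm) / px)
  out_r <- 2 * half_al + 1
  out_c <- 2 * half_ac + 1
  al <- (-half_al:half_al) * px
  ac <- (-half_ac:half_ac) * px
  alm <- matrix(al, out_r, out_c)
  acm <- matrix(ac, out_r, out_c, byrow = TRUE)
  if (is.null(annulus_nm)) annulus_nm <- c(2, 4) * w

  crops <- array(NA_real_, dim = c(out_r, out_c, nrow(geometries)))
  bgs <- numeric(nrow(geometries))
  for (i in seq_len(nrow(geometries))) {
    g <- geometries[i, ]
    co <- cos(g$orientation); si <- sin(g$orientation)
    src_r <- g$row + (alm * co - acm * si) / px
    src_c <- g$col + (alm * si + acm * co) / px
    crop <- matrix(bilinear_sample(image, as.vector(src_r),
                                   as.vector(src_c), fill = NA_real_),
                   out_r, out_c)
    bg <- 0
    if (background == "annulus") {
      bg <- annulus_background(image, g, annulus_nm)
    }
    bgs[i] <- bg
    crops[, , i] <- crop - bg
  }
  structure(crops, class = "bar_crops", width_nm = w, length_nm = len,
            pixel_size = px, background = bgs)
}

annulus_background <- function(image, g, annulus_nm) {
  px <- g$pixel_size
  ext <- ceiling((g$length_nm / 2 + annulus_nm[2] + px) / px)
  nr <- nrow(image); nc <- ncol(image)
  rows <- max(0, floor(g$row) - ext):min(nr - 1, ceiling(g$row) + ext)
  cols <- max(0, floor(g$col) - ext):min(nc - 1, ceiling(g$col) + ext)
  drm <- matrix((rows - g$row) * px, length(rows), length(cols))
  dcm <- matrix((cols - g$col) * px, length(rows), length(cols),
                byrow = TRUE)
  d <- segment_distance(drm, dcm, g$orientation,
                        (g$length_nm - g$width_nm) / 2)
  ring <- d >= annulus_nm[1] & d <= annulus_nm[2]
  sub <- image[rows + 1, cols + 1]
  median(sub[ring], na.rm = TRUE)
}

#' Average registered nanobar crops
#'
#' @param image Numeric matrix (one channel), or a `bar_crops` object.
#' @param geometries Geometry tibble (ignored when `image` is already a
#'   `bar_crops`).
#' @param ... Passed to [register_bars()].
#' @return An object of class `averaged_bar_image`: the pixel-wise mean
#'   crop with `n_bars`, `width_nm`, `length_nm`, `pixel_size`
#'   attributes.
#' @export
average_bars <- function(image, geometries = NULL, ...) {
  crops <- if (inherits(image, "bar_crops")) image else {
    register_bars(image, geometries, ...)
  }
  avg <- apply(unclass(crops), c(1, 2), mean, na.rm = TRUE)
  structure(avg, class = "averaged_bar_image",
            n_bars = dim(crops)[3],
            width_nm = attr(crops, "width_nm"),
            length_nm = attr(crops, "length_nm"),
            pixel_size = attr(crops, "pixel_size"))
}

#' @export
print.averaged_bar_image <- function(x, ...) {
  cat(sprintf("<averaged_bar_image> %d bars, width %g nm, %d x %d px\n",
              attr(x, "n_bars"), attr(x, "width_nm"), nrow(x), ncol(x)))
  invisible(x)
}

#' End and center analysis masks for a nanobar
#'
#' The end mask is two discs of diameter `width + 2 * dilation` centred on
#' the cap centres, located `(length - width) / 2` from the bar centre
#' along the axis. The center mask is an axis-aligned rectangle of width
#' `width + 2 * dilation` covering the central 40% of the bar length; when
#' the dilated end discs would intrude into that rectangle (wide bars),
#' the rectangle is shortened to keep a one-pixel gap, never below 20% of
#' the bar length. The masks are guaranteed disjoint or an error is
#' raised.
#'
#' @param width_nm,length_nm Bar width and tip-to-tip length in nm.
#' @param pixel_size Pixel size in nm/pixel.
#' @param dim Output mask dimensions `c(rows, cols)`; the bar centre sits
#'   at the grid centre (canonical upright frame).
#' @param dilation_nm Mask dilation in nm (default 150, about one PSF
#'   sigma, so the blurred cap signal is captured).
#' @param center_fraction Fraction of the bar length the center rectangle
#'   aims to cover (default 0.4).
#' @return A list with logical matrices `end` and `center`.
#' @export
bar_masks <- function(width_nm, length_nm, pixel_size, dim,
                      dilation_nm = 150, center_fraction = 0.4) {
  if (length_nm <= width_nm) {
    abort("bar length must exceed width.",
          class = "curvesense_geometry_error")
  }
  half_seg <- (length_nm - width_nm) / 2
  rad <- width_nm / 2 + dilation_nm
  inner_reach <- half_seg - rad             # closest approach of the discs
  center_half <- min(center_fraction / 2 * length_nm,
                     inner_reach - pixel_size)
  if (center_half < 0.1 * length_nm) {
    abort("end and center masks overlap: bar too short for this dilation.",
          class = "curvesense_geometry_error")
  }
  ctr_r <- (dim[1] - 1) / 2
  ctr_c <- (dim[2] - 1) / 2
  al <- (seq_len(dim[1]) - 1 - ctr_r) * pixel_size
  ac <- (seq_len(dim[2]) - 1 - ctr_c) * pixel_size
  alm <- matrix(al, dim[1], dim[2])
  acm <- matrix(ac, dim[1], dim[2], byrow = TRUE)
  end <- pmin((alm - half_seg)^2 + acm^2,
              (alm + half_seg)^2 + acm^2) <= rad^2
  center <- abs(alm) <= center_half & abs(acm) <= rad
  if (any(end & center)) {
    abort("end and center masks overlap.",
          class = "curvesense_geometry_error")
  }
  list(end = end, center = center)
}

mask_means <- function(img, masks) {
  c(end = mean(img[masks$end], na.rm = TRUE),
    center = mean(img[masks$center], na.rm = TRUE))
}

#' End-to-center fluorescence ratio
#'
#' The primary curvature-preference statistic: mean background-subtracted
#' intensity over the two curved cap regions divided by the mean over the
#' flat bar middle. On a stack of per-bar crops the ratio is computed per
#' bar and summarized (mean, SEM over bars); on an averaged image a single
#' ratio is returned. A uniform image gives exactly 1.
#'
#' @param x A `bar_crops` stack or an `averaged_bar_image`.
#' @param dilation_nm Mask dilation in nm (see [bar_masks()]).
#' @param ... Unused.
#' @return A tibble of class `ratio_result`: `end_to_center_ratio`,
#'   `sem`, `n_bars`, with per-bar ratios in the `per_bar` attribute
#'   (crops input only).
#' @export
end_center_ratio <- function(x, dilation_nm = 150, ...) {
  UseMethod("end_center_ratio")
}

#' @export
end_center_ratio.bar_crops <- function(x, dilation_nm = 150, ...) {
  masks <- bar_masks(attr(x, "width_nm"), attr(x, "length_nm"),
                     attr(x, "pixel_size"), dim(x)[1:2], dilation_nm)
  per_bar <- vapply(seq_len(dim(x)[3]), function(i) {
    m <- mask_means(x[, , i], masks)
    if (!is.finite(m["center"]) || m["center"] <= 0) {
      abort("center intensity not positive after background subtraction.",
            class = "curvesense_degenerate_signal")
    }
    m["end"] / m["center"]
  }, numeric(1))
  out <- tibble::tibble(end_to_center_ratio = mean(per_bar),
                        sem = sem(per_bar), n_bars = length(per_bar))
  attr(out, "per_bar") <- per_bar
  class(out) <- c("ratio_result", class(out))
  out
}

#' @export
end_center_ratio.averaged_bar_image <- function(x, dilation_nm = 150,
                                                ...) {
  masks <- bar_masks(attr(x, "width_nm"), attr(x, "length_nm"),
                     attr(x, "pixel_size"), dim(x), dilation_nm)
  m <- mask_means(unclass(x), masks)
  if (!is.finite(m["center"]) || m["center"] <= 0) {
    abort("center intensity not positive after background subtraction.",
          class = "curvesense_degenerate_signal")
  }
  out <- tibble::tibble(end_to_center_ratio = unname(m["end"] / m["center"]),
                        sem = NA_real_, n_bars = attr(x, "n_bars"))
  class(out) <- c("ratio_result", class(out))
  out
}

#' @export
end_center_ratio.matrix <- function(x, dilation_nm = 150, width_nm,
                                    length_nm, pixel_size, ...) {
  masks <- bar_masks(width_nm, length_nm, pixel_size, dim(x), dilation_nm)
  m <- mask_means(x, masks)
  if (!is.finite(m["center"]) || m["center"] <= 0) {
    abort("center intensity not positive after background subtraction.",
          class = "curvesense_degenerate_signal")
  }
  out <- tibble::tibble(end_to_center_ratio = unname(m["end"] / m["center"]),
                        sem = NA_real_, n_bars = 1L)
  class(out) <- c("ratio_result", class(out))
  out
}

#' Lipid-normalized nanobar-end protein density
#'
#' Protein intensity at the curved bar ends per unit lipid intensity at
#' the same location, which cancels the membrane surface-area differences
#' across bar widths. Inputs must be registered on the same canonical
#' grid (same geometry).
#'
#' @param protein,lipid `averaged_bar_image`s or `bar_crops` stacks of
#'   the same geometry (the crops variant pairs bars by index and yields
#'   per-bar densities with an SEM).
#' @param dilation_nm Mask dilation in nm.
#' @return A one-row tibble: `density`, `sem` (NA for averaged input),
#'   `n_bars`.
#' @export
end_density <- function(protein, lipid, dilation_nm = 150) {
  same_dims <- all(dim(protein)[1:2] == dim(lipid)[1:2])
  if (!same_dims || attr(protein, "width_nm") != attr(lipid, "width_nm")) {
    abort("protein and lipid inputs must share geometry and registration.",
          class = "curvesense_geometry_error")
  }
  masks <- bar_masks(attr(protein, "width_nm"), attr(protein, "length_nm"),
                     attr(protein, "pixel_size"), dim(protein)[1:2],
                     dilation_nm)
  if (inherits(protein, "bar_crops") && inherits(lipid, "bar_crops")) {
    if (dim(protein)[3] != dim(lipid)[3]) {
      abort("protein and lipid crop stacks must pair the same bars.",
            class = "curvesense_geometry_error")
    }
    dens <- vapply(seq_len(dim(protein)[3]), function(i) {
      le <- mean(lipid[, , i][masks$end], na.rm = TRUE)
      if (!is.finite(le) || le <= 0) {
        abort("lipid end intensity not positive.",
              class = "curvesense_degenerate_signal")
      }
      mean(protein[, , i][masks$end], na.rm = TRUE) / le
    }, numeric(1))
    return(tibble::tibble(density = mean(dens), sem = sem(dens),
                          n_bars = length(dens)))
  }
  le <- mean(unclass(lipid)[masks$end], na.rm = TRUE)
  if (!is.finite(le) || le <= 0) {
    abort("lipid end intensity not positive.",
          class = "curvesense_degenerate_signal")
  }
  pe <- mean(unclass(protein)[masks$end], na.rm = TRUE)
  tibble::tibble(density = pe / le, sem = NA_real_,
                 n_bars = attr(protein, "n_bars") %||% 1L)
}

#' Nanobar-end density across bar widths
#'
#' Applies [end_density()] per width and assembles the density-vs-width
#' profile used to read out curvature preference (protein binding per
#' unit membrane as a function of cap curvature, which is set by the bar
#' width).
#'
#' @param datasets A list; each element is a list with components
#'   `width` (nm), `protein` and `lipid` (paired `bar_crops` or
#'   `averaged_bar_image`s).
#' @param dilation_nm Mask dilation in nm.
#' @param rescale Divide all densities by the largest-width value for
#'   cross-protein display (default `FALSE`).
#' @return A tibble of class `density_profile` sorted by width:
#'   `width_nm`, `density`, `sem`, `n_bars`.
#' @export
width_profile <- function(datasets, dilation_nm = 150, rescale = FALSE) {
  if (length(datasets) < 2L) {
    abort("need at least two widths for a profile.",
          class = "curvesense_invalid_parameters")
  }
  rows <- purrr::map_dfr(datasets, function(d) {
    if (is.null(d$lipid)) {
      abort("missing lipid channel for one width.",
            class = "curvesense_invalid_parameters")
    }
    dens <- end_density(d$protein, d$lipid, dilation_nm)
    tibble::tibble(width_nm = d$width, density = dens$density,
                   sem = dens$sem, n_bars = dens$n_bars)
  })
  rows <- dplyr::arrange(rows, .data$width_nm)
  if (anyDuplicated(rows$width_nm)) {
    abort("duplicate widths in profile.",
          class = "curvesense_invalid_parameters")
  }
  if (rescale) {
    ref <- rows$density[nrow(rows)]
    rows <- dplyr::mutate(rows, density = .data$density / ref,
                          sem = .data$sem / ref)
  }
  class(rows) <- c("density_profile", class(rows))
  rows
}
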