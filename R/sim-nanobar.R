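#' Parameters for a simulated nanobar supported-lipid-bilayer field
#'
#' Forward model of a confocal image of a lithographic nanobar array coated
#' with a supported lipid bilayer (SLB). Each nanobar is a stadium-shaped
#' structure (rectangle with two half-circle caps whose curvature diameter
#' equals the bar width). The projected membrane density is 1 everywhere
#' (flat SLB around the bars and membrane draped over the flat bar top),
#' plus `wall_factor` on the one-pixel bar outline, standing in for the
#' vertical sidewall membrane collapsed into the imaging plane. The protein
#' channel is the membrane map multiplied by a width-specific enrichment
#' factor on the curved cap regions; both channels are blurred with a
#' Gaussian point-spread function and noised.
#'
#' @param widths Bar widths in nm (one or several; several widths are laid
#'   out in separate column blocks). Defaults to the 200-600 nm gradient in
#'   100 nm steps.
#' @param bars_per_width Number of bars fabricated per width.
#' @param bar_length Tip-to-tip bar length in nm (default 2000 nm).
#' @param bar_height Bar height in nm (default 600 nm); sets the default
#'   sidewall contribution.
#' @param pitch Center-to-center bar spacing in nm, both directions; must
#'   exceed the bar footprint.
#' @param pixel_size Physical pixel size in nm/pixel.
#' @param psf_sigma Gaussian PSF sigma in nm.
#' @param wall_factor Extra projected membrane per outline pixel. Default
#'   `bar_height / pixel_size`: the sidewall area of one outline pixel
#'   divided by the pixel footprint.
#' @param end_enrichment Either a single factor applied to all widths or a
#'   named vector mapping width (nm, as names) to the multiplicative
#'   protein enrichment on cap regions. Values must be >= 0; 1 means no
#'   curvature preference.
#' @param intensity Photon scale: expected counts per unit membrane
#'   density.
#' @param background Constant background level in counts.
#' @param noise_model `"poisson"` (shot noise on expected counts, gain 1,
#'   the default), `"gaussian"` (additive, SD = `noise_sd`) or `"none"`.
#' @param noise_sd Gaussian noise SD in counts (used when
#'   `noise_model = "gaussian"`).
#' @param position_jitter Uniform sub-pixel placement jitter, half-range in
#'   nm, applied independently per bar.
#' @param seed Integer seed.
#' @return A validated `nanobar_field_params` list.
#' @export
nanobar_field_params <- function(widths = seq(200, 600, by = 100),
                                 bars_per_width = 60,
                                 bar_length = 2000, bar_height = 600,
                                 pitch = 3000, pixel_size = 50,
                                 psf_sigma = 150,
                                 wall_factor = bar_height / pixel_size,
                                 end_enrichment = 1,
                                 intensity = 1000, background = 100,
                                 noise_model = c("poisson", "gaussian",
                                                 "none"),
                                 noise_sd = 20,
                                 position_jitter = 0, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (any(widths <= 0)) {
    abort("all `widths` must be positive.",
          class = "curvesense_invalid_parameters")
  }
  if (bar_length <= max(widths)) {
    abort("`bar_length` must exceed the largest width.",
          class = "curvesense_invalid_parameters")
  }
  if (pitch <= bar_length) {
    abort("`pitch` smaller than the bar footprint: bars would overlap.",
          class = "curvesense_overlap_error")
  }
  enr <- enrichment_for_widths(end_enrichment, widths)
  if (any(enr < 0)) {
    abort("`end_enrichment` values must be >= 0.",
          class = "curvesense_invalid_parameters")
  }
  structure(list(widths = widths, bars_per_width = as.integer(bars_per_width),
                 bar_length = bar_length, bar_height = bar_height,
                 pitch = pitch, pixel_size = pixel_size,
                 psf_sigma = psf_sigma, wall_factor = wall_factor,
                 end_enrichment = end_enrichment, intensity = intensity,
                 background = background, noise_model = noise_model,
                 noise_sd = noise_sd, position_jitter = position_jitter,
                 seed = as.integer(seed)),
            class = "nanobar_field_params")
}

enrichment_for_widths <- function(end_enrichment, widths) {
  if (length(end_enrichment) == 1L && is.null(names(end_enrichment))) {
    return(setNames(rep(as.numeric(end_enrichment), length(widths)),
                    as.character(widths)))
  }
  key <- as.character(widths)
  if (!all(key %in% names(end_enrichment))) {
    abort("`end_enrichment` must name every width.",
          class = "curvesense_invalid_parameters")
  }
  setNames(as.numeric(end_enrichment[key]), key)
}

## signed distance from pixel centres to the bar's medial segment, in nm;
## the stadium footprint is dist <= width/2
segment_distance <- function(drow_nm, dcol_nm, orientation, half_seg_nm) {
  ## axis unit vector (CCW from the vertical/row axis)
  ar <- cos(orientation); ac <- sin(orientation)
  along <- drow_nm * ar + dcol_nm * ac
  across <- -drow_nm * ac + dcol_nm * ar
  clamped <- pmax(pmin(along, half_seg_nm), -half_seg_nm)
  sqrt((along - clamped)^2 + across^2)
}

#' Simulate a two-channel nanobar SLB image with ground truth
#'
#' @param params A [nanobar_field_params()] object.
#' @return A list of class `nanobar_field` with elements `lipid` and
#'   `protein` (numeric matrices, counts), `clean_lipid` / `clean_protein`
#'   (the noiseless expectations, for oracle computations), and `geometry`,
#'   a tibble of exact bar ground truth: `bar`, `row`, `col` (0-based
#'   pixel-centre coordinates), `orientation` (radians), `width_nm`,
#'   `length_nm`, `pixel_size`, `enrichment`.
#' @examples
#' fld <- simulate_nanobar_field(nanobar_field_params(widths = 300,
#'   bars_per_width = 4, end_enrichment = 1.4, seed = 3))
#' @export
simulate_nanobar_field <- function(params) {
  stopifnot(inherits(params, "nanobar_field_params"))
  px <- params$pixel_size
  pitch_px <- params$pitch / px
  n_rows <- ceiling(sqrt(params$bars_per_width))
  cols_per_width <- ceiling(params$bars_per_width / n_rows)
  n_cols <- cols_per_width * length(params$widths)
  margin_px <- ceiling(pitch_px / 2)
  nr <- ceiling((n_rows - 1) * pitch_px + 2 * margin_px) + 1L
  nc <- ceiling((n_cols - 1) * pitch_px + 2 * margin_px) + 1L

  local_seed(params$seed)
  enr_map <- enrichment_for_widths(params$end_enrichment, params$widths)

  geo <- purrr::imap_dfr(params$widths, function(w, wi) {
    ids <- seq_len(params$bars_per_width)
    gr <- (ids - 1L) %% n_rows
    gc <- (ids - 1L) %/% n_rows + (wi - 1L) * cols_per_width
    jit <- if (params$position_jitter > 0) {
      matrix(runif(2 * length(ids), -params$position_jitter,
                   params$position_jitter) / px, ncol = 2)
    } else matrix(0, length(ids), 2)
    tibble::tibble(
      width_nm = w,
      row = margin_px + gr * pitch_px + jit[, 1],
      col = margin_px + gc * pitch_px + jit[, 2],
      orientation = 0,
      length_nm = params$bar_length,
      pixel_size = px,
      enrichment = unname(enr_map[as.character(w)])
    )
  })
  geo <- dplyr::mutate(geo, bar = dplyr::row_number(), .before = 1)

  membrane <- matrix(1, nr, nc)
  enrich <- matrix(1, nr, nc)
  half_out <- px / 2
  for (i in seq_len(nrow(geo))) {
    g <- geo[i, ]
    half_seg <- (g$length_nm - g$width_nm) / 2
    ext <- ceiling((g$length_nm / 2 + g$width_nm + px) / px)
    rows <- max(0, floor(g$row) - ext):min(nr - 1, ceiling(g$row) + ext)
    cols <- max(0, floor(g$col) - ext):min(nc - 1, ceiling(g$col) + ext)
    dr <- (rows - g$row) * px
    dc <- (cols - g$col) * px
    drm <- matrix(dr, length(rows), length(cols))
    dcm <- matrix(dc, length(rows), length(cols), byrow = TRUE)
    d <- segment_distance(drm, dcm, g$orientation, half_seg)
    outline <- abs(d - g$width_nm / 2) <= half_out
    sub <- membrane[rows + 1, cols + 1]
    sub[outline] <- sub[outline] + params$wall_factor
    membrane[rows + 1, cols + 1] <- sub
    if (g$enrichment != 1) {
      ## cap regions: discs of radius width/2 (+ half a pixel so the cap
      ## wall outline is included) around the two cap centres
      ar <- cos(g$orientation); ac <- sin(g$orientation)
      cap_d2 <- pmin(
        (drm - half_seg * ar)^2 + (dcm - half_seg * ac)^2,
        (drm + half_seg * ar)^2 + (dcm + half_seg * ac)^2)
      cap <- cap_d2 <= (g$width_nm / 2 + half_out)^2
      esub <- enrich[rows + 1, cols + 1]
      esub[cap] <- g$enrichment
      enrich[rows + 1, cols + 1] <- esub
    }
  }

  sigma_px <- params$psf_sigma / px
  clean_lipid <- params$background +
    params$intensity * gaussian_blur_fft(membrane, sigma_px)
  clean_protein <- params$background +
    params$intensity * gaussian_blur_fft(membrane * enrich, sigma_px)

  noise <- function(x) {
    switch(params$noise_model,
           poisson = matrix(rpois(length(x), pmax(x, 0)), nrow(x), ncol(x)),
           gaussian = x + matrix(rnorm(length(x), 0, params$noise_sd),
                                 nrow(x), ncol(x)),
           none = x)
  }
  structure(list(lipid = noise(clean_lipid),
                 protein = noise(clean_protein),
                 clean_lipid = clean_lipid,
                 clean_protein = clean_protein,
                 geometry = geo, params = params),
            class = "nanobar_field")
}

#' @export
print.nanobar_field <- function(x, ...) {
  cat(sprintf("<nanobar_field> %d bars (%s nm wide), %d x %d px\n",
              nrow(x$geometry),
              paste(unique(x$geometry$width_nm), collapse = "/"),
              nrow(x$lipid), ncol(x$lipid)))
  invisible(x)
}
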