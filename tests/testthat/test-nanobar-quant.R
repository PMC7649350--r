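test_that("noiseless fields are detected with sub-pixel accuracy", {
  fld <- simulate_nanobar_field(nanobar_field_params(
    widths = 300, bars_per_width = 60, noise_model = "none", seed = 1))
  det <- detect_nanobars(fld$lipid,
                         list(width = 300, length = 2000, pitch = 3000),
                         pixel_size = 50)
  expect_equal(nrow(det), 60)
  gt <- fld$geometry
  errs <- vapply(seq_len(nrow(det)), function(i) {
    min(sqrt((gt$row - det$row[i])^2 + (gt$col - det$col[i])^2))
  }, numeric(1))
  expect_lt(max(errs), 0.5)
})

test_that("blank images yield an empty geometry with a warning", {
  expect_warning(
    det <- detect_nanobars(matrix(100, 150, 150),
                           list(width = 300, length = 2000,
                                pitch = 3000), pixel_size = 50),
    "no nanobar")
  expect_equal(nrow(det), 0)
})

test_that("noisy fields are detected without off-lattice false positives", {
  for (seed in 1:5) {
    fld <- small_field(n_bars = 12, seed = seed)
    det <- detect_nanobars(fld$lipid,
                           list(width = 300, length = 2000,
                                pitch = 3000), pixel_size = 50)
    gt <- fld$geometry
    errs <- vapply(seq_len(nrow(det)), function(i) {
      min(sqrt((gt$row - det$row[i])^2 + (gt$col - det$col[i])^2))
    }, numeric(1))
    expect_gte(nrow(det), ceiling(0.95 * 12))
    expect_lt(max(errs), 2)  # every detection sits on a true bar
  }
})

test_that("cap centers and mask geometry follow the bar definition", {
  ## width 300, length 2000: cap centres sit 850 nm from the bar centre
  dims <- c(61, 25)
  masks <- bar_masks(300, 2000, pixel_size = 50, dim = dims,
                     dilation_nm = 0)
  ctr <- (dims[1] - 1) / 2
  on_axis <- which(masks$end[, (dims[2] + 1) / 2])
  ## discs of diameter exactly the width: 300/50 = 6 px reach
  expect_equal(range((on_axis - 1 - ctr) * 50), c(-1000, 1000))
  expect_equal(min(abs((on_axis - 1 - ctr) * 50)), 700)

  ## disjoint for dilations up to 100 nm at width 300 (exhaustive check)
  for (dil in c(0, 50, 100)) {
    m <- bar_masks(300, 2000, 50, dims, dilation_nm = dil)
    expect_false(any(m$end & m$center))
  }
})

test_that("oversized dilations that collide the masks raise errors", {
  expect_error(bar_masks(600, 2000, 50, c(61, 31), dilation_nm = 300),
               class = "curvesense_geometry_error")
})

test_that("a uniform image has end/center ratio exactly 1", {
  r <- end_center_ratio(matrix(5, 61, 25), dilation_nm = 150,
                        width_nm = 300, length_nm = 2000,
                        pixel_size = 50)
  expect_equal(r$end_to_center_ratio, 1, tolerance = 1e-6)
})

test_that("ratios are invariant under global gain and offset", {
  fld <- small_field(n_bars = 6, seed = 31)
  base <- end_center_ratio(register_bars(fld$protein, fld$geometry))
  scaled <- end_center_ratio(register_bars(3 * fld$protein + 250,
                                           fld$geometry))
  expect_equal(scaled$end_to_center_ratio, base$end_to_center_ratio,
               tolerance = 1e-6)
})

test_that("averaging a single bar returns its own registered crop", {
  fld <- small_field(n_bars = 1, noise_model = "none", seed = 2)
  crops <- register_bars(fld$lipid, fld$geometry)
  avg <- average_bars(crops)
  expect_equal(unclass(avg), crops[, , 1], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("averaging N bars shrinks pixel noise about sqrt(N)-fold", {
  fld <- simulate_nanobar_field(nanobar_field_params(
    widths = 300, bars_per_width = 25, seed = 5))
  noisy <- register_bars(fld$protein, fld$geometry)
  clean <- register_bars(fld$clean_protein, fld$geometry)
  avg_noise <- unclass(average_bars(noisy)) -
    unclass(average_bars(clean))
  single_noise <- noisy[, , 1] - clean[, , 1]
  shrink <- sd(single_noise) / sd(avg_noise)
  expect_gt(shrink, sqrt(25) * 0.7)
  expect_lt(shrink, sqrt(25) * 1.3)
})

test_that("sub-pixel placed bars average onto the forward model", {
  fld <- simulate_nanobar_field(nanobar_field_params(
    widths = 300, bars_per_width = 20, position_jitter = 25, seed = 6))
  avg <- average_bars(fld$protein, fld$geometry)
  oracle <- average_bars(fld$clean_protein, fld$geometry)
  rel_rms <- sqrt(mean((unclass(avg) - unclass(oracle))^2)) /
    mean(unclass(oracle))
  expect_lt(rel_rms, 0.02)
})

test_that("mixed widths cannot be registered together", {
  p <- nanobar_field_params(widths = c(200, 400), bars_per_width = 2,
                            seed = 1)
  fld <- simulate_nanobar_field(p)
  expect_error(register_bars(fld$lipid, fld$geometry),
               class = "curvesense_mixed_widths")
})

test_that("end density is a pure protein-per-lipid ratio", {
  fld <- small_field(n_bars = 4, noise_model = "none", seed = 3,
                     enrichment = 1)
  lip <- register_bars(fld$lipid, fld$geometry)
  expect_equal(end_density(lip, lip)$density, 1, tolerance = 1e-9)
  twice <- fld$lipid * 2
  prot2 <- register_bars(twice, fld$geometry)
  expect_equal(end_density(prot2, lip)$density, 2, tolerance = 1e-6)
})

test_that("recovered ratio increases strictly with generator enrichment", {
  ratios <- vapply(c(1.0, 1.2, 1.4, 1.8, 2.6), function(enr) {
    fld <- small_field(enrichment = enr, n_bars = 8, seed = 13)
    end_center_ratio(
      register_bars(fld$protein, fld$geometry))$end_to_center_ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("width profiles respond to curvature-dependent enrichment", {
  widths <- c(200, 400, 600)
  make_sets <- function(enr_fun, ...) {
    purrr::map(widths, function(w) {
      fld <- simulate_nanobar_field(nanobar_field_params(
        widths = w, bars_per_width = 6,
        end_enrichment = enr_fun(w), seed = 40 + w, ...))
      list(width = w,
           protein = register_bars(fld$protein, fld$geometry,
                                   annulus_nm = c(400, 800)),
           lipid = register_bars(fld$lipid, fld$geometry,
                                 annulus_nm = c(400, 800)))
    })
  }
  dil <- 100  # keeps masks valid at 600 nm
  ## identical enrichment reads out flat in the unblurred, zero-background
  ## ideal case (the annulus background subtracts the flat-SLB level, and
  ## a PSF attenuates small caps more, so flatness is exact only there)
  flat_sets <- purrr::map(widths, function(w) {
    fld <- simulate_nanobar_field(nanobar_field_params(
      widths = w, bars_per_width = 6, end_enrichment = 1.5,
      psf_sigma = 0, background = 0, noise_model = "none",
      seed = 40 + w))
    list(width = w,
         protein = register_bars(fld$protein, fld$geometry,
                                 background = "none"),
         lipid = register_bars(fld$lipid, fld$geometry,
                               background = "none"))
  })
  flat <- width_profile(flat_sets, dilation_nm = 0)
  expect_lt(diff(range(flat$density)) / mean(flat$density), 1e-6)

  curved <- width_profile(make_sets(function(w) 1 + 200 / w),
                          dilation_nm = dil)
  expect_true(all(diff(curved$density) < 0))

  ## order invariance
  sets <- make_sets(function(w) 1 + 200 / w)
  perm <- width_profile(sets[c(3, 1, 2)], dilation_nm = dil)
  expect_equal(perm, curved)
})
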