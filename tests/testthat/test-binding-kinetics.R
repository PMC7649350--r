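test_that("the Hill model honours its closed forms", {
  expect_equal(hill_model(0.6, Bmax = 1, K_D = 0.6, H = 2.7), 0.5)
  expect_equal(hill_model(0, 1, 0.6, 2), 0)
  expect_equal(hill_model(3 * 0.6, 1, 0.6, 1), 0.75)
  ## monotone in c and Bmax
  c_grid <- seq(0.01, 5, length.out = 50)
  expect_true(all(diff(hill_model(c_grid, 1, 0.6, 2.5)) > 0))
  expect_true(all(hill_model(c_grid, 2, 0.6, 2.5) >
                    hill_model(c_grid, 1, 0.6, 2.5)))
})

test_that("noiseless Hill data are recovered to numerical precision", {
  conc <- c(0.1, 0.2, 0.4, 0.6, 1, 2, 5)
  d <- tibble::tibble(concentration_uM = conc,
                      density = hill_model(conc, 1, 0.6, 2.5))
  fit <- fit_hill(d)
  e <- setNames(fit$estimate$estimate, fit$estimate$term)
  expect_true(fit$converged)
  expect_equal(unname(e["Bmax"]), 1, tolerance = 1e-6)
  expect_equal(unname(e["K_D"]), 0.6, tolerance = 1e-6)
  expect_equal(unname(e["H"]), 2.5, tolerance = 1e-6)

  hyp <- tibble::tibble(concentration_uM = conc,
                        density = hill_model(conc, 2, 0.5, 1))
  eh <- setNames(tidy(fit_hill(hyp))$estimate, c("Bmax", "K_D", "H"))
  expect_equal(unname(eh["H"]), 1, tolerance = 1e-4)
})

test_that("residuals at the Hill solution satisfy first-order optimality", {
  conc <- c(0.1, 0.25, 0.5, 0.8, 1.5, 3, 6)
  set.seed(8)
  d <- tibble::tibble(
    concentration_uM = conc,
    density = hill_model(conc, 1, 0.6, 2.5) * (1 + rnorm(7, 0, 0.03)))
  fit <- fit_hill(d)
  J <- fit$fitted_model$m$gradient()
  g <- crossprod(J, residuals(fit$fitted_model))
  expect_lt(max(abs(g)), 1e-5 * max(abs(crossprod(J))))
})

test_that("Hill fits are equivariant under intensity rescaling", {
  conc <- c(0.1, 0.25, 0.5, 0.8, 1.5, 3, 6)
  set.seed(9)
  dens <- hill_model(conc, 1, 0.6, 2.5) * (1 + rnorm(7, 0, 0.02))
  f1 <- fit_hill(tibble::tibble(concentration_uM = conc,
                                density = dens))
  f2 <- fit_hill(tibble::tibble(concentration_uM = conc,
                                density = dens * 7))
  e1 <- setNames(f1$estimate$estimate, f1$estimate$term)
  e2 <- setNames(f2$estimate$estimate, f2$estimate$term)
  expect_equal(unname(e2["Bmax"] / e1["Bmax"]), 7, tolerance = 1e-4)
  expect_equal(unname(e2["K_D"]), unname(e1["K_D"]), tolerance = 1e-4)
  expect_equal(unname(e2["H"]), unname(e1["H"]), tolerance = 1e-4)
})

test_that("noisy Hill replicates stay near truth", {
  conc <- c(0.1, 0.2, 0.3, 0.45, 0.6, 0.9, 1.5, 2.5, 5)
  res <- purrr::map_dfr(1:25, function(seed) {
    set.seed(seed)
    d <- tibble::tibble(
      concentration_uM = conc,
      density = hill_model(conc, 1, 0.6, 2.5) *
        (1 + rnorm(length(conc), 0, 0.05)))
    e <- setNames(tidy(fit_hill(d))$estimate, c("Bmax", "K_D", "H"))
    tibble::tibble(kd = e[["K_D"]], h = e[["H"]])
  })
  expect_lt(abs(median(res$kd) / 0.6 - 1), 0.05)
  expect_true(median(res$h) >= 2 && median(res$h) <= 3)
})

test_that("underdetermined series are rejected and weights validated", {
  d3 <- tibble::tibble(concentration_uM = c(0.1, 0.5, 1),
                       density = c(0.1, 0.5, 0.9))
  expect_error(fit_hill(d3), class = "curvesense_insufficient_data")
  d <- tibble::tibble(concentration_uM = c(0.1, 0.5, 1, 2),
                      density = c(0.1, 0.5, 0.8, 0.9))
  expect_error(fit_hill(d, weight_by_sem = TRUE),
               class = "curvesense_invalid_parameters")
})

test_that("FRAP normalization anchors the pre-bleach plateau at 1", {
  flat <- tibble::tibble(time_s = 0:19, intensity = rep(480, 20))
  nf <- normalize_frap(flat, bleach_index = 6)
  expect_equal(nf$intensity, rep(1, 20))

  stepped <- tibble::tibble(time_s = 0:19,
                            intensity = c(rep(800, 5), rep(400, 15)))
  ns <- normalize_frap(stepped, bleach_index = 6)
  expect_equal(ns$intensity[6:20], rep(0.5, 15))
  expect_error(normalize_frap(stepped, bleach_index = 2),
               class = "curvesense_invalid_parameters")
})

test_that("reference correction removes acquisition photobleaching bias", {
  make <- function(seed, bleach_rate) {
    tr <- simulate_frap_trace(frap_params(t_half = 20, noise_sd = 0.01,
                                          seed = seed))
    decay <- exp(-bleach_rate * (tr$time_s - tr$time_s[1]))
    list(raw = tibble::tibble(time_s = tr$time_s,
                              intensity = tr$intensity * decay),
         ref = tibble::tibble(time_s = tr$time_s, intensity = decay),
         bi = attr(tr, "bleach_index"))
  }
  t_plain <- vapply(1:10, function(s) {
    tr <- simulate_frap_trace(frap_params(t_half = 20, noise_sd = 0.01,
                                          seed = s))
    fit_frap(tr)$t_half
  }, numeric(1))
  t_corr <- vapply(1:10, function(s) {
    m <- make(s, 0.002)  # ~2% per 10 s acquisition bleaching
    fit_frap(normalize_frap(m$raw, m$bi, reference = m$ref))$t_half
  }, numeric(1))
  expect_lt(abs(median(t_corr) - median(t_plain)) / median(t_plain),
            0.05)
})

test_that("noiseless FRAP fits return the exact half-time", {
  for (th in c(9, 35)) {
    tr <- simulate_frap_trace(frap_params(t_half = th, noise_sd = 0))
    fit <- fit_frap(tr)
    expect_equal(fit$t_half, th, tolerance = 1e-6)
    expect_equal(fit$mobile_fraction, 1, tolerance = 1e-6)
  }
})

test_that("flat traces are flagged as no-recovery, not errors", {
  tr <- simulate_frap_trace(frap_params(mobile_fraction = 0,
                                        noise_sd = 0.02, seed = 2))
  fit <- fit_frap(tr)
  expect_equal(fit$mobile_fraction, 0)
  expect_true(fit$no_recovery)
  expect_true(glance(fit)$no_recovery)
})

test_that("truncated recoveries still bracket the half-time", {
  tr <- simulate_frap_trace(frap_params(t_half = 35, duration = 105,
                                        noise_sd = 0.02, seed = 3))
  keep <- tr$time_s <= tr$time_s[attr(tr, "bleach_index")] + 3 * 35
  short <- tr[keep, ]
  attr(short, "bleach_index") <- attr(tr, "bleach_index")
  fit <- fit_frap(short)
  expect_lt(abs(fit$t_half - 35) / 35, 0.15)
})

test_that("fit objects expose broom-style summaries", {
  tr <- simulate_frap_trace(frap_params(t_half = 9, noise_sd = 0.01,
                                        seed = 5))
  fit <- fit_frap(tr)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_true("t_half" %in% td$term)
  conc <- c(0.1, 0.2, 0.5, 1, 2, 5)
  hf <- fit_hill(tibble::tibble(concentration_uM = conc,
                                density = hill_model(conc, 1, 0.6, 2.5)))
  expect_named(glance(hf), c("sse", "n", "converged", "at_bounds"))
})
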