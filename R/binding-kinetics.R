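#' Hill cooperative-binding model
#'
#' Fractional occupancy scaled by `Bmax`:
#' \deqn{B(c) = B_{max} \frac{c^H}{K_D^H + c^H}}
#' `H = 1` is a simple hyperbola; `H > 1` indicates cooperative,
#' ultrasensitive binding. At `c = K_D` the model returns `Bmax / 2` for
#' any `H`.
#'
#' @param c Concentration(s), uM.
#' @param Bmax Saturating density (same units as the measured density).
#' @param K_D Half-saturation constant, uM.
#' @param H Hill coefficient (dimensionless, > 0).
#' @return Predicted density, same length as `c`.
#' @export
hill_model <- function(c, Bmax, K_D, H) {
  stopifnot(Bmax > 0, K_D > 0, H > 0)
  ch <- c^H
  Bmax * ch / (K_D^H + ch)
}

#' Fit the Hill equation to a concentration-density series
#'
#' Weighted or unweighted least squares over `(Bmax, K_D, H)` by
#' Levenberg-Marquardt with box bounds, from multiple starts: `K_D`
#' initialized at the concentration nearest half-max and `H` at 1, 2 and
#' 4; the start with the smallest final sum of squares wins, ties towards
#' the smaller `H`. Bounds `H` in \[0.2, 10\] and `K_D` in
#' \[min(c)/10, max(c) * 10\] keep non-saturating series (which cannot pin
#' down `Bmax`) from diverging; a fit stopped at a bound is flagged, not
#' raised.
#'
#' @param series A data frame with columns `concentration_uM`, `density`
#'   and optionally `sem`.
#' @param weight_by_sem Weight residuals by `1 / sem^2` (default
#'   `FALSE`; the unweighted fit is the baseline, weighting is a flag).
#' @return An object of class `hill_fit`: a list with `estimate` (tibble
#'   of term/estimate/std.error), `converged`, `at_bounds`, `sse`, `n`,
#'   `fitted_model` (the underlying `nls` object) and `data`.
#' @examples
#' conc <- c(0.1, 0.2, 0.5, 1, 2, 5)
#' d <- tibble::tibble(concentration_uM = conc,
#'                     density = hill_model(conc, 1, 0.6, 2.5))
#' coef(fit_hill(d)$fitted_model)
#' @export
fit_hill <- function(series, weight_by_sem = FALSE) {
  conc <- series$concentration_uM
  dens <- series$density
  if (length(conc) < 4L) {
    abort("need at least 4 concentration points for a Hill fit.",
          class = "curvesense_insufficient_data")
  }
  if (is.unsorted(conc, strictly = TRUE) || any(conc < 0)) {
    abort("concentrations must be non-negative and strictly increasing.",
          class = "curvesense_invalid_parameters")
  }
  w <- if (weight_by_sem) {
    if (is.null(series[["sem"]]) || any(!is.finite(series[["sem"]])) ||
        any(series[["sem"]] <= 0)) {
      abort("`weight_by_sem = TRUE` needs positive finite `sem` values.",
            class = "curvesense_invalid_parameters")
    }
    1 / series[["sem"]]^2
  } else rep(1, length(conc))

  bmax0 <- max(dens)
  kd0 <- conc[which.min(abs(dens - bmax0 / 2))]
  kd0 <- max(kd0, min(conc[conc > 0]) / 2)
  lower <- c(Bmax = 1e-12, K_D = min(conc[conc > 0]) / 10, H = 0.2)
  upper <- c(Bmax = Inf, K_D = max(conc) * 10, H = 10)

  fits <- purrr::map(c(1, 2, 4), function(h0) {
    tryCatch(
      minpack.lm::nlsLM(
        dens ~ Bmax * conc^H / (K_D^H + conc^H),
        start = list(Bmax = max(bmax0, 1e-6), K_D = kd0, H = h0),
        weights = w, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    return(new_hill_fit(NULL, series, converged = FALSE))
  }
  sse <- vapply(fits, function(f) {
    if (is.null(f)) Inf else sum(w * residuals(f)^2)
  }, numeric(1))
  ## ties (within numerical noise) towards the smaller starting H
  best <- which(sse <= min(sse) * (1 + 1e-9))[1]
  new_hill_fit(fits[[best]], series, converged = TRUE,
               lower = lower, upper = upper)
}

new_hill_fit <- function(fit, series, converged, lower = NULL,
                         upper = NULL) {
  if (is.null(fit)) {
    est <- tibble::tibble(term = c("Bmax", "K_D", "H"),
                          estimate = NA_real_, std.error = NA_real_)
    return(structure(list(estimate = est, converged = FALSE,
                          at_bounds = NA, sse = NA_real_,
                          n = nrow(series), fitted_model = NULL,
                          data = series),
                     class = "hill_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) {
    rep(NA_real_, length(cf))
  })
  tol <- 1e-6
  at_bounds <- any(cf <= lower * (1 + tol) + 1e-15) ||
    any(is.finite(upper) & cf >= upper * (1 - tol))
  est <- tibble::tibble(term = names(cf), estimate = unname(cf),
                        std.error = unname(se))
  structure(list(estimate = est, converged = converged,
                 at_bounds = at_bounds,
                 sse = sum(residuals(fit)^2), n = nrow(series),
                 fitted_model = fit, data = series),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<hill_fit> did not converge\n")
    return(invisible(x))
  }
  e <- setNames(x$estimate$estimate, x$estimate$term)
  cat(sprintf(
    "<hill_fit> Bmax %.4g, K_D %.4g uM, H %.3g (n = %d%s)\n",
    e["Bmax"], e["K_D"], e["H"], x$n,
    if (isTRUE(x$at_bounds)) ", at bounds" else ""))
  invisible(x)
}

#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) x$estimate

#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, n = x$n, converged = x$converged,
                 at_bounds = x$at_bounds)
}

#' Normalize a raw FRAP trace
#'
#' Divides by the mean pre-bleach intensity so the plateau before the
#' bleach sits at 1. When a reference trace from an unbleached region is
#' supplied, the raw trace is first divided point-wise by the reference
#' (itself scaled to its pre-bleach mean), correcting acquisition
#' photobleaching.
#'
#' @param raw A data frame with `time_s` and `intensity`.
#' @param bleach_index 1-based index of the first post-bleach frame; at
#'   least 3 pre-bleach frames are required.
#' @param reference Optional data frame, same grid, unbleached region.
#' @return A tibble with `time_s`, `intensity` and attribute
#'   `bleach_index`.
#' @export
normalize_frap <- function(raw, bleach_index, reference = NULL) {
  if (bleach_index < 4L) {
    abort("need at least 3 pre-bleach frames.",
          class = "curvesense_invalid_parameters")
  }
  intens <- raw$intensity
  if (!is.null(reference)) {
    ref <- reference$intensity /
      mean(reference$intensity[seq_len(bleach_index - 1L)])
    intens <- intens / ref
  }
  pre <- mean(intens[seq_len(bleach_index - 1L)])
  out <- tibble::tibble(time_s = raw$time_s, intensity = intens / pre)
  attr(out, "bleach_index") <- as.integer(bleach_index)
  out
}

#' Fit single-exponential FRAP recovery
#'
#' Fits \eqn{I(t) = I_0 + A (1 - 2^{-(t - t_b)/t_{1/2}})} to the
#' post-bleach frames of a normalized trace. The mobile fraction is
#' `A / (1 - I_0)` (the recovered share of the bleached signal, with the
#' pre-bleach level normalized to 1). When the recovery amplitude is not
#' distinguishable from zero at 2 standard errors — or the fit cannot
#' converge on an essentially flat trace — the fit returns
#' `mobile_fraction = 0` with `no_recovery = TRUE` rather than failing,
#' which is the washed-out / oligomerized regime where no exchange is
#' seen within the observation window.
#'
#' @param trace A normalized trace from [normalize_frap()] or
#'   [simulate_frap_trace()] (attribute `bleach_index`), or a data frame
#'   plus an explicit `bleach_index` argument.
#' @param bleach_index Optional override of the trace attribute.
#' @return An object of class `frap_fit`: list with `t_half` (s),
#'   `mobile_fraction`, `plateau`, `I0`, `std.errors`, `converged`,
#'   `no_recovery`, `n_post`, `fitted_model`, `data`.
#' @examples
#' fr <- simulate_frap_trace(frap_params(t_half = 9, noise_sd = 0))
#' fit_frap(fr)$t_half
#' @export
fit_frap <- function(trace, bleach_index = NULL) {
  bi <- bleach_index %||% attr(trace, "bleach_index")
  if (is.null(bi)) {
    abort("`bleach_index` is required (attribute or argument).",
          class = "curvesense_invalid_parameters")
  }
  post <- trace[bi:nrow(trace), ]
  if (nrow(post) < 10L) {
    abort("need at least 10 post-bleach frames.",
          class = "curvesense_insufficient_data")
  }
  t <- post$time_s - post$time_s[1]
  y <- post$intensity
  pre <- mean(trace$intensity[seq_len(bi - 1L)])
  i0 <- y[1]
  a0 <- max(mean(tail(y, 3)) - i0, 1e-3)
  span <- max(t)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ I0 + A * (1 - 2^(-t / t_half)),
      start = list(I0 = i0, A = a0,
                   t_half = max(span / 8, t[2])),
      lower = c(I0 = -Inf, A = 0, t_half = 1e-6),
      upper = c(I0 = Inf, A = Inf, t_half = span * 100),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    return(new_frap_fit_flat(trace, bi, pre, i0, n_post = nrow(post)))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) {
    setNames(rep(NA_real_, 3), names(cf))
  })
  if (is.finite(se["A"]) && cf["A"] < 2 * se["A"]) {
    return(new_frap_fit_flat(trace, bi, pre, cf["I0"],
                             n_post = nrow(post), fit = fit))
  }
  denom <- pre - cf["I0"]
  mf <- if (denom > 0) cf["A"] / denom else NA_real_
  clipped <- FALSE
  if (is.finite(mf) && (mf < 0 || mf > 1)) {
    clipped <- mf < -1e-6 || mf > 1 + 1e-6
    ## warn only on excursions larger than ordinary estimation noise
    if (mf < -0.05 || mf > 1.05) {
      warn("mobile fraction well outside [0, 1]; clipping.")
    }
    mf <- min(max(mf, 0), 1)
  }
  structure(list(t_half = unname(cf["t_half"]),
                 mobile_fraction = unname(mf),
                 plateau = unname(cf["I0"] + cf["A"]),
                 I0 = unname(cf["I0"]),
                 std.errors = se, converged = TRUE, no_recovery = FALSE,
                 clipped = clipped, n_post = nrow(post),
                 fitted_model = fit, data = trace),
            class = "frap_fit")
}

new_frap_fit_flat <- function(trace, bi, pre, i0, n_post, fit = NULL) {
  structure(list(t_half = NA_real_, mobile_fraction = 0,
                 plateau = unname(i0), I0 = unname(i0),
                 std.errors = c(I0 = NA_real_, A = NA_real_,
                                t_half = NA_real_),
                 converged = !is.null(fit), no_recovery = TRUE,
                 clipped = FALSE, n_post = n_post, fitted_model = fit,
                 data = trace),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  if (x$no_recovery) {
    cat("<frap_fit> no detectable recovery (mobile fraction 0)\n")
  } else {
    cat(sprintf(
      "<frap_fit> t_half %.3g s, mobile fraction %.3g, plateau %.3g\n",
      x$t_half, x$mobile_fraction, x$plateau))
  }
  invisible(x)
}

#' @method tidy frap_fit
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble::tibble(
    term = c("t_half", "mobile_fraction", "plateau", "I0"),
    estimate = c(x$t_half, x$mobile_fraction, x$plateau, x$I0),
    std.error = c(unname(x$std.errors["t_half"]), NA_real_, NA_real_,
                  unname(x$std.errors["I0"])))
}

#' @method glance frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(converged = x$converged, no_recovery = x$no_recovery,
                 n_post = x$n_post)
}
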