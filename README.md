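# curvesense

Quantifies how membrane-binding proteins — BAR domains and their
intrinsically disordered regions (IDRs) — sense membrane curvature, from
four complementary read-outs:

* **Cortical wave phase shifts.** Proteins riding oscillatory cortical
  waves (period 20–30 s) are recruited at times set by their curvature
  preference. The phase shift between two channels is the lag τ
  maximizing the Pearson-normalized cross-correlation
  r(τ) = corr(a(t), b(t − τ)) computed on overlapping segments, with
  optional matched smoothing and parabolic sub-frame refinement.
* **Nanobar supported-lipid-bilayer images.** Vertical nanobars
  (half-circle caps of diameter = bar width, flat middle) impose defined
  curvature on a coating bilayer. The package detects and registers bars,
  averages them, and computes the end-to-center ratio
  ⟨I_end⟩/⟨I_center⟩ and the lipid-normalized nanobar-end density
  ⟨P_end⟩/⟨L_end⟩ across bar widths 200–600 nm.
* **Binding kinetics.** Hill fits B(c) = Bmax·c^H/(K_D^H + c^H) of
  concentration–density series (K_D, Hill coefficient H), and
  single-exponential FRAP recovery fits
  I(t) = I₀ + A·(1 − 2^(−t/t½)) giving the half-time and mobile
  fraction.
* **Sequence conservation.** Per-column information content
  R = log₂20 − H_obs (bits) and occupancy weight of protein alignments,
  with two-sided Mann-Whitney U contrasts between regions (e.g. the
  alternatively spliced IDR of one paralog versus another).

Every input modality has a synthetic generator with exact ground truth
(`simulate_wave_traces()`, `simulate_nanobar_field()`,
`simulate_frap_trace()`, `simulate_msa()`), so the entire pipeline is
validated by parameter recovery. See the methods vignette
(`vignettes/curvesense-methods.Rmd`) for models, defaults and numerical
choices.

## Worked example

```r
library(curvesense)

## two-channel wave traces with a 0.8 s offset, 5 Hz sampling
tr <- simulate_wave_traces(wave_params(phase_offsets = c(0, 0.8),
                                       frame_interval = 0.2, seed = 1))
xcorr_lag(trace_channel(tr, 1), trace_channel(tr, 0),
          max_lag = 8, smooth_window = 2, subsample = TRUE)
#> <phase_shift> lag 0.804 s (r = 0.996, sub-frame)

## a field of 60 nanobars (300 nm wide) with 1.385-fold cap enrichment:
## detect on the lipid channel, register, per-bar end/center ratio
fld <- simulate_nanobar_field(nanobar_field_params(
  widths = 300, bars_per_width = 60, end_enrichment = 1.385, seed = 1))
geo <- detect_nanobars(fld$lipid,
                       list(width = 300, length = 2000, pitch = 3000),
                       pixel_size = 50)
end_center_ratio(register_bars(fld$protein, geo))
#> # A tibble: 1 × 3
#>   end_to_center_ratio      sem n_bars
#>                 <dbl>    <dbl>  <int>
#> 1                1.18 0.000480     60

## Hill fit of a noiseless binding series (K_D 0.6 uM, H 2.5)
conc <- c(0.1, 0.2, 0.3, 0.45, 0.6, 0.9, 1.5, 2.5, 5)
fit <- fit_hill(tibble::tibble(concentration_uM = conc,
                               density = hill_model(conc, 1, 0.6, 2.5)))
tidy(fit)
#> # A tibble: 3 × 3
#>   term  estimate std.error
#>   <chr>    <dbl>     <dbl>
#> 1 Bmax       1           0
#> 2 K_D        0.6         0
#> 3 H          2.5         0

## slow FRAP recovery (t_half 35 s) with 2% noise
fit_frap(simulate_frap_trace(frap_params(t_half = 35, noise_sd = 0.02,
                                         seed = 2)))
#> <frap_fit> t_half 35.9 s, mobile fraction 1, plateau 1
```

The measured end/center ratio (1.18) is smaller than the imposed cap
enrichment (1.385) because the point-spread function blurs cap signal
out of the end masks; recovery tests therefore compare against the
noiseless forward-model oracle, not the raw factor.

Each result type has an `autoplot()` method (correlation curves, aligned
peak profiles, averaged bar images, width profiles, Hill and FRAP fits),
and the fit objects support broom-style `tidy()`/`glance()`.

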