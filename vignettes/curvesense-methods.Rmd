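---
title: "Methods: quantifying membrane curvature sensing with curvesense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying membrane curvature sensing with curvesense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvesense)
library(dplyr)
```

## Scope

`curvesense` implements the quantitative workflow used to characterize how
BAR-domain proteins and their intrinsically disordered regions (IDRs) sense
membrane curvature, across four read-outs:

1. **Cortical wave phase shifts** — cross-correlation lags between
   two-channel fluorescence traces of proteins riding oscillatory cortical
   waves (period 20–30 s), which report the relative timing of recruitment
   as membrane curvature develops.
2. **Nanobar SLB quantification** — detection, registration and averaging
   of nanobar images (supported lipid bilayers draped over lithographic
   bars with half-circle caps), and the two curvature statistics: the
   end-to-center intensity ratio and the lipid-normalized nanobar-end
   density across bar widths (200–600 nm).
3. **Binding kinetics** — Hill cooperative-binding fits of
   concentration–density series and single-exponential FRAP recovery fits
   (half-time, mobile fraction).
4. **Sequence conservation** — per-column information content (bits) and
   occupancy ("weight") of protein alignments, with Mann-Whitney contrasts
   between regions such as paralogous IDRs.

Because raw microscopy and binding data for this kind of study are rarely
deposited, the package ships a first-class synthetic-data generator for
every modality, with exact ground truth, so the full pipeline can be
validated by parameter recovery.

## Wave phase estimation

An intensity trace is the mean over a ~2×2 µm region of interest per
frame. Phase shifts are estimated by `xcorr_lag()`:

* Pearson-normalized correlation is computed per integer lag on the
  *overlapping segment only*. Traces are short (a few periods) and drift;
  overlap-wise normalization avoids the wrap-around artifacts of circular
  FFT correlation.
* **Detrending** (on by default, 25 s centered moving average with
  symmetrically shrinking edges) removes baseline drift that otherwise
  dominates the correlation. It is a flagged, reversible choice.
* **Sign convention**: positive lag means the first trace peaks after the
  second.
* **Sub-frame refinement**: a parabola through the peak and its two
  neighbours. Ties on the discrete maximum break towards smaller |lag|.
* **Matched smoothing** (`smooth_window`, off by default): at sampling
  much faster than the signal bandwidth (0.2 s frames against ~8 s
  recruitment pulses), adjacent correlation lags differ by less than the
  white-noise floor of the correlation estimate, so the discrete argmax
  jitters by several samples. A centred moving average much shorter than
  the pulse width (we use 2 s), applied identically to both channels,
  suppresses that floor without biasing the delay (a symmetric filter
  shared by both channels shifts neither). With it, the discrete argmax
  at fast sampling becomes stable and recovery is limited only by the
  information bound discussed below.

A note on attainable precision: for 150 s traces at amplitude/noise = 5,
the Cramér–Rao bound for the delay is ≈ 0.05–0.07 s *regardless of the
frame interval* — delay precision is set by total signal-to-noise and
bandwidth, not by the sampling grid. The package therefore treats
"quarter-frame" accuracy at 0.2 s sampling as a statement about the
replicate-mean (bias), while single-estimate repeatability at that
operating point is ±0.1 s, which is also what our acceptance tests
assert. Recovered lags are independent of the frame interval for
intervals up to half the true lag.

`align_peaks()` provides an independent estimator: peaks are detected on
the detrended reference (topographic prominence ≥ 0.3 of the amplitude
range by default), windows around each reference peak are averaged from
both channels, and the follower's mean-profile maximum locates the shift.
Agreement of the two estimators within one frame interval is a standing
consistency check.

## Nanobar forward model and quantification

The generator's forward model is deliberately simple and fully inspectable:

* Projected membrane density is 1 everywhere (flat SLB and bar top),
  plus `wall_factor` on the one-pixel bar outline. The default
  `wall_factor = bar_height / pixel_size` is the sidewall area of an
  outline pixel divided by its footprint — a flat projection of 3D
  confocal sectioning, justified because only relative intensities enter
  the statistics.
* Protein = membrane × a width-specific enrichment factor on the cap
  regions (discs at the two cap centres). Enrichment is imposed directly
  rather than via a curvature→affinity law so that ground truth for
  recovery tests is unambiguous.
* Both channels are convolved with a Gaussian PSF (FFT, cyclic: the
  kernel is normalized so summed intensity is conserved exactly) and
  noised (Poisson on expected counts with gain 1 by default; Gaussian for
  analytic tests).

Quantification follows the classic matched-filter + register + average
recipe:

* `detect_nanobars()` correlates the lipid channel with a bar template
  (interior + wall outline, blurred to the expected PSF) using normalized
  cross-correlation, keeps strict local maxima above threshold separated
  by ≥ 0.6 pitch, refines centres parabolically, and discards bars
  touching the border. The 0.75 default threshold sits between the
  scores of true bars and of between-bar sidelobes on simulated fields.
* `register_bars()` resamples each bar onto a canonical upright grid in a
  single bilinear mapping (rotation and sub-pixel shift together, no
  double interpolation) and subtracts the per-bar background, the median
  of an annulus 2–4 bar-widths from the bar axis. The surrounding flat
  SLB therefore acts as the local reference: the statistics quantify the
  *excess* signal on the bar. The median makes the estimate robust to a
  neighbouring bar's blurred walls entering the annulus.
* `end_center_ratio()` computes per-bar mask means and summarizes over
  bars (mean ± SEM over per-bar ratios, not a ratio of averages, so the
  SEM reflects the per-bar n). `end_density()` divides protein by lipid
  over the end mask, cancelling membrane surface-area differences across
  widths; `width_profile()` assembles the density-versus-width curve.

**Mask geometry.** The end mask is two discs of diameter
`width + 2·dilation` at the cap centres (±(length−width)/2 along the
axis); the center mask is a rectangle of the same width covering the
central 40% of the bar length. The default dilation of 150 nm (≈ 1 PSF
sigma) captures blurred cap signal. For wide bars the dilated discs
would intrude into the 40% rectangle — at 600 nm width on a 2 µm bar
they do so for *any* positive dilation — so the rectangle is shortened
to keep a one-pixel gap, never below 20% of the bar length (an error
otherwise). At widths ≤ 400 nm the exact 40% definition is in effect.

Because the imposed enrichment is a pre-PSF quantity, the *measured*
ratio is attenuated by blurring (small caps more than large ones). All
recovery tests therefore compare against the noiseless forward-model
oracle — the same mask arithmetic applied to the noise-free image — not
against the raw enrichment factor.

## Binding kinetics

**Hill fits.** `fit_hill()` performs (optionally SEM-weighted) least
squares of `Bmax·c^H/(K_D^H + c^H)` by Levenberg-Marquardt with box
bounds, from multiple starts (`K_D` at the concentration nearest
half-max; `H` ∈ {1, 2, 4}; best final SSE wins, ties to the smaller
start). Bounds `H` ∈ [0.2, 10] and `K_D` ∈ [min c/10, max c×10] keep
non-saturating series — which cannot pin down `Bmax` — from diverging;
such fits return flagged (`at_bounds`), never raise. The fit is
unweighted by default since per-point SEMs do not imply the original
analysis weighted them; weighting is a flag.

**FRAP.** Normalization divides by the mean pre-bleach intensity, with an
optional unbleached-region reference divided out first to correct
acquisition photobleaching. `fit_frap()` fits the reaction-dominant
single-exponential form `I(t) = I0 + A·(1 − 2^(−t/t_half))` to post-bleach
frames — appropriate because the read-out region is small and recovery is
dominated by exchange with solution rather than lateral diffusion — and
reports `t_half` directly along with the mobile fraction `A/(1 − I0)`.
When the amplitude is indistinguishable from zero at 2 standard errors
(or the optimizer cannot converge on a flat trace) the result is
`mobile_fraction = 0` with a `no_recovery` flag, mirroring immobile and
washed-out experiments. Mobile fractions just outside [0, 1] are clipped
silently within ±0.05 (ordinary estimation noise) and with a warning
beyond.

## Conservation statistics

Information content follows the standard sequence-logo definition:
`log2(20)` minus the Shannon entropy of residue frequencies among non-gap
symbols, so a perfectly conserved column scores ≈ 4.32 bits and a uniform
column 0. Gaps enter only the *weight* (fraction of sequences with a
residue at the column), keeping conservation and splicing prevalence on
separate axes. The small-sample entropy correction `19/(2·ln2·n)` is
available but off by default — with the hundreds of sequences typical of
these alignments it is negligible. Region contrasts use the two-sided
Mann-Whitney U test via `stats::wilcox.test`: exact enumeration for
groups below 20 tie-free columns, otherwise the normal approximation with
tie and continuity correction. Information and weight are tested
separately and both reported.

The MSA generator substitutes each column independently (uniformly over
the 19 non-consensus residues, with region-specific rates) and deletes
whole named regions per sequence to emulate alternative splicing. It has
no phylogeny: no tree, no rate matrices, no indel model beyond
region-level deletion. Statistical power estimated on it transfers to
real alignments only insofar as columns are approximately independent.

## The synthetic generator as study design

Generator defaults are the study conditions, fixed once:

| Quantity | Default | Rationale |
|---|---|---|
| wave period | 25 s | middle of the observed 20–30 s range |
| pulse width | 8 s | observed lifetime of protein puncta per cycle |
| waveform | raised-cosine pulse train | puncta are transient, not sinusoidal; sinusoid selectable for closed-form tests |
| trace duration | 150 s | six periods, enough repeats for correlation |
| bar length / height | 2 µm / 600 nm | fabricated array geometry |
| bar widths | 200–600 nm, 100 nm steps | fabricated gradient |
| pixel size / PSF sigma | 50 nm / 150 nm | confocal sampling near Nyquist |
| photon scale | 1000 counts per unit density | shot-noise SNR ≈ 30 on the flat SLB |
| FRAP sampling | 2 s over 120 s | the experimental acquisition |
| MSA size | 200 sequences | order of the 299/183-species alignments |

What the generator does **not** emulate: 3D optical sectioning or
vectorial PSFs, photobleaching during wave acquisition, wave propagation
in space (traces are ROI-level), membrane tension effects, and
phylogenetic correlation between sequences. Passing recovery tests on
synthetic data therefore validates the estimators and their
implementation, not the biological model.

## Numerical choices

* All random draws for one dataset flow from a single seed; fixed seed ⇒
  bit-identical output.
* PSF convolution is cyclic FFT with a normalized kernel: flux conserved
  to machine precision; fields include a half-pitch margin so wrap-around
  never touches a bar.
* Bilinear resampling everywhere; rotation and translation composed into
  one mapping.
* Moving averages shrink their window symmetrically at trace edges rather
  than dropping samples.
* 0-based, pixel-centre image coordinates; orientation measured
  counterclockwise from the vertical image axis.
* Degenerate inputs fail loudly with typed conditions
  (`curvesense_*` classes): zero-variance traces, mismatched grids,
  all-gap columns, overlapping masks, non-positive centre intensities.

## Problem sizes

The shipped tests and the acceptance script use: 100 replicate trace
pairs per phase operating point (21 combinations of offset × frame
interval), fields of 60 bars for ratio recovery and 30 bars per width for
the density profile, 50–100 replicate fits for Hill and FRAP noise
studies, and 20–100 replicate alignments (200 × 132) for the conservation
contrast. These sizes give standard errors comfortably below the decision
thresholds while keeping a full run in minutes on one core.

## Worked example

```{r example, eval = FALSE}
## two-channel waves with a 0.8 s offset, fast-stream sampling
tr <- simulate_wave_traces(wave_params(phase_offsets = c(0, 0.8),
                                       frame_interval = 0.2, seed = 1))
xcorr_lag(trace_channel(tr, 1), trace_channel(tr, 0),
          max_lag = 8, smooth_window = 2, subsample = TRUE)

## nanobar field -> detection -> end/center ratio
fld <- simulate_nanobar_field(nanobar_field_params(
  widths = 300, bars_per_width = 60, end_enrichment = 1.385, seed = 1))
geo <- detect_nanobars(fld$lipid,
                       list(width = 300, length = 2000, pitch = 3000),
                       pixel_size = 50)
end_center_ratio(register_bars(fld$protein, geo))

## Hill fit at the reported affinity
conc <- c(0.1, 0.2, 0.3, 0.45, 0.6, 0.9, 1.5, 2.5, 5)
fit <- fit_hill(tibble::tibble(concentration_uM = conc,
                               density = hill_model(conc, 1, 0.6, 2.5)))
tidy(fit)
```

## Known limitations

* The phase estimator assumes a single dominant periodic component;
  multi-frequency or strongly non-stationary traces need windowing the
  caller must provide.
* Nanobar detection assumes the nominal orientation is known (arrays are
  lithographically regular); it does not search over angle.
* The FRAP model is single-exponential by design; diffusion-coupled or
  two-component recoveries will show systematic residuals.
* `detect_nanobars()` assigns every detection the expected width; fields
  mixing widths should be analysed per width (the generator lays widths
  out in separate blocks for exactly this reason).
* Mann-Whitney on columns treats columns as independent, which real
  alignments violate through phylogenetic structure; p-values on real
  data are anti-conservative to an unknown degree.
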