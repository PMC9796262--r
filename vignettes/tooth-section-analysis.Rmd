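---
title: "Quantitative microanalysis of tooth thin sections: models and methods"
author: "enamelQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative microanalysis of tooth thin sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enamelQuant)
```

# The measurement model

Enamel forms incrementally. Ameloblasts deposit matrix with a circadian
rhythm that is preserved as *cross-striations* along each enamel prism: the
spacing between two adjacent cross-striations is the amount of enamel formed
in one day, the daily secretion rate (DSR, µm/day). A longer-period rhythm
produces the accentuated *striae of Retzius*; their periodicity — the number
of daily increments between successive striae — is constant within a tooth
(here 8 days, determined at three independent locations). These two clocks
make the crown a datable archive: any feature that can be located along a
prism path can be assigned an age in days after the onset of crown
formation.

The chronology stage implements the standard accounting:

* **Cuspal enamel.** A prism path from the enamel–dentin junction (EDJ) to
  the outer enamel surface (OES) is divided into contiguous 100 µm zones.
  Each measurement spans at least three cross-striations; the zone rate is
  the mean of `span/crossings` over the zone's replicates. Cuspal formation
  time is the cuspal thickness divided by the *unweighted* mean of the zone
  rates. The unweighted mean was chosen because equal-width zones make the
  unweighted and length-weighted means coincide everywhere except in the
  partial outermost zone, where the difference is far below measurement
  noise.
* **Lateral enamel.** Crown height is divided into ten deciles. For deciles
  3–10 the formation time is (stria count) × (periodicity). In deciles 1–2
  individual striae cannot be resolved, so their time is the prism-path
  length between the cuspal–lateral boundary and the first stria of decile
  3, divided by the local DSR, rounded to whole days. Whether that path
  should be measured straight or along the prism curvature is not settled;
  the synthetic generator exposes both conventions (`deciles12PathMode`),
  with "curved" lengthening the straight path by 5% for sensitivity
  checks.
* **Total.** Total crown formation time is the sum of cuspal and lateral
  times; years use a 365-day year rounded to two decimals. All internal
  arithmetic is floating point; rounding to whole days happens only in
  `chronologyReport()`.

Periodicity uses the modal count across locations. A tie between modes
resolves to the *smallest* candidate — the conservative choice, since
periodicity multiplies every lateral decile — and both ties and
disagreements raise warnings for analyst review.

```{r chronology-example}
rec <- retziusRecord(c(8, 8, 8), c(0, 0, 3, 5, 7, 9, 11, 15, 19, 20),
                     deciles12LengthUm = 104, deciles12Dsr = 2)
totalCrownTime(564, lateralTime(rec))
```

# Registering elemental events on developmental time

Trace-element bands that run parallel to the striae of Retzius are growth
markings: they were written into the tissue at deposition. The event stage
turns a concentration transect (ppm against cumulative prism-path distance
from the EDJ) into a lettered, dated event timeline.

**Detection.** "Significant variation" has no published operational
definition, so the package defines events as maximal runs where the
concentration deviates from a robust baseline by more than `k` noise scales
(default `k = 3`). Two estimators needed care:

* *Baseline.* A running median tracks any band wider than its window, and
  the Sr bands of interest (33–121 days, i.e. roughly 65–560 µm at typical
  DSRs) are wider than any window that would still follow genuine baseline
  drift. The default baseline is therefore the global median
  (`baselineWindowUm = Inf`), which is exact when enrichments and
  depletions roughly balance — the observed geometry of alternating bands —
  and a finite running-median window remains available for profiles with
  real drift.
* *Noise scale.* The median absolute deviation of the residuals is inflated
  by the bands themselves (they occupy most of the profile), so the scale
  starts from `mad(diff(values))/sqrt(2)`, which piecewise-constant bands
  barely perturb. Because smoothing correlates neighboring samples, that
  difference-based scale understates the marginal noise of a denoised
  profile; a second pass re-estimates the scale from the residuals outside
  the provisional runs (sigma-clipping) and takes the larger of the two.
  In the noiseless limit both estimates are zero and detection is exact.

Runs of the same sign closer than one sample are merged; runs narrower than
`minWidthUm` (default three sample spacings) are discarded as noise. A
constant profile yields no events, and detection is invariant to adding a
global constant.

**Dating.** Distance converts to days by exact piecewise-constant
integration over the DSR zones: the time to traverse a zone is its length
over the zone rate. This deliberately reuses the cuspal-time methodology
with *local* rates rather than one global mean, because a global mean
distorts ages wherever the gradient is steep. The conversion is strictly
increasing and additive, with `daysToDistance()` as its inverse.

**Regularity.** Events are lettered A, B, … in formation order and the
inter-onset intervals summarized by their coefficient of variation. The
verdict is "aperiodic" above a CV of 0.25, "periodic" below, and
"indeterminate" with fewer than three events; an optional Monte-Carlo
p-value compares the observed CV against uniform random onsets over the
same span. The 0.25 threshold is a deliberate operationalization of a
qualitative claim: a strict clock has CV near 0, and the irregular
schedules of interest sit near 0.5, so the verdict is insensitive to the
exact threshold over a wide range.

**Sr-for-Ca substitution.** `srMolarRatio()` converts mass fractions to a
Sr/(Sr+Ca) molar ratio with M(Sr) = 87.62 and M(Ca) = 40.08 g/mol. Applied
to a 860 ppm Sr peak over 4.0×10⁵ ppm Ca it gives ≈ 9.8×10⁻⁴; the package
reports the computed arithmetic and never substitutes a remembered value
for it.

# SXRF quantification

Net per-element intensity maps (spectral deconvolution is upstream and out
of scope) are calibrated to mass fractions in five steps per pixel:

1. normalization to incoming flux (zero-flux pixels are masked, never
   propagated as NaN);
2. substrate background subtraction, with negative results clipped to zero
   and counted;
3. division by the line sensitivity (counts per µg/cm²) to an apparent
   areal density;
4. division by the self-absorption factor
   \(A = (1 - e^{-\chi\rho t})/(\chi\rho t)\), with
   \(\chi = (\mu/\rho)(E_0)/\sin\psi_{in} +
   (\mu/\rho)(E_{line})/\sin\psi_{out}\);
5. conversion to mass fraction, ppm = areal density / (ρ·t).

Sensitivities come from thin-foil standards (Ti, Fe, Cu at 59.0, 55.0 and
47.9 µg/cm²): each foil anchors the curve at its Kα energy, and other lines
are interpolated log-linearly in energy — a smooth-yield assumption that is
adequate between anchors and is *flagged* whenever a query extrapolates
beyond them (e.g. Ca below Ti, Zn and Sr above Cu).

The matrix is hydroxyapatite Ca₁₀(PO₄)₆(OH)₂ with mass-weighted µ/ρ over
Ca, P, O and H; enamel and dentin differ only by density (2.85 vs
1.6 g/cm³). µ/ρ values are an embedded NIST-XCOM-style table (1–20 keV,
with the P and Ca K-edges represented by paired below/above-edge rows so
log–log interpolation never bridges an edge); embedding keeps the
correction reproducible without external data. The beam geometry is not
fully determined by a detector scattering angle alone, so the defaults are
normal incidence and a 45° take-off — the standard reading of a
backscatter dual-detector layout, with both angles configurable and the
two detectors reduced to one summed channel. The intermediate-thickness
form of A is used throughout because it subsumes both the thin-sample
limit (A → 1 as t → 0) and the thick-sample limit.

The Gaussian map filter (`denoiseMap()`, default σ = 0.8 px) uses a
normalized separable kernel with edge replication, so constants are fixed
points and interior mass is preserved to 10⁻⁹.

# Raman band metrics

Crystallinity and carbonate substitution are monitored through the 960 cm⁻¹
ν₁ phosphate band and the 1070 cm⁻¹ carbonate band. Instrument-side
baseline and fitting settings were not published, so the package defaults
are stated explicitly and logged in output metadata:

* baseline: straight line through flanking anchor windows (a rubberband —
  lower convex hull — alternative is provided); a spectrum that *is* a
  line subtracts to exactly zero;
* integration windows: 930–990 cm⁻¹ and 1050–1090 cm⁻¹, standard apatite
  practice, configurable;
* band profile: pseudo-Voigt with a *common* width parameter for the
  Gaussian and Lorentzian parts, so the fitted width is the FWHM itself
  and both pure limits are nested (mixing 0 and 1); the 960 center is
  imposed rather than fitted, the convention for FWHM₉₆₀ maps.

One numerical trap matters: with a ~3 cm⁻¹ spectral step, a width seeded
from the discrete half-maximum crossing can underestimate the FWHM and
strand Levenberg–Marquardt in a pure-Lorentzian local minimum. The fit is
therefore multi-started over three widths and two mixing values and the
lowest-deviance solution kept. Non-convergent pixels are flagged and set
to missing rather than failing the map; a run-level warning fires above
20% failures. The FWHM₉₆₀ raster is rendered clipped to 10–16 cm⁻¹ for
shared color scales, but the data are never clipped.

# EDX ratios

`layerSummary()` reports per-layer max/min/mean/sd of P, Ca and Mg atomic
percents and computes Ca/P and (Ca+Mg)/P as ratios of the *unrounded*
means, rounding only at report time (elements to one decimal, ratios to
two). Ratio-of-means was preferred over mean-of-ratios because it
reproduces published inner-layer values exactly; where a published ratio
disagrees with the arithmetic of its own rounded means (the outer-layer
(Ca+Mg)/P case), the package reports its computed value rather than
silently matching the table.

# The synthetic generator: what it emulates, and what it does not

`generateSection()` builds a 2D wedge — a dentin strip left of the EDJ,
cuspal enamel from EDJ to OES — with *straight* prism paths. Real prisms
curve, but chronology depends only on the path-length parameterization, so
curvature is an image-reading concern, not a computational one. Defaults
are the study conditions:

* 1330 µm of cuspal enamel; zone-mean DSR rising linearly from 1.96 µm/day
  (innermost 100 µm zone) to 4.62 µm/day (outermost). The gradient is
  calibrated on *zone means* because published per-zone rates are zone
  averages; with a linear gradient this differs from endpoint calibration
  by the half-zone slope (~5% at the EDJ), which would otherwise be
  visible in the recovery tests. Linearity itself is a modeling choice:
  the published gradient is monotone without a stated functional form.
* 8-day periodicity; decile stria counts 3, 5, 7, 9, 11, 15, 19, 20
  (deciles 3–10, monotone toward the cervix, summing to 89); deciles 1–2
  as 104 µm of path at 2 µm/day (52 days). Only the published totals (89
  striae, deciles 3 and 10 counts) constrain the intermediate counts.
* eight alternating Sr enrichment/depletion events with durations between
  33 and 60 days (inside the published 33–121 day range) and irregular
  onsets (inter-onset CV ≈ 0.5): the specimen's banding is explicitly
  aperiodic, so the fixture must be too. Enrichments peak near 860 ppm and
  depletions near 320 ppm over a 500 ppm enamel baseline; the same
  schedule is imprinted synchronously in the dentin at 0.55 amplitude
  (peaks ~650 ppm), matching the observation that the markings occur
  simultaneously in both tissues. The dentin clock is a constant
  2.5 µm/day apposition rate — a simplification; real dentin rates vary.
* uniform Ca (4.0×10⁵ ppm enamel, 3.4×10⁵ dentin) and Zn rising
  exponentially (60 µm length scale) from ~100 ppm interior to an
  1800 ppm OES peak.

Noise models are standard detector statistics: multiplicative Gaussian
(default 5%) on rasters and spectra, Poisson on foil counts. Everything is
reproducible under the configured seed, with the caller's RNG state left
untouched.

Daily increments are laid down sequentially — the spacing at each step is
the local DSR — and the measurement tables are generated *from the
increments*, so the chronology stage applied to noiseless tables returns
the ground-truth chronology exactly. The ground truth is defined through
the same estimators the analysis uses (e.g. cuspal time = thickness over
mean zone rate); the raw increment count differs from the estimator's
output by design, since the estimator, not the hidden truth, is what a
real analysis reports.

What passing tests on these fixtures shows is that the *pipeline
arithmetic* is correct under realistic magnitudes and noise; it does not
validate image reading (prism tracing, stria counting from micrographs),
curved-prism geometry, spatially correlated instrument noise, or
overprinting of elemental signals after formation — none of which the
generator emulates.

# Problem sizes and numerical choices

The shipped tests run sections of 1330 µm at 2 µm pixels (≈ 440
increments, ≈ 770 × 8–24 px rasters), Raman cubes at 18 µm steps with
451-point spectra, and 100-replicate Monte-Carlo foil calibrations —
sizes chosen so the whole suite exercises every stage end to end in a few
seconds while remaining well above the granularity of the effects under
test. Degenerate inputs have defined behavior throughout: constant
profiles detect nothing, empty event sets return an "indeterminate"
timeline, flat spectra are flagged rather than fitted, zero-flux pixels
are masked, and invalid configurations (gradient decreasing outward,
double-counted deciles 1–2, non-positive thickness) fail fast with
explicit messages.

# Known limitations

* Detection assumes bands alternate around a recoverable baseline; a
  profile dominated by same-signed excursions would bias the global
  median. The running-median option mitigates this only when bands are
  narrower than the window.
* The embedded µ/ρ table covers H, O, P, Ca between 1 and 20 keV at
  tabulation accuracy; exotic matrices or lines outside that range need a
  replacement table.
* Sensitivity extrapolation beyond the foil anchors (notably Sr) is
  log-linear and flagged, but unvalidated against measured yields.
* EDX ratios inherit whatever ZAF/matrix corrections the instrument
  applied upstream; the package only does the descriptive arithmetic.
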