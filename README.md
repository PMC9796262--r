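# enamelQuant

Quantitative microanalysis of tooth thin sections in R.

Dental enamel grows incrementally and never remodels, so a crown section is
a developmental archive: daily **cross-striations** along enamel prisms give
the daily secretion rate (DSR), the long-period **striae of Retzius**
partition the crown into datable intervals, and any chemical feature mapped
on the section — a strontium band, a zinc gradient — can be assigned an age
in days after the onset of crown formation. enamelQuant is for
histologists, bioarchaeologists and mineralized-tissue researchers who need
that chain of inference as tested, reusable code rather than spreadsheet
arithmetic.

The package implements five analysis stages plus a synthetic-data module:

* **Chronology** — per-zone DSR from cross-striation spacings
  (`dsrProfile`), stria periodicity (`striaPeriodicity`), cuspal time
  `T_cusp = h / mean(DSR_zone)`, lateral time per decile
  `T_d = n_d × P`, and the total `T_crown = T_cusp + T_lateral`
  (`totalCrownTime`).
* **Event registration** — robust detection of enrichment/depletion bands
  along an EDJ→OES transect (`detectEvents`), exact piecewise conversion of
  distance to developmental days `t(x) = Σ ℓ_z / DSR_z`
  (`distanceToDays`), lettered timelines with a regularity verdict
  (`timeEvents`), and Sr/(Sr+Ca) molar ratios (`srMolarRatio`).
* **SXRF quantification** — foil-standard sensitivity calibration
  (`calibrateSensitivity`), hydroxyapatite matrix self-absorption
  correction `A = (1 − e^{−χρt})/(χρt)` (`attenuationFactor`), and the full
  counts → ppm chain (`quantifyMap`), with Gaussian map denoising
  (`denoiseMap`).
* **Raman metrics** — baseline subtraction, band areas, and FWHM of the
  960 cm⁻¹ phosphate band from a fixed-center pseudo-Voigt fit
  (`bandMetrics`, `metricMaps`), yielding I₁₀₇₀/I₉₆₀ and FWHM₉₆₀ rasters.
* **EDX ratios** — per-layer atomic-percent summaries with Ca/P and
  (Ca+Mg)/P computed from unrounded means (`layerSummary`).
* **Synthetic sections** — `generateSection()` builds a 2D enamel/dentin
  wedge with known ground truth (increment positions, chronology, event
  schedule, element fields) so every stage is testable without instrument
  data.

## Worked example

Chronology from the published worked example (cuspal enamel 564 days,
deciles 1–2 as 104 µm at 2 µm/day, 89 striae in deciles 3–10, periodicity
8 days):

```r
library(enamelQuant)
rec <- retziusRecord(c(8, 8, 8), c(0, 0, 3, 5, 7, 9, 11, 15, 19, 20),
                     deciles12LengthUm = 104, deciles12Dsr = 2)
totalCrownTime(564, lateralTime(rec))
#> CrownChronology
#>   cuspal:    564 days
#>   lateral:   764 days (deciles 1-2: 52, deciles 3-10: 712)
#>   total:    1328 days (3.64 years)
```

The lateral deciles 3–10 contribute 89 × 8 = 712 days; with the 52 days of
deciles 1–2 and the 564 cuspal days the crown took 1328 days (3.64 years)
to form.

Sr banding on a synthetic section generated under the study conditions
(DSR gradient 1.96 → 4.62 µm/day, 8 aperiodic events, 5% noise):

```r
sec  <- generateSection(sectionConfig(seed = 7), includeRaman = FALSE)
det  <- detectEvents(extractTransect(denoiseMap(sectionMaps(sec)$Sr)))
prof <- dsrProfile(sectionTables(generateSection(
          sectionConfig(noiseSd = 0, heightPx = 4), includeRaman = FALSE))$spacings)
timeEvents(det, prof)
#> EventTimeline: 8 events, verdict 'aperiodic'
#>   inter-onset CV 0.542
#>  label    kind start_um end_um peak_ppm  onset_day   end_day duration_days
#>      A  enrich        8     78 879.8708   4.090387  39.88127      35.79088
#>      B deplete       84    154 307.2430  42.949059  76.04210      33.09304
#>      C  enrich      164    306 892.3004  80.655487 141.64576      60.99027
#>      ...
srMolarRatio(860, 4.0e5)
#> [1] 0.0009825078
```

All eight injected events are recovered in order with durations within a
few percent of the configured schedule, the inter-onset intervals read as
aperiodic (CV 0.54), and the 860 ppm Sr peak over 4.0×10⁵ ppm Ca
corresponds to a Sr/(Sr+Ca) molar ratio of ~1×10⁻³ — far below the
substitution levels known to alter apatite structure.

A full pipeline run (`runPipeline`) executes any subset of the stages
`simulate`, `chronology`, `events`, `sxrf`, `raman`, `edx`,
`replicate-paper` and writes a JSON report plus calibrated rasters; a thin
CLI wrapper lives at `inst/scripts/enamelquant.R`.

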