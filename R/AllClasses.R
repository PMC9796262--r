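#' @import methods
NULL

#' Daily secretion rate profile along a prism path
#'
#' Per-zone daily secretion rates (DSR) measured along an enamel prism path
#' from the enamel-dentin junction (EDJ) outward. The path is divided into
#' contiguous zones of equal width (conventionally 100 um); each zone carries
#' the mean cross-striation spacing measured there, in um/day, together with
#' the number of replicate measurements behind that mean.
#'
#' @slot zoneWidthUm width of each zone in um.
#' @slot zoneIndex integer zone indices, contiguous from 0 at the EDJ.
#' @slot zoneRate mean DSR per zone, um/day.
#' @slot nMeasurements replicate measurement count per zone.
#' @seealso [dsrProfile()], [distanceToDays()]
#' @export
setClass("DSRProfile",
  slots = c(
    zoneWidthUm   = "numeric",
    zoneIndex     = "integer",
    zoneRate      = "numeric",
    nMeasurements = "integer"
  )
)

setValidity("DSRProfile", function(object) {
  msg <- character()
  if (length(object@zoneWidthUm) != 1L || object@zoneWidthUm <= 0)
    msg <- c(msg, "zoneWidthUm must be a single positive number")
  n <- length(object@zoneIndex)
  if (length(object@zoneRate) != n || length(object@nMeasurements) != n)
    msg <- c(msg, "zoneIndex, zoneRate and nMeasurements must have equal length")
  if (n > 0 && !identical(object@zoneIndex, seq_len(n) - 1L))
    msg <- c(msg, "zone indices must be contiguous from 0 at the EDJ")
  if (any(!is.finite(object@zoneRate)) || any(object@zoneRate <= 0))
    msg <- c(msg, "all zone rates must be positive and finite")
  if (length(msg)) msg else TRUE
})

#' Striae of Retzius record
#'
#' Counts of long-period growth lines (striae of Retzius) needed to time the
#' lateral enamel: the stria periodicity in days, the raw cross-striation
#' counts between successive striae at each sampling location, the stria
#' count per decile of crown height, and the prism-path length and local DSR
#' used for the first two deciles where individual striae cannot be resolved.
#'
#' @slot periodicityDays integer stria periodicity in days.
#' @slot periodicityCounts cross-striation counts between adjacent striae at
#'   each sampling location (three locations in typical practice).
#' @slot decileStriaCounts integer stria counts for deciles 1..10 (deciles
#'   1-2 are usually 0 and handled through `deciles12LengthUm`).
#' @slot deciles12LengthUm prism-path length covering deciles 1-2, um.
#' @slot deciles12Dsr local DSR for deciles 1-2, um/day.
#' @export
setClass("RetziusRecord",
  slots = c(
    periodicityDays   = "integer",
    periodicityCounts = "integer",
    decileStriaCounts = "integer",
    deciles12LengthUm = "numeric",
    deciles12Dsr      = "numeric"
  )
)

setValidity("RetziusRecord", function(object) {
  msg <- character()
  if (length(object@periodicityDays) != 1L || object@periodicityDays < 1L)
    msg <- c(msg, "periodicityDays must be a single integer >= 1")
  if (length(object@periodicityCounts) < 1L)
    msg <- c(msg, "periodicityCounts must be non-empty")
  if (length(object@decileStriaCounts) != 10L)
    msg <- c(msg, "decileStriaCounts must have length 10")
  if (any(object@decileStriaCounts < 0L))
    msg <- c(msg, "decile stria counts must be non-negative")
  if (object@deciles12LengthUm < 0 || object@deciles12Dsr <= 0)
    msg <- c(msg, "deciles 1-2 length must be >= 0 and local DSR > 0")
  if (length(msg)) msg else TRUE
})

#' Crown formation chronology
#'
#' Formation-time budget of a molar crown: cuspal enamel time, the time for
#' deciles 1-2 of the lateral enamel (estimated from prism-path length and
#' local DSR), per-decile times for deciles 3-10 (stria count x periodicity),
#' the lateral total, and the grand total in days and years.
#'
#' @slot cuspalDays cuspal enamel formation time, days.
#' @slot deciles12Days formation time of deciles 1-2, days.
#' @slot perDecileDays formation time per decile (length 10; deciles 1-2 are
#'   NA, their joint time lives in `deciles12Days`).
#' @slot lateralDays lateral enamel formation time, days.
#' @slot totalDays total crown formation time, days.
#' @slot totalYears total time in years (`totalDays/365`, 2 decimals).
#' @slot meanCuspalDsr mean cuspal DSR used for the cuspal time, um/day.
#' @export
setClass("CrownChronology",
  slots = c(
    cuspalDays    = "numeric",
    deciles12Days = "numeric",
    perDecileDays = "numeric",
    lateralDays   = "numeric",
    totalDays     = "numeric",
    totalYears    = "numeric",
    meanCuspalDsr = "numeric"
  )
)

setValidity("CrownChronology", function(object) {
  msg <- character()
  tol <- 1e-6
  if (length(object@perDecileDays) != 10L)
    msg <- c(msg, "perDecileDays must have length 10")
  lat <- object@deciles12Days + sum(object@perDecileDays[3:10])
  if (is.finite(lat) && abs(lat - object@lateralDays) > tol)
    msg <- c(msg, "lateralDays must equal deciles12Days + sum of decile 3-10 days")
  if (abs(object@cuspalDays + object@lateralDays - object@totalDays) > tol)
    msg <- c(msg, "totalDays must equal cuspalDays + lateralDays")
  if (abs(object@totalYears - round(object@totalDays / 365, 2)) > tol)
    msg <- c(msg, "totalYears must be totalDays/365 rounded to 2 decimals")
  if (length(msg)) msg else TRUE
})

#' Concentration transect along a prism path
#'
#' A profile of element concentration sampled along a prism path, with
#' cumulative path distance from the EDJ in um.
#'
#' @slot positionsUm strictly increasing distances from the EDJ, starting at 0.
#' @slot valuesPpm concentrations (ppm) at each position.
#' @export
setClass("TransectProfile",
  slots = c(positionsUm = "numeric", valuesPpm = "numeric")
)

setValidity("TransectProfile", function(object) {
  msg <- character()
  if (length(object@positionsUm) != length(object@valuesPpm))
    msg <- c(msg, "positions and values must have equal length")
  if (length(object@positionsUm) > 0) {
    if (object@positionsUm[1] != 0)
      msg <- c(msg, "positions must start at 0 (the EDJ)")
    if (any(diff(object@positionsUm) <= 0))
      msg <- c(msg, "positions must be strictly increasing")
  }
  if (any(object@valuesPpm < 0, na.rm = TRUE))
    msg <- c(msg, "concentrations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Timeline of trace-element banding events
#'
#' Lettered enrichment/depletion events along a transect, placed on the
#' developmental time axis, together with a regularity assessment of the
#' inter-onset intervals.
#'
#' @slot events data.frame with columns `label`, `kind` (enrich/deplete),
#'   `start_um`, `end_um`, `peak_ppm`, `onset_day`, `end_day`,
#'   `duration_days`.
#' @slot intervalsDays inter-onset intervals, days.
#' @slot cv coefficient of variation of the inter-onset intervals.
#' @slot pValue Monte-Carlo p-value of the observed CV under uniform random
#'   onsets (NA when not simulated).
#' @slot verdict one of "periodic", "aperiodic", "indeterminate".
#' @export
setClass("EventTimeline",
  slots = c(
    events        = "data.frame",
    intervalsDays = "numeric",
    cv            = "numeric",
    pValue        = "numeric",
    verdict       = "character"
  )
)

setValidity("EventTimeline", function(object) {
  if (!object@verdict %in% c("periodic", "aperiodic", "indeterminate"))
    return("verdict must be periodic, aperiodic or indeterminate")
  TRUE
})

#' Hydroxyapatite matrix model for XRF attenuation correction
#'
#' Sample model used to correct fluorescence intensities for absorption in
#' the mineral matrix: hydroxyapatite Ca10(PO4)6(OH)2 with phase-specific
#' densities, section thickness, incident beam energy and beam geometry.
#'
#' @slot densityEnamel enamel density, g/cm^3.
#' @slot densityDentin dentin density, g/cm^3.
#' @slot thicknessUm section thickness, um.
#' @slot incidentEnergyKeV incident beam energy, keV.
#' @slot psiInDeg incidence angle from the sample surface, degrees.
#' @slot psiOutDeg take-off angle from the sample surface, degrees.
#' @seealso [matrixModel()], [attenuationFactor()]
#' @export
setClass("MatrixModel",
  slots = c(
    densityEnamel     = "numeric",
    densityDentin     = "numeric",
    thicknessUm       = "numeric",
    incidentEnergyKeV = "numeric",
    psiInDeg          = "numeric",
    psiOutDeg         = "numeric"
  )
)

setValidity("MatrixModel", function(object) {
  msg <- character()
  if (object@densityEnamel <= 0 || object@densityDentin <= 0)
    msg <- c(msg, "phase densities must be positive")
  if (object@thicknessUm <= 0)
    msg <- c(msg, "thickness must be positive")
  if (object@incidentEnergyKeV <= 0)
    msg <- c(msg, "incident energy must be positive")
  for (a in c(object@psiInDeg, object@psiOutDeg))
    if (!(a > 0 && a <= 90))
      msg <- c(msg, "angles must lie in (0, 90] degrees")
  if (length(msg)) msg else TRUE
})

#' Per-element raster map
#'
#' A gridded single-element raster with an explicit units state that tracks
#' its position along the calibration chain (raw counts, flux-normalized
#' counts, areal density in ug/cm^2, or mass fraction in ppm), the pixel
#' size, and a per-pixel phase mask (enamel / dentin / background).
#'
#' @slot element element symbol (e.g. "Ca", "Zn", "Sr").
#' @slot grid numeric matrix of pixel values.
#' @slot pixelSizeUm pixel edge length, um.
#' @slot unitsState one of "counts", "flux_normalized", "areal_density",
#'   "ppm".
#' @slot phaseMask character matrix, same shape as `grid`, with entries
#'   "enamel", "dentin" or "background".
#' @export
setClass("ElementMap",
  slots = c(
    element     = "character",
    grid        = "matrix",
    pixelSizeUm = "numeric",
    unitsState  = "character",
    phaseMask   = "matrix"
  )
)

.unitsStates <- c("counts", "flux_normalized", "areal_density", "ppm")

setValidity("ElementMap", function(object) {
  msg <- character()
  if (!object@unitsState %in% .unitsStates)
    msg <- c(msg, paste("unitsState must be one of:",
                        paste(.unitsStates, collapse = ", ")))
  if (!identical(dim(object@grid), dim(object@phaseMask)))
    msg <- c(msg, "grid and phaseMask must have the same dimensions")
  if (!all(object@phaseMask %in% c("enamel", "dentin", "background")))
    msg <- c(msg, "phaseMask entries must be enamel, dentin or background")
  if (object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be positive")
  if (object@unitsState == "ppm" &&
      any(object@grid < 0, na.rm = TRUE))
    msg <- c(msg, "ppm values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Raman spectral map
#'
#' A rectangular grid of Raman spectra sharing one wavenumber axis, as
#' acquired by raster-scanning a tooth section (conventionally ~18 um
#' steps, 450-1800 cm^-1 window).
#'
#' @slot wavenumbers strictly increasing wavenumber axis, cm^-1.
#' @slot cube numeric array (rows x cols x wavenumbers) of intensities.
#' @slot stepUm raster step, um.
#' @slot phaseMask character matrix (rows x cols) of tissue phases.
#' @export
setClass("RamanMap",
  slots = c(
    wavenumbers = "numeric",
    cube        = "array",
    stepUm      = "numeric",
    phaseMask   = "matrix"
  )
)

setValidity("RamanMap", function(object) {
  msg <- character()
  d <- dim(object@cube)
  if (length(d) != 3L)
    msg <- c(msg, "cube must be a 3-d array (rows x cols x wavenumbers)")
  else {
    if (d[3] != length(object@wavenumbers))
      msg <- c(msg, "third cube dimension must match the wavenumber axis")
    if (!identical(dim(object@phaseMask), d[1:2]))
      msg <- c(msg, "phaseMask must match the spatial grid")
  }
  if (any(diff(object@wavenumbers) <= 0))
    msg <- c(msg, "wavenumbers must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Foil-sensitivity calibration curve
#'
#' Per-element areal-density sensitivities (normalized counts per ug/cm^2)
#' anchored at the fluorescence-line energies of the measured foil
#' standards; sensitivities at other line energies are interpolated
#' log-linearly in energy.
#'
#' @slot element foil element symbols.
#' @slot lineEnergyKeV K-alpha line energy per anchor, keV.
#' @slot sensitivity sensitivity per anchor, counts per (ug/cm^2).
#' @seealso [calibrateSensitivity()], [predictSensitivity()]
#' @export
setClass("SensitivityCurve",
  slots = c(
    element       = "character",
    lineEnergyKeV = "numeric",
    sensitivity   = "numeric"
  )
)

setValidity("SensitivityCurve", function(object) {
  msg <- character()
  n <- length(object@element)
  if (length(object@lineEnergyKeV) != n || length(object@sensitivity) != n)
    msg <- c(msg, "slots must have equal length")
  if (n < 1L) msg <- c(msg, "at least one anchor is required")
  if (any(object@sensitivity <= 0)) msg <- c(msg, "sensitivities must be positive")
  if (is.unsorted(object@lineEnergyKeV, strictly = TRUE))
    msg <- c(msg, "anchors must be ordered by increasing line energy")
  if (length(msg)) msg else TRUE
})

#' Configuration of a synthetic tooth section
#'
#' Parameters of the synthetic 2D enamel wedge generator: geometry, growth
#' kinetics (DSR gradient, stria periodicity, decile counts), the schedule of
#' Sr enrichment/depletion events on the developmental-day axis, element
#' concentration levels, raster resolution, noise and seed. Defaults are set
#' in [sectionConfig()].
#'
#' @slot cuspalThicknessUm enamel thickness along the cuspal prism path, um.
#' @slot dsrInner,dsrOuter mean DSR of the innermost / outermost 100-um zone,
#'   um/day (linear gradient in between).
#' @slot periodicityDays stria periodicity, days.
#' @slot decileStriaCounts stria counts for deciles 1..10.
#' @slot deciles12LengthUm,deciles12Dsr prism-path length and local DSR for
#'   deciles 1-2.
#' @slot deciles12PathMode "straight" or "curved" prism-path length
#'   convention for deciles 1-2.
#' @slot srEventSpec data.frame with columns `onset_day`, `duration_days`,
#'   `amplitude_ppm`, `sign` ("enrich"/"deplete").
#' @slot znSurfacePeakPpm,znInteriorPpm,caLevelPpm,srBaselinePpm element
#'   levels in enamel, ppm.
#' @slot caDentinPpm,znDentinPpm,srDentinBaselinePpm dentin levels, ppm.
#' @slot dentinBandFactor scaling of Sr band amplitudes in dentin.
#' @slot dentinDsr dentin apposition rate used to imprint the synchronous
#'   dentin banding, um/day.
#' @slot dentinWidthUm width of the dentin strip left of the EDJ, um.
#' @slot heightPx raster height in pixels.
#' @slot pixelSizeUm raster pixel size, um.
#' @slot noiseSd fractional (multiplicative Gaussian) noise on maps.
#' @slot seed integer seed.
#' @export
setClass("SectionConfig",
  slots = c(
    cuspalThicknessUm  = "numeric",
    dsrInner           = "numeric",
    dsrOuter           = "numeric",
    periodicityDays    = "integer",
    decileStriaCounts  = "integer",
    deciles12LengthUm  = "numeric",
    deciles12Dsr       = "numeric",
    deciles12PathMode  = "character",
    srEventSpec        = "data.frame",
    znSurfacePeakPpm   = "numeric",
    znInteriorPpm      = "numeric",
    caLevelPpm         = "numeric",
    srBaselinePpm      = "numeric",
    caDentinPpm        = "numeric",
    znDentinPpm        = "numeric",
    srDentinBaselinePpm = "numeric",
    dentinBandFactor   = "numeric",
    dentinDsr          = "numeric",
    dentinWidthUm      = "numeric",
    heightPx           = "integer",
    pixelSizeUm        = "numeric",
    noiseSd            = "numeric",
    seed               = "integer"
  )
)

setValidity("SectionConfig", function(object) {
  msg <- character()
  if (object@dsrInner > object@dsrOuter)
    msg <- c(msg, "dsrInner must be <= dsrOuter")
  if (object@dsrInner <= 0) msg <- c(msg, "DSR values must be positive")
  if (object@periodicityDays < 1L) msg <- c(msg, "periodicityDays must be >= 1")
  if (length(object@decileStriaCounts) != 10L)
    msg <- c(msg, "decileStriaCounts must have length 10")
  if (any(object@decileStriaCounts < 0L))
    msg <- c(msg, "decile stria counts must be non-negative")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be positive")
  if (object@cuspalThicknessUm <= 0)
    msg <- c(msg, "cuspalThicknessUm must be positive")
  es <- object@srEventSpec
  need <- c("onset_day", "duration_days", "amplitude_ppm", "sign")
  if (!all(need %in% names(es)))
    msg <- c(msg, paste("srEventSpec needs columns:", paste(need, collapse = ", ")))
  else if (nrow(es) > 0) {
    if (any(es$duration_days <= 0)) msg <- c(msg, "event durations must be > 0")
    if (any(es$amplitude_ppm < 0)) msg <- c(msg, "event amplitudes must be >= 0")
    if (is.unsorted(es$onset_day, strictly = TRUE))
      msg <- c(msg, "event onsets must be strictly increasing")
    if (!all(es$sign %in% c("enrich", "deplete")))
      msg <- c(msg, "event sign must be enrich or deplete")
  }
  if (!object@deciles12PathMode %in% c("straight", "curved"))
    msg <- c(msg, "deciles12PathMode must be straight or curved")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic section
#'
#' Noise-free truth attached to a generated section: the chronology implied
#' by the configuration (through the same estimators the analysis stages
#' use), the event schedule in days, per-element noiseless concentration
#' fields, the daily increment positions, and the per-zone true rates.
#'
#' @slot chronology a [CrownChronology-class].
#' @slot eventDays data.frame `label`, `onset_day`, `duration_days`, `sign`.
#' @slot elementFields named list of noiseless ppm matrices.
#' @slot incrementPositionsUm cumulative daily-increment positions from the
#'   EDJ, um (element k+1 is the position reached after k days).
#' @slot zoneRates true mean DSR per 100-um zone, um/day.
#' @export
setClass("GroundTruth",
  slots = c(
    chronology           = "CrownChronology",
    eventDays            = "data.frame",
    elementFields        = "list",
    incrementPositionsUm = "numeric",
    zoneRates            = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  if (nrow(object@eventDays) > 1 &&
      is.unsorted(object@eventDays$onset_day, strictly = TRUE))
    return("event onsets must be strictly increasing")
  TRUE
})

#' A generated synthetic tooth section
#'
#' Bundle returned by [generateSection()]: measurement tables (as the
#' chronology stage consumes them), element maps in raw-counts and ppm
#' state, a Raman map, and the ground truth.
#'
#' @slot config the [SectionConfig-class] used.
#' @slot tables named list of data.frames: `spacings`, `deciles`,
#'   `periodicity`.
#' @slot maps named list of [ElementMap-class] objects (ppm state, with
#'   noise when configured).
#' @slot truth the [GroundTruth-class].
#' @slot raman a [RamanMap-class] (may be a 0-pixel stub when disabled).
#' @export
setClass("SyntheticSection",
  slots = c(
    config = "SectionConfig",
    tables = "list",
    maps   = "list",
    truth  = "GroundTruth",
    raman  = "RamanMap"
  )
)
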