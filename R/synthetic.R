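#' @include AllClasses.R sxrf.R chronology.R events.R
NULL

#' Default Sr event schedule for the synthetic section
#'
#' Eight alternating enrichment/depletion events with durations between 33
#' and 60 days and irregular onsets (inter-onset CV ~0.5, i.e. clearly
#' aperiodic), fitting inside the formation span of the default cuspal
#' transect (~437 days). Amplitudes place enrichment peaks near 860 ppm and
#' depletion troughs near 320 ppm over a 500 ppm baseline.
#'
#' @return data.frame with columns `onset_day`, `duration_days`,
#'   `amplitude_ppm`, `sign`.
#' @export
defaultSrEvents <- function() {
  data.frame(
    onset_day     = c(5, 44, 82, 150, 196, 238, 360, 401),
    duration_days = c(35, 33, 60, 40, 34, 55, 36, 33),
    amplitude_ppm = rep(c(360, 180), 4),
    sign          = rep(c("enrich", "deplete"), 4)
  )
}

#' Build a synthetic-section configuration
#'
#' Defaults reproduce the study conditions of the analyzed molar: 1330 um of
#' cuspal enamel, zone-mean DSR rising linearly from 1.96 um/day in the
#' innermost 100-um zone to 4.62 um/day in the outermost, 8-day stria
#' periodicity, decile stria counts 3..20 summing to 89 for deciles 3-10,
#' deciles 1-2 covered by 104 um of prism path at 2 um/day (52 days),
#' uniform Ca at 4.0e5 ppm (3.4e5 in dentin), Zn rising from ~100 ppm
#' interior to an 1800 ppm surface peak, and eight aperiodic Sr events over
#' a 500 ppm baseline, imprinted synchronously in the dentin.
#'
#' @param cuspalThicknessUm,dsrInner,dsrOuter,periodicityDays growth model.
#' @param decileStriaCounts,deciles12LengthUm,deciles12Dsr,deciles12PathMode
#'   lateral-enamel geometry ("curved" lengthens the deciles 1-2 path by
#'   5 percent for sensitivity checks).
#' @param srEventSpec Sr event schedule (see [defaultSrEvents()]).
#' @param znSurfacePeakPpm,znInteriorPpm,caLevelPpm,srBaselinePpm enamel
#'   levels, ppm.
#' @param caDentinPpm,znDentinPpm,srDentinBaselinePpm dentin levels, ppm.
#' @param dentinBandFactor scaling of Sr event amplitudes in dentin.
#' @param dentinDsr dentin apposition rate, um/day.
#' @param dentinWidthUm width of the dentin strip, um.
#' @param heightPx raster height, pixels.
#' @param pixelSizeUm raster pixel size, um.
#' @param noiseSd fractional Gaussian noise on maps (0 disables).
#' @param seed integer seed.
#' @return a [SectionConfig-class].
#' @export
sectionConfig <- function(cuspalThicknessUm = 1330,
                          dsrInner = 1.96, dsrOuter = 4.62,
                          periodicityDays = 8L,
                          decileStriaCounts = c(0L, 0L, 3L, 5L, 7L, 9L,
                                                11L, 15L, 19L, 20L),
                          deciles12LengthUm = 104, deciles12Dsr = 2,
                          deciles12PathMode = "straight",
                          srEventSpec = defaultSrEvents(),
                          znSurfacePeakPpm = 1800, znInteriorPpm = 100,
                          caLevelPpm = 4.0e5, srBaselinePpm = 500,
                          caDentinPpm = 3.4e5, znDentinPpm = 220,
                          srDentinBaselinePpm = 450,
                          dentinBandFactor = 0.55,
                          dentinDsr = 2.5, dentinWidthUm = 200,
                          heightPx = 24L, pixelSizeUm = 2,
                          noiseSd = 0.05, seed = 1L) {
  new("SectionConfig",
             cuspalThicknessUm = cuspalThicknessUm,
             dsrInner = dsrInner, dsrOuter = dsrOuter,
             periodicityDays = as.integer(periodicityDays),
             decileStriaCounts = as.integer(decileStriaCounts),
             deciles12LengthUm = deciles12LengthUm,
             deciles12Dsr = deciles12Dsr,
             deciles12PathMode = deciles12PathMode,
             srEventSpec = srEventSpec,
             znSurfacePeakPpm = znSurfacePeakPpm,
             znInteriorPpm = znInteriorPpm,
             caLevelPpm = caLevelPpm, srBaselinePpm = srBaselinePpm,
             caDentinPpm = caDentinPpm, znDentinPpm = znDentinPpm,
             srDentinBaselinePpm = srDentinBaselinePpm,
             dentinBandFactor = dentinBandFactor,
             dentinDsr = dentinDsr, dentinWidthUm = dentinWidthUm,
             heightPx = as.integer(heightPx), pixelSizeUm = pixelSizeUm,
             noiseSd = noiseSd, seed = as.integer(seed))
}

# linear DSR gradient calibrated so that the innermost / outermost 100-um
# zone MEANS equal dsrInner / dsrOuter (published per-zone rates are zone
# averages, not endpoint values)
.dsrGradient <- function(config, zoneWidthUm = 100) {
  X <- config@cuspalThicknessUm
  nZones <- ceiling(X / zoneWidthUm)
  if (config@dsrInner == config@dsrOuter || nZones < 2)
    return(list(a = config@dsrInner, b = 0, nZones = nZones))
  wLast <- X - zoneWidthUm * (nZones - 1)
  c0 <- zoneWidthUm / 2
  cLast <- zoneWidthUm * (nZones - 1) + wLast / 2
  b <- (config@dsrOuter - config@dsrInner) / (cLast - c0)
  a <- config@dsrInner - b * c0
  list(a = a, b = b, nZones = nZones)
}

# cumulative daily increment positions: element k+1 is the distance reached
# after k days; spacing at x is the local DSR
.incrementPositions <- function(config) {
  g <- .dsrGradient(config)
  X <- config@cuspalThicknessUm
  pos <- numeric(ceiling(X / config@dsrInner) + 2L)
  pos[1] <- 0
  k <- 1L
  while (pos[k] < X) {
    sp <- g$a + g$b * pos[k]
    if (sp <= 0) stop("DSR gradient became non-positive")
    if (k + 1L > length(pos)) pos <- c(pos, numeric(length(pos)))
    pos[k + 1L] <- pos[k] + sp
    k <- k + 1L
  }
  pos[seq_len(k)]
}

.dayAtDistance <- function(distanceUm, incPos) {
  stats::approx(incPos, seq_along(incPos) - 1, xout = distanceUm,
                rule = 2)$y
}

# partition each zone's increments into runs of >= 3 crossings and emit
# span/crossing measurements (noise multiplies the spans)
.spacingTable <- function(incPos, X, zoneWidthUm, noiseSd, nPerZone = 3L) {
  nZones <- ceiling(X / zoneWidthUm)
  rows <- list()
  for (z in seq_len(nZones) - 1L) {
    lo <- z * zoneWidthUm
    hi <- min((z + 1) * zoneWidthUm, X)
    # increment intervals fully inside the zone
    idx <- which(incPos >= lo - 1e-9 & incPos <= hi + 1e-9)
    if (length(idx) < 4L) idx <- which(incPos >= lo - 1e-9)[1:4]
    nInt <- length(idx) - 1L
    nGrp <- max(1L, min(nPerZone, nInt %/% 3L))
    bounds <- round(seq(0, nInt, length.out = nGrp + 1L))
    for (gi in seq_len(nGrp)) {
      i1 <- idx[1] + bounds[gi]
      i2 <- idx[1] + bounds[gi + 1L]
      span <- incPos[i2] - incPos[i1]
      rows[[length(rows) + 1L]] <-
        data.frame(zone_index = z, span_um = span,
                   n_crossings = bounds[gi + 1L] - bounds[gi])
    }
  }
  out <- do.call(rbind, rows)
  if (noiseSd > 0)
    out$span_um <- out$span_um *
      (1 + stats::rnorm(nrow(out), sd = noiseSd))
  out
}

.srField <- function(dayAt, baseline, spec, factor = 1) {
  function(x) {
    d <- dayAt(x)
    v <- rep(baseline, length(x))
    if (nrow(spec)) for (j in seq_len(nrow(spec))) {
      inBand <- d >= spec$onset_day[j] &
                d < spec$onset_day[j] + spec$duration_days[j]
      amp <- spec$amplitude_ppm[j] * factor
      v[inBand] <- v[inBand] +
        if (spec$sign[j] == "enrich") amp else -amp
    }
    v
  }
}

.pseudoVoigt <- function(x, center, fwhm, eta) {
  u <- (x - center) / (fwhm / 2)
  eta / (1 + u^2) + (1 - eta) * exp(-log(2) * u^2)
}

.ramanCube <- function(config, phaseRow) {
  wn <- seq(450, 1800, by = 3)
  step <- 18
  nCols <- max(4L, floor(length(phaseRow) * config@pixelSizeUm / step))
  nRows <- 4L
  # pick the phase at each coarse pixel from the fine mask
  fineIdx <- pmin(length(phaseRow),
                  pmax(1L, round((seq_len(nCols) - 0.5) * step /
                                 config@pixelSizeUm)))
  phases <- phaseRow[fineIdx]
  spec1 <- function(phase) {
    base <- 50 + 0.02 * wn
    if (phase == "dentin") {
      s <- 600 * .pseudoVoigt(wn, 960, 15.5, 0.3)
      s <- s + 146.2 * .pseudoVoigt(wn, 1070, 14, 0.3)
    } else {
      s <- 1000 * .pseudoVoigt(wn, 960, 11, 0.3)
      s <- s + 62.9 * .pseudoVoigt(wn, 1070, 14, 0.3)
    }
    base + s
  }
  cube <- array(0, dim = c(nRows, nCols, length(wn)))
  for (j in seq_len(nCols)) {
    s <- spec1(phases[j])
    for (i in seq_len(nRows)) {
      si <- s
      if (config@noiseSd > 0)
        si <- si * (1 + stats::rnorm(length(si), sd = config@noiseSd))
      cube[i, j, ] <- si
    }
  }
  new("RamanMap", wavenumbers = wn, cube = cube, stepUm = step,
      phaseMask = matrix(rep(phases, each = nRows), nRows, nCols))
}

#' Generate a synthetic tooth section with known ground truth
#'
#' Builds a 2D wedge with a dentin strip left of the EDJ and cuspal enamel
#' from the EDJ to the OES, with straight prism paths. Daily increments are
#' laid down with spacing equal to the local DSR (linear gradient along the
#' path); every `periodicityDays`-th increment is an accentuated stria. Sr
#' bands run parallel to the striae between each event's onset and end day
#' and are imprinted synchronously in the dentin. The return bundle carries
#' the measurement tables the chronology stage consumes, per-element ppm
#' maps (with configured noise), a Raman map, and the noise-free ground
#' truth. Reproducible under the configured seed.
#'
#' @param config a [SectionConfig-class].
#' @param includeRaman generate the Raman map (default TRUE).
#' @return a [SyntheticSection-class].
#' @examples
#' sec <- generateSection(sectionConfig(noiseSd = 0, heightPx = 4L))
#' groundTruth(sec)@chronology
#' @export
generateSection <- function(config, includeRaman = TRUE) {
  stopifnot(is(config, "SectionConfig"))
  validObject(config)
  if (any(config@decileStriaCounts[1:2] > 0L) && config@deciles12LengthUm > 0)
    stop("configuration error: deciles 1-2 carry both stria counts and a ",
         "prism-path length; their time would be counted twice")
  .withSeed(config@seed, {
    X <- config@cuspalThicknessUm
    px <- config@pixelSizeUm
    incPos <- .incrementPositions(config)
    dayAt <- function(x) .dayAtDistance(x, incPos)

    ## measurement tables ---------------------------------------------------
    spacings <- .spacingTable(incPos, X, 100, config@noiseSd)
    deciles <- data.frame(decile = 1:10,
                          stria_count = config@decileStriaCounts)
    periodicity <- data.frame(location = 1:3,
                              n_cross_striations =
                                rep(config@periodicityDays, 3L))
    striae <- incPos[seq(1L, length(incPos),
                         by = config@periodicityDays)]

    ## rasters ---------------------------------------------------------------
    nD <- max(1L, round(config@dentinWidthUm / px))
    nE <- max(1L, round(X / px))
    nR <- config@heightPx
    phaseRow <- c(rep("dentin", nD), rep("enamel", nE))
    phase <- matrix(rep(phaseRow, each = nR), nR, nD + nE)
    xE <- (seq_len(nE) - 0.5) * px          # distance from EDJ, enamel
    xD <- (rev(seq_len(nD)) - 0.5) * px     # distance from EDJ, dentin

    dbf <- config@dentinBandFactor
    srE <- .srField(dayAt, config@srBaselinePpm, config@srEventSpec)(xE)
    srD <- .srField(function(x) x / config@dentinDsr,
                    config@srDentinBaselinePpm, config@srEventSpec,
                    factor = dbf)(xD)
    znE <- config@znInteriorPpm +
      (config@znSurfacePeakPpm - config@znInteriorPpm) * exp((xE - X) / 60)
    fields <- list(
      Ca = cbind(matrix(config@caDentinPpm, nR, nD),
                 matrix(config@caLevelPpm, nR, nE)),
      Zn = cbind(matrix(config@znDentinPpm, nR, nD),
                 matrix(rep(znE, each = nR), nR, nE)),
      Sr = cbind(matrix(rep(srD, each = nR), nR, nD),
                 matrix(rep(srE, each = nR), nR, nE))
    )
    maps <- lapply(names(fields), function(el) {
      g <- fields[[el]]
      if (config@noiseSd > 0)
        g <- g * matrix(1 + stats::rnorm(length(g), sd = config@noiseSd),
                        nR, ncol(g))
      new("ElementMap", element = el, grid = pmax(g, 0), pixelSizeUm = px,
          unitsState = "ppm", phaseMask = phase)
    })
    names(maps) <- names(fields)

    raman <- if (includeRaman) .ramanCube(config, phaseRow)
             else new("RamanMap", wavenumbers = c(450, 453),
                      cube = array(0, c(1, 1, 2)), stepUm = 18,
                      phaseMask = matrix("enamel", 1, 1))

    ## ground truth ----------------------------------------------------------
    spacings0 <- .spacingTable(incPos, X, 100, noiseSd = 0)
    d12len <- config@deciles12LengthUm *
      if (config@deciles12PathMode == "curved") 1.05 else 1
    chron <- crownChronology(
      spacings0, rep(config@periodicityDays, 3L),
      config@decileStriaCounts, X, d12len, config@deciles12Dsr)
    spec <- config@srEventSpec
    eventDays <- if (nrow(spec)) data.frame(
      label = LETTERS[seq_len(nrow(spec))],
      onset_day = spec$onset_day,
      duration_days = spec$duration_days,
      sign = spec$sign)
    else data.frame(label = character(), onset_day = numeric(),
                    duration_days = numeric(), sign = character())
    truth <- new("GroundTruth",
                 chronology = chron$chronology,
                 eventDays = eventDays,
                 elementFields = fields,
                 incrementPositionsUm = incPos,
                 zoneRates = unname(zoneRates(chron$profile)))

    new("SyntheticSection",
        config = config,
        tables = list(spacings = spacings, deciles = deciles,
                      periodicity = periodicity,
                      striae = data.frame(position_um = striae)),
        maps = maps, truth = truth, raman = raman)
  })
}

#' Generate foil-standard pseudo-measurements
#'
#' Thin-foil calibration standards of known areal density measured under a
#' known flux: expected counts are sensitivity x areal density x flux, with
#' optional Poisson counting noise.
#'
#' @param elements foil element symbols (default Ti, Fe, Cu).
#' @param arealDensities areal densities, ug/cm^2 (defaults 59.0, 55.0,
#'   47.9).
#' @param sensitivityTruth true sensitivities, counts per (ug/cm^2), one
#'   per foil.
#' @param flux incoming flux (single positive number).
#' @param poissonNoise draw counts from a Poisson law (default FALSE).
#' @param seed seed used when noise is enabled.
#' @return data.frame with columns `element`, `areal_density`, `counts`,
#'   `flux`.
#' @export
generateFoilStandards <- function(elements = c("Ti", "Fe", "Cu"),
                                  arealDensities = c(59.0, 55.0, 47.9),
                                  sensitivityTruth,
                                  flux = 1, poissonNoise = FALSE,
                                  seed = 1L) {
  if (flux <= 0) stop("flux must be positive")
  if (any(arealDensities <= 0)) stop("areal densities must be positive")
  stopifnot(length(elements) == length(arealDensities),
            length(sensitivityTruth) == length(elements))
  expected <- sensitivityTruth * arealDensities * flux
  counts <- if (poissonNoise)
    .withSeed(seed, stats::rpois(length(expected), expected))
  else expected
  data.frame(element = elements, areal_density = arealDensities,
             counts = as.numeric(counts), flux = flux)
}
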