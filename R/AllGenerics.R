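#' @include AllClasses.R
NULL

#' Accessors for enamelQuant classes
#'
#' Small accessor family: slot access stays behind functions so internal
#' representations can evolve.
#'
#' @param object an enamelQuant S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mapElement", function(object) standardGeneric("mapElement"))

#' @rdname accessors
#' @export
setMethod("mapElement", "ElementMap", function(object) object@element)

#' @rdname accessors
#' @export
setGeneric("unitsState", function(object) standardGeneric("unitsState"))

#' @rdname accessors
#' @export
setMethod("unitsState", "ElementMap", function(object) object@unitsState)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setMethod("pixelSize", "ElementMap", function(object) object@pixelSizeUm)

#' @rdname accessors
#' @export
setGeneric("phaseMask", function(object) standardGeneric("phaseMask"))

#' @rdname accessors
#' @export
setMethod("phaseMask", "ElementMap", function(object) object@phaseMask)

#' @rdname accessors
#' @export
setMethod("phaseMask", "RamanMap", function(object) object@phaseMask)

#' @rdname accessors
#' @param x an `ElementMap`.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "ElementMap", function(x, ...) x@grid)

#' @rdname accessors
#' @export
setMethod("dim", "ElementMap", function(x) dim(x@grid))

#' @rdname accessors
#' @export
setGeneric("zoneRates", function(object) standardGeneric("zoneRates"))

#' @rdname accessors
#' @export
setMethod("zoneRates", "DSRProfile", function(object) {
  stats::setNames(object@zoneRate, object@zoneIndex)
})

#' @rdname accessors
#' @export
setMethod("zoneRates", "GroundTruth", function(object) object@zoneRates)

#' @rdname accessors
#' @export
setGeneric("zoneWidth", function(object) standardGeneric("zoneWidth"))

#' @rdname accessors
#' @export
setMethod("zoneWidth", "DSRProfile", function(object) object@zoneWidthUm)

#' @rdname accessors
#' @export
setGeneric("totalDays", function(object) standardGeneric("totalDays"))

#' @rdname accessors
#' @export
setMethod("totalDays", "CrownChronology", function(object) object@totalDays)

#' @rdname accessors
#' @export
setGeneric("totalYears", function(object) standardGeneric("totalYears"))

#' @rdname accessors
#' @export
setMethod("totalYears", "CrownChronology", function(object) object@totalYears)

#' @rdname accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))

#' @rdname accessors
#' @export
setMethod("events", "EventTimeline", function(object) object@events)

#' @rdname accessors
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))

#' @rdname accessors
#' @export
setMethod("verdict", "EventTimeline", function(object) object@verdict)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setMethod("groundTruth", "SyntheticSection", function(object) object@truth)

#' @rdname accessors
#' @export
setGeneric("sectionTables", function(object) standardGeneric("sectionTables"))

#' @rdname accessors
#' @export
setMethod("sectionTables", "SyntheticSection", function(object) object@tables)

#' @rdname accessors
#' @export
setGeneric("sectionMaps", function(object) standardGeneric("sectionMaps"))

#' @rdname accessors
#' @export
setMethod("sectionMaps", "SyntheticSection", function(object) object@maps)

#' @rdname accessors
#' @export
setGeneric("sectionRaman", function(object) standardGeneric("sectionRaman"))

#' @rdname accessors
#' @export
setMethod("sectionRaman", "SyntheticSection", function(object) object@raman)

## ---- show methods -------------------------------------------------------

setMethod("show", "DSRProfile", function(object) {
  cat(sprintf("DSRProfile: %d zones of %g um\n",
              length(object@zoneRate), object@zoneWidthUm))
  cat(sprintf("  rates %.3g -> %.3g um/day (EDJ -> OES), %d measurements\n",
              object@zoneRate[1], object@zoneRate[length(object@zoneRate)],
              sum(object@nMeasurements)))
})

setMethod("show", "CrownChronology", function(object) {
  cat("CrownChronology\n")
  if (is.finite(object@meanCuspalDsr))
    cat(sprintf("  cuspal:   %4.0f days (mean DSR %.3g um/day)\n",
                object@cuspalDays, object@meanCuspalDsr))
  else
    cat(sprintf("  cuspal:   %4.0f days\n", object@cuspalDays))
  cat(sprintf("  lateral:  %4.0f days (deciles 1-2: %.0f, deciles 3-10: %.0f)\n",
              object@lateralDays, object@deciles12Days,
              sum(object@perDecileDays[3:10])))
  cat(sprintf("  total:    %4.0f days (%.2f years)\n",
              object@totalDays, object@totalYears))
})

setMethod("show", "ElementMap", function(object) {
  d <- dim(object@grid)
  cat(sprintf("ElementMap %s: %d x %d px @ %g um [%s]\n",
              object@element, d[1], d[2], object@pixelSizeUm,
              object@unitsState))
  rng <- range(object@grid, na.rm = TRUE)
  cat(sprintf("  values %.4g .. %.4g\n", rng[1], rng[2]))
})

setMethod("show", "EventTimeline", function(object) {
  cat(sprintf("EventTimeline: %d events, verdict '%s'\n",
              nrow(object@events), object@verdict))
  if (nrow(object@events)) {
    cat(sprintf("  inter-onset CV %.3g", object@cv))
    if (is.finite(object@pValue)) cat(sprintf(" (MC p = %.3g)", object@pValue))
    cat("\n")
    print(object@events, row.names = FALSE)
  }
})

setMethod("show", "RamanMap", function(object) {
  d <- dim(object@cube)
  cat(sprintf("RamanMap: %d x %d px @ %g um, %d wavenumbers (%g-%g cm^-1)\n",
              d[1], d[2], object@stepUm, d[3],
              min(object@wavenumbers), max(object@wavenumbers)))
})

setMethod("show", "SensitivityCurve", function(object) {
  cat("SensitivityCurve anchors:\n")
  print(data.frame(element = object@element,
                   line_keV = object@lineEnergyKeV,
                   sensitivity = object@sensitivity), row.names = FALSE)
})

setMethod("show", "SyntheticSection", function(object) {
  cat("SyntheticSection\n")
  cat(sprintf("  enamel %g um, DSR %g -> %g um/day, periodicity %d days\n",
              object@config@cuspalThicknessUm, object@config@dsrInner,
              object@config@dsrOuter, object@config@periodicityDays))
  cat(sprintf("  %d Sr events, maps: %s\n",
              nrow(object@truth@eventDays),
              paste(names(object@maps), collapse = ", ")))
})
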