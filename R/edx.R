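#' @include AllClasses.R
NULL

#' Per-layer EDX summary with Ca/P and (Ca+Mg)/P ratios
#'
#' Summarizes energy-dispersive X-ray (EDX) atomic-percent measurements of
#' P, Ca and Mg per specimen and enamel layer (outer/inner): max, min, mean
#' and standard deviation per element, plus the Ca/P and (Ca+Mg)/P ratios
#' of the layer means. Ratios are computed from the unrounded means;
#' rounding (one decimal for elements, two for ratios) happens only in
#' [formatLayerSummary()]. The summary is invariant to the order of the
#' measurements, and the ratios are invariant to a uniform rescaling of all
#' atomic percents.
#'
#' @param measurements data.frame with columns `specimen`, `layer`
#'   ("outer"/"inner"), `P`, `Ca`, `Mg` (atomic percent). At least three
#'   measurements per specimen-layer group are required.
#' @return data.frame with one row per specimen, layer and element
#'   statistic, plus the two ratios per group (unrounded).
#' @export
layerSummary <- function(measurements) {
  need <- c("specimen", "layer", "P", "Ca", "Mg")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(measurements[, c("P", "Ca", "Mg")] < 0))
    stop("atomic percents must be >= 0")
  groups <- split(measurements,
                  interaction(measurements$specimen, measurements$layer,
                              drop = TRUE))
  rows <- lapply(groups, function(g) {
    if (nrow(g) < 3L)
      stop("specimen '", g$specimen[1], "' layer '", g$layer[1],
           "' has fewer than three measurements")
    st <- vapply(c("P", "Ca", "Mg"), function(el) {
      v <- g[[el]]
      c(max = max(v), min = min(v), mean = mean(v), sd = stats::sd(v))
    }, numeric(4))
    data.frame(specimen = g$specimen[1], layer = g$layer[1],
               statistic = rownames(st),
               P = st[, "P"], Ca = st[, "Ca"], Mg = st[, "Mg"],
               ca_p = st["mean", "Ca"] / st["mean", "P"],
               ca_mg_p = (st["mean", "Ca"] + st["mean", "Mg"]) /
                         st["mean", "P"],
               n = nrow(g))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a layer summary at reporting precision
#'
#' Elements to one decimal, ratios to two decimals, as conventionally
#' tabulated for EDX atomic quantification.
#'
#' @param summary output of [layerSummary()].
#' @return data.frame rounded for reporting.
#' @export
formatLayerSummary <- function(summary) {
  out <- summary
  for (el in c("P", "Ca", "Mg")) out[[el]] <- round(out[[el]], 1)
  out$ca_p <- round(out$ca_p, 2)
  out$ca_mg_p <- round(out$ca_mg_p, 2)
  out
}

#' Reference EDX measurements (synthetic reconstruction)
#'
#' Per-measurement EDX values reconstructed from published per-layer
#' summaries of a claudin-10-deficient (HELIX) molar and a control molar:
#' for each specimen, layer and element, three values (reported minimum,
#' reported maximum, and 3*mean - min - max) whose mean equals the reported
#' layer mean exactly. The reconstruction preserves the means - and hence
#' the ratio-of-means statistics - but is synthetic at the level of
#' individual measurements. Also shipped as
#' `extdata/edx_layer_means_synthetic.csv`.
#'
#' @return data.frame with columns `specimen`, `layer`, `P`, `Ca`, `Mg`.
#' @export
edxReferenceMeasurements <- function() {
  spec <- list(
    #            element  min   max   mean
    list("HELIX",  "outer", P = c(13.5, 13.7, 13.6),
                            Ca = c(20.9, 21.0, 21.0), Mg = c(0.1, 0.2, 0.2)),
    list("control", "outer", P = c(13.5, 13.7, 13.6),
                            Ca = c(21.4, 21.6, 21.5), Mg = c(0.1, 0.2, 0.2)),
    list("HELIX",  "inner", P = c(12.7, 13.6, 13.0),
                            Ca = c(20.2, 21.4, 20.7), Mg = c(0.4, 0.5, 0.4)),
    list("control", "inner", P = c(13.8, 14.0, 13.9),
                            Ca = c(22.1, 22.4, 22.2), Mg = c(0.4, 0.4, 0.4))
  )
  three <- function(v) c(v[1], v[2], 3 * v[3] - v[1] - v[2])
  do.call(rbind, lapply(spec, function(s)
    data.frame(specimen = s[[1]], layer = s[[2]],
               P = three(s$P), Ca = three(s$Ca), Mg = three(s$Mg))))
}
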