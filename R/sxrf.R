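#' @include AllClasses.R xrf-data.R
NULL

#' Construct a matrix model
#'
#' Defaults follow the study conditions for tooth thin sections: a
#' hydroxyapatite matrix with enamel density 2.85 g/cm^3 and dentin density
#' 1.6 g/cm^3, 16.6 keV incident beam, normal incidence and a 45-degree
#' take-off (backscatter dual-detector layout reduced to one summed
#' channel).
#'
#' @param thicknessUm section thickness, um.
#' @param densityEnamel,densityDentin phase densities, g/cm^3.
#' @param incidentEnergyKeV incident beam energy, keV.
#' @param psiInDeg,psiOutDeg incidence and take-off angles, degrees.
#' @return a [MatrixModel-class].
#' @export
matrixModel <- function(thicknessUm = 160, densityEnamel = 2.85,
                        densityDentin = 1.6, incidentEnergyKeV = 16.6,
                        psiInDeg = 90, psiOutDeg = 45) {
  new("MatrixModel", densityEnamel = densityEnamel,
      densityDentin = densityDentin, thicknessUm = thicknessUm,
      incidentEnergyKeV = incidentEnergyKeV,
      psiInDeg = psiInDeg, psiOutDeg = psiOutDeg)
}

#' Construct an element map
#'
#' @param element element symbol.
#' @param grid numeric matrix.
#' @param pixelSizeUm pixel size, um.
#' @param unitsState units state; one of "counts", "flux_normalized",
#'   "areal_density", "ppm".
#' @param phaseMask character matrix of phases; default all "enamel".
#' @return an [ElementMap-class].
#' @export
elementMap <- function(element, grid, pixelSizeUm, unitsState = "counts",
                       phaseMask = NULL) {
  if (is.null(phaseMask))
    phaseMask <- matrix("enamel", nrow(grid), ncol(grid))
  new("ElementMap", element = element, grid = grid,
      pixelSizeUm = pixelSizeUm, unitsState = unitsState,
      phaseMask = phaseMask)
}

.phaseDensity <- function(matrix, phase) {
  switch(phase,
         enamel = matrix@densityEnamel,
         dentin = matrix@densityDentin,
         stop("unknown phase '", phase, "'"))
}

#' Self-absorption correction factor
#'
#' For a sample of finite thickness the fluorescence produced at depth z is
#' attenuated on the way in (at the incident energy) and on the way out (at
#' the line energy). Integrating over the section thickness gives the
#' intermediate-thickness factor
#' \deqn{A = (1 - e^{-\chi \rho t}) / (\chi \rho t),}
#' with \eqn{\chi = (\mu/\rho)(E_0)/\sin\psi_{in} +
#' (\mu/\rho)(E_{line})/\sin\psi_{out}} evaluated for the hydroxyapatite
#' matrix. The thin-sample limit is A = 1; A decreases monotonically with
#' thickness and with mu/rho.
#'
#' @param line an element symbol (K-alpha looked up) or a line energy in
#'   keV.
#' @param model a [MatrixModel-class].
#' @param phase "enamel" or "dentin".
#' @return dimensionless factor in (0, 1].
#' @examples
#' attenuationFactor("Sr", matrixModel(thicknessUm = 160), "enamel")
#' @export
attenuationFactor <- function(line, model, phase = "enamel") {
  stopifnot(is(model, "MatrixModel"))
  energy <- if (is.character(line)) kAlphaEnergy(line) else as.numeric(line)
  chi <- hydroxyapatiteMuRho(model@incidentEnergyKeV) /
           sin(model@psiInDeg * pi / 180) +
         hydroxyapatiteMuRho(energy) /
           sin(model@psiOutDeg * pi / 180)
  rho <- .phaseDensity(model, phase)
  x <- chi * rho * model@thicknessUm * 1e-4  # t in cm
  if (x < 1e-12) return(1)
  -expm1(-x) / x
}

#' Calibrate areal-density sensitivities from foil standards
#'
#' Each thin-foil standard of known areal density gives a sensitivity
#' (flux-normalized counts per ug/cm^2) at its K-alpha line energy; these
#' anchors form the calibration curve used to quantify arbitrary analytes.
#'
#' @param foils data.frame with columns `element`, `areal_density`
#'   (ug/cm^2), `counts`, and optionally `flux` (default 1, i.e. counts
#'   already flux-normalized).
#' @return a [SensitivityCurve-class].
#' @examples
#' foils <- data.frame(element = c("Ti", "Fe", "Cu"),
#'                     areal_density = c(59.0, 55.0, 47.9),
#'                     counts = c(118, 165, 191.6))
#' calibrateSensitivity(foils)
#' @export
calibrateSensitivity <- function(foils) {
  need <- c("element", "areal_density", "counts")
  if (!all(need %in% names(foils)))
    stop("foils must have columns: ", paste(need, collapse = ", "))
  if (nrow(foils) < 1L) stop("at least one foil standard is required")
  if (any(foils$areal_density <= 0)) stop("areal densities must be positive")
  if (any(foils$counts <= 0)) stop("foil counts must be positive")
  flux <- if ("flux" %in% names(foils)) foils$flux else rep(1, nrow(foils))
  if (any(flux <= 0)) stop("flux must be positive")
  en <- vapply(foils$element, kAlphaEnergy, numeric(1))
  s <- foils$counts / flux / foils$areal_density
  o <- order(en)
  new("SensitivityCurve", element = as.character(foils$element)[o],
      lineEnergyKeV = unname(en[o]), sensitivity = s[o])
}

#' Sensitivity at an arbitrary fluorescence line
#'
#' Log-linear interpolation of the anchor sensitivities in line energy
#' (linear in energy, logarithmic in sensitivity). Queries outside the
#' anchor energy range are linearly extrapolated on the same scale and
#' flagged through the `"extrapolated"` attribute.
#'
#' @param curve a [SensitivityCurve-class].
#' @param line element symbol or line energy in keV.
#' @return sensitivity in counts per (ug/cm^2), with attribute
#'   `extrapolated` (logical).
#' @export
predictSensitivity <- function(curve, line) {
  stopifnot(is(curve, "SensitivityCurve"))
  energy <- if (is.character(line)) kAlphaEnergy(line) else as.numeric(line)
  e <- curve@lineEnergyKeV
  ls <- log(curve@sensitivity)
  extrap <- energy < min(e) || energy > max(e)
  val <- if (length(e) == 1L) {
    exp(ls)
  } else if (!extrap) {
    exp(stats::approx(e, ls, xout = energy)$y)
  } else {
    # extend the nearest segment
    if (energy < min(e)) i <- 1L else i <- length(e) - 1L
    slope <- (ls[i + 1] - ls[i]) / (e[i + 1] - e[i])
    exp(ls[i] + slope * (energy - e[i]))
  }
  if (length(e) == 1L && energy != e) extrap <- TRUE
  structure(val, extrapolated = extrap)
}

#' Quantify a raw counts map to areal density and mass fraction
#'
#' Runs the calibration chain per pixel: flux normalization, substrate
#' background subtraction (negatives clipped to zero and counted), division
#' by the line sensitivity to an apparent areal density (ug/cm^2),
#' correction for matrix self-absorption (division by the phase's
#' [attenuationFactor()]), and conversion to mass fraction
#' ppm = areal density / (rho t). Pixels with non-positive flux are masked
#' (NA), background-phase pixels report 0 ppm.
#'
#' @param raw an [ElementMap-class] in "counts" state.
#' @param sensitivity a [SensitivityCurve-class] or a single sensitivity
#'   value for the map's element.
#' @param model a [MatrixModel-class].
#' @param flux scalar or matrix of incoming flux (default 1).
#' @param background scalar or matrix of substrate background counts
#'   (default 0, flux-normalized units).
#' @return list with `ppm` and `arealDensity` ([ElementMap-class]s),
#'   `nClipped` (pixels clipped at zero) and `nMasked` (flux-masked
#'   pixels).
#' @export
quantifyMap <- function(raw, sensitivity, model, flux = 1, background = 0) {
  stopifnot(is(raw, "ElementMap"), is(model, "MatrixModel"))
  if (unitsState(raw) != "counts")
    stop("quantifyMap expects a map in 'counts' state")
  S <- if (is(sensitivity, "SensitivityCurve"))
    as.numeric(predictSensitivity(sensitivity, raw@element))
  else as.numeric(sensitivity)
  if (S <= 0) stop("sensitivity must be positive")
  g <- raw@grid
  fluxM <- if (is.matrix(flux)) flux else matrix(flux, nrow(g), ncol(g))
  masked <- fluxM <= 0
  net <- ifelse(masked, NA_real_, g / fluxM)
  bg <- if (is.matrix(background)) background
        else matrix(background, nrow(g), ncol(g))
  net <- net - bg
  nClipped <- sum(net < 0, na.rm = TRUE)
  net[net < 0] <- 0
  A <- c(enamel = attenuationFactor(raw@element, model, "enamel"),
         dentin = attenuationFactor(raw@element, model, "dentin"),
         background = 1)
  rho <- c(enamel = model@densityEnamel, dentin = model@densityDentin,
           background = NA_real_)
  Apix <- matrix(A[raw@phaseMask], nrow(g), ncol(g))
  rhoPix <- matrix(rho[raw@phaseMask], nrow(g), ncol(g))
  ad <- net / S / Apix                       # ug/cm^2, absorption-corrected
  tcm <- model@thicknessUm * 1e-4
  ppm <- ad / (rhoPix * tcm)                 # ug/g
  ppm[raw@phaseMask == "background"] <- 0
  ad[raw@phaseMask == "background"] <- 0
  list(
    ppm = new("ElementMap", element = raw@element, grid = ppm,
              pixelSizeUm = raw@pixelSizeUm, unitsState = "ppm",
              phaseMask = raw@phaseMask),
    arealDensity = new("ElementMap", element = raw@element, grid = ad,
                       pixelSizeUm = raw@pixelSizeUm,
                       unitsState = "areal_density",
                       phaseMask = raw@phaseMask),
    nClipped = nClipped,
    nMasked = sum(masked)
  )
}

#' Forward-model a counts map from a concentration field
#'
#' Inverse of [quantifyMap()]: converts a ppm field to the flux-normalized
#' counts a detector would record through the same sensitivity, matrix
#' attenuation and background model. Used by the synthetic-section
#' generator and for round-trip validation.
#'
#' @param truth an [ElementMap-class] in "ppm" state (noise-free field).
#' @param sensitivity sensitivity for the element (counts per ug/cm^2).
#' @param model a [MatrixModel-class].
#' @param flux scalar or matrix flux.
#' @param background scalar or matrix background counts.
#' @param noiseSd fractional Gaussian noise on the counts (0 = noiseless).
#' @param seed seed used when `noiseSd > 0`.
#' @return an [ElementMap-class] in "counts" state.
#' @export
forwardCountsMap <- function(truth, sensitivity, model, flux = 1,
                             background = 0, noiseSd = 0, seed = 1L) {
  stopifnot(is(truth, "ElementMap"), is(model, "MatrixModel"))
  if (unitsState(truth) != "ppm")
    stop("forwardCountsMap expects a map in 'ppm' state")
  g <- truth@grid
  A <- c(enamel = attenuationFactor(truth@element, model, "enamel"),
         dentin = attenuationFactor(truth@element, model, "dentin"),
         background = 1)
  rho <- c(enamel = model@densityEnamel, dentin = model@densityDentin,
           background = 0)
  Apix <- matrix(A[truth@phaseMask], nrow(g), ncol(g))
  rhoPix <- matrix(rho[truth@phaseMask], nrow(g), ncol(g))
  tcm <- model@thicknessUm * 1e-4
  ad <- g * rhoPix * tcm                     # ug/cm^2 in the section
  counts <- ad * Apix * sensitivity
  fluxM <- if (is.matrix(flux)) flux else matrix(flux, nrow(g), ncol(g))
  bg <- if (is.matrix(background)) background
        else matrix(background, nrow(g), ncol(g))
  counts <- (counts + bg) * fluxM
  if (noiseSd > 0)
    counts <- .withSeed(seed, counts * matrix(
      1 + stats::rnorm(length(counts), sd = noiseSd), nrow(g), ncol(g)))
  new("ElementMap", element = truth@element, grid = counts,
      pixelSizeUm = truth@pixelSizeUm, unitsState = "counts",
      phaseMask = truth@phaseMask)
}

#' Gaussian denoising of a map
#'
#' Separable Gaussian convolution with a normalized kernel (default sigma
#' 0.8 px) and edge replication, so a constant map is unchanged and the
#' interior mean is preserved.
#'
#' @param map an [ElementMap-class].
#' @param kernelSigma Gaussian sigma in pixels (default 0.8).
#' @return the smoothed [ElementMap-class].
#' @export
denoiseMap <- function(map, kernelSigma = 0.8) {
  stopifnot(is(map, "ElementMap"))
  if (kernelSigma <= 0) stop("kernelSigma must be positive")
  r <- max(1L, ceiling(4 * kernelSigma))
  k <- stats::dnorm(-r:r, sd = kernelSigma)
  k <- k / sum(k)
  smooth1 <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    stats::filter(vp, k, sides = 2)[(r + 1):(r + n)]
  }
  g <- map@grid
  g <- t(apply(g, 1, smooth1))
  g <- apply(g, 2, smooth1)
  new("ElementMap", element = map@element, grid = g,
      pixelSizeUm = map@pixelSizeUm, unitsState = map@unitsState,
      phaseMask = map@phaseMask)
}

#' Per-phase summary of an element map
#'
#' @param map an [ElementMap-class] (typically in ppm state).
#' @return data.frame with per-phase mean, min, max and pixel count.
#' @export
phaseSummary <- function(map) {
  stopifnot(is(map, "ElementMap"))
  phases <- c("enamel", "dentin")
  rows <- lapply(phases, function(ph) {
    v <- map@grid[map@phaseMask == ph]
    v <- v[is.finite(v)]
    if (!length(v)) return(NULL)
    data.frame(element = map@element, phase = ph, mean = mean(v),
               min = min(v), max = max(v), n_pixels = length(v))
  })
  do.call(rbind, rows)
}
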