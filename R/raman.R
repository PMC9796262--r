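#' @include AllClasses.R
NULL

#' Baseline subtraction for a Raman spectrum
#'
#' Default ("linear"): a straight line is fitted by least squares through
#' the points inside the anchor windows (flanking regions assumed free of
#' band intensity) and subtracted, so a spectrum that is exactly a straight
#' line becomes exactly zero. "rubberband" instead subtracts the lower
#' convex hull of the spectrum.
#'
#' @param wavenumbers wavenumber axis, cm^-1 (strictly increasing).
#' @param intensities intensities.
#' @param anchorWindows list of c(lo, hi) wavenumber windows used to fit
#'   the linear baseline.
#' @param method "linear" or "rubberband".
#' @return baseline-subtracted intensities.
#' @export
subtractBaseline <- function(wavenumbers, intensities,
                             anchorWindows = list(c(905, 925),
                                                  c(1100, 1130)),
                             method = c("linear", "rubberband")) {
  method <- match.arg(method)
  stopifnot(length(wavenumbers) == length(intensities))
  if (method == "linear") {
    sel <- Reduce(`|`, lapply(anchorWindows, function(w)
      wavenumbers >= w[1] & wavenumbers <= w[2]))
    if (!any(sel))
      stop("anchor windows fall outside the spectrum range")
    fit <- stats::lm.fit(cbind(1, wavenumbers[sel]), intensities[sel])
    baseline <- cbind(1, wavenumbers) %*% fit$coefficients
    intensities - as.numeric(baseline)
  } else {
    base <- .lowerHullBaseline(wavenumbers, intensities)
    intensities - base
  }
}

# rubberband baseline: lower convex hull (Andrew monotone chain),
# interpolated over the full axis
.lowerHullBaseline <- function(x, y) {
  stack <- integer(0)
  for (i in seq_along(x)) {
    while (length(stack) >= 2) {
      a <- stack[length(stack) - 1]; b <- stack[length(stack)]
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross <= 0) stack <- stack[-length(stack)] else break
    }
    stack <- c(stack, i)
  }
  stats::approx(x[stack], y[stack], xout = x)$y
}

.pvModel <- function(x, height, center, fwhm, eta) {
  u <- (x - center) / (fwhm / 2)
  height * (eta / (1 + u^2) + (1 - eta) * exp(-log(2) * u^2))
}

#' Band area and width metrics for one spectrum
#'
#' Computes the integrated band area (trapezoidal, after local linear
#' baseline subtraction through flanking anchors) and the full width at
#' half maximum from a pseudo-Voigt profile fit. The pseudo-Voigt mixes a
#' Gaussian and a Lorentzian of common FWHM, so the fitted width parameter
#' is the FWHM itself and the Gaussian / Lorentzian limits are recovered at
#' mixing 0 / 1. With `fixCenter` the band position is imposed rather than
#' fitted, the convention used for crystallinity (FWHM of the 960 cm^-1
#' phosphate band) maps.
#'
#' @param wavenumbers,intensities the spectrum.
#' @param bandCenter imposed band center, cm^-1.
#' @param window integration window c(lo, hi), cm^-1.
#' @param fixCenter impose the center (default TRUE).
#' @param anchorWidth width of each flanking baseline anchor, cm^-1.
#' @param baseline subtract the local linear baseline first (default TRUE).
#' @return list with `center`, `area`, `fwhm`, `eta`, `height`,
#'   `residual` (RMS), `converged`. Non-convergent fits return NA metrics
#'   with `converged = FALSE`.
#' @examples
#' wn <- seq(900, 1020, 0.5)
#' y <- exp(-(wn - 960)^2 / (2 * 5^2))
#' bandMetrics(wn, y, 960, c(930, 990))$fwhm  # ~ 2.3548 * 5
#' @export
bandMetrics <- function(wavenumbers, intensities, bandCenter, window,
                        fixCenter = TRUE, anchorWidth = 10,
                        baseline = TRUE) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (window[1] < min(wavenumbers) || window[2] > max(wavenumbers))
    stop("integration window outside the spectrum range")
  y <- intensities
  if (baseline) {
    anchors <- list(c(window[1] - anchorWidth, window[1]),
                    c(window[2], window[2] + anchorWidth))
    anchors <- lapply(anchors, function(w)
      c(max(w[1], min(wavenumbers)), min(w[2], max(wavenumbers))))
    y <- subtractBaseline(wavenumbers, y, anchors, method = "linear")
  }
  sel <- wavenumbers >= window[1] & wavenumbers <= window[2]
  wx <- wavenumbers[sel]
  wy <- y[sel]
  area <- pracma::trapz(wx, wy)

  h0 <- max(wy)
  fit <- NULL
  if (h0 > 0) {
    half <- wy >= h0 / 2
    f0 <- if (sum(half) >= 2) diff(range(wx[half])) else diff(window) / 4
    f0 <- max(f0, 1)
    df <- data.frame(x = wx, y = wy)
    # multi-start: a width underestimated from a coarse grid traps the
    # Levenberg-Marquardt fit in a pure-Lorentzian local minimum
    for (fs in c(f0, 1.8 * f0, 3 * f0)) for (es in c(0.2, 0.8)) {
      cand <- tryCatch({
        if (fixCenter) {
          minpack.lm::nlsLM(
            y ~ .pvModel(x, height, bandCenter, fwhm, eta), data = df,
            start = list(height = h0, fwhm = fs, eta = es),
            lower = c(0, 1e-3, 0), upper = c(Inf, diff(window) * 4, 1),
            control = minpack.lm::nls.lm.control(maxiter = 200))
        } else {
          minpack.lm::nlsLM(
            y ~ .pvModel(x, height, center, fwhm, eta), data = df,
            start = list(height = h0, center = bandCenter,
                         fwhm = fs, eta = es),
            lower = c(0, window[1], 1e-3, 0),
            upper = c(Inf, window[2], diff(window) * 4, 1),
            control = minpack.lm::nls.lm.control(maxiter = 200))
        }
      }, error = function(e) NULL)
      if (!is.null(cand) &&
          (is.null(fit) || stats::deviance(cand) < stats::deviance(fit)))
        fit <- cand
    }
  }
  if (is.null(fit)) {
    return(list(center = bandCenter, area = area, fwhm = NA_real_,
                eta = NA_real_, height = NA_real_, residual = NA_real_,
                converged = FALSE))
  }
  cf <- stats::coef(fit)
  list(center = if (fixCenter) bandCenter else unname(cf["center"]),
       area = area,
       fwhm = unname(cf["fwhm"]),
       eta = unname(cf["eta"]),
       height = unname(cf["height"]),
       residual = sqrt(mean(stats::resid(fit)^2)),
       converged = TRUE)
}

#' Per-pixel metric rasters from a Raman map
#'
#' Fits every pixel's spectrum and assembles the carbonate-to-phosphate
#' band-area ratio map (I1070/I960) and the crystallinity map (FWHM of the
#' 960 cm^-1 phosphate band with imposed center). Failed pixels are NA; a
#' run-level warning is raised when more than 20 percent fail. The FWHM
#' raster is returned unclipped; [clipForDisplay()] applies the
#' conventional 10-16 cm^-1 rendering scale.
#'
#' @param map a [RamanMap-class].
#' @param band960Window,band1070Window integration windows, cm^-1.
#' @return list of matrices `i960`, `i1070`, `ratio`, `fwhm960`, plus
#'   `failed` (logical matrix).
#' @export
metricMaps <- function(map, band960Window = c(930, 990),
                       band1070Window = c(1050, 1090)) {
  stopifnot(is(map, "RamanMap"))
  d <- dim(map@cube)
  i960 <- i1070 <- fwhm960 <- matrix(NA_real_, d[1], d[2])
  failed <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    sp <- map@cube[i, j, ]
    m960 <- bandMetrics(map@wavenumbers, sp, 960, band960Window,
                        fixCenter = TRUE)
    m1070 <- bandMetrics(map@wavenumbers, sp, 1070, band1070Window,
                         fixCenter = TRUE)
    i960[i, j] <- m960$area
    i1070[i, j] <- m1070$area
    fwhm960[i, j] <- m960$fwhm
    failed[i, j] <- !m960$converged
  }
  if (mean(failed) > 0.2)
    warning(sprintf("%.0f%% of pixels failed to fit", 100 * mean(failed)))
  list(i960 = i960, i1070 = i1070, ratio = i1070 / i960,
       fwhm960 = fwhm960, failed = failed)
}

#' Clip a metric raster to a display scale
#'
#' Rendering helper for shared color schemes across specimens; the data
#' themselves are never clipped by [metricMaps()].
#'
#' @param x numeric matrix.
#' @param limits display limits (default the conventional FWHM960 scale
#'   c(10, 16) cm^-1).
#' @return the clipped matrix.
#' @export
clipForDisplay <- function(x, limits = c(10, 16)) {
  pmin(pmax(x, limits[1]), limits[2])
}
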