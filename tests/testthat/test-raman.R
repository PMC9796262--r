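test_that("linear baselines subtract to zero and flats stay flat", {
  wn <- seq(450, 1800, by = 3)
  line <- 12 + 0.03 * wn
  expect_equal(subtractBaseline(wn, line), rep(0, length(wn)),
               tolerance = 1e-9)
  expect_equal(subtractBaseline(wn, rep(0, length(wn))),
               rep(0, length(wn)), tolerance = 1e-12)
  expect_error(subtractBaseline(wn, line, anchorWindows = list(c(1, 2))),
               "anchor")
})

test_that("band area survives baseline subtraction within 1%", {
  wn <- seq(450, 1800, by = 0.5)
  A <- 50; G <- 6
  y <- A / (1 + ((wn - 1100) / (G / 2))^2) + 0.05 * wn + 20
  ys <- subtractBaseline(wn, y, list(c(460, 600), c(1600, 1790)))
  area <- pracma::trapz(wn, ys)
  expect_equal(area, pi * A * G / 2, tolerance = 0.01)
})

test_that("rubberband baseline removes a convex background", {
  wn <- seq(450, 1800, by = 3)
  y <- 100 * exp(-(wn - 960)^2 / 50) + 0.0001 * (wn - 1000)^2
  ys <- subtractBaseline(wn, y, method = "rubberband")
  expect_true(all(ys >= -1e-9))
  expect_lt(abs(ys[1]), 1e-9)
})

test_that("pseudo-Voigt fit recovers Gaussian and Lorentzian widths", {
  wn <- seq(900, 1020, by = 0.5)
  sig <- 5
  g <- bandMetrics(wn, 100 * exp(-(wn - 960)^2 / (2 * sig^2)), 960,
                   c(930, 990), baseline = FALSE)
  expect_equal(g$fwhm, 2.3548 * sig, tolerance = 0.005)
  expect_lt(g$eta, 0.05)
  Gam <- 8
  l <- bandMetrics(wn, 100 / (1 + ((wn - 960) / (Gam / 2))^2), 960,
                   c(930, 990), baseline = FALSE)
  expect_equal(l$fwhm, Gam, tolerance = 0.005)
  expect_gt(l$eta, 0.95)
})

test_that("FWHM estimates are scale invariant", {
  wn <- seq(900, 1020, by = 1)
  y <- 80 * exp(-(wn - 960)^2 / (2 * 4^2))
  f1 <- bandMetrics(wn, y, 960, c(930, 990), baseline = FALSE)$fwhm
  f2 <- bandMetrics(wn, 1000 * y, 960, c(930, 990), baseline = FALSE)$fwhm
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("constructed band-area ratios are recovered within 1%", {
  wn <- seq(450, 1800, by = 1)
  sig <- 6
  # area of a Gaussian = h * sigma * sqrt(2 pi); choose heights for 0.25
  y <- 100 * exp(-(wn - 960)^2 / (2 * sig^2)) +
       25 * exp(-(wn - 1070)^2 / (2 * sig^2))
  a960 <- bandMetrics(wn, y, 960, c(930, 990))$area
  a1070 <- bandMetrics(wn, y, 1070, c(1050, 1090))$area
  expect_equal(a1070 / a960, 0.25, tolerance = 0.01)
})

test_that("non-convergent pixels are flagged instead of failing", {
  wn <- seq(900, 1020, by = 1)
  m <- bandMetrics(wn, rep(0, length(wn)), 960, c(930, 990),
                   baseline = FALSE)
  expect_false(m$converged)
  expect_true(is.na(m$fwhm))
})

test_that("metric maps separate dentin from enamel and warn on failures", {
  sec <- ramanSection()
  rm <- sectionRaman(sec)
  mm <- metricMaps(rm)
  ph <- phaseMask(rm)
  expect_gt(mean(mm$fwhm960[ph == "dentin"], na.rm = TRUE),
            mean(mm$fwhm960[ph == "enamel"], na.rm = TRUE))
  expect_gt(mean(mm$ratio[ph == "dentin"], na.rm = TRUE),
            mean(mm$ratio[ph == "enamel"], na.rm = TRUE))
  expect_equal(dim(mm$ratio), dim(ph))

  # all-zero spectra cannot be fitted; the run warns
  zero <- new("RamanMap", wavenumbers = rm@wavenumbers,
              cube = array(0, c(2, 2, length(rm@wavenumbers))),
              stepUm = 18, phaseMask = matrix("enamel", 2, 2))
  expect_warning(metricMaps(zero), "failed")
})

test_that("uniform maps give constant rasters and unit self-ratios", {
  wn <- seq(450, 1800, by = 3)
  spec <- 100 * exp(-(wn - 960)^2 / (2 * 5^2)) +
          100 * exp(-(wn - 1070)^2 / (2 * 5^2))
  cube <- array(rep(spec, each = 6), c(2, 3, length(wn)))
  rm <- new("RamanMap", wavenumbers = wn, cube = cube, stepUm = 18,
            phaseMask = matrix("enamel", 2, 3))
  mm <- metricMaps(rm)
  expect_equal(max(mm$fwhm960) - min(mm$fwhm960), 0, tolerance = 1e-8)
  # identical band shapes in numerator and denominator: ratio raster is 1
  expect_equal(unname(mm$ratio), matrix(1, 2, 3), tolerance = 0.01)
})

test_that("display clipping bounds values without touching the data", {
  x <- matrix(c(8, 12, 19), 1, 3)
  expect_equal(as.numeric(clipForDisplay(x)), c(10, 12, 16))
})
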