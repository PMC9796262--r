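test_that("foil sensitivity is counts per areal density", {
  curve <- calibrateSensitivity(data.frame(element = "Fe",
                                           areal_density = 59.0,
                                           counts = 118.0))
  expect_equal(curve@sensitivity, 2.0)
  expect_error(calibrateSensitivity(data.frame(element = "Fe",
                                               areal_density = 59.0,
                                               counts = 0)), "counts")
})

test_that("queries outside the foil energy range carry an extrapolation flag", {
  truth <- c(Ti = 2.0, Fe = 2.5, Cu = 3.1)
  curve <- calibrateSensitivity(
    generateFoilStandards(names(truth), c(59.0, 55.0, 47.9),
                          sensitivityTruth = unname(truth)))
  sFe <- predictSensitivity(curve, "Fe")
  expect_false(attr(sFe, "extrapolated"))
  for (el in c("Ca", "Sr", "Zn")) {
    s <- predictSensitivity(curve, el)
    expect_true(attr(s, "extrapolated"))
    expect_gt(as.numeric(s), 0)
  }
  # interpolation is log-linear in energy
  sMn <- predictSensitivity(curve, "Mn")
  eTi <- kAlphaEnergy("Ti"); eFe <- kAlphaEnergy("Fe")
  lS <- log(2.0) + (log(2.5) - log(2.0)) *
    (kAlphaEnergy("Mn") - eTi) / (eFe - eTi)
  expect_equal(as.numeric(sMn), exp(lS))
})

test_that("attenuation factor has the correct limits and closed form", {
  m <- matrixModel()
  expect_equal(attenuationFactor("Sr", matrixModel(thicknessUm = 1e-9)), 1)
  # x = chi rho t = 1  =>  A = 1 - e^-1
  chi <- hydroxyapatiteMuRho(m@incidentEnergyKeV) / sin(pi / 2) +
    hydroxyapatiteMuRho(kAlphaEnergy("Sr")) / sin(pi / 4)
  tUm <- 1 / (chi * 2.85) * 1e4
  expect_equal(attenuationFactor("Sr", matrixModel(thicknessUm = tUm)),
               1 - exp(-1), tolerance = 1e-12)
  expect_error(attenuationFactor("Xx", m), "Xx")
})

test_that("attenuation factor matches the quadrature oracle to 1e-10", {
  for (el in c("Ca", "Fe", "Zn", "Sr")) {
    for (th in c(61, 160, 400)) for (phase in c("enamel", "dentin")) {
      m <- matrixModel(thicknessUm = th)
      rho <- if (phase == "enamel") m@densityEnamel else m@densityDentin
      chi <- hydroxyapatiteMuRho(m@incidentEnergyKeV) /
        sin(m@psiInDeg * pi / 180) +
        hydroxyapatiteMuRho(kAlphaEnergy(el)) /
        sin(m@psiOutDeg * pi / 180)
      tcm <- th * 1e-4
      oracle <- stats::integrate(function(z) exp(-chi * rho * z), 0, tcm,
                                 rel.tol = 1e-13)$value / tcm
      expect_lt(abs(attenuationFactor(el, m, phase) - oracle), 1e-10)
    }
  }
})

test_that("attenuation factor decreases with thickness and line absorption", {
  th <- c(10, 50, 160, 500)
  a <- vapply(th, function(t)
    attenuationFactor("Sr", matrixModel(thicknessUm = t)), numeric(1))
  expect_true(all(diff(a) < 0))
  # mu/rho at the Ca K-line is far larger than at the Sr K-line
  m <- matrixModel()
  expect_lt(attenuationFactor("Ca", m), attenuationFactor("Sr", m))
})

test_that("forward-model then quantify round-trips a uniform Ca field", {
  m <- matrixModel()
  ph <- matrix("enamel", 6, 9)
  ph[, 1] <- "background"
  tm <- elementMap("Ca", matrix(4.0e5, 6, 9), 2, "ppm", ph)
  tm@grid[ph == "background"] <- 0
  counts <- forwardCountsMap(tm, 2.1, m)
  q <- quantifyMap(counts, 2.1, m)
  en <- as.matrix(q$ppm)[ph == "enamel"]
  expect_equal(mean(en), 4.0e5, tolerance = 0.001)
  expect_true(all(as.matrix(q$ppm)[ph == "background"] == 0))
})

test_that("quantification is linear in concentration", {
  m <- matrixModel()
  t1 <- elementMap("Zn", matrix(300, 4, 4), 2, "ppm")
  t2 <- elementMap("Zn", matrix(600, 4, 4), 2, "ppm")
  q1 <- quantifyMap(forwardCountsMap(t1, 1.7, m, background = 5), 1.7, m,
                    background = 5)
  q2 <- quantifyMap(forwardCountsMap(t2, 1.7, m, background = 5), 1.7, m,
                    background = 5)
  expect_equal(as.matrix(q2$ppm), 2 * as.matrix(q1$ppm), tolerance = 1e-9)
})

test_that("full synthetic quantification recovers the Zn surface peak", {
  sec <- noiselessSection()
  m <- matrixModel()
  truthZn <- groundTruth(sec)@elementFields$Zn
  tm <- elementMap("Zn", truthZn, sec@config@pixelSizeUm, "ppm",
                   phaseMask(sectionMaps(sec)$Zn))
  q <- quantifyMap(forwardCountsMap(tm, 1.7, m), 1.7, m)
  peak <- max(as.matrix(q$ppm)[phaseMask(sectionMaps(sec)$Zn) == "enamel"])
  expect_equal(peak, sec@config@znSurfacePeakPpm, tolerance = 0.02)
})

test_that("zero-flux pixels are masked rather than propagating NaN", {
  m <- matrixModel()
  tm <- elementMap("Sr", matrix(500, 3, 3), 2, "ppm")
  counts <- forwardCountsMap(tm, 2, m)
  flux <- matrix(1, 3, 3); flux[2, 2] <- 0
  q <- quantifyMap(counts, 2, m, flux = flux)
  expect_equal(q$nMasked, 1L)
  expect_true(is.na(as.matrix(q$ppm)[2, 2]))
  expect_false(any(is.nan(as.matrix(q$ppm))))
})

test_that("negative post-subtraction values clip to zero with a count", {
  m <- matrixModel()
  tm <- elementMap("Sr", matrix(c(0, 500, 500, 500), 2, 2), 2, "ppm")
  counts <- forwardCountsMap(tm, 2, m, background = 10)
  q <- quantifyMap(counts, 2, m, background = 11)  # oversubtract
  expect_equal(q$nClipped, 1L)
  expect_true(all(as.matrix(q$ppm) >= 0))
})

test_that("Gaussian denoising preserves constants and impulse mass", {
  cm <- elementMap("Ca", matrix(7, 5, 5), 2, "ppm")
  expect_equal(as.matrix(denoiseMap(cm)), matrix(7, 5, 5),
               tolerance = 1e-12)
  g <- matrix(0, 21, 21); g[11, 11] <- 1
  sm <- denoiseMap(elementMap("Ca", g, 2, "ppm"), kernelSigma = 0.8)
  expect_equal(sum(as.matrix(sm)), 1, tolerance = 1e-9)
  expect_equal(which.max(as.matrix(sm)), which.max(g))
  expect_error(denoiseMap(cm, kernelSigma = 0), "positive")
})

test_that("smoothing does not displace band positions", {
  sec <- noisySection()
  det0 <- detectEvents(extractTransect(denoiseMap(sectionMaps(sec)$Sr)))
  detRaw <- detectEvents(extractTransect(sectionMaps(sec)$Sr),
                         minWidthUm = 10)
  px <- sec@config@pixelSizeUm
  # same events; positions agree within a pixel after smoothing
  expect_equal(nrow(det0), nrow(groundTruth(sec)@eventDays))
  common <- min(nrow(det0), nrow(detRaw))
  expect_lt(stats::median(abs(det0$start_um[seq_len(common)] -
                              detRaw$start_um[seq_len(common)])), px + 0.1)
})

test_that("per-phase summaries report the calibrated scale", {
  sec <- noiselessSection()
  s <- phaseSummary(sectionMaps(sec)$Ca)
  expect_equal(s$mean[s$phase == "enamel"], 4.0e5)
  expect_equal(s$mean[s$phase == "dentin"], 3.4e5)
})
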