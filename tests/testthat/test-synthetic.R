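test_that("uniform-rate section lays down evenly spaced increments and striae", {
  cfg <- sectionConfig(cuspalThicknessUm = 200, dsrInner = 2, dsrOuter = 2,
                       periodicityDays = 8L, noiseSd = 0, heightPx = 2L)
  sec <- generateSection(cfg, includeRaman = FALSE)
  inc <- groundTruth(sec)@incrementPositionsUm
  expect_equal(diff(inc), rep(2, length(inc) - 1))
  striae <- sectionTables(sec)$striae$position_um
  expect_equal(diff(striae), rep(16, length(striae) - 1))
})

test_that("study-condition chronology ground truth matches hand-computed sums", {
  tr <- groundTruth(noiselessSection())
  ch <- tr@chronology
  # deciles 3-10: counts 3+5+7+9+11+15+19+20 = 89 striae x 8 days
  expect_equal(sum(ch@perDecileDays[3:10]), 89 * 8)
  expect_equal(ch@deciles12Days, 52)
  expect_equal(ch@lateralDays, 52 + 712)
  expect_equal(totalDays(ch), ch@cuspalDays + ch@lateralDays)
})

test_that("Sr raster carries one band per configured event at oracle positions", {
  sec <- noiselessSection()
  cfg <- sec@config
  tp <- extractTransect(sectionMaps(sec)$Sr)
  det <- detectEvents(tp)
  spec <- cfg@srEventSpec
  expect_equal(nrow(det), nrow(spec))
  expect_equal(det$kind, spec$sign)
  px <- cfg@pixelSizeUm
  xOracle <- oracleDayToDistance(cfg, spec$onset_day)
  expect_lt(max(abs(det$start_um - xOracle)), px + 0.51)
  # the trailing edge is additionally quantized by the local daily spacing
  maxSpacing <- max(diff(groundTruth(sec)@incrementPositionsUm))
  xEnd <- oracleDayToDistance(cfg, spec$onset_day + spec$duration_days)
  expect_lt(max(abs(det$end_um - xEnd)), px + maxSpacing + 0.51)
})

test_that("synchronous banding is imprinted in the dentin region", {
  sec <- noiselessSection()
  cfg <- sec@config
  srField <- groundTruth(sec)@elementFields$Sr
  ph <- phaseMask(sectionMaps(sec)$Sr)
  dentinRow <- srField[1, ph[1, ] == "dentin"]
  base <- cfg@srDentinBaselinePpm
  # first event (enrichment) spans days 5..40 at the dentin apposition rate
  expect_true(any(dentinRow > base + 1))
  expect_true(any(dentinRow < base - 1))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generateSection(sectionConfig(seed = 11L, heightPx = 2L,
                                     cuspalThicknessUm = 300),
                       includeRaman = FALSE)
  b <- generateSection(sectionConfig(seed = 11L, heightPx = 2L,
                                     cuspalThicknessUm = 300),
                       includeRaman = FALSE)
  d <- generateSection(sectionConfig(seed = 12L, heightPx = 2L,
                                     cuspalThicknessUm = 300),
                       includeRaman = FALSE)
  expect_identical(as.matrix(sectionMaps(a)$Sr), as.matrix(sectionMaps(b)$Sr))
  expect_identical(sectionTables(a)$spacings, sectionTables(b)$spacings)
  expect_false(identical(as.matrix(sectionMaps(a)$Sr),
                         as.matrix(sectionMaps(d)$Sr)))
})

test_that("inconsistent decile configuration is rejected", {
  counts <- c(2L, 1L, 3L, 5L, 7L, 9L, 11L, 15L, 19L, 20L)
  cfg <- sectionConfig(decileStriaCounts = counts, heightPx = 2L)
  expect_error(generateSection(cfg, includeRaman = FALSE),
               "configuration error")
  expect_error(sectionConfig(dsrInner = 5, dsrOuter = 2), "dsrInner")
  expect_error(sectionConfig(periodicityDays = 0L), "periodicityDays")
})

test_that("foil standards obey the proportional forward model", {
  f <- generateFoilStandards("Ti", 59.0, sensitivityTruth = 1.0)
  expect_equal(f$counts, 59.0)
  expect_error(generateFoilStandards("Ti", 59.0, 1.0, flux = 0), "flux")
  expect_error(generateFoilStandards("Ti", -1, 1.0), "areal")
})

test_that("noiseless foil calibration recovers generator sensitivities exactly", {
  truth <- c(Ti = 2.0, Fe = 2.5, Cu = 3.1)
  foils <- generateFoilStandards(names(truth), c(59.0, 55.0, 47.9),
                                 sensitivityTruth = unname(truth))
  curve <- calibrateSensitivity(foils)
  for (el in names(truth))
    expect_equal(as.numeric(predictSensitivity(curve, el)),
                 unname(truth[el]))
})

test_that("Poisson-noise calibration recovers sensitivity within 3 SE", {
  truth <- 2.0
  ad <- 59.0
  flux <- 50  # counts ~ 5900 per replicate
  est <- vapply(1:100, function(i) {
    f <- generateFoilStandards("Ti", ad, truth, flux = flux,
                               poissonNoise = TRUE, seed = i)
    calibrateSensitivity(f)@sensitivity
  }, numeric(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 3 * se + 1e-12)
})

test_that("noiseless measurement tables round-trip to the ground-truth chronology", {
  sec <- noiselessSection()
  cfg <- sec@config
  ch <- crownChronology(sectionTables(sec)$spacings,
                        sectionTables(sec)$periodicity$n_cross_striations,
                        sectionTables(sec)$deciles$stria_count,
                        cfg@cuspalThicknessUm,
                        cfg@deciles12LengthUm, cfg@deciles12Dsr)
  truth <- groundTruth(sec)@chronology
  expect_equal(totalDays(ch$chronology), totalDays(truth))
  expect_equal(ch$chronology@perDecileDays, truth@perDecileDays)
  expect_equal(zoneRates(ch$profile),
               stats::setNames(zoneRates(groundTruth(sec)),
                               names(zoneRates(ch$profile))))
})

test_that("day and distance maps are mutually inverse within one increment", {
  prof <- noiselessProfile()
  d <- c(0, 13, 250, 777.5, 1200)
  back <- daysToDistance(distanceToDays(d, prof), prof)
  expect_equal(back, d, tolerance = 1e-10)
  inc <- groundTruth(noiselessSection())@incrementPositionsUm
  maxSpacing <- max(diff(inc))
  t <- c(1, 50, 200, 400)
  xProfile <- daysToDistance(t, prof)
  xIncrement <- stats::approx(seq_along(inc) - 1, inc, xout = t)$y
  expect_lt(max(abs(xProfile - xIncrement)), maxSpacing)
})
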