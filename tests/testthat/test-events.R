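test_that("a flat profile yields no events and detection ignores global offsets", {
  pos <- seq(0, 800, by = 2)
  flat <- transectProfile(pos, rep(100, length(pos)))
  expect_equal(nrow(detectEvents(flat)), 0L)

  v <- rep(100, length(pos))
  v[pos >= 300 & pos <= 350] <- 150
  d1 <- detectEvents(transectProfile(pos, v))
  d2 <- detectEvents(transectProfile(pos, v + 75))
  expect_equal(d1[, c("kind", "start_um", "end_um")],
               d2[, c("kind", "start_um", "end_um")])
})

test_that("a rectangular enrichment is recovered with its width", {
  pos <- seq(0, 800, by = 1)
  v <- rep(100, length(pos))
  v[pos >= 300 & pos <= 350] <- 200
  d <- detectEvents(transectProfile(pos, v))
  expect_equal(nrow(d), 1L)
  expect_equal(d$kind, "enrich")
  expect_equal(d$end_um - d$start_um, 50, tolerance = 2 / 50)
  # depletion tagging
  v2 <- rep(100, length(pos))
  v2[pos >= 500 & pos <= 540] <- 40
  d2 <- detectEvents(transectProfile(pos, v2))
  expect_equal(d2$kind, "deplete")
})

test_that("distance-to-days integrates piecewise zone rates exactly", {
  p <- dsrProfile(data.frame(zone_index = c(0, 1), span_um = c(6, 12),
                             n_crossings = c(3, 3)))
  expect_equal(distanceToDays(0, p), 0)
  expect_equal(distanceToDays(200, p), 100 / 2 + 100 / 4)
  expect_equal(distanceToDays(150, p), 50 + 50 / 4)
  expect_error(distanceToDays(201, p), "beyond")
})

test_that("distance-to-days matches a fine-grid integration oracle", {
  set.seed(42)
  for (rep in 1:5) {
    nz <- sample(3:12, 1)
    rates <- stats::runif(nz, 1.5, 5)
    m <- data.frame(zone_index = rep(seq_len(nz) - 1L, each = 1),
                    span_um = 3 * rates, n_crossings = 3)
    p <- dsrProfile(m)
    # oracle: trapezoid integration of 1/r over a fine grid with the
    # piecewise-constant rate field
    xg <- seq(0, nz * 100, by = 0.05)
    rg <- rates[pmin(nz, floor(xg / 100) + 1)]
    tg <- pracma::cumtrapz(xg, 1 / rg)
    d <- stats::runif(8, 0, nz * 100)
    oracle <- stats::approx(xg, tg, xout = d)$y
    expect_lt(max(abs(distanceToDays(d, p) - oracle)), 0.5)
  }
})

test_that("distance-to-days is strictly increasing and additive", {
  p <- noiselessProfile()
  d <- sort(stats::runif(20, 0, 1300))
  t <- distanceToDays(d, p)
  expect_true(all(diff(t) > 0))
  # additivity over concatenated segments: t(b) - t(a) depends only on [a,b]
  expect_equal(distanceToDays(900, p) - distanceToDays(400, p),
               sum(100 / unname(zoneRates(p))[5:9]))
})

test_that("event timing recovers injected durations within 10%", {
  sec <- noisySection()
  tp <- extractTransect(denoiseMap(sectionMaps(sec)$Sr))
  det <- detectEvents(tp)
  truth <- groundTruth(sec)@eventDays
  expect_equal(nrow(det), nrow(truth))
  tl <- timeEvents(det, noiselessProfile())
  ev <- events(tl)
  expect_equal(ev$label, truth$label)
  relErr <- abs(ev$duration_days - truth$duration_days) /
    truth$duration_days
  expect_lt(max(relErr), 0.10)
  expect_true(all(truth$duration_days >= 33 & truth$duration_days <= 121))
})

test_that("evenly spaced events read periodic, irregular ones aperiodic", {
  p <- dsrProfile(data.frame(zone_index = 0:4, span_um = rep(6, 5),
                             n_crossings = rep(3, 5)))
  mk <- function(starts) data.frame(kind = "enrich", start_um = starts,
                                    end_um = starts + 10,
                                    peak_ppm = 900)
  even <- timeEvents(mk(c(50, 150, 250, 350)), p)
  expect_equal(verdict(even), "periodic")
  expect_equal(even@cv, 0)
  # irregular onsets; CV computed by hand from intervals 30, 200, 70
  irr <- timeEvents(mk(c(20, 50, 250, 320)), p)
  iv <- diff(c(20, 50, 250, 320)) / 2  # 2 um/day everywhere
  expect_equal(irr@cv, stats::sd(iv) / mean(iv))
  expect_equal(verdict(irr), "aperiodic")
  expect_equal(verdict(timeEvents(mk(c(100, 300)), p)), "indeterminate")
})

test_that("unsorted events are auto-sorted with a warning", {
  p <- dsrProfile(data.frame(zone_index = 0, span_um = 6, n_crossings = 3))
  df <- data.frame(kind = c("enrich", "deplete"), start_um = c(60, 10),
                   end_um = c(80, 30), peak_ppm = c(900, 300))
  expect_warning(tl <- timeEvents(df, p), "sort")
  expect_equal(events(tl)$start_um, c(10, 60))
  expect_equal(events(tl)$label, c("A", "B"))
})

test_that("Sr molar ratio follows molar arithmetic", {
  expect_equal(srMolarRatio(100, 100),
               (100 / 87.62) / (100 / 87.62 + 100 / 40.08))
  expect_equal(round(srMolarRatio(1, 1), 4), 0.3139)
  expect_equal(srMolarRatio(0, 4e5), 0)
  # printed peak Sr over printed enamel Ca
  expect_equal(srMolarRatio(860, 4.0e5), 0.00098, tolerance = 0.01)
  expect_error(srMolarRatio(100, 0), "Ca")
})
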