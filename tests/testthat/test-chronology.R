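test_that("dsrProfile divides spans by crossings and averages within zones", {
  p <- dsrProfile(data.frame(zone_index = 0, span_um = 6, n_crossings = 3))
  expect_equal(unname(zoneRates(p)), 2.0)
  p2 <- dsrProfile(data.frame(zone_index = c(0, 0),
                              span_um = c(6, 10), n_crossings = c(3, 4)))
  expect_equal(unname(zoneRates(p2)), mean(c(2.0, 2.5)))
})

test_that("dsrProfile is invariant to measurement order and rejects bad input", {
  m <- data.frame(zone_index = c(1, 0, 0, 1), span_um = c(9, 6, 10, 12),
                  n_crossings = c(3, 3, 4, 4))
  p1 <- dsrProfile(m)
  p2 <- dsrProfile(m[sample.int(4, 4), ])
  expect_equal(zoneRates(p1), zoneRates(p2))
  expect_error(dsrProfile(data.frame(zone_index = c(0, 2), span_um = c(6, 6),
                                     n_crossings = c(3, 3))),
               "zone\\(s\\): 1")
  expect_error(dsrProfile(data.frame(zone_index = 0, span_um = 4,
                                     n_crossings = 2)),
               "three cross-striations")
})

test_that("recovered zone rates reproduce the published DSR gradient", {
  p <- noiselessProfile()
  r <- unname(zoneRates(p))
  expect_equal(r[1], 1.96, tolerance = 0.02)
  expect_equal(r[length(r)], 4.62, tolerance = 0.02)
  expect_true(all(diff(r) > 0))
})

test_that("cuspal time is thickness over mean zone rate", {
  p <- dsrProfile(data.frame(zone_index = 0, span_um = 6, n_crossings = 3))
  ct <- cuspalTime(100, p)
  expect_equal(ct$days, 50)
  expect_equal(ct$meanDsr, 2)
  # published cross-check: ~1330 um at the published mean DSR gives ~564 d
  pMean <- dsrProfile(data.frame(zone_index = 0, span_um = 3 * 2.3582,
                                 n_crossings = 3))
  expect_equal(round(cuspalTime(1330, pMean)$days), 564)
})

test_that("doubling every zone rate halves the cuspal time", {
  m <- data.frame(zone_index = 0:2, span_um = c(6, 7, 8),
                  n_crossings = c(3, 3, 3))
  d1 <- cuspalTime(300, dsrProfile(m))$days
  m2 <- m; m2$span_um <- m2$span_um * 2
  expect_equal(cuspalTime(300, dsrProfile(m2))$days, d1 / 2)
})

test_that("periodicity is the modal count with disagreement and tie flags", {
  expect_equal(striaPeriodicity(c(8, 8, 8)), 8)
  expect_equal(striaPeriodicity(5), 5)
  expect_warning(p <- striaPeriodicity(c(7, 8, 8)), "disagree")
  expect_equal(p, 8)
  expect_warning(expect_warning(pt <- striaPeriodicity(c(7, 7, 8, 8)),
                                "tie"), "disagree")
  expect_equal(pt, 7)
  expect_error(striaPeriodicity(integer(0)), "at least one")
})

test_that("lateral time multiplies decile counts by periodicity", {
  rec <- retziusRecord(c(8, 8, 8), c(0, 0, 3, 5, 7, 9, 11, 15, 19, 20),
                       104, 2)
  lat <- lateralTime(rec)
  expect_equal(sum(lat$perDecileDays[3:10]), 712)  # 89 striae x 8 days
  expect_equal(lat$perDecileDays[10], 160)         # cervical decile, 20 x 8
  expect_equal(lat$deciles12Days, 52)
  expect_equal(lat$lateralDays, 764)
  rec0 <- retziusRecord(8, rep(0L, 10), 0, 2)
  expect_equal(lateralTime(rec0)$lateralDays, 0)
})

test_that("total crown time sums cuspal and lateral and reports years", {
  rec <- retziusRecord(c(8, 8, 8), c(0, 0, 3, 5, 7, 9, 11, 15, 19, 20),
                       104, 2)
  ch <- totalCrownTime(564, lateralTime(rec))
  expect_equal(totalDays(ch), 1328)
  expect_equal(totalYears(ch), 3.64)
  ch0 <- totalCrownTime(0, 0)
  expect_equal(totalDays(ch0), 0)
  expect_equal(totalYears(ch0), 0)
})

test_that("total time is monotone in stria counts and cuspal thickness", {
  base <- c(0L, 0L, 3L, 5L, 7L, 9L, 11L, 15L, 19L, 20L)
  lat0 <- lateralTime(retziusRecord(8, base, 104, 2))$lateralDays
  for (d in 3:10) {
    bumped <- base
    bumped[d] <- bumped[d] + 1L
    expect_gt(lateralTime(retziusRecord(8, bumped, 104, 2))$lateralDays,
              lat0)
  }
  p <- dsrProfile(data.frame(zone_index = 0, span_um = 6, n_crossings = 3))
  expect_gt(cuspalTime(120, p)$days, cuspalTime(100, p)$days)
})

test_that("chronology report rounds only at report time", {
  ch <- totalCrownTime(563.6, 764.2)
  rep <- chronologyReport(ch)
  expect_equal(rep$total_days, round(563.6 + 764.2))
  expect_equal(ch@totalDays, 563.6 + 764.2)
})
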