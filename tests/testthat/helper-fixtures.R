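# Shared synthetic fixtures, generated once per test run.

.fixtures <- new.env(parent = emptyenv())

# noiseless study-condition section (no Raman cube): exact recovery cases
noiselessSection <- function() {
  if (is.null(.fixtures$sec0))
    .fixtures$sec0 <- generateSection(
      sectionConfig(noiseSd = 0, heightPx = 4L), includeRaman = FALSE)
  .fixtures$sec0
}

# study-condition section with the default 5% multiplicative noise
noisySection <- function() {
  if (is.null(.fixtures$sec1))
    .fixtures$sec1 <- generateSection(
      sectionConfig(seed = 7L, heightPx = 8L), includeRaman = FALSE)
  .fixtures$sec1
}

# small Raman-bearing section
ramanSection <- function() {
  if (is.null(.fixtures$sec2))
    .fixtures$sec2 <- generateSection(
      sectionConfig(seed = 2L, heightPx = 4L, cuspalThicknessUm = 700,
                    srEventSpec = defaultSrEvents()[1:3, ]))
  .fixtures$sec2
}

# DSR profile of the noiseless fixture (used to time events)
noiselessProfile <- function() {
  if (is.null(.fixtures$prof0))
    .fixtures$prof0 <- dsrProfile(sectionTables(noiselessSection())$spacings)
  .fixtures$prof0
}

# independent day -> distance oracle: fine-grid trapezoid integration of
# 1/DSR(x) for the generator's zone-mean-calibrated linear gradient
oracleDayToDistance <- function(config, days) {
  X <- config@cuspalThicknessUm
  w <- 100
  nZones <- ceiling(X / w)
  if (config@dsrInner == config@dsrOuter) {
    a <- config@dsrInner; b <- 0
  } else {
    wLast <- X - w * (nZones - 1)
    c0 <- w / 2
    cLast <- w * (nZones - 1) + wLast / 2
    b <- (config@dsrOuter - config@dsrInner) / (cLast - c0)
    a <- config@dsrInner - b * c0
  }
  x <- seq(0, X, by = 0.01)
  tAtX <- pracma::cumtrapz(x, 1 / (a + b * x))
  stats::approx(tAtX, x, xout = days)$y
}
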