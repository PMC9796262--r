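#' @include AllClasses.R
NULL

#' Construct a transect profile
#'
#' @param positionsUm strictly increasing distances from the EDJ (um),
#'   starting at 0.
#' @param valuesPpm concentrations at each position, ppm.
#' @return a [TransectProfile-class].
#' @export
transectProfile <- function(positionsUm, valuesPpm) {
  new("TransectProfile", positionsUm = as.numeric(positionsUm),
      valuesPpm = as.numeric(valuesPpm))
}

#' Detect enrichment/depletion bands along a transect
#'
#' Events are maximal runs of positions whose concentration deviates from a
#' robust baseline by more than `kThreshold` noise scales. The baseline is
#' a running median of width `baselineWindowUm`; the default (`Inf`) uses
#' the global median, appropriate when the bands are wider than any
#' reasonable local window. The noise scale is, by default, the median
#' absolute deviation of the first differences divided by sqrt(2), which is
#' insensitive to the piecewise-constant banding itself; `scaleMethod =
#' "mad"` instead uses the MAD of the residuals about the baseline. Runs of
#' the same sign separated by less than `mergeGapUm` are merged, and runs
#' narrower than `minWidthUm` are discarded as noise.
#'
#' A constant profile yields no events, and detection is invariant to adding
#' a global constant.
#'
#' @param profile a [TransectProfile-class].
#' @param baselineWindowUm running-median window, um; `Inf` for the global
#'   median.
#' @param kThreshold threshold in noise-scale units (default 3).
#' @param minWidthUm minimum event width, um; default 3 sample spacings.
#' @param mergeGapUm merge same-sign runs closer than this, um; default one
#'   sample spacing.
#' @param scaleMethod "diff" (default) or "mad".
#' @return data.frame with columns `kind`, `start_um`, `end_um`, `peak_ppm`,
#'   ordered by position (equivalently by formation order).
#' @export
detectEvents <- function(profile, baselineWindowUm = Inf, kThreshold = 3,
                         minWidthUm = NULL, mergeGapUm = NULL,
                         scaleMethod = c("diff", "mad")) {
  stopifnot(is(profile, "TransectProfile"))
  scaleMethod <- match.arg(scaleMethod)
  x <- profile@positionsUm
  v <- profile@valuesPpm
  n <- length(v)
  empty <- data.frame(kind = character(), start_um = numeric(),
                      end_um = numeric(), peak_ppm = numeric())
  if (n < 3L) return(empty)
  px <- stats::median(diff(x))
  if (is.finite(baselineWindowUm)) {
    if (x[n] - x[1] <= baselineWindowUm)
      stop("profile must be longer than the baseline window")
    k <- max(3L, round(baselineWindowUm / px))
    if (k %% 2L == 0L) k <- k + 1L
    k <- min(k, if (n %% 2L) n else n - 1L)
    baseline <- stats::runmed(v, k, endrule = "median")
  } else {
    baseline <- rep(stats::median(v), n)
  }
  resid <- v - baseline
  scale <- if (scaleMethod == "diff") stats::mad(diff(v)) / sqrt(2)
           else stats::mad(resid)
  exceed0 <- abs(resid) > kThreshold * scale
  if (scaleMethod == "diff" && any(!exceed0)) {
    # second pass: the difference-based scale understates the marginal
    # noise of a smoothed profile, so re-estimate it from the residuals of
    # the samples outside the provisional runs (sigma-clipping); in the
    # noiseless case both scales are zero and the behavior is unchanged
    scale <- max(scale, stats::mad(resid[!exceed0], center = 0))
  }
  thr <- kThreshold * scale
  state <- integer(n)
  state[resid >  thr] <- 1L
  state[resid < -thr] <- -1L
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  if (!any(keep)) return(empty)
  runs <- data.frame(sign = r$values[keep], i1 = starts[keep], i2 = ends[keep])
  # merge same-sign runs separated by less than one increment spacing
  if (is.null(mergeGapUm)) mergeGapUm <- px
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (j in 2:nrow(runs)) {
      last <- nrow(merged)
      gap <- x[runs$i1[j]] - x[merged$i2[last]]
      if (runs$sign[j] == merged$sign[last] && gap <= mergeGapUm + 1e-9) {
        merged$i2[last] <- runs$i2[j]
      } else {
        merged <- rbind(merged, runs[j, ])
      }
    }
  }
  if (is.null(minWidthUm)) minWidthUm <- 3 * px
  width <- x[merged$i2] - x[merged$i1]
  merged <- merged[width + 1e-9 >= minWidthUm, , drop = FALSE]
  if (nrow(merged) == 0L) return(empty)
  peak <- vapply(seq_len(nrow(merged)), function(j) {
    seg <- v[merged$i1[j]:merged$i2[j]]
    if (merged$sign[j] > 0) max(seg) else min(seg)
  }, numeric(1))
  data.frame(kind = ifelse(merged$sign > 0, "enrich", "deplete"),
             start_um = x[merged$i1], end_um = x[merged$i2],
             peak_ppm = peak)
}

#' Convert prism-path distance to developmental days
#'
#' Integrates the reciprocal DSR along the prism path: the time to traverse
#' each 100-um zone is its length divided by the zone's rate, and the time
#' to reach a distance is the exact piecewise-constant sum over the zones
#' traversed. The conversion is strictly increasing and additive over
#' concatenated segments.
#'
#' @param distanceUm distances from the EDJ, um (vectorized).
#' @param profile a [DSRProfile-class] covering the distances.
#' @return days since crown-formation onset at each distance.
#' @examples
#' p <- dsrProfile(data.frame(zone_index = c(0, 1), span_um = c(6, 12),
#'                            n_crossings = c(3, 3)))
#' distanceToDays(200, p)  # 100/2 + 100/4 = 75
#' @export
distanceToDays <- function(distanceUm, profile) {
  stopifnot(is(profile, "DSRProfile"))
  w <- profile@zoneWidthUm
  r <- profile@zoneRate
  coverage <- length(r) * w
  if (any(distanceUm < 0)) stop("distances must be >= 0")
  if (any(distanceUm > coverage + 1e-9))
    stop("distance beyond the DSR profile coverage (", coverage, " um)")
  cumDays <- c(0, cumsum(w / r))
  vapply(distanceUm, function(d) {
    i <- min(floor(d / w), length(r) - 1L)
    cumDays[i + 1] + (d - i * w) / r[i + 1]
  }, numeric(1))
}

#' Convert developmental days to prism-path distance
#'
#' Inverse of [distanceToDays()] under the same piecewise-constant zone
#' rates.
#'
#' @param days days since crown-formation onset (vectorized).
#' @param profile a [DSRProfile-class].
#' @return distances from the EDJ, um.
#' @export
daysToDistance <- function(days, profile) {
  stopifnot(is(profile, "DSRProfile"))
  w <- profile@zoneWidthUm
  r <- profile@zoneRate
  cumDays <- c(0, cumsum(w / r))
  if (any(days < 0)) stop("days must be >= 0")
  if (any(days > cumDays[length(cumDays)] + 1e-9))
    stop("days beyond the DSR profile coverage")
  vapply(days, function(t) {
    i <- findInterval(t, cumDays, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(r))
    (i - 1L) * w + (t - cumDays[i]) * r[i]
  }, numeric(1))
}

#' Time detected events and assess their regularity
#'
#' Converts event start/end distances to developmental days through the DSR
#' profile, letters the events in chronological order of formation (A, B,
#' ...), and assesses temporal regularity from the coefficient of variation
#' (CV) of the inter-onset intervals: CV above `cvThreshold` is called
#' aperiodic, below periodic; fewer than three events is indeterminate.
#' Optionally a Monte-Carlo p-value is computed by drawing `nSim` sets of
#' uniform random onsets over the observed span and recording how often
#' their CV falls at or below the observed one (small p means more regular
#' than random).
#'
#' @param eventsDf data.frame from [detectEvents()] (auto-sorted by start
#'   position with a warning if unsorted).
#' @param profile a [DSRProfile-class].
#' @param cvThreshold CV above which the verdict is aperiodic (default
#'   0.25).
#' @param nSim Monte-Carlo draws for the p-value (0 disables; default 0).
#' @param seed seed for the Monte-Carlo draw.
#' @return an [EventTimeline-class].
#' @export
timeEvents <- function(eventsDf, profile, cvThreshold = 0.25,
                       nSim = 0, seed = 1L) {
  stopifnot(is(profile, "DSRProfile"))
  if (nrow(eventsDf) > 1 && is.unsorted(eventsDf$start_um)) {
    warning("events were not sorted by formation order; sorting")
    eventsDf <- eventsDf[order(eventsDf$start_um), ]
  }
  n <- nrow(eventsDf)
  if (n == 0L) {
    return(new("EventTimeline",
               events = data.frame(label = character(), kind = character(),
                                   start_um = numeric(), end_um = numeric(),
                                   peak_ppm = numeric(), onset_day = numeric(),
                                   end_day = numeric(),
                                   duration_days = numeric()),
               intervalsDays = numeric(), cv = NA_real_, pValue = NA_real_,
               verdict = "indeterminate"))
  }
  onset <- distanceToDays(eventsDf$start_um, profile)
  endd <- distanceToDays(eventsDf$end_um, profile)
  ev <- data.frame(label = LETTERS[seq_len(n)],
                   kind = eventsDf$kind,
                   start_um = eventsDf$start_um,
                   end_um = eventsDf$end_um,
                   peak_ppm = eventsDf$peak_ppm,
                   onset_day = onset, end_day = endd,
                   duration_days = endd - onset)
  intervals <- diff(onset)
  cv <- if (length(intervals) >= 2)
    stats::sd(intervals) / mean(intervals) else NA_real_
  verdict <- if (!is.finite(cv)) "indeterminate"
             else if (cv > cvThreshold) "aperiodic" else "periodic"
  pval <- NA_real_
  if (nSim > 0 && length(intervals) >= 2) {
    span <- range(onset)
    sims <- .withSeed(seed, {
      vapply(seq_len(nSim), function(i) {
        o <- sort(stats::runif(n, span[1], span[2]))
        iv <- diff(o)
        stats::sd(iv) / mean(iv)
      }, numeric(1))
    })
    pval <- (1 + sum(sims <= cv)) / (nSim + 1)
  }
  new("EventTimeline", events = ev, intervalsDays = intervals,
      cv = cv, pValue = pval, verdict = verdict)
}

#' Sr/(Sr + Ca) molar ratio
#'
#' Converts mass fractions (ppm) to moles with atomic masses M_Sr = 87.62
#' and M_Ca = 40.08 g/mol and returns the strontium molar share of the
#' (Sr + Ca) pool, the standard gauge of Sr-for-Ca substitution in
#' hydroxyapatite.
#'
#' @param srPpm strontium mass fraction, ppm.
#' @param caPpm calcium mass fraction, ppm (must be positive).
#' @return dimensionless molar ratio in \[0, 1).
#' @examples
#' srMolarRatio(860, 4.0e5)
#' @export
srMolarRatio <- function(srPpm, caPpm) {
  if (any(caPpm <= 0)) stop("Ca concentration must be positive")
  if (any(srPpm < 0)) stop("Sr concentration must be >= 0")
  mSr <- srPpm / 87.62
  mCa <- caPpm / 40.08
  mSr / (mSr + mCa)
}

#' Extract a transect from an element map
#'
#' Reads one raster row of an [ElementMap-class] across its enamel pixels
#' and returns the concentration profile against cumulative distance from
#' the EDJ (the first enamel pixel of the row).
#'
#' @param map an [ElementMap-class].
#' @param row raster row to read (default: middle row).
#' @return a [TransectProfile-class].
#' @export
extractTransect <- function(map, row = NULL) {
  stopifnot(is(map, "ElementMap"))
  if (is.null(row)) row <- ceiling(nrow(map@grid) / 2)
  sel <- which(map@phaseMask[row, ] == "enamel")
  if (length(sel) == 0L) stop("row contains no enamel pixels")
  vals <- map@grid[row, sel]
  pos <- (seq_along(sel) - 1L) * map@pixelSizeUm
  transectProfile(pos, pmax(vals, 0))
}
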