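#' @include AllClasses.R
NULL

#' Build a daily-secretion-rate profile from cross-striation spacings
#'
#' Cross-striations are daily incremental markings along enamel prisms; the
#' distance covered by `n_crossings` consecutive daily intervals, divided by
#' that count, estimates the daily secretion rate (DSR) where the
#' measurement was taken. Measurements are grouped into contiguous zones of
#' `zoneWidthUm` along the prism path (zone 0 at the EDJ) and averaged
#' per zone.
#'
#' @param measurements data.frame with columns `zone_index` (integer, 0 at
#'   the EDJ), `span_um` (length of the measured run, um) and `n_crossings`
#'   (number of daily intervals spanned, at least 3).
#' @param zoneWidthUm zone width in um (default 100).
#' @return a [DSRProfile-class].
#' @details Every zone between the EDJ and the outermost measured zone must
#'   carry at least one measurement; gaps raise an error naming the missing
#'   zones. Each per-zone rate is the arithmetic mean of `span_um /
#'   n_crossings` over that zone's measurements, so it is invariant to the
#'   order of the rows.
#' @examples
#' m <- data.frame(zone_index = c(0, 0, 1),
#'                 span_um = c(6, 10, 9), n_crossings = c(3, 4, 3))
#' dsrProfile(m)
#' @export
dsrProfile <- function(measurements, zoneWidthUm = 100) {
  need <- c("zone_index", "span_um", "n_crossings")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  if (nrow(measurements) == 0L) stop("no measurements supplied")
  if (any(measurements$n_crossings < 3L))
    stop("each measurement must span at least three cross-striations")
  if (any(measurements$span_um <= 0))
    stop("spans must be positive")
  zi <- as.integer(measurements$zone_index)
  zmax <- max(zi)
  missing <- setdiff(0:zmax, unique(zi))
  if (length(missing))
    stop("no measurements in zone(s): ", paste(missing, collapse = ", "))
  rate1 <- measurements$span_um / measurements$n_crossings
  agg <- tapply(rate1, factor(zi, levels = 0:zmax), mean)
  n <- tapply(rate1, factor(zi, levels = 0:zmax), length)
  new("DSRProfile",
      zoneWidthUm = zoneWidthUm,
      zoneIndex = 0:zmax,
      zoneRate = as.numeric(agg),
      nMeasurements = as.integer(n))
}

#' Cuspal enamel formation time
#'
#' The time to form the cuspal enamel is its thickness along the prism path
#' divided by the overall average DSR, taken as the unweighted mean of the
#' per-zone rates.
#'
#' @param cuspalThicknessUm cuspal enamel thickness, um.
#' @param profile a [DSRProfile-class] covering the cuspal transect.
#' @return list with `days` (unrounded) and `meanDsr` (um/day).
#' @examples
#' p <- dsrProfile(data.frame(zone_index = 0, span_um = 6, n_crossings = 3))
#' cuspalTime(100, p)  # 50 days at 2 um/day
#' @export
cuspalTime <- function(cuspalThicknessUm, profile) {
  stopifnot(is(profile, "DSRProfile"))
  if (length(profile@zoneRate) == 0L) stop("empty DSR profile")
  if (cuspalThicknessUm <= 0) stop("thickness must be positive")
  meanDsr <- mean(profile@zoneRate)
  list(days = cuspalThicknessUm / meanDsr, meanDsr = meanDsr)
}

#' Stria periodicity from repeat counts
#'
#' The periodicity of the striae of Retzius is the number of daily
#' cross-striations between two successive striae, counted at several
#' locations and assumed constant over the whole crown. The modal count is
#' returned; disagreement between locations is flagged with a warning, and a
#' tie between modes resolves to the smallest value (conservative), also
#' with a warning.
#'
#' @param countsBetweenStriae integer counts, one per sampling location.
#' @return the modal periodicity (integer days).
#' @examples
#' striaPeriodicity(c(8, 8, 8))
#' @export
striaPeriodicity <- function(countsBetweenStriae) {
  if (length(countsBetweenStriae) == 0L)
    stop("at least one periodicity count is required")
  cnt <- as.integer(countsBetweenStriae)
  if (any(cnt < 1L)) stop("counts must be >= 1")
  tab <- table(cnt)
  modes <- as.integer(names(tab)[tab == max(tab)])
  if (length(modes) > 1L)
    warning("periodicity tie between ", paste(modes, collapse = " and "),
            "; taking the smallest")
  p <- min(modes)
  if (length(unique(cnt)) > 1L)
    warning("periodicity counts disagree between locations: ",
            paste(cnt, collapse = ", "))
  p
}

#' Construct a striae-of-Retzius record
#'
#' @param periodicityCounts cross-striation counts between adjacent striae,
#'   one per sampling location.
#' @param decileStriaCounts stria counts for deciles 1..10 (use 0 for
#'   deciles 1-2 when they are timed through the prism-path length).
#' @param deciles12LengthUm prism-path length for deciles 1-2, um.
#' @param deciles12Dsr local DSR for deciles 1-2, um/day.
#' @param periodicityDays periodicity override; computed with
#'   [striaPeriodicity()] when NULL.
#' @return a [RetziusRecord-class].
#' @export
retziusRecord <- function(periodicityCounts, decileStriaCounts,
                          deciles12LengthUm, deciles12Dsr,
                          periodicityDays = NULL) {
  if (is.null(periodicityDays))
    periodicityDays <- striaPeriodicity(periodicityCounts)
  new("RetziusRecord",
      periodicityDays = as.integer(periodicityDays),
      periodicityCounts = as.integer(periodicityCounts),
      decileStriaCounts = as.integer(decileStriaCounts),
      deciles12LengthUm = as.numeric(deciles12LengthUm),
      deciles12Dsr = as.numeric(deciles12Dsr))
}

#' Lateral enamel formation time
#'
#' In the lateral enamel the striae of Retzius crop out at the surface, so
#' each decile of crown height forms over (stria count x periodicity) days.
#' Deciles 1 and 2, where individual striae are hard to resolve, are timed
#' by dividing the prism-path length between the cuspal-lateral boundary and
#' the first stria of decile 3 by the local DSR, rounded to whole days.
#'
#' @param record a [RetziusRecord-class].
#' @return list with `deciles12Days`, `perDecileDays` (length 10, deciles
#'   1-2 NA), and `lateralDays`.
#' @examples
#' r <- retziusRecord(c(8, 8, 8), c(0, 0, 3, 5, 7, 9, 11, 15, 19, 20),
#'                    deciles12LengthUm = 104, deciles12Dsr = 2)
#' lateralTime(r)$lateralDays  # 52 + 712
#' @export
lateralTime <- function(record) {
  stopifnot(is(record, "RetziusRecord"))
  P <- record@periodicityDays
  if (length(P) == 0L || is.na(P)) stop("missing periodicity")
  perDecile <- rep(NA_real_, 10)
  perDecile[3:10] <- as.numeric(record@decileStriaCounts[3:10]) * P
  d12 <- if (record@deciles12LengthUm > 0)
    round(record@deciles12LengthUm / record@deciles12Dsr)
  else 0
  list(deciles12Days = d12,
       perDecileDays = perDecile,
       lateralDays = d12 + sum(perDecile[3:10]))
}

#' Total crown formation time
#'
#' Total crown formation time is the sum of the cuspal and lateral enamel
#' formation times; the result is also expressed in years (365-day year,
#' two decimals). Day values are kept in floating point internally and
#' rounded only for reporting.
#'
#' @param cuspalDays cuspal formation time, days.
#' @param lateral either the list returned by [lateralTime()] or a single
#'   number of lateral days.
#' @param meanCuspalDsr optional mean cuspal DSR to carry in the report.
#' @return a [CrownChronology-class].
#' @examples
#' totalCrownTime(564, 764)  # 1328 days, 3.64 years
#' @export
totalCrownTime <- function(cuspalDays, lateral, meanCuspalDsr = NA_real_) {
  if (cuspalDays < 0) stop("cuspalDays must be >= 0")
  if (is.list(lateral)) {
    d12 <- lateral$deciles12Days
    perDecile <- lateral$perDecileDays
    lateralDays <- lateral$lateralDays
  } else {
    if (lateral < 0) stop("lateral days must be >= 0")
    d12 <- lateral
    perDecile <- c(NA_real_, NA_real_, rep(0, 8))
    lateralDays <- lateral
  }
  total <- cuspalDays + lateralDays
  new("CrownChronology",
      cuspalDays = cuspalDays,
      deciles12Days = d12,
      perDecileDays = perDecile,
      lateralDays = lateralDays,
      totalDays = total,
      totalYears = round(total / 365, 2),
      meanCuspalDsr = meanCuspalDsr)
}

#' Full chronology from measurement tables
#'
#' Convenience wrapper running the whole chronology stage: DSR profile from
#' spacing measurements, periodicity from repeat counts, lateral time from
#' the decile record, cuspal time from the thickness, and the total.
#'
#' @param spacings data.frame for [dsrProfile()].
#' @param periodicityCounts counts for [striaPeriodicity()].
#' @param decileStriaCounts stria counts for deciles 1..10.
#' @param cuspalThicknessUm cuspal enamel thickness, um.
#' @param deciles12LengthUm,deciles12Dsr deciles 1-2 geometry.
#' @param zoneWidthUm zone width for the DSR profile.
#' @return list with `profile` ([DSRProfile-class]) and `chronology`
#'   ([CrownChronology-class]).
#' @export
crownChronology <- function(spacings, periodicityCounts, decileStriaCounts,
                            cuspalThicknessUm, deciles12LengthUm,
                            deciles12Dsr, zoneWidthUm = 100) {
  profile <- dsrProfile(spacings, zoneWidthUm)
  rec <- retziusRecord(periodicityCounts, decileStriaCounts,
                       deciles12LengthUm, deciles12Dsr)
  lat <- lateralTime(rec)
  cusp <- cuspalTime(cuspalThicknessUm, profile)
  list(profile = profile,
       chronology = totalCrownTime(cusp$days, lat,
                                   meanCuspalDsr = cusp$meanDsr))
}

#' Report a chronology as a plain list
#'
#' Flattens a [CrownChronology-class] into report-ready values, rounding
#' day totals to whole days (the convention used when publishing crown
#' formation times) and years to two decimals.
#'
#' @param chronology a [CrownChronology-class].
#' @return a named list suitable for JSON serialization.
#' @export
chronologyReport <- function(chronology) {
  stopifnot(is(chronology, "CrownChronology"))
  list(
    cuspal_days = round(chronology@cuspalDays),
    deciles12_days = round(chronology@deciles12Days),
    per_decile_days = ifelse(is.na(chronology@perDecileDays), NA,
                             round(chronology@perDecileDays)),
    deciles3_10_days = round(sum(chronology@perDecileDays[3:10])),
    lateral_days = round(chronology@lateralDays),
    total_days = round(chronology@totalDays),
    total_years = chronology@totalYears,
    mean_cuspal_dsr = chronology@meanCuspalDsr
  )
}
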