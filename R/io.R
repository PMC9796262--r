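#' @include AllClasses.R sxrf.R
NULL

#' Write an element map as TIFF plus YAML sidecar
#'
#' Pixel values are stored scaled to \[0, 1\] in a single-channel 32-bit
#' TIFF; the scale factor, element, units state, pixel size and phase
#' legend go to a YAML sidecar (`<path>.yml`) so the map round-trips
#' losslessly at raster precision.
#'
#' @param map an [ElementMap-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeElementMap <- function(map, path) {
  stopifnot(is(map, "ElementMap"))
  g <- map@grid
  g[!is.finite(g)] <- 0
  lo <- min(g)
  hi <- max(g)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((g - lo) / scale, path, bits.per.sample = 32L)
  phaseCode <- matrix(match(map@phaseMask,
                            c("enamel", "dentin", "background")),
                      nrow(g), ncol(g))
  meta <- list(element = map@element,
               pixel_size_um = map@pixelSizeUm,
               units_state = map@unitsState,
               offset = lo, scale = scale,
               phase_legend = c("enamel", "dentin", "background"),
               phase_rle = list(lengths = rle(as.vector(phaseCode))$lengths,
                                values = rle(as.vector(phaseCode))$values))
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' Read an element map written by [writeElementMap()]
#'
#' @param path TIFF path (sidecar `<path>.yml` must exist).
#' @return an [ElementMap-class].
#' @export
readElementMap <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  g <- tiff::readTIFF(path)
  g <- g * meta$scale + meta$offset
  code <- inverse.rle(structure(list(
    lengths = as.integer(meta$phase_rle$lengths),
    values = as.integer(meta$phase_rle$values)), class = "rle"))
  phase <- matrix(meta$phase_legend[code], nrow(g), ncol(g))
  new("ElementMap", element = meta$element, grid = g,
      pixelSizeUm = meta$pixel_size_um, unitsState = meta$units_state,
      phaseMask = phase)
}

#' Read cross-striation spacing measurements
#'
#' Expects a CSV with columns `zone_index`, `span_um`, `n_crossings`.
#'
#' @param path CSV path.
#' @return data.frame for [dsrProfile()].
#' @export
readSpacings <- function(path) {
  df <- utils::read.csv(path)
  need <- c("zone_index", "span_um", "n_crossings")
  if (!all(need %in% names(df)))
    stop(path, " must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read per-decile stria counts
#'
#' Expects a CSV with columns `decile`, `stria_count`.
#'
#' @param path CSV path.
#' @return integer vector of length 10 (counts for deciles 1..10).
#' @export
readDecileCounts <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("decile", "stria_count") %in% names(df)))
    stop(path, " must have columns: decile, stria_count")
  counts <- integer(10)
  counts[df$decile] <- as.integer(df$stria_count)
  counts
}

#' Read a concentration transect
#'
#' Expects a CSV with columns `position_um`, `value_ppm`.
#'
#' @param path CSV path.
#' @return a [TransectProfile-class].
#' @export
readTransect <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("position_um", "value_ppm") %in% names(df)))
    stop(path, " must have columns: position_um, value_ppm")
  transectProfile(df$position_um, df$value_ppm)
}

#' Write a transect to CSV
#'
#' @param profile a [TransectProfile-class].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeTransect <- function(profile, path) {
  stopifnot(is(profile, "TransectProfile"))
  utils::write.csv(data.frame(position_um = profile@positionsUm,
                              value_ppm = profile@valuesPpm),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read EDX measurements
#'
#' Expects a CSV with columns `specimen`, `layer`, `P`, `Ca`, `Mg`.
#'
#' @param path CSV path.
#' @return data.frame for [layerSummary()].
#' @export
readEdx <- function(path) {
  df <- utils::read.csv(path)
  need <- c("specimen", "layer", "P", "Ca", "Mg")
  if (!all(need %in% names(df)))
    stop(path, " must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write an event table as CSV
#'
#' Columns follow the reporting convention for lettered events: label,
#' kind, distance range from the EDJ, peak concentration, and cumulative
#' formation time at onset and end.
#'
#' @param timeline an [EventTimeline-class].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeEventTable <- function(timeline, path) {
  stopifnot(is(timeline, "EventTimeline"))
  utils::write.csv(events(timeline), path, row.names = FALSE)
  invisible(path)
}
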