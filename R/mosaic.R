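#' Consecutive internuclear distances of an RPE trace
#'
#' @param trace an [RPETrace-class] with at least two nuclei.
#' @return numeric vector of consecutive differences (um), length
#'   `length(positions) - 1`, all strictly positive.
#' @examples
#' internuclearDistances(rpeTrace(c(0, 20, 40, 70)))  # 20 20 30
#' @rdname internuclearDistances
#' @export
setMethod("internuclearDistances", "RPETrace", function(trace) {
  p <- positions(trace)
  if (length(p) < 2L)
    stop("at least 2 nucleus positions are required to form distances")
  d <- diff(p)
  if (any(d <= 0)) stop("positions must be strictly increasing")
  d
})

#' Median-threshold classification of internuclear gaps
#'
#' Classifies every raw internuclear distance against thresholds derived
#' from the median of the *raw, unfiltered* distances: gaps strictly
#' below half the median are artifacts of binucleate cells (two nuclei
#' of one cell), gaps strictly above twice the median are artifacts of a
#' missing intermediate nucleus (dropout); everything else, including
#' gaps exactly at a threshold, is a normal cell boundary. The median of
#' an even-length list is the mean of the two central values.
#'
#' @param distances raw internuclear distances (um), non-empty.
#' @return list with `median`, `lower` (= median / 2), `upper`
#'   (= 2 * median) and `classes` (character vector
#'   `normal|binucleate|dropout`, one per gap).
#' @examples
#' classifyGaps(c(20, 20, 30, 9, 41))
#' @export
classifyGaps <- function(distances) {
  if (length(distances) == 0L) stop("no distances to classify")
  if (any(!is.finite(distances)) || any(distances <= 0))
    stop("distances must be finite and > 0")
  med <- stats::median(distances)
  lower <- med / 2
  upper <- 2 * med
  classes <- rep("normal", length(distances))
  classes[distances < lower] <- "binucleate"
  classes[distances > upper] <- "dropout"
  list(median = med, lower = lower, upper = upper, classes = classes)
}

#' Merge binucleate nucleus pairs and drop dropout gaps
#'
#' Applies the corrections the classification calls for: the two nuclei
#' flanking each binucleate-classified gap are one cell and are replaced
#' by their midpoint; distances are then recomputed from the merged
#' positions; gaps classified as dropout are excluded from the corrected
#' distance list while their flanking nuclei are retained. When two
#' consecutive gaps are both classified binucleate (a chain of three
#' close nuclei) the merge is resolved greedily left to right and the
#' event is counted in `chainEvents`.
#'
#' @param trace an [RPETrace-class].
#' @param classification result of [classifyGaps()] on
#'   `internuclearDistances(trace)`.
#' @return list with `positions` (merged nucleus positions),
#'   `distances` (corrected distances, dropout gaps excluded),
#'   `gapClasses` (class of each merged-position gap, inherited from the
#'   original gap between the adjacent raw nuclei),
#'   `binucleateFraction` (merges / raw nuclei), `binucleateCellFraction`
#'   (merges / corrected cells), `dropoutFraction` (dropout gaps / raw
#'   gaps), `nMerged`, `chainEvents`.
#' @examples
#' tr <- rpeTrace(c(0, 3, 23), segmentLength = 250)
#' cls <- classifyGaps(internuclearDistances(tr))
#' correctBinucleates(tr, cls)$distances  # 21.5
#' @export
correctBinucleates <- function(trace, classification) {
  p <- positions(trace)
  classes <- classification$classes
  if (length(classes) != length(p) - 1L)
    stop("classification does not align with the gaps of the trace")
  n <- length(p)
  merged <- numeric(0)
  lastRaw <- integer(0)   # raw index of the last nucleus of each unit
  chainEvents <- 0L
  i <- 1L
  while (i <= n) {
    if (i < n && classes[i] == "binucleate") {
      merged <- c(merged, (p[i] + p[i + 1L]) / 2)
      lastRaw <- c(lastRaw, i + 1L)
      if (i + 1L < n && classes[i + 1L] == "binucleate")
        chainEvents <- chainEvents + 1L   # third nucleus stays separate
      i <- i + 2L
    } else {
      merged <- c(merged, p[i])
      lastRaw <- c(lastRaw, i)
      i <- i + 1L
    }
  }
  nMerged <- n - length(merged)
  # each between-unit gap inherits the class of the raw gap between the
  # adjacent raw nuclei (never a merged-away binucleate gap)
  gapClasses <- if (length(lastRaw) > 1L)
    classes[lastRaw[-length(lastRaw)]] else character(0)
  gapClasses[gapClasses == "binucleate"] <- "normal"  # unresolved chains
  dists <- diff(merged)
  corrected <- dists[gapClasses != "dropout"]
  list(
    positions = merged,
    distances = corrected,
    gapClasses = gapClasses,
    binucleateFraction = if (n > 0) nMerged / n else NA_real_,
    binucleateCellFraction = if (length(merged) > 0)
      nMerged / length(merged) else NA_real_,
    dropoutFraction = if (n > 1L)
      sum(classes == "dropout") / (n - 1L) else NA_real_,
    nMerged = nMerged,
    chainEvents = chainEvents
  )
}

#' Hexagon-model RPE cell area from an internuclear distance
#'
#' The RPE mosaic is idealized as a packing of regular hexagons whose
#' centers are the cell nuclei, so the internuclear distance D of
#' adjacent cells is twice the apothem h. For a regular hexagon of side
#' a: h = (sqrt(3)/2) a, D = 2 h = sqrt(3) a, and the area is
#' A = 3 h a = (sqrt(3)/2) D^2.
#'
#' @param distance internuclear distance D (um), >= 0; vectorized.
#' @return cell area in um^2.
#' @examples
#' hexagonArea(19.16)   # 317.9 um^2, a visual-streak-sized cell
#' hexagonArea(22.59)   # 441.9 um^2, a peripheral cell
#' @export
hexagonArea <- function(distance) {
  if (any(!is.finite(distance)) || any(distance < 0))
    stop("distance must be finite and >= 0")
  sqrt(3) / 2 * distance^2
}

#' @describeIn hexagonArea the full hexagon geometry: side
#'   `a = D / sqrt(3)`, apothem (half-distance) `h = D / 2`, and area
#'   `A = 3 h a = (sqrt(3)/2) D^2`, as a data.frame.
#' @export
hexagonGeometry <- function(distance) {
  area <- hexagonArea(distance)
  data.frame(distance = distance,
             side = distance / sqrt(3),
             height = distance / 2,
             area = area)
}

#' Relative increase of a measurement over a reference
#'
#' `(value / reference - 1) * 100`, in percent; used e.g. for RPE height
#' and phagosome load of the visual streak relative to the periphery.
#'
#' @param value measurement in the region of interest.
#' @param reference measurement in the reference region, > 0.
#' @return percent increase (negative for a decrease).
#' @examples
#' relativeIncrease(12.08, 7)   # ~72.6% taller
#' @export
relativeIncrease <- function(value, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("reference must be > 0")
  (value / reference - 1) * 100
}

#' Phagosomes per RPE cell
#'
#' @param phagosomeCount phagosomes counted through the z-stack of a
#'   section.
#' @param rpeCellCount RPE cells in the same section, > 0.
#' @return phagosomes per cell.
#' @examples
#' phagosomesPerCell(12, 4)   # 3
#' @export
phagosomesPerCell <- function(phagosomeCount, rpeCellCount) {
  if (any(!is.finite(rpeCellCount)) || any(rpeCellCount <= 0))
    stop("rpeCellCount must be > 0")
  if (any(phagosomeCount < 0, na.rm = TRUE))
    stop("phagosomeCount must be >= 0")
  phagosomeCount / rpeCellCount
}

#' Full mosaic analysis of one RPE trace
#'
#' Runs the pipeline of [internuclearDistances()], [classifyGaps()],
#' [correctBinucleates()] and [hexagonArea()] on one trace. Two
#' treatments of binucleate gaps are available: `"midpoint"` (default)
#' replaces each flagged nucleus pair by its midpoint before
#' recomputing distances; `"exclude"` simply removes the flagged gaps
#' from the distance list (binucleate cells left out of the area
#' calculation). Dropout gaps are excluded from distance statistics in
#' both modes.
#'
#' @param trace an [RPETrace-class] with >= 2 nuclei.
#' @param correction `"midpoint"` or `"exclude"`.
#' @return a [MosaicResult-class].
#' @examples
#' p <- truthParams("VS")
#' sim <- simulateRpeTrace(p, segmentLength = 2000, seed = 2)
#' analyzeTrace(sim$trace)
#' @rdname analyzeTrace
#' @export
setMethod("analyzeTrace", "RPETrace",
  function(trace, correction = c("midpoint", "exclude")) {
    correction <- match.arg(correction)
    d <- internuclearDistances(trace)
    cls <- classifyGaps(d)
    if (correction == "midpoint") {
      corr <- correctBinucleates(trace, cls)
      corrected <- corr$distances
      correctedPos <- corr$positions
      binuFrac <- corr$binucleateFraction
      binuCellFrac <- corr$binucleateCellFraction
      dropFrac <- corr$dropoutFraction
      chains <- corr$chainEvents
    } else {
      corrected <- d[cls$classes == "normal"]
      correctedPos <- positions(trace)
      nB <- sum(cls$classes == "binucleate")
      binuFrac <- nB / length(positions(trace))
      binuCellFrac <- nB / (length(positions(trace)) - nB)
      dropFrac <- sum(cls$classes == "dropout") / length(d)
      chains <- 0L
    }
    meanD <- if (length(corrected)) mean(corrected) else NA_real_
    new("MosaicResult",
        animalId = animalId(trace), region = region(trace),
        rawDistances = d,
        medianDistance = cls$median,
        lowerThreshold = cls$lower, upperThreshold = cls$upper,
        classifications = cls$classes,
        correctedPositions = correctedPos,
        correctedDistances = corrected,
        binucleateFraction = binuFrac,
        binucleateCellFraction = binuCellFrac,
        dropoutFraction = dropFrac,
        chainEvents = as.integer(chains),
        cellAreaMean = if (length(corrected))
          mean(hexagonArea(corrected)) else NA_real_,
        cellAreaFromMeanDistance = if (is.na(meanD)) NA_real_
          else hexagonArea(meanD),
        meanCorrectedDistance = meanD,
        hexagonSide = meanD / sqrt(3),
        hexagonHeight = meanD / 2,
        correction = correction)
  })

#' Tabulate mosaic analyses of many traces
#'
#' Applies [analyzeTrace()] to each trace and returns one row per trace
#' with thresholds, artifact fractions, mean corrected distance and both
#' cell-area estimators.
#'
#' @param traces list of [RPETrace-class] objects.
#' @param correction passed to [analyzeTrace()].
#' @return a data.frame, one row per trace.
#' @export
mosaicReport <- function(traces, correction = c("midpoint", "exclude")) {
  correction <- match.arg(correction)
  rows <- lapply(traces, function(tr) {
    m <- analyzeTrace(tr, correction = correction)
    data.frame(
      animal_id = animalId(m), region = region(m),
      n_nuclei = length(positions(tr)),
      median_distance_um = m@medianDistance,
      lower_threshold_um = m@lowerThreshold,
      upper_threshold_um = m@upperThreshold,
      binucleate_fraction = binucleateFraction(m),
      dropout_fraction = dropoutFraction(m),
      mean_corrected_distance_um = m@meanCorrectedDistance,
      cell_area_um2 = cellArea(m),
      cell_area_from_mean_um2 = cellArea(m, "fromMeanDistance"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
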