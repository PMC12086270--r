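#' Accessors for streakmorph S4 objects
#'
#' Small accessor generics: nucleus `positions()` and `segmentLength()`
#' of an [RPETrace-class]; `animalId()` and `region()` provenance labels;
#' `rawDistances()`, `correctedDistances()`, `gapClassifications()`,
#' `binucleateFraction()`, `dropoutFraction()` and `cellArea()` of a
#' [MosaicResult-class]; `quantScale()` and `sampleGroups()` of a
#' [ProteinQuant-class].
#'
#' @param x an object of the respective class.
#' @param ... for `cellArea`, `estimator = c("perDistance",
#'   "fromMeanDistance")` selecting between the mean of per-distance
#'   hexagon areas and the hexagon area at the mean corrected distance.
#' @name accessors
#' @aliases positions segmentLength animalId region rawDistances
#'   correctedDistances gapClassifications binucleateFraction
#'   dropoutFraction cellArea quantScale sampleGroups
NULL

#' @rdname accessors
#' @export
setMethod("positions", "RPETrace", function(x) x@positions)

#' @rdname accessors
#' @export
setMethod("segmentLength", "RPETrace", function(x) x@segmentLength)

#' @rdname accessors
#' @export
setMethod("animalId", "RPETrace", function(x) x@animalId)

#' @rdname accessors
#' @export
setMethod("region", "RPETrace", function(x) x@region)

#' @rdname accessors
#' @export
setMethod("animalId", "MosaicResult", function(x) x@animalId)

#' @rdname accessors
#' @export
setMethod("region", "MosaicResult", function(x) x@region)

#' @rdname accessors
#' @export
setMethod("rawDistances", "MosaicResult", function(x) x@rawDistances)

#' @rdname accessors
#' @export
setMethod("correctedDistances", "MosaicResult",
          function(x) x@correctedDistances)

#' @rdname accessors
#' @export
setMethod("gapClassifications", "MosaicResult",
          function(x) x@classifications)

#' @rdname accessors
#' @export
setMethod("binucleateFraction", "MosaicResult",
          function(x) x@binucleateFraction)

#' @rdname accessors
#' @export
setMethod("dropoutFraction", "MosaicResult", function(x) x@dropoutFraction)

#' @rdname accessors
#' @export
setMethod("cellArea", "MosaicResult",
  function(x, estimator = c("perDistance", "fromMeanDistance")) {
    estimator <- match.arg(estimator)
    if (estimator == "perDistance") x@cellAreaMean
    else x@cellAreaFromMeanDistance
  })

#' @rdname accessors
#' @export
setMethod("quantScale", "ProteinQuant",
          function(x) S4Vectors::metadata(x)$scale)

#' @rdname accessors
#' @export
setMethod("sampleGroups", "ProteinQuant",
          function(x) SummarizedExperiment::colData(x)$group)

setMethod("show", "TruthParams", function(object) {
  cat("TruthParams for region", object@region, "\n")
  cat(sprintf("  cones/window %.3f | ONL rows %.3f (sd %.2f) | nucleus d %.2f um\n",
              object@coneRate, object@onlRows, object@onlRowsSd,
              object@nucleusDiameter))
  cat(sprintf("  OS length %.1f (sd %.1f) um | RPE height %.2f (sd %.1f) um\n",
              object@osLengthMean, object@osLengthSd,
              object@rpeHeightMean, object@rpeHeightSd))
  cat(sprintf("  RPE spacing %.2f um (cv %.2f) | binucleate %.1f%% (offset %.1f um) | dropout %.1f%%\n",
              object@rpeSpacingMean, object@rpeSpacingCv,
              100 * object@binucleateProb, object@binucleateOffset,
              100 * object@dropoutProb))
  cat(sprintf("  phagosomes/cell %.2f | %d animals x %d sections | seed %d\n",
              object@phagosomeRate, object@nAnimals, object@nSections,
              object@seed))
  invisible(object)
})

setMethod("show", "RPETrace", function(object) {
  cat(sprintf("RPETrace: %d nuclei over %.0f um (%s, %s)\n",
              length(object@positions), object@segmentLength,
              object@animalId, object@region))
  if (length(object@positions)) {
    p <- object@positions
    cat("  positions (um):", paste(signif(utils::head(p, 6), 4),
                                   collapse = ", "),
        if (length(p) > 6) "...", "\n")
  }
  invisible(object)
})

setMethod("show", "MosaicResult", function(object) {
  cat(sprintf("MosaicResult (%s, %s; correction = %s)\n",
              object@animalId, object@region, object@correction))
  cat(sprintf("  %d raw gaps, median %.2f um; thresholds [%.2f, %.2f] um\n",
              length(object@rawDistances), object@medianDistance,
              object@lowerThreshold, object@upperThreshold))
  tab <- table(factor(object@classifications,
                      levels = c("normal", "binucleate", "dropout")))
  cat(sprintf("  gaps: %d normal, %d binucleate, %d dropout\n",
              tab[["normal"]], tab[["binucleate"]], tab[["dropout"]]))
  cat(sprintf("  binucleate fraction %.1f%% (of nuclei), dropout fraction %.1f%%\n",
              100 * object@binucleateFraction, 100 * object@dropoutFraction))
  cat(sprintf("  mean corrected distance %.2f um; cell area %.1f um^2 (per-distance), %.1f um^2 (from mean D)\n",
              object@meanCorrectedDistance, object@cellAreaMean,
              object@cellAreaFromMeanDistance))
  invisible(object)
})
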