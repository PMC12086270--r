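#' @import methods
#' @importFrom stats median quantile sd var rnorm rpois rgamma rbinom runif
#'   pt pf aov shapiro.test t.test setNames complete.cases
NULL

#' Ground-truth simulation parameters for one eccentricity region
#'
#' `TruthParams` holds the generating parameters of the synthetic-section
#' model for a single retinal region (visual streak, near or far
#' periphery): the expected cone count per counting window, the outer
#' nuclear layer (ONL) stereology inputs, cone outer-segment (OS) length,
#' RPE internuclear spacing with binucleate/dropout artifact rates, the
#' phagosome load per RPE cell, and the sampling design (animals and
#' sections per animal).
#'
#' All rates and means are strictly positive, probabilities lie in
#' \[0, 1\], and the within-cell nucleus separation of a binucleate cell
#' (`binucleateOffset`) must be smaller than half the mean internuclear
#' spacing, so that planted binucleate gaps fall below the half-median
#' classification threshold by construction.
#'
#' @slot region single region label, e.g. `"VS"`, `"NP"`, `"FP"`.
#' @slot coneRate expected cones per 1,200 um^2 counting window.
#' @slot onlRows,onlRowsSd mean and per-section SD of the ONL row count.
#' @slot nucleusDiameter,nucleusDiameterSd ONL nucleus diameter (um).
#' @slot osLengthMean,osLengthSd cone OS length (um).
#' @slot rpeSpacingMean mean RPE internuclear spacing (um).
#' @slot rpeSpacingCv coefficient of variation of individual spacings.
#' @slot binucleateProb probability that an RPE cell is binucleate.
#' @slot dropoutProb probability that a nucleus is missing from a trace.
#' @slot binucleateOffset separation of the two nuclei of a binucleate
#'   cell (um).
#' @slot phagosomeRate expected phagosomes per RPE cell.
#' @slot rpeHeightMean,rpeHeightSd RPE height (um).
#' @slot nSections sections per animal per region.
#' @slot nAnimals number of animals.
#' @slot seed integer seed used when none is supplied to a generator.
#'
#' @seealso [truthParams()], [gerbilTruthDefaults()]
#' @export
setClass("TruthParams",
  representation(
    region            = "character",
    coneRate          = "numeric",
    onlRows           = "numeric",
    onlRowsSd         = "numeric",
    nucleusDiameter   = "numeric",
    nucleusDiameterSd = "numeric",
    osLengthMean      = "numeric",
    osLengthSd        = "numeric",
    rpeSpacingMean    = "numeric",
    rpeSpacingCv      = "numeric",
    binucleateProb    = "numeric",
    dropoutProb       = "numeric",
    binucleateOffset  = "numeric",
    phagosomeRate     = "numeric",
    rpeHeightMean     = "numeric",
    rpeHeightSd       = "numeric",
    nSections         = "integer",
    nAnimals          = "integer",
    seed              = "integer"
  )
)

setValidity("TruthParams", function(object) {
  msg <- character()
  pos <- c(
    coneRate = object@coneRate, onlRows = object@onlRows,
    nucleusDiameter = object@nucleusDiameter,
    osLengthMean = object@osLengthMean,
    rpeSpacingMean = object@rpeSpacingMean,
    binucleateOffset = object@binucleateOffset,
    phagosomeRate = object@phagosomeRate,
    rpeHeightMean = object@rpeHeightMean
  )
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    msg <- c(msg, paste0("strictly positive value required for: ",
                         paste(bad, collapse = ", ")))
  nn <- c(
    onlRowsSd = object@onlRowsSd, nucleusDiameterSd = object@nucleusDiameterSd,
    osLengthSd = object@osLengthSd, rpeSpacingCv = object@rpeSpacingCv,
    rpeHeightSd = object@rpeHeightSd
  )
  badnn <- names(nn)[!is.finite(nn) | nn < 0]
  if (length(badnn))
    msg <- c(msg, paste0("non-negative value required for: ",
                         paste(badnn, collapse = ", ")))
  pr <- c(binucleateProb = object@binucleateProb,
          dropoutProb = object@dropoutProb)
  badpr <- names(pr)[!is.finite(pr) | pr < 0 | pr > 1]
  if (length(badpr))
    msg <- c(msg, paste0("probability in [0, 1] required for: ",
                         paste(badpr, collapse = ", ")))
  if (is.finite(object@binucleateOffset) &&
      is.finite(object@rpeSpacingMean) &&
      object@binucleateOffset >= object@rpeSpacingMean / 2)
    msg <- c(msg, "binucleateOffset must be < rpeSpacingMean / 2")
  if (object@nSections < 1L) msg <- c(msg, "nSections must be >= 1")
  if (object@nAnimals < 1L) msg <- c(msg, "nAnimals must be >= 1")
  if (length(object@region) != 1L || is.na(object@region) ||
      !nzchar(object@region))
    msg <- c(msg, "region must be a single non-empty label")
  if (length(msg)) msg else TRUE
})

#' One-dimensional trace of RPE nucleus positions
#'
#' An `RPETrace` stores the ordered x-coordinates (um) of RPE nucleus
#' centers along a dorsoventral retinal segment, together with the animal
#' and region it came from. Positions are strictly increasing and lie in
#' the half-open interval \[0, segmentLength).
#'
#' @slot animalId animal label.
#' @slot region region label.
#' @slot segmentLength segment length in um (250 um in the standard
#'   sampling design).
#' @slot positions strictly increasing nucleus x-coordinates (um).
#'
#' @seealso [rpeTrace()], [analyzeTrace()], [internuclearDistances()]
#' @export
setClass("RPETrace",
  representation(
    animalId      = "character",
    region        = "character",
    segmentLength = "numeric",
    positions     = "numeric"
  )
)

setValidity("RPETrace", function(object) {
  msg <- character()
  if (length(object@segmentLength) != 1L || !is.finite(object@segmentLength) ||
      object@segmentLength <= 0)
    msg <- c(msg, "segmentLength must be a single positive number")
  p <- object@positions
  if (anyNA(p)) msg <- c(msg, "positions must not contain NA")
  else {
    if (length(p) && (any(p < 0) || any(p >= object@segmentLength)))
      msg <- c(msg, "positions must lie in [0, segmentLength)")
    if (length(p) > 1L && any(diff(p) <= 0))
      msg <- c(msg, "positions must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Result of the RPE mosaic analysis of one trace
#'
#' `MosaicResult` bundles everything the median-threshold artifact filter
#' and the hexagon cell-area model derive from a single [RPETrace]: the
#' raw internuclear distances, the classification thresholds (half and
#' twice the raw median), the per-gap labels, the artifact-corrected
#' nucleus positions and distances, binucleate/dropout bookkeeping, and
#' the regular-hexagon cell geometry (side, apothem/height, area).
#'
#' Two cell-area estimators are kept: the mean of per-distance areas and
#' the area of the hexagon whose internuclear distance is the mean
#' corrected distance.
#'
#' @slot animalId,region provenance labels copied from the trace.
#' @slot rawDistances raw consecutive internuclear distances (um).
#' @slot medianDistance median of the raw distances (um).
#' @slot lowerThreshold,upperThreshold medianDistance / 2 and
#'   2 * medianDistance (um).
#' @slot classifications per-gap label: `"normal"`, `"binucleate"` or
#'   `"dropout"`.
#' @slot correctedPositions nucleus positions after midpoint-merging
#'   binucleate pairs (um).
#' @slot correctedDistances distances between corrected positions,
#'   dropout gaps excluded (um).
#' @slot binucleateFraction flagged binucleate cells / raw nucleus count
#'   (the convention in which 64 flagged cells among 454 nuclei reads 14%).
#' @slot binucleateCellFraction flagged binucleate cells / corrected cell
#'   count; the direct estimator of the per-cell binucleate probability.
#' @slot dropoutFraction dropout gaps / raw gap count.
#' @slot chainEvents number of consecutive-binucleate chains resolved
#'   greedily left to right.
#' @slot cellAreaMean mean over corrected distances of the per-distance
#'   hexagon area (um^2).
#' @slot cellAreaFromMeanDistance hexagon area at the mean corrected
#'   distance (um^2).
#' @slot meanCorrectedDistance mean corrected internuclear distance (um).
#' @slot hexagonSide,hexagonHeight side a = D / sqrt(3) and half-distance
#'   h = D / 2 at the mean corrected distance (um).
#' @slot correction `"midpoint"` or `"exclude"` (see [analyzeTrace()]).
#'
#' @seealso [analyzeTrace()], [hexagonArea()]
#' @export
setClass("MosaicResult",
  representation(
    animalId                 = "character",
    region                   = "character",
    rawDistances             = "numeric",
    medianDistance           = "numeric",
    lowerThreshold           = "numeric",
    upperThreshold           = "numeric",
    classifications          = "character",
    correctedPositions       = "numeric",
    correctedDistances       = "numeric",
    binucleateFraction       = "numeric",
    binucleateCellFraction   = "numeric",
    dropoutFraction          = "numeric",
    chainEvents              = "integer",
    cellAreaMean             = "numeric",
    cellAreaFromMeanDistance = "numeric",
    meanCorrectedDistance    = "numeric",
    hexagonSide              = "numeric",
    hexagonHeight            = "numeric",
    correction               = "character"
  )
)

setValidity("MosaicResult", function(object) {
  msg <- character()
  if (length(object@medianDistance) == 1L && is.finite(object@medianDistance)) {
    if (!isTRUE(all.equal(object@lowerThreshold, object@medianDistance / 2)))
      msg <- c(msg, "lowerThreshold must equal medianDistance / 2")
    if (!isTRUE(all.equal(object@upperThreshold, object@medianDistance * 2)))
      msg <- c(msg, "upperThreshold must equal 2 * medianDistance")
  }
  if (!all(object@classifications %in% c("normal", "binucleate", "dropout")))
    msg <- c(msg, "classifications must be normal/binucleate/dropout")
  if (length(msg)) msg else TRUE
})

#' Protein quantification matrix with group labels
#'
#' `ProteinQuant` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' for a proteins x samples intensity matrix. The single assay
#' `"intensity"` holds raw (linear-scale, strictly positive) or
#' log2-transformed intensities with `NA` for missing quantifications;
#' `colData()$group` assigns every sample to exactly one biological
#' group; `metadata()$scale` records whether the assay is `"raw"` or
#' `"log2"`. Planted ground-truth effects of the synthetic generator, if
#' any, live in `metadata()$truth`.
#'
#' @seealso [proteinQuant()], [log2Transform()], [permutationFdrTtest()]
#' @export
#' @import SummarizedExperiment
setClass("ProteinQuant", contains = "SummarizedExperiment")

setValidity("ProteinQuant", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "unique protein ids (rownames) are required")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "unique sample ids (colnames) are required")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd) || anyNA(cd$group))
    msg <- c(msg, "colData()$group must assign every sample to a group")
  sc <- S4Vectors::metadata(object)$scale
  if (is.null(sc) || !sc %in% c("raw", "log2"))
    msg <- c(msg, "metadata()$scale must be 'raw' or 'log2'")
  # positivity of raw intensities is enforced (cell by cell, with a
  # useful message) by log2Transform(), not here
  if (length(msg)) msg else TRUE
})
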