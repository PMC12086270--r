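#' Construct a TruthParams object
#'
#' Builds and validates the ground-truth parameter set of the synthetic
#' generator for one region. See [TruthParams-class] for the meaning and
#' units of every field; see [gerbilTruthDefaults()] for a complete
#' parameter set anchored to measured gerbil retina values.
#'
#' @param region region label (e.g. `"VS"`, `"NP"`, `"FP"`).
#' @param coneRate expected cones per 1,200 um^2 window.
#' @param onlRows,onlRowsSd ONL row count mean and per-section SD.
#' @param nucleusDiameter,nucleusDiameterSd ONL nucleus diameter (um).
#' @param osLengthMean,osLengthSd cone outer-segment length (um).
#' @param rpeSpacingMean mean RPE internuclear spacing (um).
#' @param rpeSpacingCv CV of individual internuclear spacings.
#' @param binucleateProb per-cell binucleate probability.
#' @param dropoutProb per-nucleus dropout probability.
#' @param binucleateOffset within-cell nucleus separation (um); must be
#'   below `rpeSpacingMean / 2`.
#' @param phagosomeRate expected phagosomes per RPE cell.
#' @param rpeHeightMean,rpeHeightSd RPE height (um).
#' @param nSections sections per animal.
#' @param nAnimals number of animals.
#' @param seed default integer seed for the generators.
#'
#' @return a validated [TruthParams-class] object.
#' @examples
#' vs <- truthParams("VS", coneRate = 60.792)
#' vs
#' @export
truthParams <- function(region,
                        coneRate = 60.792,
                        onlRows = 8.625, onlRowsSd = 0.6,
                        nucleusDiameter = 5, nucleusDiameterSd = 0.25,
                        osLengthMean = 20, osLengthSd = 2,
                        rpeSpacingMean = 19.16, rpeSpacingCv = 0.2,
                        binucleateProb = 0.14, dropoutProb = 0.04,
                        binucleateOffset = 3,
                        phagosomeRate = 4.18,
                        rpeHeightMean = 12.08, rpeHeightSd = 2,
                        nSections = 4L, nAnimals = 5L, seed = 1L) {
  new("TruthParams",
      region = as.character(region),
      coneRate = as.numeric(coneRate),
      onlRows = as.numeric(onlRows), onlRowsSd = as.numeric(onlRowsSd),
      nucleusDiameter = as.numeric(nucleusDiameter),
      nucleusDiameterSd = as.numeric(nucleusDiameterSd),
      osLengthMean = as.numeric(osLengthMean),
      osLengthSd = as.numeric(osLengthSd),
      rpeSpacingMean = as.numeric(rpeSpacingMean),
      rpeSpacingCv = as.numeric(rpeSpacingCv),
      binucleateProb = as.numeric(binucleateProb),
      dropoutProb = as.numeric(dropoutProb),
      binucleateOffset = as.numeric(binucleateOffset),
      phagosomeRate = as.numeric(phagosomeRate),
      rpeHeightMean = as.numeric(rpeHeightMean),
      rpeHeightSd = as.numeric(rpeHeightSd),
      nSections = as.integer(nSections),
      nAnimals = as.integer(nAnimals),
      seed = as.integer(seed))
}

#' Region-wise ground truth anchored to the measured gerbil retina
#'
#' Returns the default three-region parameter set of the synthetic
#' generator. Cone rates are the measured regional densities converted
#' to expected counts per 1,200 um^2 window (density / 1e6 * 1200); ONL
#' row counts are chosen so that, with a 5 um nucleus diameter, the
#' stereological rod densities equal the measured regional values
#' (rows = rod density * d^2 / 1e6). RPE spacing means, binucleate and
#' dropout rates, heights, and the visual-streak : periphery phagosome
#' ratio are likewise anchored to the measured values; quantities the
#' measurements do not pin down (per-gap spacing CV, OS lengths, the
#' absolute phagosome rate) are fixed at realistic values discussed in
#' the package vignette.
#'
#' @param nSections sections per animal per region.
#' @param nAnimals number of animals.
#' @param seed default integer seed.
#' @return named list of [TruthParams-class], one per region
#'   (`VS`, `NP`, `FP`).
#' @examples
#' truth <- gerbilTruthDefaults()
#' truth$VS
#' @export
gerbilTruthDefaults <- function(nSections = 4L, nAnimals = 5L, seed = 1L) {
  list(
    VS = truthParams("VS",
      coneRate = 50660 * 1200 / 1e6,       # 60.792 cones / window
      onlRows = 345014 * 25 / 1e6,         # 8.6254 rows
      osLengthMean = 20, osLengthSd = 2,
      rpeSpacingMean = 19.16, binucleateProb = 0.14, dropoutProb = 0.04,
      phagosomeRate = 3.0 * 1.393,         # +39.3% over periphery
      rpeHeightMean = 12.08, rpeHeightSd = 2,
      nSections = nSections, nAnimals = nAnimals, seed = seed),
    NP = truthParams("NP",
      coneRate = 37743 * 1200 / 1e6,
      onlRows = 339391 * 25 / 1e6,
      osLengthMean = 14, osLengthSd = 1.5,
      rpeSpacingMean = 21.0, binucleateProb = 0.12, dropoutProb = 0.045,
      phagosomeRate = 3.5,
      rpeHeightMean = 9.5, rpeHeightSd = 2,
      nSections = nSections, nAnimals = nAnimals, seed = seed),
    FP = truthParams("FP",
      coneRate = 28476 * 1200 / 1e6,
      onlRows = 312946 * 25 / 1e6,
      osLengthMean = 10, osLengthSd = 1.5,
      rpeSpacingMean = 22.59, binucleateProb = 0.10, dropoutProb = 0.05,
      phagosomeRate = 3.0,
      rpeHeightMean = 7.0, rpeHeightSd = 2,
      nSections = nSections, nAnimals = nAnimals, seed = seed)
  )
}

#' Construct an RPETrace
#'
#' @param positions strictly increasing nucleus x-coordinates (um) in
#'   \[0, segmentLength).
#' @param segmentLength segment length (um); the standard sampling design
#'   uses 250 um dorsoventral segments.
#' @param animalId,region provenance labels.
#' @return a validated [RPETrace-class] object.
#' @examples
#' tr <- rpeTrace(c(10, 30, 50, 80), segmentLength = 250)
#' internuclearDistances(tr)
#' @export
rpeTrace <- function(positions, segmentLength = 250,
                     animalId = "A1", region = "VS") {
  new("RPETrace",
      animalId = as.character(animalId),
      region = as.character(region),
      segmentLength = as.numeric(segmentLength),
      positions = as.numeric(positions))
}

#' Construct a ProteinQuant object
#'
#' @param intensities numeric matrix, proteins x samples; rownames are
#'   protein ids, colnames sample ids; `NA` marks missing values. Raw
#'   intensities must be strictly positive where present.
#' @param groups group label per sample (length `ncol(intensities)`), or
#'   a named vector matched to the column names.
#' @param scale `"raw"` or `"log2"`.
#' @param truth optional data.frame of planted effects
#'   (`protein_id`, `log2fc`, `group`), kept in `metadata()$truth`.
#' @return a [ProteinQuant-class] object.
#' @examples
#' m <- matrix(2^rnorm(12, 20), 3, 4,
#'             dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
#' pq <- proteinQuant(m, groups = c("VS", "VS", "periphery", "periphery"))
#' quantScale(pq)
#' @export
proteinQuant <- function(intensities, groups, scale = c("raw", "log2"),
                         truth = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("intensities must be a numeric matrix")
  if (is.null(rownames(intensities)))
    rownames(intensities) <- paste0("protein_", seq_len(nrow(intensities)))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- paste0("sample_", seq_len(ncol(intensities)))
  if (!is.null(names(groups)))
    groups <- groups[colnames(intensities)]
  if (length(groups) != ncol(intensities))
    stop("need one group label per sample")
  groups <- factor(groups)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensities),
    colData = S4Vectors::DataFrame(group = groups,
                                   row.names = colnames(intensities))
  )
  S4Vectors::metadata(se)$scale <- scale
  if (!is.null(truth)) S4Vectors::metadata(se)$truth <- truth
  new("ProteinQuant", se)
}
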