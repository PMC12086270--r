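# Draws from a normal truncated at zero via the probability-integral
# transform, so the number of RNG calls per draw is fixed (determinism
# of downstream draws does not depend on rejection counts).
.rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  mean + sd * stats::qnorm(lo + (1 - lo) * stats::runif(n))
}

.assertSeed <- function(seed) {
  if (is.null(seed) || !is.finite(seed))
    stop("an explicit integer seed is required")
  as.integer(seed)
}

#' Simulate per-section counting-window annotations
#'
#' Generates the table a manual count of stained cryosections produces:
#' for every animal, region and section, one 100 um x 12 um counting
#' window with a Poisson cone count, truncated-Gaussian ONL row count,
#' nucleus diameter, outer-segment length and RPE height, a Poisson RPE
#' cell count (expected `width / rpeSpacingMean` cells, at least one),
#' and a Poisson phagosome count with mean `phagosomeRate` per RPE cell.
#'
#' @param truth a [TruthParams-class] object or a (possibly named) list
#'   of them, one per region.
#' @param seed integer seed; defaults to the `seed` field of the first
#'   `TruthParams`.
#' @param width,thickness window geometry in um.
#' @return a `data.frame` of section records with columns `animal_id`,
#'   `region`, `section`, `width_um`, `thickness_um`, `cone_count`,
#'   `onl_rows`, `nucleus_diameter_um`, `os_length_um`, `rpe_height_um`,
#'   `phagosome_count`, `rpe_cell_count`.
#' @examples
#' sec <- simulateSections(gerbilTruthDefaults(), seed = 7)
#' head(sec)
#' @export
simulateSections <- function(truth, seed = NULL, width = 100, thickness = 12) {
  if (is(truth, "TruthParams")) truth <- list(truth)
  stopifnot(all(vapply(truth, is, logical(1), "TruthParams")))
  if (is.null(seed)) seed <- truth[[1]]@seed
  seed <- .assertSeed(seed)
  withr::with_seed(seed, {
    out <- lapply(truth, function(p) {
      validObject(p)
      n <- p@nAnimals * p@nSections
      cells <- pmax(1L, stats::rpois(n, width / p@rpeSpacingMean))
      data.frame(
        animal_id = rep(paste0("A", seq_len(p@nAnimals)),
                        each = p@nSections),
        region = p@region,
        section = rep(seq_len(p@nSections), times = p@nAnimals),
        width_um = width,
        thickness_um = thickness,
        cone_count = stats::rpois(n, p@coneRate * width * thickness / 1200),
        onl_rows = .rtruncnorm0(n, p@onlRows, p@onlRowsSd),
        nucleus_diameter_um = .rtruncnorm0(n, p@nucleusDiameter,
                                           p@nucleusDiameterSd),
        os_length_um = .rtruncnorm0(n, p@osLengthMean, p@osLengthSd),
        rpe_height_um = .rtruncnorm0(n, p@rpeHeightMean, p@rpeHeightSd),
        rpe_cell_count = cells,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, out)
    out$phagosome_count <- stats::rpois(
      nrow(out),
      out$rpe_cell_count *
        rep(vapply(truth, slot, numeric(1), "phagosomeRate"),
            vapply(truth, function(p) p@nAnimals * p@nSections, integer(1)))
    )
    rownames(out) <- NULL
    out
  })
}

#' Simulate a 1-D RPE nucleus trace with planted artifacts
#'
#' Emulates the measurement of RPE nucleus centers along a dorsoventral
#' segment. Cell centers are laid down with Gamma-distributed spacings of
#' the requested mean and CV (a Gamma keeps spacings positive with mild
#' right skew); each cell is independently binucleate with probability
#' `binucleateProb`, in which case its two nuclei sit at the center
#' +/- `binucleateOffset / 2`; each nucleus is then independently dropped
#' with probability `dropoutProb`. Ground-truth per-nucleus labels are
#' returned alongside the trace so classifier recovery can be scored.
#'
#' @param params a [TruthParams-class] object.
#' @param segmentLength segment length in um (default 250, the standard
#'   sampling design); must exceed `rpeSpacingMean`.
#' @param seed integer seed; defaults to `params@seed`.
#' @param animalId,region provenance labels for the trace (region
#'   defaults to `params@region`).
#' @return a list with elements `trace` (an [RPETrace-class] of the
#'   retained nuclei), `truth` (data.frame with one row per *generated*
#'   nucleus: `position`, `cell`, `role` in `single|binucleate_1|
#'   binucleate_2`, `dropped`), `nCells`, `nBinucleate`, `nDropped`, and
#'   `empty` (TRUE when every nucleus dropped out).
#' @examples
#' p <- truthParams("VS", rpeSpacingMean = 20, rpeSpacingCv = 0,
#'                  binucleateProb = 0, dropoutProb = 0)
#' sim <- simulateRpeTrace(p, segmentLength = 250, seed = 1)
#' positions(sim$trace)
#' @export
simulateRpeTrace <- function(params, segmentLength = 250, seed = NULL,
                             animalId = "A1", region = params@region) {
  stopifnot(is(params, "TruthParams"))
  validObject(params)
  if (!is.finite(segmentLength) || segmentLength <= 0)
    stop("segmentLength must be positive")
  if (params@rpeSpacingMean >= segmentLength)
    stop("rpeSpacingMean must be smaller than segmentLength")
  if (is.null(seed)) seed <- params@seed
  seed <- .assertSeed(seed)

  withr::with_seed(seed, {
    mu <- params@rpeSpacingMean
    cv <- params@rpeSpacingCv
    # cell centers: first at half a spacing from the segment edge
    nMax <- ceiling(segmentLength / mu * 1.5) + 25L
    gaps <- if (cv == 0) rep(mu, nMax)
            else stats::rgamma(nMax, shape = 1 / cv^2, scale = mu * cv^2)
    centers <- cumsum(gaps) - gaps[1] / 2
    while (centers[length(centers)] < segmentLength) {  # rarely needed
      more <- if (cv == 0) rep(mu, 25L)
              else stats::rgamma(25L, shape = 1 / cv^2, scale = mu * cv^2)
      centers <- c(centers, centers[length(centers)] + cumsum(more))
    }
    centers <- centers[centers < segmentLength]
    nCells <- length(centers)
    binu <- stats::runif(nCells) < params@binucleateProb

    pos <- vector("list", nCells)
    cellIdx <- role <- vector("list", nCells)
    for (i in seq_len(nCells)) {
      if (binu[i]) {
        pos[[i]] <- centers[i] + c(-0.5, 0.5) * params@binucleateOffset
        role[[i]] <- c("binucleate_1", "binucleate_2")
        cellIdx[[i]] <- c(i, i)
      } else {
        pos[[i]] <- centers[i]
        role[[i]] <- "single"
        cellIdx[[i]] <- i
      }
    }
    truth <- data.frame(
      position = unlist(pos), cell = unlist(cellIdx),
      role = unlist(role), stringsAsFactors = FALSE
    )
    truth$dropped <- stats::runif(nrow(truth)) < params@dropoutProb
    # nuclei pushed outside the half-open segment by the binucleate
    # offset are unobservable, like any off-section nucleus
    truth$dropped <- truth$dropped |
      truth$position < 0 | truth$position >= segmentLength

    kept <- truth$position[!truth$dropped]
    kept <- sort(kept)
    trace <- rpeTrace(kept, segmentLength = segmentLength,
                      animalId = animalId, region = region)
    list(trace = trace, truth = truth,
         nCells = nCells, nBinucleate = sum(binu),
         nDropped = sum(truth$dropped),
         empty = length(kept) == 0L)
  })
}

#' Simulate RPE traces for a whole sampling design
#'
#' One trace per animal and section for each region in `truth`.
#'
#' @param truth list of [TruthParams-class] (one per region).
#' @param segmentLength segment length in um.
#' @param seed integer seed.
#' @return list with `traces` (list of [RPETrace-class]) and `truth`
#'   (data.frame of per-trace generated cell/binucleate/dropout counts).
#' @export
simulateTraces <- function(truth, segmentLength = 250, seed = NULL) {
  if (is(truth, "TruthParams")) truth <- list(truth)
  if (is.null(seed)) seed <- truth[[1]]@seed
  seed <- .assertSeed(seed)
  traces <- list()
  rows <- list()
  k <- 0L
  for (p in truth) {
    for (a in seq_len(p@nAnimals)) {
      for (s in seq_len(p@nSections)) {
        k <- k + 1L
        sim <- simulateRpeTrace(p, segmentLength = segmentLength,
                                seed = seed + k,
                                animalId = paste0("A", a))
        traces[[k]] <- sim$trace
        rows[[k]] <- data.frame(
          animal_id = paste0("A", a), region = p@region, section = s,
          n_cells = sim$nCells, n_binucleate = sim$nBinucleate,
          n_dropped = sim$nDropped, stringsAsFactors = FALSE)
      }
    }
  }
  list(traces = traces, truth = do.call(rbind, rows))
}

#' Simulate a protein-quantification matrix with planted effects
#'
#' Draws log-normal intensities: each protein has a baseline log2
#' abundance from N(`baselineMean`, `baselineSd`), samples scatter around
#' it with SD `noiseSd` on the log2 scale, planted proteins are shifted
#' by their log2 fold-change in the samples of `effectGroup`, and each
#' cell is then independently set to missing with probability
#' `missingProb`. The returned object is on the raw (linear) scale, as a
#' quantification engine would report it.
#'
#' @param nProteins number of proteins (rows).
#' @param groups named integer vector of replicate counts per group,
#'   e.g. `c(VS = 3, periphery = 3)`; at least 2 replicates per group.
#' @param plantedEffects data.frame with columns `index` (row index) and
#'   `log2fc`, or NULL for a null matrix.
#' @param effectGroup group receiving the planted shifts (default: first
#'   group).
#' @param missingProb per-cell missingness probability.
#' @param baselineMean,baselineSd,noiseSd log2-scale distribution
#'   parameters.
#' @param seed integer seed.
#' @return a [ProteinQuant-class] with `metadata()$truth` recording the
#'   planted effects (empty data.frame for a null matrix).
#' @examples
#' pq <- simulateProteinMatrix(200, c(VS = 3, periphery = 3),
#'                             plantedEffects = data.frame(index = 1:5,
#'                                                         log2fc = 2),
#'                             seed = 11)
#' S4Vectors::metadata(pq)$truth
#' @export
simulateProteinMatrix <- function(nProteins, groups,
                                  plantedEffects = NULL,
                                  effectGroup = names(groups)[1],
                                  missingProb = 0,
                                  baselineMean = 20, baselineSd = 2,
                                  noiseSd = 0.3, seed = NULL) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named vector of replicate counts")
  if (any(groups < 2)) stop("at least 2 replicates per group are required")
  if (missingProb < 0 || missingProb > 1)
    stop("missingProb must be in [0, 1]")
  seed <- .assertSeed(if (is.null(seed)) 1L else seed)
  if (!is.null(plantedEffects) && nrow(plantedEffects)) {
    if (!all(c("index", "log2fc") %in% names(plantedEffects)))
      stop("plantedEffects needs columns 'index' and 'log2fc'")
    if (any(plantedEffects$index < 1 | plantedEffects$index > nProteins))
      stop("plantedEffects index out of range")
    if (!effectGroup %in% names(groups))
      stop("effectGroup must be one of the group names")
  }
  nSamples <- sum(groups)
  groupOf <- rep(names(groups), times = groups)
  withr::with_seed(seed, {
    base <- stats::rnorm(nProteins, baselineMean, baselineSd)
    l2 <- matrix(stats::rnorm(nProteins * nSamples, 0, noiseSd),
                 nProteins, nSamples) + base
    if (!is.null(plantedEffects) && nrow(plantedEffects)) {
      cols <- which(groupOf == effectGroup)
      l2[plantedEffects$index, cols] <-
        l2[plantedEffects$index, cols] + plantedEffects$log2fc
    }
    raw <- 2^l2
    if (missingProb > 0)
      raw[stats::runif(length(raw)) < missingProb] <- NA_real_
    dimnames(raw) <- list(
      sprintf("protein_%04d", seq_len(nProteins)),
      paste0(groupOf, "_", unlist(lapply(groups, seq_len)))
    )
    truth <- if (is.null(plantedEffects) || !nrow(plantedEffects)) {
      data.frame(protein_id = character(), index = integer(),
                 log2fc = numeric(), group = character(),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(protein_id = rownames(raw)[plantedEffects$index],
                 index = plantedEffects$index,
                 log2fc = plantedEffects$log2fc,
                 group = effectGroup, stringsAsFactors = FALSE)
    }
    proteinQuant(raw, groups = groupOf, scale = "raw", truth = truth)
  })
}

#' Simulate a complete synthetic study
#'
#' Bundles [simulateSections()], [simulateTraces()] and
#' [simulateProteinMatrix()] under one seed: the annotation tables, RPE
#' traces and protein matrix of one synthetic study with known ground
#' truth.
#'
#' @param truth list of [TruthParams-class]; defaults to
#'   [gerbilTruthDefaults()].
#' @param seed integer seed.
#' @param nProteins,proteinGroups,plantedEffects,missingProb passed to
#'   [simulateProteinMatrix()]; the default plants 50 up-regulated
#'   proteins at log2 fold-change 2 in the first group.
#' @param segmentLength RPE segment length (um).
#' @return list with `sections`, `traces`, `traceTruth`,
#'   `proteinMatrix`, `truth`, `seed`.
#' @examples
#' b <- simulateBundle(seed = 3, nProteins = 100)
#' names(b)
#' @export
simulateBundle <- function(truth = gerbilTruthDefaults(), seed = 1L,
                           nProteins = 2000,
                           proteinGroups = c(VS = 3, periphery = 3),
                           plantedEffects = data.frame(index = 1:50,
                                                       log2fc = 2),
                           missingProb = 0.05,
                           segmentLength = 250) {
  seed <- .assertSeed(seed)
  sections <- simulateSections(truth, seed = seed)
  tr <- simulateTraces(truth, segmentLength = segmentLength,
                       seed = seed + 10000L)
  pm <- simulateProteinMatrix(nProteins, proteinGroups,
                              plantedEffects = plantedEffects,
                              missingProb = missingProb,
                              seed = seed + 20000L)
  list(sections = sections, traces = tr$traces, traceTruth = tr$truth,
       proteinMatrix = pm, truth = truth, seed = seed)
}
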