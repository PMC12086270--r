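#' Run configuration for the end-to-end pipeline
#'
#' Collects paths, geometry and options; defaults mirror the standard
#' sampling design (100 um x 12 um counting windows, 250 um RPE
#' segments). Configurations can be loaded from a YAML file with
#' [readRunConfig()].
#'
#' @param sections,traces,proteins,proteinGroups input file paths
#'   (NULL to skip a stage).
#' @param outDir output directory.
#' @param regions region labels in eccentricity order (center first).
#' @param width,thickness counting-window geometry (um).
#' @param segmentLength RPE segment length (um).
#' @param metrics section metrics to summarize and test.
#' @param referenceRegion region used as the reference of relative
#'   increases (default: last of `regions`).
#' @param nPermutations,fdrThreshold proteomics options.
#' @param seed integer seed recorded in every output.
#' @return a list of class `"RunConfig"`.
#' @export
runConfig <- function(sections = NULL, traces = NULL, proteins = NULL,
                      proteinGroups = NULL, outDir = ".",
                      regions = c("VS", "NP", "FP"),
                      width = 100, thickness = 12, segmentLength = 250,
                      metrics = c("cone_density", "rod_density", "rcr",
                                  "os_length_um", "rpe_height_um",
                                  "phagosomes_per_cell"),
                      referenceRegion = regions[length(regions)],
                      nPermutations = 250, fdrThreshold = 0.05,
                      seed = 1L) {
  stopifnot(width > 0, thickness > 0, segmentLength > 0)
  for (p in c(sections, traces, proteins, proteinGroups))
    if (!is.null(p) && !file.exists(p)) stop("path not resolvable: ", p)
  structure(list(
    sections = sections, traces = traces, proteins = proteins,
    proteinGroups = proteinGroups, outDir = outDir, regions = regions,
    width = width, thickness = thickness, segmentLength = segmentLength,
    metrics = metrics, referenceRegion = referenceRegion,
    nPermutations = nPermutations, fdrThreshold = fdrThreshold,
    seed = .assertSeed(seed)), class = "RunConfig")
}

#' @describeIn runConfig load a configuration from a YAML file; keys
#'   match the arguments of `runConfig()`, relative paths are resolved
#'   against the file's directory.
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("sections", "traces", "proteins", "proteinGroups", "outDir"))
    if (!is.null(y[[k]]) && !grepl("^/", y[[k]]))
      y[[k]] <- file.path(base, y[[k]])
  do.call(runConfig, y)
}

.stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages on the configured inputs: density and region
#' summaries from the section table, mosaic analysis of the RPE traces,
#' the group-statistics battery, and the proteomics differential
#' abundance step. Writes `densities.tsv`, `summary.json`,
#' `mosaic.tsv`, `mosaic_summary.json`, `stats.tsv`,
#' `diff_results.tsv`, and a `manifest.json` recording the seed, options
#' and an MD5 checksum of every output. Deterministic given the seed;
#' any stage error aborts with the stage name.
#'
#' @param config a [runConfig()].
#' @return (invisibly) a list with the in-memory results and the
#'   manifest.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' b <- simulateBundle(seed = 1, nProteins = 50)
#' writeSections(b$sections, file.path(dir, "sections.tsv"))
#' cfg <- runConfig(sections = file.path(dir, "sections.tsv"),
#'                  outDir = dir, seed = 1)
#' res <- runPipeline(cfg)
#' names(res)
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  results <- list()

  if (!is.null(config$sections)) {
    sec <- .stageTry("densities", {
      s <- readSections(config$sections)
      unknown <- setdiff(unique(s$region), config$regions)
      if (length(unknown))
        stop("unknown region label(s): ", paste(unknown, collapse = ", "))
      s
    })
    dens <- .stageTry("densities", densityReport(sec))
    f <- file.path(config$outDir, "densities.tsv")
    .writeDelim(dens, f); outputs <- c(outputs, f)
    summaries <- .stageTry("summaries", {
      lst <- lapply(config$metrics, function(m) regionSummary(sec, m))
      do.call(rbind, lst)
    })
    ref <- config$referenceRegion
    increases <- .stageTry("summaries", {
      do.call(rbind, lapply(split(summaries, summaries$metric),
        function(d) {
          refRow <- d[d$region == ref, ]
          if (!nrow(refRow)) return(NULL)
          data.frame(metric = d$metric, region = d$region,
                     relative_increase_pct =
                       relativeIncrease(d$mean, refRow$mean),
                     stringsAsFactors = FALSE)
        }))
    })
    f <- file.path(config$outDir, "summary.json")
    jsonlite::write_json(
      list(seed = config$seed, summaries = summaries,
           relative_increases = increases),
      f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- c(outputs, f)
    stats <- .stageTry("stats",
      metricStats(sec, config$metrics,
                  regions = intersect(config$regions,
                                      unique(sec$region))))
    f <- file.path(config$outDir, "stats.tsv")
    .writeDelim(stats, f); outputs <- c(outputs, f)
    results$densities <- dens
    results$summaries <- summaries
    results$increases <- increases
    results$stats <- stats
  }

  if (!is.null(config$traces)) {
    mos <- .stageTry("mosaic", {
      traces <- readTraces(config$traces)
      mosaicReport(traces)
    })
    f <- file.path(config$outDir, "mosaic.tsv")
    .writeDelim(mos, f); outputs <- c(outputs, f)
    mosSummary <- .stageTry("mosaic", {
      lapply(split(mos, mos$region), function(d) list(
        n_traces = nrow(d),
        mean_corrected_distance_um = mean(d$mean_corrected_distance_um,
                                          na.rm = TRUE),
        mean_cell_area_um2 = mean(d$cell_area_um2, na.rm = TRUE),
        binucleate_fraction = mean(d$binucleate_fraction, na.rm = TRUE),
        dropout_fraction = mean(d$dropout_fraction, na.rm = TRUE)))
    })
    f <- file.path(config$outDir, "mosaic_summary.json")
    jsonlite::write_json(list(seed = config$seed, regions = mosSummary),
                         f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- c(outputs, f)
    results$mosaic <- mos
    results$mosaicSummary <- mosSummary
  }

  if (!is.null(config$proteins)) {
    diff <- .stageTry("proteomics", {
      pq <- readProteinMatrix(config$proteins, config$proteinGroups,
                              scale = "raw")
      pq <- groupCompletenessFilter(pq)
      pq <- log2Transform(pq)
      permutationFdrTtest(pq, nPermutations = config$nPermutations,
                          fdrThreshold = config$fdrThreshold,
                          seed = config$seed)
    })
    f <- file.path(config$outDir, "diff_results.tsv")
    .writeDelim(diff, f); outputs <- c(outputs, f)
    results$diff <- diff
  }

  manifest <- list(
    package = "streakmorph",
    version = as.character(utils::packageVersion("streakmorph")),
    seed = config$seed,
    options = config[c("regions", "width", "thickness", "segmentLength",
                       "nPermutations", "fdrThreshold",
                       "referenceRegion")],
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) list(md5 = unname(tools::md5sum(f))))
  )
  f <- file.path(config$outDir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
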