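#' Cone density from a counting window
#'
#' Scales a cone count made in a `width x thickness` um window (the
#' standard window is 100 um x 12 um = 1,200 um^2) to cones per mm^2:
#' `count * 1e6 / (width * thickness)`. Fractional counts (per-animal
#' means of several sections) are accepted and preserved.
#'
#' @param coneCount cones counted in the window (may be fractional).
#' @param width,thickness window geometry in um.
#' @return cones per mm^2.
#' @examples
#' coneDensity(60)              # 50,000 / mm^2
#' coneDensity(60.792)          # 50,660 / mm^2
#' @export
coneDensity <- function(coneCount, width = 100, thickness = 12) {
  if (any(!is.finite(width)) || any(!is.finite(thickness)) ||
      any(width * thickness <= 0))
    stop("window area (width * thickness) must be positive")
  if (any(coneCount < 0, na.rm = TRUE)) stop("cone count must be >= 0")
  coneCount * 1e6 / (width * thickness)
}

#' Rod density by ONL stereology
#'
#' Rods are not counted directly: the number of outer-nuclear-layer rows
#' gives rods stacked radially, `width / nucleusDiameter` gives nuclei
#' along the section, and `thickness / nucleusDiameter` gives nuclei
#' through the section depth. Their product is the rod count per window,
#' scaled to rods per mm^2 like [coneDensity()]. Fractional values are
#' retained throughout; no rounding.
#'
#' @param onlRows number of ONL rows attributed to rods (may be a
#'   fractional mean).
#' @param nucleusDiameter mean ONL nucleus diameter (um), > 0.
#' @param width,thickness window geometry in um.
#' @return rods per mm^2.
#' @examples
#' rodDensity(10, 5)            # 400,000 / mm^2
#' @export
rodDensity <- function(onlRows, nucleusDiameter, width = 100, thickness = 12) {
  if (any(!is.finite(nucleusDiameter)) || any(nucleusDiameter <= 0))
    stop("nucleusDiameter must be > 0")
  if (any(width * thickness <= 0))
    stop("window area (width * thickness) must be positive")
  if (any(onlRows < 0, na.rm = TRUE)) stop("onlRows must be >= 0")
  rodsPerWindow <- onlRows * (width / nucleusDiameter) *
    (thickness / nucleusDiameter)
  rodsPerWindow * 1e6 / (width * thickness)
}

#' Rod-to-cone ratio
#'
#' `rodDensity / coneDensity`. Cone density is the denominator because
#' it never reaches zero anywhere in the retina, whereas rod density
#' does (in a fovea); a zero cone density is therefore rejected rather
#' than returned as an infinite ratio.
#'
#' @param rodDensity rods per mm^2.
#' @param coneDensity cones per mm^2, strictly positive.
#' @return the dimensionless rod-to-cone ratio (RCR).
#' @examples
#' rodConeRatio(345014, 50660)  # about 6.8 in a visual streak
#' @export
rodConeRatio <- function(rodDensity, coneDensity) {
  if (any(!is.finite(coneDensity)) || any(coneDensity <= 0))
    stop("cone density must be > 0: rod density can vanish (e.g. in a ",
         "fovea) and is not a valid denominator")
  if (any(rodDensity < 0, na.rm = TRUE)) stop("rod density must be >= 0")
  rodDensity / coneDensity
}

.sectionMetric <- function(sections, metric) {
  known <- c("cone_density", "rod_density", "rcr", "cone_count", "onl_rows",
             "nucleus_diameter_um", "os_length_um", "rpe_height_um",
             "phagosome_count", "rpe_cell_count", "phagosomes_per_cell")
  if (!metric %in% known && !metric %in% names(sections))
    stop("unknown metric '", metric, "'; known: ",
         paste(known, collapse = ", "))
  switch(metric,
    cone_density = coneDensity(sections$cone_count, sections$width_um,
                               sections$thickness_um),
    rod_density = rodDensity(sections$onl_rows,
                             sections$nucleus_diameter_um,
                             sections$width_um, sections$thickness_um),
    rcr = rodConeRatio(
      rodDensity(sections$onl_rows, sections$nucleus_diameter_um,
                 sections$width_um, sections$thickness_um),
      coneDensity(sections$cone_count, sections$width_um,
                  sections$thickness_um)),
    phagosomes_per_cell = phagosomesPerCell(sections$phagosome_count,
                                            sections$rpe_cell_count),
    sections[[metric]]
  )
}

# per-animal values of a metric: sections -> animal mean. The RCR is
# special: each animal's ratio is formed from that animal's mean rod
# and cone densities (ratios of per-section counts would carry a
# Jensen bias from the Poisson noise of the denominator).
.perAnimalValues <- function(sections, metric) {
  agg <- function(v) {
    d <- stats::aggregate(
      v, by = list(region = sections$region,
                   animal_id = sections$animal_id), FUN = mean)
    names(d)[3] <- "value"
    d
  }
  if (identical(metric, "rcr")) {
    rod <- agg(.sectionMetric(sections, "rod_density"))
    cone <- agg(.sectionMetric(sections, "cone_density"))
    stopifnot(identical(rod[1:2], cone[1:2]))
    rod$value <- rodConeRatio(rod$value, cone$value)
    rod
  } else {
    agg(.sectionMetric(sections, metric))
  }
}

#' Per-region summary of a section metric across animals
#'
#' Aggregation follows the sampling design in two fixed levels: section
#' values are averaged within each animal, then the across-animal mean,
#' SD and quantiles are reported per region. The SD is therefore the
#' between-animal SD (n = number of animals), not the between-section
#' one. With a single animal the SD is undefined and returned as `NA`
#' with `n_animals = 1` flagging it. The `"rcr"` metric is computed per
#' animal as the ratio of that animal's mean rod and cone densities.
#'
#' @param sections a section-record data.frame (see
#'   [simulateSections()] / [readSections()]).
#' @param metric a raw column (`cone_count`, `onl_rows`, `os_length_um`,
#'   `rpe_height_um`, ...) or a derived metric: `"cone_density"`,
#'   `"rod_density"`, `"rcr"`, `"phagosomes_per_cell"`.
#' @return a data.frame with one row per region: `region`, `metric`,
#'   `n_animals`, `mean`, `sd`, `median`, `q05`, `q25`, `q75`, `q95`.
#' @examples
#' sec <- simulateSections(gerbilTruthDefaults(), seed = 1)
#' regionSummary(sec, "cone_density")
#' @export
regionSummary <- function(sections, metric) {
  stopifnot(is.data.frame(sections), nrow(sections) > 0)
  perAnimal <- .perAnimalValues(sections, metric)
  out <- do.call(rbind, lapply(split(perAnimal, perAnimal$region),
    function(d) {
      q <- stats::quantile(d$value, c(0.05, 0.25, 0.5, 0.75, 0.95),
                           names = FALSE)
      data.frame(region = d$region[1], metric = metric,
                 n_animals = nrow(d),
                 mean = mean(d$value),
                 sd = if (nrow(d) > 1) stats::sd(d$value) else NA_real_,
                 median = q[3], q05 = q[1], q25 = q[2], q75 = q[4],
                 q95 = q[5], stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Per-region photoreceptor densities and rod-to-cone ratios
#'
#' Convenience wrapper computing the three headline region summaries
#' (cone density, rod density, RCR) plus the RCR both ways the field
#' reports it: as the mean of per-animal ratios and as the ratio of the
#' across-animal mean densities. Both coincide closely when per-animal
#' densities are homogeneous.
#'
#' @param sections a section-record data.frame.
#' @return a data.frame with one row per region: densities (mean, sd),
#'   `rcr_mean`, `rcr_sd`, `rcr_median` (per-animal ratios) and
#'   `rcr_of_means` (ratio of mean densities).
#' @examples
#' densityReport(simulateSections(gerbilTruthDefaults(), seed = 1))
#' @export
densityReport <- function(sections) {
  cone <- regionSummary(sections, "cone_density")
  rod <- regionSummary(sections, "rod_density")
  rcr <- regionSummary(sections, "rcr")
  stopifnot(identical(cone$region, rod$region),
            identical(cone$region, rcr$region))
  data.frame(
    region = cone$region,
    n_animals = cone$n_animals,
    cone_density_mean = cone$mean, cone_density_sd = cone$sd,
    rod_density_mean = rod$mean, rod_density_sd = rod$sd,
    rcr_mean = rcr$mean, rcr_sd = rcr$sd, rcr_median = rcr$median,
    rcr_of_means = rodConeRatio(rod$mean, cone$mean),
    stringsAsFactors = FALSE
  )
}
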