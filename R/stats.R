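#' Repeated-measures design of per-animal values
#'
#' A complete animals x groups table of per-animal means, the input to
#' [pairedT()] (2 groups) and [rmAnovaBonferroni()] (3 groups). Every
#' animal must have a value in every group.
#'
#' @param values numeric matrix (animals x groups) or a long data.frame
#'   with columns `animal_id`, `group`, `value`.
#' @param groups optional group (column) names when `values` is an
#'   unnamed matrix.
#' @return a list of class `"PairedDesign"` with elements `values`
#'   (matrix), `animals`, `groups`.
#' @examples
#' d <- pairedDesign(cbind(VS = c(6.5, 6.9, 7.0, 6.6, 6.8),
#'                         FP = c(10.8, 11.2, 11.0, 10.9, 11.3)))
#' pairedT(d)
#' @export
pairedDesign <- function(values, groups = NULL) {
  if (is.data.frame(values) &&
      all(c("animal_id", "group", "value") %in% names(values))) {
    wide <- stats::reshape(
      values[c("animal_id", "group", "value")],
      idvar = "animal_id", timevar = "group", direction = "wide")
    m <- as.matrix(wide[-1])
    colnames(m) <- sub("^value\\.", "", colnames(m))
    rownames(m) <- wide$animal_id
    values <- m
  }
  values <- as.matrix(values)
  if (!is.null(groups)) colnames(values) <- groups
  if (is.null(colnames(values)))
    colnames(values) <- paste0("group", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("animal", seq_len(nrow(values)))
  if (anyNA(values))
    stop("incomplete design: every animal needs a value in every group")
  if (nrow(values) < 3L)
    stop("at least 3 animals are required for testing")
  structure(list(values = values, animals = rownames(values),
                 groups = colnames(values)),
            class = "PairedDesign")
}

#' @export
print.PairedDesign <- function(x, ...) {
  cat("PairedDesign:", length(x$animals), "animals x",
      length(x$groups), "groups (", paste(x$groups, collapse = ", "), ")\n")
  print(x$values)
  invisible(x)
}

.stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else ""
}

#' Significance star labels
#'
#' The usual convention: `""` for p >= 0.05, `*` for p < 0.05, `**` for
#' p < 0.01, `***` for p < 0.001, `****` for p < 0.0001; all strict
#' inequalities, the most extreme label wins.
#'
#' @param p p-value(s) in \[0, 1\]; vectorized.
#' @return character vector of labels.
#' @examples
#' starLabels(c(0.04, 0.05, 5e-5))
#' @export
starLabels <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p must lie in [0, 1]")
  vapply(p, .stars, character(1))
}

#' Two-tailed paired t-test on per-animal values
#'
#' @param design a [pairedDesign()] with exactly 2 groups.
#' @return a data.frame row (`StatReport`): `test`, `comparison`,
#'   `statistic`, `df`, `p_value`, `adjusted_p` (= `p_value`, single
#'   comparison), `stars`, `normality_p` (Shapiro-Wilk on the paired
#'   differences, advisory only), `mean_difference`, `note`. Differences
#'   with zero variance make t undefined: the effect is reported as the
#'   mean difference with `NA` statistic and an explanatory note.
#' @examples
#' d <- pairedDesign(cbind(a = c(1, 2, 3, 2, 2) + 10, b = rep(10, 5)))
#' pairedT(d)
#' @export
pairedT <- function(design) {
  stopifnot(inherits(design, "PairedDesign"))
  if (length(design$groups) != 2L)
    stop("pairedT needs exactly 2 groups")
  v <- design$values
  diffs <- v[, 1] - v[, 2]
  comparison <- paste(design$groups, collapse = " vs ")
  if (stats::sd(diffs) == 0) {
    return(data.frame(
      test = "paired t", comparison = comparison,
      statistic = NA_real_, df = length(diffs) - 1L,
      p_value = NA_real_, adjusted_p = NA_real_, stars = NA_character_,
      normality_p = NA_real_, mean_difference = mean(diffs),
      note = "zero variance of paired differences: t undefined",
      stringsAsFactors = FALSE))
  }
  tt <- stats::t.test(v[, 1], v[, 2], paired = TRUE,
                      alternative = "two.sided")
  sw <- tryCatch(stats::shapiro.test(diffs)$p.value,
                 error = function(e) NA_real_)
  data.frame(
    test = "paired t", comparison = comparison,
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, adjusted_p = tt$p.value,
    stars = starLabels(tt$p.value), normality_p = sw,
    mean_difference = mean(diffs), note = "",
    stringsAsFactors = FALSE)
}

# Greenhouse-Geisser epsilon from the double-centered covariance of the
# animals x groups matrix.
.ggEpsilon <- function(values) {
  S <- stats::cov(values)
  k <- ncol(S)
  Sc <- S - outer(rowMeans(S), rep(1, k)) -
    outer(rep(1, k), colMeans(S)) + mean(S)
  tr <- sum(diag(Sc))
  eps <- tr^2 / ((k - 1) * sum(Sc^2))
  if (!is.finite(eps)) eps <- 1   # degenerate (e.g. zero) covariance
  min(1, max(eps, 1 / (k - 1)))
}

#' Repeated-measures one-way ANOVA with Bonferroni pairwise tests
#'
#' One-way repeated-measures ANOVA across three (or more) regions
#' measured in the same animals, with the Greenhouse-Geisser epsilon
#' applied unconditionally to the degrees of freedom of the omnibus
#' test, followed by all pairwise paired t-tests with Bonferroni
#' correction (raw p times the number of comparisons, capped at 1).
#'
#' @param design a [pairedDesign()] with >= 3 groups.
#' @return list with `omnibus` (data.frame: F, uncorrected and
#'   GG-corrected df and p, epsilon) and `pairwise` (data.frame of
#'   [pairedT()] rows with `adjusted_p` Bonferroni-corrected and stars
#'   from the adjusted p).
#' @examples
#' d <- pairedDesign(cbind(VS = c(6.8, 6.6, 7.0, 6.9, 6.7),
#'                         NP = c(9.0, 8.8, 9.3, 9.1, 8.9),
#'                         FP = c(11.0, 10.7, 11.3, 11.1, 10.8)))
#' rmAnovaBonferroni(d)$omnibus
#' @export
rmAnovaBonferroni <- function(design) {
  stopifnot(inherits(design, "PairedDesign"))
  v <- design$values
  k <- ncol(v)
  if (k < 3L) stop("rmAnovaBonferroni needs at least 3 groups")
  n <- nrow(v)
  long <- data.frame(
    value = as.vector(v),
    group = factor(rep(design$groups, each = n), levels = design$groups),
    animal = factor(rep(design$animals, times = k))
  )
  fit <- stats::aov(value ~ group + Error(animal), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fval <- tab["group", "F value"]
  df1 <- tab["group", "Df"]
  df2 <- tab["Residuals", "Df"]
  ssg <- tab["group", "Sum Sq"]
  sse <- tab["Residuals", "Sum Sq"]
  eps <- .ggEpsilon(v)
  if (ssg <= 1e-12 * max(1, ssg + sse)) {        # no group effect at all
    Fval <- 0; pGG <- 1; pRaw <- 1
  } else if (sse <= 1e-12 * (ssg + sse)) {       # zero residual variance
    Fval <- Inf; pGG <- 0; pRaw <- 0
  } else {
    pGG <- stats::pf(Fval, df1 * eps, df2 * eps, lower.tail = FALSE)
    pRaw <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
  }
  omnibus <- data.frame(
    test = "RM one-way ANOVA", F = Fval, df1 = df1, df2 = df2,
    epsilon_gg = eps, df1_gg = df1 * eps, df2_gg = df2 * eps,
    p_uncorrected = pRaw, p_value = pGG, stars = starLabels(pGG),
    stringsAsFactors = FALSE)
  pairs <- utils::combn(seq_len(k), 2, simplify = FALSE)
  m <- length(pairs)
  pairwise <- do.call(rbind, lapply(pairs, function(ix) {
    sub <- pairedDesign(v[, ix, drop = FALSE])
    row <- pairedT(sub)
    row$adjusted_p <- pmin(1, row$p_value * m)
    row$stars <- starLabels(row$adjusted_p)
    row
  }))
  list(omnibus = omnibus, pairwise = pairwise)
}

#' Shapiro-Wilk normality screen
#'
#' Advisory normality check; it never gates the pipeline, the p-value is
#' simply reported alongside the tests.
#'
#' @param values numeric vector, 3 <= n <= 5000, non-constant.
#' @return the Shapiro-Wilk p-value.
#' @examples
#' shapiroScreen(rnorm(20))
#' @export
shapiroScreen <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L || length(values) > 5000L)
    stop("shapiroScreen requires 3 <= n <= 5000")
  if (stats::sd(values) == 0)
    stop("constant values: normality test undefined")
  stats::shapiro.test(values)$p.value
}

#' Statistical battery over region summaries of section metrics
#'
#' For each metric, builds the per-animal x region [pairedDesign()] from
#' the section table and runs [pairedT()] (2 regions) or
#' [rmAnovaBonferroni()] (>= 3 regions), returning one tidy table of all
#' comparisons.
#'
#' @param sections section-record data.frame.
#' @param metrics character vector of metrics (see [regionSummary()]).
#' @param regions regions to include, in eccentricity order; default all
#'   present.
#' @return data.frame: `metric`, `test`, `comparison`, `statistic`,
#'   `p_value`, `adjusted_p`, `stars`, `normality_p`.
#' @examples
#' sec <- simulateSections(gerbilTruthDefaults(), seed = 1)
#' metricStats(sec, c("cone_density", "rcr"))
#' @export
metricStats <- function(sections, metrics, regions = NULL) {
  if (is.null(regions)) regions <- unique(sections$region)
  out <- list()
  for (metric in metrics) {
    perAnimal <- .perAnimalValues(sections, metric)
    names(perAnimal)[names(perAnimal) == "region"] <- "group"
    perAnimal <- perAnimal[perAnimal$group %in% regions, ]
    design <- pairedDesign(perAnimal)
    design$values <- design$values[, regions, drop = FALSE]
    design$groups <- regions
    if (length(regions) == 2L) {
      row <- pairedT(design)
      row <- row[c("test", "comparison", "statistic", "p_value",
                   "adjusted_p", "stars", "normality_p")]
      row$metric <- metric
      out[[length(out) + 1L]] <- row
    } else {
      res <- rmAnovaBonferroni(design)
      om <- data.frame(
        test = res$omnibus$test, comparison = "omnibus",
        statistic = res$omnibus$F, p_value = res$omnibus$p_value,
        adjusted_p = res$omnibus$p_value, stars = res$omnibus$stars,
        normality_p = NA_real_, metric = metric,
        stringsAsFactors = FALSE)
      pw <- res$pairwise[c("test", "comparison", "statistic", "p_value",
                           "adjusted_p", "stars", "normality_p")]
      pw$metric <- metric
      out[[length(out) + 1L]] <- rbind(om, pw)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("metric", setdiff(names(res), "metric"))]
}
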