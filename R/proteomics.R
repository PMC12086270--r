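#' Keep proteins fully quantified in at least one group
#'
#' Retains exactly the rows that have zero missing values in at least
#' one biological group; everything else is removed. The operation is
#' idempotent. Retained/removed counts are recorded in
#' `metadata()$filter`.
#'
#' @param x a [ProteinQuant-class].
#' @return the filtered [ProteinQuant-class]; a warning (not an error)
#'   is raised when nothing survives.
#' @examples
#' pq <- simulateProteinMatrix(50, c(VS = 3, periphery = 3),
#'                             missingProb = 0.3, seed = 5)
#' nrow(groupCompletenessFilter(pq))
#' @export
groupCompletenessFilter <- function(x) {
  stopifnot(is(x, "ProteinQuant"))
  a <- SummarizedExperiment::assay(x, "intensity")
  g <- sampleGroups(x)
  keep <- Reduce(`|`, lapply(levels(g), function(lv)
    rowSums(is.na(a[, g == lv, drop = FALSE])) == 0L))
  if (!any(keep))
    warning("group-completeness filter removed every protein")
  out <- x[keep, ]
  S4Vectors::metadata(out)$filter <-
    list(retained = sum(keep), removed = sum(!keep))
  out
}

#' Log2-transform a raw intensity matrix
#'
#' Elementwise log2 of the strictly positive raw intensities; missing
#' values stay missing; the scale flag flips to `"log2"`. Applying it to
#' an already transformed object is an error, as is any non-positive
#' intensity (reported with its protein and sample).
#'
#' @param x a [ProteinQuant-class] on the raw scale.
#' @return the transformed [ProteinQuant-class].
#' @examples
#' pq <- simulateProteinMatrix(10, c(a = 2, b = 2), seed = 1)
#' quantScale(log2Transform(pq))
#' @export
log2Transform <- function(x) {
  stopifnot(is(x, "ProteinQuant"))
  if (quantScale(x) == "log2")
    stop("already on the log2 scale")
  a <- SummarizedExperiment::assay(x, "intensity")
  bad <- which(!is.na(a) & a <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive intensity at protein ", rownames(a)[bad[1, 1]],
         ", sample ", colnames(a)[bad[1, 2]])
  SummarizedExperiment::assay(x, "intensity") <- log2(a)
  S4Vectors::metadata(x)$scale <- "log2"
  validObject(x)
  x
}

# Row-wise two-sample t statistics with available-case handling.
# Returns NA where either group has fewer than 2 observed values.
# s0 is added to the denominator (SAM moderation); 0 = plain t.
.rowTStats <- function(a, idx1, idx2, varEqual = TRUE, s0 = 0) {
  x1 <- a[, idx1, drop = FALSE]
  x2 <- a[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- rowSums((x1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((x2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  if (varEqual) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  d <- m1 - m2
  t <- d / (s0 + se)
  t[s0 + se == 0 & d == 0] <- 0
  t[n1 < 2 | n2 < 2] <- NA_real_
  list(t = t, diff = d, df = df, n1 = n1, n2 = n2, se = se)
}

# All group-1 column index sets for the permutation null, excluding the
# observed assignment and (for equal group sizes) its mirror image.
.permutationSets <- function(n, idx1, nPermutations) {
  n1 <- length(idx1)
  total <- choose(n, n1)
  obs <- sort(idx1)
  mirror <- sort(setdiff(seq_len(n), idx1))
  isExcluded <- function(s)
    identical(s, obs) || (length(mirror) == n1 && identical(s, mirror))
  if (total - 2 <= nPermutations) {
    sets <- utils::combn(n, n1, simplify = FALSE)
    sets <- Filter(function(s) !isExcluded(sort(s)), sets)
    list(sets = sets, method = "exhaustive")
  } else {
    sets <- vector("list", nPermutations)
    b <- 0L
    while (b < nPermutations) {
      s <- sort(sample.int(n, n1))
      if (isExcluded(s)) next
      b <- b + 1L
      sets[[b]] <- s
    }
    list(sets = sets, method = "sampled")
  }
}

# number of elements of sortedAbs that are >= each value in q
.countGE <- function(q, sortedAbs) {
  length(sortedAbs) - findInterval(q, sortedAbs, left.open = TRUE)
}

#' Permutation-FDR two-sample t-tests on a protein matrix
#'
#' For every protein, a two-sample t-test (pooled-variance Student by
#' default, Welch optionally) on the available log2 intensities of the
#' two groups. The null distribution is built by permuting the sample
#' group labels as whole columns -- the same permutation for every
#' protein, preserving between-protein correlation -- `nPermutations`
#' times (all distinct assignments are enumerated instead when there are
#' no more than requested; the observed assignment and its mirror image
#' are never part of the null). The q-value of protein i is the
#' permutation tail-count ratio
#' \deqn{q_i = \frac{\mathrm{agg}_b\, \#\{|t_b| \ge |t_i|\}}{\#\{|t_{obs}| \ge |t_i|\}},}
#' aggregated over permutations with the mean (default) or the median,
#' monotonized to be non-increasing in |t| and capped at 1. Proteins
#' with `q < fdrThreshold` are flagged significant.
#'
#' An optional SAM-style `s0` is added to the denominator of t; the
#' default 0 is the plain t-statistic, `"auto"` uses the median of the
#' per-protein standard errors. With very few replicates per group the
#' plain t has heavy null tails (a lucky small within-group variance
#' inflates |t|), which caps the attainable sensitivity of any
#' tail-count FDR estimate; the s0 moderation exists to damp exactly
#' those small-denominator outliers. Proteins with fewer than two
#' observed values in either group get `NA` results and never count
#' toward the null.
#'
#' @param x a [ProteinQuant-class] on the log2 scale, two groups.
#' @param nPermutations permutations for the null (default 250).
#' @param fdrThreshold significance threshold on q (default 0.05).
#' @param seed integer seed for the random permutations.
#' @param s0 variance-stabilizing fudge factor: a number (default 0) or
#'   `"auto"` for the median per-protein standard error.
#' @param varEqual pooled-variance Student t (TRUE, default) or Welch.
#' @param aggregate `"mean"` (default) or `"median"` tail-count
#'   aggregation over permutations.
#' @return a `data.frame` with one row per protein: `protein_id`,
#'   `log2_fc` (group1 - group2 mean), `t_stat`, `df`, `p_raw`
#'   (parametric reference p), `q_value`, `significant`, `n1`, `n2`;
#'   attributes `nPermutations`, `method` (`exhaustive`/`sampled`),
#'   `groups`, `seed`.
#' @examples
#' pq <- simulateProteinMatrix(300, c(VS = 3, periphery = 3),
#'                             plantedEffects = data.frame(index = 1:10,
#'                                                         log2fc = 2),
#'                             seed = 2)
#' res <- permutationFdrTtest(log2Transform(pq), seed = 2)
#' head(res[res$significant, ])
#' @export
permutationFdrTtest <- function(x, nPermutations = 250,
                                fdrThreshold = 0.05, seed = 1L,
                                s0 = 0, varEqual = TRUE,
                                aggregate = c("mean", "median")) {
  stopifnot(is(x, "ProteinQuant"))
  aggregate <- match.arg(aggregate)
  if (quantScale(x) != "log2")
    stop("log2-transform the matrix first (see log2Transform())")
  g <- droplevels(factor(sampleGroups(x)))
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  a <- SummarizedExperiment::assay(x, "intensity")
  idx1 <- which(g == levels(g)[1])
  idx2 <- which(g == levels(g)[2])
  if (length(idx1) < 2L || length(idx2) < 2L)
    stop("at least 2 samples per group are required")
  if (length(idx1) < 3L || length(idx2) < 3L)
    warning("fewer than 3 replicates per group: permutation inference ",
            "is weakly powered at this size")
  seed <- .assertSeed(seed)

  if (identical(s0, "auto")) {
    se <- .rowTStats(a, idx1, idx2, varEqual = varEqual, s0 = 0)$se
    s0 <- stats::median(se[is.finite(se) & se > 0])
  }
  obs <- .rowTStats(a, idx1, idx2, varEqual = varEqual, s0 = s0)
  absT <- abs(obs$t)
  ok <- !is.na(absT)
  nOk <- sum(ok)
  sortedObs <- sort(absT[ok])
  obsCount <- .countGE(absT[ok], sortedObs)

  perm <- withr::with_seed(seed,
    .permutationSets(ncol(a), idx1, nPermutations))
  nullCounts <- matrix(0, nOk, length(perm$sets))
  for (b in seq_along(perm$sets)) {
    i1 <- perm$sets[[b]]
    i2 <- setdiff(seq_len(ncol(a)), i1)
    tb <- abs(.rowTStats(a, i1, i2, varEqual = varEqual, s0 = s0)$t)
    tb <- tb[!is.na(tb)]
    nullCounts[, b] <- .countGE(absT[ok], sort(tb))
  }
  aggCount <- if (aggregate == "mean") rowMeans(nullCounts)
              else apply(nullCounts, 1, stats::median)
  qRaw <- pmin(1, aggCount / obsCount)
  # monotonize: q never decreases as |t| decreases
  ord <- order(absT[ok], decreasing = TRUE)
  qm <- qRaw
  qm[ord] <- rev(cummin(rev(qRaw[ord])))

  q <- rep(NA_real_, nrow(a))
  q[ok] <- qm
  pRaw <- 2 * stats::pt(abs(obs$t), df = obs$df, lower.tail = FALSE)
  res <- data.frame(
    protein_id = rownames(a),
    log2_fc = obs$diff,
    t_stat = obs$t,
    df = obs$df,
    p_raw = pRaw,
    q_value = q,
    significant = !is.na(q) & q < fdrThreshold,
    n1 = obs$n1, n2 = obs$n2,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "nPermutations") <- length(perm$sets)
  attr(res, "method") <- perm$method
  attr(res, "groups") <- levels(g)
  attr(res, "seed") <- seed
  attr(res, "s0") <- s0
  res
}

#' Report a named marker panel from differential results
#'
#' Subsets the differential-abundance results to a panel of proteins of
#' interest (e.g. phagocytosis machinery: MERTK, Gas6, FAK; visual-cycle
#' enzymes: ABCA4, RDH8) with a direction-of-change flag; panel ids
#' absent from the results are listed, not dropped silently.
#'
#' @param results a data.frame from [permutationFdrTtest()].
#' @param panel character vector of protein ids.
#' @return list with `table` (the matching rows plus a `direction`
#'   column: `"up"`, `"down"` or `"unchanged"`) and `missing`.
#' @examples
#' pq <- simulateProteinMatrix(20, c(a = 3, b = 3), seed = 1)
#' res <- permutationFdrTtest(log2Transform(pq), seed = 1)
#' markerPanelReport(res, c("protein_0001", "ABSENT"))
#' @export
markerPanelReport <- function(results, panel) {
  hit <- results[match(panel, results$protein_id), , drop = FALSE]
  missing <- panel[is.na(hit$protein_id)]
  tab <- hit[!is.na(hit$protein_id), , drop = FALSE]
  if (nrow(tab)) {
    tab$direction <- ifelse(!tab$significant, "unchanged",
                            ifelse(tab$log2_fc > 0, "up", "down"))
  } else {
    tab$direction <- character(0)
  }
  rownames(tab) <- NULL
  list(table = tab, missing = missing)
}
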