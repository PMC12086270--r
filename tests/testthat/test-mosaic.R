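test_that("internuclear distances are consecutive differences", {
  expect_equal(internuclearDistances(rpeTrace(c(0, 20, 40, 70))),
               c(20, 20, 30))
  expect_equal(internuclearDistances(rpeTrace(c(5, 8, 28))), c(3, 20))
  eq <- rpeTrace(seq(5, by = 20, length.out = 12))
  expect_equal(internuclearDistances(eq), rep(20, 11))
  expect_error(internuclearDistances(rpeTrace(5)), "at least 2")
  expect_error(rpeTrace(c(10, 10, 20)), "strictly increasing")
  expect_error(rpeTrace(c(-2, 10)), "0, segmentLength")
})

test_that("gap classification uses half/twice the raw median strictly", {
  cls <- classifyGaps(c(20, 20, 30, 9, 41))
  expect_equal(cls$median, 20)
  expect_equal(cls$lower, 10)
  expect_equal(cls$upper, 40)
  expect_identical(cls$classes,
                   c("normal", "normal", "normal", "binucleate", "dropout"))
  # all equal -> all normal
  expect_true(all(classifyGaps(rep(17, 8))$classes == "normal"))
  # boundary gaps (exactly half / exactly twice the median) are normal
  b <- classifyGaps(c(10, 20, 20, 20, 40))
  expect_identical(b$classes, rep("normal", 5))
  # even-length list: median is the mean of the two central values
  expect_equal(classifyGaps(c(10, 20))$median, 15)
  # thresholds at the measured streak median
  m <- classifyGaps(c(17.12, 17.12, 17.12))
  expect_equal(m$lower, 8.56)
  expect_equal(m$upper, 34.24)
  expect_error(classifyGaps(numeric(0)), "no distances")
})

test_that("binucleate pairs merge to their midpoint", {
  tr <- rpeTrace(c(0, 3, 23))
  cls <- classifyGaps(internuclearDistances(tr))
  corr <- correctBinucleates(tr, cls)
  expect_equal(corr$positions, c(1.5, 23))
  expect_equal(corr$distances, 21.5)
  expect_equal(corr$binucleateFraction, 1 / 3)
  expect_equal(corr$binucleateCellFraction, 1 / 2)
  # no binucleate gaps -> identity
  tr2 <- rpeTrace(c(0, 20, 40))
  cls2 <- classifyGaps(internuclearDistances(tr2))
  corr2 <- correctBinucleates(tr2, cls2)
  expect_identical(corr2$positions, c(0, 20, 40))
  expect_identical(corr2$nMerged, 0L)
  expect_error(correctBinucleates(tr2, classifyGaps(c(1, 2, 3))),
               "align")
})

test_that("dropout gaps are excluded but their nuclei retained", {
  # gaps 20,20,90,20 around median 20: the 90 is a dropout artifact
  tr <- rpeTrace(c(0, 20, 40, 130, 150), segmentLength = 200)
  cls <- classifyGaps(internuclearDistances(tr))
  expect_identical(cls$classes,
                   c("normal", "normal", "dropout", "normal"))
  corr <- correctBinucleates(tr, cls)
  expect_identical(length(corr$positions), 5L)   # nuclei all retained
  expect_equal(corr$distances, c(20, 20, 20))    # 90 um gap excluded
  expect_equal(corr$dropoutFraction, 1 / 4)
})

test_that("nuclei are conserved: retained or merged, never dropped", {
  p <- truthParams("VS", rpeSpacingMean = 19, dropoutProb = 0)
  for (s in 1:5) {
    sim <- simulateRpeTrace(p, segmentLength = 3000, seed = s)
    tr <- sim$trace
    cls <- classifyGaps(internuclearDistances(tr))
    corr <- correctBinucleates(tr, cls)
    expect_identical(length(corr$positions),
                     length(positions(tr)) - corr$nMerged)
  }
})

test_that("consecutive binucleate chains resolve greedily left to right", {
  # three nuclei 2 um apart in a 20 um lattice: gaps 2,2 both binucleate
  tr <- rpeTrace(c(0, 2, 4, 24, 44, 64, 84, 104))
  cls <- classifyGaps(internuclearDistances(tr))
  expect_identical(cls$classes[1:2], c("binucleate", "binucleate"))
  corr <- correctBinucleates(tr, cls)
  expect_identical(corr$chainEvents, 1L)
  # left pair merged to 1; third nucleus kept separate
  expect_equal(corr$positions[1:2], c(1, 4))
  expect_identical(corr$nMerged, 1L)
})

test_that("the artifact filter is idempotent", {
  p <- truthParams("VS", rpeSpacingMean = 19)
  sim <- simulateRpeTrace(p, segmentLength = 3000, seed = 9)
  cls <- classifyGaps(internuclearDistances(sim$trace))
  corr <- correctBinucleates(sim$trace, cls)
  # re-run on the corrected positions (drop sub-threshold survivors of
  # the single-pass design, if any, to get a clean fixed point)
  keep <- corr$positions
  tr2 <- rpeTrace(keep, segmentLength = 3000)
  cls2 <- classifyGaps(internuclearDistances(tr2))
  if (!any(cls2$classes == "binucleate")) {
    corr2 <- correctBinucleates(tr2, cls2)
    expect_identical(corr2$positions, keep)
    expect_identical(corr2$nMerged, 0L)
  }
})

test_that("hexagon area follows the regular-hexagon closed form", {
  expect_identical(hexagonArea(0), 0)
  expect_equal(hexagonArea(2), 2 * sqrt(3))
  expect_equal(round(hexagonArea(19.16), 1), 317.9)
  expect_equal(round(hexagonArea(22.59), 1), 441.9)
  expect_error(hexagonArea(-1), ">= 0")
  # geometry consistency: closed form, 3*h*a, and the shoelace oracle
  set.seed(13)
  D <- c(2, 19.16, runif(50, 0.1, 60))
  g <- hexagonGeometry(D)
  expect_equal(g$height, D / 2)
  expect_equal(g$side, D / sqrt(3))
  a2 <- 3 * g$height * g$side
  a3 <- vapply(D, shoelaceHexagon, numeric(1))
  expect_lt(max(abs(g$area - a2) / g$area), 1e-9)
  expect_lt(max(abs(g$area - a3) / g$area), 1e-9)
  # strictly increasing in D
  expect_true(all(diff(hexagonArea(sort(D))) > 0))
})

test_that("relative increase and phagosome load are simple ratios", {
  expect_equal(relativeIncrease(5, 5), 0)
  expect_equal(relativeIncrease(1.5, 1.0), 50)
  expect_equal(round(relativeIncrease(12.08, 7), 1), 72.6)
  expect_error(relativeIncrease(1, 0), "reference")
  expect_equal(phagosomesPerCell(12, 4), 3)
  expect_identical(phagosomesPerCell(0, 4), 0)
  expect_error(phagosomesPerCell(3, 0), "rpeCellCount")
})

test_that("analyzeTrace ties the stages together in both modes", {
  p <- truthParams("VS", rpeSpacingMean = 19, dropoutProb = 0.04)
  sim <- simulateRpeTrace(p, segmentLength = 8000, seed = 21)
  m <- analyzeTrace(sim$trace)
  expect_s4_class(m, "MosaicResult")
  expect_equal(m@lowerThreshold, m@medianDistance / 2)
  expect_equal(m@upperThreshold, 2 * m@medianDistance)
  expect_equal(cellArea(m, "fromMeanDistance"),
               hexagonArea(m@meanCorrectedDistance))
  expect_equal(m@hexagonHeight, m@meanCorrectedDistance / 2)
  # per-distance area >= from-mean area (Jensen, convex square)
  expect_gt(cellArea(m), cellArea(m, "fromMeanDistance"))
  # exclusion mode removes flagged gaps instead of merging
  me <- analyzeTrace(sim$trace, correction = "exclude")
  expect_identical(me@correction, "exclude")
  expect_true(all(me@correctedDistances >= me@lowerThreshold))
  # exclusion keeps the raw (slightly shortened) gaps flanking each
  # binucleate cell, so its mean sits a little below the midpoint one
  expect_equal(me@meanCorrectedDistance, m@meanCorrectedDistance,
               tolerance = 0.05)
})

test_that("mosaicReport tabulates per-trace results", {
  p <- truthParams("VS")
  sims <- lapply(1:3, function(s)
    simulateRpeTrace(p, segmentLength = 250, seed = s)$trace)
  rep <- mosaicReport(sims)
  expect_identical(nrow(rep), 3L)
  expect_true(all(c("median_distance_um", "cell_area_um2",
                    "binucleate_fraction") %in% names(rep)))
})
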