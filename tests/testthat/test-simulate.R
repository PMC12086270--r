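test_that("TruthParams enforces its invariants", {
  expect_error(truthParams("VS", coneRate = 0), "strictly positive")
  expect_error(truthParams("VS", coneRate = -3), "strictly positive")
  expect_error(truthParams("VS", binucleateProb = 1.2), "probability")
  expect_error(truthParams("VS", dropoutProb = -0.1), "probability")
  expect_error(truthParams("VS", rpeSpacingMean = 5, binucleateOffset = 3),
               "binucleateOffset")
  expect_s4_class(truthParams("VS"), "TruthParams")
})

test_that("identical seeds give byte-identical simulations", {
  truth <- gerbilTruthDefaults()
  expect_identical(simulateSections(truth, seed = 11),
                   simulateSections(truth, seed = 11))
  a <- simulateRpeTrace(truth$VS, seed = 11)
  b <- simulateRpeTrace(truth$VS, seed = 11)
  expect_identical(positions(a$trace), positions(b$trace))
  expect_identical(a$truth, b$truth)
  p1 <- simulateProteinMatrix(50, c(a = 3, b = 3), seed = 11)
  p2 <- simulateProteinMatrix(50, c(a = 3, b = 3), seed = 11)
  expect_identical(SummarizedExperiment::assay(p1),
                   SummarizedExperiment::assay(p2))
  expect_false(identical(simulateSections(truth, seed = 11),
                         simulateSections(truth, seed = 12)))
})

test_that("section generator recovers its moments", {
  p <- truthParams("VS", coneRate = 60.8, nAnimals = 100L,
                   nSections = 100L)
  sec <- simulateSections(p, seed = 2)
  expect_equal(nrow(sec), 10000L)
  # law of large numbers: mean within 1% of the rate
  expect_lt(abs(mean(sec$cone_count) - 60.8) / 60.8, 0.01)
  # every generated quantity within 3 standard errors of truth
  for (col in c(onl_rows = "onl_rows", os = "os_length_um",
                h = "rpe_height_um")) {
    tr <- switch(col, onl_rows = p@onlRows, os_length_um = p@osLengthMean,
                 rpe_height_um = p@rpeHeightMean)
    se <- stats::sd(sec[[col]]) / sqrt(nrow(sec))
    expect_lt(abs(mean(sec[[col]]) - tr), 3 * se)
  }
  # phagosome counts: mean per cell near the rate
  expect_lt(abs(mean(sec$phagosome_count / sec$rpe_cell_count) -
                p@phagosomeRate) / p@phagosomeRate, 0.02)
})

test_that("noise-free trace is an equally spaced lattice", {
  p <- truthParams("VS", rpeSpacingMean = 20, rpeSpacingCv = 0,
                   binucleateProb = 0, dropoutProb = 0)
  sim <- simulateRpeTrace(p, segmentLength = 250, seed = 1)
  expect_identical(length(positions(sim$trace)), 12L)
  expect_equal(internuclearDistances(sim$trace), rep(20, 11))
  expect_false(sim$empty)
})

test_that("trace generator plants the requested structure", {
  p <- truthParams("VS", rpeSpacingMean = 19, binucleateProb = 0.14,
                   dropoutProb = 0.05, binucleateOffset = 3)
  sim <- simulateRpeTrace(p, segmentLength = 19 * 5000, seed = 3)
  expect_gte(sim$nCells, 4800)
  # binomial sampling: planted binucleate fraction within 1.5 pp of 14%
  expect_lt(abs(sim$nBinucleate / sim$nCells - 0.14), 0.015)
  # bookkeeping: truth labels reproduce the configuration exactly
  expect_identical(sum(sim$truth$role == "binucleate_1"), sim$nBinucleate)
  expect_identical(sum(sim$truth$role == "binucleate_2"), sim$nBinucleate)
  expect_identical(nrow(sim$truth), sim$nCells + sim$nBinucleate)
  expect_identical(sum(sim$truth$dropped), sim$nDropped)
  expect_identical(length(positions(sim$trace)),
                   nrow(sim$truth) - sim$nDropped)
})

test_that("full dropout gives an empty, flagged trace", {
  p <- truthParams("VS", dropoutProb = 1)
  sim <- simulateRpeTrace(p, seed = 1)
  expect_true(sim$empty)
  expect_identical(length(positions(sim$trace)), 0L)
})

test_that("trace generator rejects impossible geometry", {
  p <- truthParams("VS", rpeSpacingMean = 300)
  expect_error(simulateRpeTrace(p, segmentLength = 250, seed = 1),
               "segmentLength")
  expect_error(simulateRpeTrace(truthParams("VS"), segmentLength = -1,
                                seed = 1), "positive")
})

test_that("protein generator plants effects and records truth", {
  # noise-free construction: group-mean difference equals the planted fc
  pq <- simulateProteinMatrix(100, c(VS = 3, periphery = 3),
                              plantedEffects = data.frame(index = 1:10,
                                                          log2fc = 2),
                              noiseSd = 0, seed = 5)
  a <- log2(SummarizedExperiment::assay(pq))
  d <- rowMeans(a[, 1:3]) - rowMeans(a[, 4:6])
  expect_equal(unname(d[1:10]), rep(2, 10), tolerance = 1e-12)
  expect_equal(unname(d[11:100]), rep(0, 90), tolerance = 1e-12)
  truth <- S4Vectors::metadata(pq)$truth
  expect_identical(truth$index, 1:10)
  expect_identical(truth$group, rep("VS", 10))
  # no planted effects -> empty truth; missingProb 0 -> no NA
  pq0 <- simulateProteinMatrix(20, c(a = 3, b = 3), seed = 5)
  expect_identical(nrow(S4Vectors::metadata(pq0)$truth), 0L)
  expect_false(anyNA(SummarizedExperiment::assay(pq0)))
  # missingness applied at the requested rate
  pqm <- simulateProteinMatrix(500, c(a = 3, b = 3), missingProb = 0.1,
                               seed = 5)
  expect_lt(abs(mean(is.na(SummarizedExperiment::assay(pqm))) - 0.1),
            0.02)
})

test_that("protein generator validates its arguments", {
  expect_error(simulateProteinMatrix(10, c(a = 1, b = 3), seed = 1),
               "2 replicates")
  expect_error(simulateProteinMatrix(10, c(3, 3), seed = 1), "named")
  expect_error(
    simulateProteinMatrix(10, c(a = 3, b = 3), seed = 1,
                          plantedEffects = data.frame(index = 99,
                                                      log2fc = 1)),
    "out of range")
  expect_error(simulateProteinMatrix(10, c(a = 3, b = 3),
                                     missingProb = 2, seed = 1),
               "missingProb")
})

test_that("bundles are coherent: labels, indices, determinism", {
  b <- simulateBundle(seed = 4, nProteins = 60,
                      plantedEffects = data.frame(index = 1:5, log2fc = 2))
  regions <- names(b$truth)
  expect_true(all(b$sections$region %in% regions))
  expect_true(all(vapply(b$traces, region, character(1)) %in% regions))
  expect_true(all(S4Vectors::metadata(b$proteinMatrix)$truth$index
                  %in% seq_len(60)))
  b2 <- simulateBundle(seed = 4, nProteins = 60,
                       plantedEffects = data.frame(index = 1:5, log2fc = 2))
  expect_identical(b$sections, b2$sections)
  expect_identical(SummarizedExperiment::assay(b$proteinMatrix),
                   SummarizedExperiment::assay(b2$proteinMatrix))
})
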