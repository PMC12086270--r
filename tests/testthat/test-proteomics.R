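makePQ <- function(m, groups, scale = "log2") {
  if (is.null(rownames(m))) rownames(m) <- paste0("P", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  proteinQuant(m, groups = groups, scale = scale)
}

test_that("group-completeness filter keeps rows complete in >= 1 group", {
  m <- 2^matrix(rnorm(24, 20), 4, 6)
  g <- rep(c("A", "B"), each = 3)
  m[1, 4:5] <- NA          # complete in A, half-missing in B -> keep
  m[2, c(1, 4)] <- NA      # one missing in every group -> remove
  m[3, 6] <- NA            # complete in A -> keep
  pq <- makePQ(m, g, scale = "raw")
  f <- groupCompletenessFilter(pq)
  expect_identical(rownames(f), c("P1", "P3", "P4"))
  expect_identical(S4Vectors::metadata(f)$filter$removed, 1L)
  # fully complete matrix -> identity; filter is idempotent
  pq2 <- makePQ(2^matrix(rnorm(12, 20), 2, 6), g, scale = "raw")
  expect_identical(dim(groupCompletenessFilter(pq2)), dim(pq2))
  expect_identical(rownames(groupCompletenessFilter(f)), rownames(f))
  # nothing surviving is a warning, not an error
  m3 <- 2^matrix(rnorm(6, 20), 1, 6); m3[1, c(1, 4)] <- NA
  expect_warning(groupCompletenessFilter(makePQ(m3, g, scale = "raw")),
                 "every protein")
})

test_that("log2 transform is guarded and exact", {
  m <- matrix(c(1024, 1, 2, NA, 8, 0.5), 1, 6,
              dimnames = list("P1", paste0("S", 1:6)))
  pq <- makePQ(m, rep(c("A", "B"), each = 3), scale = "raw")
  lg <- log2Transform(pq)
  expect_equal(unname(SummarizedExperiment::assay(lg)[1, ]),
               c(10, 0, 1, NA, 3, -1))
  expect_identical(quantScale(lg), "log2")
  expect_error(log2Transform(lg), "already")
  mBad <- m; mBad[1, 2] <- -4
  pqBad <- makePQ(mBad, rep(c("A", "B"), each = 3), scale = "raw")
  expect_error(log2Transform(pqBad), "S2")
})

test_that("permutation FDR t-test is deterministic and symmetric", {
  pq <- simulateProteinMatrix(150, c(VS = 4, periphery = 4),
                              plantedEffects = data.frame(index = 1:8,
                                                          log2fc = 2),
                              noiseSd = 0.3, seed = 31)
  lq <- log2Transform(pq)
  r1 <- permutationFdrTtest(lq, nPermutations = 50, seed = 7)
  r2 <- permutationFdrTtest(lq, nPermutations = 50, seed = 7)
  expect_identical(r1$q_value, r2$q_value)
  # swapping group labels negates effects, leaves q unchanged
  a <- SummarizedExperiment::assay(lq)
  swapped <- proteinQuant(a, groups = rep(c("periphery", "VS"), each = 4),
                          scale = "log2")
  # relevel so "periphery" is group 1
  r3 <- permutationFdrTtest(swapped, nPermutations = 50, seed = 7)
  expect_equal(r3$log2_fc, -r1$log2_fc)
  expect_equal(r3$t_stat, -r1$t_stat)
  expect_equal(r3$q_value, r1$q_value)
})

test_that("q-values are monotone in |t| and identical values give t=0", {
  set.seed(32)
  m <- matrix(rnorm(600, 20, 0.5), 100, 6)
  m[1, ] <- rep(c(20, 21, 22), 2)   # identical in both groups
  pq <- makePQ(m, rep(c("A", "B"), each = 3))
  res <- suppressWarnings(permutationFdrTtest(pq, seed = 1))
  expect_equal(res$t_stat[1], 0)
  expect_false(res$significant[1])
  expect_equal(res$q_value[1], 1)
  ord <- order(abs(res$t_stat), decreasing = TRUE)
  expect_true(all(diff(res$q_value[ord]) >= 0))
  expect_true(all(res$q_value >= 0 & res$q_value <= 1))
})

test_that("tiny designs fall back to exhaustive enumeration", {
  pq <- simulateProteinMatrix(40, c(a = 3, b = 3), seed = 2)
  res <- suppressWarnings(permutationFdrTtest(log2Transform(pq),
                                              nPermutations = 250,
                                              seed = 2))
  expect_identical(attr(res, "method"), "exhaustive")
  # 20 assignments minus the observed one and its mirror
  expect_identical(attr(res, "nPermutations"), 18L)
  expect_warning(
    permutationFdrTtest(log2Transform(
      simulateProteinMatrix(10, c(a = 2, b = 2), seed = 1)), seed = 1),
    "weakly powered")
})

test_that("available-case guard excludes under-observed proteins", {
  m <- matrix(rnorm(36, 20, 0.3), 6, 6)
  m[1, c(1, 2)] <- NA   # only 1 observation left in group A
  pq <- makePQ(m, rep(c("A", "B"), each = 3))
  res <- suppressWarnings(permutationFdrTtest(pq, seed = 3))
  expect_true(is.na(res$t_stat[1]))
  expect_true(is.na(res$q_value[1]))
  expect_false(res$significant[1])
})

test_that("planted effects are recovered with direction", {
  pq <- simulateProteinMatrix(300, c(VS = 3, periphery = 3),
                              plantedEffects = data.frame(index = 1:10,
                                                          log2fc = 2),
                              noiseSd = 0.3, seed = 12)
  res <- suppressWarnings(
    permutationFdrTtest(log2Transform(pq), seed = 12, s0 = "auto"))
  expect_gte(mean(res$significant[1:10]), 0.9)
  expect_true(all(res$log2_fc[1:10] > 1))
  panel <- markerPanelReport(res, c("protein_0001", "NOT_A_PROTEIN"))
  expect_identical(panel$table$direction, "up")
  expect_identical(panel$missing, "NOT_A_PROTEIN")
  empty <- markerPanelReport(res, character(0))
  expect_identical(nrow(empty$table), 0L)
})

test_that("pipeline inputs are validated", {
  pq <- simulateProteinMatrix(10, c(a = 3, b = 3), seed = 1)
  expect_error(permutationFdrTtest(pq, seed = 1), "log2")
  m <- matrix(rnorm(30, 20), 10, 3)
  expect_error(
    permutationFdrTtest(makePQ(m, c("a", "b", "c")), seed = 1),
    "two groups")
})
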