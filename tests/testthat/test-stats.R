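test_that("paired t matches the textbook formula", {
  d <- c(1, 2, 3, 2, 2)
  des <- pairedDesign(cbind(a = d + 10, b = rep(10, 5)))
  res <- pairedT(des)
  tHand <- mean(d) / (stats::sd(d) / sqrt(5))
  expect_equal(res$statistic, tHand, tolerance = 1e-12)
  expect_equal(res$statistic, 6.3246, tolerance = 1e-4)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * stats::pt(-tHand, 4), tolerance = 1e-12)
  expect_equal(res$p_value, 0.0032, tolerance = 1e-2)
  # swapping the groups negates t, keeps p
  swap <- pairedT(pairedDesign(cbind(b = rep(10, 5), a = d + 10)))
  expect_equal(swap$statistic, -res$statistic)
  expect_equal(swap$p_value, res$p_value)
})

test_that("degenerate paired designs are flagged, not mis-tested", {
  des <- pairedDesign(cbind(a = c(5, 6, 7), b = c(5, 6, 7)))
  res <- pairedT(des)
  expect_true(is.na(res$statistic))
  expect_equal(res$mean_difference, 0)
  expect_match(res$note, "zero variance")
  expect_error(pairedDesign(cbind(a = c(1, NA, 3), b = 1:3)),
               "incomplete")
  expect_error(pairedDesign(cbind(a = 1:2, b = 3:4)), "3 animals")
  expect_error(pairedT(pairedDesign(matrix(rnorm(9), 3, 3))),
               "exactly 2 groups")
})

test_that("star labels follow the strict significance thresholds", {
  expect_identical(starLabels(c(0.04, 0.05, 0.009, 0.0009, 5e-5, 0.5)),
                   c("*", "", "**", "***", "****", ""))
  expect_identical(starLabels(0.01), "*")     # strict: 0.01 is not **
  expect_identical(starLabels(1e-4), "***")   # strict: 1e-4 is not ****
  expect_error(starLabels(1.2), "\\[0, 1\\]")
  expect_error(starLabels(-0.1), "\\[0, 1\\]")
})

test_that("RM-ANOVA F matches the sums-of-squares oracle", {
  set.seed(41)
  for (i in 1:10) {
    v <- matrix(rnorm(15, mean = rep(c(0, 1, 2), each = 5)), 5, 3,
                dimnames = list(NULL, c("VS", "NP", "FP")))
    res <- rmAnovaBonferroni(pairedDesign(v))
    expect_equal(res$omnibus$F, rmAnovaOracleF(v), tolerance = 1e-10)
    eps <- res$omnibus$epsilon_gg
    expect_gte(eps, 0.5)   # lower bound 1/(k-1) for k = 3
    expect_lte(eps, 1)
  }
})

test_that("identical groups give F = 0 and p = 1", {
  v <- matrix(rep(rnorm(5), 3), 5, 3)
  res <- rmAnovaBonferroni(pairedDesign(v))
  expect_equal(res$omnibus$F, 0)
  expect_equal(res$omnibus$p_value, 1)
})

test_that("Bonferroni multiplies pairwise p by 3, capped at 1", {
  set.seed(42)
  v <- matrix(rnorm(15, rep(c(0, 0.5, 3), each = 5), 0.5), 5, 3,
              dimnames = list(NULL, c("g1", "g2", "g3")))
  res <- rmAnovaBonferroni(pairedDesign(v))
  expect_identical(nrow(res$pairwise), 3L)
  expect_equal(res$pairwise$adjusted_p,
               pmin(1, res$pairwise$p_value * 3))
  expect_true(all(res$pairwise$adjusted_p >= res$pairwise$p_value))
})

test_that("a 2-group RM-ANOVA is the squared paired t", {
  # consistency of the two tests, both checked against oracles: the
  # within-subject F on 2 groups equals t^2 of the paired test
  set.seed(43)
  for (i in 1:5) {
    v <- matrix(rnorm(10, rep(c(0, 1), each = 5)), 5, 2)
    tt <- pairedT(pairedDesign(v))
    expect_equal(rmAnovaOracleF(v), tt$statistic^2, tolerance = 1e-10)
  }
})

test_that("Shapiro screen is advisory and validates its input", {
  expect_error(shapiroScreen(c(1, 2)), "3 <= n")
  expect_error(shapiroScreen(rep(3, 10)), "constant")
  set.seed(44)
  expect_gt(shapiroScreen(rnorm(50)), 0.05)
  # strongly skewed samples are reliably rejected at n = 50
  rejections <- vapply(1:20, function(i)
    shapiroScreen(rexp(50)^2) < 0.05, logical(1))
  expect_gte(mean(rejections), 0.9)
})

test_that("metricStats runs the right test per number of regions", {
  sec <- simulateSections(gerbilTruthDefaults(), seed = 6)
  res3 <- metricStats(sec, c("cone_density", "rcr"))
  expect_true(all(c("omnibus", "VS vs NP", "VS vs FP", "NP vs FP")
                  %in% res3$comparison))
  # strong regional differences must be detected
  omni <- res3[res3$comparison == "omnibus", ]
  expect_true(all(omni$p_value < 0.05))
  res2 <- metricStats(sec, "cone_density", regions = c("VS", "FP"))
  expect_identical(res2$test, "paired t")
  expect_identical(res2$comparison, "VS vs FP")
})
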