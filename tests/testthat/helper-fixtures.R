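# Small builders shared across test files.

# a section table with exact, hand-checkable values
fixedSections <- function() {
  data.frame(
    animal_id = rep(c("A1", "A2"), each = 2),
    region = "VS",
    section = rep(1:2, 2),
    width_um = 100, thickness_um = 12,
    cone_count = c(60, 62, 58, 64),
    onl_rows = c(10, 10, 9, 9),
    nucleus_diameter_um = 5,
    os_length_um = c(20, 21, 19, 22),
    rpe_height_um = c(12, 12.5, 11.5, 12),
    phagosome_count = c(12, 8, 10, 9),
    rpe_cell_count = c(4, 4, 5, 3),
    stringsAsFactors = FALSE
  )
}

# shoelace polygon area, the independent oracle for the hexagon model:
# vertices of the regular hexagon with apothem h = D/2 (circumradius
# a = D/sqrt(3), one vertex on the x-axis)
shoelaceHexagon <- function(D) {
  a <- D / sqrt(3)
  th <- (0:5) * pi / 3
  x <- a * cos(th); y <- a * sin(th)
  xs <- c(x, x[1]); ys <- c(y, y[1])
  abs(sum(xs[-7] * ys[-1] - xs[-1] * ys[-7])) / 2
}

# brute-force sums-of-squares oracle for the one-way RM-ANOVA F
rmAnovaOracleF <- function(v) {
  n <- nrow(v); k <- ncol(v); gm <- mean(v)
  ssg <- n * sum((colMeans(v) - gm)^2)
  sss <- k * sum((rowMeans(v) - gm)^2)
  sse <- sum((v - gm)^2) - ssg - sss
  (ssg / (k - 1)) / (sse / ((n - 1) * (k - 1)))
}
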