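---
title: "Quantifying the visual streak: stereology, the RPE hexagon model, and permutation-FDR proteomics"
author: "streakmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the visual streak}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streakmorph)
```

## The problem

Some mammals concentrate their photoreceptors not in a fovea but in a
*visual streak*: a horizontal band of elevated cone density supporting
high-acuity vision along the horizon. Characterizing such a region
quantitatively means answering a chain of questions from a set of
stained cryosections: how dense are cones and rods at each
eccentricity, how does their ratio change, how big and how tall are the
retinal pigment epithelium (RPE) cells underneath, how much
outer-segment phagocytosis are those cells doing, and which proteins
distinguish the central from the peripheral tissue. `streakmorph`
implements that chain as a reusable, tested pipeline, together with a
synthetic-section generator so every stage can be validated against
known ground truth.

## Photoreceptor stereology

Counts are made in windows of 100 µm (dorsoventral extent) by 12 µm
(section thickness), i.e. 1,200 µm². Cone outer segments are counted
directly, so the cone density is simply

$$\rho_{cone} = n_{cone} \cdot \frac{10^6}{w\,t} \quad [\mathrm{mm^{-2}}].$$

Rods are too numerous to count one by one; they are estimated
stereologically from the outer nuclear layer (ONL): with $r$ ONL rows
of rod nuclei of mean diameter $d$, a window holds
$r \cdot (w/d) \cdot (t/d)$ rods, scaled to mm² the same way. Counts
stay fractional throughout; rounding happens only in display. The
rod-to-cone ratio (RCR) uses cone density as the denominator because
cone density never vanishes anywhere in the retina, while rod density
does in a fovea.

Aggregation is fixed at two levels, mirroring the sampling design:
sections are averaged within an animal, then means, SDs and quantiles
are taken across animals — the reported SD is the between-animal one.
The RCR of an animal is the ratio of that animal's mean densities, not
the mean of per-section ratios: a per-section ratio carries a Jensen
bias of order $CV^2$ of the denominator count (about +3% at these
window sizes), whereas the per-animal ratio reduces it by the number of
sections. `densityReport()` also exposes the ratio-of-regional-means
estimator; on homogeneous data the two agree closely.

## The RPE mosaic: 1-D distances, artifact filtering, hexagon areas

RPE cell size is measured in one dimension: the x-coordinates of
nucleus centers along 250 µm dorsoventral segments. Two artifacts
contaminate the raw internuclear distances. Some RPE cells are
*binucleate* — their two nuclei produce one spuriously tiny gap — and
occasionally a nucleus is missed entirely (*dropout*), producing one
spuriously huge gap. Both are handled by a median-threshold filter:
with $M$ the median of the **raw** distances of a segment population,

* a gap $< M/2$ is classified `binucleate`,
* a gap $> 2M$ is classified `dropout`,
* boundary gaps (exactly $M/2$ or $2M$) are `normal` (strict
  inequalities).

The filter is a single pass: the median is computed once on the raw
distances, and corrections never trigger re-classification. For a
binucleate pair the two nuclei are replaced by their midpoint (one
cell) and distances are recomputed; dropout gaps are excluded from the
distance statistics while their flanking nuclei are retained (no
imputation). An alternative `correction = "exclude"` mode simply drops
the flagged gaps, leaving binucleate cells out of the area calculation;
midpoint correction is the default. Chains of consecutive
sub-threshold gaps are resolved greedily left-to-right and counted.
Two consequences of the single-pass design are deliberate: a gap
flanking a merged pair shrinks by half the nucleus offset and may end
slightly below $M/2$ without being re-flagged, and under spacing noise
the filter trims small gaps slightly more often than large ones,
biasing the mean corrected distance upward by a few tenths of a
percent.

The mosaic is then idealized as a packing of regular hexagons whose
apothem is half the internuclear distance $D$. For side $a$:
$h = \frac{\sqrt3}{2}a$, $D = 2h = \sqrt3\,a$, and the cell area is

$$A = 3\,h\,a = \frac{\sqrt3}{2} D^2.$$

At a streak-typical $D = 19.16\ \mu m$ this gives $317.9\ \mu m^2$; at
a peripheral $D = 22.59\ \mu m$, $441.9\ \mu m^2$. Two area estimators
are exposed, because they differ by Jensen's inequality: the mean of
per-distance areas (larger) and the area at the mean distance. Which
one a study reports matters at the 1% level; `MosaicResult` carries
both. The geometry is tested against an independent shoelace
polygon-area oracle to $10^{-9}$ relative error.

Binucleate bookkeeping follows the convention of reporting flagged
cells per raw nucleus (64 flagged among 454 nuclei reads 14%);
`MosaicResult` additionally carries the flagged-cells-per-cell
fraction, which is the direct estimator of the per-cell binucleate
probability and is what recovery tests compare against the generator's
truth. When dropouts are present, a binucleate pair that loses one
nucleus becomes undetectable, so the recovered fraction is lower than
the planted probability by roughly the factor $(1-p_{drop})^2$ — a
property of the measurement, not a defect of the filter.

## Group statistics

Tests run on per-animal means (one value per animal per region):
two-tailed paired t for two regions; for three, a one-way
repeated-measures ANOVA followed by all three pairwise paired t-tests
with Bonferroni correction ($p_{adj} = \min(1, 3p)$). The
Greenhouse–Geisser epsilon is applied to the omnibus degrees of
freedom *unconditionally*: sphericity in a 3-level within-subject
design with five animals is essentially untestable, and unconditional
correction is conservative and reproducible. Epsilon is computed from
the double-centered covariance of the animals × groups matrix and
clamped to $[1/(k-1), 1]$. A Shapiro–Wilk p-value is reported alongside
every paired test as an advisory screen; it never gates the pipeline.
Degenerate inputs are flagged rather than mis-tested: zero-variance
paired differences yield an explicit note with the effect size, and
identical groups yield $F = 0$, $p = 1$. Significance stars follow the
strict convention `*` < 0.05, `**` < 0.01, `***` < 0.001,
`****` < 0.0001.

## Differential protein abundance

The proteomics stage starts from a proteins × samples intensity matrix
(missing cells allowed) and follows the standard
filter–transform–test sequence:

1. **Group-completeness filter** — keep proteins quantified in *all*
   replicates of at least one group (idempotent).
2. **log2 transform** — guarded: non-positive intensities and double
   transformation are errors.
3. **Two-sample t per protein** (pooled-variance Student by default,
   Welch optional), available-case with a minimum of two observations
   per group; missing values are never imputed.
4. **Permutation FDR** — group labels are permuted as whole columns,
   the same permutation for every protein, preserving between-protein
   correlation. With $c_b(i)$ the number of null $|t|$ values in
   permutation $b$ at or above $|t_i|$, and $o(i)$ the number of
   observed ones,
   $$q_i = \mathrm{mean}_b\, c_b(i) \,/\, o(i),$$
   monotonized to be non-increasing in $|t|$ and capped at 1. A
   protein is significant when $q < 0.05$. 250 permutations are the
   default; when fewer distinct assignments exist, they are enumerated
   exhaustively and the result flagged.

Three design choices deserve justification:

* **The observed assignment (and, for equal group sizes, its mirror
  image) is excluded from the null.** In tiny designs the exhaustive
  null otherwise contains the observed labeling itself: with 3 vs 3
  samples it receives weight 2/20, which floors every q-value at 0.1
  and makes the procedure blind to even enormous effects.
* **Mean, not median, tail-count aggregation (default).** The median
  of the per-permutation counts is 0 at the top-ranked protein for
  about half of *pure-null* datasets (the observed maximum is
  essentially exchangeable with the permutation maxima), which yields
  q = 0 and a false discovery. The mean estimator keeps the realized
  false-discovery proportion on null matrices at the nominal level
  (measured at 0.06 over 100 null matrices in the acceptance suite).
  Both aggregations are exposed via `aggregate=`.
* **`s0` moderation.** With very few replicates the plain t has heavy
  null tails — a protein with a luckily small within-group variance
  produces $|t| > 8$ far more often than Gaussian intuition suggests
  ($P(|t_4|>8)\approx 10^{-3}$, i.e. ~2 exceedances per permutation
  among 2,000 proteins) — which caps the sensitivity of any tail-count
  FDR estimate regardless of effect size. The classic remedy is the
  SAM fudge factor $s_0$ added to the denominator of t; `s0 = "auto"`
  uses the median per-protein standard error. The default remains
  `s0 = 0` (the plain two-sample t); power analyses in the acceptance
  suite use `s0 = "auto"` and reach 100% sensitivity on planted
  log2FC = 2 effects at SD 0.3, n = 3 vs 3, where the plain t
  recovers about a quarter of them.

Two biological replicates per group, as constrained studies sometimes
have, cannot support permutation inference at all; the module warns
below three.

## The synthetic generator

`gerbilTruthDefaults()` fixes the generating parameters at the
measured values of the gerbil retina wherever a measurement exists:
cone rates of 60.79 / 45.29 / 34.17 per window (equivalent to
50,660 / 37,743 / 28,476 cones/mm²) for streak, near and far
periphery; ONL rows chosen so that, with 5 µm nuclei, rod stereology
returns 345,014 / 339,391 / 312,946 rods/mm²; RPE spacing means of
19.16 / 21.0 / 22.59 µm; binucleate probabilities 0.14 / 0.12 / 0.10
and dropout probabilities 0.04 / 0.045 / 0.05; RPE heights
12.08 / 9.5 / 7.0 µm; and a streak phagosome rate 1.393× the
peripheral one (a 39.3% elevation). Five animals with four sections
each is the default design.

Distributional families are declared choices, not measurements: counts
are Poisson (maximum-entropy for a count given a mean), continuous
quantities are Gaussian truncated at zero via the probability-integral
transform (so the RNG call count per draw is fixed and downstream
draws stay reproducible), and RPE spacings are Gamma with the stated
mean and a per-gap CV of 0.2 — Gamma keeps spacings positive with the
mild right skew real mosaics show, and 0.2 is a realistic regularity
for an epithelial monolayer (at that CV a *normal* gap almost never
falls below the half-median threshold, so planted binucleates — at a
3 µm within-cell offset, far below half the ~19 µm spacing — dominate
the flagged class by construction). Quantities no measurement pins
down (outer-segment lengths per region, the absolute phagosome rate,
the per-section SDs) are fixed once at values typical for rodent
retinas and are not tuned.

The generator emits annotation-level tables — exactly what manual
counting produces — not images. It therefore validates the analysis
chain, not segmentation or staining: passing recovery tests show the
estimators are consistent and the filter recovers planted structure,
but say nothing about observer bias, section-quality selection, or
real spatial correlation between neighboring sections, none of which
are modeled (sections are independent draws).

## Numerical conventions and problem sizes

Medians of even-length lists are the mean of the two central values.
Exact-boundary gaps classify as normal. Seeds are explicit arguments
everywhere; the same seed gives byte-identical outputs (the writers
serialize doubles at 17 significant digits so files round-trip
exactly). The test suite sizes its simulations for tight turnaround
while keeping Monte-Carlo error well below the tolerances tested:
10,000 windows for moment recovery, ~5,300 cells for classifier
recovery, 200 replicate studies for the RCR eccentricity ordering,
10,000 null replicates for paired-t calibration, and 100 null
matrices × 250 permutations for false-discovery control.

## Known limitations

The hexagon model converts a 1-D distance into an area through a
perfect-packing idealization; it does not measure 2-D mosaic disorder
(no Voronoi analysis), and the two area estimators bracket rather than
resolve the per-eye averaging a given study may have used. The
artifact filter assumes binucleate offsets well below half the median
spacing; mosaics with strongly bimodal spacing would confuse it. The
RM-ANOVA applies the Greenhouse–Geisser correction always, which is
slightly conservative under true sphericity. And with two replicates
per group the proteomics stage degrades to a warning — no estimator
rescues permutation inference at that size.
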