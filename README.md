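# streakmorph

Quantitative morphometry of retinas with a **visual streak** — the
horizontal band of elevated cone density that gives some mammals
high-acuity vision along the horizon — and of the retinal pigment
epithelium (RPE) monolayer beneath it. The package is written for
vision scientists who annotate stained cryosections by hand and need
the downstream numbers to be reproducible: photoreceptor densities and
rod-to-cone ratios, RPE mosaic geometry, phagosome loads, group
statistics, and differential protein abundance.

## What it computes

**Photoreceptor stereology.** Cone density from counts in
100 µm × 12 µm windows, `ρ = n · 10⁶ / (w·t)` per mm²; rod density
from outer-nuclear-layer stereology, `r · (w/d) · (t/d)` rods per
window with `r` ONL rows and nucleus diameter `d`; and the rod-to-cone
ratio RCR = ρ_rod / ρ_cone, formed per animal from that animal's mean
densities. Aggregation is always sections → animal → region.

**RPE mosaic model.** Internuclear distances along 250 µm segments
are cleaned with a median-threshold filter — gaps below half the raw
median are binucleate-cell artifacts (merged to their midpoint), gaps
above twice the median are missing-nucleus artifacts (excluded) — and
converted to cell areas by a regular-hexagon idealization with apothem
D/2:

    A = 3·h·a = (√3 / 2) · D²,   a = D/√3,   h = D/2.

**Group statistics.** Paired two-tailed t (2 regions) or
repeated-measures one-way ANOVA with unconditional Greenhouse–Geisser
correction plus Bonferroni-adjusted pairwise paired t (3 regions), on
per-animal means; Shapiro–Wilk reported as an advisory screen.

**Proteomics.** Group-completeness filtering, log2 transform, and
per-protein two-sample t-tests with permutation-based FDR (whole-column
label permutations, tail-count q-values, 250 permutations, q < 0.05).

**Synthetic ground truth.** A generator emitting annotation tables,
1-D RPE nucleus traces (with planted binucleates and dropouts) and
log-normal protein matrices (with planted fold-changes) at parameters
anchored to measured gerbil-retina values, so every stage is testable
end to end.

## Worked example

```r
library(streakmorph)

sec <- simulateSections(gerbilTruthDefaults(), seed = 42)
densityReport(sec)[c("region", "cone_density_mean", "rcr_mean")]
#>  region cone_density_mean rcr_mean
#>      FP          30291.67    10.44
#>      NP          37291.67     9.52
#>      VS          53208.33     6.41
```

The simulated streak (VS) recovers its generating cone density
(50,660/mm², here 53,208 ± 3,276 across five animals) and the RCR
rises from ~6.4 in the streak to ~10.4 in the far periphery — the
low-ratio signature of a high-acuity region. Mosaic analysis of one
simulated streak trace:

```r
p <- gerbilTruthDefaults()$VS
tr <- simulateRpeTrace(p, segmentLength = 2000, seed = 42)$trace
analyzeTrace(tr)
#> MosaicResult (A1, VS; correction = midpoint)
#>   118 raw gaps, median 17.53 um; thresholds [8.76, 35.05] um
#>   gaps: 99 normal, 18 binucleate, 1 dropout
#>   binucleate fraction 15.1% (of nuclei), dropout fraction 0.8%
#>   mean corrected distance 19.09 um; cell area 328.7 um^2 (per-distance),
#>   315.5 um^2 (from mean D)
```

The filter flags the planted binucleate pairs (truth: 14% of cells),
and the corrected mean distance returns the generating 19.16 µm
spacing; `hexagonArea(19.16)` is 317.9 µm². Regional differences are
then tested on per-animal means:

```r
metricStats(sec, "rcr")[c("comparison", "statistic", "p_value",
                          "adjusted_p", "stars")]
#>  comparison statistic  p_value adjusted_p stars
#>     omnibus     54.97 0.001310    0.00131    **
#>    VS vs NP     -5.89 0.004160    0.01250     *
#>    VS vs FP     -9.30 0.000743    0.00223    **
#>    NP vs FP     -6.49 0.002910    0.00873    **
```

`runPipeline(runConfig(...))` chains all stages on TSV inputs and
writes `densities.tsv`, `mosaic.tsv`, `stats.tsv`, `diff_results.tsv`
and a checksummed `manifest.json`; `inst/scripts/streakmorph.R` wraps
the same calls for the shell.

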