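---
title: "Methods: whole-plant drought physiology, association scans and candidate genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-plant drought physiology, association scans and candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drylysim)
```

drylysim implements an integrated analysis of genotypic drought responses in
asparagus bean (*Vigna unguiculata* ssp. *sesquipedalis*): gravimetric
lysimeter physiology, a segmented transpiration-versus-soil-water model,
ordinal visual drought scores, a Q+K marker-trait association scan,
microarray differential-expression filtering, and DEG-SNP co-localization.
This vignette documents the models, the tunable parameters and the design
choices, and states precisely what the synthetic-data generator does and
does not emulate.

## Lysimetric physiology

A plant sits in a pot inside a water-filled container on a load cell. The
container drains through an overflow hole, so every irrigation-drainage
cycle returns the system to a reproducible base weight; in between, the
covered soil surface means the container weight falls solely through
transpiration. From the raw weight trace the package derives:

* **PDT** (plant daily transpiration): the mean weight over a predawn
  window minus the mean over an evening window of the same day, each a
  30-min average. Defaults: 04:30-05:00 and 19:30-20:00 local time; the
  windows are configuration, since "before dawn" and "in the evening"
  depend on the greenhouse.
* **dPW** (daily weight gain): the difference of post-drainage morning
  weights of consecutive days. Because drainage resets the water store to a
  fixed level, this difference is attributed to plant biomass gain. A
  morning qualifies only if a drainage-complete marker occurred within the
  preceding 24 h — otherwise (e.g. during drought) the day is skipped, never
  silently imputed.
* **WUE**: the ordinary-least-squares slope of cumulative biomass gain on
  cumulative transpiration over the pretreatment phase. The cumulative
  series are rebuilt from the days that carry *both* measurements; this
  matters because the first morning of a run has no preceding drainage and
  must not enter as a zero gain (doing so biases the slope upward by
  roughly 15-20% at typical growth rates).
* **Transpiration rate**: the negative first derivative of the smoothed
  weight. Smoothing is a centered moving average (default window 30 min)
  with a Savitzky-Golay option; both preserve the daily integral to first
  order, and the choice is configuration because the raw-noise spectrum of
  a load cell varies by installation. Irrigation intervals are masked
  before differentiation.
* **ETW**: rate normalized to plant weight and vapor pressure deficit,
  `ETW(t) = rate(t) / W(day) / VPD(t)` in g g^-1 kPa^-1 min^-1. `W(day)` is
  the plant weight on the morning of each day: a required initial weight
  plus accumulated dPW, extrapolated through the drought phase as
  `WUE x PDT` because there are no drainage resets to measure against. VPD
  uses the Tetens saturation formula; ETW is undefined below a VPD floor of
  0.1 kPa (nighttime values are never used downstream, and the floor
  prevents division blow-ups).

A day is valid when at least 90% of its expected samples are present;
invalid days are flagged, not dropped. Soil-probe permittivity converts to
volumetric water content through the cubic Topp calibration with
overridable coefficients; downstream analyses use soil water content
*relative* to pot capacity, which is what the transpiration response is
plotted against.

## The segmented water-response model

For each plant, one midday point per drought day pairs the median ETW over
an 11:00-14:00 window with the mean relative soil water content (SWC) over
the same window. The response is a continuous plateau-hinge:

$$ETW(s) = E_{max} \;\; (s \ge \theta_{cr}); \qquad
  ETW(s) = E_{max} - slope\,(\theta_{cr} - s) \;\; (s < \theta_{cr})$$

Continuity at the breakpoint is enforced — the biology is a gradual
stomatal limitation, not a jump. At a fixed breakpoint the model is linear
in $(E_{max}, slope)$, so the fit grid-searches the breakpoint over the
observed SWC range (step 0.005 relative-SWC units, candidates keeping at
least two points strictly below and one at or above), solves the
conditional least-squares problem, then refines the best candidate with a
local optimizer. Ties in residual sum of squares break toward the smallest
breakpoint: the conservative reading is the earliest stomatal response.
Grid search was chosen over derivative-based segmented regression because
the per-plant point count (about 7-14) makes gradient methods fragile. If
no breakpoint beats a flat line, the flat fit is returned with an explicit
`no_breakpoint` flag rather than a fabricated parameter.

Genotypes are compared parameter-by-parameter with pairwise Welch t-tests
on per-plant fits (mean +/- SE per genotype), summarized by a compact
letter display built by the insert-absorb algorithm: genotypes sharing a
letter are not significantly different at the chosen alpha (default 0.05).

Two aggregation modes exist in the field — pooling points across plants
before fitting versus averaging per-plant fits. The package fits per plant
and aggregates, which keeps the genotype comparison an honest
between-plant test; pooling can be emulated by passing concatenated point
sets to `fit_segmented()`.

## Visual scores and correlations

The senescence-of-unifoliates index maps the senesced leaf-area fraction
to 0-5 through closed-right bins of width 20% (`ceiling(5 f)`), with 0
reserved for no senescence and 5 for complete senescence or a dead/fallen
plant. The printed scale leaves the (80%, 100%] band without a number; the
package assigns 5, completing the scale monotonically. Wilting and
stem-greenness scores are validated 0-5 inputs — their published anchors
define only the endpoints. Leaf relative water content is
`(FW - DW)/(TW - DW) x 100`.

Cross-year trait correlations average replicates per accession first, then
correlate trait-year vectors across accessions (Pearson by default;
Spearman is offered because the scores are ordinal). Cells with p above
alpha are masked, mirroring significance-filtered correlation tables, and
pairs sharing fewer than 10 accessions are skipped.

## Association scan

Traits enter as replicate-mean scores per accession and year. Two models
are fitted per marker:

* **GLM**: least squares of trait on intercept, the structure proportions
  Q (last column dropped, because rows sum to one) and marker dosage; the
  marker term's partial F test gives the p-value and its partial R^2 the
  variance explained.
* **MLM**: $y = X\beta + u + e$ with $u \sim N(0, \sigma_g^2 K)$,
  $e \sim N(0, \sigma_e^2 I)$. The variance ratio is estimated once by
  REML on the null model through the spectral decomposition of K and then
  held fixed for every marker test (the
  population-parameters-previously-determined shortcut, standard at panel
  sizes near 100). After rotating by the eigenvectors and whitening by
  $(\lambda_i + \delta)^{-1/2}$, each marker test is ordinary least
  squares, so with K = I the MLM collapses exactly onto the GLM — a
  property the test suite asserts to 1e-6.

Missing genotype calls are mean-imputed per marker (panel is inbred, coded
0/2); monomorphic or covariate-collinear markers are flagged, not
scanned. P-values are capped at 1e-16 so that perfect fits print as a
finite -log10(P) of 16 with a flag. A marker is declared significant for a
trait when -log10(P) exceeds 3 in at least two distinct (model, year)
combinations; the threshold follows the stated significance rule and the
consistency minimum of two reflects that reported loci always carry at
least two supporting detections. The looser P < 0.01 reading that appears
alongside is exposed as a parameter (`threshold = 2`), with 3 the default.

## Expression filtering

The pipeline starts from a gene-level intensity matrix (probe
summarization is upstream and out of scope). Columns are quantile
normalized (cross-sample mean of order statistics, ties averaged — the
implementation delegates to limma), replicate quality is checked by
within-condition Pearson correlations on the log2 scale, and each
genotype-by-tissue drought-versus-control contrast gets a per-gene Welch
t-test on log2 intensities. The test behind the published FDR is not
named in the source methods; Welch on the log scale is the default here
and is documented as a choice. Benjamini-Hochberg adjustment is applied
within each contrast, because DEG sets are reported contrast-wise. DEGs
require fold change >= 2 (|log2 FC| >= 1) and FDR <= 0.01, both
inclusive. Venn-style shared/unique counts per direction across the two
genotypes, and family profiles (e.g. the 52 aquaporins on the array, of
which the drought-regulated, tissue-specific and genotype-specific members
are counted), are bookkeeping on the filtered records.

With triplicates, the Welch statistic has only 2-4 degrees of freedom and
its attainable p-values are floored near 1/t^2; recovering planted
two-fold effects at FDR 0.01 therefore requires low residual noise. The
generator's default log2-scale noise (sd 0.07) is calibrated for that
regime; it produces replicate correlations in the high 0.9s rather than
the wider 0.944-0.993 band of a full-size array experiment, a deliberate
trade-off documented here and in the generator help.

## Co-localization

Candidates are DEGs in linkage disequilibrium with significant SNPs, by
either route:

* **Genetic map**: same linkage group and distance coincident (0 cM) or
  strictly less than 2 cM — the stated LD-decay window, with the strict
  inequality adopted for the non-coincident case because the wording
  separates "coincident with" from "< 2 cm from".
* **Ortholog physical**: both sides mapped to a common assembly by their
  best BLAST hit (aligned length >= 80 bp, e-value <= 1e-10; best = lowest
  e-value, ties by bitscore then alignment length). A pair qualifies on
  the same chromosome when the edge gap between hit intervals (zero when
  overlapping) is at most 1.8 Mb, inclusive, since that maximum "was
  allowed"; the midpoint distance is reported alongside. The edge gap is
  used because unigene hits are intervals, and the closest-ends reading is
  the conservative LD-window interpretation.

The two candidate lists deduplicate by (gene, SNP), with pairs supported
by both routes marked as such.

## The synthetic-data generator

Every input has a generator with known ground truth: diurnal climate
(sinusoidal 15-34 degC, anti-phase humidity), lysimeter runs
(pretreatment/drought/recovery phases, nightly irrigation-drainage cycles,
the piecewise transpiration law, biomass accumulating as WUE times
transpired water and appearing on the scale at drainage resets), a
95 x 1127-style inbred panel with two Balding-Nichols subpopulations, Q,
VanRaden kinship and liability-based 0-5 scores (equal-probability bins
under the null), a 2 genotypes x 2 tissues x 2 treatments x 3 replicates
log-normal intensity matrix with planted log2 fold changes, and map/BLAST
fixtures with exactly the requested number of DEG-SNP pairs inside the
co-localization windows (planted pairs use SNPs isolated from all others,
so recovery is exact by construction).

Default physiology is calibrated to a realistic bean seedling on a 4-L
pot: plateau ETW 0.002 g g^-1 kPa^-1 min^-1, critical relative SWC 0.4,
decline slope 0.007 per unit SWC (near closure before the pot dries out),
WUE 0.05 g/g, 20 g initial plant weight, 1000 g pot water capacity,
load-cell noise 0.5 g, and 5% multiplicative fluctuation on the
instantaneous transpiration rate. Pot capacity and soil parameters are
configuration, not inferred from any published value.

What the generator does **not** emulate — and therefore what passing tests
do not demonstrate about real data: linkage disequilibrium beyond
subpopulation structure (no coalescent history), soil physics (no
Richards-equation water redistribution, no evaporation), canopy energy
balance, probe-level array artifacts, genotype-by-environment interaction
across years (year effects are independent noise), and scorer bias in the
visual scales.

## Numerical choices and problem sizes

Breakpoint grid step 0.005 relative-SWC units; p-value cap 1e-16; VPD
floor 0.1 kPa; QC defaults MAF >= 0.05 and missingness <= 0.20; REML
search over log variance ratio in [-12, 12]. Degenerate inputs return
flags or typed errors (`no_breakpoint`, invalid schedule, empty panel)
rather than numbers.

The test suite exercises the recovery studies at desk scale chosen as the
package's own verification design: the segmented-fit study uses 200 seeds
of 7 plants at 15-min sampling (median breakpoint error well inside 0.02
relative-SWC units; median slope error inside 15%), the WUE study 20
seeds at the logger's native 3-min sampling (all errors inside 10%), the
permutation calibration 500 permutations of a 95 x 200 panel, and the
co-localization oracle 100 x 39 random placements. End-to-end breakpoint
recovery carries a slightly wider tolerance (0.015) than the fit-level
grid bias (0.005) because the midday point is a chord average of falling
soil water, an observation effect the real instrument shares.

## Known limitations

Per-marker variance explained is the partial R^2 on the (whitened) scale
and is not additive across loci. The MLM holds the variance ratio at its
null-model estimate; for strongly associated markers this understates the
polygenic adjustment slightly, the standard trade-off of the one-pass
approximation. The Welch default for expression is conservative at n = 3;
a moderated-variance test would gain power but would depart from the
plain two-sample reading of the published filter. Scores are treated as
interval data in the Pearson default; the Spearman option is provided
where that approximation is uncomfortable.
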