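---
title: "Methods: from unigene set to validated expression calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from unigene set to validated expression calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoarray)
library(dplyr)
```

oligoarray re-implements the computational backbone of a custom
long-oligonucleotide two-color expression microarray: building the probe set
from an EST-derived unigene collection, screening it for specificity,
and analysing the dye-swap hybridizations it produces — through
normalization, permutation-based differential expression, replicate power
planning, qPCR cross-validation and downstream set analysis. This vignette
explains the models and procedures, the parameters that matter, and the
choices made where the design was genuinely open.

## Sequence pre-clustering

ESTs are cleaned (exact adaptor trimming; low-complexity masking by windowed
Shannon entropy, default window 16 nt and threshold 1.2 bits) and grouped by
single-linkage over pairwise local alignments: two reads are linked when
their best Smith-Waterman alignment reaches **90% identity over at least 30
aligned bases**. Identity is counted over aligned columns including internal
gaps; both strands are compared because ESTs are unoriented; masked bases are
rewritten to distinct out-of-alphabet letters on the two sides before
alignment so they can never produce a match. Clusters are connected
components labelled by their lexicographically smallest member, which makes
the output invariant to input order.

The 90%/30 bp rule is applied to the single best-scoring local alignment of
each pair, not to cumulative coverage across multiple alignments — the
looser reading would only merge more, and the threshold pair is the
operative contract. The alignment itself is a full dynamic-programming
Smith-Waterman (linear gap penalty, deterministic traceback) implemented in
C++; at the scale this package targets a banded or seeded heuristic would
buy nothing and would add a seed-length parameter whose value the alignment
result should not depend on. The test suite checks the resulting partitions
against an independent implementation (Biostrings) on randomized instances
with planted homologous blocks.

The masking default is mononucleotide entropy; a dinucleotide-aware mode
(entropy of overlapping dinucleotides divided by two, an entropy-per-base
rate on the same 0-2 bit scale) additionally catches short-period repeats
such as `ACGTACGT...` whose base composition is perfectly balanced.

## Probe design

One probe per unigene is chosen among all windows with length 65 ± 5 nt
whose 3'-most base lies within 1000 nt of the unigene 3' end (expression is
measured with 3'-biased labelling, so probes far from the 3' end see less
target). Hard constraints:

| parameter | default | meaning |
|---|---|---|
| `tm_target` ± `tm_tol` | 67 ± 3 °C | nearest-neighbor duplex melting temperature |
| `length_target` ± `length_tol` | 65 ± 5 nt | probe length |
| `gc_target` ± `gc_tol` | 43 ± 5 % | GC content |
| `max_dist_3prime` | 1000 nt | distance of probe 3' end to unigene 3' end |
| `max_stem` | 8 nt | longest hairpin stem (loop ≥ `min_loop` = 3 nt) |
| `max_selfdimer` | 12 nt | longest self-complementary stretch between two copies |

Among feasible windows the selected probe minimises
`|Tm − 67| + |GC − 43| + stem + selfdimer + 0.001·dist3'`: constraint
closeness dominates and the small 3'-distance term breaks near-ties in
favour of 3'-proximal windows, with a deterministic (`dist3'`, start)
tie-break after that. A unigene with no window at all is reported missing
as `too_short`; one with windows but no feasible one as
`no_window_meets_constraints`. The design report always partitions the
input: designed plus missing equals the number of unigenes.

**Tm model.** Unified nearest-neighbor thermodynamics (the standard ΔH/ΔS
table with per-terminal initiation terms), an entropy salt correction
`0.368·(L−1)·ln[Na+]`, and the duplex-fraction term `R·ln(CT/4)` for
non-self-complementary strands. Defaults are `oligo_nM = 50` and
`na_mM = 50`. The salt default deserves a note: vendor Tm models are never
disclosed, and the choice of [Na+] shifts all Tm values together. At
150 mM, 65-mers with GC ≥ 38% essentially all melt above 70 °C, so the
design windows above would be mutually inconsistent; at 50 mM — ordinary
hybridization-buffer ionic strength — a 43%-GC 65-mer sits near 67 °C and
the windows select non-trivially. Both parameters are exposed in
`probe_constraints()` and in the pipeline config.

**Structure scores.** Full free-energy folding is out of scope; the two
exact-pairing scores (longest hairpin stem with a minimum loop, longest
reverse-complementary stretch against a second copy) are cheap, monotone
proxies used as caps, validated against brute-force enumeration in the
tests.

## Cross-hybridization screen

A designed probe is flagged when some *other* unigene has **both** more than
70% overall identity to the probe **and** a contiguous identical stretch of
more than 20 nt (both inequalities strict, per the screening rule the array
was published with). "Overall identity" is counted over the probe length —
probe bases the local alignment leaves out count as mismatches — which is
the conservative reading; identity over aligned columns is available as a
switch (`denominator = "alignment"`). Both strands of every target are
screened. The report records each probe's worst-case hit, so the flag is
monotone: lowering either threshold never unflags a probe.

## Spot-level QC

The spot table is a strict tab-delimited subset of GenePix-results
conventions (per-channel foreground/background, control class, manual
flag). Flagged spots are excluded from every statistic. Local background is
reported as the median of the up-to-four surrounding-region medians but is
*not* subtracted — no background correction is applied anywhere in the
pipeline, matching the acquisition convention the package emulates.

Background noise is estimated from the negative-control (NC) spots of each
slide: a gene is called expressed in a channel when its foreground strictly
exceeds `median(NC) + 2·SD(NC)` (sample SD; both the multiplier and the
combination are config keys, and per-channel, union and intersection calls
are all available since the published convention does not say which was
used). Presence across an experiment requires the call in at least 5 of 6
hybridizations.

Spot filtering before normalization retains spots whose foreground exceeds,
in **both** channels, the 90th percentile of the empty/negative control
intensities plus twice their SD. The published description of this filter
is garbled ("a median of 90 percent of the control spots plus twice the
deviation standard"); the percentile-plus-SD reading is the closest
consistent interpretation, and both knobs (`filter_percentile`,
`filter_sd_multiplier`) are exposed rather than hard-coded.

## Normalization and differential expression

Per slide, `M = log2(R/G)` and `A = ½·log2(RG)` are computed from
foreground intensities of unflagged probe spots; control spots are excluded
from the fit. A loess regression of M on A (span 0.4, degree 1, tricube
weights, symmetric family with 2 robustness iterations) is subtracted:
`M' = M − fit(A)`. A is never changed. The span default is a compromise:
small enough to track the curvature dye bias shows at low intensity, large
enough not to chase differential expression; it is a config key.

Observations enter inference as dye-corrected values: hybridizations with
swapped dye orientation contribute `−M'`. Two tests are run per gene:

* **Linear fit** — the one-parameter model "mean corrected log2 ratio",
  with an ordinary one-sample t against 0 and two-sided p, BH-adjusted
  across testable genes. Genes with fewer than 2 observations are
  untestable; a zero-SD gene with nonzero mean gets a `t = Inf` sentinel
  and is excluded from BH (its evidence is assessed by the permutation test
  instead); an all-zero gene gets `p = 1`.
* **SAM-style permutation test** — `d = mean/(s + s0)` with `s` the
  per-gene SD and `s0` the 5th percentile of the `s` distribution (the full
  `s0` search is deliberately replaced by this percentile rule for
  determinism; the quantile is a parameter). The null distribution comes
  from sign-flip permutations of the observation columns — the natural null
  for a one-sample dye-swap design — and the per-gene FDR is the median
  permuted count of `|d|` values at or above `|d_i|` over the observed
  count, capped at 1 and made monotone non-increasing in `|d|`.

The published analysis used an empirical-Bayes moderated linear model; this
package deliberately uses the ordinary per-gene fit and documents the
difference — the consensus list (genes significant under both the linear
and the permutation test, with provenance retained) is the robust output.

Calibration is part of the test suite: on 1000-gene null fixtures the
linear-model p-values are approximately uniform (KS < 0.05) and the SAM
empirical false-positive proportion at nominal FDR 0.05, averaged over 20
seeded replicates, stays at or below 0.08; planted log2 folds at 6
observations and SD 0.3 are recovered with |bias| < 0.05 and RMSE < 0.15.

## Replicate power planning

Replicate variability is summarised per feature as the CV (percent sample
SD over mean) of raw mean intensities across the 6 hybridizations (2 dyes ×
3 biological replicates), with CV ranks expressed on a 100-based scale and
the P90 reported as the order statistic at rank 90.

Power statements use a two-sample t-test. Under the default lognormal
model, a raw-scale CV maps to the log-scale SD `σ = √ln(1 + cv²)` and the
test is the equal-variance t on log values with noncentrality
`ln(fold)/(σ·√(2/n))` and `2n − 2` df; this is the natural model when
ratios are analysed in log2. An additive model (group SDs `cv·mean`,
Welch-Satterthwaite df) is provided alongside because the software
originally used for these estimates, and hence its model, is not stated;
the two agree to a few percent over the relevant grid, with the additive
model slightly more conservative. With the default model, 6 measurements
per group at CV 35% detect a 2-fold change with ≈ 95% power at two-sided α
= 0.10, and a 1.5-fold change remains detectable at 90% power up to CV
≈ 22.6% — both statements are recomputed by `scripts/acceptance.R` and
verified against a seeded Monte-Carlo simulation of the t-test.
`min_detectable_fold()` and `max_cv_for_power()` invert the power function
by bisection to a relative tolerance of 1e-4. The α = 0.10 used in these
planning statements is a reporting convention of the statements themselves;
the stricter α = 0.01 remains available as a parameter.

## qPCR quantification

Target Cts are normalized to the arithmetic mean Ct of a 3-gene reference
panel — equivalent to the geometric mean of reference expression levels —
as `2^(−(Ct_x − mean(Ct_refs)))` after averaging technical replicates.
A published rendering of this formula shows a positive exponent, which
would invert the Ct-expression relationship; that form is almost certainly
a typesetting loss of the minus sign, so the standard negative-exponent
convention is the default and the as-printed form is retained as an
explicit option (`convention = "as_printed"`) rather than silently
corrected. Amplification efficiency is the exponent base (default 2.0,
per-gene bases settable).

Reference genes are ranked by the geNorm-style stability measure M: for
each candidate, the mean over other candidates of the SD across samples of
their pairwise Ct difference (identically, of the pairwise log2 expression
ratio at perfect efficiency). The default is a single-pass ranking — the
use case is picking a top-3 panel — with the original iterative
worst-candidate elimination available as `method = "iterative"`.
Platform agreement between microarray and qPCR log2 ratios is reported as
the Pearson correlation plus the sign-concordance fraction, the two
quantities practitioners actually compare.

## Downstream set analysis

A gene is tissue-specific for condition T when it is up-regulated in T in
both pairwise comparisons involving T; the three-set Venn partition is
computed exactly (seven disjoint regions whose sizes sum to the union).
Functional enrichment uses Fisher's exact test per term on the 2×2 table of
set/background term hits, two-sided by convention (sum of table
probabilities at or below the observed), BH-adjusted across terms, with the
full probe set of the array as the natural background. Genes absent from
the annotation map still count in the set and background sizes; annotation
counting is per gene-term pair, deduplicated per gene. GO-graph
propagation is out of scope — term maps are taken as given.

Hybridization profiles are clustered agglomeratively with Euclidean
distance and average linkage (UPGMA); genes with any missing value are
dropped first. The dendrogram exports to newick with ultrametric branch
lengths. On fixtures with planted condition signatures, replicates of the
same condition merge before any cross-condition merge — the qualitative
structure such experiments are expected to show.

## Simulators

Every input has a seeded generator returning data plus a ground-truth
sidecar, so recovery tests never re-derive truth from data:

* `simulate_unigenes()` — random AT-rich sequences (40% GC, the composition
  typical of plant EST 3' ends) with homologous blocks planted at *exactly*
  the requested identity and length (constructed by copying and mutating a
  fixed number of evenly spaced positions, not sampled).
* `simulate_two_color_slides()` — a dye-swap contrast (default 6 slides =
  3 replicates × 2 dyes, the study layout): negative-control and empty
  spots from a Gaussian truncated at zero (mean 100, SD 20 fluorescence
  units), probe spots with per-gene baseline A in [8, 14] log2 units,
  planted log2 folds, Gaussian log-ratio noise (SD 0.3, matching the
  replicate CV regime the power analysis assumes) and a smooth quadratic
  dye bias in A (amplitude 0.5 log2 units) added to M — enough curvature
  for the loess step to be non-trivial, and exactly recoverable.
* `simulate_ct_table()` — reference genes with constant expected Ct across
  samples (small constant per-gene offsets that cancel in the panel mean)
  and targets offset by minus the planted log2 expression, one cycle per
  2-fold.

What the simulators do *not* emulate: spatial print-tip effects, scanner
saturation, intensity-dependent variance, correlated probe sets, or
realistic annotation structure. Passing calibration on these fixtures
therefore shows the estimators are correct under the stated noise model,
not that real slides are free of artifacts the model lacks.

## Numerical and scale choices

Problem sizes in the test suite are chosen for a desk-scale machine: oracle
equivalence runs use 30 sequences × 100 trials (pre-clustering), 50
unigenes × 10 trials (cross-hybridization), exhaustive Fisher tables to
background size 20 with randomized coverage to 60, dendrograms to 10
leaves; calibration uses 1000-gene null fixtures with 100-200 sign-flip
permutations and 20 replicates. Monte-Carlo power checks use 1e5 simulated
experiments. Coordinates are 0-based half-open throughout the sequence
modules; spot tables use the 1-based grid conventions of their source
format. Ties in probe selection and clustering are broken
deterministically, and every stochastic step takes an explicit seed, so
identical configs reproduce byte-identical outputs.

Known limitations: the screen's identity denominator and the expression
call's channel rule are conventions chosen where the published description
under-specifies them (both are switches); the loess step absorbs part of a
planted fold when a large fraction of genes shift in one direction (an
intrinsic property of within-array normalization, visible in the tests'
balanced-fold fixtures); `d`-statistic FDRs are permutation estimates and
granular below ~1/(genes × permutations); and the ordinary linear fit is
slightly anticonservative for genes with very small observed SD compared
with a moderated fit — the consensus list mitigates this.
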