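# oligoarray

Design and analysis of custom long-oligonucleotide two-color expression
microarrays built from EST-derived unigene collections.

Species without a reference genome are still profiled with custom spotted
arrays: a unigene set is assembled from ESTs, one ~65-mer probe is designed
per unigene, and two-color (Cy3/Cy5-style) hybridizations with dye swaps
measure per-gene expression ratios. This package implements the
computational steps of that workflow end to end, for people building such
an array or re-analysing the data one produced:

* **Pre-clustering** — single-linkage grouping of sequences whose best
  Smith-Waterman local alignment reaches ≥ 90% identity over ≥ 30 bases
  (both strands; low-complexity masking by windowed entropy).
* **Probe design** — one probe per unigene with Tm 67 ± 3 °C (unified
  nearest-neighbor model with salt correction), length 65 ± 5 nt, GC
  43 ± 5%, capped hairpin-stem/self-dimer scores, and the probe's 3' end
  within 1000 nt of the unigene 3' end; unigenes with no feasible window
  are reported as *missing genes* with a reason.
* **Specificity screen** — a probe is flagged when another unigene shows
  both > 70% overall identity *and* a > 20 nt contiguous identical stretch.
* **Array QC** — expression calls against the negative-control
  distribution (`median + 2·SD`, strict), presence in ≥ 5 of 6
  hybridizations, and a both-channel spot filter.
* **Normalization & DE** — within-array loess of M on A; per-gene linear
  fits with BH adjustment and a SAM-style sign-flip permutation test
  (`d = mean/(s + s0)`) with per-gene FDR; consensus lists.
* **Replicate power planning** — per-feature CVs on a 100-based rank
  scale; analytic two-sample t-test power under a lognormal noise model
  (`σ = √ln(1 + cv²)`), minimal detectable fold and maximal admissible CV
  by bisection, Monte-Carlo cross-checks.
* **qPCR validation** — relative expression `2^(−ΔCt)` against the
  geometric-mean expression of a 3-gene reference panel, geNorm-style
  stability ranking, and array/qPCR agreement (Pearson r, sign
  concordance).
* **Downstream sets** — tissue-specific calling from directed DE lists,
  three-set Venn partitioning, Fisher-exact enrichment with FDR, and
  average-linkage hierarchical clustering with newick export.

Seeded simulators (`simulate_unigenes()`, `simulate_two_color_slides()`,
`simulate_ct_table()`) generate every input with ground-truth sidecars, so
the whole toolkit is testable without any external data.

## Worked example

Simulate a dye-swap experiment with 30 planted fold changes, analyse it,
and plan replicates:

```r
library(oligoarray)
library(dplyr)

sl <- simulate_two_color_slides(n_genes = 600, n_slides = 6, seed = 29,
                                n_de_genes = 30, de_log2_fold = c(1, -1),
                                noise_sd = 0.3)
mat <- sl$spots |>
  filter_spots() |>
  normalize_slides() |>
  build_expression_matrix(sl$layout)

sam <- sam_test(mat, n_permutations = 200, seed = 1)
glance(sam)
#> # A tibble: 1 × 4
#>   n_genes    s0 n_permutations n_significant
#>     <int> <dbl>          <dbl>         <int>
#> 1     600 0.147            200            31

tidy(sam) |> filter(fdr <= 0.01) |> inner_join(sl$truth, by = "feature_id") |>
  count(planted = log2_fold != 0)
#> # A tibble: 1 × 2
#>   planted     n
#>   <lgl>   <int>
#> 1 TRUE       30
```

All 30 significant genes at FDR ≤ 0.01 are the planted ones. Replicate
planning for this design (6 measurements per group, two-sided α = 0.10):

```r
power_two_sample_t(n_per_group = 6, cv = 35, fold = 2, alpha = 0.10)
#> [1] 0.9489135
max_cv_for_power(n_per_group = 6, fold = 1.5, alpha = 0.10, target_power = 0.90)
#> [1] 22.57874
```

A CV of 35% still detects 2-fold changes with ~95% power, and 1.5-fold
changes remain detectable at 90% power up to a CV of ~22.6%.

Probe design on simulated unigenes:

```r
fx <- simulate_unigenes(30, seed = 555)
report <- design_probes(fx$unigenes)
count(report, outcome)
#> # A tibble: 1 × 2
#>   outcome      n
#>   <chr>    <int>
#> 1 designed    30
```

Every designed probe satisfies all constraint windows; infeasible unigenes
would appear as `outcome == "missing"` with a reason. See the methods
vignette (`vignettes/oligoarray-methods.Rmd`) for the models, defaults and
their rationale, and `inst/cli/oligoarray.R` for a command-line front end
(`simulate`, `precluster`, `design`, `screen`, `qc`, `normalize`, `de`,
`power`, `qpcr`, `run-all`).

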