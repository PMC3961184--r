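---
title: "Attributing insecticide resistance to its mechanisms: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing insecticide resistance to its mechanisms: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistscope)
library(dplyr)
```

## The scientific problem

Malaria vector control leans on a small set of insecticide classes, and
*Anopheles gambiae* populations in West Africa now combine resistance to
several of them. Dissecting such a phenotype requires evidence from several
assay families at once: genome-wide expression contrasts to nominate
candidate detoxification genes (prominently CYP6-family P450
monooxygenases), qRT-PCR to quantify their over-expression, TaqMan
allelic discrimination to type the *ACE-1* G119S target-site mutation,
qPCR copy-number assays to detect *ACE-1* duplication, and bioassays —
synergist (PBO) exposures, transgenic *Drosophila* dose-response lines, and
in-vitro metabolism — to tie candidates to the phenotype.

`resistscope` implements that inference chain as a single tested pipeline.
Every stage consumes plain tables and returns tibbles, so stages chain with
the pipe; and every stage has a matching synthetic-data generator that
plants known ground truth, so the whole chain is testable without access to
any particular study's raw data.

## Stage models

### Two-colour expression contrasts

Arrays are modelled at the normalized log-ratio (M-value) level. For probe
$p$ on array $a$ carrying samples from groups $g_5$ (Cy5) and $g_3$ (Cy3),

$$M_{pa} = \mu_{p,g_5} - \mu_{p,g_3} + \varepsilon_{pa},$$

where $\mu_{p,g}$ is the true log2 expression offset of the probe's gene in
group $g$. `fit_contrasts()` solves this system per probe by least squares
(one group's offset fixed at zero; reported contrasts are invariant to that
choice) and reports each requested resistant-vs-susceptible comparison with
its standard error and residual degrees of freedom. One estimator serves
both supported designs — the pairwise full dye-swap and the fully
interwoven loop — deliberately replacing the design-specific commercial and
ANOVA-based engines such experiments are often analysed with: a single
well-specified linear model is testable against planted truth, and exact
replication of proprietary normalization settings is out of scope.

Two nuisance terms motivate the surrounding steps. A per-array global
offset (intensity imbalance) is removed by `normalize_arrays(method =
"median")`; a per-probe dye bias attaches to the Cy5 channel on every array
and cancels exactly in dye-swap averaging — the simulator plants both so
the tests can demonstrate each cancellation rather than assume it.

Variance moderation (`moderate_contrasts(moderation = "eb")`) shrinks
per-probe residual variances toward a common prior by method-of-moments
empirical Bayes under the scaled-F model $s^2 \sim s_0^2 F(d, d_0)$:
the posterior variance is $(d_0 s_0^2 + d s^2)/(d_0 + d)$ and the moderated
t-statistic has $d + d_0$ degrees of freedom. The moment equations give
$d_0 \in (4, \infty]$; when the observed variances show no excess
dispersion the prior degrees of freedom go to infinity and every posterior
collapses onto the common variance. `"plain"` is retained as an unmoderated
reference. Benjamini–Hochberg q-values (`add_fdr()`) are computed within
each comparison, since each pairwise comparison is its own testing family.

### The consensus filter

Candidate probes must satisfy conjunctive criteria, evaluated by
`evaluate_probes()` under a `comparison_plan()`:

1. **direction** — every comparison in the plan shows the same sign of
   log2 fold-change. Over- and under-expression are treated symmetrically:
   the criterion is consistency, not a fixed sign.
2. **q** — every comparison has $q < \alpha$ (default 0.05), strictly:
   a probe at exactly the threshold fails, and one failing comparison out
   of six vetoes the probe.
3. **escalation** (selected-line design only) — for every pair of
   comparisons sharing a susceptible partner, the insecticide-selected
   contrast must be strictly more extreme (same sign, larger magnitude)
   than the unexposed contrast. This targets genes tracking the resistance
   phenotype rather than population differences or exposure induction.

Overall significance requires significance in both experiments
(`combine_experiments()`); probes evaluated in only one experiment are
reported as untested, never silently promoted. Genes are summarized with
significant/total probe counts and the median contrast over their
significant probes. The direct selected-vs-unexposed contrast is low
powered at this replication and is never part of overall significance.

### Efficiency-corrected ΔΔCt quantification

Cycle thresholds follow the exponential amplification model: a template
quantity $Q$ amplified at efficiency $E$ crosses threshold at
$C_t = c - \log Q / \log(1+E)$. `normalized_expression()` averages
technical replicates on the Ct scale, converts each amplicon with its own
efficiency, and divides the target quantity by the **geometric mean** of
the reference-gene quantities (the combination rule is unstated in most
assay descriptions; the geometric mean is arithmetic on the Ct scale,
which is where the measurement error lives). Group fold-changes are means
relative to the calibrator group; with all $E = 1$ the pipeline reduces
exactly to the textbook $2^{-\Delta\Delta C_t}$, a property the test suite
asserts at $10^{-12}$. Over-expression tests select pooled versus Welch
two-sample t on log2 normalized expression via a two-sided F-test at
$\alpha = 0.05$.

Copy-number ratios (`copy_number_ratio()`) normalize three target-gene
exon amplicons against two single-copy reference genes relative to
calibrator pools from a susceptible laboratory strain. Each
(target, reference) pair contributes a Pfaffl-style per-amplicon corrected
ratio

$$(1+E_t)^{C_{t,t}^{cal} - C_{t,t}^{s}} \cdot
  (1+E_r)^{C_{t,r}^{s} - C_{t,r}^{cal}},$$

which reduces to the single-base form $(1+E)^{\Delta C_t^s - \Delta
C_t^{cal}}$ when the two efficiencies are equal. The six contributions are
averaged on the ratio scale by default (`average = "ddct"` gives the
geometric mean, i.e. ΔΔCt-scale averaging; `scale = "two"` forces base 2
for assays quoted without efficiencies). A sample is classified as
carrying an extra gene copy when its ratio strictly exceeds 1.5 — a
noise-free 3-versus-2-copy sample lands exactly *at* 1.5 and is documented
as below threshold (a $10^{-9}$ relative guard keeps floating-point
round-off from breaking that boundary). `classify_copy_number()` converts
ratios to nearest-integer copy estimates against the calibrator's known
copy number; the midpoints between consecutive integers (ratio 1.25
between 2 and 3 copies, 1.75 between 3 and 4) are the implied class
boundaries.

### TaqMan genotype calling

Endpoint fluorescence puts each well at an angle
$\theta = \mathrm{atan2}(\mathrm{FAM}, \mathrm{VIC})$ in the dye plane.
Genotypes are called qualitatively in practice, so the caller makes the
rules explicit and configurable: homozygote reference angles are anchored
on the plate's SS and GG controls, the heterozygote reference is **fixed**
at 45° (the 1:1 dye-balance line) rather than estimated — because *ACE-1*
duplication skews the empirical heterozygote cluster toward the serine
(FAM) label, exactly the signal later stages quantify. Wells are assigned
to the nearest reference; a well is excluded (no-call) when its total
signal falls below 20% of the mean control signal or it sits more than 15°
from every reference. Both guards are exposed as parameters. The caller is
scale-invariant by construction.

Downstream statistics: heterozygote dye-balance contrast
(Welch t on raw FAM/VIC ratios, log-ratio option), allele and heterozygote
frequencies with Wilson intervals, the Hardy–Weinberg chi-square from
expected counts, the 2×2 genotype-outcome association (Pearson chi-square
without continuity correction — none is stated for this assay family —
plus odds ratio with Woolf interval and Haldane–Anscombe +0.5 correction
when a cell is zero), and Woolf's inverse-variance test for homogeneity of
odds ratios across strata. Woolf's method was chosen for the unnamed
"homogeneity chi-square" of stratified bioassay data because it is the
classical weighted test on log odds ratios; Breslow–Day could substitute
but adds nothing at two strata.

### Bioassay and dose-response statistics

WHO-bioassay replicates are pooled per condition; binomial confidence
limits use the Wilson score interval (Clopper–Pearson behind a flag) —
the method behind published "95% binomial confidence limits" is rarely
stated, and Wilson keeps nominal coverage at $n = 100$ without the
conservatism of the exact interval (the suite checks 93–97% empirical
coverage). PBO synergism is the odds of mortality with PBO pre-exposure
versus insecticide alone, replicates and seasons pooled before the 2×2 is
formed; replicate-level heterogeneity is a diagnostic, not a model term.

Dose-response lines are fit as survival proportion on $\log_{10}$ dose by
ordinary least squares over the partial-response range — observations at
exactly 0 or 1 survival are outside the linear regime and excluded. The
LC50 is the inverse prediction $10^{(0.5 - a)/b}$ with a Fieller interval;
a noise-free profile collapses the interval onto the estimate. A linear
(not probit/logit) response was chosen to match the log-linear plots such
assays are reported with; the simulator offers a logistic alternative for
robustness checks. Profiles with fewer than three partial-response doses
(the sharp inflection typical of carbamates in transgenic lines) are
refused with an explicit pointer to the discriminating-dose comparison,
which reports the ratio of mean per-vial survivals and an exact two-sided
Mann–Whitney p obtained by full enumeration of assignments (the
permutation distribution over observed values when ties are present;
normal approximation with tie correction beyond $n_1 + n_2 = 20$). With
two groups of eight and complete separation the smallest achievable
two-sided p is $2/\binom{16}{8} = 2/12870 \approx 0.0002$. Vials, not
flies, are the exchangeable units: the test runs on per-vial proportions.

Substrate depletion is the ratio-of-means estimate
$100\,(1 - \bar{A}_{+\mathrm{NADPH}}/\bar{A}_{-\mathrm{NADPH}})$ over HPLC
peak areas, clamped at zero with the raw value retained and flagged —
a no-activity condition with measurement noise should report 0%, not a
spurious negative depletion.

## The synthetic-data generator

`sim_*()` functions generate every input table with planted truth. They
emulate the *structure* of the motivating study designs: a five-group
selected-line experiment (two resistant Tiassalé-like groups, one of them
bendiocarb-selected, against three susceptible populations; pairwise full
dye swap; three biological replicates) and an 18-array interwoven double
loop over three populations of three replicates. Default noise follows the
stated study conditions where they exist (array noise sd 0.25 log2 units)
and otherwise values a field scientist would call realistic: qPCR Ct noise
0.15 cycles, TaqMan angular noise 3° with clusters tens of degrees apart,
four replicate tubes of 25 females per bioassay condition. Planted
resistance offsets default to selected 1.5 / unexposed 1.0 (log2) versus
susceptible 0 — satisfying the resistance rank order with $|{\log_2
FC}| \ge 1$ and a strict selected-over-unexposed margin so the escalation
criterion is decidable rather than a coin flip.

What the generators deliberately do **not** model: scanner artefacts,
spatial array effects, probe cross-hybridization, qPCR inhibition, batch
effects, or biological replicate variance structure beyond i.i.d. noise.
Passing tests therefore demonstrate the estimators' correctness and
calibration under the stated model, not robustness to every failure mode
of real laboratory data.

## Numerical choices and degenerate inputs

* Fixed seeds give bit-identical generator output (`withr::local_seed`).
* Contrasts with zero residual df return their estimate with `se`/`t`
  flagged `NA`; probes with missing arrays are fit on the equations
  available rather than dropped.
* A disconnected hybridization design fails fast, naming the group
  components.
* Degenerate two-group tests (both variances zero) return p = 1 at equal
  means and p = 0 at separated means rather than erroring mid-pipeline.
* TaqMan cluster angles are truncated to the first quadrant so simulated
  fluorescence is never negative.
* All thresholds are strict inequalities (`q < 0.05`, ratio `> 1.5`), with
  boundary behaviour documented and tested.

## Calibration checks and problem sizes

The test suite verifies, beyond unit behaviour: exact recovery of planted
contrasts, LC50s and fold-changes on noise-free data; equivalence of the
consensus filter, the exact Mann–Whitney and the Hardy–Weinberg statistic
with independent brute-force oracles; recovery under noise (consensus
sensitivity ≥ 0.8 with realized FDR ≤ 0.10 over 20 seeded runs at the
default conditions; ≥ 95% copy-number classification accuracy; ≥ 99%
genotype concordance at six-sd cluster separation); and null calibration —
p-values from the moderated test, the dye-balance contrast and the
association test are uniform within KS distance 0.02 (10,000 null probes)
and 0.03 respectively.

Null-calibration simulation sizes deserve a note: the expected
Kolmogorov–Smirnov distance of a perfectly uniform sample of size $m$ is
$\approx 0.87/\sqrt{m}$, i.e. 0.0275 at $m = 1000$ — at the bound itself.
The suite therefore uses 2,000 dye-balance plates and 10,000 association
tables (with $n = 1000$ per arm, where the chi-square approximation is
accurate) so that the Monte-Carlo noise floor sits well under the asserted
bounds. These sizes control simulation error; they are not tuning knobs.
The 20-seed consensus recovery runs at 500 genes × 2 probes per
experiment, which the estimators' vectorized fitting completes in seconds
while leaving the per-contrast power identical to a full-size array (power
depends on replication and noise, not probe count).

## Known limitations

* The expression model is a simplified stand-in: no intensity-dependent
  (loess) normalization, background correction, or probe-level QC beyond
  missingness, and no attempt to reproduce any specific commercial
  pipeline's output.
* Efficiencies are inputs; standard-curve estimation from dilution series
  is out of scope.
* Copy-number calls are relative; beyond the binary extra-copy
  classification, integer copy estimates from large ratios inherit all the
  uncertainty of ratio-scale qPCR.
* Functional enrichment/annotation clustering of candidate genes is out of
  scope, as are GLMs of bioassay mortality on environmental covariates.

## A compact end-to-end run

```{r, eval = FALSE}
tr <- sim_truth(500, 2, 10, c(Tia_sel = 1.5, Tia_unexp = 1, Kovie = 1))
sch1 <- sim_scheme_dyeswap(c("Tia_sel", "Tia_unexp"),
                           c("NG", "Mali", "Oky"))
sch2 <- sim_scheme_loop(c("Kovie", "Mal", "Oky"))
cmp1 <- c("Tia_sel:NG", "Tia_sel:Mali", "Tia_sel:Oky",
          "Tia_unexp:NG", "Tia_unexp:Mali", "Tia_unexp:Oky")
pairs <- tibble::tibble(
  selected  = c("Tia_sel:NG", "Tia_sel:Mali", "Tia_sel:Oky"),
  unexposed = c("Tia_unexp:NG", "Tia_unexp:Mali", "Tia_unexp:Oky"))

v1 <- sim_mvalues(sch1, tr, 0.25, seed = 1) |>
  normalize_arrays() |>
  fit_contrasts(sch1, cmp1) |>
  moderate_contrasts() |>
  add_fdr() |>
  evaluate_probes(comparison_plan(cmp1, pairs))
v2 <- sim_mvalues(sch2, tr, 0.25, seed = 2) |>
  normalize_arrays() |>
  fit_contrasts(sch2, c("Kovie:Mal", "Kovie:Oky")) |>
  moderate_contrasts() |>
  add_fdr() |>
  evaluate_probes(comparison_plan(c("Kovie:Mal", "Kovie:Oky")))

combine_experiments(v1, v2, tr$probes)$genes |>
  dplyr::filter(n_probes_significant > 0)
```

`run_pipeline()` drives the same chain (plus the qPCR, genotyping and
bioassay stages) from a single configuration list or YAML file and returns
a report whose provenance block records the configuration hash and seed;
`write_report()` serializes every table as TSV plus a JSON report.
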