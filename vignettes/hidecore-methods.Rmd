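---
title: "Methods: cross-species divergence analysis of the infant prefrontal cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species divergence analysis of the infant prefrontal cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hidecore)
library(dplyr)
```

## The scientific problem

Comparative single-nucleus transcriptomics of infant human, chimpanzee and
rhesus macaque prefrontal cortex asks which gene expression programs are
*human infant-specific*: altered in human samples relative to both other
primates, during infancy, in a given cell type, and not similarly altered
in adults. Such programs can then be interrogated for overlap with disease
risk genes and patient expression changes, and for a regulatory core — TF
to target-gene relationships mediated by open chromatin that carries
human-specific sequence changes (HARs, human-specific insertions and
deletions).

`hidecore` implements that analysis chain as composable, tested pieces:

1. **Pseudobulk differential expression** (`nb_wald_test()` and friends):
   negative-binomial Wald tests between species within a cell type and age
   group, on per-individual, per-cell-type summed counts.
2. **Divergence set algebra** (`species_specific_de()`,
   `age_specific_sets()`): the hiDE/ciDE construction.
3. **Enrichment statistics** (`hypergeom_upper_tail()`, `fisher_exact()`,
   `odds_ratio()`, `chi_square_independence()`): the exact and asymptotic
   machinery used by every downstream comparison.
4. **Disease intersection** (`risk_gene_overrepresentation()`,
   `patient_de_scatter()`, `directionality_contingency()`).
5. **hiDECORE network construction** (`annotate_regions()`,
   `build_hidecore()`, `lineage_disease_enrichment()`, ...).
6. **Developmental trajectories** (`score_module()`,
   `proportions_by_age()`, `fit_trend()`).
7. **A synthetic data generator** (`sim_config()`, `simulate_bundle()`)
   that plants known effects so the whole chain can be validated without
   restricted primary data.

## The differential expression model

Counts for gene $g$ in pseudobulk sample $j$ are modelled as negative
binomial with mean $\mu_{gj} = s_j q_{g,\mathrm{group}(j)}$ and variance
$\mu + \alpha_g \mu^2$:

* **Size factors** $s_j$ are median-of-ratios: the median over
  always-expressed genes of the ratio of a sample's count to the gene's
  geometric mean, rescaled to geometric mean one. When no gene is
  expressed everywhere the total-count ratio is used, with a warning.
* **Dispersions** $\alpha_g$ come from a method-of-moments estimator on
  normalized counts, $\hat\alpha = (s^2 - m)/m^2$, floored at $10^{-8}$.
  When the contrast's group labels are supplied (the default inside
  `nb_wald_test()`), the estimate is formed *within* each group and pooled
  with degrees-of-freedom weights. This matters: a marginal estimator
  applied across a contrast with a real expression difference absorbs the
  signal into the noise term and inflates the dispersion of exactly the
  genes under test.
* **Group means** $q_{gA}, q_{gB}$ are fitted by maximum likelihood with
  the dispersion held fixed, via Newton iterations on $\log q$ using the
  expected information $\sum_j \mu_{gj}/(1 + \alpha_g \mu_{gj})$. The fit
  is vectorised across genes, so a full contrast over thousands of genes
  takes well under a second.
* The reported effect is $\log_2(q_A/q_B)$ with a pseudo-mean floor of
  half a count spread over the group ($0.5/\sum_j s_j$), so a group of
  all zeros yields a large finite, flagged fold change rather than
  infinity.
* The Wald statistic divides by the standard error from the two groups'
  information. P-values use a **t reference with $n_A + n_B - 2$ degrees
  of freedom** rather than a normal: the dispersion is a finite-sample
  plug-in, and on null simulations at ten individuals per group the
  normal reference is visibly anticonservative (rejection rate near
  0.065 at the 0.05 level) while the t reference restores calibration.
  FDR is Benjamini–Hochberg within one cell type and contrast, matching
  how per-cell-type DE counts are reported.

Calling uses strict bounds — $|\log_2\mathrm{FC}| > 0.5$ and
$\mathrm{FDR} < 0.05$ — both configurable.

### Set logic

"Human-specific" is operationalised as *significant in both pairwise
contrasts with concordant sign* (human vs chimpanzee AND human vs rhesus);
a one-vs-pooled union mode exists behind `mode = "either"` for
sensitivity analyses but is not the default, because the intersection
logic of the divergence sets requires per-contrast direction agreement.
Age specificity then removes genes present in the adult set of the same
cell type *and the same direction*: a gene gained in infants but lost in
adults stays.

## Exact statistics

Overrepresentation uses the upper-tail hypergeometric probability
$P(X \ge k)$, evaluated through `phyper()` (log-space internally).
Fisher's exact test sums hypergeometric point masses over all tables with
the observed margins; the two-sided p follows the point-probability rule
with a relative tie tolerance of $10^{-7}$, the dominant convention. The
odds ratio is the unconditional cross-product $(ad)/(bc)$ — this is what
published contingency statistics print, and the two worked tables in the
package's acceptance checks (24/40 vs 4/64, giving 9.6 exactly, and 7/19
vs 1/25, giving 9.21) reproduce their published values only under this
estimator, not under the conditional MLE. Sidedness deserves a note: for
the TF-level table the one-sided (greater) p is about 0.0248 and the
two-sided about 0.0496; published values of ~0.024 correspond to the
one-sided tail, so `lineage_disease_enrichment()` reports both.

The chi-square test of independence reports Pearson residuals
$(O - E)/\sqrt{E}$ as the per-cell effect measure; rows or columns with a
zero margin are dropped with a warning, and cells with expected counts
below a configurable floor (default 5) are flagged rather than hidden.

## hiDECORE construction

A regulon edge TF → region → target is retained iff

1. *(node rule)* both the TF and the target are hiDE expression **gains**
   in the lineage — an edge with a non-hiDE TF is excluded even if its
   target qualifies;
2. *(annot)* the mediating region overlaps (≥ 1 bp, half-open
   coordinates) at least one HAR/hINS/hDEL interval;
3. *(tf2g)* the TF-to-gene score is positive;
4. *(r2g)* the region-to-gene score is positive;
5. *(role)* the regulon is an activator — repressor regulons cannot
   satisfy the positive-correlation requirements and are excluded, with
   their count reported.

Every excluded edge is attributed to its *first* failing rule in the
fixed order (node, annot, tf2g, r2g, role), so provenance counts always
sum to the number of input edges (plus any edges excluded because a gene
is absent from the DE universe, counted separately). Disabling a rule via
the `rules` argument can only grow the network; the test suite asserts
this monotonicity directly. Interval overlap is computed with the
interval-tree machinery of `GenomicRanges` behind a half-open interface,
and is checked against a quadratic all-pairs oracle on random fixtures.

## Module scores and trajectories

`score_module()` follows the control-gene convention of single-cell
module scoring: genes are binned by mean expression (25 bins), each
module gene draws 50 controls from its bin, and the score per nucleus is
mean(module) − mean(controls). The score of a random module is therefore
zero in expectation, and a constant matrix scores exactly zero — both are
asserted in the tests. "Normalized module score" means this
control-subtracted score; no additional z-scaling is applied by default.
Age axes are plotted and fitted on $\log_2(\mathrm{years} + 0.1)$, the
offset admitting prenatal and 0-year samples; age-group bin edges
(prenatal, 0–1, 1–20, >20 years) are configuration, defaulting to the
narrative groups used in developmental atlases.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults define the validation conditions: 3 species × 2
age groups × 4 cell types (two neural, two oligodendrocyte-lineage), 10
individuals per species per age group, 2000 genes, planted
$|\log_2\mathrm{FC}| = 1$. Per cell type, each gene is independently
labelled hiDE gain/loss (probability 0.05 each), ciDE gain/loss (0.05
each), adult-shared human DE (0.025 each) or null, which makes the
planted categories disjoint by construction — the hiDE vs adult-shared
exclusion invariant holds exactly. Counts are drawn at the pseudobulk
level from the same NB parameterization the DE engine assumes
(dispersion log-uniform on [0.01, 0.2], baselines log-uniform on
[10, 1000], log-normal size factors with sd 0.2 on the log scale); a thin
multinomial cell-splitter exists only to exercise aggregation. Depth and
dispersion defaults were chosen once for test power — real pseudobulk
dispersions are unknown for this tissue — and are stated here rather than
tuned.

Regulon edges are designed so every retention rule has members that pass
and members that fail it; annotation intervals live on a single synthetic
chromosome `chrS` and cover roughly half of the regulon regions; disease
deregulation is planted lineage-matched (ASD concentrated in OL-lineage
hiDE gains, PD in neural ones, rate 0.4 versus 0.1 across lineages); the
capture assay reproduces network pairs at a planted rate of 0.9.

What passing on this generator shows: the engine recovers planted effects
above its thresholds with calibrated error rates, the set algebra and
network filter are exact, and the statistics match their enumeration
oracles. What it does not show: robustness to features of real
single-nucleus data that are deliberately out of scope — ambient RNA,
doublets, batch structure, cell-type misassignment, mean-dispersion
trends, or the genome-scale correlation structure of real regulomes.
Genome-scale published quantities (total DE counts, specific odds ratios
over thousands of genes) depend on restricted primary data and are not
reproduced here; only the printed small-table statistics are reproduced
exactly.

## Numerical and design choices

* Newton steps on $\log q$ are clamped to ±2 per iteration; convergence
  tolerance $10^{-10}$ on the step, 100 iterations maximum.
* Jaccard of two empty sets is defined as 1, with a warning.
* Gene identifiers are opaque strings matched exactly; no alias
  resolution is attempted, and unmatched identifiers are counted and
  warned about, never silently dropped.
* BH-FDR for risk-gene grids is applied once across the whole
  (cell type × disease list) grid within a direction; the scope is
  recorded in the output so subset re-runs are interpretable.
* Patient DE significance is taken as given (the loader pre-filters at
  FDR < 0.05, configurable); re-deriving patient DE is out of scope.
* All randomness flows from explicit seeds; operations that draw
  (control genes, synthetic data) restore the caller's RNG state.
* Validation problem sizes: the default bundle (2000 genes × 240
  samples) runs the full DE chain in a few seconds; exact-test
  enumeration covers every 2×2 table with total ≤ 30; interval checks
  use 10^3 × 10^3 random pairs.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
bundle <- simulate_bundle(cfg)
hide <- infant_specific_sets(bundle$pseudobulk, "human",
                             c("chimp", "rhesus"))
nrow(hide$specific)        # recovered human infant-specific DE events

regions <- parse_region_ids(unique(bundle$regulons$region))
ann <- annotate_regions(regions, bundle$annotations)
net <- build_hidecore(bundle$regulons, bundle$truth$hide_gains$OL,
                      ann, "OL")
net
```

## Known limitations

The dispersion estimator has no empirical-Bayes shrinkage toward a
mean-dispersion trend, so per-gene estimates are noisier than those of a
full shrinkage engine at very small sample sizes; the t reference
compensates for calibration but not for ranking. The one-vs-rest pooled
contrast mode shares the dispersion estimate of the pairwise machinery.
The pipeline treats the regulon table as given — regulon inference itself,
clustering, integration and ligand-receptor modelling are out of scope.
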