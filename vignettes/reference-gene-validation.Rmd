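---
title: "Reference-gene validation and qPCR normalization: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene validation and qPCR normalization: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

# The problem

Relative quantification by qPCR stands or falls with the reference genes
used for normalization: a "housekeeping" gene that itself responds to the
experimental condition biases every target-gene fold change built on it.
refstab implements a complete validation workflow for candidate reference
genes and the downstream quantification that depends on them:

1. **Candidate screening from RNA-Seq** (optional): filter a differential
   expression results table for genes that behave like references, and draw
   a panel spanning the expression range.
2. **Cq quality control**: aggregate technical replicates under a
   consistency rule and check primer amplification efficiencies.
3. **Stability ranking**: coefficient-of-variation screening, per-gene
   intrinsic-variation testing, and a model-based variance-components
   estimator with a best-pair search.
4. **Quantification**: a per-sample normalization factor from the best
   pair, target fold changes by `2^-ddCt`, and parallel fold changes from
   RNA-Seq normalized counts.
5. **Cross-method comparison**: Kruskal-Wallis plus Dunn's
   control-versus-others post test on the fold-change distributions
   produced by different normalization strategies.

Every stage is testable without laboratory data through seeded simulators
with known ground truth.

# Replicate aggregation

Each biological sample is measured in technical replicates (typically
triplicate). The arithmetic mean of the replicates represents the sample;
a replicate standard deviation above 0.20 cycles marks the cell
inconsistent. In that case exactly one outlier is removed — the replicate
farthest from the within-cell median, ties resolved to the lowest replicate
index — and the SD recomputed. Cells that remain spread after the removal
keep the mean over all replicates and carry an `inconsistent` flag rather
than being dropped: exclusion is a downstream decision, not an I/O side
effect. The outlier rule is deliberately deterministic; the median-distance
criterion is robust to the case where two replicates agree and one strays.

The 0.20-cycle threshold is strict (`> 0.20` triggers the rule). At a
technical SD of 0.05 cycles the rule essentially never fires (the
probability that a triplicate SD exceeds 0.20 is that of a chi-square far
in its tail), which the simulation tests confirm empirically.

# Amplification efficiency

A standard curve regresses Cq on `log10` relative template concentration;
the efficiency is `E = 10^(-1/slope)`, with E = 2 (slope −3.3219) the
ideal doubling. Primers pass when `1.9 <= E <= 2.1` and `R^2 >= 0.99`.
The most dilute point of a series sometimes leaves the detection range;
the fit accepts an explicit point mask rather than dropping points
automatically, so the decision is visible in the caller's code. A flat or
positive slope yields an undefined E and an automatic fail.

# RNA-Seq candidate screening

The screen consumes a DESeq2-style results table (`baseMean`,
`log2FoldChange`, `padj`, `dispersion`). The per-gene dispersion of a
negative-binomial fit approximates the squared biological coefficient of
variation, so `100 * sqrt(dispersion)` serves as a CV-like percentage
(`cv_from_disp`). Four conjunctive filters retain candidates:

* `padj > 0.05` — no evidence of differential expression. Genes with
  missing `padj` cannot satisfy this affirmatively and are excluded.
* `|log2FC| <= 0.1` — negligible intergroup change (inclusive bounds).
* `10 <= cv_from_disp <= 20` — moderate variability (inclusive); genes
  below 10 are often so invariant that dispersion estimates are unstable,
  genes above 20 too variable.
* `baseMean >= 500` — enough expression for reliable qPCR detection.

Boundary semantics follow the wording of the rules ("above", "between",
"greater than or equal to"); boundary ties are rare and the choices are
documented in the function help. The surviving pool is ranked by
`baseMean` and split into four rank-quartiles (remainders to the lower
quartiles); 3 genes are drawn from each of the first three quartiles and 1
from the fourth, spanning low through high expression. Quartile 1 defaults
to the lowest expression ranks, exposed as a flag since the orientation is
a convention. Within a quartile the members are drawn either uniformly at
random under a seed (the default — in practice the choice is constrained
by primer design, which has no statistical preference) or deterministically
by smallest `cv_from_disp`.

Target genes are selected from the other end of the table: `padj < 0.05`
and `log2FC` strictly beyond ±0.6, split into up- and down-regulated
lists, with a seeded draw of 3 per direction.

# The stability model

Let `y_igj` be the Cq of gene `i` (of `k` genes) in sample `j` of group
`g` (sizes `n_g`, `G >= 2` groups). Cq is already log2-scale, so it feeds
the model directly; the sign flip relative to abundance affects neither
variances nor deviation magnitudes. The model decomposes, within each
group, a gene effect, a sample (loading) effect, and residual noise:

* Double centering within group `g` gives residuals
  `r_igj = y_igj - mean_j(y_igj) - mean_i(y_igj) + mean_ij(y_igj)` and the
  naive variance `s²_ig = sum_j r²_igj / (n_g - 1)`.
* The naive variance is biased by the centering over the finite gene panel;
  the corrected intragroup variance is
  `sigma²_ig = max{ (s²_ig - S_g/(k(k-1))) * k/(k-2), 0 }` with
  `S_g = sum_i s²_ig`. The correction is exact in expectation even when
  genes have unequal variances (this is verified by the Monte-Carlo
  recovery test at `k = 10`, `n_g = 50`). The `k/(k-2)` factor is why at
  least 3 genes are required; negative method-of-moments estimates are
  clipped at zero.
* The gene-by-group expression difference is
  `a_ig = mean_j(y_igj) - mean_ij(y_igj)`, and the intergroup deviation
  `d_ig = a_ig - mean_g(a_ig)` is doubly centred: it sums to zero across
  groups for every gene and across genes for every group.
* Deviations are shrunken empirically:
  `gamma² = max{ sum(d²)/((G-1)(k-1)) - mean(sigma²_ig/n_g), 0 }` estimates
  the panel-wide variance of true deviations, and
  `d~_ig = d_ig * gamma²/(gamma² + sigma²_ig/n_g)` pulls noisy deviations
  toward zero (never past it: `|d~| <= |d|`).
* The stability value averages deviation magnitude and sampling noise over
  groups: `S_i = mean_g( |d~_ig| + sqrt(sigma²_ig/n_g *
  gamma²/(gamma² + sigma²_ig/n_g)) )`. Lower is more stable.

Because the model centres per sample and per gene, `S` is invariant under
adding any per-sample constant (loading and pipetting effects) and any
per-gene constant (baseline expression) — both invariances are asserted to
`1e-10` in the tests.

**Best pair.** Averaging two genes halves opposing deviations and reduces
sampling variance, so a pair often beats the single best gene. For each
unordered pair the deviation is the mean of the two shrunken deviations and
the sampling variance `(sigma²_a + sigma²_b)/(4 n_g)`, shrunken exactly as
in the single-gene case; the search is exhaustive over all `choose(k, 2)`
pairs (equivalence with a brute-force loop is tested), with ties broken
lexicographically by gene id.

**A structural caveat: stability is relative.** The deviations `d_ig` are
measured against the panel mean. If the whole candidate panel drifts with
the condition, the drift is invisible to the estimator, and any
normalization factor built from the panel inherits the panel-mean
contrast. This limitation is shared by all reference-based normalization
and shapes the design of the equivalence experiment below.

# Gates and flags around the model

* **CV screen.** On linearized quantities (`2^-Cq`), the coefficient of
  variation per gene over all samples pooled (sample SD, `n-1`
  denominator) gates candidates: CV strictly above 50% excludes a gene
  from the stability fit and the pair search. Very high overall variation
  destabilizes the variance-components estimates.
* **Intrinsic variation.** Each gene is tested for a group difference with
  the exact two-sided Mann-Whitney U test. Significance is reported as a
  flag only, never an exclusion — a gene with a modest systematic shift may
  still be the best available partner, and the stability model accounts
  for the shift explicitly.

# Quantification

The normalization factor of a sample is the arithmetic mean of the two
best reference genes' Cq (the geometric mean of their abundances). For a
target, `dCq = Cq_target - NF` per sample; `ddCq` re-centres `dCq` on the
arithmetic mean over calibrator-group samples, and `FC = 2^-ddCq`. The
arithmetic-mean centering (geometric mean on the linear scale) makes the
calibrator group's fold changes scatter around 1 rather than pinning them
there, preserving the biological spread in plots. A per-sample additive Cq
shift applied jointly to the target and both reference genes cancels
exactly — the identity the NF exists to provide.

RNA-Seq fold changes divide each sample's normalized count of the target
by the calibrator-group mean, so the calibrator mean FC is 1 by
construction. This is a convention — a per-group mean ratio would be
another — chosen so the per-sample distributions are comparable across
methods.

# Rank-based testing

Group sizes in qPCR experiments are small, so all group comparisons are
nonparametric:

* **Mann-Whitney U** (two groups): for combined `n <= 20` the two-sided p
  comes from full enumeration of the mid-rank sum over all
  `choose(n1+n2, n1)` assignments — ties are handled exactly by permuting
  the mid-ranks; the two-sided p doubles the smaller tail and caps at 1.
  Above the limit, a normal approximation with tie and continuity
  correction takes over. The enumeration is verified against an
  independent value-level oracle for all combined sizes up to 12.
* **Kruskal-Wallis** (3+ methods/groups): tie-corrected H with a
  chi-square p, delegated to `stats::kruskal.test`.
* **Dunn's post test**: control-versus-others z statistics on the pooled
  mid-ranks with the `sum(t³-t)` tie correction, two-sided normal p,
  adjusted over the planned comparisons. The default adjustment is
  Bonferroni — conservative and reproducible; Šidák and none are
  available. The calibrator group is omitted from cross-method
  comparisons: its fold changes sit at 1 under every method by
  construction.

# The synthetic-data generators

**Cq generator.** `y_igjr = mu_i + delta_ig + b_gj + e_igj + t_igjr` with
loading effects `b ~ N(0, sigma_s²)` shared by all genes of a sample,
biological noise `e ~ N(0, sigma_b,i²)`, technical noise
`t ~ N(0, sigma_t²)`, and zero-sum group shifts `delta`. Gaussian noise on
the Cq (log2) scale is exactly the variance-components model the stability
estimator assumes — passing recovery tests therefore shows correctness of
the estimator, not robustness to model misspecification. Real data depart
from this model through non-Gaussian outliers, plate effects beyond a
scalar loading term, and efficiency differences between assays; none of
those are emulated.

Default study conditions, used throughout the tests: 7 samples per group
and 2 groups (a typical validation cohort), triplicate wells,
`sigma_t = 0.05` cycles (instrument-grade precision), `sigma_s = 0.2`
cycles of loading variation, `sigma_b = 0.1` cycles for stable reference
genes. Planted instability uses `delta = 0.8` cycles (shift mechanism) or
`sigma_b = 0.6` (noise mechanism).

**Count generator.** Negative binomial with mean `q_i * s_j * 2^theta_ig`
and dispersion `alpha_i` (Poisson at zero), with explicit size factors.
The companion `deseq_like_results()` reproduces the median-of-ratios size
factors and the results-table schema, but the differential test is a
transparent surrogate (Welch's t on `log2(normalized count + 0.5)`,
Benjamini-Hochberg adjusted) and the dispersion column a method-of-moments
estimate overridable by the simulation truth. The screen's behaviour
depends on the table's schema and the filters, not on the DE engine, so a
faithful GLM refit would add nothing testable here. The pseudo-count is a
fixed, documented 0.5.

# The equivalence experiment

The workflow's central claim is that two independently sourced candidate
panels, each containing discoverable stable genes, yield interchangeable
normalization. The packaged experiment simulates two disjoint 10-gene
panels — 8 planted-stable genes plus 2 dispersion-type unstable members
each — and 6 targets with planted effects
`theta ∈ {−2, −1, −0.7, +0.7, +1, +2}` (log2), with target biological SD
0.35 cycles, the magnitude seen in published per-sample fold-change
spreads. Each run validates both panels independently (QC → CV gate →
stability fit → best pair), quantifies all targets under both NFs, and
compares the two fold-change distributions per target with
Kruskal-Wallis + Dunn (panel-1 NF as control).

Two design points deserve emphasis:

* The unstable panel members are *noise-type*, not shift-type. A
  group-shifted candidate biases its panel's mean contrast, and — by the
  relativity argument above — the best pair inherits a fraction of that
  bias no matter how well the search works. With shift-type contamination
  the experiment would measure that structural bias, not pipeline-induced
  differences; shift detection and exclusion are exercised separately by
  the ranking-recovery experiment.
* Recovery of each planted `theta` is judged against a 99% Monte-Carlo
  interval of the mean estimate over the 100 seeded runs; the ddCt
  estimator is unbiased under the generator, so this is a calibration
  check, not a tolerance tuned to pass.

Problem sizes across the packaged experiments — 500 replicates at
`k = 10, n_g = 50` for variance recovery, 100 seeded runs for ranking and
equivalence, 2000 replicates for the Dunn type-I check — were chosen so
each property estimate has comfortable Monte-Carlo precision while the
whole suite remains quick to run routinely.

# Numerical choices and degenerate inputs

* Negative variance and `gamma²` estimates are clipped at zero (small-`n`
  method-of-moments estimators go negative routinely); when `gamma² = 0`
  the shrinkage factor is defined as 0, avoiding 0/0.
* The exact Mann-Whitney tail comparison guards mid-rank rounding with a
  `1e-9` epsilon.
* Identical values in every group give Kruskal-Wallis H = 0, p = 1 — a
  valid degenerate outcome, not an error; a flat standard curve, by
  contrast, is an undefined efficiency and fails QC.
* A gene with zero mean linear expression has no CV and raises a specific
  error rather than an `Inf`.
* Aggregation requires at least two replicates per cell; the stability
  estimator requires `k >= 3`, `G >= 2`, and `n_g >= 2` for every group.

# Known limitations

* The stability estimator cannot detect whole-panel drift (relativity of
  stability) — a limitation inherent to reference-gene normalization.
* The Dunn-based cross-method comparison treats methods as independent
  groups although they quantify the same samples; this mirrors standard
  practice but is conservative in power and can be anticonservative when
  a run-level offset between methods coexists with small within-group
  spread.
* Efficiency correction beyond the pass/fail gate (e.g. Pfaffl-style
  quantification) is out of scope: the workflow assumes assays restricted
  to `E ∈ [1.9, 2.1]` and the base-2 model.
* Instrument-native export formats are not parsed; tables must arrive as
  CSV/TSV.
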