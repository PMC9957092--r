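---
title: "Drug-response signature scoring: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-response signature scoring: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

scDR predicts whether an expression profile — a bulk RNA-seq sample or a
single cell — behaves like a drug-resistant or drug-sensitive population,
one drug at a time. It rests on a simple transfer idea: resistance-associated
transcriptional differences learned from pharmacogenomic cell-line panels
(expression plus dose-response AUC values) carry over to new profiles, down
to single-cell resolution.

The pipeline has three steps.

**1. Labelling.** For a drug $d$, every profiled cell line has an AUC (area
under the percent-viability dose-response curve; higher AUC means more
surviving cells, i.e. more resistant). Lines are labelled

$$\text{R} : \text{AUC} > \mu + k\sigma, \qquad
  \text{S} : \text{AUC} < \mu - k\sigma,$$

with $\mu$, $\sigma$ the mean and sample standard deviation of the AUCs of
all lines profiled for that drug and $k = 0.8$ by default. The middle band
stays unlabelled. The inequalities are strict, so boundary lines are left
out. Because the rule only uses the AUC distribution's own location and
scale, it is invariant under positive affine transforms of the AUC — the
units of the response measure never matter (this is property-tested).

**2. Signature derivation.** For each gene $i$,

$$\log_2\!FC_i \;=\; \log_2\frac{\overline{\exp}_{i,R} + c}
                                {\overline{\exp}_{i,S} + c},$$

the log2 ratio of mean linear-scale expression in resistant versus
sensitive lines, with pseudocount $c$ (default 0.01). The top `n_top`
(default 200) most up-regulated and top 200 most down-regulated genes form
the drug-response genes (DRGs); each keeps its $\log_2 FC$ as a signed
weight.

**3. Scoring.** The profile being scored is standardized gene-wise,

$$z_{im} = \frac{\exp_{im} - \text{mean}(\exp_i)}{\text{sd}(\exp_i)},$$

with mean and sd taken across all samples *of the scored dataset*, and the
drug-response score of sample $m$ is the weighted mean over the $q$
signature genes present in the profile:

$$DRS_{dm} = \frac{1}{q}\sum_{i=1}^{q} \log_2\!FC_{id}\, z_{im}.$$

Higher DRS predicts resistance. Two structural consequences follow directly
and are enforced as tests: the mean DRS over all scored samples is exactly
zero for every drug (each $z$ row averages zero), so the score is a
*relative* statistic within a dataset; and any gene-wise positive affine
transform of the scored matrix leaves the DRS unchanged, so the score is
insensitive to per-gene scaling or units.

For single-cell data, per-cell scores are aggregated to the cell-line mean
(mDRS) before being compared against line-level response truth.

## Assumptions worth stating

- Fold changes compare *group means* on linear scale. A matrix flagged
  log-scale is rejected unless the caller explicitly opts into log-scale
  means, because the two statistics differ and the choice must be conscious.
- Z-scores are computed on the dataset at hand, never carried over from the
  training cohort. Scores are therefore only comparable within one scored
  dataset — which is also why cross-validation rescales each test fold into
  $[0,1]$ before testing.
- DRS separates groups only if the scored dataset has genuine heterogeneity
  in signature-gene expression; a dataset of identical cells scores flat.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 0.8 | AUC threshold multiplier; larger = purer but smaller R/S sets |
| `n_top` | 200 | DRGs kept per direction |
| `pseudocount` | 0.01 | keeps fold changes finite for genes unexpressed in one group (0 allowed; such genes then rank first with infinite weight) |
| `alpha` | 0.05 | significance level of the one-sided separation test |
| `folds`, `permutations` | 3, 100 | cross-validation design: each fold of each permutation is one test (900 at defaults) |
| `min_genes_per_cell`, `max_mito_fraction`, `min_cells_per_gene` | 200, 0.20, 3 | single-cell QC thresholds, applied cells-then-genes |
| `noise_sd` (WPCI) | 0.1 × sd(AUC) | assumed AUC measurement noise; see below |

## Validation framework

Separation of resistant from sensitive scores is tested with a one-sided
Wilcoxon rank-sum test (H1: resistant higher); `p < alpha` counts the drug
as accurately predicted, and accuracy over drugs is the fraction of
significant drugs. No multiplicity correction is applied in this accuracy
bookkeeping; `group_drs_comparison()` can attach Benjamini–Hochberg
adjusted values when many drugs are screened at once, off by default.

Cross-validation re-derives the signature on each training split only, and
each (fold, permutation) pair is one test. Folds whose training half loses
a class are excluded from the denominator and counted in the report, rather
than failing the run.

The weighted probabilistic concordance index (WPCI) compares predicted
scores with true AUCs over all line pairs with distinct AUC. Each pair is
weighted by the probability that its observed AUC ordering is real under
Gaussian measurement noise, $w_{ij} = \Phi(|\Delta \text{AUC}_{ij}| /
(\sigma_\varepsilon\sqrt{2}))$; credit is 1 for a concordantly ordered
pair, 0.5 for a prediction tie, 0 otherwise, and the index is the weighted
mean credit. With all weights forced to 1 it reduces exactly to the
classical concordance index (tested against brute-force pair counting).
The absolute WPCI depends on the assumed noise scale $\sigma_\varepsilon$,
which is exposed as `noise_sd`; rankings between competing methods are
stable under it. The default ties $\sigma_\varepsilon$ to 10% of the
observed AUC spread, a deliberately mild assumption that down-weights only
near-tied pairs.

## Numerical and design choices

Some choices that an implementer must make but the model statement leaves
open; each is fixed here and tested:

- **Sample standard deviation** ($n-1$) everywhere — labelling, z-scores —
  matching the default of the statistical environments this kind of
  analysis is done in.
- **Fold change as a difference of logs.** $\log_2(\bar x + c) -
  \log_2(\bar y + c)$ rather than the log of the ratio: mathematically
  identical, but bit-exactly antisymmetric under an R/S label swap, which
  makes the swap property testable at machine precision.
- **Genes with zero mean in both groups are dropped**, not scored 0:
  a zero would let unexpressed genes dilute the rank selection.
- **Ties in the top-`n_top` ranking break lexicographically by gene id**,
  so builds are deterministic.
- **Zero-variance genes are removed before scoring**, and `q` counts only
  scoreable genes; both counts are reported so users can see the
  difference from the raw intersection.
- **Exact versus approximate rank-sum p-values.** Whenever
  $\binom{m+n}{m} \le 20000$ (covers both groups up to size 8), the
  one-sided p-value is computed by exact enumeration of all assignments of
  the pooled midranks — exact under ties too. Larger problems use the
  normal approximation with tie and continuity corrections. The exact path
  is cross-checked against `wilcox.test`'s exact distribution where ties
  are absent, and against enumeration where they are not.
- **Min–max rescaling of a constant vector maps to 0.5** (midpoint), so a
  degenerate CV fold produces an uninformative rather than an undefined
  test.
- **QC order is cells first, then genes**, since gene detection counts are
  only meaningful over retained cells. QC never alters values, and on data
  where the gene filter removes nothing it is idempotent; when the gene
  pass does remove genes, a cell's detected-gene count can in principle
  drop below threshold, a boundary effect shared with the standard
  single-cell toolkits that use the same two-pass rule.
- **Mitochondrial genes are recognized by an id prefix** (default `MT-`);
  no annotation lookup.

## The synthetic generator

Because the real pharmacogenomic panels cannot be bundled, every claim is
exercised on seeded synthetic cohorts whose generator is itself a tested,
first-class module. It emulates:

- per-gene log-normal baseline expression (meanlog $\log 20$, sdlog 1),
  with multiplicative log-normal noise (`noise_sd` = 0.25 on the natural
  log scale, ~1.4-fold typical line-to-line variation — appropriate for
  cohort-level *mean* expression of reasonably expressed genes);
- planted DRGs: each drug owns a disjoint gene block; planted up-genes are
  shifted $+e/2$ log2 units in that drug's resistant lines and $-e/2$ in
  sensitive lines (down-genes mirrored), so the realized R-vs-S log2FC of
  a planted gene equals `effect_log2fc`, with intermediate lines at
  baseline to exercise the unlabelled AUC band;
- AUC values: the standardized per-line signature activity (signed mean of
  planted genes' standardized log-expression) mixed with standard-normal
  noise at weight `auc_coupling` (default 0.7), then affine-mapped to an
  arbitrary positive range — legitimate because labelling is provably
  affine-invariant;
- single-cell counts: per-cell library sizes log-normal around 20,000,
  negative-binomial counts (size 2) with per-gene means following the
  line's profile, thinned by Bernoulli dropout (rate 0.3) — the minimal
  standard model of droplet overdispersion and sparsity.

What it does **not** emulate: correlated gene modules, batch effects,
cell-cycle structure, ambient RNA, doublets, compositional shifts between
lines, or heavy-tailed AUC error. Passing tests on these cohorts therefore
demonstrate the *statistical machinery* — recovery of planted signal,
calibration under the null, invariances — not performance on any real
cohort.

One construction detail matters for calibration: deriving a signature and
testing separation on the *same* samples is circular (the selection of
top-ranked genes guarantees separation even under a global null — which is
also why discovery-cohort accuracy is near 100% by design). The null
calibration therefore trains on half of the labelled lines and tests on
the held-out half; under `effect_log2fc = 0, auc_coupling = 0` the
fraction of drugs called accurate then sits at the binomial-sampling
neighbourhood of $\alpha$.

## Problem sizes in the shipped tests

The test suite and the acceptance script run on reduced-scale cohorts
chosen to make every property measurable in seconds while keeping the
relevant group sizes realistic: discovery-style cohorts of 90 lines × 2000
genes; cross-validation with 12 R + 12 S lines over 5 permutations;
null calibration over 100–500 simulated drugs of 60 lines each; and
single-cell runs of 20 lines × 100 cells × 500 genes with 100 replicates.

## Known limitations

- Signatures come from marginal fold changes; correlated or interacting
  genes, and any non-linear expression–response relation, are invisible.
- DRS is relative to the scored dataset: a homogeneous dataset cannot be
  split into resistant and sensitive, and scores are not comparable across
  datasets without a shared scale.
- Gene matching is exact string equality after whitespace trimming; no
  alias or identifier-system resolution.
- The WPCI's absolute level depends on the assumed measurement-noise scale;
  only comparisons at a fixed `noise_sd` are meaningful.
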