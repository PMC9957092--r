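# scDR — drug-response signature scoring for bulk and single-cell expression

Tumor cell populations are heterogeneous, and so is their response to a
drug. scDR transfers resistance signatures learned from pharmacogenomic
cell-line panels (expression profiles plus dose–response AUC values) onto
any new expression profile — a bulk RNA-seq sample or an individual cell —
and returns a per-drug **drug-response score (DRS)** whose higher values
predict resistance. It is aimed at computational biologists who want to
rank cells, samples, or clusters by predicted response, e.g. to find an
intrinsically resistant subpopulation before treatment.

## The method

For one drug, with AUC the area under the percent-viability curve (higher =
more resistant):

1. **Label training lines.** With μ, σ the mean and sample sd of the drug's
   AUCs: lines with `AUC > μ + 0.8σ` are resistant (R), lines with
   `AUC < μ − 0.8σ` sensitive (S); the middle band is unlabelled.
2. **Derive the signature.** Per gene,
   `log2FC = log2((mean_R + c) / (mean_S + c))` on linear-scale expression
   (pseudocount `c = 0.01`); the top 200 up- and top 200 down-regulated
   genes are the drug-response genes (DRGs), weighted by their log2FC.
3. **Score.** Standardize each gene across the samples being scored,
   `z = (exp − mean)/sd`, then
   `DRS = (1/q) Σ log2FC_i · z_i` over the `q` signature genes present.
   For single-cell data, cell scores aggregate to cell-line means (mDRS).

Validation utilities implement the matching statistical framework:
one-sided Wilcoxon separation of R vs S scores (`p < 0.05` = accurate
prediction, exact enumeration for small groups), threefold cross-validation
with per-test min–max rescaling and permutations, and the weighted
probabilistic concordance index (WPCI) for method comparison. A seeded
synthetic-cohort generator (bulk, and negative-binomial single-cell counts
with dropout) makes the whole pipeline testable offline.

## Worked example

The built-in toy cohort is small enough to check by hand:

```r
library(scDR)

toy <- make_toy_fixture()
labels <- classify_cell_lines(toy$response, "toy")
#> <response_labels> drug toy: 2 resistant, 2 sensitive (k = 0.8)

sig <- derive_signature(toy$expr_train, labels, n_top = 2, pseudocount = 0)
sig
#>   gene log2fc
#> 1  UP1      2
#> 2  UP2      1
#> 3  DN1     -2
#> 4  DN2     -1

z <- zscore_transform(toy$expr_score)
#> dropped 1 zero-variance gene(s) before scoring
score_samples(z, sig)$scores
#>   T1   T2   T3
#> -1.5  0.0  1.5
```

Gene UP1 averages 4 in resistant lines and 1 in sensitive lines, hence
`log2FC = 2`; sample T3 expresses the up-genes one sd above the dataset
mean and the down-genes one sd below, hence the maximal score +1.5, while
T1 mirrors it at −1.5. On a realistic synthetic cohort the full loop —
simulate, label from AUC, derive, score, validate — looks like:

```r
cfg  <- sim_config(n_genes = 1000, n_signature_up = 100, n_signature_down = 100,
                   n_resistant = 20, n_sensitive = 20, n_intermediate = 10,
                   effect_log2fc = 1, seed = 7)
bulk <- simulate_bulk_cohort(cfg)
sigs <- derive_all_signatures(bulk$expr, bulk$response, n_top = 100)
drs  <- score_all(bulk$expr, sigs)

lab <- classify_cell_lines(bulk$response, "D01")
wilcoxon_separation(drs$scores["D01", lab$resistant],
                    drs$scores["D01", lab$sensitive], drug = "D01")
#> <separation_result> drug D01: U = 168, p = 8.743e-06 (12 R vs 14 S) -> accurate
```

i.e. held-out-of-nothing discovery scoring cleanly separates the
AUC-labelled resistant lines, and the 200 selected DRGs coincide with the
planted ones (100% recovery on this seed).

## Command line

A thin wrapper over the same functions ships at `inst/cli/scdr.R`
(after installation: `system.file("cli", "scdr.R", package = "scDR")`):

```sh
Rscript scdr.R simulate --preset bulk --seed 1 --out-dir fixtures/
Rscript scdr.R derive   --expr fixtures/expr.tsv --response fixtures/auc.csv \
                        --out signatures.tsv --n-top 200
Rscript scdr.R score    --expr fixtures/expr.tsv --signatures signatures.tsv \
                        --out drs.tsv
Rscript scdr.R validate --drs drs.tsv --labels groups.tsv --out report.tsv
```

Subcommands: `derive`, `score` (dense or MTX input, optional `--qc`
`--normalize`), `mdrs`, `validate`, `cv`, `wpci`, `compare-groups`,
`simulate`. Exit codes: 0 ok, 1 domain error, 2 usage error.

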