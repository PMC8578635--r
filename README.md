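# drugselect

Tools for finding lineage-selective compounds in large cancer cell line
drug screens and characterizing their pharmacology, written for
computational biologists working with pharmacogenomic screening data
(GDSC/PRISM-style IC50 tables), checkerboard combination plates, tumor
expression cohorts, in vitro enzyme inhibition assays, and preclinical
PK profiles.

## What it computes

**Selectivity Score.** For each drug, cell lines are ranked ascending
by IC50 (ties get mean ranks) and the score is

    S = median rank of target-lineage lines / number of lines screened

so S ∈ (0, 1] and a low S flags a compound whose activity concentrates
in the target lineage. Accompanied by Welch two-sided t-tests on
log10 IC50 and Pearson rescreen concordance.

**Dose–response.** Four-parameter log-logistic fits
y(d) = lower + (upper − lower) / (1 + (d/ec50)^(−hill)), closed-form
ICx inversion d = ec50 · (f/(1−f))^(1/hill), and case-resampling
bootstrap confidence intervals (compiled Levenberg–Marquardt core).

**ZIP synergy.** Combination plates normalized to percent cell death
against vehicle/max-kill controls; delta surfaces against the
zero-interaction-potency expectation E = y1 + y2 − y1·y2/100 using
two-directional conditional 4PL fits; synergy/antagonism calls at the
surface extrema by per-replicate log2 fold change (threshold 1.5) and
one-sample t-test (p ≤ 0.01).

**Genomics.** Multivariate IC50 models with directional fold-change
effects (10^|b|-fold per log10 coefficient), genome-wide Spearman
scans of expression vs sensitivity, gene-set shift tests,
regression-based mediation (y ~ exposure vs y ~ exposure + mediator),
ElasticNet feature selection (alpha = 0.5, seeded 10-fold CV via
glmnet), and housekeeping-normalized expression.

**Paralog preference.** From replicated enzyme decatenation assays:
per-run IC25s per paralog, geometric-mean fold preference with a
t-interval CI, and a two-sided simulation p-value (label swap +
residual resampling around a pooled curve).

**PK.** Non-compartmental summaries: trapezoidal AUC, terminal
half-life from the log-linear tail, and Cavg against an exposure
target.

Every input has a seeded synthetic generator (`simulate_*`) with the
ground truth returned next to the data, and `run_pipeline()` drives the
stages end-to-end from a config list or YAML file.

## Worked example

```r
library(drugselect)

# a 50-line x 20-drug screen with one drug given a -1 log10 IC50 shift
# in the target lineage
sim <- simulate_screen(n_lines = 50, n_drugs = 20, target_fraction = 0.2,
                       selective_shift = c(drug010 = -1),
                       tp53_effect = 0, mycn_effect = 0, seed = 1)
rk <- rank_drugs(sim$screen, sim$annotations, "neuroblastoma")
head(rk$results, 3)
#>      drug score n_screened n_target median_target_rank t_statistic     p_value
#> 1 drug010  0.08         50        7                  4  -4.2167445 0.004350393
#> 2 drug013  0.20         50        7                 10  -2.4119868 0.034751736
#> 3 drug005  0.28         50        7                 14  -0.3682461 0.723411584
```

The planted drug ranks first: its median target-lineage line sits at
rank 4 of 50 (score 0.08), and the Welch t-test on log10 IC50 separates
the lineages at p ≈ 0.004. Unshifted drugs drift toward score 0.5.

```r
# paralog preference from a simulated 5-run decatenation assay with a
# true 3-fold preference for enzyme B
dec <- simulate_decatenation(ic25_A = 30, ic25_B = 10, seed = 1)
st <- simulation_test(dec$decat, n_sim = 2000, seed = 1)
st$preference
#> Paralog preference (TOP2A / TOP2B), IC25 fold ratio: 2.96 (95% CI 2.39-3.67) over 5 runs
st$p_value
#> [1] 0.0004997501
```

The estimate brackets the planted 3-fold preference and the simulation
test rejects the no-difference null at the resolution of 2000 null
draws.

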