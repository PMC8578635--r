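---
title: "Methods: selectivity scoring, synergy surfaces, and paralog preference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selectivity scoring, synergy surfaces, and paralog preference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugselect)
```

`drugselect` implements the computational chain by which a
lineage-selective compound can be identified in public drug screens and
then characterized: selectivity scoring, dose–response and ICx work,
combination synergy, genomic association and mediation, an enzyme
paralog preference estimator, and non-compartmental pharmacokinetics.
This vignette records the models, the choices behind them, and what the
synthetic-data generators do and do not emulate.

## Selectivity Score

For a drug screened against $N$ cell lines, lines are ranked ascending
by IC$_{50}$ (rank 1 = most sensitive, ties get mean ranks) and the
score is

$$S = \frac{\mathrm{median\ rank\ of\ target\mbox{-}lineage\ lines}}{N} \in (0, 1],$$

so low $S$ means the target lineage concentrates among the most
sensitive lines. The score depends only on ranks, hence is invariant
under any strictly increasing transform of the sensitivity measure —
which is why `rank_drugs()` accepts any sensitivity column (IC$_{50}$s
or screening fold changes) through `value_col`.

Choices worth recording: ranking direction (ascending, so the top of
the list is the most selective) is fixed here; ties take fractional
mean ranks for permutation invariance; an even number of target lines
takes the standard mean-of-middle-two median; the denominator $N$ is
drug-specific, counting only lines actually screened against that drug.
A subgroup filter (e.g. MYCN-amplified/TP53-wild-type lines) restricts
which target lines define the median while $N$ still counts every
screened line. Drugs with fewer than `min_target` (default 3) target
lines are reported as skipped rather than scored on a meaningless
median. Group comparisons use Welch's unequal-variance two-sided t-test
on log$_{10}$ IC$_{50}$; "t-test" alone underdetermines the flavor and
Welch is the safer default for unequal group sizes and variances.

## Four-parameter log-logistic dose–response

All curve work uses
$$y(d) = \mathrm{lower} + \frac{\mathrm{upper} - \mathrm{lower}}{1 + (d/\mathrm{ec}_{50})^{-h}},$$
with the sign of the hill slope $h$ encoding direction. A 5PL
asymmetry parameter is deliberately out of scope. Fitting is
least-squares in log-dose via a Levenberg–Marquardt core (compiled, so
the resampling machinery stays cheap) with multi-start initialization:
asymptotes from the response extremes, $\mathrm{ec}_{50}$ from the dose
bracketing the half-range crossing, $h \in \{\pm 1, \pm 2\}$; best SSE
wins, ties toward the smallest $|h|$; relative SSE tolerance
$10^{-10}$, at most 10,000 steps. Failures return the best-found
parameters flagged `converged = FALSE`. Zero doses are accepted as data
but excluded from the log-dose fit; predictions treat them as the
limiting asymptote.

ICx values invert the curve in closed form,
$d = \mathrm{ec}_{50}\,(f/(1-f))^{1/h}$ with
$f = (\mathrm{effect} - \mathrm{lower})/(\mathrm{upper} -
\mathrm{lower})$. The default scale is *absolute*: an IC$_{25}$ on a
percent-of-total-activity assay is the dose at which the response
crosses 75% of total, matching how "inhibit 25% of total" is used for
enzyme assays; a relative-to-asymptote mode is available via
`scale = "relative"`. Confidence intervals use a case-resampling
bootstrap (percentile 2.5/97.5, default $B = 1000$, seeded); residual
resampling was rejected because replicate structure in these assays is
at the well level and case resampling makes the fewest distributional
assumptions.

## ZIP synergy surfaces

Combination plates are normalized to percent cell death against the
mean vehicle ($\bar v$, 0% death) and max-kill ($\bar k$, 100% death)
controls: $100(\bar v - x)/(\bar v - \bar k)$. Normalized values are
*not* clipped to $[0, 100]$; clipping would bias the replicate-level
t-tests. The zero-interaction-potency expectation for two percent
effects is $E = y_1 + y_2 - y_1 y_2 / 100$, computed on copies clamped
to $[0, 100]$ inside the formula only.

The reference $\delta$ surface follows the two-directional
conditional-fit scheme of the original ZIP method: 4PL fits to each
monotherapy; per drug-2 dose, a conditional 4PL in the drug-1 dose with
the lower asymptote pinned to the fitted drug-2 effect at that dose
(and symmetrically per drug-1 dose); the fitted combination response is
the mean of the two conditional predictions, and
$\delta(c_1, c_2)$ is that response minus
$E(\hat y_1(c_1), \hat y_2(c_2))$. Rows or columns whose conditional
fit fails fall back to observed values and are flagged. A simpler
observed-minus-expectation mode is available (`mode = "naive"`).
Replicates are averaged before surface fitting; synergy calls go back
to the per-replicate values.

Calls are made at the surface extrema: per-replicate
$\log_2(\mathrm{observed}/E)$ at the highest- and lowest-scoring
concentration pairs, a one-sample two-sided t-test against 0, and
classification at $|\log_2 \mathrm{FC}| \ge 1.5$ with $p \le 0.01$.
The log$_2$-scale threshold is primary; a linear fold-change variant
(`fc_scale = "linear"`) covers the alternative reading of "fold change
of > 1.5". Pairs with non-positive expectation — or a non-positive
observed death, where the log fold change is undefined — are skipped in
favor of the next-ranked pair and logged. Monotherapy responses come
from dedicated single-agent wells when present (the simulator emits
them); a zero-dose row/column would serve the same role.

## Genomic association, mediation, ElasticNet

Associations with sensitivity use log$_{10}$ IC$_{50}$ for regression
models and $1/\mathrm{IC}_{50}$ for genome-wide Spearman scans — both
conventions appear in screening analyses and both are exposed. A
coefficient $b$ on log$_{10}$ IC$_{50}$ is reported as a
$10^{|b|}$-fold increase ($b > 0$) or decrease ($b < 0$) in IC$_{50}$,
with the CI mapped through the same monotone transform. Gene-set shift
tests default to unpaired Welch: a "paired" comparison between an
11-gene set and the remaining genome has no canonical pairing, so the
paired mode exists but demands an explicit pairing rather than guessing
one.

Mediation is the regression formulation: fit $y \sim e$ and
$y \sim e + m$ and report both exposure coefficients and the mediator's
conditional coefficient with their p-values. Full mediation shows up as
a significant marginal exposure effect that disappears conditionally
while the mediator stays significant. No causal search or bootstrap of
indirect effects is attempted.

ElasticNet feature selection fixes $\alpha = 0.5$ and chooses
$\lambda$ by seeded 10-fold cross-validation at the CV minimum (not the
1-SE rule). Fitting is delegated to glmnet, with features standardized
before penalization and an unpenalized intercept. One convention
matters for anyone checking optimality conditions: glmnet's gaussian
path standardizes the response internally, which makes the ridge
component of the mixed penalty effectively
$\lambda(1-\alpha)\|\beta\|^2 / (2\,\mathrm{sd}(y))$ on the original
response scale. The package keeps glmnet's behavior as the reference
(it is the field's standard implementation); the test suite states its
KKT and objective oracles under that convention. Housekeeping
normalization is
$\log_2(\mathrm{TPM} + 1) - \mathrm{mean}_{hk}\,\log_2(\mathrm{TPM}_{hk} + 1)$
with ACTB and GAPDH as the default set; the $+1$ keeps zeros finite and
matches the ubiquitous $\log_2(\mathrm{TPM}+1)$ convention.

## Paralog preference and its simulation test

Each decatenation run yields an IC$_{25}$ per enzyme paralog (dose
inhibiting 25% of total activity, i.e. the 4PL crossing 75% remaining).
"Relative difference" between paralogs is implemented as a fold ratio
aggregated geometrically —
$\exp(\mathrm{mean}_r \log(\mathrm{IC25}_A/\mathrm{IC25}_B))$ — because
a 2–4-fold preference is naturally multiplicative; a percent-difference
summary is also reported per run. The 95% CI is a t-interval on the
per-run log ratios. Runs where either enzyme's curve cannot be fit are
dropped and logged; fewer than three surviving runs is an error. An
optional dose mask removes points beyond a compound's active range
before fitting, as required when an IC level is not reached within the
tested ladder.

Significance comes from simulation, since the per-run statistic is a
nonlinear functional of two fitted curves. The reference null, chosen
here and documented as swappable: per run, fit one pooled curve to the
combined A+B data, randomly swap the enzyme labels, and resample
residuals with replacement (pooled within run) around the shared curve.
Raw residuals from a fitted curve underestimate the noise scale because
the fit absorbs its parameters, which makes a naive residual null
anti-conservative; the resampled residuals are therefore inflated by
the standard degrees-of-freedom factor $\sqrt{m/(m-p)}$ ($m$ pooled
points, $p = 4$ parameters). The null then refits both enzymes and
recomputes the statistic
$|\mathrm{mean}_r \log(\mathrm{IC25}_A/\mathrm{IC25}_B)|$. The p-value
is $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_{sim})$,
deterministic given the seed. Alternatives (resampling runs, or
parameter draws from the fit covariance) would also be defensible; the
label-swap-plus-residual null is the most assumption-light of the
three and is type-I calibrated in the test suite.

## Non-compartmental PK

AUC uses the linear trapezoid by default (a linear-up/log-down variant
is a flag); the terminal slope regresses $\ln C$ on time over the final
`n_terminal` points (default 3, no automatic best-fit point selection —
kept simple and predictable), giving $t_{1/2} = \ln 2 / \lambda_z$; and
$C_{avg} = \mathrm{AUC}/\mathrm{interval}$ is compared
boundary-inclusively against an exposure target (default 100 µg/L).
Exposure comparisons across species are reported as AUC and
$C_{avg}$ ratios; no allometric scaling model is implemented.

## Synthetic data: what it emulates, and what it does not

The generators produce inputs with exactly the statistical structure
the estimators assume, with all parameters overridable and every output
deterministic given its seed (ground truth is returned alongside the
data):

* `simulate_screen()`: log$_{10}$ IC$_{50}$ = drug baseline
  ($\mathcal N(0.5, 0.6)$) + target-lineage shift + genotype effects +
  Gaussian noise (sd 0.4). Defaults anchor to realistic screen
  composition and effect sizes: target-lineage fraction $31/1001$,
  TP53-mutation effect $+\log_{10}(17.45)$ and MYCN-amplification
  effect $-\log_{10}(10.9)$ on log$_{10}$ IC$_{50}$, with genotype
  flags drawn only inside the target lineage (40% and 25% prevalence —
  typical of high-risk neuroblastoma panels).
* `simulate_combination_plate()`: truth = ZIP expectation of two 4PL
  monotherapies plus a configurable interaction (zero, dose-block, or
  smooth bump), pushed through the inverse control-normalization map to
  raw signal, Gaussian noise in percent-death points, 12-point 1:2
  ladders, 4 replicates, dedicated single-agent wells.
* `simulate_expression_chain()`: the exposure→mediator→outcome chain
  (defaults $a = 0.8$, so exposure–mediator correlation $\approx 0.8$;
  direct path 0 for full mediation) plus a 38-column feature matrix
  with 3 planted predictors (standardized effect 0.5) among
  equicorrelated noise ($\rho = 0.3$), and housekeeping genes at fixed
  TPM levels.
* `simulate_decatenation()`: decreasing 4PL activity truths
  parameterized by per-enzyme IC$_{25}$s over a 9-dose geometric ladder
  spanning 1.734–400 µM (an exact 1:2 series cannot hit both printed
  endpoints, so the ladder is geometric with ratio $\approx 1.97$),
  5 runs, Gaussian noise (sd 5 points — moderate for gel
  densitometry).
* `simulate_pk()`: one-compartment $C(t) = (D/V)e^{-kt}$ with
  multiplicative lognormal noise on a 0.5–24 h grid; the default $k$
  corresponds to a 3.7 h half-life.

Noise is Gaussian on log-scale IC$_{50}$s and percent scales and
lognormal on concentrations — the simplest forms consistent with
positivity. The generators make no attempt to match the marginal
distributions of real public screens (drug-class structure, assay
artifacts, batch effects, heavy tails), so passing recovery tests shows
the estimators are correct and calibrated under their stated
assumptions, not that real screens satisfy those assumptions.

## Problem sizes and numerical choices

The test suite exercises the oracle-equivalence check on 1,000 random
tables; planted-effect recovery on 100–200 seeds per estimator;
ZIP null calibration on 200 plates; bootstrap coverage on 200 outer
simulations with $B = 1000$; and the paralog null on 500 datasets at
$n_{sim} = 2000$ (power runs use $n_{sim} = 500$, which still resolves
$p \le 0.01$). These sizes give Monte-Carlo error comfortably inside
the asserted bands. Degenerate inputs fail early with specific errors
(constant responses, fewer than four distinct doses, inverted plate
controls, empty target groups, collinear designs, non-positive
expression); extrapolated ICx values are flagged rather than censored.

## Known limitations

Numerical agreement with any particular release of an external synergy
implementation is not guaranteed (conditional-fit details differ across
versions); the 4PL fitter is a local optimizer — pathological biphasic
data can converge to a local optimum, which is why masks and the
`converged` flag exist; the mediation analysis is associational; and
the PK module is strictly non-compartmental.
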