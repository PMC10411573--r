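---
title: "Predicting tested lines in untested environments with difference-response GBLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting tested lines in untested environments with difference-response GBLUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffgblup)
```

## The prediction problem

Plant-breeding programs routinely need to forecast how lines that have
already been phenotyped somewhere will perform in an environment where
nothing has been measured yet — a new site, season, or management regime.
This is the hardest of the standard genomic-prediction targets: the test
environment contributes no data, and real environments are
*non-stationary*, so the distribution of phenotypes in the new environment
can differ systematically (in mean, most visibly) from every training
environment.

`diffgblup` implements two families of predictors for balanced
multi-environment trials, evaluated with leave-one-environment-out (LOEO)
cross-validation:

* **M1** — conventional multi-environment GBLUP,
  $y_{ij} = \mu + L_i + g_j + gL_{ij} + \varepsilon_{ij}$, with random
  environment effects ($\mathrm{Var}(L) = \sigma^2_L H$), genomic line
  effects ($\sigma^2_g\, Z_g G Z_g'$) and, in the `M1_GE` variant, a
  genotype-by-environment interaction with the Hadamard kernel
  $\sigma^2_{gL}\, H \odot Z_g G Z_g'$. `M1_NO_GE` omits the interaction.
* **M2** — a difference-response method: instead of training on $y$
  directly, the model is trained on pairwise between-environment
  differences $d_{i,i',j} = y_{ij} - y_{i'j}$ and the target environment
  is reconstructed as an ensemble over predicted differences.

## The difference-response method

For $I$ environments and $J$ lines the construction proceeds in five
steps:

1. enumerate all $\binom{I}{2}$ unordered environment pairs
   ($(E_1,E_2), (E_1,E_3), \dots, (E_{I-1},E_I)$);
2. for each pair and line compute $d_{i,i',j} = y_{ij} - y_{i'j}$;
3. stack the pair blocks into one frame of $J\binom{I}{2}$ rows
   (`difference_frame()`);
4. set $d$ to `NA` on every row whose pair involves the target
   environment (`mask_target_env()`); those $J(I-1)$ rows are the testing
   set;
5. fit the GBLUP $d_{i,i',j} = \mu + g_j + \varepsilon$ on the training
   rows — an intercept plus a line effect with covariance
   $\sigma^2_g G$ — and predict $\hat d$ on the masked rows
   (`fit_difference_model()`).

Predictions return to the phenotype scale as an ensemble over the $I-1$
masked pairs containing the target environment $t$:
$$\hat y_{t,j} = \frac{1}{I-1} \sum_{i'} \left( y_{i',j} + s\,\hat
d\right),$$
where $i'$ is the training environment of each pair. The published form of
this expression is written for the case where $t$ is the pair's first
element; when $t$ is the *second* element the difference estimates
$y_{i'} - y_t$, so the term must enter as $y_{i',j} - \hat d$. We use the
signed contribution ($s = +1$ or $-1$ accordingly): it is the unique
convention under which perfect difference predictions recover the target
phenotypes exactly for *every* choice of target environment (the
telescoping identity checked in the test suite), not just the first.

Two structural points are worth stating plainly:

* The genetic main effect $g_j$ cancels in every difference, so the
  difference model's line effect captures only line-specific *patterns of
  environmental response*. The genetic main effect re-enters the
  prediction directly through the observed $y_{i',j}$ of the same line —
  M2 leans on each line's own records rather than on shrinkage through
  the relationship matrix.
* Eq-style model for $d$ carries a single global intercept. Differences
  from distinct pairs have distinct expectations ($L_i - L_{i'}$), so the
  intercept estimates their average over training pairs. A consequence,
  verified in the tests, is that level changes confined to the *target*
  environment can never reach the predictions (they touch neither the
  training differences nor the training phenotypes used by the ensemble).
  Level changes in a *training* environment propagate partially; with a
  single global intercept they do not cancel term-by-term.

## The mixed-model engine

All fits go through one engine, `fit_gblup()`, which maximizes the
restricted likelihood of the observed subvector of
$y \sim N(1\mu, \sum_k \sigma^2_k K_k + \sigma^2 I)$ and predicts random
effects at every position (observed or masked) from their conditional
mean. Held-out observations therefore receive predictions without ever
influencing estimation.

Numerical choices:

* **Average-information steps with a monotonicity guard.** Each iteration
  proposes an AI (Newton-type) update of the variance components; the
  step is halved until the restricted log-likelihood does not decrease,
  and falls back to the EM direction (a positively-scaled gradient, hence
  guaranteed ascent) when the AI step fails. The stored `loglik_trace` is
  consequently non-decreasing, which the test suite asserts. AI steps
  converge in roughly 10–30 iterations where plain EM needs hundreds of
  equally expensive $O(n^3)$ passes.
* **Convergence** when the maximum relative component change falls below
  `tol` (default `1e-6`), or when the likelihood gain of an iteration
  drops below `1e-7` of the total improvement — near-flat likelihood
  ridges (e.g. an environment variance supported by three environments)
  otherwise produce long, irrelevant crawls. 500 iterations maximum,
  with an honest `converged` flag.
* **Variance floor** at `1e-10 * var(y_obs)`, keeping the covariance
  invertible. The floor is relative, so rescaling the response rescales
  every estimate exactly (scale equivariance holds even at the floor).
* **Stabilizing ridge** `1e-8 * mean(diag(G))` on the GRM diagonal, since
  finite-precision Gram matrices can carry tiny negative eigenvalues.
* Variance components fixed via `fix =` skip estimation; with all
  components fixed the fit is the kernel-ridge/BLUP closed form, which
  the tests compare against an explicit matrix-inverse oracle.

A compact Gibbs sampler (`method = "gibbs"`; eigen-basis single-site
updates, scaled inverse-$\chi^2$ priors with 5 degrees of freedom, prior
scales from an equal-split $R^2 = 0.5$ heuristic, defaults
6000/1000/thin 2) is included for comparison runs. It requires an
explicit seed; REML is the default everywhere and is what the evaluation
pipeline and all reported numbers use, because it is deterministic.

## Relationship matrices and marker QC

The genomic relationship matrix is VanRaden's
$G = WW' / (2\sum_k p_k(1-p_k))$ with columns centered at $2p_k$.
Markers fixed for one allele ($p_k \in \{0, 1\}$) are excluded from
numerator and denominator; zero-variance columns at intermediate
frequency (possible after imputation) contribute zero to $W$ but keep
their denominator term, matching the standard formula. Marker QC removes
markers with more than 15% missing genotypes or minor allele frequency
below 0.05 (both configurable); MAF is always computed on raw,
pre-imputation dosages so imputation cannot alter QC decisions. Missing
genotypes are mean-imputed per marker — a deterministic choice adequate
at the low missingness rates simulated here; model-based imputation of
heavily missing panels is out of scope.

The environmental kernel is the incidence cross-product
$H = X_L X_L' / \mathrm{scale}$. The divisor is exposed as `scale`
(default 1) because any positive value is absorbed into $\sigma^2_L$
during fitting; predictions are invariant to it.

## The trial simulator

`simulate_markers()` draws allele frequencies uniformly from a MAF window
and dosages as independent $\mathrm{Binomial}(2, p)$ — an unstructured,
linkage-free panel. `simulate_trial()` generates phenotypes from the same
additive model M1 fits: marker-determined line values
$g = Ww$ with $w \sim N(0, \sigma^2_g / 2\sum p_k q_k)$, environment
effects $L_i \sim N(0, \sigma^2_L)$, interaction from independent
environment-specific marker-effect deviations (so the interaction
covariance is separable, matching the Hadamard kernel in expectation),
and i.i.d. residuals. Defaults
($\sigma^2_g, \sigma^2_L, \sigma^2_{gL}, \sigma^2$) = (1, 1, 0.25, 0.5)
give a per-environment heritability around 0.6, typical of yield-type
traits in the trial sizes this package emulates.

Non-stationarity is injected as a deterministic mean `shift` added to one
designated environment — the simplest train/test distribution mismatch:
when the shifted environment is held out, no predictor can see the shift;
when it is in training, it biases whatever absorbs environment levels.

What the simulator deliberately does **not** emulate: linkage
disequilibrium and population structure; heteroscedastic environments;
non-Gaussian tails; and — importantly — genetic variation not captured by
the markers. The last point shapes what the simulation study can show
(next section).

## What the synthetic comparison does and does not show

On data generated *from M1's own model*, M1 with REML is essentially the
Bayes-optimal predictor, and the marker-determined $g$ makes GBLUP's
relationship-based shrinkage nearly exact. The package's simulation study
(tests and `scripts/acceptance.R`) accordingly finds M2 and M1 within a
few hundredths of a correlation point of each other, with M1 holding a
small edge that persists under the mean-shift scenario — the shift biases
both predictors' levels by comparable amounts, since M1's intercept and
M2's ensemble terms both average training-environment levels. The
structural robustness that the difference construction *does* buy —
target-environment level changes provably cannot reach the predictions —
is asserted exactly, and the two approaches agree closely (within 0.1
APC) in the stationary no-interaction setting.

The large LOEO gains reported for this method on real multi-environment
data arise where the conventional model is misspecified: genetic signal
not carried by the markers favors M2's direct use of each line's own
records over shrinkage through $G$, and real environmental structure is
richer than an exchangeable random effect. Reproducing those gains
requires the real data sets; a generator matched to M1's assumptions
cannot, and the package does not claim otherwise.

## Evaluation protocol and metrics

`loeo_evaluate()` runs every requested model over every LOEO fold and
trait and reports four testing-set metrics per (trait, environment,
model):

* **APC** — Pearson correlation between observed and predicted values,
  averaged over folds (groups with constant vectors are excluded with a
  warning);
* **Best10 / Best20** — percentage of the truly best 10% / 20% of lines
  (by observed value, within the environment) recovered among the
  predicted best; $k = \max(1, \mathrm{round}(fJ))$, ties broken by line
  order; "best" defaults to largest, with a per-trait flag for
  smaller-is-better scales such as 1–5 disease severity;
* **NRMSE** — RMSE divided by the absolute testing-group mean (range
  normalization available), lower is better.

Relative gains are $100(\text{challenger} - \text{reference}) /
|\text{reference}|$ for higher-is-better metrics and
$100(\text{reference} - \text{challenger}) / |\text{challenger}|$ for
NRMSE; the latter convention permits gains above 100%. Headline numbers
average per-environment values within trait, then across traits. Exact
formulas for the normalization and gains are conventions of this package;
they are stated here because more than one convention is in circulation.

## Problem sizes used by the shipped studies

The test suite and acceptance script run entirely on simulated data, at
sizes chosen to exercise the methods while staying desk-scale: variance
recovery at $J = 300$, $I = 4$ over 20 replicates; the mean-shift
comparison at $J = 200$, $I = 4$ over 30 replicates (shift of two
residual SDs); the acceptance script's study at $J = 150$, $I = 4$ over
10 replicates; structural checks up to $J = 722$ lines (the largest
benchmark design emulated). The REML engine handles these in seconds to a
few minutes on one core.

## Known limitations

* M2 requires at least three environments and a balanced table; it
  predicts tested lines in untested environments only — untested lines
  are out of scope.
* Differences sharing an environment are correlated, but the difference
  model treats residuals as i.i.d., as the method's single-residual
  formulation specifies; modeling the induced correlation is a possible
  extension.
* One trait is modeled at a time; multi-trait covariance and
  environmental covariates are not implemented.
* The Gibbs fitter is a comparison tool, not the default; its prior
  scales follow a simple variance-split heuristic.
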