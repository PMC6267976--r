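---
title: "Predicting community assembly from traits: the CATS pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting community assembly from traits: the CATS pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catspredict)
```

## The problem

Environmental filtering theory holds that abiotic conditions select species
whose functional traits confer high local fitness, so the trait profile of a
community tracks its environment. The Community Assembly by Trait Selection
(CATS) model turns that premise into a quantitative prediction: given the
community-weighted mean (CWM) trait values $\bar T_j$ expected in an
environment, it predicts the relative abundance $p_i$ of every species in
the pool as the solution of

$$\max_p \; -\sum_{i=1}^S p_i \ln p_i
\quad\text{s.t.}\quad \sum_i p_i t_{ij} = \bar T_j \;(j = 1 \ldots J),
\quad \sum_i p_i = 1,\; p_i \ge 0,$$

i.e. the most even distribution consistent with the trait constraints. With
fewer constraints than species the linear system is underdetermined;
maximizing entropy resolves the ambiguity without injecting information
beyond the constraints themselves.

`catspredict` implements the full workflow around that core: calibrating
CWM–environment relationships on vegetation survey data, predicting CWM
constraints for new environments, solving the maxent problem, and scoring
predictions against observed communities with permutation inference.

## The maxent solver

The solution has the Gibbs form
$p_i \propto q_i \exp(\sum_j \lambda_j \tilde t_{ij})$ with prior $q$
(uniform by default — the unweighted model, which is the standard choice
when no independent metacommunity abundance information exists). We solve
the convex dual $\log Z(\lambda) - \lambda^\top \tilde T$ by damped Newton
iteration with log–sum–exp stabilization; the Hessian is the trait
covariance under the current $p$, so convergence is quadratic and the
problems arising here (a handful of species, up to three traits) converge
in a few iterations. Convergence is declared when the largest constraint
residual falls below `tol` (default $10^{-8}$) *in standardized trait
units*: trait columns are z-scored over the species pool before solving
because seed mass (mg), specific root length (m g$^{-1}$) and flowering
date (Julian day) are incommensurate. The reported solution is provably
invariant to any affine rescaling of a trait column and its constraint, and
the test suite checks this, so standardization affects only the meaning of
the tolerance, never the answer.

A CWM constraint vector is attainable only if it lies in the convex hull of
the species' trait vectors. Constraints predicted by a regression model can
leave the hull — particularly when the model extrapolates, as it must for a
full-sun prediction at the edge of a shaded field gradient. By default
`solve_maxent()` refuses such targets with the projection report;
`on_infeasible = "project"` substitutes the Euclidean projection onto the
hull (computed by accelerated projected gradient with an exact active-set
polish) and records the projection distance, because silently projecting
would mask calibration pathologies. Degenerate pools behave sensibly:
species with identical trait vectors receive identical abundances, forced
by the symmetry of the objective.

## The trait–environment stage

CWM traits are modeled as additive smooth functions of soil pH and pine
basal area with penalized cubic regression splines
(`mgcv::gam`, basis dimension $k = 10$ per term — the conventional
"maximum smoothing" setting — Gaussian errors, smoothness chosen by
generalized cross-validation, the historical default of that fitting
engine). Per-term significance uses approximate F-tests on effective
degrees of freedom and is labeled as approximate in the fit object.

Predictions outside the training range of either predictor are returned
with an explicit extrapolation flag rather than refused: predicting a
full-sun treatment means evaluating at basal area 0, the very edge of (or
beyond) typical field coverage, and that decision belongs to the analyst.
Fits serialize to JSON (coefficients, smoothing parameters, training data
and ranges); reconstruction refits the same bases with the smoothing
parameters fixed, which reproduces coefficients and predictions exactly and
lets calibration and prediction run as separate steps.

## Evaluation

Two complementary fit statistics compare a treatment × species matrix of
predictions with observed treatment means: the squared Pearson correlation
over all flattened cells of the *untransformed* relative abundances
(a "degree of correlation" measure, not regression-through-origin), and the
root-mean-square error of *square-root transformed* abundances, which
weights subordinate species more evenly. Significance comes from a
permutation null (999 draws by default): species entries are permuted
independently within each treatment row while predictions stay fixed. The
within-row scheme preserves each treatment's abundance profile (and row
sums) while destroying species identity — which is exactly the hypothesis
a trait-based prediction stakes out. Permuting whole rows across treatments
is available as an option (`scheme = "rows"`) since either reading of
"permuting observed abundances" is defensible. The p-value includes the
observed statistic, $p = (1 + b)/(1 + m)$, guaranteeing validity and an
attainable minimum of 0.001 at 999 permutations.

Dominant-species accuracy asks a blunter question — does the model name the
right winner per treatment, and in what fraction of individual pots? Ties
in an observed maximum count as a hit when the predicted dominant is among
the tied species. Pots where nothing emerged are flagged at load time and
excluded from treatment means and accuracy denominators, never silently
dropped from the data.

Two-way PerMANOVA (Bray–Curtis distances for community composition,
Euclidean for single species or per-pot CWM traits) partitions the
distance matrix by sequential (Type I) projections for the two factors and
their interaction, with free permutation of samples. Fitting is delegated
to `vegan::adonis2`, the field-standard implementation; the projection
formulation handles mildly unbalanced cell counts such as 17/17/16/16.
For Euclidean distances on a univariate response each pseudo-F equals the
classical two-way ANOVA F exactly, and the test suite verifies this
identity to $10^{-8}$ against `lm()`/`anova()` as well as the nominal
type-I error of the permutation p.

## The synthetic-data generator

No public deposit exists for field quadrat data of the kind this pipeline
calibrates on, so the package carries its own generator, and every stage is
validated by parameter recovery against generated truth.

`generate_landscape()` emulates a survey of 96 one-m² quadrats spread over
soil pH 5.5–7.5 and pine basal area 0–59 m² ha$^{-1}$, with a 79-species
pool (lognormal seed mass and SRL, normal flowering dates). Expected
relative abundance follows a Gaussian fitness kernel per trait,
$\exp(-(t_i - \mathrm{opt}(q))^2 / 2\sigma^2)$, multiplied across traits,
with optima moving linearly along the gradients in field-typical
directions (community seed mass declining with pH and rising with shade;
SRL and flowering date the converse). The kernel operates on a log scale
for the two multiplicative traits. This is deliberately the simplest
mechanism that yields both smooth CWM–environment surfaces for the
regression stage and treatment-dependent dominance for the experiment
stage. Defaults, chosen once: kernel width 0.6 pool-SD (strong filtering),
optimum sweep ±1 pool-SD, and Dirichlet concentration 22 for realized
cover, calibrated so quadrat-level CWM noise is roughly one tenth of the
CWM signal range — a moderately noisy survey.

`generate_experiment()` sows a five-species subset (by default the five
most abundant in expectation, mirroring how dominant grasses would be
picked from a survey) into a 2×2 sun/shade × limestone/basalt design
(pH 6.8/5.9, basal area 0/59) with 17/17/16/16 replicate pots and 12 seeds
per species per pot. Emergence is an independent binomial per species with
probability proportional to the same kernel at the treatment environment
(0.6 at the kernel optimum). Competition is deliberately absent:
post-emergence survival in such experiments is near-total, so the filter
acts at emergence.

What the generator does *not* emulate — and therefore what passing tests do
not demonstrate about real data: pot-level overdispersion and
micro-environmental heterogeneity, species interactions, dispersal
limitation, dormancy, observer error in cover estimates, and
trait measurement error. Binomial-only emergence noise makes treatment
signals crisper than real pot data, which is visible in the package's
synthetic stand-in experiment: its variance-partition statistics are
substantially stronger than those typically reported from comparable real
experiments.

## The shipped stand-in data

`inst/extdata/` contains three small CSVs prefixed `synthetic_`: a
five-grass trait table, a table of treatment-level CWM constraints and a
66-pot observed count matrix. They are *synthetic stand-ins*, constructed
once from qualitative published descriptions of such systems (C4 grasses
with small seeds, high SRL and late flowering; C3 grasses the converse;
sun treatments with higher CWM SRL and later flowering; a narrow
sun-limestone race between *Bouteloua gracilis* and *Poa fendleriana*),
not measured data. They exist so that every stage of the pipeline has a
runnable, shape-faithful example; quantitative statistics computed from
them characterize the stand-ins, not any field study.

## Numerical choices and conventions

- Relative-abundance rows must sum to 1 within $10^{-9}$ absolute — ample
  for double accumulation at $S \le 100$ species.
- All-zero samples are kept and flagged (`zero_rows` attribute); CWMs for
  them are `NA` and they are excluded from fitting, treatment means and
  accuracy counts.
- Missing trait values are a hard error, not imputed.
- Hull membership uses a $10^{-8}$ tolerance on the projection distance in
  standardized units; `standardize = FALSE` reproduces raw-unit distances.
- The end-to-end recovery check (simulate → calibrate → predict → maxent →
  score) asserts mean $R^2 \ge 0.5$ over 10 generator seeds, with a 0.3
  per-seed floor: the chain includes a deliberate model mismatch (the
  maxent stage sees only 5 of 79 species and regression-predicted
  constraints), so per-seed variation is expected and the mean is the
  meaningful summary.
- Null-model behavior of the smooth fits is likewise checked on the mean of
  replicates: GCV occasionally overfits a single pure-noise draw, which is
  a known property of GCV, not a defect of the wrapper.
- Validation problem sizes (96 quadrats, 79 species, 10 seeds, 999
  permutations for headline statistics, 199 for repeated level checks,
  500 null replicates) were chosen as the smallest sizes at which the
  corresponding sampling distributions are informative.

## Known limitations

- Predicted CWM constraints can fall outside the five-species trait hull
  when the regression extrapolates; `project` mode keeps the pipeline
  running but solutions then sit on the hull boundary (some species pinned
  to zero), and recovery quality degrades with projection distance. The
  per-treatment diagnostics record that distance; inspect it.
- The dual Newton solver assumes a feasible target after projection;
  targets exactly on a hull vertex drive $\lambda \to \infty$ and are
  reported with the boundary solution and a non-converged flag.
- Smoothness selection by GCV is mildly optimistic in small samples;
  per-term p-values are approximate and should be read as guidance.
- Bray–Curtis distances are undefined for empty communities; exclude
  flagged zero pots before calling `bray_curtis()`.
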