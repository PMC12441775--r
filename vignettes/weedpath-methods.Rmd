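---
title: "Methods behind weedpath: diversity, herbicide intensity, and their mutual influence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind weedpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weedpath)
```

## The scientific setting

`weedpath` implements the statistical chain of a randomized-block
herbicide field-trial study in winter wheat.  Fifteen experimental
fields act as blocks; within each field, plots receive one of five
decision-making treatments for herbicide use: a decision support system
(DSS) with standard density-dependent target efficacies (`DSSstd`), the
same DSS with targets reduced by 3–15 percentage points (`DSSred`), a
local advisor who inspects the field (`AdvLoc`), the standard
recommendation of an advisory service without field inspection
(`AdvSer`), and an untreated control.  Weed densities are counted per
species in autumn before any treatment; weed dry biomass per species is
cut, dried and weighed in early summer.

The scientific questions are (i) whether the decision rules differ in
herbicide intensity and in the weed diversity they leave behind, and
(ii) whether weed diversity and herbicide intensity influence each
other mutually: diversity in autumn may lower the intensity a decision
rule demands, and intensity in turn suppresses diversity later in the
season.

## Diversity along the Hill series

All diversity metrics are Hill numbers
$$ {}^{a}D \;=\; \Big(\sum_{i=1}^{S} p_i^{\,a}\Big)^{1/(1-a)}, $$
where $p_i$ is the proportional abundance of species $i$ (plant counts
in autumn, dry biomass in summer).  The series interpolates species
richness ($a = 0$), the exponential of Shannon entropy ($a = 1$,
evaluated by its analytic limit $\exp(-\sum p_i \ln p_i)$), the inverse
Simpson index ($a = 2$) and the reciprocal Berger–Parker dominance
index ($a = \infty$, evaluated as $1/\max_i p_i$).  Values of $a$
within $10^{-9}$ of 1 dispatch to the entropy limit, and `Inf` to the
dominance limit, so the profile is continuous across its special
points.  Species with zero abundance are dropped before any
exponentiation, which avoids the $0^0$ ambiguity at $a = 0$ and makes
the order-0 value exactly the count of species present.  Shannon
entropy uses natural logarithms throughout, so
`exp(shannon_index(p)) == hill_diversity(p, 1)` holds exactly.

Gamma-diversity pools raw quantities over fields before normalizing;
alpha-diversity is the unweighted arithmetic mean of per-field
diversities (Whittaker partitioning; no field weighting is applied
because field areas are identical by design).  Within a field,
quantities are pooled across the four blocks before computing
proportions, mirroring how the surveys are aggregated for decisions.

## Treatment frequency index

Herbicide intensity is the treatment frequency index
$$ \mathrm{TFI} = \sum_{r} \frac{\text{applied dose}_r}{\text{registered dose}_r} $$
over all product applications $r$ of one field and treatment within a
cropping year.  Tank-mix partners contribute one term each, follow-up
treatments simply add, and the untreated control has TFI 0.  The index
is additive over disjoint record sets and invariant to rescaling a
product's dose unit.  An applied dose above the registered dose raises
a warning rather than an error: products are authorized *up to* the
registered dose, so such a record is a data-entry anomaly worth
flagging but not necessarily fatal.  Relative biomass reports
(`relative_biomass()`) round half away from zero to whole percent,
matching the convention of printed trial tables.

## Exact all-pairs comparisons of Friedman-type ranks

Treatment effects on TFI, biomass and diversity are tested by ranking
the responses within each field (blocks) and comparing, for every
unordered treatment pair $(i, j)$, the rank-sum difference
$D = \sum_b (r_{bi} - r_{bj})$.  Under the null hypothesis each
block's joint ranking is uniform over the $k!$ permutations, so the
single-block difference $d$ has
$$ P(d) = \frac{k - |d|}{k(k-1)}, \qquad d \in \{\pm 1, \dots, \pm(k-1)\}, $$
and the $n$-block difference is the $n$-fold convolution of this pmf.
The two-sided p-value is $P(|D^\ast| \ge |D|)$ computed from the exact
convolution; no multiplicity adjustment is applied, matching the
reporting convention of the trial.  The convolution is validated in the
test suite against exhaustive enumeration over all $(k!)^n$ joint
rankings for $n \le 3$, $k \le 4$.

The exact null assumes tie-free ranks.  When any block contains tied
responses, the package falls back to a seeded Monte-Carlo permutation
test that permutes each block's observed mid-ranks (default $10^5$
resamples, reported as `method = "approximate"`), because the
convolution null is not defined for ties.

Homogeneous subgroups are displayed as compact letters via
insert-and-absorb: starting from one set holding all treatments, each
significant pair splits every set containing both members, and sets
contained in others are absorbed.  Letters are ordered by decreasing
mean rank; this ordering is cosmetic but fixed for determinism.  Two
treatments share a letter exactly when their pairwise p-value exceeds
$\alpha$ (default 0.05).

Because the null distribution is discrete, the largest attainable test
size at $\alpha = 0.05$ with 15 blocks and 4 treatments is 0.0392, not
0.05; simulation checks of the rejection rate are therefore calibrated
against that attainable size.

## The multi-group path model

Per treatment group $g$, four observed variables — autumn diversity
$D_{aut}$ (richness or Shannon index), log autumn density
$\log N_{aut}$, TFI, and summer diversity $D_{sum}$ — follow the
recursive system

$$ \mathrm{TFI} = \alpha_1 + a\,D_{aut} + b \log N_{aut} + \varepsilon_1,
\qquad
D_{sum} = \alpha_2 + c\,\mathrm{TFI} + d\,D_{aut} + e \log N_{aut} + \varepsilon_2, $$

with $f = \mathrm{cov}(D_{aut}, \log N_{aut})$ the exogenous
covariance.  Densities are log-transformed (natural log by
convention; the base only rescales $b$ and $e$) to tame the leverage of
high-density fields.  Only treated groups enter the model: the
untreated control has constant TFI 0, which makes the first equation's
likelihood degenerate, and the fitter rejects any group with a constant
response outright.

Estimation is normal-theory maximum likelihood.  Because the system is
recursive, the likelihood factorizes into the exogenous bivariate
normal block and two Gaussian regressions.  With no cross-group
constraints every block is saturated and the coefficient estimates
coincide with per-group ordinary least squares (verified against a
normal-equations oracle to $10^{-8}$).  With equality constraints the
affected equation is maximized by coordinate ascent — weighted least
squares across groups given the group residual variances, exact ML
variance updates given the coefficients — iterated until successive
log-likelihoods differ by less than $10^{-10}$; both half-steps are
exact maximizations, so the likelihood ascends monotonically.
Constraining $f$ leaves the exogenous variances free and equates only
the covariance, fitted by a block-coordinate scheme with the covariance
profiled on its positive-definite interval.

Conventions worth stating because $n = 15$ per group makes them
visible:

* The likelihood and the reported residual variances use ML ($1/n$)
  moments.
* Standard errors of coefficients use degrees-of-freedom-corrected
  residual variances ($n - p$ per equation and group), as in
  least-squares practice; the reported exogenous covariance $f$ uses
  the unbiased ($n-1$) convention with a matching correction.  Pure
  $1/n$ standard errors would undercover noticeably at this sample
  size (measured 88.8% for nominal 95% intervals; 92.6% with the
  correction).
* Standardized coefficients multiply each estimate by
  sd(predictor)/sd(response) within the group; the ratio is invariant
  to the variance convention.  Standardized $f$ is the Pearson
  correlation.
* Coefficient p-values are two-sided normal ($z$) tests.

Model selection constrains parameters equal across groups stepwise:
at each step every still-free family among $\{a, b, c, d, e, f\}$ is
tentatively constrained, the candidate with the largest
likelihood-ratio p-value is accepted if that p-value exceeds
`alpha_keep` (default 0.05, a conventional choice), and the loop
repeats.  Constraining one family across $G$ groups frees $G - 1$
parameters, which is the LRT's degrees of freedom.  The greedy
largest-p order is a deliberate choice where the procedure was
specified only as "stepwise"; it is deterministic given the data.

A caveat the package documents rather than hides: at 15 fields per
group the ML likelihood-ratio test is anti-conservative (empirically a
14% rejection rate at nominal 5% for a 3-df constraint; the chi-square
reference is accurate by 60 fields per group).  Uniformity of the LRT
p-value under a true constraint is therefore verified in the test
suite at $n = 60$.  Consequently, at the trial's size, stepwise
selection tends to leave a few truly-shared parameters unconstrained
more often than the nominal level suggests, and heterogeneous
parameters whose spread is near the $3\times$SE detectability
threshold are isolated in only about half of replicates; clear
patterns (spreads of $\ge 5$ SEs) are recovered reliably.

Mediation follows the product rule: the indirect effect of log density
on summer diversity through herbicide intensity is $b \times c$, and
the total effect is $e + b \times c$.

## The synthetic-trial generator

The raw trial data are not public, so the package ships a seeded
generator with two modes.

**Structural mode** draws $(D_{aut}, \log N_{aut})$ per group and field
from a bivariate normal and applies the structural equations plus
Gaussian noise.  Defaults encode the reported study conditions: 15
fields, four treated groups, autumn richness mean 10 (SD 2, giving the
surveyed 6–14 range), log density mean 4.66 and SD 0.92 (densities
about 17–662 plants m$^{-2}$), exogenous correlation 0.54, group TFI
means 1.37/1.07/1.40/1.53, and standardized path coefficients matching
the reported species-richness model; coefficients are converted to
natural units at those scales and residual variances follow from the
implied $R^2$, so the generated data reproduce the standardized
pattern in expectation.  This mode backs the parameter-recovery and
selection tests.

**Mechanistic mode** emulates the decision process itself.  Each field
receives a species community from a 21-species pool (EPPO-coded,
dominated by *Viola arvensis*, *Matricaria* spec. and *Papaver
rhoeas*) with per-species occurrence probabilities and log-normal
abundance weights; autumn counts are Poisson draws over ten 0.1-m²
quadrats per block.  Herbicide action follows log-logistic
dose–response curves per species × product,
$E(x) = E_{\max} x^s / (x^s + \mathrm{ED}_{50}^s)$ with $x$ the dose as
a fraction of the registered dose — the curve family a dose-response
DSS is built on, with invented parameters since no real herbicide
database is public.  The DSS rule assigns each species a fixed
most-cost-efficient product and inverts its curve at a
density-dependent target efficacy; the target rises with density and
competitiveness.  Because the species-to-product assignment does not
depend on the targets (all default curves reach their maximum efficacy
above any default target), reducing target efficacies — the `DSSred`
rule, 3–15 points depending on competitiveness — provably never
increases the TFI, a property the tests assert seed by seed.  The two
advisor rules are deliberate caricatures: `AdvLoc` treats the
dominant species of the inspected field with their portfolio products
at a fixed strong dose, `AdvSer` applies a fixed broad-spectrum plan
regardless of field state.  Survival per species multiplies
$(1 - \text{efficacy})$ across applied products under a stochastic
application-quality factor; summer biomass is a Poisson count of
survivors over the four 1-m² cut plots times per-species unit mass
under log-normal noise, so rare species genuinely drop out of treated
plots and summer richness falls below autumn richness.

Default calibration targets the printed trial summaries: treated
relative biomass means of roughly 6–12% of the untreated control and
treatment-mean TFIs near 1.3/1.2/1.3/1.5, with the density→intensity
coupling ($b$) strong under the DSS rules and near zero under the
fixed advisor plans.  What the generator does **not** emulate — and
what passing tests therefore cannot certify about real data — includes
spatial heterogeneity within fields, weather and soil effects,
seed-bank dynamics, herbicide resistance, and real advisory behaviour;
the advisor rules in particular are calibration devices, not claims
about practice.

## The pipeline

`run_pipeline()` chains generation (or user tables), validation,
TFI computation, biomass summaries with exact rank tests and letters,
alpha/gamma partitioning, Hill profiles per order with letters, and
the stepwise multi-group path model, writing tidy CSVs plus a JSON
manifest (package version, seed, configuration hash) sufficient to
reproduce a run.  Validation distinguishes errors (negative biomass,
nonpositive doses, incomplete field × treatment layouts) from warnings
(applied dose above registered dose).  The observations table it
writes is itself a valid path-model input, so outputs are closed under
re-ingestion.

## Problem sizes used in the checks

Simulation-based tests use sizes chosen to make their Monte-Carlo
error small relative to the asserted bounds: 1000 random communities
for the Hill-series laws, 5000 null matrices for the rank-test size,
500 structural datasets for parameter recovery and interval coverage,
100 seeds for stepwise selection, and 10–30 mechanistic trials for the
generator's qualitative pattern.  All are driven by fixed or
command-line seeds and are deterministic end to end.
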