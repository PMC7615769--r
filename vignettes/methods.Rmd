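---
title: "Methods: hierarchical meta-regression for the double burden of malnutrition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical meta-regression for the double burden of malnutrition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

National trends in the prevalence of low BMI (underweight in adults,
thinness in school-aged children and adolescents) and obesity must be
estimated from a heterogeneous pool of population-based studies: countries
differ enormously in how many studies they have (some have none), studies
differ in coverage (nationally representative, subnational, or
community-based), in urban/rural composition, in sample size, and in the
years and age ranges they measured.  A hierarchical Bayesian
meta-regression handles all of this in one model: each country-year
estimate is informed by that country's own data where available, and
otherwise borrows strength from other years in the same country, from its
region, and from the world.  All reported quantities — the double burden
(the sum of low-BMI and obesity prevalence), the obesity share of the
double burden, age-standardised rates, posterior probabilities of change
and of dominance, persons affected — are computed at the posterior draw
level, never from summaries.

## Model

For study observation $i$ of one BMI category and one sex, with observed
prevalence $p_i$ from $n_i$ measured participants, the likelihood operates
on the logit scale.  With $x_i = \mathrm{round}(p_i n_i)$ (ties away from
zero) and the continuity-corrected proportion
$\tilde p_i = (x_i + 1/2)/(n_i + 1)$,

$$ y_i = \mathrm{logit}(\tilde p_i), \qquad
   v_i = \frac{1}{(n_i+1)\,\tilde p_i (1-\tilde p_i)}, $$

the delta-method sampling variance.  The correction keeps $y_i$ and $v_i$
finite for observed prevalences of exactly 0 or 1.  The model is

$$ y_i \sim \mathcal N(\mu_i, v_i), \qquad
   \mu_i = a_0 + a_{r(i)} + a_{c(i)}
         + (b_0 + b_{r(i)} + b_{c(i)})\,t_i
         + u_0(t_i) + u_{r(i)}(t_i) + u_{c(i)}(t_i)
         + B(\mathrm{age}_i)^\top(\gamma_0 + \gamma_{r(i)} + \gamma_{c(i)})
         + \delta_{\mathrm{cov}(i)} + \beta_u u_i + e_{s(i)}, $$

where $r$, $c$, $s$ index region, country, and study; $t$ is calendar year
standardised to $[-1, 1]$.  Non-linear change over time enters through
second-order random walks $u_\ell(t)$ at the global, region, and country
levels, each with its own innovation variance and each constrained to be
orthogonal to the intercept and slope (sum zero and zero linear trend) so
the decomposition is identified; the constraint is built into the
parameterisation (the RW2 vectors live in the orthogonal complement of
$\{1, t\}$), so it holds to machine precision at every MCMC iteration.
Age patterns are cubic B-splines over the age-grid midpoints (interior
knots at 35/50/65 for adults, 10/15 for school ages), with hierarchical
global/region/country coefficients; the basis is centered over the grid so
the age curve carries no intercept.  The open-ended 85+ band is pinned to
the spline's boundary value at age 85.

Subnational and community studies may differ systematically from national
ones and vary more: $\delta_{\mathrm{sub}}$ and $\delta_{\mathrm{comm}}$
capture the systematic offsets, and study-level random effects $e_s$ have
coverage-class-specific variances
$\tau^2_{\mathrm{nat}} \le \tau^2_{\mathrm{sub}} \le \tau^2_{\mathrm{comm}}$
(the ordering is an empirical expectation, not a constraint).  No further
residual variance is added beyond $v_i$ and the study effects; extra-
binomial dispersion is absorbed by the $\tau^2$.  Urbanisation enters as
$\beta_u u_i$ with $u \in \{+1\ \mathrm{urban}, -1\ \mathrm{rural},
0\ \mathrm{mixed}\}$ — a deliberate simplification; predictions target the
mixed (national, representative) population, with no coverage offset and
no study effect.

Priors: $\mathcal N(0,1)$ on all fixed effects and offsets (logit scale)
and half-$\mathcal N(1)$ on every SD parameter, all configurable through
`model_spec()`.  On the logit scale these are weakly informative for
prevalences between about 1% and 99%.

Categories (low, obese) and sexes are fitted independently; the category
sum constraint $p_{\mathrm{low}} + p_{\mathrm{obese}} \le 1$ is checked at
the draw level after fitting, and violating draws are counted and reported
(`n_category_sum_violations` in the pipeline report), never altered.
With well-separated categories violations are rare; under very short MCMC
runs (smoke tests) wide posteriors can produce some.

## Sampler

`mcmc_fit()` is MH-within-Gibbs.  Every location block (global/region/
country intercepts and slopes, each RW2 vector, each spline coefficient
vector, the offsets, the urban coefficient, all study effects) has a
Gaussian full conditional and is updated by exact conjugate draws; the SD
parameters move by random-walk Metropolis on $\log\sigma$ with step sizes
adapted towards 0.44 acceptance during burn-in only (frozen afterwards, so
the retained chain is Markov).  Because the intercept hierarchy and the
coverage offsets are translation-confounded with the study effects (only
their sums enter the likelihood), plain single-block Gibbs mixes those
directions very slowly; each iteration therefore adds interweaving
"sweep" moves — exact Gaussian updates along the flat directions
(global vs region intercepts, region vs country, country intercepts vs
their studies' effects, offsets vs their class's study effects) that
leave the likelihood invariant and are driven by the priors alone.  This was chosen over black-box HMC to keep
the package dependency-light and bit-reproducible: identical data and
settings (including the seed; chain $k$ uses `seed + k`) give identical
draws.  Defaults: 4 chains, 2000 iterations, 50% burn-in, thinning 5.
Convergence is monitored with rank-normalised split R-hat and effective
sample size (flagging at R-hat > 1.05 or ESS < 100); constant chains are
flagged rather than crashed.

Numerical details worth knowing: the RW2 prior precision
$Z^\top D_2^\top D_2 Z$ is full rank on the constrained subspace, so all
densities are proper; conditional draws use Cholesky solves; percentile
summaries fix quantile type 7 (linear interpolation) for reproducibility;
crossover years are read off the integer year grid with no sub-year
interpolation, draws that never cross are tallied separately, and a
majority of draws already crossed at the grid start raises the
`already_crossed` sentinel.  Undefined obesity shares (0/0) and
zero-variance correlation draws propagate as missing markers and are
surfaced as "indeterminate", never silently dropped.

## What the synthetic generator emulates

`sample_true_surface()` + `simulate_studies()` generate data with exactly
the fitted model's structure: hierarchical linear trends, constrained RW2
non-linearity, hierarchical age splines, coverage offsets, urban effects,
per-study effects, and binomial sampling noise.  That makes recovery tests
well-posed — a correctly implemented sampler should achieve near-nominal
CrI coverage — but it also bounds what a green test establishes: it
validates the implementation, not the model's adequacy for real survey
data.  Real studies bring non-representative sampling the coverage classes
only approximate, measurement drift, reporting heterogeneity, and age
bands that straddle grid boundaries; none of these are emulated.  A
misspecification toggle was considered and deliberately left out of the
default world.

Defaults describe a desk-scale world chosen once: 3 regions x 4
countries, 21 years, both sexes, the adult 5-year grid, ~8 studies per
country with a national/subnational/community mix of 50/25/25%, per-cell
sample sizes 200–2000, coverage offsets +0.2/−0.3 logit, study-effect SDs
0.05/0.10/0.15, urban effect 0.15.  The offsets' magnitudes are chosen for
testability (large enough to detect at ~30 community studies), not
realism — the real offsets' sizes are not public knowledge.  The
`recovery` scenario raises the community share to 35% so that roughly 34
community studies exist and the offset-recovery property is well-posed;
the `crossover` scenario sets the low-BMI category high and declining and
obesity low and rising so the global crossing lands robustly inside the
window (verified across seeds); `shrinkage` gives one country zero
studies; `smoke` is a minimal table (under 200 rows) for plumbing tests.
Seed streaming is documented and additive: scenario offsets 100/200/300/
400 plus sub-steps for surface/studies/population, so adding scenarios
never perturbs existing ones.  Sample sizes are per reported cell (study x
sex x age band), a simplification of real studies' overall N.

Synthetic populations (for persons-affected and global aggregation) use
country sizes spread over two orders of magnitude, a WHO-standard-like age
structure and 1% annual growth; they are labelled synthetic and carry no
relation to real countries.

## Design choices that were genuinely open

* **Independent category fits.**  Low and obese prevalence could be
  modelled jointly (e.g. multinomial logit); independent logit fits match
  the reporting structure of the source studies, keep every block
  conjugate, and the post-hoc sum check quantifies the cost.
* **Offsets shared per fit, not per study population.**  Coverage offsets
  are fixed effects per category-sex fit; richer structures (offsets
  varying by region) are not identifiable at desk scale.
* **Draw-level Pearson correlations.**  Correlations between country-level
  quantities are computed within each draw and then summarised, which
  yields a CrI for $r$; a posterior-mean mode exists as an option.
* **JSON configs** instead of YAML: no YAML parser is available in the
  dependency budget, and the config schema is unchanged.
* **Half-away-from-zero rounding** for printed percentages: validated
  against printed halves (5.5 -> 6, 88.5 -> 89, 66.5 -> 67, 44.5 -> 45,
  32.5 -> 33); banker's rounding contradicts them.  Probability
  thresholds are inclusive (>= 0.80, "at least"); the two-point relevance
  rule is strict (> 2.0, "more than").  The classification denominator is
  always the full estimation set, including countries with no data.

## Limitations

Estimates for countries with no data are driven by the region and global
levels and by the priors; their CrIs are honest about this (wider than any
data-bearing neighbour) but the point estimates should not be
over-interpreted.  The sampler is exact but not fast: the desk-scale
recovery experiment (4 categories-sexes x 4 chains x 2000 iterations)
takes a few minutes on one CPU, and scaling to hundreds of countries
would warrant sparse-matrix joint updates.  Very small cells are handled
only through the continuity correction; studies reporting only one
category are supported (each category is transformed independently), but
no attempt is made to exploit the correlation between categories within a
study.
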