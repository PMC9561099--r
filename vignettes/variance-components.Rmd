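---
title: "Methods: pedigree-based variance components for methane and maternal sheep traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-based variance components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockreml)
```

## The scientific setting

Enteric methane from sheep can be reduced by selective breeding, but a
breeding programme that pushes methane down must not quietly degrade the
ewe traits a flock depends on: fertility, litter survival, body condition,
fleece weight, parasite resistance. Quantifying that risk needs three kinds
of quantities, all estimated from pedigreed field and respiration-chamber
data:

* **heritability** $h^2 = \sigma^2_a/\sigma^2_p$ — how much of the
  phenotypic variance is additive genetic;
* **repeatability** — the intraclass correlation of repeated records on the
  same animal, $(\sigma^2_a + \sigma^2_{pe})/\sigma^2_p$, i.e. additive
  plus permanent-environmental variance over phenotypic variance;
* **genetic correlations** $r_g$ between methane traits and maternal/disease
  traits, estimable through pedigree links even when the two traits are
  measured on disjoint sets of animals (chamber-measured progeny vs their
  adult-ewe relatives).

`flockreml` implements the whole chain — pedigree, trait derivation, model
design, REML estimation, and a synthetic-flock generator used to validate
the chain by parameter recovery.

## The repeatability animal model

Every trait is analysed under the linear mixed model

$$
y = Xb + Za + W_w\,pe_w + W_y\,pe_y + e,
$$

where $b$ collects fixed contemporary-group effects and covariates, $a$ is
the vector of additive genetic effects with
$\mathrm{var}(a) = A\sigma^2_a$ ($A$ the numerator relationship matrix from
the pedigree), $pe_w$ and $pe_y$ are permanent-environmental effects within
and across measurement rounds (or recording years) with identity
covariance, and $e$ is the residual. All random effects are independent of
one another, so the phenotypic variance is the sum
$\sigma^2_p = \sigma^2_a + \sum_k \sigma^2_{pe,k} + \sigma^2_e$.

For chamber methane traits the two PE terms separate the day-to-day
environment within a measurement round (`wgpe`, levels = animal x round)
from the persistent animal environment across rounds within a recording
year (`agpe`, levels = animal x year). For adult-ewe traits a single
animal-level PE term carries the across-year repeatability.

## Pedigree and the relationship matrix

`as_pedigree()` validates animal/sire/dam triples (unknown parents coded
`"0"`), inserts parents that appear only as parents, sorts parents-first
(cycles are a hard error naming an offending animal), and computes
inbreeding coefficients $F_i$ exactly with the Meuwissen--Luo tabular
recursion. Unknown parents are treated as unrelated, non-inbred founders
drawn from a single base population; the package does not implement
unknown-parent groups.

`relationship_matrix()` builds $A$ through its generalised Cholesky
factorisation $A = (T\sqrt{D})(T\sqrt{D})'$, with $T$ the parent-average
path coefficients and $D$ the Mendelian sampling variances
($d_i = 0.5 - 0.25(F_s + F_d)$ with both parents known, $0.75 - 0.25F$
with one, $1$ with none). The test-suite oracle recomputes $A$ by the
direct element-wise tabular recursion, so the two routes check each other.
`relationship_inverse()` never forms $A$: it assembles the sparse
$A^{-1}$ directly by Henderson's rules with inbreeding accounted through
$1/d_i$, and stores $\log\det A = \sum_i \log d_i$ for the likelihood.
$A$ is dense by nature, so the "sparse representation" above 500 animals
is a container choice only; $A^{-1}$ is genuinely sparse and is what the
estimation path consumes.

## Trait derivation rules

* Chamber records are kept only when the chamber seal held and at least
  95% of the offered feed was eaten on the measurement day (the boundary is
  kept — exactly 95% passes); incomplete records are dropped. Each
  rejection is logged with a reason (`seal`, `refusal`, `incomplete`).
* Three methane traits per daily record: gross emission (g CH$_4$/day),
  yield per intake (g CH$_4$/kg DMI, undefined — not zero — when intake is
  missing), and the molar fraction
  $(\mathrm{CH_4}/16.04)/(\mathrm{CH_4}/16.04 + \mathrm{CO_2}/44.01)$,
  which is scale-invariant in the gas amounts. Molar masses are arguments
  with those defaults, to guard against convention drift.
* Egg counts are analysed as $\log_e(x + 50)$, defined at zero and strictly
  monotone.
* Litter survival to weaning is lambs weaned / lambs born, and is treated
  as missing for a ewe-year with no lambs born (the ratio is undefined, and
  imputing 0 or 1 would bias both the mean and the variance components).
* The two daily measures within a chamber round are kept as separate
  repeated records (that is what the within-round PE term models); they are
  not averaged per round. Yields use the same-day chamber intake.

## Design construction

`build_design()` turns a phenotype table plus a declarative `model_spec()`
into the model pieces: records missing the response or any model column are
dropped *for that trait only*; fixed interactions become
observed-combination contemporary-group factors with lexicographically
ordered levels; covariates are centred (pure conditioning — variance
components are unaffected); and the dummy-coded fixed design is reduced to
full column rank by pivoted QR, dropping later (aliased) columns. Which
columns are dropped is a reporting convention, not a modelling choice:
variance ratios and correlations are estimable functions and invariant to
it, which the suite asserts by permutation. Every random term gets a sparse
one-hot incidence matrix; a pedigree-covariance term is mapped onto the
full pedigree so its covariance is exactly $A\sigma^2_a$.

`screen_fixed_effects()` reproduces the usual general-linear-model
screening step: sequential (type-I) F tests from `lm()`/`anova()`, with a
keep flag at $p < \alpha$ (default 0.05). Final models are expected to come
from shipped config files (`inst/extdata/models/`), the screen is a tool.

## REML estimation

The restricted log-likelihood is evaluated through the sparse Cholesky
factorisation of the mixed-model-equations coefficient matrix
$C = W'R^{-1}W + \mathrm{blockdiag}(0_p, G_1^{-1}, \dots)$ using

$$
-2\ell_R = (n-p)\log 2\pi + \log|R| + \textstyle\sum_k \log|G_k|
  + \log|C| + y'Py,
$$

with $y'Py = y'R^{-1}y - \hat\theta' W'R^{-1}y$. A dense projection-matrix
evaluation of the same quantity is provided as an independent cross-check
(`restricted_loglik(..., method = "dense")`); the two agree to $10^{-8}$
on random instances, which is one of the acceptance properties.

**Parameterisation.** Variances are optimised on the log scale; bivariate
2x2 covariance blocks use a log-Cholesky parameterisation
($L = [[e^{l_{11}},0],[l_{21},e^{l_{22}}]]$, $\Sigma = LL'$). Both keep
every iterate inside the parameter space, so heritabilities land in
$[0,1]$ and correlations in $[-1,1]$ by construction rather than by
clipping. Variances are floored at $10^{-10}\sigma^2_p$; a fit that ends on
the floor carries a `boundary` flag (and the average-information matrix is
then singular, so interior parameters get pseudo-inverse SEs).

**Optimisation.** Updates are average-information (AI) steps: the AI matrix
is computed exactly from solves with the factorised $C$
($\mathrm{AI}_{ij} = \tfrac12 (\dot V_i Py)' P (\dot V_j Py)$), and the
score vector by central finite differences of the factorised likelihood,
which costs two numeric re-factorisations of a fixed sparsity pattern per
parameter — cheap, because the symbolic analysis is cached. A monotone
step-halving line search keeps the restricted likelihood non-decreasing; in
the unconstrained working parameterisation every halved step is feasible,
which is the role an expectation-maximisation fallback plays in other
implementations, without its slow crawl along flat directions. Convergence
requires both a relative likelihood change below `tol_lik` ($10^{-8}$) and
a score norm below `tol_grad` ($10^{-4}$); both thresholds are scaled up
with $|\ell_R|$ because rounding noise in a factorised log-likelihood of
magnitude $10^4$ makes absolute $10^{-12}$-level comparisons meaningless.
Univariate panel fits seed bivariate starting values; the bivariate
covariance starts at a tiny non-zero value so the sparsity pattern of $C$
(and hence the cached factorisation) is stable.

**Identifiability guard.** $\sigma^2_a$ and $\sigma^2_{pe}$ are separable
only through pedigree covariance between animals. A specification with two
identity-covariance terms of identical incidence (e.g. an identity-kinship
"animal" term plus an animal-level PE term) is refused with an explanatory
error instead of returning an arbitrary ridge solution.

**Bivariate residual covariance.** The residual covariance between two
traits is estimable only from records observed on the same animal-occasion.
`fit_bivariate()` therefore estimates it only when a pairing key is
supplied (`residual_cov = "paired"`); for trait pairs never co-recorded —
the chamber-by-maternal case — it is fixed at zero and the cross-trait
information flows through the pedigree. Phenotypic correlations are derived
from the summed covariance matrices of the bivariate fit itself (no
separate phenotypic model).

**Standard errors.** All derived quantities ($h^2$, repeatability, $r_g$,
$r_p$, $r_e$, $\sigma^2_p$) are smooth transformations of the working
parameters; their SEs come from the delta method with the Jacobian of the
transformation (finite-differenced — no refitting) around the inverse AI
matrix. Wald two-sided z-tests at $\alpha = 0.05$ produce the significance
stars in the correlation tables.

## The synthetic flock generator

The published analyses in this field rest on proprietary flock recordings,
so `sim_config()`/`simulate_flock()` generate data with *exactly* the
statistical structure the model assumes, at a configurable scale:

* sire families (default 22 sires x 10 chamber progeny, a one-tenth-scale
  flock; recovery studies use 100-220 sires) with dams either explicit
  founders or unknown;
* breeding values by Mendelian sampling down the pedigree — founders
  $N(0, G)$, offspring = parent average + deviation with variance
  $d_i G$ — giving covariance exactly $A \otimes G$ at any inbreeding
  level, in $O(n)$;
* chamber records on a 2-round x 2-day layout with lot/group structure,
  contemporary-group effects, a birth-day covariate, and raw gas/intake
  columns back-composed from the simulated g/day trait so the trait module
  reproduces it; seal breaks and feed refusals injected at configurable
  rates to exercise the filters;
* adult-ewe records at ages 2--6 (recording year, flock, mob, age-class
  factors; litter sizes and weaning counts for the survival ratio);
* egg counts on the count scale (lognormal latent trait), so the offset-log
  transform is exercised end to end.

Default generating components are back-solved from the population this
package targets: methane ~24 g/d with phenotypic SD 2.99, $h^2 = 0.26$,
repeatability 0.42 (hence $\sigma^2_a = 2.324$, total PE 1.430 split
0.43/1.00 between within- and across-round, residual 5.185); ewe live
weight ~67 kg with $h^2 = 0.49$, repeatability 0.71; egg counts with
log-scale mean ~6.07 and $h^2 = 0.33$. Contemporary-group effect SDs are
order-of-magnitude choices (1.5 g/d birth cohorts, 1.0 g/d chamber groups,
3 kg ewe cohorts) — real magnitudes are unreported, and fixed effects are
estimated anyway, so they only need to be non-trivial. The default
cross-trait genetic correlations (0.3 methane x live weight, 0.18 methane x
egg count) are plausible mid-range values; recovery studies set them
explicitly.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: selection-line divergence dynamics,
non-normal trait distributions (count traits are analysed as if Gaussian,
as is standard), heterogeneous variances across flocks or years, maternal
environmental covariances, genotype-by-environment interaction, and real
egg-count overdispersion beyond the lognormal.

## Validation strategy and problem sizes

The suite validates by property, not by reproducing proprietary estimates:

* $A$ equals the brute-force tabular oracle ($<10^{-12}$, 50 random
  pedigrees up to 200 animals) and $A A^{-1} = I$ ($<10^{-8}$);
* MME and dense likelihoods agree ($<10^{-8}$, 100 random instances up to
  50 records);
* on balanced identity-kinship designs REML equals the closed-form ANOVA
  expected-mean-squares estimates ($<10^{-6}$), and one-way fits match
  `lme4` as an external reference;
* parameter recovery: 100 replicates of 100 sires x 10 progeny x 4 records
  recover $h^2 = 0.25$ and repeatability 0.40 within $\pm 0.02$ on the
  mean, with delta-method SEs within [0.7, 1.3] of the empirical spread;
  bivariate recovery over $r_g \in \{0, 0.3, 0.9\}$ (50 replicates each,
  maternal trait on 1000 half-sib ewes with 3 records) checks the mean
  estimate against a two-Monte-Carlo-SE band per level and the 5%
  false-star rate at $r_g = 0$; a two-SE band is itself a ~5%-failure
  check per level, so single-level misses at the band's edge are expected
  occasionally even from an exact estimator (at $r_g = 0$ the estimator is
  mean-unbiased by sign symmetry);
* a single full-pipeline consistency run at the full chamber scale (220
  sires x 10 progeny) re-estimates the back-solved generating ratios. At
  that scale one run carries a Monte-Carlo SD of about 0.04 on $\hat h^2$,
  so individual seeds scatter around the truth accordingly; the replicated
  recovery study above is the calibrated check.

These sizes were chosen so the complete suite runs on a single desktop
core in well under half an hour while leaving the Monte-Carlo error small
against the tolerances tested.

## Numerical details worth knowing

* Contemporary-group levels and pedigree orderings are sorted
  lexicographically (radix, locale-independent), so runs are deterministic
  across platforms given a seed.
* CSV round-trips are bit-exact: doubles are written as shortest-exact
  decimals (`%.17g`) and parsed by the base reader.
* `filter_chamber_records()` treats `offered_kg <= 0` as a data error, not
  a rejection reason.
* Degenerate inputs: a trait with a single record per animal reports
  repeatability as `NA`; a response with zero variance is an error in
  bivariate fits; an all-founder pedigree yields $A = I$.
* The self-correlation case (a trait paired with itself) drives the joint
  model towards a singular covariance; the log-Cholesky parameterisation
  approaches the unit-correlation boundary smoothly, and iteration caps
  stop the (divergent) likelihood climb.

## Limitations

Single- and two-trait models only; no unknown-parent groups or genomic
(marker-based) relationships; no Bayesian machinery; breeding-value (BLUP)
extraction is internal to the solver and not exposed as a reporting
pipeline. Fits with tens of thousands of records are comfortable; the
dense fixed-effects design would become the limit long after that.
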