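---
title: "Multiphase linkage and family-based association: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiphase linkage and family-based association: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famscan)
```

famscan implements a three-phase strategy for mapping quantitative-trait
loci in extended pedigrees, motivated by longitudinal blood-pressure
studies in which many relatives are measured repeatedly and some are under
antihypertensive treatment.  The phases are: (1) construction of a single
censoring-corrected summary phenotype per individual; (2) a two-point
variance-components linkage scan over a random sample of common markers,
with LOD-based selection of candidate regions; (3) family-based
association of all variants inside the selected regions by the measured
genotype (MG) test and the quantitative transmission disequilibrium test
(QTDT).  The rationale of the staging is economy: linkage on a few hundred
common markers is cheap and robust, and restricting single-variant
association to linkage-supported regions reduces both computation and the
multiple-testing burden.

This vignette documents the models, their assumptions, the tunable
parameters, the numerical choices, and what the simulation-based test
suite does and does not demonstrate.

## Phase 1: censored phenotype adjustment

Antihypertensive medication lowers observed systolic blood pressure (SBP),
so a treated individual's observed value is taken as a lower bound on the
underlying untreated value: medication is a right-censoring indicator.
For each exam separately, `fit_censored_exam()` fits

$$Y_{pi} = x_{pi}'\beta + u_p + \varepsilon_{pi}, \qquad
  u_p \sim N(0, \tau^2),\; \varepsilon_{pi} \sim N(0, \sigma^2),$$

with covariates sex, exam-specific age (entered linearly) and smoking
status, and a pedigree-level random intercept $u_p$ capturing
between-pedigree variation.  A medicated record contributes the survival
term $P(Y > y_{obs})$ to the likelihood, an unmedicated record the normal
density; censoring is assumed noninformative.  The random intercept is
integrated out by adaptive Gauss–Hermite quadrature (default order 20;
the posterior mode and curvature of each pedigree's intercept are located
by damped Newton iterations and the quadrature grid is centred and scaled
there).  Optimisation is quasi-Newton on $(\beta, \log\sigma, \log\tau)$
with up to three random restarts and a final unconstrained polish;
$\tau$ at its lower bound is reported as 0 with a `boundary_tau` flag.

For a medicated record the underlying value is estimated by the
conditional expectation of a truncated normal,

$$Y^* = E[Y \mid Y > y_{obs}]
      = \mu + \sigma\,\frac{\phi(\alpha)}{1 - \Phi(\alpha)},\qquad
  \alpha = \frac{y_{obs} - \mu}{\sigma},$$

where $\mu$ includes the covariate effects and the pedigree random
effect's posterior mode.  Whether to condition on the posterior mode or to
marginalise over the random effect was an open choice; the posterior mode
was chosen because it is the same quantity used in the fitted value
$\hat Y$, keeping $Y^* - \hat Y$ internally consistent.  Beyond
$\alpha > 30$ the inverse Mills ratio is replaced by its asymptote
$\alpha + 1/\alpha$ (with a warning); in double precision the exact ratio
is already indistinguishable from the asymptote well before that point.

The adjusted phenotype is $R$, the mean of $Y - \hat Y$ (unmedicated) or
$Y^* - \hat Y$ (medicated) over exams 1–3.  Individuals measured at a
subset of those exams use the mean over the available exams rather than
being dropped, which maximises the analysable sample; exam 4 is ignored.

Two properties of this construction deserve emphasis.  First, when
medication is assigned to high values of the trait (as it is in reality
and in the simulator's default), the unmedicated subset is selected toward
low values, so the mean of their raw residuals is negative by
construction; what the $Y^*$ correction restores is the mean over *all*
individuals.  The test suite asserts that corrected form.  Second, the
censored likelihood is exactly specified only when the observed value of a
censored record is a bound generated independently of the underlying value
(classical Type-I censoring).  Under the more realistic mechanism in which
treatment subtracts a positive lognormal effect from the true value, the
observed value carries information the likelihood ignores, and fixed
effects acquire a small bias (about 1.5 mmHg on the intercept at the
simulated scale).  The simulator therefore offers both mechanisms
(`censoring$observed = "treated"` or `"threshold"`): estimator-calibration
checks run under the exactly-specified mechanism, while the bias-reduction
property — that $R$ tracks true genetic values with less attenuation than
naive residuals — is demonstrated under the realistic one.  On real data
the same approximation is in force, so coefficient estimates should be
read as mildly conservative rather than exact.

## Phase 2: two-point variance-components linkage

With $R$ as the response, the phenotypic covariance of a pedigree is

$$\Sigma = \Pi\,\sigma^2_{qtl} + 2\Phi\,\sigma^2_a + I\,\sigma^2_e,$$

where $2\Phi$ is twice the kinship matrix (computed exactly by the
standard recursion, valid for inbred and looped pedigrees) and $\Pi$ holds
the expected proportions of alleles shared identical by descent (IBD) at
the tested marker.  The polygenic null drops the $\Pi$ term.  Both models
are fitted by maximum likelihood — not REML — because the LOD,

$$\mathrm{LOD} = \frac{\ell_{alt} - \ell_{null}}{\ln 10},$$

is a full-likelihood comparison.  The grand mean is profiled out by
generalised least squares inside the likelihood; the variances are
optimised by bound-constrained quasi-Newton (L-BFGS-B, lower bound 0) from
a null-informed start plus perturbed restarts, with the block likelihood
evaluated in compiled code (Cholesky per pedigree).  The LOD is clamped
to 0 when the QTL variance sits at its boundary, and a marker whose
$\Pi$ equals $2\Phi$ in every pedigree is declared confounded with the
polygenic term and scored 0 outright.  Under the null the LOD follows the
boundary mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ asymptotically,
giving $P(\mathrm{LOD} > 1.2) \approx 0.0094$; the acceptance suite
verifies this on 2,000 simulated null markers.  No small-sample kurtosis
correction is applied to LODs.

### Single-marker IBD

Because the scan is strictly two-point, $\Pi$ is estimated one marker at a
time.  `compute_ibd_exact()` computes the exact conditional expectation
$E[\pi_{ij} \mid \text{genotypes}]$ by enumerating inheritance vectors
(two transmission bits per non-founder).  Conditional on an inheritance
vector, the genotype constraints collapse onto the founder alleles:
homozygous genotypes force allele types, heterozygous genotypes are
exclusive-or constraints, so the likelihood of each vector factorises over
connected components of a founder-allele graph and is evaluated by
2-colouring in linear time.  Missing genotypes are marginalised, never
imputed.  The diagonal of $\Pi$ is $1 + f_i$.  The enumeration is
exponential in the number of non-founders, so a configurable `state_limit`
(default $2^{22}$ inheritance vectors) routes larger pedigrees to
`compute_ibd_montecarlo()`, a self-normalised importance sampler that
draws inheritance vectors from the Mendelian prior and weights them by the
same exact per-vector genotype likelihood; it reports per-entry Monte
Carlo standard errors and is reproducible under a seed.  A
Mendelian-inconsistent marker is an error by default; the pipeline layer
can instead blank that pedigree's $\Pi$ to the $2\Phi$ prior with a
logged warning (`mendel_policy = "prior"`).

### Marker sampling and region selection

`sample_markers()` draws markers uniformly without replacement among those
with estimated MAF at or above the filter (default 0.05, boundary
inclusive), excluding previously sampled markers so that repeated
samplings emulate a density sensitivity analysis; the union of the
selected regions is carried forward.  `select_regions()` keeps markers
with LOD above the threshold (default 1.2) and merges markers within
`merge_bp` (default 10 Mb — linkage peaks at this design's resolution span
several to tens of Mb, and the merge width is a tunable, not an estimate).
The threshold comparison tolerates ties at working precision, so a LOD
printed exactly at the threshold is retained, matching how the rule is
applied in published tables.  Region intervals are closed and 1-based.

## Phase 3: family-based association

Within a selected (or manually specified) region, each variant's dosage
$g$ is decomposed as $g = b + w$: $b$ is the parental-mean dosage when
both parents are genotyped, else the mean among genotyped members of the
individual's sibship cluster, else the individual's own dosage (making
$w = 0$ and the individual uninformative for within-family tests).  The
fixed-effect model is

$$E[R] = \mu + \beta_b b + \beta_w w,$$

with the polygenic random effect ($2\Phi\sigma^2_a$), optionally the
marker-specific linkage component ($\Pi\sigma^2_{qtl}$), and independent
error.  MG constrains $\beta_b = \beta_w$ and tests $\beta = 0$; QTDT
frees both and tests $\beta_w = 0$.  Both are 1-df likelihood-ratio
tests (boundary issues do not arise for fixed effects).  Because $b$
absorbs between-family structure, QTDT is robust to population
stratification at the cost of power; MG is more powerful in homogeneous
populations but inflates under stratification.  When a true QTL is linked
to, but not associated with, the tested variant, family members share
marker alleles and trait-relevant QTL alleles jointly, which inflates
association tests; modelling the linkage variance component restores
calibration.  All three behaviours are verified by simulation in the
acceptance suite.  MAF classes are rare $<1\%$, low-frequency
$[1\%, 5\%)$, common $\ge 5\%$ — half-open boundaries chosen so the three
classes partition $[0, 0.5]$ exactly.  No multiple-testing correction is
applied by default: the intended use is ranking within a
candidate region, and an appropriate region-level criterion is left to
the analyst.  `qq_diagnostics()` reports the genomic inflation factor
$\lambda$ and expected-versus-observed quantiles for calibration checks.

## The synthetic study generator

`sim_config()` / `simulate_pedigrees()` / `gene_drop()` /
`simulate_phenotypes()` generate data with exactly the structure the
analysis assumes: multiple non-inbred multigeneration pedigrees built from
a template (founding couple, configurable sibship size, married-in
spouses); founder alleles drawn Hardy–Weinberg at each marker's frequency
and transmitted by Mendelian sampling with full descent recorded (so
realized IBD is available exactly); and exam records

$$\text{SBP}_{ie} = 115 + 5\,\text{male} + 0.5\,\text{age}_{e}
  + 5\,\text{smoke} + \beta_{qtl} (g_i - 2p) + a_i + s_p
  + \varepsilon_{ie},$$

with $a \sim N(0, 2\Phi\,h^2\sigma_T^2)$ per pedigree,
$s_p \sim N(0, \tau^2)$, and per-exam noise making up the remainder of
$\sigma_T^2 = 15^2$ mmHg².  Defaults — 20 pedigrees, up to 4 exams two
years apart, heritability 0.4, pedigree scale $\tau = 5$ mmHg, covariate
effects 5, 0.5 and 5 mmHg, 25% smoking prevalence — are fixed once as
plausible values for a family blood-pressure study of this design, and
medication is assigned above the 70th percentile of the underlying trait,
yielding 30% censoring.  Markers are simulated unlinked because a
two-point analysis needs no map; a linked-pair option (one recombination
fraction, founder alleles kept independent) exists solely to create
linked-but-not-associated scenarios.  Stratification assigns whole
pedigrees to strata, matching family-based sampling designs.

What the generator does *not* emulate: linkage disequilibrium and
haplotype structure, genotyping or imputation error, informative
censoring, dose-dependent treatment effects, within-individual
longitudinal correlation beyond the pedigree intercept, and loops or
inbreeding in the simulated pedigrees (the kinship and IBD engines handle
inbreeding; the template generator simply never produces it).  Tests that
pass on these simulations therefore validate the estimators under the
model's own assumptions and the stated perturbations of them, not
performance on real sequence data.

## Numerical choices and degenerate inputs

* Variance optimisations run on the variance scale with lower bound 0
  (error variance bounded away from 0 at $10^{-8}$ of the trait
  variance); alternative fits start from the null solution, so the
  likelihood ordering $\ell_{alt} \ge \ell_{null}$ holds by construction
  and is additionally clamped.
* A phenotype set containing only mutually unrelated individuals pins
  $\sigma^2_a = 0$ (unidentifiable) and reports the ML sample variance.
* Constant dosages, zero within-family variance, or designs below the
  sample-size floor (default 20) yield flagged non-informative rows, not
  errors; per-marker convergence failures are flagged and tallied by the
  pipeline rather than aborting it.
* Pedigree IDs are kept verbatim; members are ordered internally by a
  deterministic founders-first topological sort with lexicographic
  tie-breaks, so outputs are byte-stable and rerunning a pipeline
  configuration reproduces its output files exactly.
* Parents referenced but not listed in a ped file are auto-added as
  unknown-sex founders with a warning (`strict_parents = TRUE` turns this
  into an error).

## Problem sizes used in the test suite

The acceptance checks run at deliberately moderate scale chosen as
adequate for their statistical purpose: oracle equivalence on pedigrees of
up to 12 members (where brute-force enumeration is feasible); 2,000
gene-dropped markers for IBD consistency; 200 replicates of 50 pedigrees
for censored-regression recovery; 100 replicates for heritability
recovery; 2,000 null markers for LOD and MG calibration; 400–500
replicates for the stratification, power-ordering and linkage-VC
comparisons.  These sizes give Monte-Carlo standard errors small enough
for 3-s.e. acceptance bands while keeping the full suite runnable on a
single CPU in well under half an hour.

## Known limitations

* Two-point linkage only; no multipoint IBD, and no LD-aware IBD.
* The censored model assumes noninformative censoring and a single
  pedigree-level random intercept; individual-level repeatability is not
  modelled.
* Exact IBD is exponential in non-founder count; very large pedigrees rely
  on the Monte-Carlo engine, whose error is reported but not adaptive.
* Association uses hard-call dosages; imputation uncertainty is ignored.
* No genome-wide significance machinery: the package reports ranked
  results with MAF classes and leaves region-level criteria to the user.
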