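---
title: "Quantitative genetics of twin-family phenotypes with twinvolve"
author: "twinvolve authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of twin-family phenotypes with twinvolve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinvolve)
```

## The scientific problem

Twin and family samples let us ask how much of the person-to-person
variation in a phenotype — here, cerebellar regional volumes in mm³ and
standardized cognitive/motor scores — is attributable to additive genetic
factors (A), to environmental factors shared within a family (C), and to
unique environmental factors plus measurement error (E). Identification
comes from the different degrees of genetic sharing among relatives:
monozygotic (MZ) co-twins share all segregating genes, dizygotic (DZ)
co-twins and full siblings share half on average, and everyone in a family
shares the C environment. An *extended twin design* (ETD) additionally
keeps singletons in the likelihood: they carry no information about the
A/C split but sharpen the estimates of means, covariate effects and total
variance.

`twinvolve` implements the full analysis chain for such a study:

1. a **synthetic cohort generator** with known ACE structure, calibrated
   to published summary tables from the Human Connectome Project (HCP)
   young-adult twin sample (121 MZ pairs, 67 DZ pairs, 556 singletons,
   N = 932);
2. **reshaping** of individual-wise tables into family-wise records with
   relatedness coefficients;
3. a **phenotypic stage** (correlation matrices, covariate-adjusted
   brain–behavior regressions, Benjamini–Hochberg FDR);
4. **univariate ACE models** fitted by full-information maximum likelihood
   (FIML), with profile-likelihood confidence intervals and
   boundary-corrected likelihood-ratio tests;
5. **bivariate Cholesky decompositions** yielding genetic/environmental
   correlations and their contributions to phenotypic covariance.

## The model

For one trait, a family of $m$ members contributes a multivariate normal
likelihood with mean $X\beta$ (intercept, sex, centered age, optionally
total brain volume) and covariance

$$\Sigma_{ij} = r^A_{ij} A + r^C_{ij} C + \mathbf{1}\{i=j\}\,E,$$

where $r^A_{ij}$ is 1 for MZ co-twins, 0.5 for DZ co-twins and siblings,
and $r^C_{ij} = 1$ within a family. Missing phenotypes are marginalized
out (FIML): a member with no observed phenotype simply drops from the
family's vector, and a lone twin is an informative singleton.
Standardized proportions are $a^2 = A/V$, $c^2 = C/V$, $e^2 = E/V$ with
$V = A + C + E$; $a^2$ is the narrow-sense heritability.

The bivariate model stacks two traits per member (trait-major). Each
component covariance matrix is parameterized as $L L^\top$ with $L$ a
$2\times2$ lower-triangular Cholesky factor, so the matrices are positive
semi-definite by construction. Cross-person blocks are
$r^A \Sigma_A + r^C \Sigma_C$; the unique environment never crosses
persons. Derived quantities:

* genetic correlation $r_G = \Sigma_A[1,2]/\sqrt{\Sigma_A[1,1]\,\Sigma_A[2,2]}$
  (similarly $r_C$, $r_E$);
* contributions to the phenotypic correlation
  $\mathrm{pcor}_A = \sqrt{a^2_x}\, r_G \sqrt{a^2_y}$, etc., which sum
  exactly to the model-implied phenotypic correlation. When a component
  variance is essentially zero the correlation is reported as *undefined*
  rather than a spurious $\pm 1$ — correlations standardized by vanishing
  variances are uninformative, while the pcor scale remains meaningful.

## Fitting: parameterization, optimizer, numerics

**Path parameterization.** Variance components are squares of real path
coefficients ($A = a^2_{\text{path}}$, …), which enforces
$A, C, E \ge 0$ without constrained optimization and makes the zero
boundary exactly reachable — the standard practice in twin structural
equation modeling. Dropped components (AE/CE/E submodels, or a fixed
cross-loading in the bivariate path tests) are held at exactly 0.

**Profiled mean model.** For any value of the variance parameters the
optimal mean coefficients have a closed-form generalized-least-squares
solution, so $\beta$ is profiled out at every likelihood evaluation. The
likelihood itself is evaluated from per-group sufficient statistics:
families are grouped by their observed-data pattern (member count,
relatedness structure, missingness), and within a group the sum of
quadratic forms collapses to crossproduct matrices accumulated once. An
evaluation therefore costs the same whether the cohort has 700 or 7,000
families, which is what makes the replicate-heavy recovery and
type-I-error experiments cheap.

**Standardization.** Internally each trait is centered and scaled by its
pooled mean/SD and covariates by their SDs; results are mapped back
afterwards. This keeps the optimizer well-conditioned for mm³-scale
volumes (variances of order $10^7$) and makes results exactly invariant
to unit changes — a property the test suite checks by multiplying a trait
by 1,000.

**Optimization and convergence.** Quasi-Newton BFGS with numerical
gradients from five fixed starting splits of the phenotypic variance
(equal split, A-heavy, C-heavy, E-heavy, AC-heavy); the two best
candidates are re-polished at a tight tolerance. A fit is flagged
converged when the optimizer reports success, the two best starts agree
within $10^{-4}$ in $-2\ln L$, and the gradient ∞-norm is below
$10^{-5}$ relative to $\max(1, |-2\ln L|)$ on the standardized scale (an
absolute gradient threshold would be meaningless across trait units).
Parameter points with a non-positive-definite family covariance receive a
large penalty and are simply rejected during the search, never crash.

**Profile-likelihood intervals.** A 95% bound is the extreme value of the
quantity at which the re-optimized $-2\ln L$ exceeds the minimum by
$\chi^2_1(0.95) = 3.841$; the bound is located by bisection (tolerance
$10^{-3}$ on the proportion scale) with re-optimization of the free
parameters at each step. Each constrained re-optimization runs from
several starts — the warm continuation solution, the unconstrained
solution, and neutral splits — because a warm start dragged through the
near-singular edge (e.g. $a^2 \to 1$ forces $E \to 0$) can otherwise trap
BFGS and collapse a bound onto the point estimate. Bounds that run into
the edge of the parameter space are reported as the edge (0, or 1 for
proportions).

**Boundary-corrected tests.** Dropping A or C places the null on the
boundary of the parameter space, so the deviance is referred to a 50:50
mixture of a point mass at zero and $\chi^2_1$; dropping both (the E-only
null) uses the $(\tfrac14, \tfrac12, \tfrac14)$ mixture of
$\{0, \chi^2_1, \chi^2_2\}$. The two-parameter mixture is our
interpretation of the standard result for two boundary parameters; the
one-parameter 50:50 rule is the published prescription. Bivariate
covariance-path tests drop a *cross-loading*, an interior sign-free
parameter, and therefore use a plain $\chi^2_1$.

## The synthetic-data generator

The generator is first-class, tested code: every downstream stage is
exercised against cohorts with known truth.

* **Composition.** Defaults reproduce the HCP sample: 121/67/556
  MZ-pairs/DZ-pairs/singletons (N = 932), 45% male, ages normal
  (mean 28.8, SD 3.6 years) truncated to the HCP young-adult range
  22–37; twins share age exactly, MZ twins share sex. `scale` in
  `calibration_design()` grows the cohort proportionally.
* **Latent structure.** Per trait, each person's value is
  `mean + Σ β·(centered covariate) + total_sd·(√a²·G + √c²·S + √e²·U)`
  with G shared exactly within MZ pairs and built as
  `√0.5·family + √0.5·individual` for DZ twins and siblings (giving the
  0.5 expected sharing), S common to the family, U independent.
  Cross-trait structure is injected by drawing the latent vectors with
  component correlation matrices (checked positive semi-definite at
  construction).
* **Calibration.** `inst/extdata/hcp_*.csv` transcribe the published
  demographic composition, trait means/SDs, ACE proportions (with and
  without the TBV covariate for ROIs) and two headline cross-trait
  correlations (fluid–crystallized 0.38; vermis VIII–cognition 0.26).
  Printed proportions are rounded to two decimals and do not always sum
  to 1; generating models keep `a2` and `c2` as printed and set
  `e2 = 1 − a2 − c2`, so proportions sum exactly to 1 while the reported
  recovery targets keep their printed values.
* **What it does not emulate.** Non-normal or heteroscedastic traits,
  assortative mating, dominance, sex-limitation, age trends in variance,
  household structure beyond one generation, and informative missingness
  (the `missing_rate` mechanism is missing-completely-at-random). Passing
  recovery tests therefore demonstrates correctness of the estimation
  machinery under the fitted model class, not robustness to violations of
  the twin-model assumptions.
* **Phenotypic-correlation calibration.** When only a phenotypic
  correlation is published, `cross_spec_from_phenotypic()` sets
  `rA = rC = rE = r0` with `r0` chosen to reproduce it — the least
  committal split absent component-level information.
* **TBV.** If a trait named `"tbv"` is supplied it is simulated first and
  can be referenced as a covariate; `default_tbv_spec()` provides a
  realistic young-adult generating model (mean 1,181,000 mm³, SD 110,000,
  a² = 0.85) for studies that need an independent global covariate.
  Covariate slopes act on mean-centered covariates so calibrated trait
  means are preserved.

## Problem sizes used in the recovery experiments

Recovery experiments average fitted proportions over seeded replicate
cohorts. Singletons dominate the HCP mix (556 of 744 families), so the
A/C split rests on ~190 twin pairs per 744 families and its estimator is
noisy; because components are constrained non-negative, models whose
truth sits on the boundary (working memory with $a^2 = 0$; endurance with
$c^2 = 0$) have means shifted by boundary truncation, an effect that
decays like $1/\sqrt{n}$. The packaged recovery experiments therefore use
a 24× HCP-proportioned cohort (~17,850 families) and 20 seeds, at which
point the truncation shift of the worst boundary case (endurance, mean
heritability error ≈ 0.02) sits comfortably inside the 0.05 recovery
band; calibration of sample means and
correlations (which have no boundary) uses the published N = 932 with 10
seeds. The type-I-error experiment for the boundary test uses 500
replicates of a 150 MZ + 150 DZ pair cohort — twin pairs only, since
singletons carry no information about the tested component — and the
CI-coverage experiment uses 50 replicates at the published family mix.

## Design choices where the design was open

* **Phenotypic stage ignores family clustering**, using ordinary least
  squares exactly as the replicated analysis did; a GEE or mixed-model
  correction is a documented non-goal. Effect sizes are reported both as
  standardized betas and as sign-consistent partial correlations.
* **FDR families.** Corrections default to per-analysis families
  (phenotypic; behavioral univariate; ROI univariate; bivariate), with a
  `global` option pooling every p-value in a run.
* **Ledger ambiguity.** The published test ledger (1305 = 288 + 27 + 180
  + 810) counts 32 ROI series in the phenotypic family but 30 in the
  genetic families. The ledger is configuration-driven;
  `replication_ledger_config()` uses the 30 tabled measures plus
  left/right whole-cerebellum aggregates for the phenotypic list, which
  reproduces the printed decomposition while keeping both readings
  expressible.
* **Cholesky order** is (ROI, behavior) for brain–behavior pairs; only
  the loadings depend on the order, never the derived $\Sigma$, $r_G$ or
  pcor values.
* **Covariates are never imputed**: a family member missing a covariate
  contributes no phenotypes to models using it (the FIML mean model
  requires complete covariate rows); the reshape step logs how many
  members were dropped.
* **Age centering** at the sample mean (affecting only the intercept) and
  internal standardization are numerical choices, invisible in reported
  estimates.
* **Extra siblings.** Published summaries do not enumerate the non-twin
  sibling mix, so the generator exposes `n_extra_sibs` per twin family
  rather than guessing; defaults use none.

## Worked example

```{r example, eval = FALSE}
library(twinvolve)

# a synthetic cohort on the published HCP composition
design <- calibration_design()                  # 121/67/556, N = 932
traits <- list(calibration_trait("vermis_viii"),
               calibration_trait("cog_total"))
cross <- list(cross_spec_from_phenotypic(traits[[1]], traits[[2]], 0.26))
cohort <- generate_cohort(design, seed = 1)
cohort <- simulate_phenotypes(cohort, traits, cross, seed = 2)

# phenotypic stage
fit_brain_behavior(cohort, "vermis_viii", "cog_total",
                   covariates = c("age", "sex"))

# univariate ACE with boundary-corrected tests and profile CIs
rec <- to_family_records(cohort, c("vermis_viii", "cog_total"))
full <- fit_ace(rec, "vermis_viii")
lrt(full, fit_ace(rec, "vermis_viii", "CE"))    # test for A
profile_ci(full, "a2")

# bivariate Cholesky decomposition
biv <- fit_bivariate(rec, "vermis_viii", "cog_total")
biv$pcorA + biv$pcorC + biv$pcorE - biv$r_phenotypic   # ~ 0
```

The full replication-shaped pipeline (simulate → associations →
univariate → bivariate → FDR → ledger) is driven by a YAML configuration
through `run_pipeline()`; `inst/scripts/twinvolve.R` wraps it for shell
use.

## Known limitations

* No ADE (dominance) models, sex-limitation, assortative mating, or
  GREML-style genomic methods; trivariate and higher Cholesky models are
  out of scope.
* The phenotypic stage's OLS p-values inherit mild anti-conservatism from
  twin non-independence, as in the replicated analysis.
* Profile bounds are located to $10^{-3}$ on the proportion scale;
  quantities whose likelihood is flat against an edge report the edge.
* The generator's Gaussian, MCAR world is idealized (see above); real
  cohort peculiarities (normative re-scoring, scanner batch effects) are
  deliberately absent.
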