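# Seeded recovery and calibration experiments. These wrap the full
# simulate -> reshape -> fit path so that parameter-recovery checks are a
# single call both in tests and in reproduction scripts.

#' Univariate parameter-recovery experiment
#'
#' Simulates seeded cohorts under a calibration generating model, fits the
#' univariate ACE model by FIML (age and sex in the mean model) and returns
#' the fitted variance proportions per seed. The default cohort scale
#' multiplies the HCP family mix by 2.05 (about 1,525 families), keeping
#' the MZ/DZ/singleton proportions.
#'
#' @param measure Calibration measure name (see [calibration_trait()]).
#' @param variant `"no_tbv"` or `"tbv"` generating model for ROI measures.
#' @param n_seeds Number of simulated cohorts.
#' @param design_scale Multiplier for the HCP family counts.
#' @param seed Root seed; per-cohort seeds are derived from it.
#' @return Data.frame with one row per seed (`a2`, `c2`, `e2`, `converged`)
#'   and the generating proportions as attributes.
#' @export
recovery_experiment <- function(measure, variant = "no_tbv", n_seeds = 10,
                                design_scale = 2.05, seed = 1) {
  sp <- calibration_trait(measure, variant)
  design <- calibration_design(scale = design_scale)
  seeds <- derive_seeds(seed, paste0("rep", seq_len(n_seeds)))
  rows <- lapply(seeds, function(s) {
    coh <- generate_cohort(design, s)
    coh <- simulate_phenotypes(coh, list(sp), seed = s + 1L)
    fit <- fit_ace(to_family_records(coh, measure), measure)
    data.frame(a2 = fit$a2, c2 = fit$c2, e2 = fit$e2,
               converged = fit$convergence$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "generating") <- c(a2 = sp$a2, c2 = sp$c2, e2 = sp$e2)
  out
}

#' Generator calibration experiment: sample mean of one measure
#'
#' Generates seeded cohorts with the published HCP family composition
#' (N = 932) and the calibration trait model, returning the per-seed sample
#' mean of the simulated measure.
#'
#' @inheritParams recovery_experiment
#' @return Numeric vector of per-seed sample means.
#' @export
calibration_mean_experiment <- function(measure = "total_vermis",
                                        n_seeds = 10, seed = 1) {
  sp <- calibration_trait(measure)
  design <- calibration_design()
  seeds <- derive_seeds(seed, paste0("rep", seq_len(n_seeds)))
  vapply(seeds, function(s) {
    coh <- generate_cohort(design, s)
    coh <- simulate_phenotypes(coh, list(sp), seed = s + 1L)
    mean(coh[[measure]])
  }, 0)
}

#' Cross-trait correlation recovery experiment
#'
#' Simulates a behavioral trait pair at the published HCP sample size with
#' the calibrated cross-trait phenotypic correlation (equal component
#' correlations via [cross_spec_from_phenotypic()]) and returns the
#' per-seed pairwise-complete Pearson correlation computed through the
#' phenotypic stage.
#'
#' @param measure_x,measure_y Calibration measure names.
#' @param r_phenotypic Generating phenotypic correlation.
#' @param n_seeds,seed As in [recovery_experiment()].
#' @return Numeric vector of per-seed correlations.
#' @export
correlation_experiment <- function(measure_x = "cog_fluid",
                                   measure_y = "cog_crystallized",
                                   r_phenotypic = NULL,
                                   n_seeds = 10, seed = 1) {
  cal <- hcp_calibration()
  r_phenotypic <- r_phenotypic %||%
    unname(cal$results["fluid_crystallized_r"])
  sx <- calibration_trait(measure_x)
  sy <- calibration_trait(measure_y)
  cross <- list(cross_spec_from_phenotypic(sx, sy, r_phenotypic))
  design <- calibration_design()
  seeds <- derive_seeds(seed, paste0("rep", seq_len(n_seeds)))
  vapply(seeds, function(s) {
    coh <- generate_cohort(design, s)
    coh <- simulate_phenotypes(coh, list(sx, sy), cross, seed = s + 1L)
    correlation_matrix(coh, c(measure_x, measure_y))[1, 2]
  }, 0)
}

#' Brain-behavior effect-size recovery experiment
#'
#' Simulates an ROI/behavior pair at the published HCP sample size with the
#' calibrated generating correlation (covariates independent of both
#' traits), runs the covariate-adjusted regression of
#' [fit_brain_behavior()] with age, sex and total brain volume, and
#' returns the per-seed recovered partial correlation.
#'
#' @param measure_roi,measure_behavior Calibration measure names.
#' @param r_target Generating (partial = marginal) correlation.
#' @param n_seeds,seed As in [recovery_experiment()].
#' @return Numeric vector of per-seed partial correlations.
#' @export
association_experiment <- function(measure_roi = "vermis_viii",
                                   measure_behavior = "cog_total",
                                   r_target = NULL,
                                   n_seeds = 10, seed = 1) {
  cal <- hcp_calibration()
  r_target <- r_target %||% unname(cal$results["vermis_viii_cognition_r"])
  sr <- calibration_trait(measure_roi)
  sb <- calibration_trait(measure_behavior)
  cross <- list(cross_spec_from_phenotypic(sr, sb, r_target))
  design <- calibration_design()
  seeds <- derive_seeds(seed, paste0("rep", seq_len(n_seeds)))
  vapply(seeds, function(s) {
    coh <- generate_cohort(design, s)
    coh <- simulate_phenotypes(coh, list(sr, sb, default_tbv_spec()),
                               cross, seed = s + 1L)
    fit_brain_behavior(coh, measure_roi, measure_behavior)$r_partial
  }, 0)
}

#' Type-I error of the boundary test for additive genetic effects
#'
#' Simulates replicate twin cohorts under a null with zero additive genetic
#' variance (shared environment and unique environment only), runs the
#' ACE-vs-CE likelihood-ratio test with the 50:50 boundary mixture
#' reference, and returns the per-replicate p-values. The empirical
#' rejection rate at 0.05 estimates the test's type-I error.
#'
#' @param n_reps Number of replicates (>= 500 for a stable estimate).
#' @param n_mz,n_dz Twin-pair counts per replicate cohort.
#' @param c2 Shared-environment proportion of the null model.
#' @param seed Root seed.
#' @return Numeric vector of p-values, length `n_reps`.
#' @export
null_a_test_experiment <- function(n_reps = 500, n_mz = 150, n_dz = 150,
                                   c2 = 0.36, seed = 1) {
  sp <- trait_spec("y0", 0, 1, a2 = 0, c2 = c2, e2 = 1 - c2)
  design <- cohort_design(n_mz, n_dz, 0)
  seeds <- derive_seeds(seed, paste0("rep", seq_len(n_reps)))
  vapply(seeds, function(s) {
    coh <- generate_cohort(design, s)
    coh <- simulate_phenotypes(coh, list(sp), seed = s + 1L)
    rec <- to_family_records(coh, "y0")
    lrt(fit_ace(rec, "y0", "ACE"), fit_ace(rec, "y0", "CE"))$p_value
  }, 0)
}

#' Profile-likelihood CI coverage experiment
#'
#' Simulates replicate cohorts with the published HCP family composition
#' under a calibration generating model, computes the 95% profile
#' likelihood interval for the heritability on each, and reports whether
#' each interval covers the generating value.
#'
#' @param measure Calibration measure (default the crystallized-cognition
#'   model).
#' @param n_reps Number of replicates.
#' @param seed Root seed.
#' @return Logical vector: per-replicate coverage of the generating `a2`.
#' @export
ci_coverage_experiment <- function(measure = "cog_crystallized",
                                   n_reps = 50, seed = 1) {
  sp <- calibration_trait(measure)
  design <- calibration_design()
  seeds <- derive_seeds(seed, paste0("rep", seq_len(n_reps)))
  vapply(seeds, function(s) {
    coh <- generate_cohort(design, s)
    coh <- simulate_phenotypes(coh, list(sp), seed = s + 1L)
    fit <- fit_ace(to_family_records(coh, measure), measure)
    ci <- profile_ci(fit, "a2")
    ci$lower <= sp$a2 && sp$a2 <= ci$upper
  }, TRUE)
}
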