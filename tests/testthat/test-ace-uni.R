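test_that("expected family covariance follows the relatedness algebra", {
  comp <- list(A = 2, C = 1, E = 1)
  mz <- matrix(1, 2, 2)
  expect_equal(expected_family_cov(comp, mz, mz),
               matrix(c(4, 3, 3, 4), 2, 2))
  dz <- matrix(c(1, .5, .5, 1), 2, 2)
  expect_equal(expected_family_cov(comp, dz, mz)[1, 2], 2)
  expect_equal(expected_family_cov(list(A = 0, C = 0, E = 5), mz, mz),
               diag(5, 2))
})

test_that("family log-likelihood equals the dense normal oracle and
           marginalizes missing members", {
  coh <- make_cohort(6, 6, 3, seed = 23)
  rec <- to_family_records(coh, "x")
  pars <- list(beta = c(0.2, 0.01, -0.1), A = 0.5, C = 0.2, E = 0.3)
  for (r in rec[c(1, 7, 13)]) {
    oracle <- -0.5 * dense_m2ll(list(r), "x", list(pars$beta),
                                matrix(pars$A), matrix(pars$C),
                                matrix(pars$E))
    expect_equal(family_loglik(pars, r, "x"), oracle, tolerance = 1e-10)
  }
  # one member missing -> density of the remaining member's marginal
  r2 <- rec[[1]]
  r2$y[2, "x"] <- NA
  single <- r2
  single$y <- single$y[1, , drop = FALSE]
  single$X <- single$X[1, , drop = FALSE]
  single$rA <- single$rC <- matrix(1, 1, 1)
  single$person_id <- single$person_id[1]
  expect_equal(family_loglik(pars, r2, "x"),
               family_loglik(pars, single, "x"), tolerance = 1e-12)
  # non-PD parameter points are rejected, not crashed
  expect_identical(family_loglik(list(beta = pars$beta, A = 0, C = 0, E = 0),
                                 rec[[1]], "x"), -Inf)
})

test_that("total FIML -2lnL matches the dense oracle including missingness", {
  sp <- trait_spec("x", 10, 3, .5, .2, .3, missing_rate = 0.2)
  coh <- make_cohort(15, 15, 8, seed = 29, traits = list(sp))
  rec <- to_family_records(coh, "x")
  fit <- fit_ace(rec, "x")
  oracle <- dense_m2ll(rec, "x", list(fit$mean_betas),
                       matrix(fit$A), matrix(fit$C), matrix(fit$E))
  expect_equal(fit$minus2lnL, oracle, tolerance = 1e-6)
})

test_that("the likelihood prefers generating parameters over perturbed ones", {
  sp <- trait_spec("x", 0, 1, .6, .2, .2)
  coh <- make_cohort(400, 400, 100, seed = 31, traits = list(sp))
  rec <- to_family_records(coh, "x")
  at <- function(A, C, E) {
    dense_m2ll(rec, "x", list(c(0, 0, 0)), matrix(A), matrix(C), matrix(E))
  }
  m2_true <- at(.6, .2, .2)
  expect_lt(m2_true, at(.2, .2, .6))
  expect_lt(m2_true, at(.6, .35, .05))
  expect_lt(m2_true, at(.9, .05, .05))
})

test_that("ACE estimates recover generating proportions at large n", {
  # behavioral-scale and ROI-scale generating models from the calibration
  models <- list(calibration_trait("cog_crystallized"),
                 calibration_trait("left_crus_i"),
                 trait_spec("mid", 50, 10, .4, .35, .25))
  for (sp in models) {
    errs <- vapply(1:3, function(s) {
      coh <- make_cohort(250, 150, 100, seed = 1000 + s, traits = list(sp))
      f <- fit_ace(to_family_records(coh, sp$name), sp$name)
      abs(c(f$a2 - sp$a2, f$c2 - sp$c2, f$e2 - sp$e2))
    }, numeric(3))
    expect_lt(mean(errs), 0.06)
  }
})

test_that("submodels obey constraints, boundaries and nesting monotonicity", {
  sp <- trait_spec("x", 0, 1, 0, .4, .6)   # a2 = 0 boundary
  coh <- make_cohort(150, 150, 50, seed = 37, traits = list(sp))
  rec <- to_family_records(coh, "x")
  ace <- fit_ace(rec, "x", "ACE")
  ae <- fit_ace(rec, "x", "AE")
  ce <- fit_ace(rec, "x", "CE")
  e <- fit_ace(rec, "x", "E")
  expect_equal(ae$c2, 0)
  expect_equal(ce$a2, 0)
  expect_equal(e$a2 + e$c2, 0)
  # boundary truth: ACE lands near a2 = 0 and CE fits as well as ACE
  expect_lt(ace$a2, 0.1)
  expect_lt(ce$minus2lnL - ace$minus2lnL, 1)
  # nesting monotonicity
  tol <- 1e-6
  expect_gte(ae$minus2lnL, ace$minus2lnL - tol)
  expect_gte(ce$minus2lnL, ace$minus2lnL - tol)
  expect_gte(e$minus2lnL, ae$minus2lnL - tol)
  expect_gte(e$minus2lnL, ce$minus2lnL - tol)
  # proportions sum to 1 on every fit
  for (f in list(ace, ae, ce, e)) {
    expect_equal(f$a2 + f$c2 + f$e2, 1, tolerance = 1e-8)
  }
})

test_that("standardize converts components to proportions", {
  expect_equal(standardize(list(A = 8.4, C = 0.4, E = 1.2))[["a2"]], 0.84)
  expect_equal(standardize(list(A = 0, C = 1, E = 1))[["a2"]], 0)
  expect_equal(standardize(list(A = 0, C = 0, E = 5))[["e2"]], 1)
  expect_error(standardize(list(A = 0, C = 0, E = 0)), "V")
  f <- fit_ace(to_family_records(make_cohort(20, 20, 5, seed = 41), "x"), "x")
  pr <- standardize(f)
  expect_equal(sum(pr), 1, tolerance = 1e-8)
})

test_that("results are invariant to family order and trait rescaling", {
  sp <- trait_spec("x", 100, 15, .5, .3, .2)
  coh <- make_cohort(80, 80, 40, seed = 43, traits = list(sp))
  rec <- to_family_records(coh, "x")
  f1 <- fit_ace(rec, "x")
  # shuffled family order
  set.seed(44)
  rec_shuf <- structure(rec[sample(length(rec))], class = "family_records",
                        traits = attr(rec, "traits"),
                        covariates = attr(rec, "covariates"),
                        covariate_centers = attr(rec, "covariate_centers"),
                        n_dropped_members = attr(rec, "n_dropped_members"))
  f2 <- fit_ace(rec_shuf, "x")
  expect_equal(f2$a2, f1$a2, tolerance = 1e-6)
  expect_equal(f2$minus2lnL, f1$minus2lnL, tolerance = 1e-6)
  # trait x1000
  coh3 <- coh; coh3$x <- coh3$x * 1000
  f3 <- fit_ace(to_family_records(coh3, "x"), "x")
  expect_equal(f3$a2, f1$a2, tolerance = 1e-6)
  expect_equal(f3$c2, f1$c2, tolerance = 1e-6)
  expect_equal(f3$A, f1$A * 1e6, tolerance = 1e-4 * f1$A * 1e6)
})

test_that("FIML under MAR missingness agrees with complete-data estimates", {
  sp_full <- trait_spec("x", 0, 1, .6, .2, .2)
  sp_miss <- trait_spec("x", 0, 1, .6, .2, .2, missing_rate = 0.2)
  a2 <- vapply(1:2, function(s) {
    cohF <- make_cohort(500, 300, 200, seed = 300 + s,
                        traits = list(sp_full))
    cohM <- make_cohort(500, 300, 200, seed = 300 + s,
                        traits = list(sp_miss))
    c(fit_ace(to_family_records(cohF, "x"), "x")$a2,
      fit_ace(to_family_records(cohM, "x"), "x")$a2)
  }, numeric(2))
  expect_equal(mean(a2[2, ] - a2[1, ]), 0, tolerance = 0.04)
})

test_that("boundary-mixture LRT p-values follow the stated mixtures", {
  mk <- function(m2, model, n_par) {
    structure(list(trait = "x", covariates = c("age", "sex"), model = model,
                   minus2lnL = m2, n_params = n_par), class = "ace_fit")
  }
  full <- mk(1000, "ACE", 5)
  # T = 3.841, one boundary parameter: p ~ 0.0250
  t1 <- lrt(full, mk(1003.841, "CE", 4))
  expect_equal(t1$name, "A")
  expect_equal(t1$df_dropped, 1)
  expect_equal(t1$p_value, 0.025, tolerance = 1e-3)
  # T = 0: mixture mass at zero gives p = 1
  expect_equal(lrt(full, mk(1000, "AE", 4))$p_value, 1)
  # two-parameter AC test mixture
  t2 <- lrt(full, mk(1006, "E", 3))
  expect_equal(t2$name, "AC")
  expect_equal(t2$p_value,
               0.5 * pchisq(6, 1, lower.tail = FALSE) +
                 0.25 * pchisq(6, 2, lower.tail = FALSE), tolerance = 1e-12)
  # malformed comparisons
  expect_error(lrt(mk(1000, "AE", 4), mk(1001, "CE", 4)), "not nested")
  expect_error(lrt(full, mk(990, "CE", 4)), "fits better")
})

test_that("profile CIs bracket the estimate, hit boundaries, and shrink
           with n", {
  sp0 <- trait_spec("x", 0, 1, 0, .4, .6)
  coh0 <- make_cohort(120, 120, 0, seed = 53, traits = list(sp0))
  f0 <- fit_ace(to_family_records(coh0, "x"), "x")
  ci0 <- profile_ci(f0, "a2")
  expect_equal(ci0$lower, 0)        # flat likelihood at the a2 = 0 boundary
  expect_lte(ci0$lower, ci0$point)
  expect_gte(ci0$upper, ci0$point)

  sp <- trait_spec("x", 0, 1, .5, .2, .3)
  widths <- vapply(c(1, 2), function(k) {
    mean(vapply(1:3, function(s) {
      coh <- make_cohort(150 * k, 100 * k, 50 * k, seed = 57 + s,
                         traits = list(sp))
      f <- fit_ace(to_family_records(coh, "x"), "x")
      ci <- profile_ci(f, "a2")
      expect_true(ci$lower <= f$a2 && f$a2 <= ci$upper)
      ci$upper - ci$lower
    }, 0))
  }, 0)
  expect_lt(widths[2], widths[1])   # doubling n shrinks the interval
})
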