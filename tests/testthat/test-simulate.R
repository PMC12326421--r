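test_that("cohort generation reproduces the designed family composition", {
  coh <- generate_cohort(cohort_design(121, 67, 556), seed = 42)
  expect_equal(nrow(coh), 932)
  expect_equal(sum(coh$relationship == "MZ_twin"), 242)
  expect_equal(sum(coh$relationship == "DZ_twin"), 134)
  expect_equal(sum(coh$relationship == "singleton"), 556)
  expect_equal(length(unique(coh$family_id)), 121 + 67 + 556)

  empty <- generate_cohort(cohort_design(0, 0, 0), seed = 1)
  expect_equal(nrow(empty), 0)

  one <- generate_cohort(cohort_design(1, 0, 0), seed = 7)
  expect_equal(nrow(one), 2)
  expect_equal(one$family_id[1], one$family_id[2])
  expect_equal(one$sex[1], one$sex[2])
  expect_true(all(one$relationship == "MZ_twin"))
  expect_equal(one$age[1], one$age[2])
})

test_that("cohort generation is deterministic and validates its design", {
  a <- generate_cohort(cohort_design(10, 10, 10), seed = 3)
  b <- generate_cohort(cohort_design(10, 10, 10), seed = 3)
  expect_identical(a, b)
  expect_error(cohort_design(-1, 0, 0), "non-negative")
  expect_error(cohort_design(1, 1, 1, sex_ratio = 1.2), "sex_ratio")
  # ages within the truncation range and shared within twin pairs
  coh <- generate_cohort(cohort_design(30, 30, 5), seed = 9)
  expect_true(all(coh$age >= 22 & coh$age <= 37))
  for (rel in c("MZ_twin", "DZ_twin")) {
    pv <- pair_values(coh, "age", rel)
    expect_equal(pv[, 1], pv[, 2])
  }
})

test_that("trait_spec enforces its invariants", {
  expect_error(trait_spec("x", 0, 1, .5, .5, .5), "must equal 1")
  expect_error(trait_spec("x", 0, 1, -.1, .6, .5), "\\[0, 1\\]")
  expect_error(trait_spec("x", 0, 0, .5, .2, .3), "total_sd")
  expect_error(trait_spec("x", 0, 1, .5, .2, .3,
                          covariate_betas = c(height = 2)), "unknown")
  sp <- trait_spec("x", 10, 2, .5, .25, .25)
  expect_s3_class(sp, "trait_spec")
})

test_that("purely genetic traits show the twin intraclass correlations", {
  sp <- trait_spec("g", 0, 1, a2 = 1, c2 = 0, e2 = 0)
  coh <- make_cohort(800, 800, 0, seed = 11, traits = list(sp))
  mz <- pair_values(coh, "g", "MZ_twin")
  dz <- pair_values(coh, "g", "DZ_twin")
  expect_gt(cor(mz[, 1], mz[, 2]), 0.999)
  expect_equal(cor(dz[, 1], dz[, 2]), 0.5, tolerance = 0.1)
})

test_that("simulated variance and twin covariances match the ACE structure", {
  sp <- trait_spec("v", 100, 15, a2 = 0.6, c2 = 0.2, e2 = 0.2)
  # ~10,000 individuals
  coh <- make_cohort(1500, 1500, 4000, seed = 21, traits = list(sp))
  expect_equal(var(coh$v), 15^2, tolerance = 0.05 * 15^2)
  mz <- pair_values(coh, "v", "MZ_twin")
  dz <- pair_values(coh, "v", "DZ_twin")
  expect_equal(cov(mz[, 1], mz[, 2]), (0.6 + 0.2) * 225,
               tolerance = 0.1 * 225)
  expect_equal(cov(dz[, 1], dz[, 2]), (0.5 * 0.6 + 0.2) * 225,
               tolerance = 0.1 * 225)
  # sibling sharing matches DZ sharing
  sib <- make_cohort(800, 0, 0, seed = 22, traits = list(sp), extra_sibs = 1)
  tw <- sib[sib$relationship == "MZ_twin", ]
  first_twin <- tw[!duplicated(tw$family_id), ]
  sibs <- sib[sib$relationship == "sibling", ]
  stopifnot(identical(first_twin$family_id, sibs$family_id))
  expect_equal(cov(first_twin$v, sibs$v), (0.5 * 0.6 + 0.2) * 225,
               tolerance = 0.12 * 225)
})

test_that("calibrated total-vermis trait reproduces the published scale", {
  sp <- calibration_trait("total_vermis")
  expect_equal(sp$mean, 5547.65)
  expect_equal(sp$total_sd, 640.50)
  expect_equal(sp$a2 + sp$c2 + sp$e2, 1, tolerance = 1e-13)
  coh <- make_cohort(121, 67, 556, seed = 31, traits = list(sp))
  expect_equal(mean(coh$total_vermis), 5547.65, tolerance = 3 * 640.5 / sqrt(932))
})

test_that("every calibration generating model has proportions summing to 1", {
  cal <- hcp_calibration()
  for (m in cal$behavior$measure) {
    sp <- calibration_trait(m)
    expect_equal(sp$a2 + sp$c2 + sp$e2, 1, tolerance = 1e-13)
  }
  for (m in cal$roi$measure) {
    for (v in c("no_tbv", "tbv")) {
      sp <- calibration_trait(m, v)
      expect_equal(sp$a2 + sp$c2 + sp$e2, 1, tolerance = 1e-13)
    }
  }
})

test_that("cross-trait correlations propagate to the phenotypic scale", {
  t1 <- trait_spec("p", 0, 1, .8, 0, .2)
  t2 <- trait_spec("q", 0, 1, .8, 0, .2)
  cr <- cross_trait_spec("p", "q", rA = 0.9)
  coh <- make_cohort(500, 500, 2000, seed = 41, traits = list(t1, t2),
                     cross = list(cr))
  # closed form: r_ph = sqrt(a2)*rA*sqrt(a2) = 0.8 * 0.9
  expect_equal(cor(coh$p, coh$q), 0.72, tolerance = 0.04)
  # non-PSD component matrix must be rejected at construction
  t3 <- trait_spec("z", 0, 1, .8, 0, .2)
  bad <- list(cross_trait_spec("p", "q", rA = 0.95),
              cross_trait_spec("q", "z", rA = 0.95),
              cross_trait_spec("p", "z", rA = -0.9))
  expect_error(
    simulate_phenotypes(generate_cohort(cohort_design(5, 5, 5), 1),
                        list(t1, t2, t3), bad, seed = 2),
    "positive semi-definite")
})

test_that("cohort CSV round-trips exactly and is byte-identical per seed", {
  sp <- trait_spec("x", 5, 2, .4, .3, .3, missing_rate = 0.15)
  coh <- make_cohort(10, 10, 5, seed = 51, traits = list(sp))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(coh, f1)
  back <- read_cohort(f1)
  expect_equal(back$x, coh$x)
  expect_equal(back$age, coh$age)
  expect_identical(back$person_id, coh$person_id)
  expect_true(anyNA(back$x))           # missing markers survive
  # byte-identical regeneration
  coh2 <- make_cohort(10, 10, 5, seed = 51, traits = list(sp))
  write_cohort(coh2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("cohort reading flags structural problems", {
  coh <- make_cohort(2, 1, 1, seed = 61)
  f <- tempfile(fileext = ".csv")
  # twin without a co-twin row: accepted as informative singleton
  write_cohort(coh[-1, ], f)
  expect_silent(orphan <- read_cohort(f))
  expect_equal(nrow(orphan), nrow(coh) - 1L)
  rec <- to_family_records(orphan, "x")
  expect_equal(sum(vapply(rec, function(r) length(r$person_id), 0L)),
               nrow(orphan))
  # duplicate person id: parse error naming the row
  dup <- coh; dup$person_id[2] <- dup$person_id[1]
  write_cohort(dup, f)
  expect_error(read_cohort(f), "duplicate person_id at row")
  # MZ co-twins with different sex: validation warning
  odd <- coh
  mz_rows <- which(odd$relationship == "MZ_twin")[1:2]
  odd$sex[mz_rows] <- c(0L, 1L)
  write_cohort(odd, f)
  expect_warning(read_cohort(f), "differing sex")
})
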