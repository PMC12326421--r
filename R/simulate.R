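#' Describe a twin-family cohort
#'
#' A cohort design gives the family composition of an extended twin sample:
#' monozygotic (MZ) twin pairs, dizygotic (DZ) twin pairs and singletons,
#' plus the demographic distributions used when sampling individuals.
#' Defaults reproduce the Human Connectome Project (HCP) young-adult
#' extended-twin sample used to calibrate this package: 121 MZ pairs,
#' 67 DZ pairs and 556 singletons (N = 932), 45% male, ages ~N(28.8, 3.6)
#' truncated to the 22-37 year HCP range.
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons Non-negative counts.
#' @param sex_ratio Proportion of males in `[0, 1]`.
#' @param age_mean,age_sd Age distribution in years (`age_sd >= 0`).
#' @param age_range Truncation bounds for ages, in years.
#' @param n_extra_sibs Optional count of additional non-twin siblings added
#'   to every twin family (extended twin design configurations beyond plain
#'   pairs are not enumerated in published HCP summaries, so the mix is left
#'   to the caller).
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_mz_pairs = 121, n_dz_pairs = 67,
                          n_singletons = 556, sex_ratio = 0.45,
                          age_mean = 28.8, age_sd = 3.6,
                          age_range = c(22, 37), n_extra_sibs = 0) {
  if (!is_count(n_mz_pairs) || !is_count(n_dz_pairs) ||
      !is_count(n_singletons) || !is_count(n_extra_sibs)) {
    stop("family counts must be non-negative integers")
  }
  if (!is.numeric(sex_ratio) || sex_ratio < 0 || sex_ratio > 1) {
    stop("sex_ratio must lie in [0, 1]")
  }
  if (!is.numeric(age_sd) || age_sd < 0) stop("age_sd must be >= 0")
  stopifnot(length(age_range) == 2L, age_range[1] <= age_range[2])
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 n_singletons = as.integer(n_singletons),
                 sex_ratio = sex_ratio, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 n_extra_sibs = as.integer(n_extra_sibs)),
            class = "cohort_design")
}

#' Specify the generating model for one trait
#'
#' A trait is generated as
#' `mean + sum(beta_j * centered covariate_j) + total_sd * (a*G + c*S + e*U)`
#' where `a = sqrt(a2)` etc., `G` is an additive-genetic latent score shared
#' completely by MZ co-twins and correlated 0.5 between DZ co-twins and
#' siblings, `S` is a shared-environment score common to all family members
#' and `U` is an individual-specific score. Covariate effects are applied to
#' mean-centered covariates so `mean` remains the population trait mean.
#'
#' @param name Trait label (column name in the cohort table).
#' @param mean,total_sd Trait mean and total phenotypic SD (trait units,
#'   `total_sd > 0`).
#' @param a2,c2,e2 Generating variance proportions; must be in `[0, 1]` and
#'   sum to 1 within 1e-12.
#' @param covariate_betas Optional named numeric vector of slopes (trait
#'   units per covariate unit) for `age`, `sex` and/or `tbv`.
#' @param missing_rate Missing-at-random rate in `[0, 1)` applied to this
#'   trait after generation (default 0); exercises the FIML path.
#' @return An object of class `trait_spec`.
#' @export
trait_spec <- function(name, mean, total_sd, a2, c2, e2,
                       covariate_betas = NULL, missing_rate = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(total_sd) || total_sd <= 0) stop("total_sd must be > 0")
  props <- c(a2 = a2, c2 = c2, e2 = e2)
  if (any(props < 0) || any(props > 1)) {
    stop("variance proportions must lie in [0, 1]")
  }
  if (abs(sum(props) - 1) > 1e-12) {
    stop("a2 + c2 + e2 must equal 1 (got ", format(sum(props), digits = 15), ")")
  }
  if (!is.null(covariate_betas)) {
    if (is.null(names(covariate_betas)) || any(!nzchar(names(covariate_betas)))) {
      stop("covariate_betas must be a named numeric vector")
    }
    bad <- setdiff(names(covariate_betas), c("age", "sex", "tbv"))
    if (length(bad)) stop("unknown covariates in covariate_betas: ",
                          paste(bad, collapse = ", "))
  }
  stopifnot(missing_rate >= 0, missing_rate < 1)
  structure(list(name = name, mean = mean, total_sd = total_sd,
                 a2 = a2, c2 = c2, e2 = e2,
                 covariate_betas = covariate_betas,
                 missing_rate = missing_rate),
            class = "trait_spec")
}

#' Specify cross-trait latent correlations for a pair of traits
#'
#' Component correlations between the additive-genetic (`rA`),
#' shared-environmental (`rC`) and unique-environmental (`rE`) latent scores
#' of two traits. The implied phenotypic correlation is
#' `sqrt(a2_x)*rA*sqrt(a2_y) + sqrt(c2_x)*rC*sqrt(c2_y) +
#'  sqrt(e2_x)*rE*sqrt(e2_y)`.
#'
#' @param trait_x,trait_y Trait labels.
#' @param rA,rC,rE Correlations in `[-1, 1]`.
#' @return An object of class `cross_trait_spec`.
#' @export
cross_trait_spec <- function(trait_x, trait_y, rA = 0, rC = 0, rE = 0) {
  stopifnot(is.character(trait_x), is.character(trait_y),
            trait_x != trait_y)
  for (r in c(rA, rC, rE)) {
    if (!is.numeric(r) || abs(r) > 1) stop("component correlations must lie in [-1, 1]")
  }
  structure(list(trait_x = trait_x, trait_y = trait_y,
                 rA = rA, rC = rC, rE = rE),
            class = "cross_trait_spec")
}

#' Cross-trait spec reproducing a target phenotypic correlation
#'
#' Convenience constructor that sets `rA = rC = rE = r0` with `r0` chosen so
#' the implied phenotypic correlation between the two traits equals
#' `r_phenotypic` given their generating variance proportions. Useful when a
#' study reports a phenotypic correlation without its component split.
#'
#' @param spec_x,spec_y [trait_spec()] objects for the two traits.
#' @param r_phenotypic Target phenotypic correlation.
#' @return A [cross_trait_spec()].
#' @export
cross_spec_from_phenotypic <- function(spec_x, spec_y, r_phenotypic) {
  stopifnot(inherits(spec_x, "trait_spec"), inherits(spec_y, "trait_spec"))
  w <- sqrt(spec_x$a2 * spec_y$a2) + sqrt(spec_x$c2 * spec_y$c2) +
    sqrt(spec_x$e2 * spec_y$e2)
  if (w <= 0) stop("degenerate trait specs: no shared variance channels")
  r0 <- r_phenotypic / w
  if (abs(r0) > 1) {
    stop("target phenotypic correlation ", r_phenotypic,
         " is not attainable with equal component correlations (needs |r| = ",
         format(abs(r0), digits = 3), ")")
  }
  cross_trait_spec(spec_x$name, spec_y$name, rA = r0, rC = r0, rE = r0)
}

# Assemble T x T component correlation matrices from cross specs and check
# positive semi-definiteness (construction-time invariant).
component_corr_matrices <- function(trait_names, cross) {
  Tn <- length(trait_names)
  RA <- RC <- RE <- diag(Tn)
  dimnames(RA) <- dimnames(RC) <- dimnames(RE) <- list(trait_names, trait_names)
  for (cs in cross) {
    if (!inherits(cs, "cross_trait_spec")) stop("cross must be cross_trait_spec objects")
    i <- match(cs$trait_x, trait_names)
    j <- match(cs$trait_y, trait_names)
    if (is.na(i) || is.na(j)) {
      stop("cross-trait spec references unknown trait: ",
           cs$trait_x, " / ", cs$trait_y)
    }
    RA[i, j] <- RA[j, i] <- cs$rA
    RC[i, j] <- RC[j, i] <- cs$rC
    RE[i, j] <- RE[j, i] <- cs$rE
  }
  for (nm in c("RA", "RC", "RE")) {
    M <- get(nm)
    ev <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) {
      stop("component correlation matrix ", nm,
           " is not positive semi-definite (min eigenvalue ", format(ev), ")")
    }
  }
  list(RA = RA, RC = RC, RE = RE)
}

#' Generate a twin-family cohort (demographics only)
#'
#' Samples individuals according to a [cohort_design()]: MZ co-twins share
#' sex and age, DZ co-twins share age, and each pair or singleton gets a
#' unique `family_id`. Phenotype columns are added later by
#' [simulate_phenotypes()].
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed; output is deterministic given `seed`.
#' @return A data.frame with columns `person_id`, `family_id`,
#'   `relationship` (`MZ_twin`, `DZ_twin`, `singleton`, `sibling`),
#'   `sex` (F = 0, M = 1) and `age` (years).
#' @export
generate_cohort <- function(design, seed) {
  stopifnot(inherits(design, "cohort_design"))
  n_fam <- design$n_mz_pairs + design$n_dz_pairs + design$n_singletons
  if (n_fam == 0L) {
    return(data.frame(person_id = character(), family_id = character(),
                      relationship = character(), sex = integer(),
                      age = numeric(), stringsAsFactors = FALSE))
  }
  fam_type <- rep(c("MZ", "DZ", "S"),
                  c(design$n_mz_pairs, design$n_dz_pairs, design$n_singletons))
  fam_id <- sprintf("F%05d", seq_len(n_fam))
  n_memb <- ifelse(fam_type == "S", 1L, 2L + design$n_extra_sibs)
  lo <- design$age_range[1]; hi <- design$age_range[2]

  # fully vectorized construction (one draw block per quantity; draw order
  # is fixed, so output is deterministic given the seed)
  fam_of <- rep.int(seq_len(n_fam), n_memb)
  memb_no <- sequence(n_memb)
  is_single <- fam_type[fam_of] == "S"
  is_twin <- !is_single & memb_no <= 2L
  relationship <- ifelse(is_single, "singleton",
                         ifelse(!is_twin, "sibling",
                                ifelse(fam_type[fam_of] == "MZ",
                                       "MZ_twin", "DZ_twin")))
  with_seed(seed, {
    # one "family age" per family (twins and singletons), own ages for sibs
    fam_age <- rtruncnorm(n_fam, design$age_mean, design$age_sd, lo, hi)
    sib_age <- rtruncnorm(sum(!is_single & !is_twin),
                          design$age_mean, design$age_sd, lo, hi)
    age <- fam_age[fam_of]
    age[!is_single & !is_twin] <- sib_age
    # sex: one draw per MZ pair (shared), one per person otherwise
    fam_sex <- rbinom(n_fam, 1L, design$sex_ratio)
    own_sex <- rbinom(length(fam_of), 1L, design$sex_ratio)
    share_fam_sex <- fam_type[fam_of] == "MZ" & memb_no <= 2L
    sex <- ifelse(share_fam_sex, fam_sex[fam_of], own_sex)
    data.frame(
      person_id = paste0(fam_id[fam_of], "_", memb_no),
      family_id = fam_id[fam_of], relationship = relationship,
      sex = as.integer(sex), age = age, stringsAsFactors = FALSE)
  })
}

#' Simulate phenotypes on a cohort
#'
#' Fills phenotype columns on a cohort generated by [generate_cohort()]
#' according to trait-wise ACE variance structure and optional cross-trait
#' latent correlations. Additive-genetic latent scores are identical within
#' MZ pairs and correlated 0.5 within DZ/sibling pairs (constructed as
#' `sqrt(0.5)*family + sqrt(0.5)*individual`); shared-environment scores are
#' common to a family; unique-environment scores are independent.
#'
#' If a trait named `"tbv"` is supplied it is simulated first and written to
#' the `tbv` column so other traits may reference it in `covariate_betas`.
#'
#' @param cohort Data.frame from [generate_cohort()].
#' @param traits List of [trait_spec()] objects.
#' @param cross Optional list of [cross_trait_spec()] objects; the implied
#'   component correlation matrices must be positive semi-definite.
#' @param seed Integer seed.
#' @return The cohort with a `tbv` column and one column per trait.
#' @export
simulate_phenotypes <- function(cohort, traits, cross = list(), seed) {
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  stopifnot(all(vapply(traits, inherits, TRUE, "trait_spec")))
  nms <- vapply(traits, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate trait names")
  # tbv first so it can serve as a covariate for later traits
  ord <- order(nms != "tbv")
  traits <- traits[ord]; nms <- nms[ord]
  R <- component_corr_matrices(nms, cross)
  n <- nrow(cohort)
  out <- cohort
  if (!"tbv" %in% names(out)) out$tbv <- NA_real_
  if (n == 0L) {
    for (nm in setdiff(nms, "tbv")) out[[nm]] <- numeric(0)
    return(out)
  }

  fam <- match(cohort$family_id, unique(cohort$family_id))
  n_fam <- max(fam)
  Tn <- length(nms)
  LA <- psd_sqrt(R$RA); LC <- psd_sqrt(R$RC); LE <- psd_sqrt(R$RE)

  with_seed(seed, {
    Gfam <- matrix(rnorm(n_fam * Tn), n_fam) %*% LA
    Sfam <- matrix(rnorm(n_fam * Tn), n_fam) %*% LC
    Gind <- matrix(rnorm(n * Tn), n) %*% LA
    Uind <- matrix(rnorm(n * Tn), n) %*% LE
    # MZ co-twins share their individual-level genetic draw
    is_mz <- cohort$relationship == "MZ_twin"
    if (any(is_mz)) {
      for (f in unique(fam[is_mz])) {
        idx <- which(fam == f & is_mz)
        if (length(idx) > 1L) {
          Gind[idx[-1L], ] <- rep(Gind[idx[1L], ], each = length(idx) - 1L)
        }
      }
    }
    G <- sqrt(0.5) * Gfam[fam, , drop = FALSE] + sqrt(0.5) * Gind
    S <- Sfam[fam, , drop = FALSE]

    age_c <- cohort$age - mean(cohort$age)
    sex_c <- cohort$sex - mean(cohort$sex)
    for (t in seq_len(Tn)) {
      sp <- traits[[t]]
      y <- sp$mean + sp$total_sd *
        (sqrt(sp$a2) * G[, t] + sqrt(sp$c2) * S[, t] + sqrt(sp$e2) * Uind[, t])
      if (!is.null(sp$covariate_betas)) {
        for (cv in names(sp$covariate_betas)) {
          x <- switch(cv,
                      age = age_c,
                      sex = sex_c,
                      tbv = {
                        if (all(is.na(out$tbv))) {
                          stop("trait '", sp$name, "' uses tbv as covariate but ",
                               "no tbv values are available; supply a trait_spec",
                               " named 'tbv'")
                        }
                        out$tbv - mean(out$tbv)
                      })
          y <- y + sp$covariate_betas[[cv]] * x
        }
      }
      if (sp$missing_rate > 0) {
        y[runif(n) < sp$missing_rate] <- NA_real_
      }
      out[[sp$name]] <- y
    }
    out
  })
}

#' Write a cohort table to CSV
#'
#' Numeric values are written with full (17 significant digit) precision so
#' that [read_cohort()] round-trips exactly and identical seeds yield
#' byte-identical files. Missing values are written as empty fields.
#'
#' @param cohort Cohort data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- names(cohort)
  req <- c("person_id", "family_id", "relationship", "sex", "age")
  if (!all(req %in% cols)) {
    stop("cohort is missing required columns: ",
         paste(setdiff(req, cols), collapse = ", "))
  }
  fmt <- function(x) {
    if (is.numeric(x)) {
      s <- vapply(x, function(v) {
        if (is.na(v)) "" else if (is.integer(x) || v == round(v)) {
          sprintf("%d", as.integer(v))
        } else sprintf("%.17g", v)
      }, "")
      s
    } else {
      ifelse(is.na(x), "", as.character(x))
    }
  }
  m <- vapply(cohort, fmt, character(nrow(cohort)))
  if (nrow(cohort) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, cols))
  if (nrow(cohort) == 0L) m <- matrix(character(), 0L, length(cols),
                                      dimnames = list(NULL, cols))
  lines <- c(paste(cols, collapse = ","),
             apply(m, 1L, paste, collapse = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates structural invariants: unique `person_id` (duplicates are a
#' parse error naming the offending rows), and MZ co-twins sharing sex
#' (violations produce a validation warning, not an error). A twin row whose
#' co-twin is absent is accepted and treated as an informative singleton by
#' downstream stages (its family simply has one member).
#'
#' @param path CSV path written by [write_cohort()] (or hand-built with the
#'   same columns).
#' @return Cohort data.frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"),
                        colClasses = NA, check.names = FALSE)
  req <- c("person_id", "family_id", "relationship", "sex", "age")
  if (!all(req %in% names(df))) {
    stop("malformed cohort file: missing columns ",
         paste(setdiff(req, names(df)), collapse = ", "))
  }
  dup <- which(duplicated(df$person_id))
  if (length(dup)) {
    stop("duplicate person_id at row(s) ", paste(dup, collapse = ", "),
         ": ", paste(unique(df$person_id[dup]), collapse = ", "))
  }
  num_cols <- setdiff(names(df), c("person_id", "family_id", "relationship"))
  for (nm in num_cols) {
    x <- df[[nm]]
    if (!is.numeric(x)) {
      conv <- suppressWarnings(as.numeric(x))
      if (any(!is.na(x) & is.na(conv))) {
        bad <- which(!is.na(x) & is.na(conv))[1L]
        stop("malformed numeric value in column '", nm, "' at row ", bad)
      }
      x <- conv
    }
    df[[nm]] <- x
  }
  df$sex <- as.integer(df$sex)
  validate_cohort(df)
  df
}

# Structural warnings shared by read_cohort and the reshape stage.
validate_cohort <- function(cohort) {
  mz <- cohort[cohort$relationship == "MZ_twin", , drop = FALSE]
  if (nrow(mz)) {
    bad <- vapply(split(mz$sex, mz$family_id),
                  function(s) length(unique(s[!is.na(s)])) > 1L, TRUE)
    if (any(bad)) {
      warning("MZ co-twins with differing sex in family/families: ",
              paste(names(bad)[bad], collapse = ", "))
    }
  }
  invisible(cohort)
}

#' Default total-brain-volume trait specification
#'
#' A realistic young-adult generating model for total brain volume (mm^3):
#' mean 1,181,000, SD 110,000, heritability 0.85 with a small shared
#' environmental component, typical of adult twin neuroimaging studies.
#'
#' @param missing_rate Optional MAR rate.
#' @return A [trait_spec()] named `"tbv"`.
#' @export
default_tbv_spec <- function(missing_rate = 0) {
  trait_spec("tbv", mean = 1181000, total_sd = 110000,
             a2 = 0.85, c2 = 0.05, e2 = 0.10, missing_rate = missing_rate)
}
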