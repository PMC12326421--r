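#' Convert individual-wise records to family-wise records
#'
#' Regroups an individual-wise cohort table into family-wise records, the
#' unit of analysis for the likelihood engines. Each record carries the
#' family's phenotype matrix, a per-member covariate design matrix and the
#' pairwise relatedness coefficients implied by the relationship codes:
#' additive-genetic relatedness 1 between MZ co-twins, 0.5 between DZ
#' co-twins and siblings, and shared-environment relatedness 1 within a
#' family. Singleton families yield one-member records.
#'
#' Members missing any requested covariate have all their phenotypes dropped
#' for these models (the mean model requires complete covariates); the count
#' of such members is reported in attribute `n_dropped_members` and via a
#' message. Age (and any other numeric covariate) is centered at the sample
#' mean before modeling; centers are stored in attribute `covariate_centers`
#' and only affect the intercept.
#'
#' @param cohort Individual-wise data.frame (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param traits Character vector of phenotype column names.
#' @param covariates Character vector of covariate column names (default
#'   `c("age", "sex")`; add `"tbv"` for globally adjusted models).
#' @return A list of `family_record` objects (class `family_records`),
#'   ordered by `family_id`, members ordered by `person_id` within family.
#' @export
to_family_records <- function(cohort, traits, covariates = c("age", "sex")) {
  stopifnot(is.data.frame(cohort), length(traits) >= 1L)
  missing_cols <- setdiff(c(traits, covariates), names(cohort))
  if (length(missing_cols)) {
    stop("unknown trait/covariate column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_cohort(cohort)
  centers <- vapply(covariates, function(cv) {
    x <- cohort[[cv]]
    if (is.numeric(x)) mean(x, na.rm = TRUE) else 0
  }, 0)
  cov_mat <- if (length(covariates)) {
    sapply(covariates, function(cv) as.numeric(cohort[[cv]]) - centers[[cv]])
  } else NULL
  cov_mat <- matrix(cov_mat, nrow = nrow(cohort),
                    dimnames = list(NULL, covariates))

  ord <- order(cohort$family_id, cohort$person_id)
  cohort <- cohort[ord, , drop = FALSE]
  cov_mat <- cov_mat[ord, , drop = FALSE]
  fam_split <- split(seq_len(nrow(cohort)), cohort$family_id)

  # pre-extract flat structures once; the per-family loop then only slices
  ymat <- as.matrix(cohort[traits])
  Xall <- cbind(intercept = 1, cov_mat)
  pid <- cohort$person_id
  rel_all <- cohort$relationship
  n_dropped <- 0L
  records <- lapply(names(fam_split), function(fid) {
    idx <- fam_split[[fid]]
    m <- length(idx)
    rel <- rel_all[idx]
    y <- ymat[idx, , drop = FALSE]
    dimnames(y) <- list(pid[idx], traits)
    X <- Xall[idx, , drop = FALSE]
    rownames(X) <- pid[idx]
    incomplete <- rowSums(is.na(X)) > 0
    if (any(incomplete)) {
      y[incomplete, ] <- NA_real_
      X[incomplete, ] <- 0  # inert rows; their phenotypes are all missing
      n_dropped <<- n_dropped + sum(incomplete)
    }
    is_mz <- rel == "MZ_twin"
    rA <- matrix(0.5, m, m)
    rA[is_mz, is_mz] <- 1
    diag(rA) <- 1
    rC <- matrix(1, m, m)
    structure(list(family_id = fid, person_id = pid[idx],
                   relationship = rel, y = y, X = X, rA = rA, rC = rC),
              class = "family_record")
  })
  if (n_dropped > 0L) {
    message(n_dropped, " member(s) with incomplete covariates had their ",
            "phenotypes dropped")
  }
  structure(records, class = "family_records",
            traits = traits, covariates = covariates,
            covariate_centers = centers, n_dropped_members = n_dropped)
}

#' Flatten family records back to an individual-wise table
#'
#' Inverse of [to_family_records()] (up to row order and covariate
#' centering, which is undone using the stored centers). Useful for
#' round-trip checks and diagnostics.
#'
#' @param records A `family_records` list.
#' @return Individual-wise data.frame with ids, covariates and traits.
#' @export
flatten_family_records <- function(records) {
  stopifnot(inherits(records, "family_records"))
  traits <- attr(records, "traits")
  covariates <- attr(records, "covariates")
  centers <- attr(records, "covariate_centers")
  rows <- lapply(records, function(r) {
    d <- data.frame(person_id = r$person_id, family_id = r$family_id,
                    relationship = r$relationship, stringsAsFactors = FALSE)
    for (cv in covariates) d[[cv]] <- r$X[, cv] + centers[[cv]]
    for (tr in traits) d[[tr]] <- r$y[, tr]
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
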