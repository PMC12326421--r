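# Shared fixtures and independent oracles for the test suite.
# Oracles here are deliberately written against the definitions, not the
# package's internal machinery (grouped sufficient statistics), so they can
# serve as cross-checks.

# Quick simulated cohort with one or two traits.
make_cohort <- function(n_mz = 50, n_dz = 50, n_single = 20, seed = 1,
                        traits = list(trait_spec("x", 0, 1, .5, .2, .3)),
                        cross = list(), extra_sibs = 0) {
  d <- cohort_design(n_mz, n_dz, n_single, n_extra_sibs = extra_sibs)
  coh <- generate_cohort(d, seed)
  simulate_phenotypes(coh, traits, cross, seed = seed + 1000L)
}

# Independent dense FIML -2lnL oracle: per family, assemble the stacked
# mean vector and covariance matrix directly (trait-major) and evaluate the
# multivariate normal density with solve()/determinant() on observed
# entries only.
dense_m2ll <- function(records, traits, betas, SigmaA, SigmaC, SigmaE) {
  Tn <- length(traits)
  total <- 0
  for (r in records) {
    m <- length(r$person_id)
    y <- as.vector(r$y[, traits, drop = FALSE])          # trait-major stack
    mu <- unlist(lapply(seq_len(Tn), function(t) {
      as.vector(r$X %*% betas[[t]])
    }))
    q_all <- m * Tn
    Sg <- matrix(0, q_all, q_all)
    for (k1 in seq_len(q_all)) {
      i1 <- ((k1 - 1) %% m) + 1; t1 <- ((k1 - 1) %/% m) + 1
      for (k2 in seq_len(q_all)) {
        i2 <- ((k2 - 1) %% m) + 1; t2 <- ((k2 - 1) %/% m) + 1
        Sg[k1, k2] <- r$rA[i1, i2] * SigmaA[t1, t2] +
          r$rC[i1, i2] * SigmaC[t1, t2] +
          (i1 == i2) * SigmaE[t1, t2]
      }
    }
    obs <- which(!is.na(y))
    if (!length(obs)) next
    yv <- y[obs] - mu[obs]
    So <- Sg[obs, obs, drop = FALSE]
    ld <- as.numeric(determinant(So, logarithm = TRUE)$modulus)
    total <- total + length(obs) * log(2 * pi) + ld +
      drop(t(yv) %*% solve(So, yv))
  }
  total
}

# Independent Benjamini-Hochberg step-up oracle (literal definition:
# q_(i) = min over j >= i of p_(j) * m / j, in sorted order).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Empirical intraclass covariance/correlation of co-twin pairs of one type.
pair_values <- function(cohort, trait, relationship) {
  twins <- cohort[cohort$relationship == relationship, ]
  sp <- split(twins[[trait]], twins$family_id)
  sp <- sp[vapply(sp, length, 0L) == 2L]
  t(vapply(sp, identity, numeric(2)))
}
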