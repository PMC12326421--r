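# Internal FIML machinery.
#
# Families are grouped by their observed-data pattern (member count,
# relatedness structure, and which member-trait cells are observed). Within
# a group every family shares the same model covariance matrix, so the
# -2 log-likelihood reduces to
#   n_g * (q_g log 2pi + log det Sigma_g) + sum_i r_i' Sigma_g^{-1} r_i
# and the residual quadratic form is a function of per-group sufficient
# statistics (crossproducts of phenotypes and covariate rows). Mean betas
# are profiled out by GLS at every evaluation, so each likelihood evaluation
# costs O(groups * q^2 * p^2) regardless of cohort size.
#
# Everything here works on an internally standardized scale (each trait
# centered/scaled by its pooled mean/SD, covariates likewise) for optimizer
# conditioning; fiml_prepare records the transforms needed to map results
# back to the original scale.

fiml_prepare <- function(records, traits) {
  stopifnot(inherits(records, "family_records"))
  all_traits <- attr(records, "traits")
  if (!all(traits %in% all_traits)) {
    stop("trait(s) not present in family records: ",
         paste(setdiff(traits, all_traits), collapse = ", "))
  }
  covariates <- attr(records, "covariates")
  Tn <- length(traits)
  p1 <- 1L + length(covariates)      # per-trait mean parameters
  p <- Tn * p1                       # stacked beta length

  # pooled standardization constants
  ymeans <- ysds <- numeric(Tn)
  for (t in seq_len(Tn)) {
    vals <- unlist(lapply(records, function(r) r$y[, traits[t]]))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 2L) stop("trait '", traits[t], "' has < 2 observed values")
    ymeans[t] <- mean(vals); ysds[t] <- sd(vals)
    if (ysds[t] == 0) stop("trait '", traits[t], "' is constant")
  }
  xscale <- rep(1, p1)               # intercept + covariates (already centered)
  if (length(covariates)) {
    for (k in seq_along(covariates)) {
      vals <- unlist(lapply(records, function(r) r$X[, covariates[k]]))
      s <- sd(vals)
      xscale[k + 1L] <- if (is.finite(s) && s > 0) s else 1
    }
  }

  n_obs_trait <- integer(Tn)

  # pass 1: per-record observed pattern, group key, standardized y and
  # stacked covariate rows (preallocated lists; no incremental growth)
  nr <- length(records)
  keys <- character(nr)
  yobs <- vector("list", nr)
  xobs <- vector("list", nr)
  meta <- new.env(parent = emptyenv())     # first-seen metadata per key
  for (i in seq_len(nr)) {
    r <- records[[i]]
    m <- dim(r$y)[1L]
    ystd <- r$y[, traits, drop = FALSE]
    for (t in seq_len(Tn)) {
      ystd[, t] <- (ystd[, t] - ymeans[t]) / ysds[t]
    }
    yvec <- as.vector(ystd)                 # trait-major: k = (t-1)*m + i
    obs <- which(!is.na(yvec))
    if (!length(obs)) next
    memb <- ((obs - 1L) %% m) + 1L
    trt <- ((obs - 1L) %/% m) + 1L
    n_obs_trait <- n_obs_trait + tabulate(trt, Tn)
    q <- length(obs)
    RAg <- r$rA[memb, memb, drop = FALSE]
    key <- paste(c(m, RAg, memb, trt), collapse = ",")
    if (is.null(meta[[key]])) {
      # linear index (kept as a plain vector: a 2-column matrix index
      # would be read as coordinate pairs) into a Tn x Tn component matrix
      ti_lin <- trt[rep(seq_len(q), q)] +
        (trt[rep(seq_len(q), each = q)] - 1L) * Tn
      meta[[key]] <- list(q = q, RAg = RAg,
                          RCg = r$rC[memb, memb, drop = FALSE],
                          Dg = outer(memb, memb, `==`) * 1,
                          ti_lin = ti_lin, memb = memb, trt = trt)
    }
    Xs <- r$X / rep(xscale, each = m)        # standardized covariate rows
    xrow <- matrix(0, q, p)
    for (j in seq_len(q)) {
      xrow[j, (trt[j] - 1L) * p1 + seq_len(p1)] <- Xs[memb[j], ]
    }
    keys[i] <- key
    yobs[[i]] <- yvec[obs]
    xobs[[i]] <- xrow
  }

  # pass 2: per group, assemble matrices and reduce to sufficient stats
  used <- which(nzchar(keys))
  glist <- lapply(split(used, keys[used]), function(idx) {
    g <- meta[[keys[[idx[1L]]]]]
    n <- length(idx)
    q <- g$q
    Y <- matrix(unlist(yobs[idx], use.names = FALSE), n, q, byrow = TRUE)
    S <- crossprod(Y)                              # sum_i y_i y_i'
    Xarr <- array(0, c(n, q, p))                   # covariate rows vary
    for (i in seq_len(n)) Xarr[i, , ] <- xobs[[idx[i]]]
    Tt <- array(0, c(q, q, p))
    Cc <- array(0, c(q, q, p, p))
    for (j in seq_len(q)) {
      Xj <- matrix(Xarr[, j, ], n, p)
      for (k2 in seq_len(q)) {
        Tt[j, k2, ] <- crossprod(Xj, Y[, k2])
        Cc[j, k2, , ] <- crossprod(Xj, matrix(Xarr[, k2, ], n, p))
      }
    }
    list(n = n, q = q, RAg = g$RAg, RCg = g$RCg, Dg = g$Dg,
         ti_lin = g$ti_lin, S = S, Tt = Tt, Cc = Cc)
  })
  names(glist) <- NULL

  n_obs_total <- sum(vapply(glist, function(g) g$n * g$q, 0))
  list(groups = glist, traits = traits, covariates = covariates,
       Tn = Tn, p1 = p1, p = p,
       ymeans = ymeans, ysds = ysds, xscale = xscale,
       n_obs_trait = n_obs_trait, n_obs_total = n_obs_total,
       n_families = length(records),
       # constant shifting standardized -2lnL to the original scale
       const_m2ll = 2 * sum(n_obs_trait * log(ysds)))
}

# -2 log-likelihood (standardized scale) with beta profiled out by GLS.
# SA, SC, SE: Tn x Tn component matrices on the standardized scale.
# Returns list(m2ll, beta) or +Inf-like penalty on non-PD covariance.
fiml_m2ll <- function(prep, SA, SC, SE, penalty = 1e10) {
  p <- prep$p
  if (!all(is.finite(SA)) || !all(is.finite(SC)) || !all(is.finite(SE))) {
    return(list(m2ll = 100 * penalty, beta = rep(NA_real_, p), ok = FALSE))
  }
  Atot <- matrix(0, p, p)
  btot <- numeric(p)
  c0 <- 0
  nld <- 0
  for (g in prep$groups) {
    Sg <- g$RAg * matrix(SA[g$ti_lin], g$q, g$q) +
      g$RCg * matrix(SC[g$ti_lin], g$q, g$q) +
      g$Dg * matrix(SE[g$ti_lin], g$q, g$q)
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch) || !all(is.finite(diag(ch))) || any(diag(ch) < 1e-10)) {
      return(list(m2ll = penalty + sum(SA^2) + sum(SC^2) + sum(SE^2),
                  beta = rep(NA_real_, p), ok = FALSE))
    }
    W <- chol2inv(ch)
    nld <- nld + g$n * (g$q * log(2 * pi) + 2 * sum(log(diag(ch))))
    c0 <- c0 + sum(W * g$S)
    for (j in seq_len(g$q)) {
      for (k in seq_len(g$q)) {
        w <- W[j, k]
        if (w != 0) {
          btot <- btot + w * g$Tt[j, k, ]
          Atot <- Atot + w * g$Cc[j, k, , ]
        }
      }
    }
  }
  beta <- tryCatch(solve(Atot, btot), error = function(e) NULL)
  if (is.null(beta)) {
    return(list(m2ll = penalty, beta = rep(NA_real_, p), ok = FALSE))
  }
  list(m2ll = nld + c0 - sum(btot * beta), beta = beta, ok = TRUE)
}

# Map standardized-scale betas back to the original scale for one trait.
# beta_std: (intercept, covariate slopes) on standardized y and X.
unstd_beta <- function(beta_std, ymean, ysd, xscale) {
  b <- beta_std * ysd / xscale
  b[1] <- ymean + ysd * beta_std[1]
  b
}

# -2lnL at a FIXED stacked beta (standardized scale); used for diagnostics
# and cross-checks against dense-matrix evaluation.
fiml_m2ll_fixed_beta <- function(prep, SA, SC, SE, beta) {
  total <- 0
  for (g in prep$groups) {
    Sg <- g$RAg * matrix(SA[g$ti_lin], g$q, g$q) +
      g$RCg * matrix(SC[g$ti_lin], g$q, g$q) +
      g$Dg * matrix(SE[g$ti_lin], g$q, g$q)
    ch <- chol(Sg)
    W <- chol2inv(ch)
    total <- total + g$n * (g$q * log(2 * pi) + 2 * sum(log(diag(ch))))
    for (j in seq_len(g$q)) {
      for (k in seq_len(g$q)) {
        w <- W[j, k]
        if (w != 0) {
          total <- total + w * (g$S[j, k] - 2 * sum(g$Tt[j, k, ] * beta) +
                                  drop(beta %*% g$Cc[j, k, , ] %*% beta))
        }
      }
    }
  }
  total
}

# Multi-start BFGS driver: run all starts at default tolerance, then polish
# the two best candidates tightly; returns best polished fit and the
# -2lnL agreement between the two best starts (convergence diagnostic).
multistart_optim <- function(obj, starts) {
  fits <- lapply(starts, function(st) {
    optim(st, obj, method = "BFGS", control = list(maxit = 500))
  })
  # polish every start: the squared-path parameterization has a vanishing
  # gradient at component boundaries, so a single start can stall there
  # with a deceptively good-looking objective value; ranking by polished
  # value keeps stalled candidates out of the agreement diagnostic
  polished <- lapply(fits, function(ft) {
    op <- ft
    # repeated restarts reset the Hessian approximation, which BFGS needs
    # to escape stalls along variance-component boundary ridges
    for (round in 1:4) {
      op2 <- optim(op$par, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12))
      improved <- op$value - op2$value
      if (op2$value <= op$value) op <- op2
      if (improved < 1e-9) break
    }
    op
  })
  pv <- vapply(polished, `[[`, 0, "value")
  best <- polished[[which.min(pv)]]
  list(best = best,
       spread = if (length(pv) > 1L) diff(sort(pv))[1L] else 0,
       codes = vapply(fits, `[[`, 0L, "convergence"))
}

# Central-difference gradient of f at x.
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    hi <- h * (1 + abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    (f(xp) - f(xm)) / (2 * hi)
  }, 0)
}

#' Expected phenotypic covariance matrix for one family
#'
#' Builds the model-implied covariance of a family's phenotype vector for a
#' single trait: `Sigma[i, j] = rA[i, j] * A + rC[i, j] * C + (i == j) * E`.
#'
#' @param components Named list or vector with elements `A`, `C`, `E`
#'   (trait-units squared, all `>= 0`).
#' @param rA,rC Relatedness coefficient matrices (see [to_family_records()]).
#' @return The m x m covariance matrix.
#' @export
expected_family_cov <- function(components, rA, rC) {
  A <- components[["A"]]; C <- components[["C"]]; E <- components[["E"]]
  stopifnot(A >= 0, C >= 0, E >= 0)
  stopifnot(is.matrix(rA), is.matrix(rC), all(dim(rA) == dim(rC)))
  rA * A + rC * C + diag(E, nrow(rA))
}

#' Log-likelihood contribution of one family record
#'
#' Multivariate-normal log density of a family's observed phenotypes for a
#' single trait, with mean `X beta` and covariance from
#' [expected_family_cov()]. Missing phenotypes are handled by marginalizing
#' to the observed members (full-information maximum likelihood); singleton
#' families contribute a univariate normal term. Parameter points with a
#' non-positive-definite covariance return `-Inf` (a rejected point), never
#' an error.
#'
#' @param params List with `beta` (mean coefficients matching the record's
#'   design matrix columns) and `A`, `C`, `E` variance components.
#' @param record A `family_record`.
#' @param trait Trait column name within the record.
#' @return The log-likelihood contribution (scalar; 0 for a family with no
#'   observed phenotypes).
#' @export
family_loglik <- function(params, record, trait) {
  stopifnot(inherits(record, "family_record"))
  y <- record$y[, trait]
  obs <- which(!is.na(y))
  if (!length(obs)) return(0)
  mu <- as.vector(record$X %*% params$beta)[obs]
  Sg <- expected_family_cov(params, record$rA, record$rC)[obs, obs, drop = FALSE]
  ch <- tryCatch(chol(Sg), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  r <- y[obs] - mu
  z <- backsolve(ch, r, transpose = TRUE)
  -0.5 * (length(obs) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}
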