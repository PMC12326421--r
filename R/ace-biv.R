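#' Fit a bivariate Cholesky ACE decomposition
#'
#' Decomposes the phenotypic covariance of a trait pair into additive
#' genetic, shared environmental and unique environmental components. Each
#' component covariance matrix is parameterized as `L %*% t(L)` with `L`
#' 2x2 lower-triangular (Cholesky parameterization), guaranteeing positive
#' semi-definiteness. The family likelihood stacks both traits for all
#' members (trait-major): within-person covariance is
#' `SigmaA + SigmaC + SigmaE`; cross-person blocks are
#' `rA * SigmaA + rC * SigmaC` (unique environment never crosses persons).
#' Mean coefficients per trait are profiled by GLS as in [fit_ace()].
#'
#' The first trait is the first Cholesky variable; loadings (but not the
#' derived `Sigma` matrices, correlations or covariance contributions)
#' depend on this order.
#'
#' @param records `family_records` containing both traits.
#' @param trait_x,trait_y Trait column names (x first in the Cholesky
#'   order; for brain-behavior pairs, the ROI conventionally comes first).
#' @param n_starts Number of fixed starting points (default 5).
#' @param fix_cross Optional component letter (`"A"`, `"C"` or `"E"`) whose
#'   cross-trait loading is fixed at 0 — used for covariance-path tests.
#' @return Object of class `biv_fit` with Cholesky `loadings` (La, Lc, Le,
#'   original trait units), component covariance matrices `SigmaA`,
#'   `SigmaC`, `SigmaE`, per-trait mean betas and variance proportions,
#'   `minus2lnL`, component correlations `rG`, `rC`, `rE` with
#'   defined/undefined flags, covariance contributions `pcorA`, `pcorC`,
#'   `pcorE`, the model phenotypic correlation `r_phenotypic`, and
#'   convergence diagnostics.
#' @export
fit_bivariate <- function(records, trait_x, trait_y, n_starts = 5,
                          fix_cross = NULL) {
  stopifnot(trait_x != trait_y)
  if (!is.null(fix_cross)) fix_cross <- match.arg(fix_cross, c("A", "C", "E"))
  prep <- fiml_prepare(records, c(trait_x, trait_y))

  # theta = lower-tri loadings (l11, l21, l22) for A, C, E in order;
  # cross loadings possibly fixed at zero
  free <- rep(TRUE, 9L)
  names(free) <- paste0(rep(c("a", "c", "e"), each = 3), c("11", "21", "22"))
  if (!is.null(fix_cross)) {
    free[match(fix_cross, c("A", "C", "E")) * 3L - 1L] <- FALSE
  }
  mk_sigma <- function(theta) {
    full <- numeric(9L)
    full[free] <- theta
    Ls <- lapply(0:2, function(i) {
      matrix(c(full[3 * i + 1], full[3 * i + 2], 0, full[3 * i + 3]), 2, 2)
    })
    lapply(Ls, function(L) L %*% t(L))
  }
  obj <- function(theta) {
    S <- mk_sigma(theta)
    fiml_m2ll(prep, S[[1]], S[[2]], S[[3]])$m2ll
  }

  splits <- list(c(1, 1, 1) / 3, c(.6, .1, .3), c(.1, .6, .3),
                 c(.05, .05, .9), c(.45, .45, .1))
  splits <- splits[seq_len(min(n_starts, length(splits)))]
  cross0 <- c(0, 0, 0, 0, 0.3 * sqrt(1 / 3))
  starts <- lapply(seq_along(splits), function(i) {
    sp <- splits[[i]]
    th <- numeric(9L)
    th[c(1, 4, 7)] <- sqrt(sp)   # diag loadings, trait 1
    th[c(3, 6, 9)] <- sqrt(sp)   # diag loadings, trait 2
    th[c(2, 5, 8)] <- cross0[i]  # cross loadings
    th[free]
  })
  ms <- multistart_optim(obj, starts)
  best <- ms$best
  spread <- ms$spread
  gr <- num_grad(obj, best$par)
  grad_norm <- max(abs(gr))

  S <- mk_sigma(best$par)
  res <- fiml_m2ll(prep, S[[1]], S[[2]], S[[3]])
  converged <- best$convergence == 0 && res$ok &&
    grad_norm < 1e-5 * max(1, abs(best$value)) && spread < 1e-4
  if (!res$ok) warning("bivariate fit did not reach a valid optimum")

  # back to original scale
  D <- diag(prep$ysds)
  full <- numeric(9L); full[free] <- best$par
  Ls_std <- lapply(0:2, function(i) {
    L <- matrix(c(full[3 * i + 1], full[3 * i + 2], 0, full[3 * i + 3]), 2, 2)
    # sign convention: non-negative diagonal
    if (L[1, 1] < 0) L[, 1] <- -L[, 1]
    if (L[2, 2] < 0) L[, 2] <- -L[, 2]
    L
  })
  loadings <- lapply(Ls_std, function(L) D %*% L)
  Sigma <- lapply(loadings, function(L) {
    M <- L %*% t(L)
    dimnames(M) <- list(c(trait_x, trait_y), c(trait_x, trait_y))
    M
  })
  names(loadings) <- names(Sigma) <- c("A", "C", "E")

  Vtot <- Sigma$A + Sigma$C + Sigma$E
  v <- diag(Vtot)
  props <- rbind(A = diag(Sigma$A) / v, C = diag(Sigma$C) / v,
                 E = diag(Sigma$E) / v)
  colnames(props) <- c(trait_x, trait_y)
  comp_cor <- lapply(Sigma, function(M) genetic_correlation(M))
  pcor <- vapply(Sigma, function(M) unname(M[1, 2] / sqrt(v[1] * v[2])), 0)
  r_ph <- unname(Vtot[1, 2] / sqrt(v[1] * v[2]))

  p1 <- prep$p1
  betas <- lapply(1:2, function(t) {
    b <- unstd_beta(res$beta[(t - 1) * p1 + seq_len(p1)],
                    prep$ymeans[t], prep$ysds[t], prep$xscale)
    names(b) <- c("intercept", prep$covariates)
    b
  })
  names(betas) <- c(trait_x, trait_y)

  structure(list(
    trait_x = trait_x, trait_y = trait_y,
    loadings = list(La = loadings$A, Lc = loadings$C, Le = loadings$E),
    SigmaA = Sigma$A, SigmaC = Sigma$C, SigmaE = Sigma$E,
    proportions = props, mean_betas = betas,
    minus2lnL = best$value + prep$const_m2ll,
    n_params = sum(free) + prep$p,
    rG = comp_cor$A$r, rG_defined = comp_cor$A$defined,
    rC = comp_cor$C$r, rC_defined = comp_cor$C$defined,
    rE = comp_cor$E$r, rE_defined = comp_cor$E$defined,
    pcorA = pcor[["A"]], pcorC = pcor[["C"]], pcorE = pcor[["E"]],
    r_phenotypic = r_ph,
    fixed_cross = fix_cross,
    n_families = prep$n_families, n_obs = prep$n_obs_total,
    covariates = prep$covariates,
    convergence = list(converged = converged, grad_norm = grad_norm,
                       start_spread = spread, optim_codes = ms$codes),
    internal = list(prep = prep, theta = best$par, free = free,
                    m2ll_std = best$value)
  ), class = "biv_fit")
}

#' @export
print.biv_fit <- function(x, ...) {
  cat("Bivariate Cholesky ACE fit:", x$trait_x, "~", x$trait_y, "\n")
  fmt_r <- function(r, def) if (def) sprintf("%.3f", r) else "undefined"
  cat(sprintf("  rG = %s, rC = %s, rE = %s\n",
              fmt_r(x$rG, x$rG_defined), fmt_r(x$rC, x$rC_defined),
              fmt_r(x$rE, x$rE_defined)))
  cat(sprintf("  contributions to r_ph = %.3f: A %.3f, C %.3f, E %.3f\n",
              x$r_phenotypic, x$pcorA, x$pcorC, x$pcorE))
  cat(sprintf("  -2lnL = %.4f over %d families\n", x$minus2lnL, x$n_families))
  if (!x$convergence$converged) cat("  WARNING: convergence not verified\n")
  invisible(x)
}

#' Component correlation from a 2x2 component covariance matrix
#'
#' Standardizes an off-diagonal component covariance:
#' `r = Sigma[1,2] / sqrt(Sigma[1,1] * Sigma[2,2])`. When either diagonal
#' variance is essentially zero (< `min_var`) the correlation is flagged as
#' undefined rather than returned as a spurious +/-1 or NaN — correlations
#' computed from vanishing proportional variances are uninformative.
#'
#' @param Sigma 2x2 component covariance matrix (diagonal must be >= 0).
#' @param min_var Threshold below which a diagonal variance counts as zero.
#' @return List with `r` (NA when undefined) and logical `defined`.
#' @export
genetic_correlation <- function(Sigma, min_var = 1e-12) {
  stopifnot(is.matrix(Sigma), all(dim(Sigma) == 2L))
  if (any(diag(Sigma) < 0)) stop("negative diagonal component variance")
  # scale-free threshold: relative to the matrix magnitude when nonzero
  scale <- max(abs(Sigma), 1)
  if (any(diag(Sigma) < min_var * scale)) {
    return(list(r = NA_real_, defined = FALSE))
  }
  list(r = Sigma[1, 2] / sqrt(Sigma[1, 1] * Sigma[2, 2]), defined = TRUE)
}

#' Contribution of one component to the phenotypic correlation
#'
#' `pcor = sqrt(prop_x) * r * sqrt(prop_y)` where `prop` is the component's
#' proportion of each trait's variance (e.g. the heritabilities for the
#' additive genetic contribution) and `r` the component correlation. The
#' three component contributions sum to the model phenotypic correlation.
#' The value is not bounded to `[0, 1]` and is deliberately not clipped.
#'
#' @param prop_x,prop_y Variance proportions in `[0, 1]`.
#' @param r Component correlation.
#' @return Numeric contribution to the phenotypic correlation.
#' @export
pcor_contrib <- function(prop_x, prop_y, r) {
  if (any(c(prop_x, prop_y) < 0) || any(c(prop_x, prop_y) > 1)) {
    stop("variance proportions must lie in [0, 1]")
  }
  sqrt(prop_x) * r * sqrt(prop_y)
}

#' Significance test for one covariance path
#'
#' Refits the bivariate Cholesky model with the named component's
#' cross-trait loading fixed at 0 and compares -2 log-likelihoods. Cross
#' loadings are interior (sign-free) parameters, so the deviance is
#' referred to a plain chi-square(1) — no boundary mixture.
#'
#' @param fit A full `biv_fit` (no fixed cross path).
#' @param records The `family_records` the fit was computed from.
#' @param component `"A"`, `"C"` or `"E"`.
#' @return An `ace_test` with `name` = component.
#' @export
test_cov_path <- function(fit, records, component = c("A", "C", "E")) {
  stopifnot(inherits(fit, "biv_fit"))
  component <- match.arg(component)
  if (!is.null(fit$fixed_cross)) {
    stop("fit already has a fixed cross path (", fit$fixed_cross, ")")
  }
  reduced <- fit_bivariate(records, fit$trait_x, fit$trait_y,
                           fix_cross = component)
  T_ <- reduced$minus2lnL - fit$minus2lnL
  if (T_ < -1e-6) {
    stop("reduced model fits better than full by ", format(-T_),
         "; likely non-convergence")
  }
  T_ <- max(0, T_)
  structure(list(name = component, deviance = T_, df_dropped = 1L,
                 p_value = if (T_ <= 0) 1 else pchisq(T_, 1, lower.tail = FALSE),
                 q_value = NA_real_),
            class = "ace_test")
}
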