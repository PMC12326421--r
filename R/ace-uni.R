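#' Fit a univariate ACE model by full-information maximum likelihood
#'
#' Decomposes the phenotypic variance of one trait into additive genetic
#' (A), shared environmental (C) and unique environmental (E) components
#' using all family records (MZ/DZ twin pairs, siblings and singletons).
#' The model is parameterized through path coefficients whose squares are
#' the variance components, so A, C, E >= 0 without constrained
#' optimization and the zero boundary is exactly reachable. Mean
#' coefficients (intercept plus covariates present in the records) are
#' profiled out by generalized least squares at every likelihood
#' evaluation. Optimization uses quasi-Newton BFGS from several fixed
#' starting splits of the phenotypic variance; the best -2 log-likelihood
#' is kept and convergence requires agreement of the two best starts
#' (within 1e-4) plus a small scaled gradient norm.
#'
#' @param records `family_records` from [to_family_records()]; the
#'   covariates used in the mean model are those the records were built
#'   with.
#' @param trait Trait column name.
#' @param model One of `"ACE"`, `"AE"`, `"CE"`, `"E"`; dropped components
#'   are fixed at exactly 0.
#' @param n_starts Number of starting values (default 5).
#' @return An object of class `ace_fit`: variance components `A`, `C`, `E`,
#'   `V` (trait units squared), proportions `a2`, `c2`, `e2`, mean
#'   coefficients `mean_betas` (original scale), `minus2lnL`, `n_params`,
#'   sample sizes, and a `convergence` list.
#' @export
fit_ace <- function(records, trait, model = c("ACE", "AE", "CE", "E"),
                    n_starts = 5) {
  model <- match.arg(model)
  prep <- fiml_prepare(records, trait)
  n_pairs <- sum(vapply(prep$groups, function(g) {
    if (g$q >= 2 && any(g$RAg[upper.tri(g$RAg)] > 0)) g$n else 0L
  }, 0L))
  if (model %in% c("ACE", "AE", "CE") && n_pairs < 2L) {
    warning("fewer than 2 informative relative pairs; A and C are weakly ",
            "identified")
  }
  free <- switch(model,
                 ACE = c(TRUE, TRUE, TRUE),
                 AE = c(TRUE, FALSE, TRUE),
                 CE = c(FALSE, TRUE, TRUE),
                 E = c(FALSE, FALSE, TRUE))
  names(free) <- c("a", "c", "e")

  obj <- function(theta) {
    paths <- numeric(3)
    paths[free] <- theta
    fiml_m2ll(prep,
              SA = matrix(paths[1]^2), SC = matrix(paths[2]^2),
              SE = matrix(paths[3]^2))$m2ll
  }

  # fixed variance splits (proportions of the standardized variance ~ 1)
  splits <- list(c(1, 1, 1) / 3, c(.6, .1, .3), c(.1, .6, .3),
                 c(.05, .05, .9), c(.45, .45, .1))
  splits <- splits[seq_len(min(n_starts, length(splits)))]
  starts <- lapply(splits, function(sp) {
    sp[!free] <- 0
    sp <- sp / sum(sp)
    sqrt(sp)[free]
  })
  ms <- multistart_optim(obj, starts)
  best <- ms$best
  spread <- ms$spread

  theta <- best$par
  gr <- num_grad(obj, theta)
  grad_norm <- max(abs(gr))
  res <- local({
    paths <- numeric(3); paths[free] <- theta
    fiml_m2ll(prep, matrix(paths[1]^2), matrix(paths[2]^2),
              matrix(paths[3]^2))
  })
  converged <- best$convergence == 0 && res$ok &&
    grad_norm < 1e-5 * max(1, abs(best$value)) && spread < 1e-4
  if (!res$ok) {
    warning("ACE fit for '", trait, "' did not reach a valid optimum")
  }

  paths <- numeric(3); paths[free] <- abs(theta)  # sign convention
  s2 <- prep$ysds[1]^2
  A <- paths[1]^2 * s2; C <- paths[2]^2 * s2; E <- paths[3]^2 * s2
  V <- A + C + E
  beta <- unstd_beta(res$beta, prep$ymeans[1], prep$ysds[1], prep$xscale)
  names(beta) <- c("intercept", prep$covariates)

  structure(list(
    trait = trait, model = model,
    A = A, C = C, E = E, V = V,
    a2 = A / V, c2 = C / V, e2 = E / V,
    mean_betas = beta,
    minus2lnL = best$value + prep$const_m2ll,
    n_params = sum(free) + prep$p,
    n_families = prep$n_families, n_obs = prep$n_obs_total,
    covariates = prep$covariates,
    convergence = list(converged = converged, grad_norm = grad_norm,
                       start_spread = spread, optim_codes = ms$codes),
    internal = list(prep = prep, free = free, theta = theta,
                    m2ll_std = best$value)
  ), class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("Univariate %s fit for '%s' (FIML)\n", x$model, x$trait))
  cat(sprintf("  components: A = %.4g, C = %.4g, E = %.4g (V = %.4g)\n",
              x$A, x$C, x$E, x$V))
  cat(sprintf("  proportions: a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
              x$a2, x$c2, x$e2))
  cat(sprintf("  -2lnL = %.4f over %d families (%d observations)\n",
              x$minus2lnL, x$n_families, x$n_obs))
  if (!x$convergence$converged) cat("  WARNING: convergence not verified\n")
  invisible(x)
}

#' Standardized variance proportions
#'
#' Divides variance components by the total phenotypic variance
#' `V = A + C + E`; the heritability `a2` is `A / V`.
#'
#' @param x An `ace_fit`, or a named list/vector with `A`, `C`, `E`.
#' @return Named numeric vector `c(a2, c2, e2)` summing to 1.
#' @export
standardize <- function(x) UseMethod("standardize")

#' @export
standardize.ace_fit <- function(x) c(a2 = x$a2, c2 = x$c2, e2 = x$e2)

#' @export
standardize.default <- function(x) {
  A <- x[["A"]]; C <- x[["C"]]; E <- x[["E"]]
  stopifnot(A >= 0, C >= 0, E >= 0)
  V <- A + C + E
  if (V <= 0) stop("total variance V must be > 0")
  c(a2 = A / V, c2 = C / V, e2 = E / V)
}

#' Likelihood-ratio test of nested ACE submodels
#'
#' Compares a full model to a nested submodel obtained by dropping A and/or
#' C. Because variance components sit on the boundary of the parameter
#' space under the null, the deviance follows a mixture of chi-square
#' distributions rather than a single chi-square: with one component
#' dropped, a 50:50 mixture of a point mass at 0 and chi-square(1); with
#' both A and C dropped, a (1/4, 1/2, 1/4) mixture of {0, chi-square(1),
#' chi-square(2)}.
#'
#' @param full,reduced `ace_fit` objects for the same trait and covariates;
#'   `reduced$model` must be nested in `full$model`.
#' @return Object of class `ace_test`: `name` (`"A"`, `"C"` or `"AC"`),
#'   `deviance`, `df_dropped`, `p_value` (and `q_value = NA`, filled by FDR
#'   adjustment across a test family).
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "ace_fit"), inherits(reduced, "ace_fit"))
  if (!identical(full$trait, reduced$trait) ||
      !identical(full$covariates, reduced$covariates)) {
    stop("fits are for different traits or covariate sets")
  }
  comp <- function(m) strsplit(sub("E$", "", m), "")[[1]]
  dropped <- setdiff(comp(full$model), comp(reduced$model))
  if (!length(dropped) || length(setdiff(comp(reduced$model),
                                         comp(full$model)))) {
    stop("'", reduced$model, "' is not nested in '", full$model, "'")
  }
  T_ <- reduced$minus2lnL - full$minus2lnL
  if (T_ < -1e-6) {
    stop("reduced model fits better than full by ", format(-T_),
         "; likely non-convergence")
  }
  T_ <- max(0, T_)
  k <- length(dropped)
  p <- if (T_ <= 0) 1 else if (k == 1L) {
    0.5 * pchisq(T_, 1, lower.tail = FALSE)
  } else {
    0.5 * pchisq(T_, 1, lower.tail = FALSE) +
      0.25 * pchisq(T_, 2, lower.tail = FALSE)
  }
  structure(list(name = paste(sort(dropped), collapse = ""),
                 deviance = T_, df_dropped = k, p_value = p,
                 q_value = NA_real_),
            class = "ace_test")
}

#' @export
print.ace_test <- function(x, ...) {
  cat(sprintf("LRT for %s: deviance = %.4f (df dropped = %d), p = %.4g\n",
              x$name, x$deviance, x$df_dropped, x$p_value))
  invisible(x)
}
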