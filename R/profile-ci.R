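#' Profile-likelihood confidence interval for a variance quantity
#'
#' Likelihood-based confidence bounds: a bound is the extreme value of the
#' quantity at which the re-optimized (profiled) -2 log-likelihood exceeds
#' the unconstrained minimum by the chi-square(1) critical value (3.841 at
#' the default 95% level). The constraint value is searched by bisection
#' with re-optimization of all free parameters at each step; bounds that
#' run into the edge of the parameter space are reported as the edge
#' (0, or 1 for proportions).
#'
#' @param fit A converged `ace_fit` (model `"ACE"`, `"AE"` or `"CE"`).
#' @param quantity One of `"a2"`, `"c2"`, `"e2"` (proportions) or `"A"`,
#'   `"C"`, `"E"` (unstandardized components, trait units squared).
#' @param level Confidence level (default 0.95).
#' @param tol Bisection tolerance on the quantity scale (default 1e-3;
#'   for unstandardized components the tolerance is scaled by the total
#'   variance).
#' @return Object of class `profile_ci`: `quantity`, `lower`, `upper`,
#'   `level`, `point` and a `trusted` flag (FALSE when a constrained
#'   optimization failed, so the affected bound should not be relied on).
#' @export
profile_ci <- function(fit, quantity = c("a2", "c2", "e2", "A", "C", "E"),
                       level = 0.95, tol = 1e-3) {
  stopifnot(inherits(fit, "ace_fit"))
  quantity <- match.arg(quantity)
  prep <- fit$internal$prep
  free <- fit$internal$free
  crit <- qchisq(level, 1)
  s2 <- prep$ysds[1]^2
  is_prop <- quantity %in% c("a2", "c2", "e2")
  k <- match(tolower(substr(quantity, 1, 1)), c("a", "c", "e"))
  if (!free[k]) stop("component ", quantity, " is fixed at 0 in model ",
                     fit$model)

  other <- setdiff(which(free), k)
  trusted <- TRUE
  m2ll_min <- fit$internal$m2ll_std

  if (is_prop) {
    point <- c(fit$a2, fit$c2, fit$e2)[k]
    V0 <- fit$V / s2
    # free parameters: log total variance, plus a split of the remaining
    # proportion when two other components are free
    constrained <- function(s, start) {
      objc <- function(par) {
        V <- exp(par[1])
        props <- numeric(3)
        props[k] <- s
        if (length(other) == 2L) {
          w <- plogis(par[2])
          props[other] <- (1 - s) * c(w, 1 - w)
        } else if (length(other) == 1L) {
          props[other] <- 1 - s
        }
        fiml_m2ll(prep, matrix(props[1] * V), matrix(props[2] * V),
                  matrix(props[3] * V))$m2ll
      }
      optim(start, objc, method = "BFGS",
            control = list(maxit = 300, reltol = 1e-10))
    }
    start0 <- local({
      w0 <- if (length(other) == 2L) {
        pr <- c(fit$a2, fit$c2, fit$e2)[other]
        qlogis(min(max(pr[1] / max(sum(pr), 1e-8), 1e-6), 1 - 1e-6))
      } else NULL
      c(log(max(V0, 1e-8)), w0)
    })
    edge_lo <- 0; edge_hi <- 1
  } else {
    point <- c(A = fit$A, C = fit$C, E = fit$E)[[substr(quantity, 1, 1)]]
    tol <- tol * max(fit$V, 1)
    constrained <- function(s, start) {
      s_std <- s / s2
      objc <- function(par) {
        paths <- numeric(3)
        paths[k] <- sqrt(max(s_std, 0))
        paths[other] <- par
        fiml_m2ll(prep, matrix(paths[1]^2), matrix(paths[2]^2),
                  matrix(paths[3]^2))$m2ll
      }
      optim(start, objc, method = "BFGS",
            control = list(maxit = 300, reltol = 1e-10))
    }
    start0 <- sqrt(pmax(c(fit$A, fit$C, fit$E)[other] / s2, 1e-6))
    edge_lo <- 0; edge_hi <- Inf
  }

  warm <- new.env(parent = emptyenv())
  warm$par <- start0
  # every constrained re-optimization runs from several starts (the warm
  # continuation solution, the unconstrained solution, and neutral splits):
  # a warm start inherited from a near-singular region, or a single poor
  # start, can otherwise trap BFGS in a spurious local solution and
  # collapse the bound onto the point estimate
  extra_starts <- if (is_prop) {
    if (length(other) == 2L) list(c(start0[1], 0), c(0, 0)) else list(0)
  } else {
    list(rep(sqrt(max(fit$V / s2, 1e-6) / 3), length(other)))
  }
  f <- function(s) {
    ops <- lapply(c(list(warm$par, start0), extra_starts),
                  function(st) constrained(s, st))
    op <- ops[[which.min(vapply(ops, `[[`, 0, "value"))]]
    if (op$convergence != 0 && op$value > 1e6) trusted <<- FALSE
    if (op$value < 1e6) warm$par <- op$par
    if (op$value < m2ll_min) m2ll_min <<- op$value
    op$value - (fit$internal$m2ll_std + crit)
  }

  bisect <- function(a, b, fa, fb) {
    # f(a) > 0 >= f(b); shrink to tol
    while (abs(b - a) > tol) {
      mid <- (a + b) / 2
      if (f(mid) > 0) a <- mid else b <- mid
    }
    (a + b) / 2
  }

  # lower bound
  lower <- if (point - edge_lo <= tol) edge_lo else {
    fl <- f(edge_lo)
    if (fl <= 0) edge_lo else bisect(edge_lo, point, fl, -crit)
  }
  # upper bound
  warm$par <- start0
  upper <- if (is_prop) {
    hi <- edge_hi - 1e-9
    if (hi - point <= tol) edge_hi else {
      fh <- f(hi)
      if (fh <= 0) edge_hi else bisect(hi, point, fh, -crit)
    }
  } else {
    step <- max(point, fit$V, 1e-6)
    hi <- point + step; n_try <- 0L
    fh <- f(hi)
    while (fh <= 0 && n_try < 40L) {
      step <- step * 2; hi <- point + step; n_try <- n_try + 1L
      fh <- f(hi)
    }
    if (fh <= 0) { trusted <- FALSE; Inf } else bisect(hi, point, fh, -crit)
  }

  structure(list(quantity = quantity, lower = min(lower, point),
                 upper = max(upper, point), level = level,
                 point = point, trusted = trusted),
            class = "profile_ci")
}

#' @export
print.profile_ci <- function(x, ...) {
  cat(sprintf("%g%% profile-likelihood CI for %s: %.4g [%.4g, %.4g]%s\n",
              100 * x$level, x$quantity, x$point, x$lower, x$upper,
              if (x$trusted) "" else " (untrusted)"))
  invisible(x)
}
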