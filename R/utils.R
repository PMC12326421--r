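# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive named child seeds from one root seed (all < 2^31).
derive_seeds <- function(seed, streams) {
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, length(streams))
    names(s) <- streams
    s
  })
}

# Truncated normal via inverse-CDF (exact, deterministic draw count).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(mean, n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Symmetric square root of a PSD correlation matrix; tolerant of exact
# rank deficiency (e.g. a cross-trait correlation of 1).
psd_sqrt <- function(R, tol = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -tol) {
    stop("matrix is not positive semi-definite (min eigenvalue ",
         format(min(e$values)), ")")
  }
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
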