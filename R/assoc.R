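#' Pairwise-complete Pearson correlation matrix
#'
#' Symmetric correlation matrix with unit diagonal over the requested
#' variables, using pairwise-complete observations. Cells with fewer than 3
#' complete pairs are an error; variables that are constant on the analyzed
#' pairs yield flagged `NA` cells (never a silent 0), listed in attribute
#' `flagged`.
#'
#' @param table Data.frame of individual-wise observations.
#' @param variables Character vector of column names (>= 2).
#' @return Correlation matrix with attribute `flagged` (character matrix of
#'   undefined cells, possibly empty).
#' @export
correlation_matrix <- function(table, variables) {
  stopifnot(is.data.frame(table), length(variables) >= 2L)
  missing_cols <- setdiff(variables, names(table))
  if (length(missing_cols)) {
    stop("unknown variable(s): ", paste(missing_cols, collapse = ", "))
  }
  M <- as.matrix(table[variables])
  k <- length(variables)
  R <- diag(k)
  dimnames(R) <- list(variables, variables)
  flagged <- character(0)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- !is.na(M[, i]) & !is.na(M[, j])
      if (sum(ok) < 3L) {
        stop("fewer than 3 complete pairs for (", variables[i], ", ",
             variables[j], ")")
      }
      if (sd(M[ok, i]) == 0 || sd(M[ok, j]) == 0) {
        R[i, j] <- R[j, i] <- NA_real_
        flagged <- c(flagged, paste(variables[i], variables[j], sep = ":"))
      } else {
        R[i, j] <- R[j, i] <- cor(M[ok, i], M[ok, j])
      }
    }
  }
  if (length(flagged)) {
    warning("undefined correlation cells (constant variable): ",
            paste(flagged, collapse = ", "))
  }
  attr(R, "flagged") <- flagged
  R
}

#' Deterministic average-linkage ordering of correlated variables
#'
#' Orders variables by agglomerative average-linkage (UPGMA) clustering on
#' the distance `1 - r`, for cosmetic reordering of correlation heatmaps.
#' The implementation is deliberately minimal and fully deterministic:
#' candidate merges are scanned in current list order and ties are broken
#' by the first pair encountered, so an identity correlation matrix
#' preserves the input order and perfectly correlated variables end up
#' adjacent.
#'
#' @param corr Correlation matrix with dimnames.
#' @return Character vector: the variable labels in clustered order.
#' @export
cluster_order <- function(corr) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  labels <- rownames(corr) %||% as.character(seq_len(nrow(corr)))
  n <- nrow(corr)
  if (n <= 2L) return(labels)
  d <- 1 - corr
  clusters <- as.list(seq_len(n))
  while (length(clusters) > 1L) {
    best <- NULL; best_d <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best_d - 1e-12) {   # strict improvement => first-pair ties
          best_d <- avg; best <- c(i, j)
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels[clusters[[1]]]
}

#' Covariate-adjusted brain-behavior association
#'
#' Ordinary linear regression of a behavioral score on an ROI volume with
#' covariates (default age, sex and total brain volume), on complete cases.
#' Twin non-independence is deliberately ignored at this phenotypic stage
#' (the genetic stages model it). Reported effect sizes: the standardized
#' slope `beta_std = b * sd(roi) / sd(behavior)` (computed on the analyzed
#' subsample) and the sign-consistent partial correlation
#' `r_partial = sign(t) * sqrt(t^2 / (t^2 + df))`. Two-sided p from the
#' slope's t statistic.
#'
#' @param table Individual-wise data.frame.
#' @param roi,behavior Column names.
#' @param covariates Character vector of covariate columns (may be empty).
#' @return One-row data.frame (class `assoc_result`): `roi`, `behavior`,
#'   `n`, `beta_std`, `r_partial`, `p_value`, `q_value` (NA until FDR
#'   adjustment).
#' @export
fit_brain_behavior <- function(table, roi, behavior,
                               covariates = c("age", "sex", "tbv")) {
  vars <- c(behavior, roi, covariates)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols)) {
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  }
  d <- table[vars]
  d <- d[complete.cases(d), , drop = FALSE]
  p <- 1L + length(covariates)
  if (nrow(d) < p + 2L) {
    stop("need at least ", p + 2L, " complete cases, got ", nrow(d))
  }
  X <- as.matrix(cbind(1, d[, c(roi, covariates), drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fml <- reformulate(sprintf("`%s`", c(roi, covariates)),
                     response = sprintf("`%s`", behavior))
  fit <- lm(fml, data = d)
  sm <- summary(fit)$coefficients
  b <- sm[2L, "Estimate"]; se <- sm[2L, "Std. Error"]
  df <- fit$df.residual
  tval <- if (se > 0) b / se else sign(b) * Inf
  p_value <- if (is.finite(tval)) 2 * pt(abs(tval), df, lower.tail = FALSE) else 0
  r_partial <- if (is.finite(tval)) {
    sign(tval) * sqrt(tval^2 / (tval^2 + df))
  } else sign(b)
  out <- data.frame(roi = roi, behavior = behavior, n = nrow(d),
                    beta_std = b * sd(d[[roi]]) / sd(d[[behavior]]),
                    r_partial = r_partial, p_value = p_value,
                    q_value = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values for one named correction family (the default
#' policy adjusts each analysis family separately; passing all p-values of
#' a study at once gives the stricter global correction).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (no NAs).
#' @param family Optional label recorded as attribute `family`.
#' @return Vector of q-values, same length/order as `p_values`.
#' @export
fdr_adjust <- function(p_values, family = NULL) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must be numeric in [0, 1] with no missing values")
  }
  q <- p.adjust(p_values, method = "BH")
  if (!is.null(family)) attr(q, "family") <- family
  q
}

#' Enumerate the study's hypothesis-test ledger
#'
#' Derives the number of hypothesis tests per analysis family purely from a
#' configuration: phenotypic brain-behavior regressions (ROI x behavior),
#' univariate variance-component tests for behavioral measures
#' (behavior x test), univariate tests for ROI measures
#' (ROI x test x covariate variant) and bivariate covariance-path tests
#' (ROI x behavior x component).
#'
#' @param config List with elements `rois_phenotypic`, `behaviors`,
#'   `rois_univariate`, `univariate_tests` (default `c("A","C","AC")`),
#'   `tbv_variants` (default `c(FALSE, TRUE)`), `rois_bivariate`,
#'   `bivariate_components` (default `c("A","C","E")`). Each element may be
#'   a character vector of labels or a count. Missing elements count 0.
#' @return Object of class `test_ledger`: data.frame of family counts with
#'   a `total` attribute.
#' @seealso [replication_ledger_config()] for the published configuration.
#' @export
build_ledger <- function(config) {
  n_of <- function(x) if (is.null(x)) 0L else if (is.numeric(x)) {
    as.integer(x)
  } else length(x)
  n_beh <- n_of(config$behaviors)
  counts <- c(
    phenotypic = n_of(config$rois_phenotypic) * n_beh,
    behavioral_univariate =
      n_beh * n_of(config$univariate_tests %||% c("A", "C", "AC")),
    roi_univariate = n_of(config$rois_univariate) *
      n_of(config$univariate_tests %||% c("A", "C", "AC")) *
      n_of(config$tbv_variants %||% c(FALSE, TRUE)),
    bivariate = n_of(config$rois_bivariate) * n_beh *
      n_of(config$bivariate_components %||% c("A", "C", "E"))
  )
  # families with no configured members contribute zero rows, not errors
  ledger <- data.frame(family = names(counts), count = as.integer(counts),
                       stringsAsFactors = FALSE)
  structure(ledger, class = c("test_ledger", "data.frame"),
            total = sum(counts))
}

#' @export
print.test_ledger <- function(x, ...) {
  print.data.frame(x)
  cat("total:", attr(x, "total"), "tests\n")
  invisible(x)
}

#' Replication ledger configuration
#'
#' The configuration reproducing the published test ledger: 1305 tests in
#' four correction families (288 phenotypic = 32 x 9; 27 behavioral
#' univariate = 9 x 3; 180 ROI univariate = 30 x 3 x 2; 810 bivariate =
#' 30 x 9 x 3). The phenotypic stage used 32 ROI series (the 30 tabled
#' measures plus left/right whole-cerebellum aggregates), while the genetic
#' stages modeled the 30 tabled measures; both lists are explicit here.
#'
#' @return A config list for [build_ledger()].
#' @export
replication_ledger_config <- function() {
  cal <- hcp_calibration()
  rois30 <- cal$roi$measure
  list(
    rois_phenotypic = c(rois30, "left_cerebellum_total",
                        "right_cerebellum_total"),
    behaviors = cal$behavior$measure,
    rois_univariate = rois30,
    univariate_tests = c("A", "C", "AC"),
    tbv_variants = c(FALSE, TRUE),
    rois_bivariate = rois30,
    bivariate_components = c("A", "C", "E")
  )
}
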