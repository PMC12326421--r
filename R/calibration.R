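#' Published HCP calibration values
#'
#' Loads the calibration tables shipped with the package: demographic
#' composition of the HCP S1200 extended-twin sample, published means/SDs
#' for the nine behavioral measures and thirty cerebellar ROI volumes, their
#' univariate ACE variance proportions (with and without a total-brain-volume
#' covariate for ROIs), and headline cross-trait correlations. These values
#' parameterize the synthetic-data generator so recovery experiments can be
#' run without access to the restricted individual-level data.
#'
#' @return A list with elements `design` (named numeric vector), `behavior`
#'   and `roi` (data.frames) and `results` (named numeric vector).
#' @export
hcp_calibration <- function() {
  path <- function(f) system.file("extdata", f, package = "twinvolve",
                                  mustWork = TRUE)
  kv <- function(f) {
    d <- utils::read.csv(path(f), stringsAsFactors = FALSE)
    stats::setNames(d$value, d$key)
  }
  list(design = kv("hcp_design.csv"),
       behavior = utils::read.csv(path("hcp_behavior.csv"),
                                  stringsAsFactors = FALSE),
       roi = utils::read.csv(path("hcp_roi.csv"), stringsAsFactors = FALSE),
       results = kv("hcp_results.csv"))
}

#' Cohort design matching the HCP calibration sample
#'
#' @param scale Multiplier applied to all family counts (rounded), keeping
#'   the MZ/DZ/singleton mix proportional; `scale = 1` gives the published
#'   121/67/556 composition (N = 932).
#' @return A [cohort_design()].
#' @export
calibration_design <- function(scale = 1) {
  d <- hcp_calibration()$design
  cohort_design(n_mz_pairs = round(d[["n_mz_pairs"]] * scale),
                n_dz_pairs = round(d[["n_dz_pairs"]] * scale),
                n_singletons = round(d[["n_singletons"]] * scale),
                sex_ratio = d[["sex_ratio"]],
                age_mean = d[["age_mean"]], age_sd = d[["age_sd"]])
}

#' Generating trait specification from the calibration tables
#'
#' Builds a [trait_spec()] whose mean/SD come from the published summary
#' tables and whose generating proportions are the published ACE estimates.
#' Printed proportions are rounded to two decimals and do not always sum
#' exactly to 1; the generating model keeps `a2` and `c2` as printed and sets
#' `e2 = 1 - a2 - c2`, so the sum-to-1 invariant holds exactly while the
#' recovery targets keep their printed values.
#'
#' @param measure Measure name as it appears in the calibration tables
#'   (e.g. `"left_cerebellum_cortex"`, `"cog_crystallized"`).
#' @param variant For ROI measures, which published model to use:
#'   `"no_tbv"` (default) or `"tbv"` (estimates adjusted for total brain
#'   volume). Ignored for behavioral measures.
#' @param missing_rate Optional MAR rate passed through to [trait_spec()].
#' @return A [trait_spec()].
#' @export
calibration_trait <- function(measure, variant = c("no_tbv", "tbv"),
                              missing_rate = 0) {
  variant <- match.arg(variant)
  cal <- hcp_calibration()
  if (measure %in% cal$behavior$measure) {
    row <- cal$behavior[cal$behavior$measure == measure, ]
    a2 <- row$a2; c2 <- row$c2
  } else if (measure %in% cal$roi$measure) {
    row <- cal$roi[cal$roi$measure == measure, ]
    if (variant == "no_tbv") {
      a2 <- row$a2_notbv; c2 <- row$c2_notbv
    } else {
      a2 <- row$a2_tbv; c2 <- row$c2_tbv
    }
  } else {
    stop("unknown calibration measure: ", measure)
  }
  trait_spec(measure, mean = row$mean, total_sd = row$sd,
             a2 = a2, c2 = c2, e2 = 1 - a2 - c2,
             missing_rate = missing_rate)
}
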