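#' Published development scalability statistics of the brief CSI-D
#'
#' The Mokken analysis summary published for the development of the brief
#' CSI-D scales on the 10/66 population surveys: per item and per scale, the
#' sample size, item difficulty, observed and expected Guttman error counts,
#' Loevinger H and z statistic. Whole-scale rows carry
#' `item_id = "whole_scale"`. These printed counts are the inputs for the
#' arithmetic-identity checks (`H = 1 - F/E`; pair counts halving to the
#' whole-scale count).
#'
#' @return A data frame with columns `scale`, `item_id`, `label`, `n`,
#'   `difficulty`, `observed_errors`, `expected_errors`, `H`, `z`.
#' @export
csid_development_stats <- function() {
  utils::read.csv(system.file("extdata", "csid_development_scalability.csv",
                              package = "mokkenscreen"),
                  stringsAsFactors = FALSE)
}

#' Published validation performance of the brief CSI-D
#'
#' The region-wise validity summary published for the brief CSI-D scales:
#' AUROC with 95\% CI, the optimal cutpoint(s), sensitivity and specificity
#' in percent, and Youden's index, for the informant, cognitive and combined
#' scales across the pilot regions and the Cuban population sample. The one
#' cell whose printed Youden value is inconsistent with its own sensitivity
#' and specificity (a probable misprint) is flagged.
#'
#' @return A data frame with columns `scale`, `region`, `auroc`, `ci_low`,
#'   `ci_high`, `cutpoint`, `sensitivity`, `specificity`, `youden`,
#'   `flagged_misprint`.
#' @export
csid_validation_stats <- function() {
  utils::read.csv(system.file("extdata", "csid_validation_performance.csv",
                              package = "mokkenscreen"),
                  stringsAsFactors = FALSE)
}
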