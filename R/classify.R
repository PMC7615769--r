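# Reporting conventions: direction / dominance / relevance classification
# of countries from posterior probabilities, and country counts with
# rounded percentages.

#' Classify the direction of change
#'
#' `increase` if the posterior probability of an increase is at least the
#' threshold, `decrease` if the decrease probability is, otherwise
#' `indeterminate`.  Thresholds are inclusive ("at least 0.80").
#'
#' @param p_increase,p_decrease posterior probabilities (vectors allowed;
#'   pairs must sum to at most 1)
#' @param threshold inclusive decision threshold
#' @return character vector in {increase, decrease, indeterminate}
#' @export
classify_direction <- function(p_increase, p_decrease, threshold = 0.80) {
  if (any(p_increase + p_decrease > 1 + 1e-12)) {
    stop_dbm("p_increase + p_decrease must not exceed 1")
  }
  if (any(p_increase >= threshold & p_decrease >= threshold)) {
    stop_dbm("both directions meet the threshold: impossible input")
  }
  ifelse(p_increase >= threshold, "increase",
         ifelse(p_decrease >= threshold, "decrease", "indeterminate"))
}

#' Flag changes that are relevant in size and certainty
#'
#' TRUE iff the absolute change exceeds two percentage points (strict,
#' "more than") and the posterior probability meets the threshold
#' (inclusive, "at least").
#'
#' @param delta change in percentage points
#' @param p posterior probability of the change's direction
#' @param threshold probability threshold
#' @param min_pp percentage-point cutoff
#' @return logical vector
#' @export
classify_relevant_change <- function(delta, p, threshold = 0.80,
                                     min_pp = 2.0) {
  abs(delta) > min_pp & p >= threshold
}

#' Classify dominance of the double burden
#'
#' `obesity-dominant` if P(obese > low) meets the threshold,
#' `low-dominant` if P(low > obese) does, otherwise `indistinguishable`.
#'
#' @param p_obese_gt,p_low_gt the two one-sided posterior probabilities
#' @param threshold inclusive decision threshold
#' @return character vector
#' @export
classify_dominance <- function(p_obese_gt, p_low_gt, threshold = 0.80) {
  if (any(p_obese_gt + p_low_gt > 1 + 1e-12)) {
    stop_dbm("one-sided probabilities must sum to at most 1")
  }
  ifelse(p_obese_gt >= threshold, "obesity-dominant",
         ifelse(p_low_gt >= threshold, "low-dominant", "indistinguishable"))
}

#' Count countries and express as a rounded percentage
#'
#' The percentage uses the full estimation set as denominator and
#' half-away-from-zero rounding to an integer (11 of 200 prints as 6%,
#' 89 of 200 as 45%).
#'
#' @param flags per-country logical flags (NA counts as FALSE)
#' @param total denominator (the full estimation set)
#' @return list with `count` and `percent`
#' @export
count_countries <- function(flags, total = length(flags)) {
  if (total < 1) stop_dbm("total must be at least 1")
  count <- sum(flags, na.rm = TRUE)
  list(count = count,
       percent = round_half_away(100 * count / total))
}
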