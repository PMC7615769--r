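#' Logit and inverse-logit
#'
#' Standard log-odds transform and its inverse, used throughout: the model
#' operates on logit prevalence, reporting happens on the probability scale.
#'
#' @param p probabilities in (0, 1)
#' @param x real numbers
#' @return numeric vector
#' @export
logit <- function(p) log(p / (1 - p))

#' @rdname logit
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves going away from zero
#' (5.5 -> 6, -5.5 -> -6), the convention used when printing country counts
#' as percentages.  Base R's `round()` uses banker's rounding, which would
#' print 5.5% as 5% and contradict the reporting convention.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return numeric vector
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quantile type 7 (linear interpolation between order statistics), fixed for
# reproducibility of all credible intervals
cri_quantile <- function(x, probs = c(0.025, 0.975)) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = TRUE)
}

stop_dbm <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
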