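# Independent oracles and small fixture builders used across the tests.

# Cox-de Boor recursion for B-spline basis functions, coded independently
# of splines::splineDesign
cox_de_boor <- function(x, knots, i, d) {
  if (d == 0) {
    return(as.numeric(knots[i] <= x & x < knots[i + 1]))
  }
  a <- 0
  if (knots[i + d] != knots[i]) {
    a <- (x - knots[i]) / (knots[i + d] - knots[i]) *
      cox_de_boor(x, knots, i, d - 1)
  }
  b <- 0
  if (knots[i + d + 1] != knots[i + 1]) {
    b <- (knots[i + d + 1] - x) / (knots[i + d + 1] - knots[i + 1]) *
      cox_de_boor(x, knots, i + 1, d - 1)
  }
  a + b
}

oracle_bspline_row <- function(x, lo, hi, interior) {
  kn <- c(rep(lo, 4), sort(interior), rep(hi, 4))
  k <- length(kn) - 4
  vapply(seq_len(k), function(i) cox_de_boor(x, kn, i, 3), 0)
}

# brute-force weighted sum for age-standardisation
oracle_age_standardise <- function(prev, weights) {
  sum(prev * weights) / sum(weights)
}

# textbook Pearson correlation
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# a tiny valid study table
tiny_studies <- function() {
  study_table(data.frame(
    study_id = c("s1", "s1", "s2"),
    country = c("AAA", "AAA", "BBB"),
    region = c("east", "east", "west"),
    mid_year = c(2000L, 2000L, 2010L),
    sex = c("female", "female", "male"),
    age_lo = c(20L, 25L, 20L),
    age_hi = c(25L, 30L, 25L),
    coverage = c("national", "national", "community"),
    urbanisation = c("mixed", "mixed", "rural"),
    n_sample = c(500L, 500L, 120L),
    prev_low = c(0.12, 0.10, 0.30),
    prev_obese = c(0.08, 0.09, 0.02),
    stringsAsFactors = FALSE
  ), window = c(1990, 2022))
}

tiny_hierarchy <- function() {
  region_hierarchy(data.frame(country = c("AAA", "BBB"),
                              region = c("east", "west")))
}

# posterior_draws container from a plain matrix with year cells
pd_series <- function(mat, years) {
  posterior_draws(mat, data.frame(year = years), check = FALSE)
}

# one-observation intercept-only context for conjugate oracles
conjugate_setup <- function(y = 1, v = 0.25, ...) {
  tobs <- data.frame(
    study_id = "s1", country = "AAA", region = "r", mid_year = 2000L,
    sex = "female", age_lo = 20L, age_hi = 25L, coverage = "national",
    urbanisation = "mixed", n_sample = 100L, category = "low",
    y = y, v = v)
  hier <- region_hierarchy(data.frame(country = "AAA", region = "r"))
  spec <- model_spec(
    years = 2000, age_grid = data.frame(age_lo = 20, age_hi = 25,
                                        age_mid = 22.5),
    components = "intercept", fix_variances = TRUE, ...)
  list(ctx = build_model_context(tobs, hier, spec), spec = spec,
       hier = hier, tobs = tobs)
}
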