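make_pd <- function(draws, countries = "AAA", years = 2000,
                    sexes = "female", ages = c(20, 25), category = "low") {
  cells <- expand.grid(age_lo = ages, year = years, sex = sexes,
                       country = countries, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  cells$age_hi <- cells$age_lo + 5
  cells$category <- category
  posterior_draws(draws, cells[c("country", "year", "sex", "age_lo",
                                 "age_hi", "category")], check = FALSE)
}

test_that("age standardisation: constants, two bands, and brute force", {
  std <- age_standard(data.frame(age_lo = c(20, 25), age_hi = c(25, 30),
                                 weight = c(0.5, 0.5)))
  pd <- make_pd(matrix(0.2, 5, 2))
  out <- age_standardise(pd, std)
  expect_equal(as.vector(out$draws), rep(0.2, 5))

  pd2 <- make_pd(matrix(c(0.2, 0.4), 1, 2, byrow = TRUE))
  expect_equal(as.vector(age_standardise(pd2, std)$draws), 0.3)

  # brute-force oracle on a random fixture with unequal weights
  set.seed(8)
  std3 <- age_standard(data.frame(age_lo = c(20, 25, 30),
                                  age_hi = c(25, 30, 35),
                                  weight = c(0.5, 0.3, 0.2)))
  draws <- matrix(stats::runif(60), 20, 3)
  pd3 <- make_pd(draws, ages = c(20, 25, 30))
  out3 <- age_standardise(pd3, std3)
  for (d in 1:20) {
    expect_equal(out3$draws[d, 1],
                 oracle_age_standardise(draws[d, ], c(0.5, 0.3, 0.2)),
                 tolerance = 1e-12)
  }
  # uncovered bands are reported
  pd4 <- make_pd(draws, ages = c(20, 25, 40))
  expect_error(age_standardise(pd4, std3), "40")
})

test_that("combined prevalence sums draws elementwise", {
  low <- make_pd(matrix(c(0.1, 0.0), 1, 2), category = "low")
  ob <- make_pd(matrix(c(0.2, 0.33), 1, 2), category = "obese")
  out <- combined_prevalence(low, ob)
  expect_equal(as.vector(out$draws), c(0.3, 0.33))
  expect_equal(unique(out$cells$category), "combined")
  # misaligned cells error
  ob_bad <- make_pd(matrix(0.2, 1, 2), ages = c(30, 35),
                    category = "obese")
  expect_error(combined_prevalence(low, ob_bad), "misaligned")
})

test_that("summed-draw CrIs differ from naive summed CrIs when draws are
           anticorrelated", {
  # corr = -1: x + y is constant, so the CrI of the sum has zero width
  x <- seq(0.1, 0.3, length.out = 101)
  low <- make_pd(cbind(x), ages = 20, category = "low")
  ob <- make_pd(cbind(0.4 - x), ages = 20, category = "obese")
  comb <- combined_prevalence(low, ob)
  s <- summarise_draws(comb)
  expect_equal(s$lo, s$hi)             # draw-level: degenerate interval
  naive_lo <- cri_lo <- unname(stats::quantile(x, 0.025, type = 7)) +
    unname(stats::quantile(0.4 - x, 0.025, type = 7))
  expect_gt(s$lo, naive_lo)            # naive sum of CrIs is wider
})

test_that("obesity share handles edge cases and matches brute force", {
  low <- make_pd(cbind(c(0, 0.2, 0, 0.25)), ages = 20)
  ob <- make_pd(cbind(c(0.3, 0.2, 0, 0.05)), ages = 20,
                category = "obese")
  out <- obesity_share(low, ob)
  expect_equal(as.vector(out$draws), c(1.0, 0.5, NA, 0.05 / 0.3))
  set.seed(3)
  lw <- matrix(stats::runif(40, 0.01, 0.4), 20, 2)
  obm <- matrix(stats::runif(40, 0.01, 0.4), 20, 2)
  o2 <- obesity_share(make_pd(lw, ages = c(20, 25)),
                      make_pd(obm, ages = c(20, 25), category = "obese"))
  expect_equal(as.vector(o2$draws), as.vector(obm / (lw + obm)),
               tolerance = 1e-12)
})

test_that("posterior probabilities count draws exactly", {
  t1 <- make_pd(cbind(c(0.3, 0.5, 0.6, 0.2)), ages = 20, years = 2020)
  t0 <- make_pd(cbind(c(0.4, 0.1, 0.1, 0.1)), ages = 20, years = 2000)
  pr <- posterior_prob_increase(t1, t0)
  expect_equal(pr$p_increase, 0.75)
  expect_equal(pr$p_decrease, 0.25)
  # ties count to neither; the three probabilities always sum to 1
  t1b <- make_pd(cbind(c(0.3, 0.3, 0.5)), ages = 20, years = 2020)
  t0b <- make_pd(cbind(c(0.3, 0.2, 0.6)), ages = 20, years = 2000)
  prb <- posterior_prob_increase(t1b, t0b)
  p_tie <- mean(t1b$draws == t0b$draws)
  expect_equal(prb$p_increase + prb$p_decrease + p_tie, 1)
  # brute force over many simulated draws
  set.seed(5)
  a <- stats::runif(10000); b <- stats::runif(10000)
  pr2 <- posterior_prob_increase(
    make_pd(cbind(a), ages = 20, years = 2020),
    make_pd(cbind(b), ages = 20, years = 2000))
  expect_equal(pr2$p_increase, sum(a > b) / 10000, tolerance = 1e-12)
  expect_error(posterior_prob_increase(
    make_pd(matrix(0, 0, 1), ages = 20),
    make_pd(matrix(0, 0, 1), ages = 20)), "zero draws")
})

test_that("dominance probabilities are one-sided and exclude ties", {
  ob <- make_pd(cbind(c(0.5, 0.4, 0.3)), ages = 20, category = "obese")
  low <- make_pd(cbind(c(0.1, 0.2, 0.3)), ages = 20)
  dm <- posterior_prob_dominance(ob, low)
  expect_equal(dm$p_obese_gt, 2 / 3)
  expect_equal(dm$p_low_gt, 0)
  same <- posterior_prob_dominance(ob, make_pd(ob$draws, ages = 20))
  expect_equal(same$p_obese_gt, 0)
  expect_equal(same$p_low_gt, 0)
  set.seed(6)
  a <- stats::runif(5000); b <- stats::runif(5000)
  dm2 <- posterior_prob_dominance(make_pd(cbind(a), ages = 20,
                                          category = "obese"),
                                  make_pd(cbind(b), ages = 20))
  expect_equal(dm2$p_obese_gt, mean(a > b), tolerance = 1e-12)
  expect_lte(dm2$p_obese_gt + dm2$p_low_gt, 1)
})

test_that("persons affected multiplies and aggregates per draw", {
  pd <- make_pd(matrix(0.1, 3, 2))
  pop <- population_table(data.frame(
    country = "AAA", year = 2000, sex = "female",
    age_lo = c(20, 25), age_hi = c(25, 30), persons = c(1000, 500)))
  pa <- persons_affected(pd, pop, by = c("country", "year"))
  expect_equal(as.vector(pa$draws), rep(150, 3))
  pd0 <- make_pd(matrix(0, 3, 2))
  expect_equal(as.vector(persons_affected(pd0, pop,
                                          by = "year")$draws), rep(0, 3))
  # additivity: global total equals the sum of country totals per draw
  set.seed(7)
  pd2 <- make_pd(matrix(stats::runif(12, 0, 0.5), 3, 4),
                 countries = c("AAA", "BBB"))
  pop2 <- population_table(data.frame(
    country = rep(c("AAA", "BBB"), each = 2), year = 2000,
    sex = "female", age_lo = c(20, 25, 20, 25),
    age_hi = c(25, 30, 25, 30), persons = c(1000, 500, 800, 900)))
  per_country <- persons_affected(pd2, pop2, by = c("country", "year"))
  global <- persons_affected(pd2, pop2, by = "year")
  expect_equal(rowSums(per_country$draws), as.vector(global$draws),
               tolerance = 1e-10)
  # missing population cell errors
  pop3 <- pop2[pop2$country == "AAA", ]
  expect_error(persons_affected(pd2, population_table(pop3), by = "year"),
               "missing population")
})

test_that("cross-country correlation is computed per draw", {
  cells5 <- data.frame(country = paste0("C", 1:5))
  x <- matrix(stats::runif(10), 2, 5)
  px <- posterior_draws(x, cells5, check = FALSE)
  py <- posterior_draws(2 * x, cells5, check = FALSE)
  r <- correlate_across_countries(px, py)
  expect_equal(unname(r$mean), 1, tolerance = 1e-12)
  # hand example on 5 countries, single draw
  xv <- c(0.1, 0.3, 0.2, 0.5, 0.4)
  yv <- c(0.9, 0.2, 0.4, 0.1, 0.3)
  rh <- correlate_across_countries(
    posterior_draws(matrix(xv, 1), cells5, check = FALSE),
    posterior_draws(matrix(yv, 1), cells5, check = FALSE))
  expect_equal(unname(rh$mean), oracle_pearson(xv, yv), tolerance = 1e-12)
  # independence: 200 countries, mean r near 0
  set.seed(9)
  cells200 <- data.frame(country = sprintf("C%03d", 1:200))
  xi <- matrix(stats::runif(200 * 50), 50, 200)
  yi <- matrix(stats::runif(200 * 50), 50, 200)
  ri <- correlate_across_countries(
    posterior_draws(xi, cells200, check = FALSE),
    posterior_draws(yi, cells200, check = FALSE))
  expect_lt(abs(ri$mean), 0.15)
  # zero-variance draws are marked indeterminate
  xz <- xi; xz[1, ] <- 0.5
  rz <- correlate_across_countries(
    posterior_draws(xz, cells200, check = FALSE),
    posterior_draws(yi, cells200, check = FALSE))
  expect_equal(rz$n_indeterminate, 1L)
  expect_error(correlate_across_countries(
    posterior_draws(matrix(1, 1, 2), data.frame(country = c("A", "B")),
                    check = FALSE),
    posterior_draws(matrix(1, 1, 2), data.frame(country = c("A", "B")),
                    check = FALSE)), "3 countries")
})

test_that("crossover year is read off the integer grid per draw", {
  years <- 2000:2020
  base_a <- seq(0.1, 0.3, length.out = 21)   # rising
  base_b <- rep(0.2, 21)                     # flat: crossing at index 12
  a <- pd_series(matrix(base_a, 3, 21, byrow = TRUE), years)
  b <- pd_series(matrix(base_b, 3, 21, byrow = TRUE), years)
  out <- crossover_year(a, b)
  expect_equal(out$median, years[12])
  expect_equal(out$frac_no_cross, 0)
  expect_false(out$already_crossed)
  # no draw crosses
  out2 <- crossover_year(pd_series(matrix(0.1, 2, 21), years),
                         pd_series(matrix(0.5, 2, 21), years))
  expect_equal(out2$frac_no_cross, 1)
  expect_true(is.na(out2$median))
  # already crossed at the grid start in most draws
  out3 <- crossover_year(pd_series(matrix(0.5, 2, 21), years),
                         pd_series(matrix(0.1, 2, 21), years))
  expect_true(out3$already_crossed)
})

test_that("standardise and sum commute exactly", {
  std <- age_standard(data.frame(age_lo = c(20, 25), age_hi = c(25, 30),
                                 weight = c(0.7, 0.3)))
  set.seed(10)
  lw <- matrix(stats::runif(20, 0, 0.4), 10, 2)
  ob <- matrix(stats::runif(20, 0, 0.4), 10, 2)
  low <- make_pd(lw); obese <- make_pd(ob, category = "obese")
  path1 <- combined_prevalence(age_standardise(low, std),
                               age_standardise(obese, std))
  path2 <- age_standardise(combined_prevalence(low, obese), std)
  expect_equal(path1$draws, path2$draws, tolerance = 1e-14)
})

test_that("summaries are percentiles of the transformed draws", {
  set.seed(11)
  x <- matrix(stats::runif(400), 100, 4)
  pd <- make_pd(x, ages = c(20, 25, 30, 35))
  s <- summarise_draws(pd)
  for (j in 1:4) {
    expect_equal(s$lo[j], unname(stats::quantile(x[, j], 0.025, type = 7)))
    expect_equal(s$hi[j], unname(stats::quantile(x[, j], 0.975, type = 7)))
    expect_true(s$lo[j] <= s$mean[j] && s$mean[j] <= s$hi[j])
  }
})
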