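zero_config <- function(...) {
  surface_config(
    baseline_logit = c(low = -2.197, obese = -2.197),
    trend_logit = c(low = 0, obese = 0),
    intercept_scale = c(global = 0, region = 0, country = 0),
    slope_scale = c(global = 0, region = 0, country = 0),
    rw2_scale = c(global = 0, region = 0, country = 0),
    age_scale = c(global = 0, region = 0, country = 0),
    ...)
}

test_that("all effect scales zero gives a constant surface", {
  s <- sample_true_surface(zero_config(), seed = 7)
  expect_equal(as.vector(s$prev), rep(1 / (1 + exp(2.197)),
                                      length(s$prev)), tolerance = 1e-12)
  expect_equal(unname(s$prev[1, 1, 1, 1, 1]), 0.1, tolerance = 2e-3)
})

test_that("zero RW2 innovation scale gives exactly linear logit trends", {
  cfg <- surface_config(rw2_scale = c(global = 0, region = 0, country = 0))
  s <- sample_true_surface(cfg, seed = 3)
  for (cc in c(1, 5)) {
    for (cat in 1:2) {
      lt <- s$logit[cc, , 1, 1, cat]
      expect_equal(unname(diff(lt, differences = 2)),
                   rep(0, length(lt) - 2), tolerance = 1e-10)
    }
  }
})

test_that("country intercept deviations match the configured scale", {
  # Monte-Carlo oracle: 200 countries in one region, all else switched off
  cfg <- zero_config(regions = 1, countries_per_region = 200)
  cfg$intercept_scale["country"] <- 0.25
  s <- sample_true_surface(cfg, seed = 11)
  dev <- s$params[["low.female"]]$ac
  expect_equal(length(dev), 200)
  expect_lt(abs(stats::sd(dev) - 0.25) / 0.25, 0.15)
})

test_that("surface generation is deterministic and seed-sensitive", {
  cfg <- surface_config()
  s1 <- sample_true_surface(cfg, seed = 5)
  s2 <- sample_true_surface(cfg, seed = 5)
  s3 <- sample_true_surface(cfg, seed = 6)
  expect_identical(s1$prev, s2$prev)
  expect_false(identical(s1$prev, s3$prev))
})

test_that("short year ranges are rejected (RW2 undefined)", {
  expect_error(sample_true_surface(surface_config(years = 2000:2001), 1),
               "RW2")
})

test_that("exact mode reproduces the surface verbatim", {
  cfg <- surface_config(regions = 1, countries_per_region = 2,
                        years = 2000:2004)
  s <- sample_true_surface(cfg, seed = 2)
  tab <- simulate_studies(s, design_config(studies_per_country = 1,
                                           exact = TRUE), seed = 9)
  for (i in seq_len(nrow(tab))) {
    tr <- s$prev[tab$country[i], as.character(tab$mid_year[i]),
                 tab$sex[i], as.character(tab$age_lo[i]), "low"]
    expect_equal(tab$prev_low[i], unname(tr), tolerance = 1e-12)
  }
})

test_that("community offset is recovered by a Monte-Carlo average", {
  # 2000 community studies vs national truth at a fixed cell
  cfg <- suppressWarnings(zero_config(regions = 1, countries_per_region = 1,
                                      years = 2000:2002))
  s <- sample_true_surface(cfg, seed = 4)
  design <- design_config(
    studies_per_country = 2000,
    coverage_mix = c(national = 0, subnational = 0, community = 1),
    urban_mix = c(urban = 0, rural = 0, mixed = 1),
    offsets = c(subnational = 0.2, community = -0.3),
    study_sd = c(national = 0, subnational = 0, community = 0),
    n_range = c(4000, 4000), bands_per_study = 1)
  tab <- simulate_studies(s, design, seed = 13)
  sub <- tab[!is.na(tab$prev_low) & tab$prev_low > 0 & tab$prev_low < 1, ]
  lo <- log(sub$prev_low / (1 - sub$prev_low))
  true_logit <- -2.197
  expect_lt(abs(mean(lo) - true_logit - (-0.3)), 0.05)
})

test_that("study simulation is deterministic under a fixed seed", {
  cfg <- surface_config(regions = 2, countries_per_region = 2,
                        years = 2005:2010)
  s <- sample_true_surface(cfg, seed = 1)
  d <- design_config(studies_per_country = 3)
  t1 <- simulate_studies(s, d, seed = 21)
  t2 <- simulate_studies(s, d, seed = 21)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("generated tables satisfy the category-sum constraint", {
  for (sc in c("smoke", "recovery")) {
    fx <- make_fixture(sc, 3, withr::local_tempdir())
    psum <- ifelse(is.na(fx$studies$prev_low), 0, fx$studies$prev_low) +
      ifelse(is.na(fx$studies$prev_obese), 0, fx$studies$prev_obese)
    expect_true(all(psum <= 1))
    expect_true(all(apply(fx$surface$prev, 1:4, sum) <= 1))
  }
})

test_that("smoke fixture is small and reads back valid", {
  dir <- withr::local_tempdir()
  fx <- make_fixture("smoke", 1, dir)
  tab <- read_study_table(fx$paths$studies,
                          window = range(fx$configs$surface$years))
  expect_lte(nrow(tab), 200)
  expect_equal(nrow(validate_studies(tab)), 0)
  expect_true(all(file.exists(unlist(fx$paths))))
})

test_that("shrinkage fixture has a zero-study country", {
  fx <- make_fixture("shrinkage", 1, withr::local_tempdir())
  with_data <- unique(fx$studies$country)
  all_countries <- sort(unique(read_hierarchy(fx$paths$hierarchy)$country))
  expect_equal(setdiff(all_countries, with_data), "A01")
})

test_that("crossover truth year matches brute force on the written files", {
  dir <- withr::local_tempdir()
  fx <- make_fixture("crossover", 1, dir)
  truth <- utils::read.csv(fx$paths$truth_surface)
  pop <- read_population(fx$paths$population)
  std <- read_age_standard(fx$paths$age_standard)
  years <- sort(unique(truth$year))
  glob <- sapply(c("low", "obese"), function(cat) {
    sapply(years, function(yr) {
      num <- 0; den <- 0
      for (ct in unique(truth$country)) {
        for (sx in unique(truth$sex)) {
          tt <- truth[truth$year == yr & truth$category == cat &
                        truth$country == ct & truth$sex == sx, ]
          w <- std$weight[match(tt$age_lo, std$age_lo)]
          p_as <- sum(tt$prevalence * w) / sum(w)
          persons <- sum(pop$persons[pop$year == yr & pop$country == ct &
                                       pop$sex == sx])
          num <- num + p_as * persons
          den <- den + persons
        }
      }
      num / den
    })
  })
  cross <- years[min(which(glob[, "obese"] > glob[, "low"]))]
  expect_equal(fx$truth$crossover_year, cross)
})

test_that("unknown scenarios are rejected", {
  expect_error(make_fixture("nope", 1, withr::local_tempdir()), "unknown")
})
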