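# Named fixture scenarios: complete file sets (studies, hierarchy, age
# standard, population, truth) for smoke tests and recovery experiments.
#
# Seed streaming: each scenario has a fixed offset added to the master
# seed (smoke 100, shrinkage 200, crossover 300, recovery 400); within a
# scenario the surface uses offset+0, the studies offset+1, and the
# population offset+2, so adding scenarios never perturbs existing ones.

FIXTURE_SCENARIOS <- c("smoke", "shrinkage", "crossover", "recovery")
FIXTURE_OFFSET <- c(smoke = 100L, shrinkage = 200L, crossover = 300L,
                    recovery = 400L)

fixture_configs <- function(scenario) {
  switch(scenario,
    smoke = list(
      surface = surface_config(regions = 2, countries_per_region = 2,
                               years = 2012:2020),
      design = design_config(studies_per_country = 2, bands_per_study = 3,
                             n_range = c(500, 1500))
    ),
    shrinkage = list(
      surface = surface_config(regions = 2, countries_per_region = 4),
      design = local({
        cfg <- surface_config(regions = 2, countries_per_region = 4)
        spc <- stats::setNames(rep(8L, 8), country_codes(cfg))
        spc[1] <- 0L  # the borrowing test's zero-data country
        design_config(studies_per_country = spc)
      })
    ),
    crossover = list(
      surface = surface_config(regions = 2, countries_per_region = 3,
                               baseline_logit = c(low = -1.4, obese = -2.0),
                               trend_logit = c(low = -0.5, obese = 1.0),
                               intercept_scale = c(global = 0.1,
                                                   region = 0.25,
                                                   country = 0.15),
                               age_scale = c(global = 0.3, region = 0.1,
                                             country = 0.05)),
      design = design_config(studies_per_country = 8)
    ),
    recovery = list(
      surface = surface_config(),
      design = design_config(studies_per_country = 8,
                             coverage_mix = c(national = 0.4,
                                              subnational = 0.25,
                                              community = 0.35))
    ),
    stop_dbm("unknown scenario '%s' (known: %s)", scenario,
             paste(FIXTURE_SCENARIOS, collapse = ", "))
  )
}

# deterministic synthetic population: country sizes spread over two orders
# of magnitude, WHO-like age structure, mild growth over time
simulate_population <- function(config, seed) {
  set.seed(seed)
  countries <- country_codes(config)
  base <- exp(stats::rnorm(length(countries), log(2e6), 1))
  std <- who_age_standard(
    if (config$age_grid$age_lo[1] >= 20) "adult" else "school")
  grid <- config$age_grid
  wt <- std$weight[match(grid$age_lo, std$age_lo)]
  out <- expand.grid(age_lo = grid$age_lo, sex = config$sexes,
                     year = config$years, country = countries,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$age_hi <- grid$age_hi[match(out$age_lo, grid$age_lo)]
  growth <- 1.01^(out$year - min(config$years))
  out$persons <- round(base[match(out$country, countries)] *
                         wt[match(out$age_lo, grid$age_lo)] * 0.5 * growth)
  population_table(out[c("country", "year", "sex", "age_lo", "age_hi",
                         "persons")])
}

# brute-force global age-standardised prevalence per category and year
# from a truth surface: population-weighted country mean of the
# age-standardised, sex-averaged surface
global_truth_series <- function(surface, pop, standard) {
  config <- surface$config
  grid <- config$age_grid
  wt <- standard$weight[match(grid$age_lo, standard$age_lo)]
  wt <- wt / sum(wt)
  out <- list()
  for (cat in config$categories) {
    vals <- numeric(length(config$years))
    for (ti in seq_along(config$years)) {
      num <- 0; den <- 0
      for (cc in seq_along(surface$countries)) {
        for (sx in config$sexes) {
          p_as <- sum(surface$prev[cc, ti, match(sx, config$sexes), ,
                                   match(cat, config$categories)] * wt)
          persons <- sum(pop$persons[pop$country == surface$countries[cc] &
                                       pop$year == config$years[ti] &
                                       pop$sex == sx])
          num <- num + p_as * persons
          den <- den + persons
        }
      }
      vals[ti] <- num / den
    }
    out[[cat]] <- vals
  }
  out
}

truth_surface_df <- function(surface) {
  config <- surface$config
  grid <- expand.grid(
    country = surface$countries, year = config$years,
    sex = config$sexes, age_lo = config$age_grid$age_lo,
    category = config$categories,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$age_hi <- config$age_grid$age_hi[match(grid$age_lo,
                                              config$age_grid$age_lo)]
  grid$prevalence <- as.vector(surface$prev)
  grid[c("country", "year", "sex", "age_lo", "age_hi", "category",
         "prevalence")]
}

#' Write a named fixture scenario
#'
#' Generates a latent surface, a study table, a hierarchy, the age
#' standard, a population table and the truth files for one of the
#' documented scenarios (`smoke`, `shrinkage`, `crossover`, `recovery`)
#' and writes them as CSV/JSON under `out_dir`.  The `crossover` scenario
#' embeds (and records) the year at which global obesity prevalence
#' overtakes the low-BMI category on the truth surface.  Every fixture is
#' checked for the category-sum constraint prev_low + prev_obese <= 1.
#'
#' @param scenario one of `"smoke"`, `"shrinkage"`, `"crossover"`,
#'   `"recovery"`
#' @param seed master integer seed
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with the file paths, configs, surface and
#'   truth parameters
#' @export
make_fixture <- function(scenario, seed, out_dir) {
  if (!scenario %in% FIXTURE_SCENARIOS) {
    stop_dbm("unknown scenario '%s' (known: %s)", scenario,
             paste(FIXTURE_SCENARIOS, collapse = ", "))
  }
  off <- FIXTURE_OFFSET[scenario]
  cfgs <- fixture_configs(scenario)
  surface <- sample_true_surface(cfgs$surface, seed + off)
  stopifnot(all(apply(surface$prev, 1:4, sum) <= 1))
  studies <- simulate_studies(surface, cfgs$design, seed + off + 1L)
  pop <- simulate_population(cfgs$surface, seed + off + 2L)
  hier <- config_hierarchy(cfgs$surface)
  std <- who_age_standard(
    if (cfgs$surface$age_grid$age_lo[1] >= 20) "adult" else "school")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    studies = file.path(out_dir, "studies.csv"),
    hierarchy = file.path(out_dir, "hierarchy.csv"),
    age_standard = file.path(out_dir, "age_standard.csv"),
    population = file.path(out_dir, "population.csv"),
    truth_surface = file.path(out_dir, "truth_surface.csv"),
    truth_params = file.path(out_dir, "truth_params.json")
  )
  write_study_table(studies, paths$studies)
  utils::write.csv(as.data.frame(hier), paths$hierarchy,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(std), paths$age_standard,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(pop), paths$population,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(truth_surface_df(surface), paths$truth_surface,
                   row.names = FALSE, quote = FALSE)

  truth <- list(
    scenario = scenario, seed = seed,
    offsets = as.list(cfgs$design$offsets),
    urban_effect = cfgs$design$urban_effect,
    study_sd = as.list(cfgs$design$study_sd),
    baseline_logit = as.list(cfgs$surface$baseline_logit),
    trend_logit = as.list(cfgs$surface$trend_logit),
    years = range(cfgs$surface$years)
  )
  if (scenario == "crossover") {
    gl <- global_truth_series(surface, pop, std)
    if (gl$obese[1] > gl$low[1]) {
      stop_dbm("crossover scenario degenerate: already crossed at start")
    }
    k <- which(gl$obese > gl$low)
    if (length(k) == 0) {
      stop_dbm("crossover scenario degenerate: no crossing in window")
    }
    truth$crossover_year <- cfgs$surface$years[min(k)]
  }
  jsonlite::write_json(truth, paths$truth_params, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(paths = paths, configs = cfgs, surface = surface,
                 studies = studies, population = pop, truth = truth))
}
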