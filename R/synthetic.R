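# Synthetic study-database generator.  The generator uses exactly the
# fitted model's structure (hierarchical linear trends, constrained RW2
# non-linearity, hierarchical age splines, coverage offsets, urban effects,
# study effects, binomial sampling), so downstream recovery tests are
# well-posed without any real data.

#' Configuration of the latent prevalence surface
#'
#' Defaults describe the desk-scale world: 3 regions x 4 countries,
#' 21 years, both sexes, the adult 5-year age grid, and weak-to-moderate
#' hierarchical effect scales on the logit scale.  Category baselines and
#' mean trends put underweight near 12% and declining, obesity near 8% and
#' rising -- small enough that the two categories never sum above 1.
#'
#' @param regions number of regions
#' @param countries_per_region countries in each region
#' @param years inclusive, consecutive year range (>= 3 years for RW2)
#' @param sexes subset of female/male
#' @param age_grid data.frame from [adult_age_grid()] or
#'   [school_age_grid()]
#' @param age_knots interior spline knots
#' @param categories BMI categories
#' @param baseline_logit named logit-scale baselines per category
#' @param trend_logit named mean slopes per category (logit change per
#'   unit of standardised time; total change over the window is twice
#'   this)
#' @param intercept_scale,slope_scale,rw2_scale,age_scale named
#'   global/region/country SDs of the random effects at each level
#' @return object of class `surface_config`
#' @export
surface_config <- function(regions = 3,
                           countries_per_region = 4,
                           years = 2000:2020,
                           sexes = c("female", "male"),
                           age_grid = adult_age_grid(),
                           age_knots = c(35, 50, 65),
                           categories = c("low", "obese"),
                           baseline_logit = c(low = -2.0, obese = -2.4),
                           trend_logit = c(low = -0.5, obese = 0.7),
                           intercept_scale = c(global = 0.2, region = 0.4,
                                               country = 0.25),
                           slope_scale = c(global = 0.1, region = 0.15,
                                           country = 0.1),
                           rw2_scale = c(global = 0.04, region = 0.03,
                                         country = 0.03),
                           age_scale = c(global = 0.6, region = 0.2,
                                         country = 0.1)) {
  scales <- c(intercept_scale, slope_scale, rw2_scale, age_scale)
  if (any(scales < 0)) stop_dbm("effect scales must be non-negative")
  if (regions < 1 || countries_per_region < 1) {
    stop_dbm("need at least one region and one country")
  }
  if (countries_per_region < 2) {
    warning("fewer than 2 countries per region: shrinkage is untestable")
  }
  structure(list(
    regions = regions, countries_per_region = countries_per_region,
    years = as.integer(years), sexes = sexes, age_grid = age_grid,
    age_knots = age_knots, categories = categories,
    baseline_logit = baseline_logit, trend_logit = trend_logit,
    intercept_scale = intercept_scale, slope_scale = slope_scale,
    rw2_scale = rw2_scale, age_scale = age_scale
  ), class = "surface_config")
}

#' Configuration of the study design generator
#'
#' Controls how observed studies are generated from a latent surface:
#' study counts per country, the coverage and urbanisation mixes, the true
#' systematic offsets of subnational and community samples (logit scale),
#' the coverage-class study-effect SDs (community > subnational >
#' national, mirroring their larger variability), and per-cell sample
#' sizes.
#'
#' @param studies_per_country scalar, or named vector keyed by country
#'   code (countries may have 0 studies)
#' @param coverage_mix sampling proportions of national/subnational/
#'   community studies (sums to 1)
#' @param urban_mix urbanisation proportions for non-national studies
#'   (national studies are always mixed)
#' @param n_range inclusive range of per-cell sample sizes
#' @param offsets true logit offsets of subnational and community studies
#' @param study_sd study-effect SDs per coverage class
#' @param urban_effect logit effect of urban (+) vs rural (-) samples
#' @param bands_per_study number of contiguous age bands each study
#'   reports (NULL = the whole grid)
#' @param exact if TRUE, disable offsets, study effects, urban effects and
#'   binomial noise: observed prevalence equals the surface exactly
#' @return object of class `design_config`
#' @export
design_config <- function(studies_per_country = 8,
                          coverage_mix = c(national = 0.5,
                                           subnational = 0.25,
                                           community = 0.25),
                          urban_mix = c(urban = 0.15, rural = 0.15,
                                        mixed = 0.7),
                          n_range = c(200, 2000),
                          offsets = c(subnational = 0.2, community = -0.3),
                          study_sd = c(national = 0.05, subnational = 0.1,
                                       community = 0.15),
                          urban_effect = 0.15,
                          bands_per_study = NULL,
                          exact = FALSE) {
  if (abs(sum(coverage_mix) - 1) > 1e-8) {
    stop_dbm("coverage_mix must sum to 1")
  }
  if (abs(sum(urban_mix) - 1) > 1e-8) stop_dbm("urban_mix must sum to 1")
  if (any(study_sd < 0)) stop_dbm("study-effect SDs must be non-negative")
  structure(list(
    studies_per_country = studies_per_country, coverage_mix = coverage_mix,
    urban_mix = urban_mix, n_range = as.integer(n_range),
    offsets = offsets, study_sd = study_sd, urban_effect = urban_effect,
    bands_per_study = bands_per_study, exact = exact
  ), class = "design_config")
}

country_codes <- function(config) {
  unlist(lapply(seq_len(config$regions), function(r)
    sprintf("%s%02d", LETTERS[r], seq_len(config$countries_per_region))))
}

region_names <- function(config) {
  sprintf("region-%s", LETTERS[seq_len(config$regions)])
}

#' Country-region hierarchy of a surface configuration
#'
#' @param config a [surface_config()]
#' @return a [region_hierarchy()]
#' @export
config_hierarchy <- function(config) {
  region_hierarchy(data.frame(
    country = country_codes(config),
    region = rep(region_names(config), each = config$countries_per_region)
  ))
}

# one constrained RW2 path of length T with innovation sd `scale`,
# projected orthogonal to {1, t} so it carries no intercept or slope
rw2_path <- function(T, t_std, scale, Z) {
  u <- numeric(T)
  if (scale > 0) {
    e <- stats::rnorm(T - 2, 0, scale)
    for (t in 3:T) u[t] <- 2 * u[t - 1] - u[t - 2] + e[t - 2]
    u <- as.vector(Z %*% crossprod(Z, u))
  }
  u
}

#' Sample a latent true prevalence surface
#'
#' Draws, in documented order per (category, sex): global intercept and
#' slope around the category baseline/trend; region and country
#' intercept/slope deviations; RW2 non-linear trend components at all
#' three levels (projected orthogonal to intercept and slope); and
#' hierarchical age-spline coefficients.  Identical (config, seed) yield
#' an identical surface.
#'
#' @param config a [surface_config()]
#' @param seed integer seed
#' @return object of class `true_surface`: `prev` and `logit` arrays with
#'   dims (country, year, sex, age band, category), plus the generating
#'   parameters
#' @export
sample_true_surface <- function(config, seed) {
  T <- length(config$years)
  if (T < 3) stop_dbm("year range too short: RW2 undefined for < 3 years")
  set.seed(seed)
  countries <- country_codes(config)
  R <- config$regions
  C <- length(countries)
  region_of <- rep(seq_len(R), each = config$countries_per_region)
  t_std <- year_std(config$years)
  Z <- rw2_basis(t_std)
  Braw <- build_age_basis(config$age_grid$age_mid, config$age_knots)
  B <- center_basis(Braw, Braw)
  K <- ncol(B)
  A <- nrow(config$age_grid)
  nsex <- length(config$sexes)
  ncat <- length(config$categories)

  logit_arr <- array(NA_real_, dim = c(C, T, nsex, A, ncat),
                     dimnames = list(countries, config$years, config$sexes,
                                     config$age_grid$age_lo,
                                     config$categories))
  params <- list()
  for (cat in config$categories) {
    for (sx in config$sexes) {
      a0 <- config$baseline_logit[cat] +
        stats::rnorm(1, 0, config$intercept_scale["global"])
      b0 <- config$trend_logit[cat] +
        stats::rnorm(1, 0, config$slope_scale["global"])
      ar <- stats::rnorm(R, 0, config$intercept_scale["region"])
      br <- stats::rnorm(R, 0, config$slope_scale["region"])
      ac <- stats::rnorm(C, 0, config$intercept_scale["country"])
      bc <- stats::rnorm(C, 0, config$slope_scale["country"])
      u0 <- rw2_path(T, t_std, config$rw2_scale["global"], Z)
      ur <- vapply(seq_len(R), function(r)
        rw2_path(T, t_std, config$rw2_scale["region"], Z), numeric(T))
      uc <- vapply(seq_len(C), function(cc)
        rw2_path(T, t_std, config$rw2_scale["country"], Z), numeric(T))
      g0 <- stats::rnorm(K, 0, config$age_scale["global"])
      gr <- matrix(stats::rnorm(K * R, 0, config$age_scale["region"]), K, R)
      gc <- matrix(stats::rnorm(K * C, 0, config$age_scale["country"]), K, C)

      for (cc in seq_len(C)) {
        r <- region_of[cc]
        trend <- (a0 + ar[r] + ac[cc]) + (b0 + br[r] + bc[cc]) * t_std +
          u0 + ur[, r] + uc[, cc]
        agecurve <- as.vector(B %*% (g0 + gr[, r] + gc[, cc]))
        logit_arr[cc, , match(sx, config$sexes), ,
                  match(cat, config$categories)] <-
          outer(trend, rep(1, A)) + outer(rep(1, T), agecurve)
      }
      params[[paste(cat, sx, sep = ".")]] <- list(
        a0 = a0, b0 = b0, ar = ar, br = br, ac = ac, bc = bc,
        u0 = u0, ur = ur, uc = uc, g0 = g0, gr = gr, gc = gc)
    }
  }
  structure(list(
    prev = inv_logit(logit_arr), logit = logit_arr,
    config = config, seed = seed, params = params,
    countries = countries, region_of = region_of
  ), class = "true_surface")
}

#' Simulate a study table from a true surface
#'
#' Each study draws its coverage level, urbanisation, mid-year, per-cell
#' sample size and (per category and sex) a study effect; observed counts
#' are binomial around the inverse-logit of the true logit prevalence plus
#' the coverage offset, urban effect, and study effect.  In `exact` mode
#' all perturbations and sampling noise are disabled and the observed
#' prevalence equals the surface.
#'
#' @param surface a `true_surface`
#' @param design a [design_config()]
#' @param seed integer seed
#' @return a `study_table`
#' @export
simulate_studies <- function(surface, design, seed) {
  set.seed(seed)
  config <- surface$config
  years <- config$years
  grid <- config$age_grid
  A <- nrow(grid)
  regions <- region_names(config)
  rows <- list()
  spc <- design$studies_per_country
  for (cc in seq_along(surface$countries)) {
    ctry <- surface$countries[cc]
    k <- if (length(spc) == 1 && is.null(names(spc))) spc
         else (spc[ctry] %||% 0)
    k <- if (is.na(k)) 0 else as.integer(k)
    if (k == 0) next
    for (j in seq_len(k)) {
      coverage <- sample(names(design$coverage_mix), 1,
                         prob = design$coverage_mix)
      urb <- if (coverage == "national") "mixed"
             else sample(names(design$urban_mix), 1,
                         prob = design$urban_mix)
      mid_year <- sample(years, 1)
      nsamp <- sample(design$n_range[1]:design$n_range[2], 1)
      if (is.null(design$bands_per_study) ||
          design$bands_per_study >= A) {
        bands <- seq_len(A)
      } else {
        st <- sample(seq_len(A - design$bands_per_study + 1), 1)
        bands <- st:(st + design$bands_per_study - 1)
      }
      u <- c(urban = 1, rural = -1, mixed = 0)[urb]
      off <- if (coverage == "national") 0 else design$offsets[coverage]
      sid <- sprintf("%s-%03d", ctry, j)
      ti <- match(mid_year, years)
      for (sx in config$sexes) {
        prev_by_cat <- list(low = rep(NA_real_, length(bands)),
                            obese = rep(NA_real_, length(bands)))
        for (cat in config$categories) {
          e <- stats::rnorm(1, 0, design$study_sd[coverage])
          tl <- surface$logit[cc, ti, match(sx, config$sexes), bands,
                              match(cat, config$categories)]
          if (design$exact) {
            prev_by_cat[[cat]] <- inv_logit(tl)
          } else {
            p <- inv_logit(tl + off + design$urban_effect * u + e)
            prev_by_cat[[cat]] <-
              stats::rbinom(length(bands), nsamp, p) / nsamp
          }
        }
        rows[[length(rows) + 1]] <- data.frame(
          study_id = sid, country = ctry,
          region = regions[surface$region_of[cc]],
          mid_year = mid_year, sex = sx,
          age_lo = grid$age_lo[bands], age_hi = grid$age_hi[bands],
          coverage = coverage, urbanisation = urb, n_sample = nsamp,
          prev_low = prev_by_cat$low, prev_obese = prev_by_cat$obese,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    df <- data.frame(study_id = character(), country = character(),
                     region = character(), mid_year = integer(),
                     sex = character(), age_lo = integer(),
                     age_hi = integer(), coverage = character(),
                     urbanisation = character(), n_sample = integer(),
                     prev_low = numeric(), prev_obese = numeric())
    return(study_table(df, window = range(years)))
  }
  study_table(do.call(rbind, rows), window = range(years))
}
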