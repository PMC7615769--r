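# Model specification and the model context (index maps, design
# cross-products, RW2 penalty structure) for one category x sex fit.

MODEL_COMPONENTS <- c("intercept", "slope", "hierarchy", "rw2", "age",
                      "coverage", "urban", "study")

SD_NAMES <- c("a_region", "b_region", "a_country", "b_country",
              "rw_global", "rw_region", "rw_country",
              "g_region", "g_country",
              "tau_national", "tau_subnational", "tau_community")

#' Model specification
#'
#' Bundles the structural choices (year range, age grid, spline knots,
#' active model components), the prior scales, and the MCMC settings of the
#' hierarchical meta-regression.
#'
#' Components: `intercept` and `slope` are the global linear trend;
#' `hierarchy` adds region- and country-level intercept/slope deviations;
#' `rw2` adds second-order random-walk non-linear time trends at the global,
#' region, and country levels; `age` adds hierarchical cubic-spline age
#' patterns; `coverage` adds the systematic subnational/community offsets;
#' `urban` the urban/rural coefficient; `study` the per-study random effects
#' with coverage-class-specific variances.  Dropping components yields the
#' degenerate models used by the closed-form oracles.
#'
#' @param years integer vector of estimation years (consecutive)
#' @param age_grid data.frame from [adult_age_grid()] or [school_age_grid()]
#' @param age_knots interior spline knot ages
#' @param components character subset of the component names above
#' @param prior_sd named scales of the Normal(0, sd) priors on fixed
#'   effects: `fixed` (intercept/slope), `offset`, `urban`, `gamma0`
#'   (global spline coefficients)
#' @param half_normal_scale scale of the half-Normal priors on all SD
#'   parameters
#' @param iterations MCMC iterations per chain (including burn-in)
#' @param burn_fraction fraction of iterations discarded as burn-in
#' @param thin thinning interval applied after burn-in
#' @param chains number of chains
#' @param seed integer RNG seed; chain k uses `seed + k`
#' @param init_sd initial value for all SD parameters
#' @param fix_variances if TRUE the SD parameters stay at `init_sd`
#'   (used by conjugate oracles)
#' @return object of class `model_spec`
#' @export
model_spec <- function(years,
                       age_grid = adult_age_grid(),
                       age_knots = c(35, 50, 65),
                       components = MODEL_COMPONENTS,
                       prior_sd = c(fixed = 1, offset = 1, urban = 1,
                                    gamma0 = 1),
                       half_normal_scale = 1,
                       iterations = 2000,
                       burn_fraction = 0.5,
                       thin = 5,
                       chains = 4,
                       seed = 1,
                       init_sd = 0.3,
                       fix_variances = FALSE) {
  years <- as.integer(years)
  if (length(years) > 1 && any(diff(years) != 1)) {
    stop_dbm("years must be consecutive")
  }
  bad <- setdiff(components, MODEL_COMPONENTS)
  if (length(bad) > 0) stop_dbm("unknown components: %s",
                                paste(bad, collapse = ", "))
  if ("rw2" %in% components && length(years) < 3) {
    stop_dbm("rw2 component needs at least 3 years")
  }
  if (burn_fraction < 0 || burn_fraction > 1) {
    stop_dbm("burn_fraction must be in [0, 1]")
  }
  if (floor(iterations * (1 - burn_fraction)) < 1) {
    stop_dbm("no retained draws: burn-in consumes all %d iterations",
             iterations)
  }
  prior <- c(fixed = 1, offset = 1, urban = 1, gamma0 = 1)
  prior[names(prior_sd)] <- prior_sd
  structure(list(
    years = years, age_grid = age_grid, age_knots = age_knots,
    components = components, prior_sd = prior,
    half_normal_scale = half_normal_scale,
    iterations = as.integer(iterations), burn_fraction = burn_fraction,
    thin = as.integer(thin), chains = as.integer(chains),
    seed = as.integer(seed), init_sd = init_sd,
    fix_variances = fix_variances
  ), class = "model_spec")
}

# standardised time over the year grid, in [-1, 1]
year_std <- function(years) {
  if (length(years) == 1) return(0)
  mid <- mean(range(years))
  (years - mid) / (diff(range(years)) / 2)
}

# basis of the subspace of R^T orthogonal to {1, t}; RW2 vectors live here
# so they are identified against the intercept and slope by construction
rw2_basis <- function(t_std) {
  T <- length(t_std)
  X <- cbind(1, t_std)
  qr.Q(qr(X), complete = TRUE)[, -(1:2), drop = FALSE]
}

# second-difference matrix, (T-2) x T
second_diff_matrix <- function(T) {
  D <- matrix(0, T - 2, T)
  for (i in seq_len(T - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
  D
}

sum_by <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x) > 0) {
    o <- rowsum(x, idx)
    out[as.integer(rownames(o))] <- o
  }
  out
}

#' Build the model context for one category and sex
#'
#' Compiles transformed observations into index maps, the spline basis, the
#' RW2 penalty structure and the fixed design cross-products that the
#' sampler reuses every iteration.  The context is specific to one BMI
#' category and one sex (categories and sexes are fitted independently).
#'
#' @param tobs data.frame from [logit_transform()], restricted to one sex
#' @param hierarchy a [region_hierarchy()]
#' @param spec a [model_spec()]
#' @return object of class `model_context`
#' @export
build_model_context <- function(tobs, hierarchy, spec) {
  countries <- sort(unique(hierarchy$country))
  regions <- sort(unique(hierarchy$region))
  region_of <- match(hierarchy$region[match(countries, hierarchy$country)],
                     regions)
  n <- nrow(tobs)
  if (n > 0) {
    if (length(unique(tobs$sex)) > 1) {
      stop_dbm("context must be built for a single sex")
    }
    if (!all(tobs$country %in% countries)) {
      stop_dbm("studies reference countries absent from the hierarchy: %s",
               paste(setdiff(tobs$country, countries), collapse = ", "))
    }
    if (!all(tobs$mid_year %in% spec$years)) {
      stop_dbm("study mid_year outside the model year grid")
    }
    band <- match(tobs$age_lo, spec$age_grid$age_lo)
    if (anyNA(band)) {
      stop_dbm("study age bands must match the model age grid (bad age_lo: %s)",
               paste(unique(tobs$age_lo[is.na(band)]), collapse = ", "))
    }
  } else {
    band <- integer(0)
  }

  T <- length(spec$years)
  t_std <- year_std(spec$years)
  use_rw2 <- "rw2" %in% spec$components
  Z <- if (use_rw2) rw2_basis(t_std) else NULL
  P <- NULL; logdetP <- 0
  if (use_rw2) {
    D2 <- second_diff_matrix(T)
    DZ <- D2 %*% Z
    P <- crossprod(DZ)
    logdetP <- as.numeric(determinant(P, logarithm = TRUE)$modulus)
  }

  grid_mid <- spec$age_grid$age_mid
  K <- 0; B_grid_raw <- NULL; B_grid <- NULL; B_obs <- NULL
  if ("age" %in% spec$components) {
    B_grid_raw <- build_age_basis(grid_mid, spec$age_knots)
    B_grid <- center_basis(B_grid_raw, B_grid_raw)
    K <- ncol(B_grid_raw)
    B_obs <- if (n > 0) {
      center_basis(build_age_basis(grid_mid, spec$age_knots)[band, ,
                                                             drop = FALSE],
                   B_grid_raw)
    } else matrix(0, 0, K)
  }

  ci <- match(tobs$country, countries)
  ri <- region_of[ci]
  ti <- match(tobs$mid_year, spec$years)
  study_f <- factor(tobs$study_id, levels = unique(tobs$study_id))
  si <- as.integer(study_f)
  S <- nlevels(study_f)
  study_class <- rep(NA_character_, S)
  if (n > 0) {
    cc <- tapply(tobs$coverage, si, function(z) {
      u <- unique(z)
      if (length(u) > 1) stop_dbm("study with mixed coverage levels")
      u
    })
    study_class[as.integer(names(cc))] <- unlist(cc)
  }
  u <- c(urban = 1, rural = -1, mixed = 0)[tobs$urbanisation]

  w <- if (n > 0) 1 / tobs$v else numeric(0)

  ctx <- list(
    y = tobs$y, v = tobs$v, w = w, n = n,
    countries = countries, regions = regions, region_of = region_of,
    R = length(regions), C = length(countries), S = S, T = T, K = K,
    ci = ci, ri = ri, ti = ti, si = si, band = band,
    u = unname(u), cov = tobs$coverage, study_class = study_class,
    t_std = t_std, t_obs = t_std[ti],
    Z = Z, P = P, logdetP = logdetP,
    B_grid_raw = B_grid_raw, B_grid = B_grid, B_obs = B_obs,
    idx_region = if (n > 0) split(seq_len(n), factor(ri, 1:length(regions)))
                 else rep(list(integer(0)), length(regions)),
    idx_country = if (n > 0) split(seq_len(n), factor(ci, 1:length(countries)))
                  else rep(list(integer(0)), length(countries)),
    category = if (n > 0) unique(tobs$category) else NA_character_,
    sex = if (n > 0) unique(tobs$sex) else NA_character_
  )
  class(ctx) <- "model_context"
  ctx
}
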