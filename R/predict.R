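# National prevalence predictions from parameter draws, and the
# posterior-draws container every derived quantity operates on.

#' Posterior draws container
#'
#' A draw-by-cell matrix of prevalences plus the cell index: one column per
#' (country, year, sex, age band, category) cell.  Derived quantities
#' (age-standardisation, double burden, shares, probabilities) are always
#' computed per draw on this container, never from summaries.
#'
#' @param draws numeric matrix, rows are posterior draws
#' @param cells data.frame describing the columns; any subset of the
#'   columns `country`, `year`, `sex`, `age_lo`, `age_hi`, `category`
#' @param check validate that values lie in \[0, 1\]
#' @return object of class `posterior_draws`
#' @export
posterior_draws <- function(draws, cells, check = TRUE) {
  draws <- as.matrix(draws)
  if (ncol(draws) != nrow(cells)) {
    stop_dbm("draws has %d columns but cells has %d rows",
             ncol(draws), nrow(cells))
  }
  if (check && length(draws) > 0) {
    if (any(!is.finite(draws) & !is.na(draws))) {
      stop_dbm("non-finite values in draws")
    }
    rng <- range(draws, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) {
      stop_dbm("prevalence draws outside [0, 1]")
    }
  }
  rownames(cells) <- NULL
  structure(list(draws = draws, cells = cells), class = "posterior_draws")
}

#' @rdname posterior_draws
#' @param x object
#' @export
is_posterior_draws <- function(x) inherits(x, "posterior_draws")

#' @export
dim.posterior_draws <- function(x) dim(x$draws)

n_draws <- function(pd) nrow(pd$draws)

# stack draw columns from all chains for one block; zeros if disabled
draw_block <- function(fit, nm, len) {
  if (!is.null(fit$par_index[[nm]])) {
    do.call(rbind, lapply(fit$chains, function(m)
      m[, fit$par_index[[nm]], drop = FALSE]))
  } else {
    D <- sum(vapply(fit$chains, nrow, 0L))
    matrix(0, D, len)
  }
}

#' Predict national prevalence for one country
#'
#' Assembles, per retained draw, the logit prevalence over the year and age
#' grids from the global, region, and country effects (linear, RW2, and age
#' spline), then inverse-logit transforms.  The prediction targets the
#' national, representative population: no coverage offset, no study
#' effect, and the urban term at its mixed (zero) value.
#'
#' @param fit a `dbm_mcmc` from [mcmc_fit()]
#' @param country ISO3 code present in the hierarchy
#' @param years subset of the model years (default all)
#' @return a [posterior_draws()] over (year, age band) cells
#' @export
predict_prevalence <- function(fit, country, years = NULL) {
  ctx <- fit$ctx; spec <- fit$spec
  cc <- match(toupper(country), ctx$countries)
  if (is.na(cc)) stop_dbm("unknown country: %s", country)
  r <- ctx$region_of[cc]
  years <- if (is.null(years)) spec$years else as.integer(years)
  tix <- match(years, spec$years)
  if (anyNA(tix)) stop_dbm("requested years outside the model grid")
  T <- ctx$T; Tm2 <- max(T - 2, 0); K <- ctx$K
  A <- nrow(spec$age_grid)
  D <- sum(vapply(fit$chains, nrow, 0L))

  a <- draw_block(fit, "a0", 1)[, 1] +
    draw_block(fit, "ar", ctx$R)[, r] +
    draw_block(fit, "ac", ctx$C)[, cc]
  b <- draw_block(fit, "b0", 1)[, 1] +
    draw_block(fit, "br", ctx$R)[, r] +
    draw_block(fit, "bc", ctx$C)[, cc]
  M <- matrix(a, D, T) + outer(b, ctx$t_std)
  if (has_comp(spec, "rw2")) {
    w0 <- draw_block(fit, "w0", Tm2)
    wr <- draw_block(fit, "wr", Tm2 * ctx$R)[,
      (r - 1) * Tm2 + seq_len(Tm2), drop = FALSE]
    wc <- draw_block(fit, "wc", Tm2 * ctx$C)[,
      (cc - 1) * Tm2 + seq_len(Tm2), drop = FALSE]
    M <- M + (w0 + wr + wc) %*% t(ctx$Z)
  }
  Aage <- matrix(0, D, A)
  if (has_comp(spec, "age")) {
    g <- draw_block(fit, "g0", K) +
      draw_block(fit, "gr", K * ctx$R)[, (r - 1) * K + seq_len(K),
                                       drop = FALSE] +
      draw_block(fit, "gc", K * ctx$C)[, (cc - 1) * K + seq_len(K),
                                       drop = FALSE]
    Aage <- g %*% t(ctx$B_grid)
  }
  out <- matrix(NA_real_, D, length(tix) * A)
  for (j in seq_along(tix)) {
    out[, (j - 1) * A + seq_len(A)] <- M[, tix[j]] + Aage
  }
  cells <- data.frame(
    country = ctx$countries[cc],
    year = rep(years, each = A),
    sex = fit$sex %||% NA_character_,
    age_lo = rep(spec$age_grid$age_lo, length(tix)),
    age_hi = rep(spec$age_grid$age_hi, length(tix)),
    category = fit$category %||% NA_character_,
    stringsAsFactors = FALSE
  )
  posterior_draws(inv_logit(out), cells)
}

#' Fit all category-by-sex models
#'
#' Convenience wrapper: transforms the study table per category, splits by
#' sex, builds a context and runs [mcmc_fit()] for each combination
#' independently.
#'
#' @param studies a `study_table`
#' @param hierarchy a `region_hierarchy`
#' @param spec a `model_spec`
#' @param categories BMI categories to fit
#' @param sexes sexes to fit
#' @return object of class `dbm_fit`, a named list of `dbm_mcmc` fits
#'   (names like `"low.female"`)
#' @export
fit_model <- function(studies, hierarchy, spec,
                      categories = c("low", "obese"),
                      sexes = c("female", "male")) {
  fits <- list()
  for (cat in categories) {
    tobs <- logit_transform(studies, cat)
    for (sx in sexes) {
      sub <- tobs[tobs$sex == sx, , drop = FALSE]
      ctx <- build_model_context(sub, hierarchy, spec)
      f <- mcmc_fit(ctx, spec)
      f$category <- cat
      f$sex <- sx
      fits[[paste(cat, sx, sep = ".")]] <- f
    }
  }
  structure(list(fits = fits, hierarchy = hierarchy, spec = spec),
            class = "dbm_fit")
}

#' Posterior prevalence surface over countries
#'
#' Binds [predict_prevalence()] across all requested countries and all
#' fitted category-sex combinations into one [posterior_draws()] container.
#'
#' @param fit a `dbm_fit` from [fit_model()]
#' @param countries ISO3 codes (default: every country in the hierarchy)
#' @param years subset of model years
#' @return a [posterior_draws()]
#' @export
posterior_surface <- function(fit, countries = NULL, years = NULL) {
  countries <- countries %||% sort(unique(fit$hierarchy$country))
  parts <- list()
  for (f in fit$fits) {
    for (ct in countries) {
      parts[[length(parts) + 1]] <- predict_prevalence(f, ct, years)
    }
  }
  posterior_draws(
    do.call(cbind, lapply(parts, function(p) p$draws)),
    do.call(rbind, lapply(parts, function(p) p$cells)),
    check = FALSE
  )
}

#' Write posterior draws as a tidy CSV
#'
#' One row per draw x cell: `draw,country,year,sex,age_lo,category,
#' prevalence`.  Intended for desk-scale outputs.
#'
#' @param pd a `posterior_draws`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_draws_csv <- function(pd, path) {
  D <- n_draws(pd)
  df <- pd$cells[rep(seq_len(nrow(pd$cells)), each = D),
                 intersect(c("country", "year", "sex", "age_lo", "category"),
                           names(pd$cells)), drop = FALSE]
  df <- cbind(draw = rep(seq_len(D), times = nrow(pd$cells)), df)
  df$prevalence <- as.vector(pd$draws)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
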