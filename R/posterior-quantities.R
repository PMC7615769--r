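# Derived quantities, all computed strictly at the posterior draw level:
# age-standardisation, double burden, obesity share, posterior
# probabilities of change and dominance, persons affected, cross-country
# correlations, and the crossover year.

cell_key <- function(cells, cols) {
  cols <- intersect(cols, names(cells))
  do.call(paste, c(cells[cols], sep = "\r"))
}

align_draws <- function(a, b, drop = "category") {
  if (n_draws(a) != n_draws(b)) stop_dbm("draw counts differ")
  cols <- setdiff(c("country", "year", "sex", "age_lo", "age_hi"), drop)
  ka <- cell_key(a$cells, cols)
  kb <- cell_key(b$cells, cols)
  m <- match(ka, kb)
  if (anyNA(m) || length(unique(kb)) != length(kb)) {
    stop_dbm("cell indexes are misaligned")
  }
  m
}

#' Age-standardise posterior draws
#'
#' Per draw, the weighted sum of age-specific prevalences with the
#' standard's weights, renormalised over the bands actually covered by the
#' draws.  The age dimension is collapsed; all other cell dimensions are
#' preserved.
#'
#' @param pd a [posterior_draws()] with age-specific cells
#' @param standard an [age_standard()]
#' @return a [posterior_draws()] without age columns
#' @export
age_standardise <- function(pd, standard) {
  wt <- standard$weight[match(pd$cells$age_lo, standard$age_lo)]
  if (anyNA(wt)) {
    stop_dbm("age bands not covered by the standard: %s",
             paste(sort(unique(pd$cells$age_lo[is.na(wt)])), collapse = ", "))
  }
  grp_cols <- intersect(c("country", "year", "sex", "category"),
                        names(pd$cells))
  key <- cell_key(pd$cells, grp_cols)
  groups <- unique(key)
  D <- n_draws(pd)
  out <- matrix(NA_real_, D, length(groups))
  cells_out <- pd$cells[match(groups, key), grp_cols, drop = FALSE]
  for (j in seq_along(groups)) {
    ii <- which(key == groups[j])
    wj <- wt[ii]
    if (anyDuplicated(pd$cells$age_lo[ii]) > 0) {
      stop_dbm("duplicate age bands within a cell group")
    }
    out[, j] <- pd$draws[, ii, drop = FALSE] %*% (wj / sum(wj))
  }
  posterior_draws(out, cells_out, check = FALSE)
}

#' Double burden: combined prevalence
#'
#' Per-draw elementwise sum of the low-BMI and obesity prevalences on
#' aligned cells.  Sums above 1 indicate inputs violating the category-sum
#' constraint and trigger a warning (draws are reported, never altered).
#'
#' @param low,obese aligned [posterior_draws()] for the two categories
#' @return a [posterior_draws()] with `category = "combined"`
#' @export
combined_prevalence <- function(low, obese) {
  m <- align_draws(low, obese)
  s <- low$draws + obese$draws[, m, drop = FALSE]
  if (any(s > 1 + 1e-12, na.rm = TRUE)) {
    warning("combined prevalence exceeds 1 in some draws")
  }
  cells <- low$cells
  cells$category <- "combined"
  posterior_draws(s, cells, check = FALSE)
}

#' Obesity share of the double burden
#'
#' Per draw, obese / (low + obese).  Cells where both are exactly zero are
#' undefined and propagate as `NA` (reported as indeterminate), never as
#' 0/0 noise.
#'
#' @inheritParams combined_prevalence
#' @return a [posterior_draws()] with `category = "obese_share"`
#' @export
obesity_share <- function(low, obese) {
  m <- align_draws(low, obese)
  ob <- obese$draws[, m, drop = FALSE]
  tot <- low$draws + ob
  share <- ifelse(tot == 0, NA_real_, ob / tot)
  cells <- low$cells
  cells$category <- "obese_share"
  posterior_draws(share, cells, check = FALSE)
}

#' Posterior probability of an increase (or decrease)
#'
#' Fraction of draws in which the value at `t1` exceeds the value at `t0`;
#' the decrease probability counts strict negative differences.  Ties count
#' to neither, so P(increase) + P(decrease) + P(tie) = 1 exactly.
#'
#' @param at_t1,at_t0 aligned [posterior_draws()] (same cells, two times)
#' @return data.frame of cells plus `p_increase`, `p_decrease`
#' @export
posterior_prob_increase <- function(at_t1, at_t0) {
  if (n_draws(at_t1) == 0) stop_dbm("zero draws")
  m <- align_draws(at_t1, at_t0, drop = "year")
  d <- at_t1$draws - at_t0$draws[, m, drop = FALSE]
  out <- at_t1$cells
  out$p_increase <- colMeans(d > 0)
  out$p_decrease <- colMeans(d < 0)
  out
}

#' Posterior probability of dominance
#'
#' The two one-sided proportions P(obese > low) and P(low > obese) per
#' cell; ties are excluded so the pair sums to at most 1.
#'
#' @inheritParams combined_prevalence
#' @return data.frame of cells plus `p_obese_gt`, `p_low_gt`
#' @export
posterior_prob_dominance <- function(obese, low) {
  if (n_draws(obese) == 0) stop_dbm("zero draws")
  m <- align_draws(obese, low)
  out <- obese$cells
  out$p_obese_gt <- colMeans(obese$draws > low$draws[, m, drop = FALSE])
  out$p_low_gt <- colMeans(obese$draws < low$draws[, m, drop = FALSE])
  out
}

#' Persons affected
#'
#' Per draw, prevalence times persons, summed within the requested groups
#' (e.g. `by = c("country", "year")` or `by = "year"` for global totals).
#' Every draw cell must have a matching population cell.
#'
#' @param pd a [posterior_draws()] with age-specific cells
#' @param pop a [population_table()]
#' @param by cell columns to keep (everything else is summed over)
#' @return a [posterior_draws()] of counts over the grouped cells
#' @export
persons_affected <- function(pd, pop, by = c("country", "year", "sex",
                                             "category")) {
  pop_key <- do.call(paste, c(pop[c("country", "year", "sex", "age_lo")],
                              sep = "\r"))
  cell_pop_key <- do.call(paste, c(pd$cells[c("country", "year", "sex",
                                              "age_lo")], sep = "\r"))
  m <- match(cell_pop_key, pop_key)
  if (anyNA(m)) {
    stop_dbm("missing population cell(s), e.g. %s",
             gsub("\r", "/", cell_pop_key[which(is.na(m))[1]]))
  }
  persons <- pop$persons[m]
  by <- intersect(by, names(pd$cells))
  key <- cell_key(pd$cells, by)
  groups <- unique(key)
  D <- n_draws(pd)
  out <- matrix(0, D, length(groups))
  for (j in seq_along(groups)) {
    ii <- which(key == groups[j])
    out[, j] <- pd$draws[, ii, drop = FALSE] %*% persons[ii]
  }
  cells_out <- pd$cells[match(groups, key), by, drop = FALSE]
  posterior_draws(out, cells_out, check = FALSE)
}

#' Cross-country Pearson correlation, draw level
#'
#' Per draw, the Pearson correlation between two per-country quantities
#' across countries; the draws are then summarised (posterior mean and
#' 2.5/97.5 percentiles).  A draw in which either quantity has zero
#' variance across countries is marked missing, not dropped silently.
#'
#' @param x,y [posterior_draws()] with one cell per country, aligned
#' @param use_posterior_means if TRUE, compute a single r between the
#'   posterior-mean country values instead (reported without a CrI)
#' @return a `derived_summary` list: `mean`, `lo`, `hi`, `n_indeterminate`,
#'   `r_draws`
#' @export
correlate_across_countries <- function(x, y, use_posterior_means = FALSE) {
  if (nrow(x$cells) < 3) stop_dbm("need at least 3 countries")
  m <- match(x$cells$country, y$cells$country)
  if (anyNA(m)) stop_dbm("country sets differ")
  ym <- y$draws[, m, drop = FALSE]
  if (use_posterior_means) {
    r <- stats::cor(colMeans(x$draws), colMeans(ym))
    return(structure(list(mean = r, lo = NA_real_, hi = NA_real_,
                          n_indeterminate = 0L, r_draws = r),
                     class = "derived_summary"))
  }
  D <- n_draws(x)
  r <- vapply(seq_len(D), function(d) {
    xv <- x$draws[d, ]; yv <- ym[d, ]
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0) return(NA_real_)
    stats::cor(xv, yv)
  }, 0)
  q <- cri_quantile(r)
  structure(list(mean = mean(r, na.rm = TRUE), lo = q[1], hi = q[2],
                 n_indeterminate = sum(is.na(r)), r_draws = r),
            class = "derived_summary")
}

#' Crossover year
#'
#' Per draw, the first grid year at which series `a` strictly exceeds
#' series `b`, given that `a <= b` at the start of the grid.  Draws that
#' never cross are counted separately and excluded from the percentiles;
#' if `a > b` at the start in more than half the draws the result carries
#' the `already_crossed` sentinel.  Years are reported on the integer grid
#' (no sub-year interpolation).
#'
#' @param a,b [posterior_draws()] over the same year grid (single series:
#'   one cell per year)
#' @return list: `median`, `lo`, `hi`, `frac_no_cross`,
#'   `frac_already_crossed`, `already_crossed` (logical sentinel),
#'   `year_draws`
#' @export
crossover_year <- function(a, b) {
  if (n_draws(a) == 0) stop_dbm("zero draws")
  ya <- a$cells$year; yb <- b$cells$year
  if (!identical(as.integer(ya), as.integer(yb))) {
    stop_dbm("year grids differ")
  }
  o <- order(ya)
  A <- a$draws[, o, drop = FALSE]
  B <- b$draws[, o, drop = FALSE]
  years <- as.integer(ya[o])
  D <- nrow(A)
  cross <- rep(NA_integer_, D)
  already <- A[, 1] > B[, 1]
  for (d in seq_len(D)) {
    if (already[d]) next
    k <- which(A[d, ] > B[d, ])
    if (length(k) > 0) cross[d] <- years[min(k)]
  }
  eligible <- !already
  crossed <- eligible & !is.na(cross)
  frac_already <- mean(already)
  frac_no <- if (sum(eligible) > 0) sum(eligible & is.na(cross)) / D else 0
  if (any(crossed)) {
    q <- cri_quantile(cross[crossed])
    med <- stats::median(cross[crossed])
  } else {
    q <- c(NA_real_, NA_real_); med <- NA_real_
  }
  list(median = med, lo = q[1], hi = q[2],
       frac_no_cross = frac_no,
       frac_already_crossed = frac_already,
       already_crossed = frac_already > 0.5,
       year_draws = cross)
}

#' Summarise posterior draws
#'
#' Posterior mean and the 2.5th/97.5th percentile credible interval per
#' cell, computed from the draws themselves (type-7 quantiles).
#'
#' @param pd a [posterior_draws()]
#' @return data.frame of cells plus `mean`, `lo`, `hi`
#' @export
summarise_draws <- function(pd) {
  out <- pd$cells
  out$mean <- colMeans(pd$draws, na.rm = TRUE)
  qs <- apply(pd$draws, 2, cri_quantile)
  out$lo <- qs[1, ]
  out$hi <- qs[2, ]
  out
}

#' Subset a posterior-draws container by cell attributes
#'
#' @param pd a [posterior_draws()]
#' @param ... named filters matching cell columns, e.g. `sex = "female"`,
#'   `year = 2020`
#' @return a [posterior_draws()]
#' @export
subset_draws <- function(pd, ...) {
  filt <- list(...)
  keep <- rep(TRUE, nrow(pd$cells))
  for (nm in names(filt)) {
    keep <- keep & pd$cells[[nm]] %in% filt[[nm]]
  }
  posterior_draws(pd$draws[, keep, drop = FALSE],
                  pd$cells[keep, , drop = FALSE], check = FALSE)
}
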