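# Age grids and the cubic B-spline basis for age patterns.

#' Analysis age grids
#'
#' The estimation grids: adults on 5-year bands 20-24 ... 80-84 with an
#' open-ended 85+ band; school ages on 1-year bands 5 ... 19.  Bands are
#' half-open `[age_lo, age_hi)`.
#'
#' @return data.frame with `age_lo`, `age_hi`, `age_mid` (band midpoint;
#'   the open-ended 85+ band is pinned to the spline boundary at 85)
#' @export
adult_age_grid <- function() {
  lo <- seq(20, 85, by = 5)
  hi <- c(seq(25, 85, by = 5), 200L)
  data.frame(age_lo = lo, age_hi = hi,
             age_mid = ifelse(lo == 85, 85, lo + 2.5))
}

#' @rdname adult_age_grid
#' @export
school_age_grid <- function() {
  lo <- 5:19
  data.frame(age_lo = lo, age_hi = lo + 1L, age_mid = lo + 0.5)
}

#' Cubic B-spline basis over an age grid
#'
#' Cubic B-splines with boundary knots at the extremes of `ages` and the
#' given interior knots; each row is a partition of unity (sums to 1).  A
#' degenerate single-age domain returns a 1-column matrix of ones.
#'
#' @param ages numeric ages at which to evaluate the basis
#' @param knots interior knot ages, strictly inside `range(ages)`; may be
#'   empty
#' @return numeric matrix, `length(ages)` rows
#' @export
build_age_basis <- function(ages, knots = numeric(0)) {
  lo <- min(ages); hi <- max(ages)
  if (lo == hi) {
    return(matrix(1, nrow = length(ages), ncol = 1))
  }
  if (length(knots) > 0 && (any(knots <= lo) || any(knots >= hi))) {
    stop_dbm("interior knots must lie strictly inside (%s, %s)", lo, hi)
  }
  full_knots <- c(rep(lo, 4), sort(knots), rep(hi, 4))
  splines::splineDesign(full_knots, x = ages, ord = 4)
}

# centered basis: subtract the column means taken over the grid ages so the
# age curve has zero mean over the grid, removing the confound between the
# spline coefficients and the model intercept
center_basis <- function(basis_at, grid_basis) {
  sweep(basis_at, 2, colMeans(grid_basis))
}
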