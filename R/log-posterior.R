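# Parameter state and the full log posterior density.
#
# The linear predictor for observation i (category and sex fixed) is
#   mu_i = a0 + a_r + a_c + (b0 + b_r + b_c) t_i
#        + U0(t_i) + Ur(t_i) + Uc(t_i)              (RW2, three levels)
#        + B(age_i) (g0 + g_r + g_c)                (age spline, centered)
#        + delta_{coverage(i)} + beta_u u_i + e_{s(i)}
# with y_i ~ N(mu_i, v_i); v_i is the delta-method sampling variance and no
# extra residual variance is added (overdispersion is carried by the
# coverage-class study-effect variances tau^2).

has_comp <- function(spec, comp) comp %in% spec$components

#' Initialise a parameter state
#'
#' All location parameters start at zero and all SD parameters at
#' `spec$init_sd`.  The state is a named list mirroring the model blocks;
#' disabled components are pinned at zero.
#'
#' @param ctx a `model_context`
#' @param spec a `model_spec`
#' @return object of class `parameter_state`
#' @export
init_state <- function(ctx, spec) {
  Tm2 <- max(ctx$T - 2, 0)
  st <- list(
    a0 = 0, b0 = 0,
    ar = numeric(ctx$R), br = numeric(ctx$R),
    ac = numeric(ctx$C), bc = numeric(ctx$C),
    w0 = numeric(Tm2),
    wr = matrix(0, Tm2, ctx$R), wc = matrix(0, Tm2, ctx$C),
    g0 = numeric(ctx$K),
    gr = matrix(0, ctx$K, ctx$R), gc = matrix(0, ctx$K, ctx$C),
    delta = c(subnational = 0, community = 0),
    beta_u = 0,
    e = numeric(ctx$S),
    sd = stats::setNames(rep(spec$init_sd, length(SD_NAMES)), SD_NAMES)
  )
  class(st) <- "parameter_state"
  st
}

#' Linear predictor of a parameter state
#'
#' Assembles the fitted mean of every observation in the context from a
#' parameter state, including coverage offsets, urban terms, and study
#' effects (the data-facing mean, not the national prediction target).
#'
#' @param state a `parameter_state`
#' @param ctx a `model_context`
#' @param spec a `model_spec`
#' @return numeric vector, one value per observation
#' @export
state_mean <- function(state, ctx, spec) {
  n <- ctx$n
  mu <- numeric(n)
  if (n == 0) return(mu)
  if (has_comp(spec, "intercept")) mu <- mu + state$a0
  if (has_comp(spec, "slope")) mu <- mu + state$b0 * ctx$t_obs
  if (has_comp(spec, "hierarchy")) {
    mu <- mu + state$ar[ctx$ri] + state$ac[ctx$ci]
    if (has_comp(spec, "slope")) {
      mu <- mu + (state$br[ctx$ri] + state$bc[ctx$ci]) * ctx$t_obs
    }
  }
  if (has_comp(spec, "rw2")) {
    mu <- mu + as.vector(ctx$Z %*% state$w0)[ctx$ti]
    if (has_comp(spec, "hierarchy")) {
      Ur <- ctx$Z %*% state$wr
      Uc <- ctx$Z %*% state$wc
      mu <- mu + Ur[cbind(ctx$ti, ctx$ri)] + Uc[cbind(ctx$ti, ctx$ci)]
    }
  }
  if (has_comp(spec, "age")) {
    mu <- mu + as.vector(ctx$B_obs %*% state$g0)
    if (has_comp(spec, "hierarchy")) {
      mu <- mu + rowSums(ctx$B_obs * t(state$gr[, ctx$ri, drop = FALSE])) +
        rowSums(ctx$B_obs * t(state$gc[, ctx$ci, drop = FALSE]))
    }
  }
  if (has_comp(spec, "coverage")) {
    mu <- mu + state$delta["subnational"] * (ctx$cov == "subnational") +
      state$delta["community"] * (ctx$cov == "community")
  }
  if (has_comp(spec, "urban")) mu <- mu + state$beta_u * ctx$u
  if (has_comp(spec, "study")) mu <- mu + state$e[ctx$si]
  unname(mu)
}

log_half_normal <- function(sd, scale) {
  log(2) + stats::dnorm(sd, 0, scale, log = TRUE)
}

# proper density of one constrained RW2 vector (free coordinates w, penalty
# P = Z' D2' D2 Z, innovation sd sigma)
rw2_logdens <- function(w, P, logdetP, sigma) {
  m <- length(w)
  quad <- as.numeric(crossprod(w, P %*% w))
  0.5 * logdetP - m * log(sigma) - m / 2 * log(2 * pi) - quad / (2 * sigma^2)
}

#' Log posterior density
#'
#' Sum of the Gaussian likelihood of the transformed observations, the
#' Gaussian densities of all hierarchical deviations and RW2 vectors given
#' their variance parameters, the Normal priors on fixed effects, and
#' half-Normal priors on all SD parameters in use.  Finite for any valid
#' state; errors on non-positive SDs.
#'
#' @param state a `parameter_state`
#' @param ctx a `model_context`
#' @param spec a `model_spec`
#' @return scalar log density
#' @export
log_posterior <- function(state, ctx, spec) {
  if (any(state$sd <= 0)) stop_dbm("SD parameters must be positive")
  sd <- state$sd
  lp <- 0
  if (ctx$n > 0) {
    mu <- state_mean(state, ctx, spec)
    lp <- lp + sum(stats::dnorm(ctx$y, mu, sqrt(ctx$v), log = TRUE))
  }
  pr <- spec$prior_sd
  if (has_comp(spec, "intercept")) {
    lp <- lp + stats::dnorm(state$a0, 0, pr["fixed"], log = TRUE)
  }
  if (has_comp(spec, "slope")) {
    lp <- lp + stats::dnorm(state$b0, 0, pr["fixed"], log = TRUE)
  }
  if (has_comp(spec, "hierarchy")) {
    lp <- lp + sum(stats::dnorm(state$ar, 0, sd["a_region"], log = TRUE)) +
      sum(stats::dnorm(state$ac, 0, sd["a_country"], log = TRUE)) +
      log_half_normal(sd["a_region"], spec$half_normal_scale) +
      log_half_normal(sd["a_country"], spec$half_normal_scale)
    if (has_comp(spec, "slope")) {
      lp <- lp + sum(stats::dnorm(state$br, 0, sd["b_region"], log = TRUE)) +
        sum(stats::dnorm(state$bc, 0, sd["b_country"], log = TRUE)) +
        log_half_normal(sd["b_region"], spec$half_normal_scale) +
        log_half_normal(sd["b_country"], spec$half_normal_scale)
    }
  }
  if (has_comp(spec, "rw2")) {
    lp <- lp + rw2_logdens(state$w0, ctx$P, ctx$logdetP, sd["rw_global"]) +
      log_half_normal(sd["rw_global"], spec$half_normal_scale)
    if (has_comp(spec, "hierarchy")) {
      for (r in seq_len(ctx$R)) {
        lp <- lp + rw2_logdens(state$wr[, r], ctx$P, ctx$logdetP,
                               sd["rw_region"])
      }
      for (cc in seq_len(ctx$C)) {
        lp <- lp + rw2_logdens(state$wc[, cc], ctx$P, ctx$logdetP,
                               sd["rw_country"])
      }
      lp <- lp + log_half_normal(sd["rw_region"], spec$half_normal_scale) +
        log_half_normal(sd["rw_country"], spec$half_normal_scale)
    }
  }
  if (has_comp(spec, "age")) {
    lp <- lp + sum(stats::dnorm(state$g0, 0, pr["gamma0"], log = TRUE))
    if (has_comp(spec, "hierarchy")) {
      lp <- lp + sum(stats::dnorm(state$gr, 0, sd["g_region"], log = TRUE)) +
        sum(stats::dnorm(state$gc, 0, sd["g_country"], log = TRUE)) +
        log_half_normal(sd["g_region"], spec$half_normal_scale) +
        log_half_normal(sd["g_country"], spec$half_normal_scale)
    }
  }
  if (has_comp(spec, "coverage")) {
    lp <- lp + sum(stats::dnorm(state$delta, 0, pr["offset"], log = TRUE))
  }
  if (has_comp(spec, "urban")) {
    lp <- lp + stats::dnorm(state$beta_u, 0, pr["urban"], log = TRUE)
  }
  if (has_comp(spec, "study") && ctx$S > 0) {
    tau <- sd[c("tau_national", "tau_subnational", "tau_community")]
    cls <- match(ctx$study_class,
                 c("national", "subnational", "community"))
    lp <- lp + sum(stats::dnorm(state$e, 0, tau[cls], log = TRUE))
    for (nm in c("tau_national", "tau_subnational", "tau_community")) {
      lp <- lp + log_half_normal(sd[nm], spec$half_normal_scale)
    }
  }
  as.numeric(lp)
}
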