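# MH-within-Gibbs sampler.  All location blocks have Gaussian full
# conditionals (conjugate normal updates); SD parameters move by adaptive
# random-walk Metropolis on the log scale, tuned towards 0.44 acceptance
# during burn-in and frozen afterwards.

par_layout <- function(ctx, spec) {
  Tm2 <- max(ctx$T - 2, 0)
  blocks <- list()
  add <- function(name, len) blocks[[name]] <<- len
  if (has_comp(spec, "intercept")) add("a0", 1)
  if (has_comp(spec, "slope")) add("b0", 1)
  if (has_comp(spec, "hierarchy")) {
    add("ar", ctx$R); add("ac", ctx$C)
    if (has_comp(spec, "slope")) { add("br", ctx$R); add("bc", ctx$C) }
  }
  if (has_comp(spec, "rw2")) {
    add("w0", Tm2)
    if (has_comp(spec, "hierarchy")) {
      add("wr", Tm2 * ctx$R); add("wc", Tm2 * ctx$C)
    }
  }
  if (has_comp(spec, "age")) {
    add("g0", ctx$K)
    if (has_comp(spec, "hierarchy")) {
      add("gr", ctx$K * ctx$R); add("gc", ctx$K * ctx$C)
    }
  }
  if (has_comp(spec, "coverage")) add("delta", 2)
  if (has_comp(spec, "urban")) add("beta_u", 1)
  if (has_comp(spec, "study")) add("e", ctx$S)
  add("sd", length(SD_NAMES))
  lens <- unlist(blocks)
  ends <- cumsum(lens)
  idx <- Map(function(e, l) seq.int(e - l + 1, e), ends, lens)
  names(idx) <- names(blocks)
  idx
}

flatten_state <- function(state, idx) {
  out <- numeric(max(unlist(idx)))
  for (nm in names(idx)) out[idx[[nm]]] <- as.numeric(state[[nm]])
  out
}

# draw from N(prec^-1 b, prec^-1)
draw_gaussian <- function(prec, b) {
  if (length(b) == 1) {
    m <- b / prec
    return(m + stats::rnorm(1) / sqrt(prec))
  }
  L <- chol(prec)
  m <- backsolve(L, backsolve(L, b, transpose = TRUE))
  m + backsolve(L, stats::rnorm(length(b)))
}

#' Fit the hierarchical model by MCMC
#'
#' MH-within-Gibbs: conjugate normal block updates for all location
#' parameters (global/region/country intercepts and slopes, RW2 vectors,
#' spline coefficients, coverage offsets, urban coefficient, study
#' effects), adaptive log-scale random-walk Metropolis for the SD
#' parameters with target acceptance 0.44.  Identical data and spec
#' (including seed) reproduce identical draws.  With zero observations the
#' fit samples the prior and warns.
#'
#' @param ctx a `model_context`
#' @param spec a `model_spec`
#' @return object of class `dbm_mcmc`: retained draws per chain
#'   (post-burn-in, thinned), the parameter index map, and acceptance rates
#' @export
mcmc_fit <- function(ctx, spec) {
  if (ctx$n == 0) {
    warning("no observations: sampling from the prior only")
  }
  idx <- par_layout(ctx, spec)
  n <- ctx$n
  w <- ctx$w
  y <- ctx$y
  Tm2 <- max(ctx$T - 2, 0)
  use <- function(comp) has_comp(spec, comp)
  pr <- spec$prior_sd
  hn <- spec$half_normal_scale

  # fixed design cross-products ------------------------------------------
  p_lin <- (use("intercept") || use("hierarchy")) + use("slope")
  Xg <- if (use("slope")) cbind(1, ctx$t_obs) else matrix(1, n, 1)
  XtWX_g <- crossprod(Xg, w * Xg)
  XtWX_r <- lapply(ctx$idx_region, function(ii)
    crossprod(Xg[ii, , drop = FALSE], w[ii] * Xg[ii, , drop = FALSE]))
  XtWX_c <- lapply(ctx$idx_country, function(ii)
    crossprod(Xg[ii, , drop = FALSE], w[ii] * Xg[ii, , drop = FALSE]))
  if (use("rw2")) {
    Arw_g <- crossprod(ctx$Z, sum_by(w, ctx$ti, ctx$T) * ctx$Z)
    Arw_r <- lapply(ctx$idx_region, function(ii)
      crossprod(ctx$Z, sum_by(w[ii], ctx$ti[ii], ctx$T) * ctx$Z))
    Arw_c <- lapply(ctx$idx_country, function(ii)
      crossprod(ctx$Z, sum_by(w[ii], ctx$ti[ii], ctx$T) * ctx$Z))
  }
  if (use("age")) {
    Bw_g <- crossprod(ctx$B_obs, w * ctx$B_obs)
    Bw_r <- lapply(ctx$idx_region, function(ii)
      crossprod(ctx$B_obs[ii, , drop = FALSE],
                w[ii] * ctx$B_obs[ii, , drop = FALSE]))
    Bw_c <- lapply(ctx$idx_country, function(ii)
      crossprod(ctx$B_obs[ii, , drop = FALSE],
                w[ii] * ctx$B_obs[ii, , drop = FALSE]))
  }
  idx_sub <- which(ctx$cov == "subnational")
  idx_comm <- which(ctx$cov == "community")
  idx_urb <- which(ctx$u != 0)
  sumW_urb <- sum(w[idx_urb] * ctx$u[idx_urb]^2)
  if (use("study")) {
    sumW_s <- sum_by(w, ctx$si, ctx$S)
    cls_s <- match(ctx$study_class, c("national", "subnational", "community"))
    # studies belonging to each country (for the sweep moves)
    studies_of_country <- lapply(ctx$idx_country, function(ii)
      unique(ctx$si[ii]))
    # per-study urbanisation indicator (uniform within study)
    u_study <- rep(0, ctx$S)
    if (ctx$n > 0) u_study[ctx$si] <- ctx$u
  }
  countries_in_region <- split(seq_len(ctx$C),
                               factor(ctx$region_of, seq_len(ctx$R)))

  # which SD parameters are active
  active_sd <- character(0)
  if (use("hierarchy")) {
    active_sd <- c(active_sd, "a_region", "a_country")
    if (use("slope")) active_sd <- c(active_sd, "b_region", "b_country")
    if (use("rw2")) active_sd <- c(active_sd, "rw_region", "rw_country")
    if (use("age")) active_sd <- c(active_sd, "g_region", "g_country")
  }
  if (use("rw2")) active_sd <- c(active_sd, "rw_global")
  if (use("study")) {
    for (k in seq_along(c("national", "subnational", "community"))) {
      if (any(cls_s == k)) {
        active_sd <- c(active_sd,
                       c("tau_national", "tau_subnational",
                         "tau_community")[k])
      }
    }
  }

  n_iter <- spec$iterations
  n_burn <- floor(spec$iterations * spec$burn_fraction)
  keep_at <- seq.int(n_burn + spec$thin, n_iter, by = spec$thin)
  if (length(keep_at) == 0) stop_dbm("no retained draws")
  npar <- max(unlist(idx))

  chains <- vector("list", spec$chains)
  accept_all <- vector("list", spec$chains)

  for (ch in seq_len(spec$chains)) {
    set.seed(spec$seed + ch)
    st <- init_state(ctx, spec)
    # contribution vectors
    c_glob <- numeric(n); c_reg <- numeric(n); c_cty <- numeric(n)
    c_rw0 <- numeric(n); c_rwr <- numeric(n); c_rwc <- numeric(n)
    c_age0 <- numeric(n); c_ager <- numeric(n); c_agec <- numeric(n)
    c_cov <- numeric(n); c_urb <- numeric(n); c_stu <- numeric(n)
    resid <- y
    draws <- matrix(NA_real_, length(keep_at), npar)
    keep_i <- 0
    mh_step <- stats::setNames(rep(0.5, length(SD_NAMES)), SD_NAMES)
    mh_acc <- mh_try <- stats::setNames(rep(0, length(SD_NAMES)), SD_NAMES)
    batch_acc <- batch_n <- mh_acc

    for (it in seq_len(n_iter)) {
      ## global intercept/slope
      if (p_lin > 0 && (use("intercept") || use("slope"))) {
        rp <- resid + c_glob
        prec <- XtWX_g + diag(1 / pr["fixed"]^2, ncol(Xg))
        b <- crossprod(Xg, w * rp)
        th <- draw_gaussian(prec, as.numeric(b))
        newc <- as.numeric(Xg %*% th)
        resid <- resid + c_glob - newc; c_glob <- newc
        st$a0 <- th[1]
        if (use("slope")) st$b0 <- th[2]
      }
      ## region / country linear deviations
      if (use("hierarchy")) {
        pd <- if (use("slope")) {
          c(1 / st$sd["a_region"]^2, 1 / st$sd["b_region"]^2)
        } else 1 / st$sd["a_region"]^2
        for (r in seq_len(ctx$R)) {
          ii <- ctx$idx_region[[r]]
          rp <- resid[ii] + c_reg[ii]
          b <- crossprod(Xg[ii, , drop = FALSE], w[ii] * rp)
          th <- draw_gaussian(XtWX_r[[r]] + diag(pd, ncol(Xg)),
                              as.numeric(b))
          newc <- as.numeric(Xg[ii, , drop = FALSE] %*% th)
          resid[ii] <- resid[ii] + c_reg[ii] - newc; c_reg[ii] <- newc
          st$ar[r] <- th[1]
          if (use("slope")) st$br[r] <- th[2]
        }
        pd <- if (use("slope")) {
          c(1 / st$sd["a_country"]^2, 1 / st$sd["b_country"]^2)
        } else 1 / st$sd["a_country"]^2
        for (cc in seq_len(ctx$C)) {
          ii <- ctx$idx_country[[cc]]
          rp <- resid[ii] + c_cty[ii]
          b <- crossprod(Xg[ii, , drop = FALSE], w[ii] * rp)
          th <- draw_gaussian(XtWX_c[[cc]] + diag(pd, ncol(Xg)),
                              as.numeric(b))
          newc <- as.numeric(Xg[ii, , drop = FALSE] %*% th)
          resid[ii] <- resid[ii] + c_cty[ii] - newc; c_cty[ii] <- newc
          st$ac[cc] <- th[1]
          if (use("slope")) st$bc[cc] <- th[2]
        }
      }
      ## RW2 blocks
      if (use("rw2")) {
        rp <- resid + c_rw0
        b <- crossprod(ctx$Z, sum_by(w * rp, ctx$ti, ctx$T))
        st$w0 <- draw_gaussian(Arw_g + ctx$P / st$sd["rw_global"]^2,
                               as.numeric(b))
        newc <- as.vector(ctx$Z %*% st$w0)[ctx$ti]
        resid <- resid + c_rw0 - newc; c_rw0 <- newc
        if (use("hierarchy")) {
          for (r in seq_len(ctx$R)) {
            ii <- ctx$idx_region[[r]]
            rp <- resid[ii] + c_rwr[ii]
            b <- crossprod(ctx$Z, sum_by(w[ii] * rp, ctx$ti[ii], ctx$T))
            st$wr[, r] <- draw_gaussian(
              Arw_r[[r]] + ctx$P / st$sd["rw_region"]^2, as.numeric(b))
            newc <- as.vector(ctx$Z %*% st$wr[, r])[ctx$ti[ii]]
            resid[ii] <- resid[ii] + c_rwr[ii] - newc; c_rwr[ii] <- newc
          }
          for (cc in seq_len(ctx$C)) {
            ii <- ctx$idx_country[[cc]]
            rp <- resid[ii] + c_rwc[ii]
            b <- crossprod(ctx$Z, sum_by(w[ii] * rp, ctx$ti[ii], ctx$T))
            st$wc[, cc] <- draw_gaussian(
              Arw_c[[cc]] + ctx$P / st$sd["rw_country"]^2, as.numeric(b))
            newc <- as.vector(ctx$Z %*% st$wc[, cc])[ctx$ti[ii]]
            resid[ii] <- resid[ii] + c_rwc[ii] - newc; c_rwc[ii] <- newc
          }
        }
      }
      ## age spline blocks
      if (use("age")) {
        rp <- resid + c_age0
        b <- crossprod(ctx$B_obs, w * rp)
        st$g0 <- draw_gaussian(Bw_g + diag(1 / pr["gamma0"]^2, ctx$K),
                               as.numeric(b))
        newc <- as.vector(ctx$B_obs %*% st$g0)
        resid <- resid + c_age0 - newc; c_age0 <- newc
        if (use("hierarchy")) {
          for (r in seq_len(ctx$R)) {
            ii <- ctx$idx_region[[r]]
            rp <- resid[ii] + c_ager[ii]
            b <- crossprod(ctx$B_obs[ii, , drop = FALSE], w[ii] * rp)
            st$gr[, r] <- draw_gaussian(
              Bw_r[[r]] + diag(1 / st$sd["g_region"]^2, ctx$K),
              as.numeric(b))
            newc <- as.vector(ctx$B_obs[ii, , drop = FALSE] %*% st$gr[, r])
            resid[ii] <- resid[ii] + c_ager[ii] - newc; c_ager[ii] <- newc
          }
          for (cc in seq_len(ctx$C)) {
            ii <- ctx$idx_country[[cc]]
            rp <- resid[ii] + c_agec[ii]
            b <- crossprod(ctx$B_obs[ii, , drop = FALSE], w[ii] * rp)
            st$gc[, cc] <- draw_gaussian(
              Bw_c[[cc]] + diag(1 / st$sd["g_country"]^2, ctx$K),
              as.numeric(b))
            newc <- as.vector(ctx$B_obs[ii, , drop = FALSE] %*% st$gc[, cc])
            resid[ii] <- resid[ii] + c_agec[ii] - newc; c_agec[ii] <- newc
          }
        }
      }
      ## coverage offsets
      if (use("coverage")) {
        for (lvl in c("subnational", "community")) {
          ii <- if (lvl == "subnational") idx_sub else idx_comm
          rp <- resid[ii] + st$delta[lvl]
          prec <- sum(w[ii]) + 1 / pr["offset"]^2
          b <- sum(w[ii] * rp)
          dn <- stats::rnorm(1, b / prec, 1 / sqrt(prec))
          resid[ii] <- resid[ii] + st$delta[lvl] - dn
          st$delta[lvl] <- dn
        }
        c_cov <- numeric(n)
        c_cov[idx_sub] <- st$delta["subnational"]
        c_cov[idx_comm] <- st$delta["community"]
      }
      ## urban coefficient
      if (use("urban")) {
        rp <- resid[idx_urb] + c_urb[idx_urb]
        prec <- sumW_urb + 1 / pr["urban"]^2
        b <- sum(w[idx_urb] * ctx$u[idx_urb] * rp)
        st$beta_u <- stats::rnorm(1, b / prec, 1 / sqrt(prec))
        newc <- st$beta_u * ctx$u[idx_urb]
        resid[idx_urb] <- resid[idx_urb] + c_urb[idx_urb] - newc
        c_urb[idx_urb] <- newc
      }
      ## study effects (vectorised over studies)
      if (use("study") && ctx$S > 0) {
        rp <- resid + c_stu
        tau <- st$sd[c("tau_national", "tau_subnational",
                       "tau_community")][cls_s]
        prec <- sumW_s + 1 / tau^2
        b <- sum_by(w * rp, ctx$si, ctx$S)
        st$e <- stats::rnorm(ctx$S, b / prec, 1 / sqrt(prec))
        newc <- st$e[ctx$si]
        resid <- resid + c_stu - newc; c_stu <- newc
      }
      ## sweep moves: Gibbs updates along translation-confounded
      ## directions (ancillarity-sufficiency interweaving).  Each move
      ## shifts one parameter and compensates in its partners, leaving
      ## the likelihood untouched; the conditional over the shift is
      ## Gaussian from the priors alone.  Without these, offsets and
      ## intercepts mix very slowly against the study effects.
      if (use("study") && ctx$S > 0) {
        tau_all <- st$sd[c("tau_national", "tau_subnational",
                           "tau_community")][cls_s]
        if (use("hierarchy")) {
          for (cc in seq_len(ctx$C)) {
            ss <- studies_of_country[[cc]]
            if (length(ss) == 0) next
            prec <- 1 / st$sd["a_country"]^2 + sum(1 / tau_all[ss]^2)
            b <- -st$ac[cc] / st$sd["a_country"]^2 +
              sum(st$e[ss] / tau_all[ss]^2)
            s <- stats::rnorm(1, b / prec, 1 / sqrt(prec))
            st$ac[cc] <- st$ac[cc] + s
            st$e[ss] <- st$e[ss] - s
            ii <- ctx$idx_country[[cc]]
            c_cty[ii] <- c_cty[ii] + s
            c_stu[ii] <- c_stu[ii] - s
          }
        }
        if (use("urban")) {
          ss <- which(u_study != 0)
          if (length(ss) > 0) {
            # beta_u + s with e_s - s*u_s leaves the likelihood invariant
            prec <- 1 / pr["urban"]^2 + sum(1 / tau_all[ss]^2)
            b <- -st$beta_u / pr["urban"]^2 +
              sum(u_study[ss] * st$e[ss] / tau_all[ss]^2)
            s <- stats::rnorm(1, b / prec, 1 / sqrt(prec))
            st$beta_u <- st$beta_u + s
            st$e[ss] <- st$e[ss] - s * u_study[ss]
            c_urb[idx_urb] <- c_urb[idx_urb] + s * ctx$u[idx_urb]
            c_stu <- st$e[ctx$si]
          }
        }
        if (use("coverage")) {
          for (k in 2:3) {
            lvl <- c("national", "subnational", "community")[k]
            ss <- which(cls_s == k)
            if (length(ss) == 0) next
            tau <- st$sd[paste0("tau_", lvl)]
            prec <- 1 / pr["offset"]^2 + length(ss) / tau^2
            b <- -st$delta[lvl] / pr["offset"]^2 + sum(st$e[ss]) / tau^2
            s <- stats::rnorm(1, b / prec, 1 / sqrt(prec))
            st$delta[lvl] <- st$delta[lvl] + s
            st$e[ss] <- st$e[ss] - s
            ii <- if (lvl == "subnational") idx_sub else idx_comm
            c_cov[ii] <- c_cov[ii] + s
            c_stu[ii] <- c_stu[ii] - s
          }
        }
      }
      if (use("hierarchy") && use("intercept")) {
        # a0 vs region deviations
        prec <- 1 / pr["fixed"]^2 + ctx$R / st$sd["a_region"]^2
        b <- -st$a0 / pr["fixed"]^2 + sum(st$ar) / st$sd["a_region"]^2
        s <- stats::rnorm(1, b / prec, 1 / sqrt(prec))
        st$a0 <- st$a0 + s
        st$ar <- st$ar - s
        c_glob <- c_glob + s
        c_reg <- c_reg - s
        # each region deviation vs its countries' deviations
        for (r in seq_len(ctx$R)) {
          ccs <- countries_in_region[[r]]
          prec <- 1 / st$sd["a_region"]^2 +
            length(ccs) / st$sd["a_country"]^2
          b <- -st$ar[r] / st$sd["a_region"]^2 +
            sum(st$ac[ccs]) / st$sd["a_country"]^2
          s <- stats::rnorm(1, b / prec, 1 / sqrt(prec))
          st$ar[r] <- st$ar[r] + s
          st$ac[ccs] <- st$ac[ccs] - s
          ii <- ctx$idx_region[[r]]
          c_reg[ii] <- c_reg[ii] + s
          c_cty[ii] <- c_cty[ii] - s
        }
      }
      ## SD parameters: adaptive log-scale MH
      if (!spec$fix_variances) {
        for (nm in active_sd) {
          qm <- sd_quad(nm, st, ctx, spec, cls_s = if (use("study")) cls_s)
          cur <- st$sd[nm]
          th0 <- log(cur)
          th1 <- th0 + stats::rnorm(1, 0, mh_step[nm])
          lp0 <- -qm$m * th0 - qm$quad / (2 * exp(2 * th0)) +
            log_half_normal(exp(th0), hn) + th0
          lp1 <- -qm$m * th1 - qm$quad / (2 * exp(2 * th1)) +
            log_half_normal(exp(th1), hn) + th1
          mh_try[nm] <- mh_try[nm] + 1
          batch_n[nm] <- batch_n[nm] + 1
          if (log(stats::runif(1)) < lp1 - lp0) {
            st$sd[nm] <- exp(th1)
            mh_acc[nm] <- mh_acc[nm] + 1
            batch_acc[nm] <- batch_acc[nm] + 1
          }
        }
        # Roberts-Rosenthal style adaptation during burn-in only
        if (it <= n_burn && it %% 50 == 0) {
          for (nm in active_sd) {
            if (batch_n[nm] > 0) {
              rate <- batch_acc[nm] / batch_n[nm]
              adj <- min(0.25, 1 / sqrt(it / 50))
              mh_step[nm] <- mh_step[nm] *
                exp(if (rate > 0.44) adj else -adj)
            }
          }
          batch_acc[] <- 0; batch_n[] <- 0
        }
      }
      ## store
      if (keep_i < length(keep_at) && it == keep_at[keep_i + 1]) {
        keep_i <- keep_i + 1
        row <- flatten_state(st, idx)
        if (any(!is.finite(row))) {
          stop_dbm(
            "divergence: non-finite parameter at iteration %d, chain %d (%s)",
            it, ch,
            paste(utils::capture.output(utils::str(st, max.level = 1)),
                  collapse = " "))
        }
        draws[keep_i, ] <- row
      }
    }
    chains[[ch]] <- draws
    accept_all[[ch]] <- ifelse(mh_try > 0, mh_acc / mh_try, NA_real_)
  }

  structure(list(
    spec = spec, ctx = ctx, par_index = idx, chains = chains,
    accept = accept_all,
    category = ctx$category, sex = ctx$sex
  ), class = "dbm_mcmc")
}

# sums of squares and counts driving each SD parameter's conditional
sd_quad <- function(nm, st, ctx, spec, cls_s = NULL) {
  Tm2 <- max(ctx$T - 2, 0)
  switch(nm,
    a_region = list(quad = sum(st$ar^2), m = ctx$R),
    b_region = list(quad = sum(st$br^2), m = ctx$R),
    a_country = list(quad = sum(st$ac^2), m = ctx$C),
    b_country = list(quad = sum(st$bc^2), m = ctx$C),
    rw_global = list(quad = as.numeric(crossprod(st$w0, ctx$P %*% st$w0)),
                     m = Tm2),
    rw_region = list(quad = sum(vapply(seq_len(ctx$R), function(r)
      as.numeric(crossprod(st$wr[, r], ctx$P %*% st$wr[, r])), 0)),
      m = Tm2 * ctx$R),
    rw_country = list(quad = sum(vapply(seq_len(ctx$C), function(cc)
      as.numeric(crossprod(st$wc[, cc], ctx$P %*% st$wc[, cc])), 0)),
      m = Tm2 * ctx$C),
    g_region = list(quad = sum(st$gr^2), m = ctx$K * ctx$R),
    g_country = list(quad = sum(st$gc^2), m = ctx$K * ctx$C),
    tau_national = list(quad = sum(st$e[cls_s == 1]^2),
                        m = sum(cls_s == 1)),
    tau_subnational = list(quad = sum(st$e[cls_s == 2]^2),
                           m = sum(cls_s == 2)),
    tau_community = list(quad = sum(st$e[cls_s == 3]^2),
                         m = sum(cls_s == 3)),
    stop_dbm("unknown sd parameter %s", nm)
  )
}
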