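# Convergence diagnostics: rank-normalised split R-hat and effective
# sample size, computed per monitored scalar.

#' Monitored scalar chains of a fit
#'
#' Extracts per-chain matrices of identifiable scalar summaries for
#' diagnostics: the country-level intercept sums (global + region +
#' country deviation, which mix well even when their components are
#' individually confounded), the coverage offsets, and the urban
#' coefficient.
#'
#' @param fit a `dbm_mcmc`
#' @return list of matrices, one per chain
#' @export
monitor_chains <- function(fit) {
  ctx <- fit$ctx
  idx <- fit$par_index
  lapply(fit$chains, function(m) {
    cols <- list()
    a0 <- if (!is.null(idx$a0)) m[, idx$a0] else 0
    if (!is.null(idx$ac)) {
      ar <- m[, idx$ar, drop = FALSE]
      ac <- m[, idx$ac, drop = FALSE]
      for (cc in seq_len(ctx$C)) {
        cols[[paste0("level_", ctx$countries[cc])]] <-
          a0 + ar[, ctx$region_of[cc]] + ac[, cc]
      }
    } else {
      cols[["a0"]] <- a0
    }
    if (!is.null(idx$delta)) {
      cols[["delta_sub"]] <- m[, idx$delta[1]]
      cols[["delta_comm"]] <- m[, idx$delta[2]]
    }
    if (!is.null(idx$beta_u)) cols[["beta_u"]] <- m[, idx$beta_u]
    do.call(cbind, cols)
  })
}

split_half <- function(chains) {
  N <- min(vapply(chains, length, 0L))
  h <- floor(N / 2)
  out <- list()
  for (x in chains) {
    out[[length(out) + 1]] <- x[seq_len(h)]
    out[[length(out) + 1]] <- x[seq.int(N - h + 1, N)]
  }
  out
}

rank_normalise <- function(chains) {
  all <- unlist(chains)
  S <- length(all)
  z <- stats::qnorm((rank(all, ties.method = "average") - 3 / 8) /
                      (S + 1 / 4))
  g <- factor(rep(seq_along(chains), lengths(chains)),
              levels = seq_along(chains))
  split(z, g)
}

rhat_of <- function(chains) {
  M <- length(chains)
  N <- length(chains[[1]])
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, stats::var, 0)
  W <- mean(vars)
  B <- N * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt((W * (N - 1) / N + B / N) / W)
}

ess_of <- function(chains) {
  M <- length(chains)
  N <- length(chains[[1]])
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, stats::var, 0)
  W <- mean(vars)
  B <- N * stats::var(means)
  var_plus <- W * (N - 1) / N + B / N
  if (var_plus == 0 || W == 0) return(NA_real_)
  # chain-averaged autocorrelations (Geyer initial monotone sequence)
  max_lag <- N - 1
  acovs <- vapply(chains, function(x) {
    a <- stats::acf(x, lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(max_lag + 1))
  rho <- 1 - (W - rowMeans(acovs)[-1]) / var_plus
  # pair sums, keep while positive and non-increasing
  tau <- 1
  prev_pair <- Inf
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    t <- t + 2
  }
  max(M * N / tau, 0)
}

#' Convergence diagnostics
#'
#' Rank-normalised split R-hat and effective sample size per monitored
#' scalar, with a flag for any scalar with R-hat above 1.05 or ESS below
#' 100.  Constant chains yield `NA` diagnostics and are flagged rather
#' than crashing.
#'
#' @param chains either a list of numeric vectors (one scalar summary per
#'   chain) or a list of equal-width matrices (iterations x parameters)
#' @param rhat_limit,ess_limit flagging thresholds
#' @return data.frame with `param`, `rhat`, `ess`, `flagged`
#' @export
convergence_diagnostics <- function(chains, rhat_limit = 1.05,
                                    ess_limit = 100) {
  if (!is.list(chains) || length(chains) < 2) {
    stop_dbm("need at least 2 chains for diagnostics")
  }
  if (is.matrix(chains[[1]])) {
    pn <- colnames(chains[[1]]) %||% paste0("par", seq_len(ncol(chains[[1]])))
    res <- lapply(seq_len(ncol(chains[[1]])), function(j) {
      convergence_diagnostics(lapply(chains, function(m) m[, j]),
                              rhat_limit, ess_limit)
    })
    out <- do.call(rbind, res)
    out$param <- pn
    return(out[c("param", "rhat", "ess", "flagged")])
  }
  if (min(vapply(chains, length, 0L)) < 4) {
    stop_dbm("need at least 4 draws per chain")
  }
  halves <- split_half(chains)
  z <- rank_normalise(halves)
  rhat <- rhat_of(z)
  ess <- ess_of(z)
  data.frame(
    param = "par1",
    rhat = rhat,
    ess = ess,
    flagged = is.na(rhat) || is.na(ess) || rhat > rhat_limit ||
      ess < ess_limit,
    stringsAsFactors = FALSE
  )
}
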