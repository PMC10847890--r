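#' Prior specification
#'
#' Per-parameter priors following the estimation framework: sex-specific
#' abundance gets a hierarchical `Normal(mu, sigma)` prior with
#' `mu ~ Uniform(1, 10000)` and `sigma ~ Uniform(1, 10000)` hyperpriors
#' (near-flat over the plausible range); survival and growth rate get
#' uniform priors whose bounds depend on the profile; the multiennial
#' mixture `psi` is `Uniform(0, 1)`. A parameter can be fixed by giving a
#' zero-width bound, e.g. `phi = c(0.9, 0.9)`.
#'
#' @param profile `"default"`, `"severe_decline"` (wider growth-rate
#'   bounds), or `"small_population"` (widest growth-rate bounds, higher
#'   survival ceiling).
#' @param phi,lam,psi,N_bounds,hyper_bounds Optional length-2 numeric
#'   overrides of the per-parameter bounds.
#' @return A `ckmr_priors` list of named `c(lower, upper)` bounds.
#' @export
ckmr_priors <- function(profile = c("default", "severe_decline",
                                    "small_population"),
                        phi = NULL, lam = NULL, psi = NULL,
                        N_bounds = NULL, hyper_bounds = NULL) {
  profile <- match.arg(profile)
  pr <- list(
    phi = switch(profile,
                 default = c(0.5, 0.95),
                 severe_decline = c(0.5, 0.95),
                 small_population = c(0.5, 0.99)),
    lam = switch(profile,
                 default = c(0.95, 1.05),
                 severe_decline = c(0.80, 1.20),
                 small_population = c(0.70, 1.30)),
    psi = c(0, 1),
    N = c(1, 10000),       # support of the abundance parameters
    hyper = c(1, 10000)    # Uniform hyperprior bounds for mu and sigma
  )
  if (!is.null(phi)) pr$phi <- phi
  if (!is.null(lam)) pr$lam <- lam
  if (!is.null(psi)) pr$psi <- psi
  if (!is.null(N_bounds)) pr$N <- N_bounds
  if (!is.null(hyper_bounds)) pr$hyper <- hyper_bounds
  structure(pr, class = "ckmr_priors")
}

#' MCMC configuration
#'
#' Chain protocol for the adaptive random-walk Metropolis sampler: number
#' of chains, burn-in iterations (during which the proposal covariance
#' adapts), post-burn-in iterations, and thinning. The defaults mirror the
#' estimation protocol of two chains, 50,000 burn-in and 40,000 posterior
#' iterations thinned by 20 (2,000 retained draws per chain).
#'
#' @param n_chains Number of chains.
#' @param burn_in Burn-in iterations per chain (discarded).
#' @param n_iter Post-burn-in iterations per chain.
#' @param thin Thinning interval; retained draws = `n_iter / thin`.
#' @param seed Integer seed; chain c uses sub-stream `seed + c`.
#' @param rhat_threshold Convergence gate on the split-chain Gelman-Rubin
#'   statistic.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 2L, burn_in = 50000L, n_iter = 40000L,
                        thin = 20L, seed = 1L, rhat_threshold = 1.01) {
  stopifnot(n_chains >= 1, burn_in >= 0, n_iter >= thin, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 n_iter = as.integer(n_iter), thin = as.integer(thin),
                 seed = as.integer(seed), rhat_threshold = rhat_threshold),
            class = "mcmc_config")
}

# ---- parameter transforms -------------------------------------------------
# Bounded parameters are sampled on an unconstrained scale through a scaled
# logistic map; abundances on the log scale. Log-prior densities include the
# transform Jacobians so the sampler targets the stated priors exactly.

to_bounded <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)
log_jac_bounded <- function(z, lo, hi) {
  log(hi - lo) + stats::plogis(z, log.p = TRUE) +
    stats::plogis(-z, log.p = TRUE)
}

# Parameter table for a fit: which free parameters exist given spec + data
free_params <- function(spec, priors, has_f, has_m) {
  pars <- character(0)
  if (has_f) pars <- c(pars, "N_f")
  if (has_m) pars <- c(pars, "N_m")
  if (has_f || has_m) pars <- c(pars, "mu", "sigma")
  pars <- c(pars, "phi")
  if (spec$variant != "base") pars <- c(pars, "lam")
  if (spec$variant == "multiennial") pars <- c(pars, "psi")
  fixed <- vapply(pars, function(p) {
    b <- param_bounds(p, priors)
    !is.null(b) && diff(b) == 0
  }, logical(1))
  list(names = pars, fixed = fixed)
}

param_bounds <- function(name, priors) {
  switch(name,
         N_f = , N_m = priors$N,
         mu = , sigma = priors$hyper,
         phi = priors$phi, lam = priors$lam, psi = priors$psi)
}

#' Fit a CKMR model by adaptive MCMC
#'
#' Estimates the free parameters of the chosen kinship-model variant from a
#' grouped comparison dataset using random-walk Metropolis with Haario-type
#' adaptive proposal covariance (adaptation during burn-in only, so the
#' retained chain targets the exact posterior). Honors the chain count,
#' burn-in, thinning, retained-draw count and seed of the
#' [mcmc_config()]; convergence is assessed per parameter with the
#' split-chain Gelman-Rubin statistic.
#'
#' @param dataset A `comparison_dataset` (at least two cohorts, at least
#'   one cell with comparisons).
#' @param spec A [model_spec()]; `t0` defaults to the dataset's.
#' @param priors A [ckmr_priors()].
#' @param mcmc An [mcmc_config()].
#' @return A `ckmr_fit` with elements `draws` (list of per-chain matrices,
#'   retained iterations x parameters), `summary` (median, 95% HPDI, Rhat
#'   per parameter), `converged`, `spec`, `priors`, `mcmc`, and
#'   `all_zero_positives` (flag: abundance unbounded by data).
#' @export
fit_ckmr <- function(dataset, spec, priors = ckmr_priors(),
                     mcmc = mcmc_config()) {
  cells <- dataset$cells
  if (!spec$uses_po) cells <- cells[cells$relationship != "PO", , drop = FALSE]
  if (nrow(cells) == 0L || sum(cells$R) == 0) {
    stop("degenerate dataset: no comparisons")
  }
  if (is.na(spec$t0)) spec$t0 <- dataset$t0
  all_zero <- sum(cells$Y) == 0
  if (all_zero) {
    warning("no positive kin pairs: abundance unbounded by data; ",
            "posterior will be driven to the prior upper bounds")
  }
  has_f <- any(cells$side == "maternal")
  has_m <- any(cells$side == "paternal")
  fp <- free_params(spec, priors, has_f, has_m)
  pars <- fp$names
  d_free <- sum(!fp$fixed)
  # ---- precomputed cell structure for fast likelihood evaluation ----
  str_hs_m <- cells$relationship == "HS" & cells$side == "maternal"
  str_hs_p <- cells$relationship == "HS" & cells$side == "paternal"
  str_po_m <- cells$relationship == "PO" & cells$side == "maternal"
  str_po_p <- cells$relationship == "PO" & cells$side == "paternal"
  ord <- c(which(str_hs_m), which(str_hs_p), which(str_po_m), which(str_po_p))
  cc <- cells[ord, , drop = FALSE]
  nmv <- c(sum(str_hs_m), sum(str_hs_p), sum(str_po_m), sum(str_po_p))
  idx_hm <- seq_len(nmv[1])
  idx_hp <- nmv[1] + seq_len(nmv[2])
  idx_pm <- nmv[1] + nmv[2] + seq_len(nmv[3])
  idx_pp <- nmv[1] + nmv[2] + nmv[3] + seq_len(nmv[4])
  surv_exp <- ifelse(cc$relationship == "HS", cc$delta,
                     pmax(cc$y_j - cc$c_i, 0L))
  gap <- cc$y_j - spec$t0
  Rv <- cc$R; Yv <- cc$Y
  lch <- lchoose(Rv, Yv)
  is_f <- c(rep(TRUE, nmv[1]), rep(FALSE, nmv[2]),
            rep(TRUE, nmv[3]), rep(FALSE, nmv[4]))
  multi_variant <- spec$variant == "multiennial"
  off_m <- if (multi_variant) (cc$delta[idx_hm] %% spec$a) != 0L else logical(0)
  a_fit <- spec$a
  # natural-parameter vector from the free unconstrained vector
  q_full <- c(N_f = NA_real_, N_m = NA_real_, mu = NA_real_,
              sigma = NA_real_, phi = NA_real_, lam = 1, psi = 0)
  for (p in pars[fp$fixed]) q_full[p] <- param_bounds(p, priors)[1]
  free <- pars[!fp$fixed]
  lo_b <- vapply(free, function(p) param_bounds(p, priors)[1], numeric(1))
  hi_b <- vapply(free, function(p) param_bounds(p, priors)[2], numeric(1))
  is_log <- free %in% c("N_f", "N_m")
  i_log <- which(is_log)
  i_bnd <- which(!is_log)
  # integer positions of each free parameter in the natural vector
  nat_pos <- match(free, names(q_full))
  pos_log <- nat_pos[i_log]
  pos_bnd <- nat_pos[i_bnd]
  lo_bnd <- lo_b[i_bnd]
  w_bnd <- hi_b[i_bnd] - lo_b[i_bnd]
  n_sel <- ifelse(is_f, 1L, 2L) # per-cell abundance selector (N_f, N_m)
  N_lo <- priors$N[1]; N_hi <- priors$N[2]
  plogis <- stats::plogis; dnorm <- stats::dnorm
  to_natural <- function(v) {
    q <- q_full
    q[pos_log] <- exp(v[i_log])
    q[pos_bnd] <- lo_bnd + w_bnd * plogis(v[i_bnd])
    q
  }
  log_post <- function(v) {
    q <- q_full
    lp <- 0
    if (length(i_log)) {
      N <- exp(v[i_log])
      if (any(N < N_lo | N > N_hi)) return(-Inf)
      q[pos_log] <- N
    }
    q[pos_bnd] <- lo_bnd + w_bnd * plogis(v[i_bnd])
    if (length(i_log)) {
      lp <- sum(dnorm(N, q[[3L]], q[[4L]], log = TRUE)) + sum(v[i_log])
    }
    if (length(i_bnd)) {
      lp <- lp + sum(plogis(v[i_bnd], log.p = TRUE) +
                     plogis(-v[i_bnd], log.p = TRUE))
    }
    denom <- c(q[[1L]], q[[2L]])[n_sel] * q[[6L]]^gap
    p <- q[[5L]]^surv_exp / denom
    if (multi_variant && nmv[1] > 0) {
      psi <- q[[7L]]
      fac <- a_fit / (a_fit + psi - a_fit * psi)
      p[idx_hm] <- p[idx_hm] * fac
      p[idx_hm][off_m] <- p[idx_hm][off_m] * (1 - psi)
    }
    if (any(p > 1)) return(-Inf)
    lp + ll_cells_fast(p, Rv, Yv, lch)
  }
  # independence refresh of the (mu, sigma) block: proposing from the prior
  # leaves an acceptance ratio that involves only the abundance-prior term,
  # so the likelihood need not be re-evaluated
  i_mu <- match("mu", free)
  i_sig <- match("sigma", free)
  hyper_refresh <- NULL
  if (!is.na(i_mu) && !is.na(i_sig) && length(i_log)) {
    hb <- priors$hyper
    hyper_refresh <- function(v, lp) {
      z1 <- stats::rlogis(2)
      mu0 <- to_bounded(v[i_mu], hb[1], hb[2])
      sg0 <- to_bounded(v[i_sig], hb[1], hb[2])
      mu1 <- to_bounded(z1[1], hb[1], hb[2])
      sg1 <- to_bounded(z1[2], hb[1], hb[2])
      N <- exp(v[i_log])
      d_prior <- sum(stats::dnorm(N, mu1, sg1, log = TRUE)) -
        sum(stats::dnorm(N, mu0, sg0, log = TRUE))
      if (log(stats::runif(1)) < d_prior) {
        d_jac <- sum(stats::plogis(z1, log.p = TRUE) +
                     stats::plogis(-z1, log.p = TRUE)) -
          sum(stats::plogis(v[c(i_mu, i_sig)], log.p = TRUE) +
              stats::plogis(-v[c(i_mu, i_sig)], log.p = TRUE))
        v[c(i_mu, i_sig)] <- z1
        lp <- lp + d_prior + d_jac
      }
      list(v = v, lp = lp)
    }
  }

  # crude starting center: method-of-moments abundance per side at phi mid
  start_vec <- function(jitter) {
    phi0 <- mean(priors$phi)
    v <- vapply(free, function(p) switch(p,
      N_f = log(moment_N(cells, "maternal", phi0, priors)),
      N_m = log(moment_N(cells, "paternal", phi0, priors)),
      mu = stats::qlogis(0.1), sigma = stats::qlogis(0.25),
      0), numeric(1))
    v + stats::rnorm(length(v), 0, jitter)
  }

  chain_seeds <- mcmc$seed + seq_len(mcmc$n_chains)
  draws <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(chain_seeds[ch])
    draws[[ch]] <- run_chain(start_vec(jitter = 0.15), log_post, free,
                             to_natural, mcmc$burn_in, mcmc$n_iter,
                             mcmc$thin, hyper_refresh)
  }
  par_out <- setdiff(colnames(draws[[1]]), "lp__")
  rh <- vapply(par_out, function(p) {
    rhat(lapply(draws, function(d) d[, p]))
  }, numeric(1))
  summ <- data.frame(
    parameter = par_out,
    median = vapply(par_out, function(p)
      stats::median(unlist(lapply(draws, function(d) d[, p]))), numeric(1)),
    hpdi_low = NA_real_, hpdi_high = NA_real_, rhat = rh
  )
  for (i in seq_len(nrow(summ))) {
    h <- hpdi(unlist(lapply(draws, function(d) d[, summ$parameter[i]])))
    summ$hpdi_low[i] <- h[1]; summ$hpdi_high[i] <- h[2]
  }
  rownames(summ) <- NULL
  structure(list(draws = draws, summary = summ,
                 converged = all(is.na(rh) | rh <= mcmc$rhat_threshold),
                 spec = spec, priors = priors, mcmc = mcmc,
                 all_zero_positives = all_zero),
            class = "ckmr_fit")
}

ll_cells_fast <- function(p, R, Y, lch) {
  pz <- p == 0
  if (any(pz)) {
    if (any(Y[pz] > 0)) return(-Inf)
    p <- p[!pz]; R <- R[!pz]; Y <- Y[!pz]; lch <- lch[!pz]
  }
  sum(lch + Y * log(p) + (R - Y) * log1p(-p))
}

moment_N <- function(cells, side, phi0, priors) {
  cc <- cells[cells$side == side & cells$relationship == "HS", , drop = FALSE]
  if (nrow(cc) == 0L || sum(cc$Y) == 0) {
    cc <- cells[cells$side == side, , drop = FALSE]
    if (sum(cc$Y) == 0) return(min(2000, priors$N[2]))
    return(max(2, min(sum(cc$R) / sum(cc$Y), priors$N[2] * 0.9)))
  }
  est <- sum(cc$R * phi0^cc$delta) / sum(cc$Y)
  max(2, min(est, priors$N[2] * 0.9))
}

# Adaptive random-walk Metropolis with Haario covariance adaptation during
# burn-in. The abundance hyperparameters additionally get an independence
# Metropolis refresh each iteration, proposing from their prior (a standard
# logistic on the unconstrained scale): the weakly identified (mu, sigma)
# block otherwise dominates the autocorrelation time.
run_chain <- function(theta, lp_fun, free, to_natural,
                      burn_in, n_iter, thin, hyper_refresh = NULL) {
  d <- length(free)
  cur <- theta
  cur_lp <- lp_fun(cur)
  if (!is.finite(cur_lp)) {
    # fall back to a prior-central start
    cur <- rep(0, d); names(cur) <- free
    cur_lp <- lp_fun(cur)
  }
  sd0 <- 0.1
  S <- diag(sd0^2, d)
  chol_S <- chol(S)
  mean_run <- cur
  cov_run <- diag(1e-4, d)
  eps <- 1e-8
  sc <- 2.38^2 / d
  n_keep <- n_iter %/% thin
  out <- matrix(NA_real_, n_keep, d + 1L)
  keep_row <- 0L
  total <- burn_in + n_iter
  for (it in seq_len(total)) {
    prop <- cur + drop(stats::rnorm(d) %*% chol_S)
    prop_lp <- lp_fun(prop)
    if (is.finite(prop_lp) &&
        log(stats::runif(1)) < prop_lp - cur_lp) {
      cur <- prop
      cur_lp <- prop_lp
    }
    if (!is.null(hyper_refresh)) {
      hr <- hyper_refresh(cur, cur_lp)
      cur <- hr$v
      cur_lp <- hr$lp
    }
    if (it <= burn_in) {
      # running mean / covariance for the adaptive proposal
      w <- 1 / it
      delta <- cur - mean_run
      mean_run <- mean_run + w * delta
      cov_run <- (1 - w) * (cov_run + w * tcrossprod(delta))
      if (it >= 200L && it %% 50L == 0L) {
        S_try <- sc * cov_run + diag(eps, d)
        ch <- tryCatch(chol(S_try), error = function(e) NULL)
        if (!is.null(ch)) chol_S <- ch
      }
    } else {
      k <- it - burn_in
      if (k %% thin == 0L) {
        keep_row <- keep_row + 1L
        out[keep_row, ] <- c(to_natural(cur)[free], cur_lp)
      }
    }
  }
  colnames(out) <- c(free, "lp__")
  out
}

#' Split-chain Gelman-Rubin statistic
#'
#' Potential scale reduction factor with each chain split in half, so a
#' single drifting chain is also flagged.
#'
#' @param draws_by_chain List of numeric vectors, one per chain.
#' @return The Rhat statistic (NA for constant draws).
#' @export
rhat <- function(draws_by_chain) {
  halves <- list()
  for (d in draws_by_chain) {
    n <- length(d) %/% 2L
    halves <- c(halves, list(d[seq_len(n)], d[n + seq_len(n)]))
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Highest posterior density interval
#'
#' The narrowest interval containing the requested posterior mass.
#'
#' @param draws Numeric posterior draws.
#' @param mass Probability mass (default 0.95).
#' @return `c(lower, upper)`.
#' @export
hpdi <- function(draws, mass = 0.95) {
  x <- sort(draws)
  n <- length(x)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Derived abundance trajectories
#'
#' Per retained draw, `N_s(t) = N_s(t0) * lam^(t - t0)` for each requested
#' year and available sex; under the multiennial variant the effective
#' number of female breeders is also derived via [effective_breeders()].
#' Summaries are posterior medians with 95% HPDIs.
#'
#' @param fit A `ckmr_fit`.
#' @param years Target years.
#' @return A data.frame: year, quantity, median, hpdi_low, hpdi_high.
#' @export
derive_abundance <- function(fit, years) {
  dr <- do.call(rbind, fit$draws)
  t0 <- fit$spec$t0
  lam <- if ("lam" %in% colnames(dr)) dr[, "lam"] else 1
  rows <- list()
  for (t in years) {
    for (q in intersect(c("N_f", "N_m"), colnames(dr))) {
      Nt <- dr[, q] * lam^(t - t0)
      h <- hpdi(Nt)
      rows[[length(rows) + 1L]] <- data.frame(
        year = t, quantity = q, median = stats::median(Nt),
        hpdi_low = h[1], hpdi_high = h[2])
      if (q == "N_f" && fit$spec$variant == "multiennial") {
        psi <- if ("psi" %in% colnames(dr)) dr[, "psi"] else 0
        Ne <- effective_breeders(Nt, psi, fit$spec$a)
        h <- hpdi(Ne)
        rows[[length(rows) + 1L]] <- data.frame(
          year = t, quantity = "N_f_breeders", median = stats::median(Ne),
          hpdi_low = h[1], hpdi_high = h[2])
      }
    }
  }
  do.call(rbind, rows)
}

#' Posterior cross-correlations
#'
#' Pearson correlations between pooled post-burn-in draws of each pair of
#' model parameters within one fit.
#'
#' @param fit A `ckmr_fit`.
#' @return A correlation matrix over the fit's free parameters.
#' @export
cross_correlation <- function(fit) {
  dr <- do.call(rbind, fit$draws)
  dr <- dr[, setdiff(colnames(dr), "lp__"), drop = FALSE]
  keep <- apply(dr, 2, function(x) stats::sd(x) > 0)
  stats::cor(dr[, keep, drop = FALSE])
}

#' @export
print.ckmr_fit <- function(x, ...) {
  cat(sprintf("<ckmr_fit> variant = %s%s; %d chain(s); converged: %s\n",
              x$spec$variant, if (x$spec$uses_po) " + PO" else "",
              length(x$draws), x$converged))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
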