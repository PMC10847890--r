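#' Scenario configuration
#'
#' Maps a scenario id onto the corresponding data-generating-model and
#' estimation settings: population trend regimes (stable, +/-1% per year,
#' severe decline), female breeding periodicity (annual, biennial,
#' triennial, biennial with 10% off-cycle breeding and 10% on-cycle
#' failure), aging-error severity, and the naive versus adapted model pair
#' fit to each sampled dataset.
#'
#' Scenario ids: `1.1` validation, `1.2` avuncular contamination,
#' `2.1`/`2.2`/`2.3`/`2.4` declining / growing / severely declining /
#' stable population with growth-adapted estimation, `3.1`-`3.4` biennial /
#' biennial-with-off-cycle / triennial / annual breeding with
#' multiennial-adapted estimation, `4.1`-`4.3` aging error at 5/10/20% CV.
#'
#' @param scenario_id Character id, e.g. `"2.1"`.
#' @param replicates Number of replicate populations.
#' @param seed Integer master seed; replicates use derived sub-seeds.
#' @param intensity Sampling intensity (fraction of total census per year).
#' @param schemes Character vector of sampling schemes to run.
#' @param n_years,census Simulation length and founder census.
#' @param mcmc An [mcmc_config()] (scale `burn_in`/`n_iter` down for
#'   exploratory runs).
#' @param breeding For scenarios 4.x: `"annual"` or `"biennial"`
#'   data-generating model.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario_id, replicates = 500L, seed = 1L,
                            intensity = 0.015,
                            schemes = c("target_yoy", "sample_juveniles",
                                        "sample_all_ages"),
                            n_years = 90L, census = 10270L,
                            mcmc = mcmc_config(),
                            breeding = c("annual", "biennial")) {
  breeding <- match.arg(breeding)
  known <- c("1.1", "1.2", "2.1", "2.2", "2.3", "2.4",
             "3.1", "3.2", "3.3", "3.4", "4.1", "4.2", "4.3")
  if (!scenario_id %in% known) stop("unknown scenario id: ", scenario_id)
  structure(list(scenario_id = scenario_id, replicates = as.integer(replicates),
                 seed = as.integer(seed), intensity = intensity,
                 schemes = schemes, n_years = as.integer(n_years),
                 census = as.integer(census), mcmc = mcmc,
                 breeding = breeding),
            class = "scenario_config")
}

# life history + regime + model plan for a scenario id
scenario_plan <- function(cfg) {
  id <- cfg$scenario_id
  lh_args <- list()
  regime <- NULL
  priors_adapted <- ckmr_priors("default")
  cv_old <- NULL
  if (id %in% c("3.1", "3.2")) {
    lh_args <- list(breeding_cycle_a = 2L, fraction_multiennial = 1)
    if (id == "3.2") lh_args <- c(lh_args, list(p_offcycle = 0.10, p_fail = 0.10))
  } else if (id == "3.3") {
    lh_args <- list(breeding_cycle_a = 3L, fraction_multiennial = 1)
  } else if (id == "2.1") {
    regime <- mortality_regime(adjustment = 0.01)
  } else if (id == "2.2") {
    regime <- mortality_regime(adjustment = -0.01)
  } else if (id == "2.3") {
    # ten elevated mortality transitions spanning the final 10-year window
    regime <- mortality_regime(years = (cfg$n_years - 10L):(cfg$n_years - 1L),
                               stochastic_range = c(0.04, 0.07))
    priors_adapted <- ckmr_priors("severe_decline")
  } else if (id %in% c("4.1", "4.2", "4.3")) {
    cv_old <- c("4.1" = 0.05, "4.2" = 0.10, "4.3" = 0.20)[[id]]
    if (cfg$breeding == "biennial") {
      lh_args <- list(breeding_cycle_a = 2L, fraction_multiennial = 1)
    }
  }
  a_dgm <- if (!is.null(lh_args$breeding_cycle_a)) lh_args$breeding_cycle_a else 1L

  models <- switch(substr(id, 1, 1),
    "1" = list(naive = list(variant = "base", priors = ckmr_priors("default"))),
    "2" = list(naive = list(variant = "base", priors = ckmr_priors("default")),
               adapted = list(variant = "growth", priors = priors_adapted)),
    "3" = {
      a_fit <- if (a_dgm > 1L) a_dgm else 2L
      m <- list(naive = list(variant = "growth", priors = priors_adapted),
                adapted = list(variant = "multiennial", a = a_fit,
                               priors = priors_adapted))
      if (a_dgm > 1L) {
        m$naive_filtered <- list(variant = "growth", priors = priors_adapted,
                                 filter_offcycle_a = a_dgm)
      }
      m
    },
    "4" = {
      if (cfg$breeding == "biennial") {
        list(adapted = list(variant = "multiennial", a = 2L,
                            priors = priors_adapted))
      } else {
        list(adapted = list(variant = "growth", priors = priors_adapted))
      }
    })
  list(lh_args = lh_args, regime = regime, cv_old = cv_old,
       models = models, a_dgm = a_dgm,
       avuncular = identical(id, "1.2"))
}

derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a simulation scenario
#'
#' For each replicate: simulate the population, sample it under each
#' scheme, apply aging error where the scenario calls for it, reduce to
#' independent comparison units, build the half-sibling (and, for the
#' all-ages scheme, parent-offspring) comparison matrices, fit the
#' scenario's naive and adapted models, and record posterior summaries
#' against the pedigree truths. Replicates whose population goes extinct
#' are re-simulated with a fresh sub-seed; fits failing the Gelman-Rubin
#' gate are flagged (`converged = FALSE`) and excluded from aggregates.
#'
#' @param cfg A [scenario_config()].
#' @return A list with `replicates` (one row per replicate x scheme x
#'   model) and `aggregate` (mean relative biases, abundance CV, mean kin
#'   pair counts, mean posterior cross-correlations).
#' @export
run_scenario <- function(cfg) {
  plan <- scenario_plan(cfg)
  lh <- do.call(life_history, plan$lh_args)
  sample_years <- (cfg$n_years - 3L):cfg$n_years
  seeds <- derive_seeds(cfg$seed, 4L * cfg$replicates)
  rows <- list()
  si <- 0L
  for (r in seq_len(cfg$replicates)) {
    sim <- NULL
    while (is.null(sim)) {
      si <- si + 1L
      if (si > length(seeds)) stop("exhausted sub-seeds (mass extinction?)")
      sim <- tryCatch(
        run_simulation(lh, plan$regime, n_years = cfg$n_years,
                       total_census = cfg$census, seed = seeds[si],
                       snapshot_years = sample_years),
        error = function(e) NULL)
    }
    truths <- replicate_truths(sim, lh, sample_years)
    for (sch in cfg$schemes) {
      scheme <- sampling_scheme(sch, intensity = cfg$intensity,
                                years = sample_years)
      samples <- draw_samples(sim, scheme)
      if (!is.null(plan$cv_old)) {
        curve <- growth_curve(cv_old = plan$cv_old)
        samples <- apply_aging_error(samples, curve, max_age = lh$max_age)
      }
      ded <- dedupe_samples(samples)
      ds <- tryCatch(build_comparison_set(ded, lh, uses_po =
                                            (sch == "sample_all_ages"),
                                          avuncular = plan$avuncular,
                                          ped = if (plan$avuncular) pedigree(sim)),
                     error = function(e) NULL)
      if (is.null(ds)) next
      truths$psi_true <- truth_psi(sim, ded)
      for (mn in names(plan$models)) {
        m <- plan$models[[mn]]
        row <- fit_one_model(ds, m, cfg, sch, truths, lh)
        row$replicate <- r
        row$scheme <- sch
        row$model <- mn
        row$n_samples <- nrow(samples)
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  reps <- do.call(rbind, rows)
  rownames(reps) <- NULL
  list(replicates = reps, aggregate = aggregate_scenario(reps))
}

build_comparison_set <- function(ded, lh, uses_po = FALSE,
                                 avuncular = FALSE, ped = NULL) {
  hs <- build_hs_matrix(ded, ped = ped,
                        include_avuncular_as_hsp = avuncular)
  if (uses_po) {
    po <- build_po_matrix(ded, maturity_age = lh$maturity_age)
    combine_comparisons(hs, po)
  } else hs
}

replicate_truths <- function(sim, lh, sample_years) {
  t_est <- max(sample_years)
  list(
    N_f_true = mature_count(sim, t_est, "female"),
    N_m_true = mature_count(sim, t_est, "male"),
    lambda_true = realized_lambda(sim, t_est - 10L, t_est),
    phi_true = lh$survival_adult,
    t_est = t_est
  )
}

fit_one_model <- function(ds, m, cfg, sch, truths, lh) {
  dsm <- ds
  if (!is.null(m$filter_offcycle_a)) {
    dsm <- filter_offcycle(ds, m$filter_offcycle_a)
  }
  spec <- model_spec(m$variant, uses_po = (sch == "sample_all_ages"),
                     a = if (!is.null(m$a)) m$a else 1L)
  fit <- fit_ckmr(dsm, spec, priors = m$priors, mcmc = cfg$mcmc)
  summarize_fit_row(fit, dsm, m, truths, lh)
}

summarize_fit_row <- function(fit, dsm, m, truths, lh) {
  t_est <- truths$t_est
  med <- function(p) {
    s <- fit$summary
    if (p %in% s$parameter) s$median[s$parameter == p] else NA_real_
  }
  der <- derive_abundance(fit, t_est)
  dN <- function(q) {
    v <- der$median[der$quantity == q]
    if (length(v)) v else NA_real_
  }
  N_f_t <- dN("N_f")
  N_m_t <- dN("N_m")
  # the off-cycle-filtered naive model estimates effective breeders; total
  # females are recovered by multiplying by the breeding cycle
  if (!is.null(m$filter_offcycle_a) && !is.na(N_f_t)) {
    N_f_t <- N_f_t * m$filter_offcycle_a
  }
  cc <- tryCatch(cross_correlation(fit), error = function(e) NULL)
  get_cc <- function(p1, p2) {
    if (is.null(cc) || !(p1 %in% rownames(cc)) || !(p2 %in% colnames(cc)))
      return(NA_real_)
    cc[p1, p2]
  }
  hs <- dsm$cells[dsm$cells$relationship == "HS", ]
  data.frame(
    N_f_est = N_f_t, N_m_est = N_m_t,
    phi_est = med("phi"), lambda_est = med("lam"), psi_est = med("psi"),
    N_f_true = truths$N_f_true, N_m_true = truths$N_m_true,
    phi_true = truths$phi_true, lambda_true = truths$lambda_true,
    psi_true = truths$psi_true,
    bias_N_f = (N_f_t - truths$N_f_true) / truths$N_f_true,
    bias_N_m = (N_m_t - truths$N_m_true) / truths$N_m_true,
    bias_phi = (med("phi") - truths$phi_true) / truths$phi_true,
    bias_lambda = (med("lam") - truths$lambda_true) / truths$lambda_true,
    mhsp = sum(hs$Y[hs$side == "maternal"]),
    phsp = sum(hs$Y[hs$side == "paternal"]),
    cor_Nf_phi = get_cc("N_f", "phi"),
    cor_Nf_lam = get_cc("N_f", "lam"),
    converged = fit$converged
  )
}

aggregate_scenario <- function(reps) {
  ok <- reps[reps$converged, , drop = FALSE]
  if (nrow(ok) == 0L) return(NULL)
  agg <- function(x) mean(x, na.rm = TRUE)
  out <- stats::aggregate(
    cbind(bias_N_f, bias_N_m, bias_phi, bias_lambda, mhsp, phsp,
          cor_Nf_phi, cor_Nf_lam) ~ scheme + model,
    data = ok, FUN = agg, na.action = stats::na.pass)
  cvs <- stats::aggregate(N_f_est ~ scheme + model, data = ok,
                          FUN = function(x) stats::sd(x) / mean(x))
  names(cvs)[3] <- "cv_N_f"
  merge(out, cvs, by = c("scheme", "model"), all.x = TRUE)
}

#' Realized proportion of sampled maternal half-sibling pairs from
#' multiennial mothers
#'
#' Among the true cross-cohort maternal half-sibling pairs in the (deduped)
#' sampled set, the fraction whose shared mother is a multiennial breeder —
#' the quantity the multiennial model's `psi` is compared against.
#'
#' @param sim A `ckmr_simulation`.
#' @param samples Deduped `Sample` data.frame.
#' @return A proportion (NaN when no maternal half-sibling pairs exist).
#' @export
truth_psi <- function(sim, samples) {
  pop_materialize(sim$pop)
  s <- offspring_pool(samples)
  ok <- !is.na(s$mother_id)
  if (!any(ok)) return(NaN)
  dt <- data.table::data.table(m = s$mother_id[ok],
                               by = s$assigned_birth_year[ok])
  cnt <- dt[, .N, by = c("m", "by")]
  pr <- merge(cnt, cnt, by = "m", allow.cartesian = TRUE)
  pr <- pr[pr$by.x < pr$by.y, ]
  if (nrow(pr) == 0L) return(NaN)
  pairs <- pr$N.x * pr$N.y
  multi <- sim$pop$multi[pr$m]
  sum(pairs[multi]) / sum(pairs)
}

#' Sliding-window CKMR fit
#'
#' Restricts the sample set to capture years within a window ending at
#' `year_t`, re-anchors the reference year to the earliest `y_j` of the
#' restricted comparison matrix, fits the multiennial model, and derives
#' female abundance and effective breeders in `year_t`. Fits whose window
#' contains fewer than two on-cycle birth-year gaps are flagged
#' low-information (with a biennial cycle a 3-year window holds only the
#' single informative gap of 2 years).
#'
#' @param samples A `Sample` data.frame (all years).
#' @param window `"all"`, or an integer window length in years.
#' @param year_t Most recent sampling year of the fit.
#' @param a Breeding interval for the multiennial model.
#' @param priors A [ckmr_priors()] (small-population profile fits the
#'   intended use).
#' @param mcmc An [mcmc_config()].
#' @param sides Which half-sibling sides enter the likelihood.
#' @param collapse_full_sibs Passed to [dedupe_samples()].
#' @return A `ckmr_fit` with extra elements `derived` (abundance and
#'   effective breeders at `year_t`) and `low_information`.
#' @export
sliding_window_fit <- function(samples, window = "all", year_t,
                               a = 2L, priors = ckmr_priors("small_population"),
                               mcmc = mcmc_config(), sides = "maternal",
                               collapse_full_sibs = FALSE) {
  keep <- samples$capture_year <= year_t
  if (!identical(window, "all")) {
    keep <- keep & samples$capture_year > year_t - as.integer(window)
  }
  sub <- samples[keep, , drop = FALSE]
  ded <- dedupe_samples(sub, collapse_full_sibs = collapse_full_sibs)
  hs <- build_hs_matrix(ded)
  cells <- hs$cells[hs$cells$side %in% sides, , drop = FALSE]
  ds <- new_comparison_dataset(cells, hs$t0)
  spec <- model_spec("multiennial", uses_po = FALSE, a = a)
  fit <- fit_ckmr(ds, spec, priors = priors, mcmc = mcmc)
  fit$derived <- derive_abundance(fit, year_t)
  on_cycle_deltas <- unique(cells$delta[cells$delta %% a == 0])
  fit$low_information <- length(on_cycle_deltas) < 2L
  fit
}

#' Downsampled refits
#'
#' Randomly retains a fraction of the samples from each capture year,
#' refits, and averages the posterior medians and 95% HPDI bounds over the
#' downsampling iterations.
#'
#' @param samples A `Sample` data.frame.
#' @param fit_fun Function taking a `Sample` data.frame and returning a
#'   `ckmr_fit`.
#' @param fraction Per-year retention fraction.
#' @param iterations Number of downsampling iterations.
#' @param seed Integer seed.
#' @return A data.frame of averaged parameter summaries plus the list of
#'   individual fits (as attribute `fits`).
#' @export
downsample_fit <- function(samples, fit_fun, fraction = 0.30,
                           iterations = 50L, seed = 1L) {
  seeds <- derive_seeds(seed, iterations)
  fits <- vector("list", iterations)
  for (i in seq_len(iterations)) {
    set.seed(seeds[i])
    keep <- unlist(lapply(split(seq_len(nrow(samples)),
                                samples$capture_year), function(idx) {
      k <- as.integer(round_half_away(fraction * length(idx)))
      if (k >= length(idx)) idx else sample(idx, k)
    }), use.names = FALSE)
    fits[[i]] <- fit_fun(samples[sort(keep), , drop = FALSE])
  }
  summs <- lapply(fits, function(f) f$summary)
  pars <- summs[[1]]$parameter
  avg <- data.frame(
    parameter = pars,
    median = rowMeans(sapply(summs, function(s) s$median[match(pars, s$parameter)])),
    hpdi_low = rowMeans(sapply(summs, function(s) s$hpdi_low[match(pars, s$parameter)])),
    hpdi_high = rowMeans(sapply(summs, function(s) s$hpdi_high[match(pars, s$parameter)]))
  )
  attr(avg, "fits") <- fits
  avg
}

#' Small-nursery life-history profile
#'
#' A biennially breeding population of roughly fifty adult females with
#' stochastic off-cycle breeding, intended for the heavily sampled
#' small-nursery analyses (90% of young-of-year sampled annually).
#'
#' @param adult_females Target number of mature females.
#' @return A list with `life_history` and the implied total census.
#' @export
small_nursery_profile <- function(adult_females = 50) {
  lh <- life_history(breeding_cycle_a = 2L, fraction_multiennial = 1,
                     p_offcycle = 0.10, p_fail = 0.10)
  w <- stable_age_distribution(lh)
  adult_frac <- sum(w[(lh$maturity_age + 1L):(lh$max_age + 1L)])
  census <- as.integer(round(adult_females / (adult_frac * 0.5)))
  list(life_history = lh, census = census)
}
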