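#' Life-history configuration
#'
#' Bundles the demographic parameters of the individual-based simulator:
#' stage-structured survival (young-of-year, juvenile, adult), knife-edged
#' maturity, litter composition (number of sires per female per breeding
#' event and pups per sire), sex ratio at birth, and the female breeding
#' cycle (annual, biennial or triennial, with an optional mixture of annual
#' and multiennial breeders and stochastic off-cycle breeding).
#'
#' Defaults emulate a long-lived coastal shark: maturity at 12, longevity 50,
#' 1-3 sires per litter and 2-3 pups per sire (so a female's yearly litter is
#' always 2-9 pups), juvenile and adult annual survival 0.90, and
#' young-of-year survival solved so that the implied Leslie matrix is
#' stationary (see [solve_stable_yoy_survival()]).
#'
#' @param max_age Maximum attainable age in years; individuals older than
#'   this die deterministically.
#' @param maturity_age Age (years) at which both sexes become reproductive.
#' @param mates_per_female Named numeric vector of probabilities over the
#'   number of distinct sires a breeding female mates with in one breeding
#'   event (names are the counts).
#' @param pups_per_mating Probabilities over pups produced per (female, sire)
#'   pairing, same format.
#' @param survival_yoy Annual survival probability at age 0, or `NA` to solve
#'   for the value that makes the population stationary.
#' @param survival_juvenile Annual survival, ages 1 to `maturity_age - 1`.
#' @param survival_adult Annual survival, ages `maturity_age` to `max_age`.
#' @param sex_ratio_at_birth Probability that a newborn is female.
#' @param breeding_cycle_a Integer breeding interval `a` (1 = annual,
#'   2 = biennial, 3 = triennial).
#' @param fraction_multiennial Proportion of females breeding every
#'   `breeding_cycle_a` years (the true psi); the remainder breed annually.
#' @param p_offcycle Probability that an off-cycle multiennial female breeds
#'   anyway in a given year (she returns to her schedule afterwards).
#' @param p_fail Probability that an on-cycle multiennial female fails to
#'   breed in a given year.
#'
#' @return An object of class `life_history` (a validated list).
#' @export
life_history <- function(max_age = 50L,
                         maturity_age = 12L,
                         mates_per_female = c("1" = 1/3, "2" = 1/3, "3" = 1/3),
                         pups_per_mating = c("2" = 1/2, "3" = 1/2),
                         survival_yoy = NA_real_,
                         survival_juvenile = 0.90,
                         survival_adult = 0.90,
                         sex_ratio_at_birth = 0.5,
                         breeding_cycle_a = 1L,
                         fraction_multiennial = 0,
                         p_offcycle = 0,
                         p_fail = 0) {
  cfg <- list(
    max_age = as.integer(max_age),
    maturity_age = as.integer(maturity_age),
    mates_per_female = mates_per_female,
    pups_per_mating = pups_per_mating,
    survival_yoy = survival_yoy,
    survival_juvenile = survival_juvenile,
    survival_adult = survival_adult,
    sex_ratio_at_birth = sex_ratio_at_birth,
    breeding_cycle_a = as.integer(breeding_cycle_a),
    fraction_multiennial = fraction_multiennial,
    p_offcycle = p_offcycle,
    p_fail = p_fail
  )
  class(cfg) <- "life_history"
  validate_life_history(cfg)
  if (is.na(cfg$survival_yoy)) {
    cfg$survival_yoy <- solve_stable_yoy_survival(cfg)
  }
  cfg
}

validate_life_history <- function(cfg) {
  stopifnot(inherits(cfg, "life_history"))
  probs <- c(cfg$survival_juvenile, cfg$survival_adult,
             cfg$sex_ratio_at_birth, cfg$fraction_multiennial,
             cfg$p_offcycle, cfg$p_fail)
  if (!is.na(cfg$survival_yoy)) probs <- c(probs, cfg$survival_yoy)
  if (any(probs < 0 | probs > 1)) {
    stop("all life-history probabilities must lie in [0, 1]")
  }
  if (cfg$maturity_age >= cfg$max_age) {
    stop("maturity_age must be strictly less than max_age")
  }
  if (cfg$breeding_cycle_a < 1L) stop("breeding_cycle_a must be >= 1")
  for (nm in c("mates_per_female", "pups_per_mating")) {
    d <- cfg[[nm]]
    if (is.null(names(d)) || any(d < 0) || abs(sum(d) - 1) > 1e-8) {
      stop(nm, " must be a named probability vector summing to 1")
    }
  }
  mates <- as.integer(names(cfg$mates_per_female)[cfg$mates_per_female > 0])
  pups <- as.integer(names(cfg$pups_per_mating)[cfg$pups_per_mating > 0])
  if (min(mates) * min(pups) < 2L || max(mates) * max(pups) > 9L) {
    stop("yearly litter size must stay within [2, 9]")
  }
  invisible(cfg)
}

# expected pups per breeding female per breeding event
mean_litter_size <- function(cfg) {
  mates <- as.numeric(names(cfg$mates_per_female))
  pups <- as.numeric(names(cfg$pups_per_mating))
  sum(mates * cfg$mates_per_female) * sum(pups * cfg$pups_per_mating)
}

# expected pups per mature female per YEAR, accounting for the breeding
# cycle: a fraction psi breed every a-th year (plus off-cycle extras, minus
# on-cycle failures), the rest annually.
mean_annual_fecundity <- function(cfg) {
  a <- cfg$breeding_cycle_a
  psi <- cfg$fraction_multiennial
  p_breed_multi <- (1 - cfg$p_fail) / a + cfg$p_offcycle * (a - 1) / a
  p_breed <- (1 - psi) + psi * p_breed_multi
  p_breed * mean_litter_size(cfg)
}

#' Mortality regime
#'
#' A schedule of additive adjustments to juvenile and adult annual
#' *mortality* (so a positive adjustment lowers survival). Year-specific
#' adjustments may be fixed, or drawn uniformly per year from
#' `stochastic_range` for the years listed in `years`.
#'
#' @param adjustment Fixed additive mortality adjustment (signed) applied to
#'   juvenile and adult stages for every year in `years`.
#' @param years Integer years the regime applies to; `NULL` means all years.
#' @param stochastic_range Optional length-2 numeric; when given, the
#'   per-year adjustment is drawn from `Uniform(range[1], range[2])` instead
#'   of using `adjustment`.
#' @return An object of class `mortality_regime`.
#' @export
mortality_regime <- function(adjustment = 0, years = NULL,
                             stochastic_range = NULL) {
  if (!is.null(stochastic_range)) {
    stopifnot(length(stochastic_range) == 2L,
              stochastic_range[1] <= stochastic_range[2])
  }
  structure(list(adjustment = adjustment,
                 years = if (is.null(years)) NULL else as.integer(years),
                 stochastic_range = stochastic_range),
            class = "mortality_regime")
}

# realize the mortality adjustment for one year (may consume RNG)
regime_adjustment <- function(regime, year) {
  if (is.null(regime)) return(0)
  if (!is.null(regime$years) && !(year %in% regime$years)) return(0)
  if (!is.null(regime$stochastic_range)) {
    stats::runif(1, regime$stochastic_range[1], regime$stochastic_range[2])
  } else {
    regime$adjustment
  }
}

#' Read / write a scenario configuration file
#'
#' Configuration files are YAML `key: value` text covering the
#' [life_history()] fields plus, optionally, `n_years`, `census`, `seed`
#' and a `regime:` block ([mortality_regime()] fields).
#'
#' @param path File path.
#' @return `read_config()` returns a list with elements `life_history`
#'   (a `life_history` object), `regime` (a `mortality_regime` or `NULL`),
#'   and any scalar run settings present in the file.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  lh_fields <- names(formals(life_history))
  lh_args <- raw[intersect(names(raw), lh_fields)]
  for (nm in c("mates_per_female", "pups_per_mating")) {
    if (!is.null(lh_args[[nm]])) {
      d <- unlist(lh_args[[nm]])
      lh_args[[nm]] <- d / sum(d) # guard against serialization rounding
    }
  }
  cfg <- do.call(life_history, lh_args)
  regime <- NULL
  if (!is.null(raw$regime)) {
    regime <- do.call(mortality_regime, raw$regime)
  }
  extra <- raw[setdiff(names(raw), c(lh_fields, "regime"))]
  c(list(life_history = cfg, regime = regime), extra)
}

#' @rdname read_config
#' @param cfg A `life_history` object.
#' @param regime Optional `mortality_regime`.
#' @param ... Further scalar settings (`n_years`, `census`, `seed`, ...)
#'   written verbatim.
#' @export
write_config <- function(path, cfg, regime = NULL, ...) {
  out <- unclass(cfg)
  out$mates_per_female <- as.list(cfg$mates_per_female)
  out$pups_per_mating <- as.list(cfg$pups_per_mating)
  extra <- list(...)
  out[names(extra)] <- extra
  if (!is.null(regime)) out$regime <- unclass(regime)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.life_history <- function(x, ...) {
  cat("<life_history>\n")
  cat(sprintf("  ages: maturity %d, max %d\n", x$maturity_age, x$max_age))
  cat(sprintf("  survival: yoy %.4f, juvenile %.2f, adult %.2f\n",
              x$survival_yoy, x$survival_juvenile, x$survival_adult))
  cat(sprintf("  breeding: cycle a = %d, psi = %.2f, p_offcycle = %.2f, p_fail = %.2f\n",
              x$breeding_cycle_a, x$fraction_multiennial, x$p_offcycle, x$p_fail))
  cat(sprintf("  mean litter %.2f pups; sex ratio (F) %.2f\n",
              mean_litter_size(x), x$sex_ratio_at_birth))
  invisible(x)
}
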