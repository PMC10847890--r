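#' Female Leslie matrix implied by a life-history configuration
#'
#' Builds the female-only, birth-pulse Leslie matrix on a post-breeding
#' census with ages `0..max_age`. Survival from age x to x+1 is the stage
#' survival (young-of-year, juvenile, adult); individuals at `max_age` die.
#' Fecundity applies to every age at which the individual will be mature in
#' the *next* breeding season, and equals the expected number of female pups
#' per mature female per year (litter size times breeding-cycle probability
#' times sex ratio at birth).
#'
#' @param cfg A [life_history()] configuration.
#' @param survival_yoy Optional override of the age-0 survival (used by the
#'   stationarity solver before `cfg$survival_yoy` is set).
#' @param mortality_adjust Additive adjustment to juvenile and adult
#'   mortality (positive lowers survival), as in [mortality_regime()].
#' @return A square numeric matrix of dimension `max_age + 1`.
#' @export
leslie_matrix <- function(cfg, survival_yoy = NULL, mortality_adjust = 0) {
  s0 <- if (is.null(survival_yoy)) cfg$survival_yoy else survival_yoy
  if (is.na(s0)) stop("young-of-year survival is unset; solve it first")
  amax <- cfg$max_age
  sj <- cfg$survival_juvenile - mortality_adjust
  sa <- cfg$survival_adult - mortality_adjust
  if (sj <= 0 || sj > 1 || sa <= 0 || sa > 1) {
    stop("adjusted survival falls outside (0, 1]")
  }
  # survival from age x to x+1, x = 0 .. amax-1
  s <- c(s0, rep(sj, cfg$maturity_age - 1L),
         rep(sa, amax - cfg$maturity_age))
  f <- mean_annual_fecundity(cfg) * cfg$sex_ratio_at_birth
  L <- matrix(0, amax + 1L, amax + 1L)
  L[cbind(seq_len(amax) + 1L, seq_len(amax))] <- s
  breeds_next <- which((seq_len(amax)) >= cfg$maturity_age) # age x+1 mature
  L[1L, breeds_next] <- s[breeds_next] * f
  L
}

dominant_eigenvalue <- function(L) {
  max(Re(eigen(L, only.values = TRUE)$values))
}

#' Solve young-of-year survival for a stationary population
#'
#' Finds the age-0 annual survival s0 such that the female Leslie matrix
#' implied by `cfg` has dominant eigenvalue 1, by bisection (via
#' [stats::uniroot()]) on (0, 1).
#'
#' @param cfg A [life_history()] configuration; juvenile/adult survival and
#'   the fecundity distributions are taken as fixed.
#' @param tol Convergence tolerance on the eigenvalue.
#' @return The stationary age-0 survival probability.
#' @export
solve_stable_yoy_survival <- function(cfg, tol = 1e-8) {
  g <- function(s0) dominant_eigenvalue(leslie_matrix(cfg, survival_yoy = s0)) - 1
  lo <- 1e-9
  hi <- 1 - 1e-9
  if (g(hi) < 0) {
    stop("configuration infeasible: population shrinks even at s0 = 1")
  }
  if (g(lo) > 0) {
    stop("configuration infeasible: no root in (0, 1); ",
         "population grows for any positive young-of-year survival")
  }
  stats::uniroot(g, c(lo, hi), tol = tol)$root
}

#' Stable age distribution
#'
#' Right eigenvector of the Leslie matrix associated with the dominant
#' eigenvalue, normalized to sum to one. This is the expected age
#' composition of the post-breeding census.
#'
#' @inheritParams leslie_matrix
#' @return Numeric vector of length `max_age + 1` summing to 1
#'   (index 1 = age 0).
#' @export
stable_age_distribution <- function(cfg) {
  L <- leslie_matrix(cfg)
  e <- eigen(L)
  k <- which.max(Re(e$values))
  w <- abs(Re(e$vectors[, k]))
  w / sum(w)
}
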