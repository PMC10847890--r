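#' Parameter set for the kinship models
#'
#' @param N_f_t0,N_m_t0 Mature female / male abundance at the reference year.
#' @param phi Adult annual survival, in (0, 1].
#' @param lam Annual finite population growth rate (> 0).
#' @param psi Proportion of females breeding every `a` years, in [0, 1].
#' @param a Breeding interval in years (fixed integer >= 1, never estimated).
#' @return A `param_set` list.
#' @export
param_set <- function(N_f_t0 = NA_real_, N_m_t0 = NA_real_, phi = 0.9,
                      lam = 1, psi = 0, a = 1L) {
  stopifnot(is.na(N_f_t0) || N_f_t0 >= 1, is.na(N_m_t0) || N_m_t0 >= 1,
            phi > 0, phi <= 1, lam > 0, psi >= 0, psi <= 1, a >= 1)
  structure(list(N_f_t0 = N_f_t0, N_m_t0 = N_m_t0, phi = phi,
                 lam = lam, psi = psi, a = as.integer(a)),
            class = "param_set")
}

#' Kinship model specification
#'
#' @param variant `"base"` (constant abundance; growth rate fixed at 1),
#'   `"growth"` (exponential abundance trend), or `"multiennial"` (growth
#'   plus intermittent female breeding with interval `a` and mixture `psi`).
#' @param uses_po Include parent-offspring cells in the likelihood.
#' @param t0 Reference year at which abundance is parameterized.
#' @param a Breeding interval for the multiennial variant.
#' @return A `model_spec` list.
#' @export
model_spec <- function(variant = c("base", "growth", "multiennial"),
                       uses_po = FALSE, t0 = NA_integer_, a = 1L) {
  variant <- match.arg(variant)
  if (variant == "multiennial" && a < 1L) stop("multiennial variant needs a >= 1")
  structure(list(variant = variant, uses_po = uses_po,
                 t0 = as.integer(t0), a = as.integer(a),
                 shared_phi_lambda_across_sexes = TRUE),
            class = "model_spec")
}

check_prob <- function(p, what) {
  if (any(p > 1 + 1e-12 | p < 0)) {
    stop(what, ": kinship probability outside [0, 1] ",
         "(abundance too small for the given survival and gaps?)")
  }
  pmin(p, 1)
}

#' Base-case maternal half-sibling probability
#'
#' `phi^delta / N_f`: the mother of the older sibling must survive the
#' birth-year gap and be the one (of `N_f` equally likely mature females)
#' that birthed the younger.
#'
#' @param phi Adult annual survival.
#' @param delta Birth-year gap (>= 1; vectorized).
#' @param N_f Mature female abundance in the younger sibling's birth year.
#' @return Probability (vectorized).
#' @export
p_mhsp_base <- function(phi, delta, N_f) {
  stopifnot(all(delta >= 1))
  check_prob(phi^delta / N_f, "p_mhsp_base")
}

#' Base-case maternal parent-offspring probability
#'
#' `phi^(y_j - c_i) / N_f` when the candidate mother was captured before the
#' offspring's birth year (she must survive to it), and `1 / N_f` when
#' captured in or after it (she is known alive then).
#'
#' @inheritParams p_mhsp_base
#' @param y_j Offspring birth year (vectorized).
#' @param c_i Capture year of the candidate parent.
#' @export
p_mpop_base <- function(phi, y_j, c_i, N_f) {
  surv <- ifelse(c_i < y_j, phi^(y_j - c_i), 1)
  check_prob(surv / N_f, "p_mpop_base")
}

#' Exponential abundance trajectory
#'
#' `N(t) = N_t0 * lam^(t - t0)`, applied per sex.
#'
#' @param N_t0 Abundance at the reference year.
#' @param lam Annual finite growth rate.
#' @param t Target year(s).
#' @param t0 Reference year.
#' @export
n_at <- function(N_t0, lam, t, t0) {
  N_t0 * lam^(t - t0)
}

#' Growth-adapted maternal half-sibling probability
#'
#' Base case with the denominator replaced by the exponential abundance
#' trajectory evaluated in the younger sibling's birth year.
#'
#' @inheritParams p_mhsp_base
#' @param N_f_t0 Mature female abundance at the reference year.
#' @param lam Annual finite growth rate.
#' @param y_j Younger sibling's birth year.
#' @param t0 Reference year.
#' @export
p_mhsp_growth <- function(phi, delta, N_f_t0, lam, y_j, t0) {
  stopifnot(all(delta >= 1))
  check_prob(phi^delta / n_at(N_f_t0, lam, y_j, t0), "p_mhsp_growth")
}

#' Growth-adapted maternal parent-offspring probability
#'
#' @inheritParams p_mhsp_growth
#' @param c_i Capture year of the candidate parent.
#' @export
p_mpop_growth <- function(phi, y_j, c_i, N_f_t0, lam, t0) {
  surv <- ifelse(c_i < y_j, phi^(y_j - c_i), 1)
  check_prob(surv / n_at(N_f_t0, lam, y_j, t0), "p_mpop_growth")
}

#' Effective number of female breeders
#'
#' `((a + psi - a*psi) / a) * N_f`: with a fraction `psi` of females
#' breeding every `a` years (1/a of them on-cycle in any year) and the rest
#' annually, this is the expected number of females actually breeding in a
#' given year.
#'
#' @param N_f Total mature female abundance in the year.
#' @param psi Proportion of multiennial breeders.
#' @param a Breeding interval.
#' @export
effective_breeders <- function(N_f, psi, a) {
  (a + psi - a * psi) / a * N_f
}

#' Multiennial maternal half-sibling probability
#'
#' For birth-year gaps evenly divisible by the breeding interval `a`
#' (on-cycle) the probability is
#' `a * phi^delta / ((a + psi - a*psi) * N_f_t0 * lam^(y_j - t0))`;
#' off-cycle gaps carry the additional factor `(1 - psi)` since only annual
#' breeders can produce them. With `a = 1` every gap is on-cycle and the
#' expression reduces to the growth-adapted probability, as it does for
#' `psi = 0`.
#'
#' @inheritParams p_mhsp_growth
#' @param psi Proportion of multiennial breeders.
#' @param a Breeding interval.
#' @export
p_mhsp_multiennial <- function(phi, delta, N_f_t0, lam, y_j, t0, psi, a) {
  stopifnot(all(delta >= 1), a >= 1)
  denom <- (a + psi - a * psi) * n_at(N_f_t0, lam, y_j, t0)
  p <- a * phi^delta / denom
  off <- (delta %% a) != 0
  p[off] <- p[off] * (1 - psi)
  check_prob(p, "p_mhsp_multiennial")
}

#' Paternal half-sibling probability
#'
#' Males breed annually, so paternal half-sibling probabilities follow the
#' growth-adapted form with male abundance regardless of the female
#' breeding schedule.
#'
#' @inheritParams p_mhsp_growth
#' @param N_m_t0 Mature male abundance at the reference year.
#' @export
p_phsp <- function(phi, delta, N_m_t0, lam, y_j, t0) {
  stopifnot(all(delta >= 1))
  check_prob(phi^delta / n_at(N_m_t0, lam, y_j, t0), "p_phsp")
}

#' Paternal parent-offspring probability
#'
#' @inheritParams p_mpop_growth
#' @param N_m_t0 Mature male abundance at the reference year.
#' @export
p_ppop <- function(phi, y_j, c_i, N_m_t0, lam, t0) {
  surv <- ifelse(c_i < y_j, phi^(y_j - c_i), 1)
  check_prob(surv / n_at(N_m_t0, lam, y_j, t0), "p_ppop")
}

# vectorized cell probabilities for a comparison dataset under (params, spec);
# returns NA-free numeric vector, or signals via attr when invalid (strict).
cell_probabilities <- function(cells, params, spec) {
  t0 <- spec$t0
  lam <- if (spec$variant == "base") 1 else params$lam
  p <- numeric(nrow(cells))
  hs_m <- cells$relationship == "HS" & cells$side == "maternal"
  hs_p <- cells$relationship == "HS" & cells$side == "paternal"
  po_m <- cells$relationship == "PO" & cells$side == "maternal"
  po_p <- cells$relationship == "PO" & cells$side == "paternal"
  if (any(hs_m)) {
    p[hs_m] <- if (spec$variant == "multiennial") {
      p_mhsp_multiennial(params$phi, cells$delta[hs_m], params$N_f_t0, lam,
                         cells$y_j[hs_m], t0, params$psi, spec$a)
    } else {
      p_mhsp_growth(params$phi, cells$delta[hs_m], params$N_f_t0, lam,
                    cells$y_j[hs_m], t0)
    }
  }
  if (any(hs_p)) {
    p[hs_p] <- p_phsp(params$phi, cells$delta[hs_p], params$N_m_t0, lam,
                      cells$y_j[hs_p], t0)
  }
  if (any(po_m)) {
    p[po_m] <- p_mpop_growth(params$phi, cells$y_j[po_m], cells$c_i[po_m],
                             params$N_f_t0, lam, t0)
  }
  if (any(po_p)) {
    p[po_p] <- p_ppop(params$phi, cells$y_j[po_p], cells$c_i[po_p],
                      params$N_m_t0, lam, t0)
  }
  p
}

#' Grouped-binomial log-likelihood
#'
#' Sum over comparison cells of the binomial log-mass
#' `log C(R, Y) + Y log p + (R - Y) log(1 - p)`, with the cell probability
#' given by the variant-appropriate kinship equation (maternal HS cells use
#' the base / growth / multiennial form, paternal HS cells always the
#' annual-male form, parent-offspring cells the growth form when
#' `spec$uses_po`). Cells with `p = 0` contribute 0 when `Y = 0` and
#' `-Inf` otherwise.
#'
#' @param dataset A `comparison_dataset`.
#' @param params A [param_set()].
#' @param spec A [model_spec()].
#' @return The log-likelihood (scalar; `-Inf` for impossible data).
#' @export
log_likelihood <- function(dataset, params, spec) {
  cells <- dataset$cells
  if (!spec$uses_po) cells <- cells[cells$relationship != "PO", , drop = FALSE]
  if (is.na(spec$t0)) spec$t0 <- dataset$t0
  p <- cell_probabilities(cells, params, spec)
  ll_cells(p, cells$R, cells$Y)
}

ll_cells <- function(p, R, Y) {
  out <- lchoose(R, Y)
  pz <- p == 0
  if (any(pz & Y > 0)) return(-Inf)
  ok <- !pz
  out[ok] <- out[ok] + Y[ok] * log(p[ok]) + (R[ok] - Y[ok]) * log1p(-p[ok])
  out[pz] <- 0
  sum(out)
}
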