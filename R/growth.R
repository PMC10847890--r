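#' Von Bertalanffy growth curve
#'
#' Length-at-age model used to simulate lengths for sampled animals and to
#' re-assign ages from lengths (length-based aging). Defaults are the lemon
#' shark parameters: asymptotic length 317.65 cm, growth coefficient
#' 0.057 per year, theoretical age of zero size -2.302 years. Length
#' variability is a fixed standard deviation (`sd_young`, cm) for ages 0-2
#' and a coefficient of variation (`cv_old`) on mean length-at-age for ages
#' 3 and older.
#'
#' @param L_inf Asymptotic average length, cm.
#' @param K Growth coefficient, per year.
#' @param t0_vb Theoretical age of zero size, years.
#' @param sd_young Length standard deviation for ages 0-2, cm.
#' @param cv_old Coefficient of variation of length for ages >= 3.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(L_inf = 317.65, K = 0.057, t0_vb = -2.302,
                         sd_young = 3.0, cv_old = 0.10) {
  stopifnot(L_inf > 0, K > 0, sd_young >= 0, cv_old >= 0)
  structure(list(L_inf = L_inf, K = K, t0_vb = t0_vb,
                 sd_young = sd_young, cv_old = cv_old),
            class = "growth_curve")
}

#' Mean length at age
#'
#' `L_inf * (1 - exp(-K * (age - t0_vb)))`.
#'
#' @param age Age in years (vectorized, >= 0).
#' @param curve A [growth_curve()].
#' @return Length in cm.
#' @export
vb_length <- function(age, curve) {
  stopifnot(all(age >= 0))
  curve$L_inf * (1 - exp(-curve$K * (age - curve$t0_vb)))
}

#' Age from length (reverse growth curve)
#'
#' Inverts the growth curve and rounds to the nearest integer age
#' (half-to-even, the default R rounding); results are clamped to
#' `[0, max_age]` and lengths at or above `L_inf` map to `max_age`.
#'
#' @param length Length in cm (vectorized, > 0).
#' @param curve A [growth_curve()].
#' @param max_age Upper clamp for assigned ages.
#' @return Integer ages.
#' @export
vb_inverse_age <- function(length, curve, max_age = 50L) {
  stopifnot(all(length > 0))
  age <- rep(Inf, length(length))
  ok <- length < curve$L_inf
  age[ok] <- curve$t0_vb - log(1 - length[ok] / curve$L_inf) / curve$K
  as.integer(pmin(pmax(round(age), 0), max_age))
}

#' Simulate a length for sampled animals
#'
#' Lengths are drawn from `Normal(vb_length(true_age), sigma)` where
#' `sigma = sd_young` for ages 0-2 and `sigma = cv_old * vb_length(true_age)`
#' for ages 3 and older. Negative draws are redrawn (rather than truncated)
#' so the mean stays unbiased at small ages.
#'
#' @param samples A `Sample` data.frame carrying `true_age`.
#' @param curve A [growth_curve()].
#' @return The samples with a `length` column added.
#' @export
assign_length <- function(samples, curve) {
  mu <- vb_length(samples$true_age, curve)
  sigma <- ifelse(samples$true_age <= 2, curve$sd_young, curve$cv_old * mu)
  len <- stats::rnorm(nrow(samples), mu, sigma)
  bad <- which(len < 0 & sigma > 0)
  while (length(bad)) {
    len[bad] <- stats::rnorm(length(bad), mu[bad], sigma[bad])
    bad <- bad[len[bad] < 0]
  }
  samples$length <- len
  samples
}

#' Apply length-based aging error
#'
#' Each sample receives a simulated length ([assign_length()]) and an age
#' re-assigned from that length through the reverse growth curve
#' ([vb_inverse_age()]); `assigned_birth_year` is recomputed while
#' `true_age` is retained for bias accounting. This produces plausible but
#' sometimes incorrect cohort assignments, increasingly so where the growth
#' curve flattens with age.
#'
#' @inheritParams assign_length
#' @param max_age Upper clamp for assigned ages.
#' @param seed Optional integer seed.
#' @return The samples with `length`, `assigned_age` and
#'   `assigned_birth_year` updated.
#' @export
apply_aging_error <- function(samples, curve, max_age = 50L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  samples <- assign_length(samples, curve)
  samples$assigned_age <- vb_inverse_age(samples$length, curve, max_age)
  samples$assigned_birth_year <- samples$capture_year - samples$assigned_age
  samples
}
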