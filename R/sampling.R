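#' Sampling scheme
#'
#' Annual, age-selective sampling of the standing population. Three named
#' schemes target young-of-year only (`target_yoy`, ages 0-0), juveniles
#' excluding young-of-year (`sample_juveniles`, ages 1 to maturity-1), or
#' every age class (`sample_all_ages`). The yearly draw is
#' `round(intensity * total living census)` individuals taken uniformly
#' without replacement from the age window; the intensity refers to the
#' total census even when the window is narrower (a per-window
#' interpretation is available via an explicit `age_window`).
#'
#' @param name One of `"target_yoy"`, `"sample_juveniles"`,
#'   `"sample_all_ages"`, or `"custom"` (requires `age_window`).
#' @param intensity Fraction of the total census drawn each year, in
#'   (0, 0.1].
#' @param years Strictly increasing integer sampling years.
#' @param age_window Optional inclusive integer age interval overriding the
#'   named window.
#' @param lethal Logical; the default `FALSE` leaves sampled individuals
#'   alive and available in later years (self-recapture possible).
#' @return An object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(name = c("target_yoy", "sample_juveniles",
                                     "sample_all_ages", "custom"),
                            intensity, years, age_window = NULL,
                            lethal = FALSE) {
  name <- match.arg(name)
  if (intensity <= 0 || intensity > 0.1) {
    stop("intensity must lie in (0, 0.1]")
  }
  years <- as.integer(years)
  if (length(years) > 1L && any(diff(years) <= 0L)) {
    stop("sampling years must be strictly increasing")
  }
  if (name == "custom" && is.null(age_window)) {
    stop("a custom scheme needs an explicit age_window")
  }
  structure(list(name = name, intensity = intensity, years = years,
                 age_window = age_window, lethal = lethal),
            class = "sampling_scheme")
}

scheme_window <- function(scheme, cfg) {
  if (!is.null(scheme$age_window)) return(as.integer(scheme$age_window))
  switch(scheme$name,
         target_yoy = c(0L, 0L),
         sample_juveniles = c(1L, cfg$maturity_age - 1L),
         sample_all_ages = c(0L, cfg$max_age))
}

# draw counts use round-half-away-from-zero so x.5 always rounds up
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

#' Draw samples from simulation snapshots
#'
#' For each sampling year, draws `round(intensity * total living census)`
#' individuals uniformly without replacement from the scheme's age window
#' at the post-breeding point of that year. Non-lethal sampling leaves
#' individuals available in later years, so the same animal can recur
#' across years (self-recapture).
#'
#' @param sim A `ckmr_simulation` whose `snapshot_years` covered the
#'   scheme's years.
#' @param scheme A [sampling_scheme()].
#' @param seed Optional integer seed.
#' @return A `Sample` data.frame: individual_id, capture_year, sex,
#'   true_age, assigned_age, assigned_birth_year, maturity_at_capture,
#'   mother_id, father_id. Assigned ages equal true ages until
#'   [apply_aging_error()] is used.
#' @export
draw_samples <- function(sim, scheme, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- sim$pop
  cfg <- sim$cfg
  win <- scheme_window(scheme, cfg)
  rows <- vector("list", length(scheme$years))
  for (k in seq_along(scheme$years)) {
    y <- scheme$years[k]
    ids <- sim$snapshots[[as.character(y)]]
    if (is.null(ids)) stop("no snapshot retained for sampling year ", y)
    total <- length(ids)
    age <- y - pop$birth[ids]
    avail <- ids[age >= win[1] & age <= win[2]]
    want <- as.integer(round_half_away(scheme$intensity * total))
    if (want > length(avail)) {
      warning("year ", y, ": requested ", want, " samples but only ",
              length(avail), " individuals in the age window; drawing all")
      take <- avail
    } else {
      take <- avail[sample.int(length(avail), want)]
    }
    ta <- y - pop$birth[take]
    rows[[k]] <- data.frame(
      individual_id = take,
      capture_year = y,
      sex = c("F", "M")[pop$sex[take]],
      true_age = ta,
      assigned_age = ta,
      assigned_birth_year = y - ta,
      maturity_at_capture = ta >= cfg$maturity_age,
      mother_id = pop$mother[take],
      father_id = pop$father[take]
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
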