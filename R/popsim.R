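#' @import data.table
#' @importFrom stats runif rbinom setNames quantile median cor sd
NULL

# Internal population store. The full pedigree is accumulated as per-event
# chunks (founders, one chunk per yearly cohort, a death log) and
# materialized into flat per-individual vectors once, when the simulation
# finishes; during the annual cycle only compact parallel vectors over the
# *living* animals are touched. This keeps the yearly cost proportional to
# the standing census, not to every individual ever alive.
new_population <- function(capacity = 1024L) {
  pop <- new.env(parent = emptyenv())
  pop$n <- 0L
  pop$chunks <- list()      # each: list(sex, birth, mother, father, multi, offset)
  pop$death_ids <- list()   # death log: id vectors ...
  pop$death_years <- list() # ... and matching years
  # living animals: ids plus the attributes the annual cycle needs
  pop$alive <- integer(0)
  pop$a_sex <- integer(0)
  pop$a_birth <- integer(0)
  pop$a_multi <- logical(0)
  pop$a_offset <- integer(0)
  pop$materialized <- FALSE
  pop
}

pop_add <- function(pop, sex, birth, mother, father, multi, offset) {
  k <- length(sex)
  if (k == 0L) return(integer(0))
  idx <- pop$n + seq_len(k)
  pop$chunks[[length(pop$chunks) + 1L]] <- list(
    sex = as.integer(sex), birth = as.integer(birth),
    mother = as.integer(mother), father = as.integer(father),
    multi = multi, offset = as.integer(offset))
  pop$n <- pop$n + k
  pop$alive <- c(pop$alive, idx)
  pop$a_sex <- c(pop$a_sex, as.integer(sex))
  pop$a_birth <- c(pop$a_birth, as.integer(birth))
  pop$a_multi <- c(pop$a_multi, multi)
  pop$a_offset <- c(pop$a_offset, as.integer(offset))
  pop$materialized <- FALSE
  idx
}

# flatten the chunk log into per-individual vectors (pop$sex, pop$birth,
# pop$mother, pop$father, pop$multi, pop$offset, pop$death), for pedigree
# export and post-hoc lookups
pop_materialize <- function(pop) {
  if (isTRUE(pop$materialized)) return(invisible(pop))
  take <- function(f) unlist(lapply(pop$chunks, `[[`, f), use.names = FALSE)
  pop$sex <- take("sex")
  pop$birth <- take("birth")
  pop$mother <- take("mother")
  pop$father <- take("father")
  pop$multi <- take("multi")
  pop$offset <- take("offset")
  death <- rep(NA_integer_, pop$n)
  if (length(pop$death_ids)) {
    death[unlist(pop$death_ids, use.names = FALSE)] <-
      rep.int(unlist(pop$death_years, use.names = FALSE),
              vapply(pop$death_ids, length, integer(1)))
  }
  pop$death <- death
  pop$materialized <- TRUE
  invisible(pop)
}

# drop the living animals at positions `kill` (indices into pop$alive)
pop_kill <- function(pop, kill, year) {
  if (!length(kill)) return(invisible(pop))
  pop$death_ids[[length(pop$death_ids) + 1L]] <- pop$alive[kill]
  pop$death_years[[length(pop$death_years) + 1L]] <- as.integer(year)
  keep <- -kill
  pop$alive <- pop$alive[keep]
  pop$a_sex <- pop$a_sex[keep]
  pop$a_birth <- pop$a_birth[keep]
  pop$a_multi <- pop$a_multi[keep]
  pop$a_offset <- pop$a_offset[keep]
  pop$materialized <- FALSE
  invisible(pop)
}

# sample from a named discrete distribution (safe for single-point support)
sample_discrete <- function(dist, n) {
  support <- as.integer(names(dist))
  if (length(support) == 1L) return(rep.int(support, n))
  support[sample.int(length(support), n, replace = TRUE, prob = dist)]
}

# draw multiennial status and cycle offsets for a vector of new females;
# offsets are uniform over residue classes 0..a-1, so (for a = 2) half of
# the females first breed the year they mature and half the following year.
draw_breeding_cycle <- function(cfg, n_female) {
  multi <- runif(n_female) < cfg$fraction_multiennial
  offset <- integer(n_female)
  if (cfg$breeding_cycle_a > 1L && any(multi)) {
    offset[multi] <- sample.int(cfg$breeding_cycle_a, sum(multi),
                                replace = TRUE) - 1L
  }
  list(multi = multi, offset = offset)
}

#' Initialize a population at the stable age distribution
#'
#' Founders are drawn from the stable age distribution implied by the
#' life-history configuration (post-breeding census, ages `0..max_age`),
#' carry no parent links, and multiennial females receive breeding-phase
#' offsets uniformly over the residue classes.
#'
#' @param cfg A [life_history()] configuration.
#' @param total_census Number of living founders (must be >= 100).
#' @param seed Optional integer seed (`set.seed`) for reproducibility.
#' @return A `population_state` list with elements `pop` (internal pedigree
#'   store), `year` (0), and `census` (named yearly totals).
#' @export
init_population <- function(cfg, total_census, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  total_census <- as.integer(total_census)
  if (total_census < 100L) stop("total_census must be at least 100")
  w <- stable_age_distribution(cfg)
  ages <- sample.int(cfg$max_age + 1L, total_census, replace = TRUE,
                     prob = w) - 1L
  sex <- ifelse(runif(total_census) < cfg$sex_ratio_at_birth, 1L, 2L)
  cyc <- draw_breeding_cycle(cfg, total_census)
  cyc$multi[sex != 1L] <- FALSE
  cyc$offset[sex != 1L] <- 0L
  pop <- new_population()
  pop_add(pop, sex = sex, birth = -ages, mother = rep(NA_integer_, total_census),
          father = rep(NA_integer_, total_census), multi = cyc$multi,
          offset = cyc$offset)
  pop_materialize(pop)
  state <- list(pop = pop, year = 0L,
                census = stats::setNames(total_census, "0"))
  class(state) <- "population_state"
  state
}

# is a mature female on her breeding schedule in `year`?
on_cycle <- function(cfg, year, age, multi, offset) {
  !multi | ((age - cfg$maturity_age - offset) %% cfg$breeding_cycle_a == 0L)
}

# distinct sires per female: draw all mate slots with replacement in one
# vectorized pass, then redraw the rare within-female duplicates
draw_sires <- function(males, n_mates) {
  nm <- length(males)
  fid <- rep.int(seq_along(n_mates), n_mates)
  pick <- sample.int(nm, length(fid), replace = TRUE)
  if (nm > 1L) {
    repeat {
      dup <- duplicated(fid * (nm + 1.0) + pick)
      if (!any(dup)) break
      pick[dup] <- sample.int(nm, sum(dup), replace = TRUE)
    }
  }
  males[pick]
}

#' One year of breeding
#'
#' Every eligible mature female (annual breeders always; multiennial
#' breeders when the year matches their cycle phase, perturbed by
#' `p_offcycle` / `p_fail`) draws a number of mates, selects that many
#' distinct mature males uniformly at random (clamped to the number
#' available), and produces pups per sire with recorded parent links.
#'
#' @param state A `population_state`.
#' @param cfg A [life_history()] configuration.
#' @param year The breeding year (defaults to the state's current year).
#' @return The modified state (newborns appended, census untouched).
#' @export
breed <- function(state, cfg, year = state$year) {
  pop <- state$pop
  age <- year - pop$a_birth
  mature <- age >= cfg$maturity_age
  i_fem <- which(mature & pop$a_sex == 1L)
  males <- pop$alive[mature & pop$a_sex == 2L]
  if (length(i_fem) == 0L) return(state)
  if (length(males) == 0L) {
    warning("no mature males alive in year ", year, "; breeding skipped")
    return(state)
  }
  onc <- on_cycle(cfg, year, age[i_fem], pop$a_multi[i_fem],
                  pop$a_offset[i_fem])
  breeds <- !pop$a_multi[i_fem]
  im <- which(!breeds)
  if (length(im)) {
    u <- runif(length(im))
    breeds[im] <- ifelse(onc[im], u >= cfg$p_fail, u < cfg$p_offcycle)
  }
  mothers <- pop$alive[i_fem[breeds]]
  nb <- length(mothers)
  if (nb == 0L) return(state)

  n_mates <- pmin(sample_discrete(cfg$mates_per_female, nb), length(males))
  sires <- draw_sires(males, n_mates)
  pups_per <- sample_discrete(cfg$pups_per_mating, length(sires))
  sires <- rep.int(sires, pups_per)
  moms <- rep.int(rep.int(mothers, n_mates), pups_per)
  np <- length(sires)
  sex <- ifelse(runif(np) < cfg$sex_ratio_at_birth, 1L, 2L)
  cyc <- draw_breeding_cycle(cfg, np)
  cyc$multi[sex != 1L] <- FALSE
  cyc$offset[sex != 1L] <- 0L
  pop_add(pop, sex = sex, birth = rep.int(as.integer(year), np),
          mother = moms, father = sires, multi = cyc$multi,
          offset = cyc$offset)
  state
}

#' One year of mortality
#'
#' Each living individual dies independently with its stage-specific
#' mortality (adjusted by the regime for juveniles and adults); individuals
#' at or beyond `max_age` die deterministically. Death years are recorded
#' in the pedigree; dead individuals never reappear.
#'
#' @inheritParams breed
#' @param regime Optional [mortality_regime()].
#' @return The modified state.
#' @export
apply_mortality <- function(state, cfg, regime = NULL, year = state$year) {
  pop <- state$pop
  n_alive <- length(pop$alive)
  if (n_alive == 0L) return(state)
  adj <- regime_adjustment(regime, year)
  sj <- cfg$survival_juvenile - adj
  sa <- cfg$survival_adult - adj
  if (sj <= 0 || sj > 1 || sa <= 0 || sa > 1) {
    stop("adjusted survival falls outside (0, 1] in year ", year)
  }
  age <- year - pop$a_birth
  surv <- ifelse(age == 0L, cfg$survival_yoy,
                 ifelse(age < cfg$maturity_age, sj, sa))
  surv[age >= cfg$max_age] <- 0
  pop_kill(pop, which(runif(n_alive) >= surv), year)
  state
}

#' Run the individual-based simulation
#'
#' Executes the annual cycle in fixed order — breeding, then the sampling
#' hook (post-breeding snapshot), then mortality, then age/year increment —
#' starting from founders at the stable age distribution. The full pedigree
#' (including dead individuals) is retained for truth kinship.
#'
#' The founder census is the post-breeding standing population of year 0;
#' the transition into year 1 therefore begins with year-0 mortality so the
#' expected census stays at `total_census` under the stationary
#' configuration.
#'
#' @inheritParams init_population
#' @param regime Optional [mortality_regime()]; its `years` refer to
#'   simulation years `1..n_years`.
#' @param n_years Number of simulated years (>= 1).
#' @param snapshot_years Years at which a post-breeding snapshot of living
#'   ids is kept for sampling (see [draw_samples()]).
#' @return A `ckmr_simulation` list: `pop` (pedigree store), `cfg`,
#'   `census` (post-breeding totals, years 0..n), `snapshots` (named list of
#'   living-id vectors), `final_year`.
#' @export
run_simulation <- function(cfg, regime = NULL, n_years, total_census,
                           seed = NULL, snapshot_years = integer(0)) {
  if (n_years < 1L) stop("n_years must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  state <- init_population(cfg, total_census)
  pop <- state$pop
  census <- integer(n_years + 1L)
  census[1L] <- length(pop$alive)
  snapshots <- list()
  for (y in seq_len(n_years)) {
    # mortality closing the previous year, then age increment into year y
    state <- apply_mortality(state, cfg, regime, year = y - 1L)
    state$year <- y
    if (length(pop$alive) == 0L) {
      stop("population went extinct in year ", y)
    }
    state <- breed(state, cfg, year = y)
    census[y + 1L] <- length(pop$alive)
    if (y %in% snapshot_years) {
      snapshots[[as.character(y)]] <- pop$alive
    }
  }
  fem_mature <- sum(pop$a_sex == 1L & (n_years - pop$a_birth) >= cfg$maturity_age)
  if (fem_mature == 0L) stop("population went extinct in year ", n_years)
  pop_materialize(pop)
  structure(list(pop = pop, cfg = cfg,
                 census = stats::setNames(census, 0:n_years),
                 snapshots = snapshots, final_year = as.integer(n_years)),
            class = "ckmr_simulation")
}

#' Yearly realized growth rate
#'
#' Geometric-mean census ratio over a year window.
#'
#' @param sim A `ckmr_simulation`.
#' @param from,to First and last year of the window.
#' @return The realized annual finite growth rate.
#' @export
realized_lambda <- function(sim, from, to) {
  cens <- sim$census
  (cens[[as.character(to)]] / cens[[as.character(from)]])^(1 / (to - from))
}

# living mature counts by sex at the post-breeding point of `year`
# (requires a snapshot of that year, or year == final_year)
mature_count <- function(sim, year, sex = c("female", "male")) {
  sex <- match.arg(sex)
  ids <- if (year == sim$final_year && is.null(sim$snapshots[[as.character(year)]]))
    sim$pop$alive else sim$snapshots[[as.character(year)]]
  if (is.null(ids)) stop("no snapshot retained for year ", year)
  pop <- pop_materialize(sim$pop)
  scode <- if (sex == "female") 1L else 2L
  sum(pop$sex[ids] == scode & (year - pop$birth[ids]) >= sim$cfg$maturity_age)
}

#' Pedigree as a data frame
#'
#' One row per individual ever alive: id, sex, birth_year, death_year
#' (NA while alive), mother_id, father_id, is_multiennial, cycle_offset.
#'
#' @param sim A `ckmr_simulation` (or a `population_state`).
#' @return A data.frame.
#' @export
pedigree <- function(sim) {
  pop <- pop_materialize(sim$pop)
  data.frame(
    id = seq_len(pop$n),
    sex = c("F", "M")[pop$sex],
    birth_year = pop$birth,
    death_year = pop$death,
    mother_id = pop$mother,
    father_id = pop$father,
    is_multiennial = pop$multi,
    cycle_offset = pop$offset
  )
}

#' @export
print.ckmr_simulation <- function(x, ...) {
  cat("<ckmr_simulation>\n")
  cat(sprintf("  years: 0..%d; individuals ever alive: %d; final census: %d\n",
              x$final_year, x$pop$n, length(x$pop$alive)))
  if (length(x$snapshots)) {
    cat("  snapshots:", paste(names(x$snapshots), collapse = ", "), "\n")
  }
  invisible(x)
}
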