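# Shared fixtures and independent oracles. Expensive objects are computed
# once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_lh <- function() cached("lh", life_history())

# one full-length default simulation with sampling snapshots
default_sim <- function() cached("sim", {
  run_simulation(default_lh(), NULL, n_years = 90, total_census = 10270,
                 seed = 4242, snapshot_years = 87:90)
})

quick_mcmc <- function(seed = 1L) {
  mcmc_config(burn_in = 2000, n_iter = 2000, thin = 2, seed = seed)
}

mid_mcmc <- function(seed = 1L) {
  mcmc_config(burn_in = 6000, n_iter = 6000, thin = 6, seed = seed)
}

std_mcmc <- function(seed = 1L) {
  mcmc_config(burn_in = 10000, n_iter = 10000, thin = 10, seed = seed)
}

# ---- independent O(n^2) enumeration oracles ------------------------------

# half-sibling trials/positives per (y_i, y_j), looping over every pair
brute_hs <- function(s) {
  n <- nrow(s)
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in (i + 1L):n) {
      bi <- s$assigned_birth_year[i]
      bj <- s$assigned_birth_year[j]
      if (bi == bj) next
      key <- paste(min(bi, bj), max(bi, bj))
      rec <- if (exists(key, acc)) get(key, acc) else c(R = 0L, Ym = 0L, Yp = 0L)
      rec["R"] <- rec["R"] + 1L
      if (!is.na(s$mother_id[i]) && !is.na(s$mother_id[j]) &&
          s$mother_id[i] == s$mother_id[j]) rec["Ym"] <- rec["Ym"] + 1L
      if (!is.na(s$father_id[i]) && !is.na(s$father_id[j]) &&
          s$father_id[i] == s$father_id[j]) rec["Yp"] <- rec["Yp"] + 1L
      assign(key, rec, acc)
    }
  }
  keys <- ls(acc)
  out <- do.call(rbind, lapply(keys, function(k) {
    ys <- as.integer(strsplit(k, " ")[[1]])
    rec <- get(k, acc)
    data.frame(y_i = ys[1], y_j = ys[2], R = rec[["R"]],
               Ym = rec[["Ym"]], Yp = rec[["Yp"]])
  }))
  out[order(out$y_i, out$y_j), , drop = FALSE]
}

# parent-offspring trials/positives per (sex, y_j, c_i) by double loop
brute_po <- function(s, maturity_age = 12L) {
  imm <- s[!s$maturity_at_capture, , drop = FALSE]
  acc <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(imm))) {
    yj <- imm$assigned_birth_year[k]
    for (i in seq_len(nrow(s))) {
      if (s$individual_id[i] == imm$individual_id[k]) next
      if (yj - s$assigned_birth_year[i] < maturity_age) next
      key <- paste(s$sex[i], yj, s$capture_year[i])
      rec <- if (exists(key, acc)) get(key, acc) else c(R = 0L, Y = 0L)
      rec["R"] <- rec["R"] + 1L
      truth <- if (s$sex[i] == "F") imm$mother_id[k] else imm$father_id[k]
      if (!is.na(truth) && truth == s$individual_id[i]) rec["Y"] <- rec["Y"] + 1L
      assign(key, rec, acc)
    }
  }
  keys <- ls(acc)
  do.call(rbind, lapply(keys, function(k) {
    p <- strsplit(k, " ")[[1]]
    rec <- get(k, acc)
    data.frame(sex = p[1], y_j = as.integer(p[2]), c_i = as.integer(p[3]),
               R = rec[["R"]], Y = rec[["Y"]])
  }))
}

# a randomized synthetic sample table with known parent structure
random_sample_table <- function(n = 120, n_parents = 30, cohort_years = 70:89,
                                capture_years = 88:90, seed = 99,
                                maturity_age = 12L) {
  set.seed(seed)
  by <- sample(cohort_years, n, replace = TRUE)
  cy <- pmax(sample(capture_years, n, replace = TRUE), by)
  s <- data.frame(
    individual_id = 1000L + seq_len(n),
    capture_year = cy,
    sex = sample(c("F", "M"), n, replace = TRUE),
    true_age = cy - by,
    assigned_age = cy - by,
    assigned_birth_year = by,
    maturity_at_capture = (cy - by) >= maturity_age,
    mother_id = sample(c(NA_integer_, seq_len(n_parents)), n, replace = TRUE),
    father_id = sample(c(NA_integer_, 100L + seq_len(n_parents)), n,
                       replace = TRUE)
  )
  s
}

# hand-built three-generation pedigree used in kin-labeling tests:
# grandparents (1 F, 2 M) -> mother (3) and aunt (4); mother x unrelated
# male (5) -> child (6); plus half-sib pair (7, 8) sharing mother 3.
toy_pedigree <- function() {
  data.frame(
    id = 1:9,
    sex = c("F", "M", "F", "F", "M", "F", "M", "F", "M"),
    birth_year = c(0L, 0L, 20L, 21L, 19L, 40L, 41L, 43L, 22L),
    death_year = NA_integer_,
    mother_id = c(NA, NA, 1L, 1L, NA, 3L, 3L, 3L, NA),
    father_id = c(NA, NA, 2L, 2L, NA, 5L, 5L, 9L, NA),
    is_multiennial = FALSE,
    cycle_offset = 0L
  )
}
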