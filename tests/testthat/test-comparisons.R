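test_that("kinship labels follow the parent links exactly", {
  ped <- toy_pedigree()
  expect_equal(label_kinship(ped, 7, 8), "MHSP")  # same mother, diff father
  expect_equal(label_kinship(ped, 6, 7), "FSP")   # both parents shared
  expect_equal(label_kinship(ped, 3, 4), "FSP")
  expect_equal(label_kinship(ped, 3, 6), "MPOP")
  expect_equal(label_kinship(ped, 5, 6), "PPOP")
  expect_equal(label_kinship(ped, 6, 6), "self")
  expect_equal(label_kinship(ped, 1, 5), "unrelated")
  expect_error(label_kinship(ped, 1, 999), "unknown")
})

test_that("avuncular and grand pairs contaminate only under the flag", {
  ped <- toy_pedigree()
  # child (6) and aunt (4): aunt shares both parents with the child's mother
  expect_equal(label_kinship(ped, 6, 4), "avuncular")
  expect_equal(label_kinship(ped, 6, 4, include_avuncular_as_hsp = TRUE),
               "MHSP")
  # grandmother (1) and grandchild (6), through the maternal line
  expect_equal(label_kinship(ped, 1, 6), "avuncular")
  expect_equal(label_kinship(ped, 1, 6, include_avuncular_as_hsp = TRUE),
               "MHSP")
  # brute-force check over every pair of the toy pedigree: the flag changes
  # labels only for avuncular pairs, and only into half-sibling labels
  for (i in ped$id) for (j in ped$id) {
    plain <- label_kinship(ped, i, j)
    flagged <- label_kinship(ped, i, j, include_avuncular_as_hsp = TRUE)
    if (plain == "avuncular") {
      expect_true(flagged %in% c("MHSP", "PHSP"))
    } else {
      expect_identical(plain, flagged)
    }
  }
})

test_that("deduplication keeps one littermate and one capture instance", {
  s <- data.frame(
    individual_id = c(1L, 2L, 3L, 4L, 4L),
    capture_year = c(88L, 88L, 88L, 89L, 87L),
    sex = "F", true_age = 0L, assigned_age = 0L,
    assigned_birth_year = c(88L, 88L, 88L, 89L, 87L),
    maturity_at_capture = FALSE,
    mother_id = c(10L, 10L, 10L, 11L, 11L),
    father_id = c(20L, 20L, 20L, 21L, 21L)
  )
  out <- dedupe_samples(s)
  # three littermates collapse to one; individual 4 keeps earliest capture
  expect_equal(sort(out$individual_id), c(1L, 4L))
  expect_equal(out$capture_year[out$individual_id == 4L], 87L)
  expect_equal(nrow(attr(out, "removed")), 3L)
  # full littermates retained under the exhaustive-nursery variant
  keep <- dedupe_samples(s, collapse_full_sibs = FALSE)
  expect_equal(sort(keep$individual_id), 1:4)
})

test_that("retained count matches a full-sibling graph component oracle", {
  skip_if_not_installed("igraph")
  s <- random_sample_table(n = 50, n_parents = 8, cohort_years = 80:89,
                           seed = 42)
  s <- s[!duplicated(s$individual_id), ]
  out <- dedupe_samples(s)
  # oracle: components of the graph joining samples with identical parent
  # pairs; every component contributes exactly one representative
  g <- igraph::make_empty_graph(n = nrow(s), directed = FALSE)
  for (i in seq_len(nrow(s) - 1)) for (j in (i + 1):nrow(s)) {
    if (!is.na(s$mother_id[i]) && !is.na(s$father_id[i]) &&
        identical(s$mother_id[i], s$mother_id[j]) &&
        identical(s$father_id[i], s$father_id[j])) {
      g <- igraph::add_edges(g, c(i, j))
    }
  }
  expect_equal(nrow(out), igraph::components(g)$no)
})

test_that("a four-sample toy reproduces the hand-enumerated matrix", {
  s <- data.frame(
    individual_id = 1:4, capture_year = 90L, sex = "F",
    true_age = c(3L, 3L, 2L, 1L), assigned_age = c(3L, 3L, 2L, 1L),
    assigned_birth_year = c(87L, 87L, 88L, 89L),
    maturity_at_capture = FALSE,
    mother_id = c(10L, 11L, 10L, 12L), father_id = c(20L, 21L, 22L, 20L)
  )
  ds <- build_hs_matrix(s)
  expect_equal(ds$t0, 88L)
  mat <- ds$cells[ds$cells$side == "maternal", ]
  expect_equal(sum(mat$R), 5L) # six pairs minus the within-cohort one
  # positives: (1,3) share mother 10; (1,4) share father 20
  expect_equal(sum(mat$Y), 1L)
  expect_equal(mat$Y[mat$y_j == 88 & mat$delta == 1], 1L)
  pat <- ds$cells[ds$cells$side == "paternal", ]
  expect_equal(sum(pat$R), 5L)
  expect_equal(pat$Y[pat$y_j == 89 & pat$delta == 2], 1L)
  expect_true(all(ds$cells$delta >= 1))
})

test_that("grouped matrices match the brute-force pairwise enumerator", {
  for (seed in c(11, 23)) {
    s <- random_sample_table(n = 150, n_parents = 25, seed = seed)
    s <- dedupe_samples(s)
    ds <- build_hs_matrix(s, restrict_immature = TRUE)
    oracle <- brute_hs(offspring_pool(s))
    mat <- ds$cells[ds$cells$side == "maternal", ]
    mat <- mat[order(mat$y_j - mat$delta, mat$y_j), ]
    expect_equal(mat$R, oracle$R)
    expect_equal(mat$Y, oracle$Ym)
    pat <- ds$cells[ds$cells$side == "paternal", ]
    pat <- pat[order(pat$y_j - pat$delta, pat$y_j), ]
    expect_equal(pat$Y, oracle$Yp)
    # conservation: one trial per cross-cohort pair per parental side
    pool <- offspring_pool(s)
    tab <- table(pool$assigned_birth_year)
    cross <- (sum(tab)^2 - sum(tab^2)) / 2
    expect_equal(sum(mat$R), cross)
    expect_true(all(ds$cells$Y <= ds$cells$R))
  }
})

test_that("parent-offspring matrices match the brute-force enumerator", {
  s <- random_sample_table(n = 80, n_parents = 15, cohort_years = 60:89,
                           seed = 31)
  s <- dedupe_samples(s)
  # make some candidates true parents of sampled offspring so Y > 0
  s$mother_id[1:10] <- s$individual_id[which(s$sex == "F")[1:5]]
  s$father_id[1:10] <- s$individual_id[which(s$sex == "M")[1:5]]
  ds <- build_po_matrix(s)
  oracle <- brute_po(s)
  got <- ds$cells
  got$sex <- ifelse(got$side == "maternal", "F", "M")
  got <- got[order(got$sex, got$y_j, got$c_i), ]
  oracle <- oracle[order(oracle$sex, oracle$y_j, oracle$c_i), ]
  expect_equal(got$R, oracle$R)
  expect_equal(got$Y, oracle$Y)
  expect_gt(sum(got$Y), 0)
})

test_that("parent maturity is evaluated in the offspring's birth year", {
  s <- data.frame(
    individual_id = 1:3, capture_year = c(87L, 90L, 90L), sex = "F",
    true_age = c(10L, 0L, 0L), assigned_age = c(10L, 0L, 0L),
    assigned_birth_year = c(77L, 90L, 88L),
    maturity_at_capture = c(FALSE, FALSE, FALSE),
    mother_id = NA_integer_, father_id = NA_integer_
  )
  ds <- build_po_matrix(s)
  po <- ds$cells[ds$cells$relationship == "PO", ]
  # candidate 1 is age 13 in 90 (mature: trial) but age 11 in 88 (excluded)
  expect_equal(sum(po$R[po$y_j == 90]), 1L)
  expect_false(any(po$y_j == 88))
})

test_that("no sample is its own potential parent", {
  s <- random_sample_table(n = 60, n_parents = 10, cohort_years = 60:89,
                           seed = 77)
  s <- dedupe_samples(s)
  ds <- build_po_matrix(s)
  oracle <- brute_po(s) # oracle excludes self-pairings by construction
  expect_equal(sum(ds$cells$R), sum(oracle$R))
})

test_that("off-cycle filtering drops exactly the non-divisible gaps", {
  cells <- data.frame(
    relationship = "HS", side = rep(c("maternal", "paternal"), each = 6),
    y_j = 90L, ref_gap = 2L, delta = rep(1:6, 2), c_i = NA_integer_,
    R = rep(10L, 12), Y = 0L
  )
  ds <- closekin:::new_comparison_dataset(cells, 88L)
  f2 <- filter_offcycle(ds, 2)
  kept <- f2$cells[f2$cells$side == "maternal", "delta"]
  expect_equal(sort(kept), c(2L, 4L, 6L))
  expect_equal(sum(f2$cells$side == "paternal"), 6L) # paternal untouched
  f3 <- filter_offcycle(ds, 3)
  expect_equal(sort(f3$cells$delta[f3$cells$side == "maternal"]), c(3L, 6L))
  # retained trials equal the brute sum over divisible gaps
  expect_equal(sum(f2$cells$R[f2$cells$side == "maternal"]),
               sum(cells$R[cells$side == "maternal" & cells$delta %% 2 == 0]))
  expect_error(filter_offcycle(ds, 1), ">= 2")
})

test_that("exact-age biennial positives sit only in even gaps", {
  cfg <- life_history(breeding_cycle_a = 2L, fraction_multiennial = 1)
  sim <- run_simulation(cfg, NULL, n_years = 40, total_census = 3000,
                        seed = 55, snapshot_years = 37:40)
  s <- draw_samples(sim, sampling_scheme("sample_juveniles", 0.02, 37:40),
                    seed = 56)
  ds <- build_hs_matrix(dedupe_samples(s))
  mat <- ds$cells[ds$cells$side == "maternal", ]
  expect_gt(sum(mat$Y), 0)
  expect_true(all(mat$Y[mat$delta %% 2 == 1] == 0))
})

test_that("avuncular contamination adds false positives to the matrix", {
  ped <- toy_pedigree()
  s <- data.frame(
    individual_id = c(4L, 6L), capture_year = c(31L, 43L), sex = "F",
    true_age = c(10L, 3L), assigned_age = c(10L, 3L),
    assigned_birth_year = c(21L, 40L), maturity_at_capture = FALSE,
    mother_id = c(1L, 3L), father_id = c(2L, 5L)
  )
  clean <- build_hs_matrix(s)
  expect_equal(sum(clean$cells$Y), 0L)
  dirty <- build_hs_matrix(s, ped = ped, include_avuncular_as_hsp = TRUE)
  mat <- dirty$cells[dirty$cells$side == "maternal", ]
  expect_equal(sum(mat$Y), 1L)
})

test_that("cell tables and kin-label input round-trip through text", {
  s <- random_sample_table(n = 60, n_parents = 12, seed = 13)
  s <- dedupe_samples(s)
  ds <- build_hs_matrix(s)
  path <- tempfile(fileext = ".tsv")
  write_cells(ds, path)
  back <- read_cells(path)
  expect_equal(back$t0, ds$t0)
  expect_equal(back$cells$R, ds$cells$R)
  expect_equal(back$cells$Y, ds$cells$Y)
  # kin labels reconstructed from the truth give the same positive counts
  pool <- offspring_pool(s)
  labs <- list()
  for (i in seq_len(nrow(pool) - 1)) for (j in (i + 1):nrow(pool)) {
    for (sd in c("maternal", "paternal")) {
      pid <- if (sd == "maternal") "mother_id" else "father_id"
      if (!is.na(pool[[pid]][i]) && !is.na(pool[[pid]][j]) &&
          pool[[pid]][i] == pool[[pid]][j]) {
        labs[[length(labs) + 1L]] <- data.frame(
          id_a = pool$individual_id[i], id_b = pool$individual_id[j],
          relationship = "HS", side = sd)
      }
    }
  }
  labs <- do.call(rbind, labs)
  lp <- tempfile(fileext = ".tsv")
  utils::write.table(labs, lp, sep = "\t", quote = FALSE, row.names = FALSE)
  ds2 <- hs_matrix_from_labels(s, read_kin_labels(lp))
  expect_equal(ds2$cells$Y, ds$cells$Y)
  expect_equal(ds2$cells$R, ds$cells$R)
})
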