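#' Label the kinship of a pair from the pedigree
#'
#' Exact truth labels from parent links: self, parent-offspring (maternal
#' `MPOP` / paternal `PPOP`), full sibling (`FSP`: both parents shared —
#' never reported as a half sibling), half sibling (`MHSP` / `PHSP`),
#' avuncular/grand (second-degree collateral pairs, genetically
#' indistinguishable from half siblings), or unrelated.
#'
#' @param ped A pedigree data.frame as returned by [pedigree()].
#' @param id_a,id_b Individual ids.
#' @param include_avuncular_as_hsp When `TRUE`, avuncular/grand pairs are
#'   returned as (false-positive) `MHSP`/`PHSP` according to whether the
#'   shared lineage runs through the younger member's mother or father.
#' @return A single character label.
#' @export
label_kinship <- function(ped, id_a, id_b, include_avuncular_as_hsp = FALSE) {
  idx <- match(c(id_a, id_b), ped$id)
  if (anyNA(idx)) stop("unknown individual id")
  if (id_a == id_b) return("self")
  a <- idx[1]; b <- idx[2]
  ma <- ped$mother_id[a]; fa <- ped$father_id[a]
  mb <- ped$mother_id[b]; fb <- ped$father_id[b]
  if (identical(ped$id[a], mb) || identical(ped$id[b], ma)) return("MPOP")
  if (identical(ped$id[a], fb) || identical(ped$id[b], fa)) return("PPOP")
  same_m <- !is.na(ma) && !is.na(mb) && ma == mb
  same_f <- !is.na(fa) && !is.na(fb) && fa == fb
  if (same_m && same_f) return("FSP")
  if (same_m) return("MHSP")
  if (same_f) return("PHSP")
  av <- avuncular_side(ped, a, b)
  if (!is.na(av)) {
    if (include_avuncular_as_hsp) return(if (av == "maternal") "MHSP" else "PHSP")
    return("avuncular")
  }
  "unrelated"
}

# Is (a, b) an avuncular or grandparent-type pair? Returns "maternal" /
# "paternal" for the lineage through the younger member's mother/father,
# or NA. Indices into ped, not ids.
avuncular_side <- function(ped, a, b) {
  # order so that `young` is the later-born member
  if (ped$birth_year[a] > ped$birth_year[b]) { young <- a; old <- b }
  else { young <- b; old <- a }
  for (side in c("maternal", "paternal")) {
    par_id <- if (side == "maternal") ped$mother_id[young] else ped$father_id[young]
    if (is.na(par_id)) next
    p <- match(par_id, ped$id)
    # grandparent: old IS a parent of the connecting parent
    gp <- c(ped$mother_id[p], ped$father_id[p])
    if (ped$id[old] %in% gp[!is.na(gp)]) return(side)
    # aunt/uncle: old shares a parent with the connecting parent
    mo <- ped$mother_id[old]; fo <- ped$father_id[old]
    if ((!is.na(mo) && !is.na(gp[1]) && mo == gp[1]) ||
        (!is.na(fo) && !is.na(gp[2]) && fo == gp[2])) return(side)
  }
  NA_character_
}

#' Reduce samples to independent comparison units
#'
#' Enforces the independence assumptions of the pairwise comparison matrix:
#' each individual sampled in multiple years keeps exactly one capture
#' instance, and each set of sampled full siblings (same mother AND father,
#' any birth years) keeps exactly one representative. The representative is
#' the earliest capture, ties broken by lowest id (deterministic).
#'
#' @param samples A `Sample` data.frame.
#' @param collapse_full_sibs Set `FALSE` to retain full littermates (the
#'   exhaustively-sampled-nursery variant); self-recaptures are still
#'   reduced and within-cohort comparisons are always excluded downstream.
#' @return The reduced samples; removed rows are attached as
#'   `attr(, "removed")`.
#' @export
dedupe_samples <- function(samples, collapse_full_sibs = TRUE) {
  ord <- order(samples$capture_year, samples$individual_id)
  s <- samples[ord, ]
  keep <- !duplicated(s$individual_id)
  if (collapse_full_sibs) {
    litter <- ifelse(is.na(s$mother_id) | is.na(s$father_id),
                     paste0("solo", s$individual_id),
                     paste(s$mother_id, s$father_id, sep = "_"))
    keep <- keep & !duplicated(litter)
  }
  out <- s[keep, ]
  removed <- s[!keep, ]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

new_comparison_dataset <- function(cells, t0, provenance = character()) {
  rownames(cells) <- NULL
  structure(list(cells = cells, t0 = as.integer(t0),
                 provenance = provenance),
            class = "comparison_dataset")
}

#' @export
print.comparison_dataset <- function(x, ...) {
  cat("<comparison_dataset> t0 =", x$t0, "\n")
  tab <- stats::aggregate(cbind(R, Y) ~ relationship + side, data = x$cells, sum)
  print(tab, row.names = FALSE)
  if (length(x$provenance)) cat("  filters:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

# offspring pool for comparisons: individuals immature at capture. Adults
# sampled under the all-ages scheme enter only as potential parents, which
# keeps the reference year t0 anchored to juvenile cohorts.
offspring_pool <- function(samples) {
  samples[!samples$maturity_at_capture, , drop = FALSE]
}

#' Build the grouped half-sibling comparison matrix
#'
#' Enumerates all unordered pairs of (immature-at-capture) samples with
#' distinct assigned birth years; within-cohort comparisons are excluded.
#' Each pair contributes one trial to the maternal-HS cell and one to the
#' paternal-HS cell for its `(y_j, delta)` key, where `y_j` is the younger
#' birth year and `delta = y_j - y_i` the birth-year gap. A pair is a
#' maternal positive iff the two share a mother, paternal iff they share a
#' father (after [dedupe_samples()] no pair shares both). The reference
#' year `t0` defaults to the earliest `y_j` — the second-oldest cohort
#' present.
#'
#' @param samples Deduped `Sample` data.frame with `assigned_birth_year`.
#' @param t0 Optional reference-year override.
#' @param ped Optional pedigree data.frame; required only for
#'   `include_avuncular_as_hsp`.
#' @param include_avuncular_as_hsp Count avuncular/grand pairs as
#'   (false-positive) half-sibling positives on the corresponding side.
#' @param restrict_immature Use only samples immature at capture as the
#'   comparison pool (default); set `FALSE` to compare all samples.
#' @return A `comparison_dataset` whose `cells` have columns
#'   relationship ("HS"), side ("maternal"/"paternal"), y_j, ref_gap,
#'   delta, c_i (NA), R, Y.
#' @export
build_hs_matrix <- function(samples, t0 = NULL, ped = NULL,
                            include_avuncular_as_hsp = FALSE,
                            restrict_immature = TRUE) {
  s <- if (restrict_immature) offspring_pool(samples) else samples
  by <- s$assigned_birth_year
  cohorts <- sort(unique(by))
  if (length(cohorts) < 2L) stop("need at least 2 distinct cohorts")
  if (is.null(t0)) t0 <- cohorts[2L]

  nt <- as.data.frame(table(by), stringsAsFactors = FALSE)
  nt$by <- as.integer(nt$by)
  grid <- expand.grid(i = seq_len(nrow(nt)), j = seq_len(nrow(nt)))
  grid <- grid[nt$by[grid$i] < nt$by[grid$j], , drop = FALSE]
  cells <- data.frame(
    y_i = nt$by[grid$i], y_j = nt$by[grid$j],
    R = nt$Freq[grid$i] * nt$Freq[grid$j]
  )

  pos_counts <- function(parent) {
    ok <- !is.na(parent)
    if (!any(ok)) return(cells$R * 0L)
    dt <- data.table::data.table(parent = parent[ok], by = by[ok])
    cnt <- dt[, .N, by = c("parent", "by")]
    pr <- merge(cnt, cnt, by = "parent", allow.cartesian = TRUE)
    pr <- pr[pr$by.x < pr$by.y, ]
    if (nrow(pr) == 0L) return(cells$R * 0L)
    agg <- pr[, list(Y = sum(N.x * N.y)), by = c("by.x", "by.y")]
    key <- paste(cells$y_i, cells$y_j)
    y <- integer(nrow(cells))
    m <- match(paste(agg$by.x, agg$by.y), key)
    y[m] <- agg$Y
    y
  }
  Ym <- pos_counts(s$mother_id)
  Yp <- pos_counts(s$father_id)

  if (include_avuncular_as_hsp) {
    if (is.null(ped)) stop("avuncular contamination requires the pedigree")
    av <- avuncular_pair_counts(s, ped)
    key <- paste(cells$y_i, cells$y_j)
    if (nrow(av$maternal)) {
      m <- match(paste(av$maternal$y_i, av$maternal$y_j), key)
      Ym[m] <- Ym[m] + av$maternal$n
    }
    if (nrow(av$paternal)) {
      m <- match(paste(av$paternal$y_i, av$paternal$y_j), key)
      Yp[m] <- Yp[m] + av$paternal$n
    }
  }

  two_sided <- rbind(
    data.frame(relationship = "HS", side = "maternal", y_j = cells$y_j,
               ref_gap = cells$y_j - t0, delta = cells$y_j - cells$y_i,
               c_i = NA_integer_, R = cells$R, Y = Ym),
    data.frame(relationship = "HS", side = "paternal", y_j = cells$y_j,
               ref_gap = cells$y_j - t0, delta = cells$y_j - cells$y_i,
               c_i = NA_integer_, R = cells$R, Y = Yp)
  )
  stopifnot(all(two_sided$Y <= two_sided$R), all(two_sided$delta >= 1L))
  new_comparison_dataset(two_sided, t0)
}

# counts of avuncular/grand pairs among the sampled set, by cohort pair and
# lineage side (through the younger member's mother or father)
avuncular_pair_counts <- function(s, ped) {
  n <- nrow(s)
  out_m <- list(); out_p <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ia <- match(s$individual_id[i], ped$id)
      ib <- match(s$individual_id[j], ped$id)
      # skip pairs that are already first-degree or half-sib positives
      lab <- label_kinship(ped, s$individual_id[i], s$individual_id[j])
      if (lab != "avuncular") next
      side <- avuncular_side(ped, ia, ib)
      ys <- sort(c(s$assigned_birth_year[i], s$assigned_birth_year[j]))
      if (ys[1] == ys[2]) next
      row <- data.frame(y_i = ys[1], y_j = ys[2], n = 1L)
      if (side == "maternal") out_m[[length(out_m) + 1L]] <- row
      else out_p[[length(out_p) + 1L]] <- row
    }
  }
  collapse <- function(lst) {
    if (!length(lst)) return(data.frame(y_i = integer(), y_j = integer(), n = integer()))
    d <- do.call(rbind, lst)
    stats::aggregate(n ~ y_i + y_j, data = d, sum)
  }
  list(maternal = collapse(out_m), paternal = collapse(out_p))
}

#' Build the grouped parent-offspring comparison matrix
#'
#' For each offspring cohort `y_j` among the (immature-at-capture) samples,
#' the potential parents are all other samples that are reproductively
#' mature in `y_j` (assigned age at `y_j` of at least `maturity_age`) and
#' not known dead before `y_j` (sampling is non-lethal). Trials are grouped
#' by (parent sex, `y_j`, parent capture year `c_i`); positives are pairs
#' where the candidate is the true mother (maternal) or father (paternal).
#'
#' @param samples Deduped `Sample` data.frame.
#' @param maturity_age Knife-edged maturity age used for the parent filter.
#' @param t0 Optional reference-year override (defaults to the earliest
#'   `y_j`, matching [build_hs_matrix()]).
#' @return A `comparison_dataset` with `relationship = "PO"` cells.
#' @export
build_po_matrix <- function(samples, maturity_age = 12L, t0 = NULL) {
  off <- offspring_pool(samples)
  cohorts <- sort(unique(off$assigned_birth_year))
  if (length(cohorts) == 0L) stop("no immature-at-capture offspring in samples")
  if (is.null(t0)) t0 <- cohorts[min(2L, length(cohorts))]
  rows <- list()
  for (yj in cohorts) {
    kids <- off[off$assigned_birth_year == yj, , drop = FALSE]
    age_at_yj <- yj - samples$assigned_birth_year
    par <- samples[age_at_yj >= maturity_age, , drop = FALSE]
    if (nrow(par) == 0L || nrow(kids) == 0L) next
    # exclude self-pairings (an individual cannot parent its own cohort row)
    for (sx in c("F", "M")) {
      ps <- par[par$sex == sx, , drop = FALSE]
      if (nrow(ps) == 0L) next
      for (ci in sort(unique(ps$capture_year))) {
        cand <- ps[ps$capture_year == ci, , drop = FALSE]
        R <- nrow(cand) * nrow(kids) -
          sum(cand$individual_id %in% kids$individual_id)
        if (R == 0L) next
        truth <- if (sx == "F") kids$mother_id else kids$father_id
        Y <- sum(!is.na(truth) & truth %in% cand$individual_id)
        rows[[length(rows) + 1L]] <- data.frame(
          relationship = "PO",
          side = if (sx == "F") "maternal" else "paternal",
          y_j = yj, ref_gap = yj - t0, delta = NA_integer_,
          c_i = ci, R = R, Y = Y)
      }
    }
  }
  cells <- do.call(rbind, rows)
  if (is.null(cells)) {
    cells <- data.frame(relationship = character(), side = character(),
                        y_j = integer(), ref_gap = integer(),
                        delta = integer(), c_i = integer(),
                        R = integer(), Y = integer())
  }
  new_comparison_dataset(cells, t0)
}

#' Combine comparison datasets
#'
#' Binds the cells of several datasets (typically HS and PO) into one,
#' re-anchoring `t0` to the birth year of the second-oldest cohort
#' represented across all cells (the earliest `y_j` of the half-sibling
#' matrix, whose oldest cohort appears only as the older pair member)
#' unless overridden, and recomputing `ref_gap` accordingly.
#'
#' @param ... `comparison_dataset` objects.
#' @param t0 Optional reference-year override.
#' @return A `comparison_dataset`.
#' @export
combine_comparisons <- function(..., t0 = NULL) {
  ds <- list(...)
  cells <- do.call(rbind, lapply(ds, function(d) d$cells))
  if (is.null(t0)) {
    hs <- cells$relationship == "HS"
    cohorts <- sort(unique(c(cells$y_j, cells$y_j[hs] - cells$delta[hs])))
    t0 <- cohorts[min(2L, length(cohorts))]
  }
  cells$ref_gap <- cells$y_j - t0
  new_comparison_dataset(cells, t0,
                         provenance = unlist(lapply(ds, function(d) d$provenance)))
}

#' Remove off-cycle half-sibling comparisons
#'
#' Drops every half-sibling cell whose birth-year gap is not evenly
#' divisible by the breeding interval `a` (the filtered-naive approach:
#' those cells cannot contain positives when every female breeds on the
#' same `a`-year schedule). Applied to the maternal side only by default,
#' since males breed annually.
#'
#' @param dataset A `comparison_dataset` with HS cells.
#' @param a Breeding interval (>= 2; with `a = 1` no off-cycle cells exist).
#' @param side Which side(s) to filter.
#' @return The filtered `comparison_dataset`.
#' @export
filter_offcycle <- function(dataset, a, side = "maternal") {
  if (a < 2L) stop("a must be >= 2: no off-cycle cells exist for annual breeding")
  cells <- dataset$cells
  drop <- cells$relationship == "HS" & cells$side %in% side &
    (cells$delta %% a != 0L)
  new_comparison_dataset(cells[!drop, , drop = FALSE], dataset$t0,
                         provenance = c(dataset$provenance,
                                        sprintf("offcycle_filtered(a=%d)", a)))
}
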