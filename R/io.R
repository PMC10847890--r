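#' Tabular import/export
#'
#' All tabular interfaces are headered tab-delimited text: pedigrees
#' (one row per individual ever alive), sample tables (one row per capture),
#' comparison-cell tables (relationship, side, y_j, ref_gap, delta_or_ci,
#' n_comparisons, n_positive), posterior draws (chain, iteration,
#' parameter, value) and posterior summaries.
#'
#' @param x Object to write (see the individual functions).
#' @param path File path.
#' @name ckmr_io
NULL

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = c("", "NA"),
                    stringsAsFactors = FALSE)
}

#' @rdname ckmr_io
#' @param sim A `ckmr_simulation`.
#' @export
write_pedigree <- function(sim, path) write_tsv(pedigree(sim), path)

#' @rdname ckmr_io
#' @export
read_pedigree <- function(path) read_tsv(path)

#' @rdname ckmr_io
#' @export
write_samples <- function(x, path) write_tsv(x, path)

#' @rdname ckmr_io
#' @export
read_samples <- function(path) {
  s <- read_tsv(path)
  if (is.null(s$assigned_age) && !is.null(s$true_age)) {
    s$assigned_age <- s$true_age
  }
  if (is.null(s$assigned_birth_year)) {
    s$assigned_birth_year <- s$capture_year - s$assigned_age
  }
  s
}

#' @rdname ckmr_io
#' @param dataset A `comparison_dataset`.
#' @export
write_cells <- function(dataset, path) {
  cells <- dataset$cells
  out <- data.frame(relationship = cells$relationship, side = cells$side,
                    y_j = cells$y_j, ref_gap = cells$ref_gap,
                    delta_or_ci = ifelse(cells$relationship == "HS",
                                         cells$delta, cells$c_i),
                    n_comparisons = cells$R, n_positive = cells$Y)
  attr_line <- sprintf("# t0 = %d", dataset$t0)
  con <- file(path, "w")
  writeLines(attr_line, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname ckmr_io
#' @export
read_cells <- function(path) {
  first <- readLines(path, n = 1L)
  t0 <- as.integer(sub(".*t0 = ", "", first))
  d <- utils::read.delim(path, sep = "\t", skip = 1L)
  cells <- data.frame(relationship = d$relationship, side = d$side,
                      y_j = d$y_j, ref_gap = d$ref_gap,
                      delta = ifelse(d$relationship == "HS",
                                     d$delta_or_ci, NA_integer_),
                      c_i = ifelse(d$relationship == "PO",
                                   d$delta_or_ci, NA_integer_),
                      R = d$n_comparisons, Y = d$n_positive)
  new_comparison_dataset(cells, t0)
}

#' @rdname ckmr_io
#' @param fit A `ckmr_fit`.
#' @export
write_posterior <- function(fit, path) {
  rows <- list()
  for (ch in seq_along(fit$draws)) {
    d <- fit$draws[[ch]]
    for (p in setdiff(colnames(d), "lp__")) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, iteration = seq_len(nrow(d)), parameter = p,
        value = d[, p])
    }
  }
  write_tsv(do.call(rbind, rows), path)
}

#' @rdname ckmr_io
#' @export
write_posterior_summary <- function(fit, path) write_tsv(fit$summary, path)

#' Read externally inferred kin labels
#'
#' Input dialect for real data: a headered delimited table of
#' `id_a, id_b, relationship, side` rows (relationship `HS` or `PO`;
#' side `maternal` or `paternal`) that lets genetically inferred kinship
#' bypass the pedigree.
#'
#' @param path File path.
#' @return A data.frame of kin labels.
#' @export
read_kin_labels <- function(path) {
  d <- read_tsv(path)
  stopifnot(all(c("id_a", "id_b", "relationship", "side") %in% names(d)))
  d
}

#' Half-sibling matrix from external kin labels
#'
#' Builds the grouped half-sibling comparison matrix for samples whose
#' kinship was inferred externally (e.g., from genetic markers) instead of
#' a pedigree: trials are all cross-cohort pairs, positives are the labeled
#' pairs.
#'
#' @param samples Deduped `Sample` data.frame.
#' @param labels Kin labels as from [read_kin_labels()].
#' @param t0 Optional reference-year override.
#' @param restrict_immature Restrict the comparison pool to samples
#'   immature at capture.
#' @return A `comparison_dataset`.
#' @export
hs_matrix_from_labels <- function(samples, labels, t0 = NULL,
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
  cells <- data.frame(y_i = nt$by[grid$i], y_j = nt$by[grid$j],
                      R = nt$Freq[grid$i] * nt$Freq[grid$j])
  lab <- labels[labels$relationship == "HS", , drop = FALSE]
  ba <- by[match(lab$id_a, s$individual_id)]
  bb <- by[match(lab$id_b, s$individual_id)]
  ok <- !is.na(ba) & !is.na(bb) & ba != bb
  lo <- pmin(ba, bb)[ok]; hi <- pmax(ba, bb)[ok]; side <- lab$side[ok]
  key <- paste(cells$y_i, cells$y_j)
  out <- list()
  for (sd in c("maternal", "paternal")) {
    Y <- integer(nrow(cells))
    if (any(side == sd)) {
      tab <- table(paste(lo[side == sd], hi[side == sd]))
      m <- match(names(tab), key)
      Y[m[!is.na(m)]] <- as.integer(tab)[!is.na(m)]
    }
    out[[sd]] <- data.frame(relationship = "HS", side = sd,
                            y_j = cells$y_j, ref_gap = cells$y_j - t0,
                            delta = cells$y_j - cells$y_i,
                            c_i = NA_integer_, R = cells$R, Y = Y)
  }
  new_comparison_dataset(rbind(out$maternal, out$paternal), t0)
}
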