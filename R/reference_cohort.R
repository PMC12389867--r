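#' The packaged reference cohort index table
#'
#' Per-subject values of every trajectory index for the reference smooth
#' pursuit cohort: nine patients with schizophrenia under treatment (SZ) and
#' nine healthy controls (CNT), as published to 2-decimal precision. Columns
#' follow the cohort-table layout used throughout the package: one row per
#' (subject, index, parameter), where `param` is `"r1/r2"` in mm for
#' colocality, the window length in ms for the normalised polygon area, and
#' `NA` for the two direction indices.
#'
#' @param path Optional override of the packaged CSV.
#' @return A `cohort_table` data frame (288 rows: 18 subjects x 16 index
#'   columns) with columns `subject_id`, `group`, `index`, `param`, `key`,
#'   `value`.
#' @export
#' @examples
#' tab <- reference_cohort()
#' aggregate(value ~ key + group, tab, mean)
reference_cohort <- function(path = system.file("extdata",
                                                "reference_cohort_indices.csv",
                                                package = "spemtrack")) {
  if (!nzchar(path) || !file.exists(path))
    stop("reference cohort fixture not found", call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("reference cohort fixture is empty", call. = FALSE)
  needed <- c("subject_id", "group", "index", "param", "value")
  if (!all(needed %in% names(tab)))
    stop("malformed fixture: expected columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  tab$param <- as.character(tab$param)
  tab$key <- index_key(tab$index, tab$param)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

# Published group-mean row for the reference cohort (2-decimal values), with
# the published significance asterisks.
published_reference_means <- function() {
  data.frame(
    key = c("co_5_2", "co_5_4", "co_5_8", "co_10_2", "co_10_4", "co_10_8",
            "co_15_2", "co_15_4", "co_15_8", "dtheta_sample", "dtheta_regr",
            "area_250", "area_500", "area_750", "area_1000", "area_1500"),
    mean_sz = c(0.87, 0.85, 0.37, 0.95, 0.95, 0.94, 0.97, 0.97, 0.97,
                0.66, 0.31, 0.09, 0.15, 0.17, 0.10, 0.21),
    mean_cnt = c(0.98, 0.96, 0.39, 1.00, 1.00, 0.99, 1.00, 1.00, 1.00,
                 0.56, 0.09, 0.04, 0.06, 0.08, 0.06, 0.13),
    significant_sz = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                       FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# Columns whose published group mean is inconsistent with the published
# per-subject values (re-averaging and rounding half-away-from-zero gives a
# different 2-decimal value). These are reported as documented discrepancies
# of the source table, not reproduction failures.
known_mean_discrepancies <- function() {
  data.frame(
    key = c("dtheta_sample", "co_10_4", "co_15_8", "area_1000"),
    group = c("SZ", "SZ", "SZ", "CNT"),
    published = c(0.66, 0.95, 0.97, 0.06),
    recomputed_2dec = c(0.64, 0.96, 0.98, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Reproduce the reference cohort's published group means
#'
#' Recomputes every group mean from the packaged per-subject values, compares
#' it with the published mean row after 2-decimal half-away-from-zero
#' rounding, and attaches the Mann-Whitney p-value and Hedges' g per column.
#' Four published means are internally inconsistent with their own
#' per-subject column (re-averaging gives a different 2-decimal value); these
#' are flagged as `known_discrepancy` and do not count as failures.
#'
#' @param table The reference cohort table (default [reference_cohort()]).
#' @return A data frame with one row per (index column, group): recomputed
#'   mean, published mean, `match` flag, `known_discrepancy` flag, plus
#'   per-column `U`, `p_value` and `hedges_g`. Attribute `all_pass` is `TRUE`
#'   when every non-discrepant column matches.
#' @export
#' @examples
#' rep <- reproduce_reference_means()
#' attr(rep, "all_pass")
reproduce_reference_means <- function(table = reference_cohort()) {
  comp <- summarize_cohort(table)
  pub <- published_reference_means()
  disc <- known_mean_discrepancies()
  rows <- list()
  for (i in seq_len(nrow(pub))) {
    k <- pub$key[i]
    cr <- comp[comp$key == k, ]
    if (nrow(cr) != 1L)
      stop(sprintf("index column '%s' missing from the fixture", k), call. = FALSE)
    for (grp in c("SZ", "CNT")) {
      recomputed <- if (grp == "SZ") cr$mean_a else cr$mean_b
      published <- if (grp == "SZ") pub$mean_sz[i] else pub$mean_cnt[i]
      known <- any(disc$key == k & disc$group == grp)
      rows[[length(rows) + 1L]] <- data.frame(
        key = k, group = grp,
        recomputed_mean = recomputed,
        recomputed_2dec = round_half_away(recomputed, 2),
        published_mean = published,
        match = round_half_away(recomputed, 2) == published,
        known_discrepancy = known,
        U = cr$U, p_value = cr$p_value, hedges_g = cr$hedges_g,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "all_pass") <- all(out$match | out$known_discrepancy)
  out
}
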