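# Fixed display orderings so cross-tab outputs are diffable.
LEVEL_ORDERS <- list(
  ik_class = c("high", "moderate", "low"),
  ik_class_14 = c("luminal_B", "luminal_A"),
  er_level = c("high", "low", "negative"),
  pr_level = c("high", "low", "negative"),
  luminal = c("luminal", "non_luminal"),
  npi_group = c("GPG", "MPG", "PPG")
)

order_levels <- function(values, factor_name) {
  pref <- LEVEL_ORDERS[[factor_name]]
  u <- unique(as.character(values))
  if (is.null(pref)) sort(u) else c(pref, sort(setdiff(u, pref)))
}

#' Cross-tabulate a stratified cohort
#'
#' Counts and row-percentages of `col_factor` within each level of
#' `row_factor`, in the style of published IK-distribution tables: each
#' row shows `% (n)` per column plus the row total. Percentages are
#' rounded half-up; counts are authoritative.
#'
#' @param cases a stratified cohort: data frame with one row per case
#'   (e.g. from [stratify_cohort()]).
#' @param row_factor,col_factor column names of `cases` to tabulate.
#' @param digits decimal places for percentages (default 1).
#' @return An object of class `cross_tab`: a list with `counts` (matrix,
#'   rows x columns), `pct` (row percentages), `row_totals`,
#'   `grand_total`, and the factor names.
#' @examples
#' coh <- data.frame(g = rep(c("a", "b"), c(2, 3)),
#'                   k = c("x", "y", "x", "x", "y"))
#' cohort_cross_tab(coh, "g", "k")
#' @export
cohort_cross_tab <- function(cases, row_factor, col_factor, digits = 1) {
  cases <- as.data.frame(cases)
  if (nrow(cases) == 0) abort_validation("Cannot cross-tabulate an empty cohort.")
  for (f in c(row_factor, col_factor)) {
    if (!f %in% names(cases)) {
      abort_validation(sprintf("Unknown factor '%s' (not a column of the cohort).", f))
    }
  }
  rl <- order_levels(cases[[row_factor]], row_factor)
  cl <- order_levels(cases[[col_factor]], col_factor)
  counts <- table(factor(cases[[row_factor]], rl),
                  factor(cases[[col_factor]], cl))
  counts <- matrix(as.integer(counts), nrow = length(rl),
                   dimnames = list(rl, cl))
  row_totals <- rowSums(counts)
  pct <- counts
  for (i in seq_along(rl)) {
    pct[i, ] <- if (row_totals[i] > 0) pct_of(counts[i, ], row_totals[i], digits) else 0
  }
  structure(list(row_factor = row_factor, col_factor = col_factor,
                 counts = counts, pct = pct, row_totals = row_totals,
                 grand_total = sum(counts)),
            class = "cross_tab")
}

#' @export
print.cross_tab <- function(x, ...) {
  cat(sprintf("<cross_tab> %s x %s (n = %d)\n", x$row_factor, x$col_factor,
              x$grand_total))
  cells <- matrix(sprintf("%.1f (%d)", x$pct, x$counts),
                  nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  out <- cbind(cells, Total = as.character(x$row_totals))
  print(out, quote = FALSE)
  invisible(x)
}

#' @export
as.data.frame.cross_tab <- function(x, ...) {
  df <- expand.grid(row = rownames(x$counts), col = colnames(x$counts),
                    stringsAsFactors = FALSE)
  df$count <- as.vector(x$counts)
  df$pct <- as.vector(x$pct)
  df$row_total <- x$row_totals[df$row]
  names(df)[1:2] <- c(x$row_factor, x$col_factor)
  df
}

#' Write a cross-tab to CSV
#'
#' @param x a `cross_tab`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cross_tab <- function(x, path) {
  if (!inherits(x, "cross_tab")) abort_validation("`x` must be a cross_tab.")
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Structured per-case report
#'
#' Bundles the stratification result with the case-level IK detail and
#' quality flags into a plain list that serialises to JSON and parses
#' back to identical values. The `flags` element marks a case that
#' missed the minimum-nuclei rule, carried near-duplicate marker pairs,
#' or sits in the chemotherapy-stratification-relevant combination
#' (luminal-A candidate with high IK).
#'
#' @param result a `stratification_result` from [classify_case()].
#' @param case_ik optional `case_ik` from [aggregate_case()] for the
#'   per-field detail.
#' @param near_duplicates optional result of [flag_near_duplicates()].
#' @param path optional JSON output path.
#' @return The report list (invisibly if written to `path`).
#' @export
case_report <- function(result, case_ik = NULL, near_duplicates = NULL,
                        path = NULL) {
  if (!inherits(result, "stratification_result")) {
    abort_validation("`result` must be a stratification_result.")
  }
  rep <- list(
    case_id = result$case_id,
    classification = as.list(as.data.frame(result)),
    ik_detail = if (!is.null(case_ik)) list(
      per_field_ik = case_ik$per_field_ik,
      per_field_density = round(case_ik$per_field_density),
      total_nuclei = case_ik$total_nuclei,
      n_fields = case_ik$n_fields,
      ik_mean = case_ik$ik_mean,
      ik_pooled = case_ik$ik_pooled),
    flags = list(
      minimum_unmet = if (!is.null(case_ik)) !case_ik$meets_minimum
                      else isFALSE(result$meets_minimum),
      near_duplicate_pairs = if (!is.null(near_duplicates)) nrow(near_duplicates) else 0L,
      chemo_stratification = isTRUE(result$chemo_flag))
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(rep))
  }
  rep
}
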