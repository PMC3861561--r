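#' Per-field Ki-67 proliferation index
#'
#' The IK of one field is the percentage of Ki-67-positive nuclei among
#' all tumor nuclei counted in that field: `100 * pos / (pos + neg)`.
#'
#' @param n_positive,n_negative non-negative counts (vectorised in
#'   parallel). Each field must contain at least one nucleus.
#' @return Percentage(s) in `[0, 100]`, full precision.
#' @examples
#' per_field_ik(45, 128)  # 26.01% — a typical field
#' @export
per_field_ik <- function(n_positive, n_negative) {
  if (!is.numeric(n_positive) || !is.numeric(n_negative) ||
      any(n_positive < 0) || any(n_negative < 0) ||
      any(n_positive != trunc(n_positive)) || any(n_negative != trunc(n_negative))) {
    abort_validation("`n_positive` and `n_negative` must be non-negative integer counts.")
  }
  total <- n_positive + n_negative
  if (any(total < 1)) {
    abort_validation("empty field: IK is undefined when a field has zero nuclei.")
  }
  100 * n_positive / total
}

#' Count positive and negative markers in annotated fields
#'
#' @param fields a [field_annotation()] or list of them.
#' @return A tibble with one row per field: `case_id`, `field_id`,
#'   `n_positive`, `n_negative`, `area_mm2`.
#' @export
count_markers <- function(fields) {
  if (inherits(fields, "field_annotation")) fields <- list(fields)
  rows <- lapply(fields, function(f) {
    tibble::tibble(case_id = f$case_id, field_id = f$field_id,
                   n_positive = sum(f$markers$label == "positive"),
                   n_negative = sum(f$markers$label == "negative"),
                   area_mm2 = field_area_mm2(f$geometry))
  })
  do.call(rbind, rows)
}

#' Aggregate per-field counts into a case-level IK
#'
#' The case IK is the unweighted arithmetic mean of the per-field IK
#' values (the protocol's estimator). The pooled ratio
#' `100 * sum(pos) / sum(total)` is always computed alongside as a
#' diagnostic: the two diverge when field totals are unequal. The case is
#' checked against the minimum-nuclei rule (default 1,000 counted nuclei);
#' a shortfall raises a warning and sets `meets_minimum = FALSE` rather
#' than failing, so partial cases remain inspectable.
#'
#' @param counts a data frame with columns `n_positive` and `n_negative`
#'   (one row per field; e.g. from [count_markers()]), optionally
#'   `area_mm2` for per-field densities.
#' @param case_id case identifier; taken from `counts$case_id` if present.
#' @param minimum minimum total nuclei for a reliable IK (default 1000).
#' @param area_mm2 fallback field area for densities when `counts` has no
#'   `area_mm2` column; default the reference x40 field.
#' @return An object of class `case_ik` with elements `case_id`,
#'   `per_field_ik`, `total_nuclei`, `ik_mean` (primary result),
#'   `ik_pooled` (diagnostic), `meets_minimum`, `per_field_density`,
#'   `n_fields`.
#' @examples
#' aggregate_case(data.frame(n_positive = c(1, 90), n_negative = c(9, 10)))
#' @export
aggregate_case <- function(counts, case_id = NULL, minimum = 1000,
                           area_mm2 = field_area_mm2()) {
  counts <- as.data.frame(counts)
  if (nrow(counts) == 0) abort_validation("A case needs at least one field.")
  if (!all(c("n_positive", "n_negative") %in% names(counts))) {
    abort_validation("`counts` must have columns n_positive and n_negative.")
  }
  if (!is_count(minimum)) abort_validation("`minimum` must be a non-negative count.")
  case_id <- case_id %||%
    (if ("case_id" %in% names(counts)) as.character(counts$case_id[1]) else NA_character_)
  if ("case_id" %in% names(counts) &&
      length(unique(counts$case_id)) > 1L) {
    abort_validation("`counts` mixes several case_ids; aggregate one case at a time (see score_cases()).")
  }
  ik <- per_field_ik(counts$n_positive, counts$n_negative)
  totals <- counts$n_positive + counts$n_negative
  areas <- if ("area_mm2" %in% names(counts)) counts$area_mm2 else rep(area_mm2, nrow(counts))
  total_nuclei <- sum(totals)
  meets <- total_nuclei >= minimum
  if (!meets) {
    warn(sprintf("Case %s: %d nuclei counted, below the minimum of %d.",
                 case_id, total_nuclei, minimum),
         class = "ki67_minimum_unmet")
  }
  structure(
    list(case_id = case_id,
         per_field_ik = ik,
         total_nuclei = total_nuclei,
         ik_mean = mean(ik),
         ik_pooled = 100 * sum(counts$n_positive) / total_nuclei,
         meets_minimum = meets,
         per_field_density = totals / areas,
         n_fields = nrow(counts),
         minimum = minimum),
    class = "case_ik"
  )
}

#' @export
print.case_ik <- function(x, ...) {
  cat(sprintf("<case_ik> case %s: IK %.1f%% (mean of %d fields; pooled %.1f%%)\n",
              x$case_id, round_half_up(x$ik_mean, 1), x$n_fields,
              round_half_up(x$ik_pooled, 1)))
  cat(sprintf("  %d nuclei counted — minimum of %d %s\n", x$total_nuclei,
              x$minimum, if (x$meets_minimum) "met" else "NOT met"))
  invisible(x)
}

#' @export
as.data.frame.case_ik <- function(x, ...) {
  data.frame(case_id = x$case_id, n_fields = x$n_fields,
             total_nuclei = x$total_nuclei,
             ik_mean = x$ik_mean, ik_pooled = x$ik_pooled,
             meets_minimum = x$meets_minimum,
             stringsAsFactors = FALSE)
}

#' Score annotated fields into case-level IK results
#'
#' Convenience pipeline: counts markers per field and aggregates each
#' case with [aggregate_case()].
#'
#' @param fields list of [field_annotation()]s (e.g. from
#'   [read_field_annotations()]).
#' @param minimum minimum total nuclei per case (default 1000).
#' @return A named list of `case_ik` objects, one per case.
#' @export
score_cases <- function(fields, minimum = 1000) {
  counts <- count_markers(fields)
  if (is.null(counts)) abort_validation("No fields supplied.")
  out <- lapply(split(counts, factor(counts$case_id, unique(counts$case_id))),
                aggregate_case, minimum = minimum)
  out
}

#' Export case IK results
#'
#' @param cases a `case_ik` or list of them.
#' @param path output file (`.csv` or `.json` by extension).
#' @return `path`, invisibly.
#' @export
export_case_ik <- function(cases, path) {
  if (inherits(cases, "case_ik")) cases <- list(cases)
  df <- do.call(rbind, lapply(cases, as.data.frame))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Number of images needed to reach the minimum nucleus count
#'
#' Planning helper: with a typical per-image nucleus count, how many x40
#' fields must be captured to reach the minimum (default 1,000) counted
#' nuclei? At the protocol's median of 151 nuclei/image this gives 7
#' images; dense fields (>500 nuclei/image) need only 2.
#'
#' @param nuclei_per_image expected nuclei per image (>= 1), vectorised.
#' @param minimum minimum total nuclei (default 1000).
#' @return Integer count(s): `ceiling(minimum / nuclei_per_image)`.
#' @examples
#' images_needed(c(151, 173, 500))
#' @export
images_needed <- function(nuclei_per_image, minimum = 1000) {
  if (!is.numeric(nuclei_per_image) || any(!is.finite(nuclei_per_image)) ||
      any(nuclei_per_image < 1)) {
    abort_validation("`nuclei_per_image` must be >= 1.")
  }
  if (!is_count(minimum) || minimum < 1) {
    abort_validation("`minimum` must be a positive count.")
  }
  as.integer(ceiling(minimum / nuclei_per_image))
}

#' Cohort-level summary of per-field counts and densities
#'
#' Order statistics (mean, median, min, max) over all fields pooled
#' across cases, for total nuclei, positive nuclei and nuclear density.
#' The median of an even number of fields is the mean of the two central
#' values.
#'
#' @param counts a data frame of per-field counts (`n_positive`,
#'   `n_negative`, optional `area_mm2`), e.g. from [count_markers()].
#' @param area_mm2 fallback field area when `counts` has no `area_mm2`.
#' @return A tibble with one row per metric (`total_nuclei`,
#'   `positive_nuclei`, `density_per_mm2`) and columns `mean`, `median`,
#'   `min`, `max`. Densities are rounded to integer nuclei/mm^2.
#' @export
summarize_cohort_counts <- function(counts, area_mm2 = field_area_mm2()) {
  counts <- as.data.frame(counts)
  if (nrow(counts) == 0) abort_validation("No fields to summarize.")
  if (!all(c("n_positive", "n_negative") %in% names(counts))) {
    abort_validation("`counts` must have columns n_positive and n_negative.")
  }
  totals <- counts$n_positive + counts$n_negative
  areas <- if ("area_mm2" %in% names(counts)) counts$area_mm2 else rep(area_mm2, nrow(counts))
  dens <- totals / areas
  stat_row <- function(x) c(mean = mean(x), median = stats::median(x),
                            min = min(x), max = max(x))
  out <- rbind(total_nuclei = stat_row(totals),
               positive_nuclei = stat_row(counts$n_positive),
               density_per_mm2 = round(stat_row(dens)))
  tibble::as_tibble(out, rownames = "metric")
}
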