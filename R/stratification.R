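#' Hormone-receptor expression level
#'
#' ER/PR percentages are banded as: negative if <= 1% of tumor cells
#' stain, low if in (1, 50], high above 50. Only tumors above the 1%
#' threshold count as receptor-positive.
#'
#' @param pct percentage of receptor-positive tumor cells, in `[0, 100]`
#'   (vectorised).
#' @return Factor with levels `negative`, `low`, `high`.
#' @examples
#' receptor_level(c(0.5, 30, 60))
#' @export
receptor_level <- function(pct) {
  check_percentage(pct, "pct")
  factor(ifelse(pct <= 1, "negative", ifelse(pct <= 50, "low", "high")),
         levels = c("negative", "low", "high"))
}

HER2_INTENSITIES <- c("absent", "weak", "moderate", "intense")

#' HER2 membrane-staining observation
#'
#' @param pct_cells percentage of tumor cells with membrane staining.
#' @param intensity staining intensity: `absent`, `weak` (the scoring
#'   system's "low"), `moderate`, or `intense`.
#' @param continuity `continuous` or `discontinuous` membrane staining.
#' @return An object of class `her2_observation`.
#' @export
her2_observation <- function(pct_cells, intensity, continuity) {
  check_percentage(pct_cells, "pct_cells")
  intensity <- match.arg(intensity, HER2_INTENSITIES)
  continuity <- match.arg(continuity, c("discontinuous", "continuous"))
  structure(list(pct_cells = pct_cells, intensity = intensity,
                 continuity = continuity),
            class = "her2_observation")
}

#' HER2 immunohistochemistry score (0 / 1+ / 2+ / 3+)
#'
#' HercepTest-style rules: 0 when staining is absent or present in <10%
#' of tumor cells; 1+ when membranous, weak and discontinuous in >10%;
#' 2+ when membranous, weak-to-moderate and continuous in >10%, or
#' intense and continuous in <=30%; 3+ (the only positive score) when
#' intense and continuous in >30%. Combinations the rules do not cover
#' (for instance exactly 10%, or moderate-discontinuous staining) raise
#' a classed `ki67_her2_unscorable` error — never a silent default.
#'
#' @param obs a [her2_observation()], or a precomputed integer score 0-3
#'   (for cohorts scored elsewhere), which is passed through.
#' @return A list with integer `score` (0-3) and logical `positive`
#'   (`TRUE` iff score 3).
#' @examples
#' her2_score(her2_observation(35, "intense", "continuous"))  # 3+, positive
#' her2_score(her2_observation(25, "intense", "continuous"))  # 2+
#' @export
her2_score <- function(obs) {
  if (is.numeric(obs) && length(obs) == 1L) {
    if (!obs %in% 0:3) abort_validation("A precomputed HER2 score must be 0, 1, 2 or 3.")
    return(list(score = as.integer(obs), positive = obs == 3))
  }
  if (!inherits(obs, "her2_observation")) {
    abort_validation("`obs` must be a her2_observation or a precomputed score 0-3.")
  }
  pct <- obs$pct_cells
  score <- if (obs$intensity == "absent" || pct < 10) {
    0L
  } else if (pct > 10 && obs$continuity == "discontinuous" && obs$intensity == "weak") {
    1L
  } else if (pct > 10 && obs$continuity == "continuous" &&
             obs$intensity %in% c("weak", "moderate")) {
    2L
  } else if (obs$continuity == "continuous" && obs$intensity == "intense") {
    if (pct <= 30) 2L else 3L
  } else {
    abort(sprintf(
      "HER2 observation not covered by the scoring rules: %s, %s, %.4g%% of cells.",
      obs$intensity, obs$continuity, pct),
      class = c("ki67_her2_unscorable", "ki67_validation_error"))
  }
  list(score = score, positive = score == 3L)
}

#' Ki-67 index class
#'
#' Two published banding schemes for the proliferation index of luminal
#' breast carcinoma:
#' \describe{
#'   \item{`stgallen2009`}{three therapy-guiding bands — low (IK <= 15),
#'     moderate (15 < IK <= 30), high (IK > 30). The printed bands
#'     "<=15 / 16-30 / >30" leave (15, 16) undefined for continuous IK;
#'     this implementation uses half-open bands anchored at the printed
#'     edges, so e.g. 15.5 is moderate.}
#'   \item{`luminalB14`}{binary 14% cut separating luminal A from
#'     luminal B: `luminal_B` side iff IK > 14.}
#' }
#'
#' @param ik IK percentage(s) in `[0, 100]`.
#' @param scheme `"stgallen2009"` (default) or `"luminalB14"`.
#' @return A factor: levels `low`/`moderate`/`high` for `stgallen2009`,
#'   `luminal_A`/`luminal_B` for `luminalB14`.
#' @examples
#' ik_class(c(12.6, 21.7, 59.6))
#' ik_class(14.5, scheme = "luminalB14")
#' @export
ik_class <- function(ik, scheme = c("stgallen2009", "luminalB14")) {
  scheme <- match.arg(scheme)
  check_percentage(ik, "ik")
  if (scheme == "stgallen2009") {
    factor(ifelse(ik <= 15, "low", ifelse(ik <= 30, "moderate", "high")),
           levels = c("low", "moderate", "high"))
  } else {
    factor(ifelse(ik > 14, "luminal_B", "luminal_A"),
           levels = c("luminal_A", "luminal_B"))
  }
}

#' Luminal vs non-luminal typing from the receptor profile
#'
#' A tumor is luminal when ER and/or PR is positive (> 1% of cells), with
#' any HER2 status; non-luminal when both are negative. The luminal-A
#' candidate flag marks the ER+/PR+/HER2- constellation whose therapy
#' choice hinges on the IK class.
#'
#' @param er_pct,pr_pct receptor percentages in `[0, 100]`.
#' @param her2 a [her2_observation()] or precomputed score 0-3.
#' @return A list: `luminal` (factor `luminal`/`non_luminal`),
#'   `luminal_a_candidate` (logical: ER+ and PR+ and HER2 not 3+),
#'   `er_level`, `pr_level` (from [receptor_level()]), `her2_score`,
#'   `her2_positive`.
#' @examples
#' luminal_class(40, 20, 1)   # luminal, luminal-A candidate
#' luminal_class(0, 30, 3)    # luminal, not a candidate
#' @export
luminal_class <- function(er_pct, pr_pct, her2) {
  check_percentage(er_pct, "er_pct")
  check_percentage(pr_pct, "pr_pct")
  h <- her2_score(her2)
  er_pos <- er_pct > 1
  pr_pos <- pr_pct > 1
  list(
    luminal = factor(if (er_pos || pr_pos) "luminal" else "non_luminal",
                     levels = c("luminal", "non_luminal")),
    luminal_a_candidate = er_pos && pr_pos && !h$positive,
    er_level = receptor_level(er_pct),
    pr_level = receptor_level(pr_pct),
    her2_score = h$score,
    her2_positive = h$positive
  )
}

#' Lymph-node score for the Nottingham Prognostic Index
#'
#' 1 when no nodes are positive; 2 with 1-3 positive nodes (apical node
#' negative); 3 with >= 4 positive nodes or a positive apical node.
#'
#' @param positive_nodes non-negative count of metastatic nodes
#'   (vectorised).
#' @param apical_positive logical: apical (highest axillary) node
#'   involved?
#' @return Integer score(s) 1, 2 or 3.
#' @examples
#' node_score(c(0, 3, 5), c(FALSE, FALSE, FALSE))
#' node_score(1, TRUE)
#' @export
node_score <- function(positive_nodes, apical_positive = FALSE) {
  if (!is.numeric(positive_nodes) || any(positive_nodes < 0) ||
      any(positive_nodes != trunc(positive_nodes))) {
    abort_validation("`positive_nodes` must be non-negative counts.")
  }
  if (!is.logical(apical_positive) || any(is.na(apical_positive))) {
    abort_validation("`apical_positive` must be TRUE/FALSE.")
  }
  ifelse(positive_nodes >= 4 | apical_positive, 3L,
         ifelse(positive_nodes >= 1, 2L, 1L))
}

#' Nottingham Prognostic Index
#'
#' `NPI = 0.2 * tumor size (cm) + node score (1-3) + histological grade (1-3)`.
#'
#' @param size_cm invasive tumor size in centimetres (> 0).
#' @param node_score lymph-node score 1-3 (see [node_score()]).
#' @param grade Elston-Ellis histological grade 1-3.
#' @return NPI value(s).
#' @examples
#' npi_value(2.0, 1, 1)  # 2.4
#' npi_value(2.8, 2, 3)  # 5.56
#' @export
npi_value <- function(size_cm, node_score, grade) {
  if (!is.numeric(size_cm) || any(size_cm <= 0)) {
    abort_validation("`size_cm` must be strictly positive.")
  }
  if (!all(node_score %in% 1:3)) abort_validation("`node_score` must be 1, 2 or 3.")
  if (!all(grade %in% 1:3)) abort_validation("`grade` must be 1, 2 or 3.")
  size_cm * 0.2 + node_score + grade
}

#' NPI prognostic group
#'
#' Good prognostic group (GPG) below 3.4; moderate (MPG) for the closed
#' band 3.4-5.4; poor (PPG) above 5.4.
#'
#' @param npi NPI value(s) from [npi_value()].
#' @return Factor with levels `GPG`, `MPG`, `PPG`.
#' @examples
#' npi_group(c(2.4, 3.4, 5.4, 5.56))
#' @export
npi_group <- function(npi) {
  if (!is.numeric(npi) || any(!is.finite(npi))) {
    abort_validation("`npi` must be finite.")
  }
  factor(ifelse(npi < 3.4, "GPG", ifelse(npi <= 5.4, "MPG", "PPG")),
         levels = c("GPG", "MPG", "PPG"))
}

#' Elston-Ellis grade from an SBR component score
#'
#' Standard mapping of the Scarff-Bloom-Richardson component sum
#' (tubule formation + pleomorphism + mitoses, each 1-3) to histological
#' grade: 3-5 -> G1, 6-7 -> G2, 8-9 -> G3. Grade may always be supplied
#' directly instead.
#'
#' @param sbr_score integer component sum 3-9 (vectorised).
#' @return Integer grade(s) 1-3.
#' @export
sbr_to_grade <- function(sbr_score) {
  if (!all(sbr_score %in% 3:9)) {
    abort_validation("`sbr_score` must be an SBR component sum between 3 and 9.")
  }
  ifelse(sbr_score <= 5, 1L, ifelse(sbr_score <= 7, 2L, 3L))
}

#' Full clinicopathological stratification of one case
#'
#' Composes the component rules into one record: IK class (both schemes),
#' luminal typing, receptor levels, HER2 score, node score, NPI value
#' and prognostic group, plus the chemotherapy-stratification flag for
#' luminal-A-candidate tumors with high IK.
#'
#' @param ik case-level IK percentage, or a `case_ik` object (its
#'   `ik_mean` is used).
#' @param er_pct,pr_pct receptor percentages.
#' @param her2 a [her2_observation()] or precomputed score 0-3.
#' @param size_cm tumor size in cm.
#' @param positive_nodes count of metastatic lymph nodes.
#' @param apical_positive logical, apical node involved.
#' @param grade histological grade 1-3.
#' @param case_id optional identifier.
#' @return An object of class `stratification_result` (a named list that
#'   [as.data.frame()] turns into a one-row frame).
#' @examples
#' classify_case(ik = 21.7, er_pct = 60, pr_pct = 60, her2 = 1,
#'               size_cm = 2.0, positive_nodes = 0,
#'               apical_positive = FALSE, grade = 2)
#' @export
classify_case <- function(ik, er_pct, pr_pct, her2, size_cm,
                          positive_nodes, apical_positive = FALSE,
                          grade, case_id = NULL) {
  meets_minimum <- NA
  if (inherits(ik, "case_ik")) {
    case_id <- case_id %||% ik$case_id
    meets_minimum <- ik$meets_minimum
    ik <- ik$ik_mean
  }
  check_percentage(ik, "ik")
  lum <- luminal_class(er_pct, pr_pct, her2)
  ns <- node_score(positive_nodes, apical_positive)
  npi <- npi_value(size_cm, ns, grade)
  cls <- ik_class(ik)
  structure(
    list(case_id = case_id %||% NA_character_,
         ik = ik,
         ik_class = cls,
         ik_class_14 = ik_class(ik, "luminalB14"),
         luminal = lum$luminal,
         luminal_a_candidate = lum$luminal_a_candidate,
         er_level = lum$er_level, pr_level = lum$pr_level,
         her2_score = lum$her2_score, her2_positive = lum$her2_positive,
         node_score = ns, npi = npi, npi_group = npi_group(npi),
         chemo_flag = lum$luminal_a_candidate && cls == "high",
         meets_minimum = meets_minimum),
    class = "stratification_result"
  )
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf("<stratification_result> case %s\n", x$case_id))
  cat(sprintf("  IK %.1f%% -> %s (14%% scheme: %s)\n",
              round_half_up(x$ik, 1), x$ik_class, x$ik_class_14))
  cat(sprintf("  %s (ER %s, PR %s, HER2 %d%s)%s\n", x$luminal, x$er_level,
              x$pr_level, x$her2_score, if (x$her2_positive) "+, positive" else "+",
              if (x$luminal_a_candidate) " — luminal-A candidate" else ""))
  cat(sprintf("  NPI %.2f -> %s (node score %d)\n", x$npi, x$npi_group,
              x$node_score))
  if (isTRUE(x$chemo_flag))
    cat("  flag: luminal-A candidate with high IK (chemotherapy-stratification relevant)\n")
  invisible(x)
}

#' @export
as.data.frame.stratification_result <- function(x, ...) {
  data.frame(case_id = x$case_id, ik = x$ik,
             ik_class = as.character(x$ik_class),
             ik_class_14 = as.character(x$ik_class_14),
             luminal = as.character(x$luminal),
             luminal_a_candidate = x$luminal_a_candidate,
             er_level = as.character(x$er_level),
             pr_level = as.character(x$pr_level),
             her2_score = x$her2_score, her2_positive = x$her2_positive,
             node_score = x$node_score, npi = x$npi,
             npi_group = as.character(x$npi_group),
             chemo_flag = x$chemo_flag,
             meets_minimum = x$meets_minimum,
             stringsAsFactors = FALSE)
}

#' Read a case-level clinical table
#'
#' Expected CSV columns: `case_id`, `size_cm`, `positive_nodes`,
#' `apical_positive`, `grade`, `er_pct`, `pr_pct`, and either
#' `her2_score` or the triple `her2_pct`, `her2_intensity`,
#' `her2_continuity`.
#'
#' @param path path to the clinical CSV.
#' @return A tibble, one row per case.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("Clinical table not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("case_id", "size_cm", "positive_nodes", "apical_positive",
              "grade", "er_pct", "pr_pct")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort_validation(sprintf("Clinical table is missing column(s): %s.",
                             paste(missing_cols, collapse = ", ")))
  }
  if (!"her2_score" %in% names(df) &&
      !all(c("her2_pct", "her2_intensity", "her2_continuity") %in% names(df))) {
    abort_validation("Clinical table needs her2_score or her2_pct + her2_intensity + her2_continuity.")
  }
  df$apical_positive <- as.logical(df$apical_positive)
  tibble::as_tibble(df)
}

#' Stratify a whole cohort
#'
#' Applies [classify_case()] row-wise to a clinical table joined with
#' case-level IK values.
#'
#' @param clinical a data frame as returned by [read_clinical_table()],
#'   with an `ik` column, or without one if `ik` is supplied separately.
#' @param ik optional named vector or list of IK values (or `case_ik`
#'   objects) keyed by `case_id`.
#' @return A tibble with one row per case (the
#'   [as.data.frame.stratification_result()] columns).
#' @export
stratify_cohort <- function(clinical, ik = NULL) {
  clinical <- as.data.frame(clinical)
  if (!is.null(ik)) {
    if (inherits(ik, "case_ik")) ik <- list(ik)
    vals <- vapply(ik, function(v) if (inherits(v, "case_ik")) v$ik_mean else as.numeric(v),
                   numeric(1))
    ids <- names(ik) %||% vapply(ik, function(v)
      if (inherits(v, "case_ik")) v$case_id else NA_character_, character(1))
    names(vals) <- ids
    clinical$ik <- vals[as.character(clinical$case_id)]
  }
  if (!"ik" %in% names(clinical) || any(is.na(clinical$ik))) {
    abort_validation("Every case needs an IK value (column `ik` or the `ik` argument).")
  }
  rows <- lapply(seq_len(nrow(clinical)), function(i) {
    r <- clinical[i, ]
    her2 <- if ("her2_score" %in% names(r) && !is.na(r$her2_score)) {
      r$her2_score
    } else {
      her2_observation(r$her2_pct, r$her2_intensity, r$her2_continuity)
    }
    as.data.frame(classify_case(
      ik = r$ik, er_pct = r$er_pct, pr_pct = r$pr_pct, her2 = her2,
      size_cm = r$size_cm, positive_nodes = r$positive_nodes,
      apical_positive = isTRUE(r$apical_positive), grade = r$grade,
      case_id = as.character(r$case_id)))
  })
  tibble::as_tibble(do.call(rbind, rows))
}
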