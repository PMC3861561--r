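# Deterministic fixture builders used across the suite.

ref_geometry <- function() field_geometry(310.3, 232.72, um_per_px = 0.12121)

# n_pos positive then n_neg negative markers on a regular in-bounds grid.
make_field <- function(n_pos, n_neg, case_id = "c1", field_id = "f1",
                       geometry = ref_geometry()) {
  n <- n_pos + n_neg
  ix <- seq_len(n) - 1
  ncol_grid <- ceiling(sqrt(n))
  x <- (ix %% ncol_grid + 0.5) * geometry$width_um / ncol_grid
  y <- (ix %/% ncol_grid + 0.5) * geometry$height_um / ncol_grid
  field_annotation(case_id, field_id,
                   data.frame(x = x, y = y,
                              label = rep(c("positive", "negative"),
                                          c(n_pos, n_neg))),
                   geometry)
}

# A stratified cohort whose ER/PR-level x IK-class cell counts match the
# published luminal-A (ER+/PR+/HER2-) distribution: rows are
# (ER level, PR level) and counts are (high, moderate, low) IK.
luminal_a_cohort <- function() {
  cells <- list(
    list(er = 80, pr = 80, n = c(high = 3, moderate = 14, low = 6)),
    list(er = 80, pr = 30, n = c(high = 3, moderate = 3, low = 11)),
    list(er = 30, pr = 80, n = c(high = 3, moderate = 0, low = 6)),
    list(er = 30, pr = 30, n = c(high = 3, moderate = 3, low = 0))
  )
  ik_for <- c(high = 50, moderate = 25, low = 10)
  rows <- do.call(rbind, lapply(cells, function(cl) {
    do.call(rbind, lapply(names(cl$n), function(k) {
      if (cl$n[[k]] == 0) return(NULL)
      data.frame(er_pct = cl$er, pr_pct = cl$pr, ik = ik_for[[k]],
                 count = cl$n[[k]])
    }))
  }))
  idx <- rep(seq_len(nrow(rows)), rows$count)
  clinical <- data.frame(
    case_id = sprintf("L%02d", seq_along(idx)),
    ik = rows$ik[idx], er_pct = rows$er_pct[idx], pr_pct = rows$pr_pct[idx],
    her2_score = 1, size_cm = 2, positive_nodes = 0,
    apical_positive = FALSE, grade = 2)
  stratify_cohort(clinical)
}
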