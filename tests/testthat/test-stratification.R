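test_that("receptor levels band at the 1% and 50% thresholds", {
  expect_equal(as.character(receptor_level(c(0, 0.5, 1, 1.01, 30, 50, 50.1, 60, 100))),
               c("negative", "negative", "negative", "low", "low", "low",
                 "high", "high", "high"))
  expect_error(receptor_level(101), class = "ki67_validation_error")
  expect_error(receptor_level(-1), class = "ki67_validation_error")
})

test_that("HER2 scoring follows the printed rules and only 3+ is positive", {
  s <- her2_score(her2_observation(35, "intense", "continuous"))
  expect_equal(s$score, 3L); expect_true(s$positive)
  s <- her2_score(her2_observation(25, "intense", "continuous"))
  expect_equal(s$score, 2L); expect_false(s$positive)
  expect_equal(her2_score(her2_observation(5, "intense", "continuous"))$score, 0L)
  expect_equal(her2_score(her2_observation(15, "weak", "discontinuous"))$score, 1L)
  expect_equal(her2_score(her2_observation(50, "moderate", "continuous"))$score, 2L)
  expect_equal(her2_score(her2_observation(3, "absent", "discontinuous"))$score, 0L)
  # precomputed scores pass through
  expect_equal(her2_score(2)$score, 2L)
  expect_false(her2_score(2)$positive)
  expect_error(her2_score(5), class = "ki67_validation_error")
})

test_that("HER2 rules are total over their domain: every observation scores or raises the unscorable error", {
  grid <- expand.grid(pct = c(0, 5, 9.9, 10, 10.1, 20, 30, 30.1, 50, 100),
                      intensity = c("absent", "weak", "moderate", "intense"),
                      continuity = c("discontinuous", "continuous"),
                      stringsAsFactors = FALSE)
  n_scored <- 0L; n_unscorable <- 0L
  for (i in seq_len(nrow(grid))) {
    obs <- her2_observation(grid$pct[i], grid$intensity[i], grid$continuity[i])
    res <- tryCatch(her2_score(obs),
                    ki67_her2_unscorable = function(e) "unscorable")
    if (identical(res, "unscorable")) {
      n_unscorable <- n_unscorable + 1L
      # only gaps in the printed rules may be unscorable: pct exactly 10,
      # or discontinuous staining that is not weak
      expect_true(grid$pct[i] == 10 ||
                    (grid$continuity[i] == "discontinuous" &&
                       !grid$intensity[i] %in% c("absent", "weak")),
                  label = sprintf("unexpected unscorable: %s/%s/%g",
                                  grid$intensity[i], grid$continuity[i], grid$pct[i]))
    } else {
      n_scored <- n_scored + 1L
      expect_true(res$score %in% 0:3)
      expect_identical(res$positive, res$score == 3L)
    }
  }
  expect_equal(n_scored + n_unscorable, nrow(grid))
  expect_gt(n_unscorable, 0)
})

test_that("IK classes partition [0, 100] at the 15/30 edges; the 14% scheme is binary", {
  expect_equal(as.character(ik_class(c(0, 12.6, 15, 15.5, 16, 30, 30.1, 59.6, 100))),
               c("low", "low", "low", "moderate", "moderate", "moderate",
                 "high", "high", "high"))
  grid <- seq(0, 100, by = 0.25)
  cls <- ik_class(grid)
  expect_false(any(is.na(cls)))       # every value maps to exactly one class
  expect_equal(as.character(ik_class(c(14, 14.5), scheme = "luminalB14")),
               c("luminal_A", "luminal_B"))
  expect_error(ik_class(-0.1), class = "ki67_validation_error")
})

test_that("luminal typing uses the and/or receptor rule with the HER2- candidate flag", {
  l <- luminal_class(40, 20, 1)
  expect_equal(as.character(l$luminal), "luminal")
  expect_true(l$luminal_a_candidate)
  l <- luminal_class(0, 0, 3)
  expect_equal(as.character(l$luminal), "non_luminal")
  expect_false(l$luminal_a_candidate)
  l <- luminal_class(0, 30, 3)      # PR-only positive, HER2 3+
  expect_equal(as.character(l$luminal), "luminal")
  expect_false(l$luminal_a_candidate)
  l <- luminal_class(60, 60, her2_observation(35, "intense", "continuous"))
  expect_false(l$luminal_a_candidate)  # HER2 3+ breaks candidacy
})

test_that("node score and NPI follow the printed formula and bands", {
  expect_equal(node_score(c(0, 1, 3, 4, 10), rep(FALSE, 5)), c(1L, 2L, 2L, 3L, 3L))
  expect_equal(node_score(1, TRUE), 3L)
  expect_equal(npi_value(2.0, 1, 1), 2.4)
  expect_equal(npi_value(2.8, 2, 3), 5.56)
  expect_equal(npi_value(5.0, 3, 3), 7.0)
  expect_equal(as.character(npi_group(c(2.4, 3.39, 3.4, 5.4, 5.41, 5.56))),
               c("GPG", "GPG", "MPG", "MPG", "PPG", "PPG"))
})

test_that("NPI group is monotone in size, nodes and grade", {
  grp_rank <- function(size, ns, grade) {
    as.integer(npi_group(npi_value(size, ns, grade)))
  }
  for (size in c(1, 2.8, 5, 8)) for (ns in 1:3) for (grade in 1:3) {
    r <- grp_rank(size, ns, grade)
    if (size < 8) expect_gte(grp_rank(size + 0.5, ns, grade), r)
    if (ns < 3) expect_gte(grp_rank(size, ns + 1, grade), r)
    if (grade < 3) expect_gte(grp_rank(size, ns, grade + 1), r)
  }
})

test_that("SBR component sums map to grades by the standard convention", {
  expect_equal(sbr_to_grade(3:9), c(1L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(sbr_to_grade(2), class = "ki67_validation_error")
})

test_that("classify_case composes the component rules deterministically", {
  r <- classify_case(ik = 21.7, er_pct = 60, pr_pct = 60, her2 = 1,
                     size_cm = 2.0, positive_nodes = 0, grade = 2,
                     case_id = "a")
  expect_equal(as.character(r$ik_class), "moderate")
  expect_equal(as.character(r$luminal), "luminal")
  expect_true(r$luminal_a_candidate)
  expect_equal(r$npi, 3.4)
  expect_equal(as.character(r$npi_group), "MPG")
  expect_false(r$chemo_flag)

  r <- classify_case(ik = 59.6, er_pct = 0, pr_pct = 0, her2 = 0,
                     size_cm = 2, positive_nodes = 0, grade = 3)
  expect_equal(as.character(r$ik_class), "high")
  expect_equal(as.character(r$luminal), "non_luminal")

  r <- classify_case(ik = 0, er_pct = 0, pr_pct = 0, her2 = 0,
                     size_cm = 1, positive_nodes = 0, grade = 1)
  expect_equal(as.character(r$ik_class), "low")
  expect_equal(as.character(r$npi_group), "GPG")

  # a case_ik carries its id, IK and minimum flag through
  ci <- suppressWarnings(aggregate_case(
    data.frame(n_positive = 30, n_negative = 70), case_id = "k"))
  r <- classify_case(ci, er_pct = 80, pr_pct = 80, her2 = 1, size_cm = 2,
                     positive_nodes = 0, grade = 1)
  expect_equal(r$case_id, "k")
  expect_equal(r$ik, 30)
  expect_false(r$meets_minimum)
  # luminal-A candidate with high IK raises the chemo-stratification flag
  r <- classify_case(ik = 45, er_pct = 80, pr_pct = 80, her2 = 1,
                     size_cm = 2, positive_nodes = 0, grade = 2)
  expect_true(r$chemo_flag)
})

test_that("clinical tables read, validate and stratify row-wise", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "case_id,size_cm,positive_nodes,apical_positive,grade,er_pct,pr_pct,her2_score,ik",
    "c1,2.0,0,FALSE,2,60,60,1,21.7",
    "c2,2.8,2,FALSE,3,0,0,0,59.6"), path)
  clin <- read_clinical_table(path)
  st <- stratify_cohort(clin)
  expect_equal(nrow(st), 2)
  expect_equal(st$ik_class, c("moderate", "high"))
  expect_equal(st$luminal, c("luminal", "non_luminal"))
  expect_equal(st$npi, c(3.4, 5.56))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("case_id,size_cm", bad)
  expect_error(read_clinical_table(bad), regexp = "positive_nodes",
               class = "ki67_validation_error")
})
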