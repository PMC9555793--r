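kb_diag <- trt_example_kb("diagnosis")
kb_treat <- trt_example_kb("treatment")
cases <- trt_eval_cases()
case_facts <- lapply(cases, `[[`, "facts")

test_that("fact assertion flattens profile and visit, dropping missing cells", {
  dir <- tempfile("cohort"); dir.create(dir)
  writeLines(c("patient_id,G,age,NTI", "P1,m,38,yes", "P2,f,60,no"),
             file.path(dir, "patients.csv"))
  writeLines(c("patient_id,visit_no,Tsc,Ins", "P1,0,,GHH", "P1,1,50,GHH"),
             file.path(dir, "visits.csv"))
  cohort <- load_cohort(file.path(dir, "patients.csv"), file.path(dir, "visits.csv"))
  facts <- assert_facts(patient_case(cohort, "P1"), visit_no = 0)
  expect_equal(facts$G, "m")
  expect_equal(facts$NTI, "yes")
  expect_equal(facts$Ins, "GHH")
  expect_false("Tsc" %in% names(facts))   # missing THI simply absent
  facts1 <- assert_facts(patient_case(cohort, "P1"), visit_no = 1)
  expect_equal(facts1$Tsc, 50)
  expect_error(assert_facts(patient_case(cohort, "P2")), "no visits")
  expect_error(assert_facts(patient_case(cohort, "P1"), visit_no = 9), "unknown visit")
})

test_that("rule matching requires every cedent, with half-open interval bounds", {
  case2_rule <- kb_diag$rules[[2]]$rule   # LL3 in <85;91) & hyperacusis scores
  expect_true(trtcds:::rule_matches_facts(
    case2_rule, as_facts(list(LL3 = 88, H_An = 9, H_EffLife = 9, H_Sv = 8))))
  # upper bound excluded
  expect_false(trtcds:::rule_matches_facts(
    case2_rule, as_facts(list(LL3 = 91, H_An = 9, H_EffLife = 9, H_Sv = 8))))
  # lower bound included
  expect_true(trtcds:::rule_matches_facts(
    case2_rule, as_facts(list(LL3 = 85, H_An = 9, H_EffLife = 9, H_Sv = 8))))
  # a missing fact leaves the cedent unsatisfied
  expect_false(trtcds:::rule_matches_facts(
    case2_rule, as_facts(list(LL3 = 88, H_An = 9, H_EffLife = 9))))
  expect_identical(match_rules(case_facts[[2]], kb_new(), "diagnosis"), list())
})

test_that("diagnosis ranks categories by max matched confidence", {
  res <- infer_diagnosis(case_facts[[3]], kb_diag)
  expect_true(res$covered)
  expect_equal(res$primary, "C2")
  expect_equal(res$confidence, 96.2)
  # two categories matched -> higher confidence wins, both listed
  f <- tempfile(fileext = ".rules")
  writeLines(c("T_An(>=5) => Category(1) | conf=70",
               "H_An(>=5) => Category(3) | conf=90"), f)
  kb2 <- translate(f, "diagnosis")
  res2 <- infer_diagnosis(as_facts(list(T_An = 8, H_An = 8)), kb2)
  expect_equal(res2$primary, "C3")
  expect_equal(res2$ranking$category, c("C3", "C1"))
  expect_equal(res2$ranking$confidence, c(90, 70))
  # no match -> uncovered
  res3 <- infer_diagnosis(as_facts(list(age = 30)), kb_diag)
  expect_false(res3$covered)
  expect_equal(nrow(res3$ranking), 0)
})

test_that("treatment recommendations require the stable context and the from-state", {
  rec1 <- recommend_treatment(case_facts[[1]], kb_treat)
  expect_equal(nrow(rec1), 1)
  expect_equal(rec1$gain, 41)
  expect_match(rec1$action, "change Ins from GHH to GHS")
  # cases 2 and 3 are not covered by any action rule
  expect_equal(nrow(recommend_treatment(case_facts[[2]], kb_treat)), 0)
  expect_equal(nrow(recommend_treatment(case_facts[[3]], kb_treat)), 0)
  # a patient already in the to-state is not recommended the no-op
  facts <- as_facts(list(G = "m", NTI = "yes", Ins = "GHS"))
  expect_equal(nrow(recommend_treatment(facts, kb_treat)), 0)
  # ranking is gain-first
  f <- tempfile(fileext = ".rules")
  writeLines(c("G(m) : (Ins(GHH->GHS)) => Ch(better) | conf=95 ; gain=10",
               "G(m) : (FU(A->T)) => Ch(better) | conf=60 ; gain=30"), f)
  kbr <- translate(f, "treatment")
  rec <- recommend_treatment(as_facts(list(G = "m", Ins = "GHH", FU = "A")), kbr)
  expect_equal(rec$gain, c(30, 10))
  rec_c <- recommend_treatment(as_facts(list(G = "m", Ins = "GHH", FU = "A")), kbr,
                               rank_by = "confidence")
  expect_equal(rec_c$confidence, c(95, 60))
})

test_that("indexed matching is equivalent to naive per-rule evaluation", {
  set.seed(77)
  for (trial in 1:150) {
    rf <- random_kb_and_facts(n_rules = sample(5:20, 1))
    for (kind in c("diagnosis", "treatment")) {
      ids_indexed <- vapply(match_rules(rf$facts, rf$kb, kind, "indexed"),
                            `[[`, character(1), "id")
      ids_naive <- vapply(match_rules(rf$facts, rf$kb, kind, "naive"),
                          `[[`, character(1), "id")
      expect_identical(ids_indexed, ids_naive)
      # and both agree with the independent matcher
      oracle <- vapply(Filter(function(er) er$kind == kind, rf$kb$rules),
                       function(er) {
                         if (oracle_rule_matches(er$rule, rf$facts)) er$id else NA_character_
                       }, character(1))
      expect_identical(ids_naive, oracle[!is.na(oracle)])
    }
  }
})

test_that("adding rules to the knowledge base is monotone for matching", {
  facts <- case_facts[[3]]
  base <- infer_diagnosis(facts, kb_diag)
  # an unmatched rule changes nothing
  f <- tempfile(fileext = ".rules")
  writeLines("LL3(<0;1)) => Category(0) | conf=99", f)
  kb_plus <- translate(f, "diagnosis", kb_diag)
  expect_equal(infer_diagnosis(facts, kb_plus)$ranking[, c("category", "confidence")],
               base$ranking[, c("category", "confidence")])
  # a matched rule never lowers a category's confidence
  f2 <- tempfile(fileext = ".rules")
  writeLines("R6(>=75) => Category(2) | conf=50", f2)
  kb_plus2 <- translate(f2, "diagnosis", kb_diag)
  after <- infer_diagnosis(facts, kb_plus2)
  expect_gte(after$ranking$confidence[after$ranking$category == "C2"],
             base$ranking$confidence[base$ranking$category == "C2"])
})

test_that("returned explanations are faithful: their cedents hold on the input facts", {
  for (i in seq_along(cases)) {
    res <- infer_diagnosis(case_facts[[i]], kb_diag)
    for (er in res$matched) {
      expect_true(trtcds:::rule_matches_facts(er$rule, case_facts[[i]]))
      expect_gt(nchar(er$explanation), 0)
    }
    rec <- recommend_treatment(case_facts[[i]], kb_treat)
    if (nrow(rec)) {
      for (id in rec$rule_id) {
        er <- Filter(function(e) e$id == id, kb_treat$rules)[[1]]
        expect_true(trtcds:::rule_matches_facts(er$rule, case_facts[[i]]))
      }
    }
  }
})
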