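canonical_rule_of <- function(r) trtcds:::canonical_rule(r)

test_that("the parser extracts cedents, consequents and stats from dialect lines", {
  r <- parse_rule_text("R3(<15;20)) & T_An(>=8) => Category(1) | conf=94", "diagnosis")
  expect_s3_class(r, "trt_decision_rule")
  expect_length(r$cedents, 2)
  expect_equal(r$cedents[[1]][c("attr", "op", "value", "value2")],
               list(attr = "R3", op = "interval", value = 15, value2 = 20))
  expect_equal(r$cedents[[2]]$op, "ge")
  expect_equal(r$category, "C1")
  expect_equal(r$confidence, 94)

  a <- parse_rule_text(
    "G(m) & NTI(yes) : (Ins(GHH->GHS)) => Ch(better) | conf=80 ; gain=41", "treatment")
  expect_s3_class(a, "trt_action_rule")
  expect_equal(vapply(a$stable, `[[`, character(1), "attr"), c("G", "NTI"))
  expect_equal(a$stable[[1]]$value, "m")
  expect_equal(a$flexible[[1]][c("attr", "value", "value2")],
               list(attr = "Ins", value = "GHH", value2 = "GHS"))
  expect_equal(a$gain, 41)
  # strict thresholds and numeric equality
  r2 <- parse_rule_text("L4(<10) & LSD(<=100) & age(=38) => Category(4) | conf=66.7",
                        "diagnosis")
  expect_equal(vapply(r2$cedents, `[[`, character(1), "op"), c("lt", "le", "eq"))
})

test_that("malformed lines fail with located syntax errors", {
  expect_error(parse_rule_text("R3(<15;20 => Category(1) | conf=94", "diagnosis"),
               "syntax error")
  expect_error(parse_rule_text("R3(<15;20)) => Category(1)", "diagnosis"),
               "missing '\\| conf='")
  expect_error(parse_rule_text("R3(<15;20)) => Category(7) | conf=94", "diagnosis"),
               "Category\\(0\\.\\.4\\)")
  expect_error(parse_rule_text("Zzz(yes) => Category(1) | conf=94", "diagnosis"),
               "unknown attribute")
  expect_error(parse_rule_text("R3(<15;20)) => Category(1) | conf=101", "diagnosis"),
               "\\(0,100\\]")
  expect_error(parse_rule_text("G(x) => Category(1) | conf=90", "diagnosis"),
               "not in domain")
  # change cedents only on flexible attributes
  expect_error(parse_rule_text("G(m) : (NTI(yes->no)) => Ch(better) | conf=80",
                               "treatment"),
               "flexible")
})

test_that("parse and serialize are mutually inverse on fixtures and random rules", {
  for (spec in list(c("demo_diagnosis", "diagnosis"), c("eval_diagnosis", "diagnosis"),
                    c("demo_treatment", "treatment"), c("eval_treatment", "treatment"))) {
    lines <- grep("^#|^\\s*$", readLines(trt_example_rules(spec[1])),
                  value = TRUE, invert = TRUE)
    for (line in lines) {
      r <- parse_rule_text(line, spec[2])
      expect_identical(serialize_rule(r), line)
      expect_identical(canonical_rule_of(r), canonical_rule_of(
        parse_rule_text(serialize_rule(r), spec[2])))
    }
  }
  set.seed(301)
  for (i in 1:120) {
    line <- random_dialect_rule(i)
    kind <- if (grepl("Ch\\(better\\)", line)) "treatment" else "diagnosis"
    r <- parse_rule_text(line, kind)
    expect_identical(serialize_rule(r), line)
  }
})

test_that("explanations are deterministic and carry the vocabulary phrasing", {
  lines <- grep("^#|^\\s*$", readLines(trt_example_rules("demo_diagnosis")),
                value = TRUE, invert = TRUE)
  r2 <- parse_rule_text(lines[2], "diagnosis")
  e <- build_explanation(r2)
  expect_identical(e, build_explanation(r2))   # byte-identical
  expect_match(e, "hyperacusis")
  expect_match(e, "not indicated as a problem")
  expect_match(e, "Category 1 with 85% confidence")
  a <- parse_rule_text(
    "G(m) & NTI(yes) : (Ins(GHH->GHS)) => Ch(better) | conf=80 ; gain=41", "treatment")
  ea <- build_explanation(a)
  expect_match(ea, "male whose tinnitus was induced by noise", fixed = TRUE)
  expect_match(ea, "41 percentage points")
  # single cedent -> no conjunction
  r1 <- parse_rule_text("T_An(>=8) => Category(1) | conf=90", "diagnosis")
  expect_false(grepl(" and ", build_explanation(r1)))
})

test_that("translation encodes every well-formed line once, collecting bad lines", {
  kb <- translate(trt_example_rules("eval_diagnosis"), "diagnosis")
  expect_equal(unname(kb_counts(kb)["diagnosis"]), 5L)
  s <- attr(kb, "summary")
  expect_equal(s$rejected, 0L)
  # idempotent: translating the same file twice leaves 5 rules
  kb2 <- translate(trt_example_rules("eval_diagnosis"), "diagnosis", kb)
  expect_equal(unname(kb_counts(kb2)["diagnosis"]), 5L)
  # duplicates collapse keeping the higher-confidence variant
  f <- tempfile(fileext = ".rules")
  writeLines(c("T_An(>=8) => Category(1) | conf=70",
               "T_An(>=8) => Category(1) | conf=90",
               "this is not a rule"), f)
  kb3 <- translate(f, "diagnosis")
  expect_equal(unname(kb_counts(kb3)["total"]), 1L)
  expect_equal(kb3$rules[[1]]$rule$confidence, 90)
  expect_equal(attr(kb3, "summary")$rejected, 1L)
  expect_match(attr(kb3, "summary")$errors$message[1], "syntax error")
})

test_that("translation is order-insensitive at the knowledge-base level", {
  f1 <- tempfile(fileext = ".rules"); f2 <- tempfile(fileext = ".rules")
  lines <- grep("^#|^\\s*$", readLines(trt_example_rules("demo_diagnosis")),
                value = TRUE, invert = TRUE)
  writeLines(lines, f1)
  writeLines(rev(lines), f2)
  canon <- function(kb) sort(vapply(kb$rules, function(er)
    trtcds:::canonical_rule(er$rule), character(1)))
  expect_identical(canon(translate(f1, "diagnosis")), canon(translate(f2, "diagnosis")))
})

test_that("knowledge bases round-trip through JSON Lines", {
  kb <- translate(c(trt_example_rules("eval_diagnosis")), "diagnosis")
  kb <- translate(c(trt_example_rules("eval_treatment")), "treatment", kb)
  path <- tempfile(fileext = ".jsonl")
  save_kb(kb, path)
  back <- load_kb(path)
  expect_equal(back$version, kb$version)
  expect_equal(kb_counts(back), kb_counts(kb))
  for (i in seq_along(kb$rules)) {
    expect_identical(serialize_rule(back$rules[[i]]$rule),
                     serialize_rule(kb$rules[[i]]$rule))
    expect_identical(back$rules[[i]]$explanation, kb$rules[[i]]$explanation)
    expect_identical(back$rules[[i]]$id, kb$rules[[i]]$id)
  }
  # empty KB -> valid file, loads to empty KB with its version
  p0 <- tempfile(fileext = ".jsonl")
  save_kb(kb_new(version = "7"), p0)
  kb0 <- load_kb(p0)
  expect_equal(length(kb0$rules), 0L)
  expect_equal(kb0$version, "7")
  # corrupted confidence is rejected naming the line
  lines <- readLines(path)
  lines[2] <- sub("\"confidence\":[0-9.]+", "\"confidence\":101", lines[2])
  pbad <- tempfile(fileext = ".jsonl")
  writeLines(lines, pbad)
  expect_error(load_kb(pbad), "line 2.*\\(0,100\\]")
  # version mismatch warns
  expect_warning(load_kb(path, expected_version = "99"), "version mismatch")
})
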