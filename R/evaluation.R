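#' Patient test cases for evaluation
#'
#' A test case bundles a fact set with the clinician's actual category and
#' treatment protocol (and an optional annotation, e.g. a data-inconsistency
#' note). [read_eval_cases()] loads cases from a long-format CSV with
#' columns `case`, `field`, `value` where `field` is either a vocabulary
#' attribute or one of the reserved fields `actual`, `protocol`, `note`.
#'
#' @param id Case identifier.
#' @param facts Named list of facts.
#' @param actual Actual category (`"C0"`..`"C4"`).
#' @param protocol Treatment protocol category as recorded (may differ from
#'   `actual`).
#' @param note Optional annotation.
#' @param vocab Attribute vocabulary.
#' @return A `trt_test_case`.
#' @export
test_case <- function(id, facts, actual, protocol = actual, note = "",
                      vocab = trt_vocabulary()) {
  if (!actual %in% trt_categories()) stop("actual category must be C0..C4")
  structure(list(id = id, facts = as_facts(facts, vocab), actual = actual,
                 protocol = protocol, note = note),
            class = "trt_test_case")
}

#' @rdname test_case
#' @param path Path to the long-format cases CSV.
#' @return `read_eval_cases()` returns a list of `trt_test_case`s.
#' @export
read_eval_cases <- function(path, vocab = trt_vocabulary()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("case", "field", "value")
  if (!all(need %in% names(df))) stop("cases file needs columns case, field, value")
  lapply(split(df, factor(df$case, levels = unique(df$case))), function(d) {
    get1 <- function(f, default = "") {
      v <- d$value[d$field == f]
      if (length(v)) v[1] else default
    }
    fact_rows <- !(d$field %in% c("actual", "protocol", "note"))
    facts <- stats::setNames(as.list(d$value[fact_rows]), d$field[fact_rows])
    test_case(d$case[1], facts, get1("actual"),
              get1("protocol", get1("actual")), get1("note"), vocab)
  })
}

#' Evaluate diagnostic decision support over test cases
#'
#' Runs [infer_diagnosis()] on every case and summarises: accuracy (percent
#' of cases whose primary predicted category equals the actual category;
#' an uncovered case counts as incorrect), a covered-only accuracy variant,
#' coverage (percent of cases matched by at least one rule) and the mean
#' primary confidence over covered cases using the exact stored rule
#' confidences (before any display rounding).
#'
#' @param kb A `trt_kb` with diagnosis rules.
#' @param cases List of `trt_test_case`s.
#' @param vocab Attribute vocabulary.
#' @return A `trt_eval_diagnosis`: list with the summary fields and a
#'   per-case data frame (`cases`).
#' @export
evaluate_diagnosis <- function(kb, cases, vocab = trt_vocabulary()) {
  if (!length(cases)) stop("no test cases")
  rows <- lapply(cases, function(tc) {
    res <- infer_diagnosis(tc$facts, kb, vocab)
    data.frame(case = tc$id,
               actual = tc$actual,
               predicted = if (res$covered) res$primary else NA_character_,
               confidence = if (res$covered) res$confidence else NA_real_,
               covered = res$covered,
               correct = res$covered && identical(res$primary, tc$actual),
               n_matched = length(res$matched),
               explanation = if (res$covered) res$ranking$explanations[[1]][1] else "",
               stringsAsFactors = FALSE)
  })
  per_case <- do.call(rbind, rows)
  rownames(per_case) <- NULL
  n <- nrow(per_case)
  covered <- per_case$covered
  structure(list(
    n = n,
    accuracy = 100 * sum(per_case$correct) / n,
    accuracy_covered = if (any(covered)) 100 * sum(per_case$correct) / sum(covered)
                       else NA_real_,
    coverage = 100 * sum(covered) / n,
    mean_primary_confidence = if (any(covered)) mean(per_case$confidence[covered])
                              else NA_real_,
    cases = per_case),
    class = "trt_eval_diagnosis")
}

#' @export
print.trt_eval_diagnosis <- function(x, ...) {
  cat(sprintf(
    "<diagnosis evaluation> n=%d  accuracy %.1f%%  coverage %.1f%%  mean confidence %.2f%%\n",
    x$n, x$accuracy, x$coverage, x$mean_primary_confidence))
  print(x$cases[, c("case", "actual", "predicted", "confidence", "covered")])
  invisible(x)
}

#' Evaluate treatment decision support over test cases
#'
#' Runs [recommend_treatment()] on every case; treatment coverage is the
#' number of cases that receive at least one recommendation. Every
#' recommendation carries its expected gain and explanation.
#'
#' @inheritParams evaluate_diagnosis
#' @return A `trt_eval_treatment`: list with `n`, `coverage_count`,
#'   `coverage` (percent) and a per-case data frame (`cases`) whose
#'   `recommendations` column holds each case's full recommendation table.
#' @export
evaluate_treatment <- function(kb, cases, vocab = trt_vocabulary()) {
  if (!length(cases)) stop("no test cases")
  rows <- lapply(cases, function(tc) {
    rec <- recommend_treatment(tc$facts, kb, vocab = vocab)
    data.frame(case = tc$id,
               n_recommendations = nrow(rec),
               top_action = if (nrow(rec)) rec$action[1] else "",
               top_gain = if (nrow(rec)) rec$gain[1] else NA_real_,
               top_confidence = if (nrow(rec)) rec$confidence[1] else NA_real_,
               explanation = if (nrow(rec)) rec$explanation[1] else "",
               stringsAsFactors = FALSE)
  })
  per_case <- do.call(rbind, rows)
  rownames(per_case) <- NULL
  per_case$recommendations <- lapply(cases, function(tc) {
    recommend_treatment(tc$facts, kb, vocab = vocab)
  })
  covered <- per_case$n_recommendations > 0
  structure(list(n = nrow(per_case),
                 coverage_count = sum(covered),
                 coverage = 100 * mean(covered),
                 cases = per_case),
            class = "trt_eval_treatment")
}

#' @export
print.trt_eval_treatment <- function(x, ...) {
  cat(sprintf("<treatment evaluation> n=%d  covered %d (%.0f%%)\n",
              x$n, x$coverage_count, x$coverage))
  print(x$cases[, c("case", "n_recommendations", "top_action", "top_gain")])
  invisible(x)
}

#' Shipped reference rules and evaluation cases
#'
#' The package ships a small reference knowledge base and five worked
#' patient cases, used in the examples, the test suite and the acceptance
#' script: `demo_diagnosis.rules` / `demo_treatment.rules` (sample mined
#' diagnostic and treatment patterns) and `eval_diagnosis.rules` /
#' `eval_treatment.rules` + `eval_cases.csv` (the rules and fact sets of the
#' worked evaluation study).
#'
#' @param which One of `"demo_diagnosis"`, `"demo_treatment"`,
#'   `"eval_diagnosis"`, `"eval_treatment"`.
#' @return `trt_example_rules()` returns the file path;
#'   `trt_example_kb()` a translated `trt_kb`; `trt_eval_cases()` the list
#'   of five `trt_test_case`s.
#' @export
trt_example_rules <- function(which = c("demo_diagnosis", "demo_treatment",
                                        "eval_diagnosis", "eval_treatment")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".rules"), package = "trtcds")
  if (!nzchar(path)) stop("fixture not found: ", which)
  path
}

#' @rdname trt_example_rules
#' @param kind `"diagnosis"` builds the evaluation diagnosis KB;
#'   `"treatment"` the treatment KB (demo + evaluation action rules,
#'   deduplicated).
#' @export
trt_example_kb <- function(kind = c("diagnosis", "treatment")) {
  kind <- match.arg(kind)
  if (kind == "diagnosis") {
    translate(trt_example_rules("eval_diagnosis"), "diagnosis")
  } else {
    translate(c(trt_example_rules("demo_treatment"),
                trt_example_rules("eval_treatment")), "treatment")
  }
}

#' @rdname trt_example_rules
#' @export
trt_eval_cases <- function() {
  read_eval_cases(system.file("extdata", "eval_cases.csv", package = "trtcds"))
}
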