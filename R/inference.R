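#' Assemble a fact set for one patient at one visit
#'
#' Flattens the patient profile and the chosen visit into a single
#' attribute-to-value map (a named list). Missing cells are dropped (a
#' missing fact leaves any cedent on that attribute unsatisfied at match
#' time); binary values are normalised to `"yes"`/`"no"`. Raw numerics are
#' retained: interval and threshold cedents are evaluated against the raw
#' values, not against re-discretized labels.
#'
#' @param case A `trt_patient_case` (see [patient_case()]).
#' @param visit_no Visit ordinal to assert; defaults to the first visit.
#' @param vocab Attribute vocabulary.
#' @return Named list of facts (class `trt_facts`).
#' @export
assert_facts <- function(case, visit_no = NULL, vocab = trt_vocabulary()) {
  stopifnot(inherits(case, "trt_patient_case"))
  if (!nrow(case$visits)) stop("patient has no visits")
  if (is.null(visit_no)) visit_no <- case$visits$visit_no[1]
  vi <- match(visit_no, case$visits$visit_no)
  if (is.na(vi)) stop("unknown visit: ", visit_no)
  row_facts <- function(row) {
    row <- as.list(row)
    row <- row[!vapply(row, function(v) is.null(v) || is.na(v), logical(1))]
    row
  }
  facts <- c(row_facts(case$profile[1, setdiff(names(case$profile), "patient_id"),
                                    drop = FALSE]),
             row_facts(case$visits[vi, setdiff(names(case$visits),
                                               c("patient_id", "visit_no")),
                                   drop = FALSE]))
  as_facts(facts, vocab)
}

#' @rdname assert_facts
#' @param facts Named list/vector of attribute values.
#' @return `as_facts()` validates names against the vocabulary and returns a
#'   `trt_facts`.
#' @export
as_facts <- function(facts, vocab = trt_vocabulary()) {
  facts <- as.list(facts)
  if (!length(facts)) return(structure(list(), class = "trt_facts"))
  if (is.null(names(facts)) || any(!nzchar(names(facts)))) {
    stop("facts must be a named attribute->value map")
  }
  if (anyDuplicated(names(facts))) stop("one value per attribute: duplicated fact names")
  unknown <- names(facts)[!vapply(names(facts), vocab_has, logical(1), vocab = vocab)]
  if (length(unknown)) stop("unknown attribute(s) in facts: ",
                            paste(unknown, collapse = ", "))
  for (a in names(facts)) {
    if (vocab_dtype(a, vocab) == "binary") facts[[a]] <- norm_binary(facts[[a]])
  }
  structure(facts, class = "trt_facts")
}

# Does a rule's premise hold for a fact set? For treatment rules both the
# stable context and every change's from-state must be satisfied.
rule_matches_facts <- function(rule, facts, vocab = trt_vocabulary()) {
  ceds <- if (inherits(rule, "trt_decision_rule")) rule$cedents
          else c(rule$stable, rule$flexible)
  for (ced in ceds) {
    v <- facts[[ced$attr]]
    if (is.null(v) || !cedent_matches_value(ced, v, vocab)) return(FALSE)
  }
  TRUE
}

#' Match knowledge-base rules against a fact set
#'
#' A rule matches iff every cedent is satisfied by the facts (half-open
#' interval semantics; a missing fact leaves a cedent unsatisfied). The
#' default `"indexed"` method pre-filters rules through an
#' attribute-indexed (alpha-memory style) candidate set before evaluating
#' cedents; it is behaviourally identical to `"naive"` per-rule evaluation,
#' which is the binding contract.
#'
#' @param facts A `trt_facts` (or named list).
#' @param kb A `trt_kb`.
#' @param kind `"diagnosis"` or `"treatment"`.
#' @param method `"indexed"` or `"naive"`.
#' @param vocab Attribute vocabulary.
#' @return List of matched encoded rules, in knowledge-base order.
#' @export
match_rules <- function(facts, kb, kind = c("diagnosis", "treatment"),
                        method = c("indexed", "naive"), vocab = trt_vocabulary()) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  if (!inherits(facts, "trt_facts")) facts <- as_facts(facts, vocab)
  rules <- Filter(function(er) er$kind == kind, kb$rules)
  if (!length(rules)) return(list())
  if (method == "indexed") {
    fact_names <- names(facts)
    candidate <- vapply(rules, function(er) {
      all(rule_attrs(er$rule) %in% fact_names)
    }, logical(1))
    rules <- rules[candidate]
  }
  Filter(function(er) rule_matches_facts(er$rule, facts, vocab), rules)
}

#' Confidence-ranked diagnosis from the knowledge base
#'
#' Fires every matching diagnosis rule and aggregates per category by the
#' maximum matched-rule confidence; categories are ranked by confidence
#' (descending), ties broken by category order C0 < ... < C4 then rule id.
#' The primary diagnosis is the first ranked category. When no rule matches
#' the result is flagged uncovered with an empty ranking.
#'
#' @param facts A `trt_facts`.
#' @param kb A `trt_kb` containing diagnosis rules.
#' @param vocab Attribute vocabulary.
#' @return A `trt_diagnosis`: list with `ranking` (data frame: category,
#'   confidence, rule_ids, explanations), `primary`, `confidence`,
#'   `covered`.
#' @export
infer_diagnosis <- function(facts, kb, vocab = trt_vocabulary()) {
  matched <- match_rules(facts, kb, "diagnosis", vocab = vocab)
  if (!length(matched)) {
    return(structure(list(
      ranking = data.frame(category = character(0), confidence = numeric(0),
                           stringsAsFactors = FALSE),
      primary = NA_character_, confidence = NA_real_, covered = FALSE,
      matched = list()), class = "trt_diagnosis"))
  }
  cats <- vapply(matched, function(er) er$rule$category, character(1))
  conf <- vapply(matched, function(er) er$rule$confidence, numeric(1))
  uc <- sort(unique(cats))   # category order C0 < ... < C4
  ranking <- data.frame(
    category = uc,
    confidence = vapply(uc, function(ct) max(conf[cats == ct]), numeric(1)),
    stringsAsFactors = FALSE)
  ranking$rule_ids <- lapply(uc, function(ct) {
    ids <- vapply(matched[cats == ct], `[[`, character(1), "id")
    ids[order(-conf[cats == ct], ids)]
  })
  ranking$explanations <- lapply(uc, function(ct) {
    ex <- vapply(matched[cats == ct], `[[`, character(1), "explanation")
    ex[order(-conf[cats == ct])]
  })
  ranking <- ranking[order(-ranking$confidence, ranking$category), , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, primary = ranking$category[1],
                 confidence = ranking$confidence[1], covered = TRUE,
                 matched = matched),
            class = "trt_diagnosis")
}

#' @export
print.trt_diagnosis <- function(x, ...) {
  if (!x$covered) {
    cat("<trt_diagnosis> uncovered: no rule matched\n")
  } else {
    cat(sprintf("<trt_diagnosis> primary %s (confidence %s%%)\n",
                x$primary, fmt_num(round(x$confidence, 1))))
    print(x$ranking[, c("category", "confidence")])
  }
  invisible(x)
}

#' Treatment recommendations from action rules
#'
#' Returns one recommended action per matching action rule: the rule's
#' stable context must be satisfied by the facts and the current facts must
#' be in every change's from-state (a patient already in the to-state is not
#' recommended a no-op). Ranked by expected gain (descending, unknown gains
#' last), then confidence, then rule id.
#'
#' @param facts A `trt_facts`.
#' @param kb A `trt_kb` containing treatment rules.
#' @param rank_by `"gain"` (default) or `"confidence"`.
#' @param vocab Attribute vocabulary.
#' @return A `trt_recommendation`: data frame with columns `action`,
#'   `attribute`, `from`, `to`, `gain`, `confidence`, `rule_id`,
#'   `explanation`; zero rows when no rule applies.
#' @export
recommend_treatment <- function(facts, kb, rank_by = c("gain", "confidence"),
                                vocab = trt_vocabulary()) {
  rank_by <- match.arg(rank_by)
  matched <- match_rules(facts, kb, "treatment", vocab = vocab)
  rows <- lapply(matched, function(er) {
    r <- er$rule
    acts <- vapply(r$flexible, function(ced) {
      sprintf("change %s from %s to %s", ced$attr, ced$value, ced$value2)
    }, character(1))
    data.frame(
      action = paste(acts, collapse = "; "),
      attribute = paste(vapply(r$flexible, `[[`, character(1), "attr"), collapse = ";"),
      from = paste(vapply(r$flexible, function(c) as.character(c$value), character(1)),
                   collapse = ";"),
      to = paste(vapply(r$flexible, function(c) as.character(c$value2), character(1)),
                 collapse = ";"),
      gain = if (is.null(r$gain)) NA_real_ else r$gain,
      confidence = r$confidence,
      rule_id = er$id,
      explanation = er$explanation,
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(action = character(0), attribute = character(0), from = character(0),
               to = character(0), gain = numeric(0), confidence = numeric(0),
               rule_id = character(0), explanation = character(0),
               stringsAsFactors = FALSE)
  if (nrow(out)) {
    gain_key <- ifelse(is.na(out$gain), -Inf, out$gain)
    ord <- if (rank_by == "gain") order(-gain_key, -out$confidence, out$rule_id)
           else order(-out$confidence, -gain_key, out$rule_id)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("trt_recommendation", "data.frame")
  out
}
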