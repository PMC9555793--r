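#' Rule cedents
#'
#' A cedent is one attribute condition inside a rule: an equality, a
#' threshold (`>=`, `<=`, `>`, `<`), a half-open interval `[a;b)`, or (for
#' action rules) a from-to change of a flexible attribute.
#'
#' @param attr Attribute name (must resolve in the vocabulary when rules are
#'   parsed or encoded).
#' @param op One of `"eq"`, `"ge"`, `"le"`, `"gt"`, `"lt"`, `"interval"`,
#'   `"change"`.
#' @param value For `eq`/thresholds the value; for `interval` the lower
#'   bound; for `change` the from-state.
#' @param value2 For `interval` the upper bound; for `change` the to-state.
#' @param eq_form For `eq`: `"literal"` (rendered `Attr(v)`) or `"num"`
#'   (rendered `Attr(=v)`); preserved so parse/serialize round-trips.
#' @return A list of class `trt_cedent`.
#' @export
cedent <- function(attr, op, value, value2 = NULL, eq_form = "literal") {
  op <- match.arg(op, c("eq", "ge", "le", "gt", "lt", "interval", "change"))
  if (op == "interval") {
    a <- as.numeric(value); b <- as.numeric(value2)
    if (is.na(a) || is.na(b) || !a < b) {
      stop("malformed interval cedent on '", attr, "': need numeric a < b")
    }
    value <- a; value2 <- b
  }
  if (op == "change") {
    if (is.null(value2)) stop("change cedent needs both a from and a to state")
    if (identical(as.character(value), as.character(value2))) {
      stop("change cedent on '", attr, "' must alter the value")
    }
  }
  structure(list(attr = attr, op = op, value = value, value2 = value2,
                 eq_form = eq_form),
            class = "trt_cedent")
}

# --- scalar satisfaction ---------------------------------------------------

# Does a single fact value satisfy a cedent? Missing facts never satisfy.
cedent_matches_value <- function(ced, value, vocab = trt_vocabulary()) {
  if (is.null(value) || length(value) == 0 || is.na(value)) return(FALSE)
  num <- suppressWarnings(as.numeric(value))
  switch(ced$op,
    eq = {
      if (ced$eq_form == "num") {
        !is.na(num) && num == as.numeric(ced$value)
      } else {
        target <- as.character(ced$value)
        v <- as.character(value)
        if (vocab_has(ced$attr, vocab) && vocab_dtype(ced$attr, vocab) == "binary") {
          identical(norm_binary(v), norm_binary(target))
        } else if (!is.na(num) && !is.na(suppressWarnings(as.numeric(target)))) {
          num == as.numeric(target)
        } else {
          identical(v, target)
        }
      }
    },
    ge = !is.na(num) && num >= as.numeric(ced$value),
    le = !is.na(num) && num <= as.numeric(ced$value),
    gt = !is.na(num) && num > as.numeric(ced$value),
    lt = !is.na(num) && num < as.numeric(ced$value),
    interval = {
      if (!is.na(num)) {
        num >= ced$value && num < ced$value2
      } else {
        # discretized (label-valued) fact: match the rendered label
        identical(as.character(value), render_interval(ced$value, ced$value2))
      }
    },
    change = state_matches(ced$value, value),
    stop("unsupported cedent op: ", ced$op)
  )
}

# Match a from/to state token (interval label or literal) against a fact value.
state_matches <- function(state, value) {
  if (is.na(value)) return(FALSE)
  if (is_interval_label(state)) {
    num <- suppressWarnings(as.numeric(value))
    ab <- parse_interval(state)
    if (!is.na(num)) return(num >= ab[1] && num < ab[2])
    return(identical(as.character(value), render_interval(ab[1], ab[2])))
  }
  sn <- suppressWarnings(as.numeric(state))
  vn <- suppressWarnings(as.numeric(value))
  if (!is.na(sn) && !is.na(vn)) return(sn == vn)
  identical(as.character(value), as.character(state))
}

# Vectorised satisfaction of a cedent over a table column.
cedent_matches_column <- function(ced, column, vocab = trt_vocabulary()) {
  vapply(column, function(v) cedent_matches_value(ced, v, vocab), logical(1))
}

# --- rule objects ----------------------------------------------------------

#' Decision rules and action rules
#'
#' A decision rule is a conjunction of cedents implying a TRT category, with
#' support (number of objects matching the antecedent) and confidence
#' (percent of those that also match the category). An action rule pairs a
#' stable context with one or more flexible-attribute changes that shift the
#' treatment outcome for the better; its composite confidence is the
#' confidence of the after-rule and it carries the expected improvement gain
#' in percentage points.
#'
#' @param cedents List of [cedent()]s forming the antecedent (non-empty).
#' @param category Target category `"C0"`..`"C4"`.
#' @param confidence Percent in (0, 100].
#' @param support Absolute object count (may be `NA` for rules quoted
#'   without support).
#' @return `decision_rule()` returns a `trt_decision_rule`;
#'   `action_rule()` a `trt_action_rule`.
#' @export
decision_rule <- function(cedents, category, confidence, support = NA_integer_) {
  if (!length(cedents)) stop("decision rule needs a non-empty antecedent")
  stopifnot(all(vapply(cedents, inherits, logical(1), "trt_cedent")))
  if (any(vapply(cedents, function(x) x$op == "change", logical(1)))) {
    stop("decision rules cannot contain change cedents")
  }
  if (!category %in% trt_categories()) stop("unknown category: ", category)
  check_confidence(confidence)
  if (!is.na(support) && support < 1) stop("support must be >= 1")
  structure(list(cedents = cedents, category = category,
                 confidence = confidence, support = support),
            class = "trt_decision_rule")
}

#' @rdname decision_rule
#' @param stable List of [cedent()]s forming the stable context (may be
#'   empty).
#' @param flexible Non-empty list of `change` cedents.
#' @param gain Expected improvement in percentage points (may be `NA`).
#' @param before_support,before_confidence,after_support,after_confidence
#'   Stats of the two classification rules the action rule decomposes into.
#' @export
action_rule <- function(stable, flexible, confidence, support = NA_integer_,
                        gain = NA_real_,
                        before_support = NA_integer_, before_confidence = NA_real_,
                        after_support = NA_integer_, after_confidence = NA_real_) {
  if (!length(flexible)) stop("action rule needs a non-empty flexible change")
  stopifnot(all(vapply(flexible, function(x) inherits(x, "trt_cedent") &&
                         x$op == "change", logical(1))))
  stopifnot(all(vapply(stable, inherits, logical(1), "trt_cedent")))
  check_confidence(confidence)
  if (!is.na(gain) && !is.finite(gain)) stop("expected gain must be finite")
  structure(list(stable = stable, flexible = flexible,
                 effect = list(attr = "Ch", from = "not-better", to = "better"),
                 confidence = confidence, support = support, gain = gain,
                 before_support = before_support,
                 before_confidence = before_confidence,
                 after_support = after_support,
                 after_confidence = after_confidence),
            class = "trt_action_rule")
}

check_confidence <- function(confidence) {
  if (is.na(confidence) || confidence <= 0 || confidence > 100) {
    stop("confidence must lie in (0,100]; got ", confidence)
  }
}

rule_kind <- function(rule) {
  if (inherits(rule, "trt_decision_rule")) "diagnosis"
  else if (inherits(rule, "trt_action_rule")) "treatment"
  else stop("not a rule object")
}

# Attributes a rule's premises reference (used by the alpha index).
rule_attrs <- function(rule) {
  if (inherits(rule, "trt_decision_rule")) {
    vapply(rule$cedents, `[[`, character(1), "attr")
  } else {
    c(vapply(rule$stable, `[[`, character(1), "attr"),
      vapply(rule$flexible, `[[`, character(1), "attr"))
  }
}

# --- serialization (the rule-text dialect) ---------------------------------

serialize_cedent <- function(ced) {
  pred <- switch(ced$op,
    eq = if (identical(ced$eq_form, "num")) paste0("=", fmt_num(as.numeric(ced$value)))
         else as.character(ced$value),
    ge = paste0(">=", fmt_num(as.numeric(ced$value))),
    le = paste0("<=", fmt_num(as.numeric(ced$value))),
    gt = paste0(">", fmt_num(as.numeric(ced$value))),
    lt = paste0("<", fmt_num(as.numeric(ced$value))),
    interval = render_interval(ced$value, ced$value2),
    change = paste0(ced$value, "->", ced$value2)
  )
  paste0(ced$attr, "(", pred, ")")
}

#' Serialize a rule to the rule-text dialect
#'
#' Inverse of [parse_rule_text()]: `parse_rule_text(serialize_rule(r))`
#' reproduces `r`, and serializing a parsed dialect line reproduces the line
#' (canonical spacing).
#'
#' @param rule A `trt_decision_rule` or `trt_action_rule`.
#' @return A single-line character string.
#' @export
serialize_rule <- function(rule) {
  if (inherits(rule, "trt_decision_rule")) {
    lhs <- paste(vapply(rule$cedents, serialize_cedent, character(1)), collapse = " & ")
    line <- paste0(lhs, " => Category(", sub("^C", "", rule$category), ")",
                   " | conf=", fmt_num(rule$confidence))
    if (!is.na(rule$support)) line <- paste0(line, " ; sup=", fmt_num(rule$support))
    line
  } else if (inherits(rule, "trt_action_rule")) {
    stable <- paste(vapply(rule$stable, serialize_cedent, character(1)), collapse = " & ")
    flex <- paste(vapply(rule$flexible, serialize_cedent, character(1)), collapse = " & ")
    line <- paste0(if (nzchar(stable)) paste0(stable, " ") else "", ": (", flex,
                   ") => Ch(better) | conf=", fmt_num(rule$confidence))
    if (!is.na(rule$support)) line <- paste0(line, " ; sup=", fmt_num(rule$support))
    if (!is.na(rule$gain)) line <- paste0(line, " ; gain=", fmt_num(rule$gain))
    line
  } else {
    stop("not a rule object")
  }
}

# Canonical form used for deduplication: premises sorted, stats stripped.
canonical_rule <- function(rule) {
  if (inherits(rule, "trt_decision_rule")) {
    lhs <- sort(vapply(rule$cedents, serialize_cedent, character(1)))
    paste0("D|", paste(lhs, collapse = "&"), "=>", rule$category)
  } else {
    st <- sort(vapply(rule$stable, serialize_cedent, character(1)))
    fl <- sort(vapply(rule$flexible, serialize_cedent, character(1)))
    paste0("A|", paste(st, collapse = "&"), ":", paste(fl, collapse = "&"))
  }
}

#' @export
print.trt_decision_rule <- function(x, ...) {
  cat(serialize_rule(x), "\n"); invisible(x)
}

#' @export
print.trt_action_rule <- function(x, ...) {
  cat(serialize_rule(x), "\n"); invisible(x)
}

# --- support / confidence --------------------------------------------------

#' Support and confidence of a decision rule on a table
#'
#' Support is the number of rows matching the rule's antecedent; confidence
#' is the percentage of those rows that also carry the rule's category.
#'
#' @param rule A `trt_decision_rule`.
#' @param table Data frame; must contain every antecedent attribute and the
#'   target column.
#' @param target_attr Name of the category column (default `"Cat"`).
#' @param vocab Attribute vocabulary.
#' @return List with `support` (count) and `confidence` (percent).
#' @export
rule_stats <- function(rule, table, target_attr = "Cat", vocab = trt_vocabulary()) {
  missing_attr <- setdiff(c(rule_attrs(rule), target_attr), names(table))
  if (length(missing_attr)) {
    stop("table lacks attribute(s): ", paste(missing_attr, collapse = ", "))
  }
  match_ant <- rep(TRUE, nrow(table))
  for (ced in rule$cedents) {
    match_ant <- match_ant & cedent_matches_column(ced, table[[ced$attr]], vocab)
  }
  support <- sum(match_ant)
  if (support == 0) stop("antecedent matches no rows; confidence undefined")
  joint <- sum(match_ant & !is.na(table[[target_attr]]) &
                 as.character(table[[target_attr]]) == rule$category)
  list(support = support, confidence = 100 * joint / support)
}
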