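#' Parse one line of the rule-text dialect
#'
#' The dialect expresses every rule the knowledge translator handles:
#'
#' * diagnosis: `cedent ("&" cedent)* "=>" "Category(" k ")" "|" "conf=" num
#'   ["; sup=" int]`
#' * treatment: `[stable-cedents] ":" "(" flexchange ("&" flexchange)* ")"
#'   "=>" "Ch(better)" "|" "conf=" num ["; sup=" int] ["; gain=" num]`
#'
#' A cedent is `Attr(pred)` with `pred` one of an interval `"<a;b)"`, a
#' threshold `">=v"`, `"<=v"`, `">v"`, `"<v"`, a numeric equality `"=v"`, or
#' a literal level (`yes`, `no`, `m`, `GHH`, ...). A flexchange is
#' `Attr(from->to)` where `from`/`to` are literals or interval labels.
#' Attributes are validated against the vocabulary; categorical literals
#' against their declared domain.
#'
#' @param line One rule line.
#' @param kind `"diagnosis"` or `"treatment"`.
#' @param vocab Attribute vocabulary.
#' @return A `trt_decision_rule` or `trt_action_rule`.
#' @export
#' @examples
#' parse_rule_text("R3(<15;20)) & T_An(>=8) => Category(1) | conf=94", "diagnosis")
parse_rule_text <- function(line, kind = c("diagnosis", "treatment"),
                            vocab = trt_vocabulary()) {
  kind <- match.arg(kind)
  parts <- split_fixed_once(line, "=>")
  if (is.null(parts)) stop("syntax error at char ", nchar(line) + 1L,
                           ": missing '=>' in rule line")
  lhs <- trimws(parts[1]); rhs <- trimws(parts[2])

  meta_parts <- split_fixed_once(rhs, "|")
  if (is.null(meta_parts)) stop("syntax error: missing '| conf=' metadata")
  consequent <- trimws(meta_parts[1])
  meta <- parse_rule_meta(meta_parts[2])
  if (is.na(meta$conf)) stop("syntax error: missing confidence ('conf=')")
  check_confidence(meta$conf)

  if (kind == "diagnosis") {
    m <- regmatches(consequent, regexec("^Category\\(\\s*C?([0-4])\\s*\\)$", consequent))[[1]]
    if (length(m) != 2) stop("syntax error in consequent '", consequent,
                             "': expected Category(0..4)")
    category <- paste0("C", m[2])
    cedents <- parse_cedent_list(lhs, line, vocab)
    if (!length(cedents)) stop("syntax error: empty antecedent")
    decision_rule(cedents, category, meta$conf, meta$sup)
  } else {
    if (!grepl("^Ch\\(\\s*better\\s*\\)$", consequent)) {
      stop("syntax error in consequent '", consequent, "': expected Ch(better)")
    }
    sf <- split_fixed_once(lhs, ":")
    if (is.null(sf)) stop("syntax error: treatment rule needs ':' before the action group")
    stable_txt <- trimws(sf[1]); group_txt <- trimws(sf[2])
    stable <- if (nzchar(stable_txt)) parse_cedent_list(stable_txt, line, vocab) else list()
    gm <- regmatches(group_txt, regexec("^\\((.*)\\)$", group_txt))[[1]]
    if (length(gm) != 2) stop("syntax error at char ", regexpr(":", line, fixed = TRUE) + 1L,
                              ": action group must be parenthesised")
    flex_parts <- trimws(strsplit(gm[2], "&", fixed = TRUE)[[1]])
    flexible <- lapply(flex_parts, parse_flexchange, line = line, vocab = vocab)
    action_rule(stable, flexible, meta$conf, support = meta$sup, gain = meta$gain)
  }
}

split_fixed_once <- function(s, sep) {
  i <- regexpr(sep, s, fixed = TRUE)
  if (i < 0) return(NULL)
  c(substr(s, 1, i - 1), substr(s, i + nchar(sep), nchar(s)))
}

parse_rule_meta <- function(txt) {
  out <- list(conf = NA_real_, sup = NA_integer_, gain = NA_real_)
  for (piece in trimws(strsplit(txt, ";", fixed = TRUE)[[1]])) {
    m <- regmatches(piece, regexec("^(conf|sup|gain)\\s*=\\s*(-?[0-9.]+)$", piece))[[1]]
    if (length(m) != 3) stop("syntax error in rule metadata: '", piece, "'")
    val <- as.numeric(m[3])
    if (m[2] == "conf") out$conf <- val
    if (m[2] == "sup") out$sup <- as.integer(val)
    if (m[2] == "gain") out$gain <- val
  }
  out
}

parse_cedent_list <- function(txt, line, vocab) {
  pieces <- trimws(strsplit(txt, "&", fixed = TRUE)[[1]])
  lapply(pieces, parse_cedent, line = line, vocab = vocab)
}

parse_cedent <- function(txt, line, vocab) {
  m <- regmatches(txt, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\((.*)\\)$", txt))[[1]]
  if (length(m) != 3) {
    pos <- regexpr(txt, line, fixed = TRUE)
    stop("syntax error at char ", max(pos, 1), ": malformed cedent '", txt, "'")
  }
  attr <- m[2]; pred <- trimws(m[3])
  if (!vocab_has(attr, vocab)) stop("unknown attribute: '", attr, "'")
  if (!nzchar(pred)) stop("syntax error: empty predicate in '", txt, "'")
  if (is_interval_label(pred)) {
    ab <- parse_interval(pred)
    return(cedent(attr, "interval", ab[1], ab[2]))
  }
  num_pred <- function(op, chars) {
    v <- suppressWarnings(as.numeric(substr(pred, chars + 1, nchar(pred))))
    if (is.na(v)) stop("syntax error: non-numeric threshold in '", txt, "'")
    cedent(attr, op, v)
  }
  if (startsWith(pred, ">=")) return(num_pred("ge", 2))
  if (startsWith(pred, "<=")) return(num_pred("le", 2))
  if (startsWith(pred, ">")) return(num_pred("gt", 1))
  if (startsWith(pred, "<")) {
    if (grepl(";", pred, fixed = TRUE)) stop("syntax error: unclosed interval in '", txt, "'")
    return(num_pred("lt", 1))
  }
  if (startsWith(pred, "=")) return(set_eq_num(num_pred("eq", 1)))
  # literal equality; validate categorical levels against the domain
  dom <- vocab_domain(attr, vocab)
  if (!is.null(dom) && dom$type == "levels" && !pred %in% dom$levels) {
    stop("attribute '", attr, "': literal '", pred, "' not in domain {",
         paste(dom$levels, collapse = ", "), "}")
  }
  if (vocab_dtype(attr, vocab) == "binary" && !pred %in% c("yes", "no")) {
    stop("attribute '", attr, "': binary predicate must be yes/no, got '", pred, "'")
  }
  cedent(attr, "eq", pred)
}

set_eq_num <- function(ced) { ced$eq_form <- "num"; ced }

parse_flexchange <- function(txt, line, vocab) {
  m <- regmatches(txt, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\((.*)\\)$", txt))[[1]]
  if (length(m) != 3) stop("syntax error: malformed flexible change '", txt, "'")
  attr <- m[2]
  if (!vocab_has(attr, vocab)) stop("unknown attribute: '", attr, "'")
  if (vocab_kind(attr, vocab) != "flexible") {
    stop("change cedents are only allowed on flexible attributes; '", attr,
         "' is ", vocab_kind(attr, vocab))
  }
  ft <- split_fixed_once(m[3], "->")
  if (is.null(ft)) stop("syntax error: flexible change '", txt, "' needs 'from->to'")
  from <- trimws(ft[1]); to <- trimws(ft[2])
  for (side in c(from, to)) {
    if (!nzchar(side)) stop("syntax error: empty state in '", txt, "'")
    if (startsWith(side, "<") && !is_interval_label(side)) {
      stop("syntax error: unclosed interval in '", txt, "'")
    }
    dom <- vocab_domain(attr, vocab)
    if (!is.null(dom) && dom$type == "levels" && !side %in% dom$levels) {
      stop("attribute '", attr, "': state '", side, "' not in domain {",
           paste(dom$levels, collapse = ", "), "}")
    }
  }
  cedent(attr, "change", from, to)
}

# --- explanations ----------------------------------------------------------

#' Deterministic natural-language explanation for a rule
#'
#' One clause per cedent, joined by "and", followed by the consequent and
#' confidence phrase; treatment rules phrase each flexible change as "change
#' X from a to b" and append the expected gain. The wording comes from the
#' vocabulary's display phrases (with optional per-value phrases); an
#' attribute with no display phrase falls back to its raw name.
#'
#' @param rule A parsed rule.
#' @param vocab Attribute vocabulary.
#' @return A single explanation string; identical rules always yield
#'   byte-identical text.
#' @export
build_explanation <- function(rule, vocab = trt_vocabulary()) {
  if (inherits(rule, "trt_decision_rule")) {
    clauses <- vapply(rule$cedents, explain_cedent, character(1), vocab = vocab)
    sprintf("If %s, then the patient falls under Category %s with %s%% confidence.",
            paste(clauses, collapse = " and "), sub("^C", "", rule$category),
            fmt_num(round(rule$confidence, 1)))
  } else if (inherits(rule, "trt_action_rule")) {
    actions <- vapply(rule$flexible, function(ced) {
      sprintf("change %s from %s to %s", phrase_of(ced$attr, vocab),
              ced$value, ced$value2)
    }, character(1))
    action_txt <- paste(actions, collapse = " and ")
    gain_txt <- if (!is.na(rule$gain)) {
      sprintf(" with an expected gain of %s percentage points", fmt_num(rule$gain))
    } else ""
    conf_txt <- sprintf(" (%s%% confidence)", fmt_num(round(rule$confidence, 1)))
    if (length(rule$stable)) {
      ctx <- treatment_context_phrase(rule$stable, vocab)
      sprintf("%s: %s%s%s.", ctx, action_txt, gain_txt, conf_txt)
    } else {
      sprintf("%s%s%s.", capitalize(action_txt), gain_txt, conf_txt)
    }
  } else {
    stop("not a rule object")
  }
}

phrase_of <- function(attr, vocab) {
  p <- vocab_phrase(attr, vocab)
  as.character(p)
}

explain_cedent <- function(ced, vocab) {
  phrase <- phrase_of(ced$attr, vocab)
  units <- vocab_entry(ced$attr, vocab)$units
  dtype <- vocab_dtype(ced$attr, vocab)
  unit_sfx <- if (nzchar(units)) paste0(" ", units) else ""
  switch(ced$op,
    interval = {
      if (dtype == "ordinal_0_10" && ced$value2 <= 0.5) {
        sprintf("%s is not indicated as a problem (score in %s)",
                phrase, render_interval(ced$value, ced$value2))
      } else if (dtype == "ordinal_0_10" && ced$value >= 6) {
        sprintf("%s is indicated as a problem (score in %s)",
                phrase, render_interval(ced$value, ced$value2))
      } else {
        sprintf("%s is in the range %s", phrase, render_interval(ced$value, ced$value2))
      }
    },
    ge = sprintf("%s is greater than or equal to %s%s", phrase,
                 fmt_num(as.numeric(ced$value)), unit_sfx),
    le = sprintf("%s is less than or equal to %s%s", phrase,
                 fmt_num(as.numeric(ced$value)), unit_sfx),
    gt = sprintf("%s is greater than %s%s", phrase, fmt_num(as.numeric(ced$value)), unit_sfx),
    lt = sprintf("%s is less than %s%s", phrase, fmt_num(as.numeric(ced$value)), unit_sfx),
    eq = {
      if (dtype == "binary") {
        if (identical(norm_binary(ced$value), "yes")) sprintf("%s is reported", phrase)
        else sprintf("%s is not reported", phrase)
      } else {
        vp <- vocab_value_phrase(ced$attr, ced$value, vocab)
        if (!is.null(vp) && !startsWith(vp, "whose")) {
          sprintf("the patient is %s", vp)
        } else {
          sprintf("%s is %s", phrase, ced$value)
        }
      }
    },
    change = sprintf("%s changes from %s to %s", phrase, ced$value, ced$value2)
  )
}

# Stable context of a treatment rule, phrased as a patient description when
# per-value phrases exist ("a male" + "whose tinnitus was induced by noise").
treatment_context_phrase <- function(stable, vocab) {
  parts <- vapply(stable, function(ced) {
    if (ced$op == "eq") {
      vp <- vocab_value_phrase(ced$attr, ced$value, vocab)
      if (!is.null(vp)) return(vp)
      if (vocab_dtype(ced$attr, vocab) == "binary" &&
          identical(norm_binary(ced$value), "yes")) {
        return(sprintf("with %s", phrase_of(ced$attr, vocab)))
      }
    }
    explain_cedent(ced, vocab)
  }, character(1))
  txt <- parts[1]
  for (p in parts[-1]) {
    txt <- if (startsWith(p, "whose") || startsWith(p, "with ")) paste(txt, p)
           else paste(txt, "and", p)
  }
  capitalize(txt)
}

capitalize <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

# --- knowledge base --------------------------------------------------------

#' Knowledge bases of encoded rules
#'
#' A knowledge base is a versioned collection of encoded rules; each encoded
#' rule carries a unique id, its kind (diagnosis/treatment), the parsed rule
#' object, a natural-language explanation and the provenance (source file
#' and line) it was translated from.
#'
#' @param version Version tag string.
#' @return `kb_new()` returns an empty `trt_kb`.
#' @export
kb_new <- function(version = "1") {
  structure(list(version = version, rules = list()), class = "trt_kb")
}

#' @rdname kb_new
#' @param kb A `trt_kb`.
#' @export
kb_counts <- function(kb) {
  kinds <- vapply(kb$rules, function(r) r$kind, character(1))
  c(diagnosis = sum(kinds == "diagnosis"),
    treatment = sum(kinds == "treatment"),
    total = length(kb$rules))
}

#' @export
print.trt_kb <- function(x, ...) {
  n <- kb_counts(x)
  cat(sprintf("<trt_kb v%s> %d rules (%d diagnosis, %d treatment)\n",
              x$version, n["total"], n["diagnosis"], n["treatment"]))
  invisible(x)
}

encoded_rule <- function(id, kind, rule, explanation, provenance) {
  if (!nzchar(explanation)) stop("explanation must be non-empty")
  structure(list(id = id, kind = kind, rule = rule, explanation = explanation,
                 provenance = provenance),
            class = "trt_encoded_rule")
}

#' Translate rule-text files into a knowledge base
#'
#' The knowledge translator: reads rules line by line, parses each line,
#' builds its explanation and encodes it into the knowledge base. Blank
#' lines and `#` comments are skipped; a malformed line is collected in the
#' summary (with its file, line number and message) without aborting the
#' translation. Duplicate rules (identical canonical premises and
#' consequent) are collapsed keeping the higher-confidence variant (on ties,
#' the variant that carries an expected gain).
#'
#' @param files Character vector of rule-text file paths.
#' @param kind `"diagnosis"` or `"treatment"` (applies to all `files`).
#' @param kb Knowledge base to extend (default: a fresh one).
#' @param vocab Attribute vocabulary.
#' @return The extended `trt_kb`; attribute `"summary"` holds counts of
#'   lines read/encoded/rejected and the per-line errors.
#' @export
translate <- function(files, kind = c("diagnosis", "treatment"), kb = kb_new(),
                      vocab = trt_vocabulary()) {
  kind <- match.arg(kind)
  stopifnot(inherits(kb, "trt_kb"))
  read <- 0L; encoded <- 0L
  errors <- list()
  canon_index <- vapply(kb$rules, function(r) canonical_rule(r$rule), character(1))
  for (f in files) {
    if (!file.exists(f)) stop("unreadable rule file: ", f)
    lines <- readLines(f, warn = FALSE)
    for (i in seq_along(lines)) {
      line <- trimws(lines[i])
      if (!nzchar(line) || startsWith(line, "#")) next
      read <- read + 1L
      rule <- tryCatch(parse_rule_text(line, kind, vocab), error = function(e) e)
      if (inherits(rule, "error")) {
        errors[[length(errors) + 1]] <- data.frame(
          file = f, line = i, message = conditionMessage(rule),
          stringsAsFactors = FALSE)
        next
      }
      canon <- canonical_rule(rule)
      dup <- match(canon, canon_index)
      if (!is.na(dup)) {
        old <- kb$rules[[dup]]$rule
        better <- rule$confidence > old$confidence ||
          (rule$confidence == old$confidence &&
             !is.null(rule$gain) && !is.na(rule$gain) &&
             (is.null(old$gain) || is.na(old$gain)))
        if (better) {
          kb$rules[[dup]] <- encoded_rule(
            kb$rules[[dup]]$id, kind, rule, build_explanation(rule, vocab),
            sprintf("%s:%d", basename(f), i))
        }
        encoded <- encoded + 1L
        next
      }
      id <- sprintf("%s-%04d", substr(kind, 1, 1), length(kb$rules) + 1L)
      kb$rules[[length(kb$rules) + 1L]] <- encoded_rule(
        id, kind, rule, build_explanation(rule, vocab),
        sprintf("%s:%d", basename(f), i))
      canon_index <- c(canon_index, canon)
      encoded <- encoded + 1L
    }
  }
  attr(kb, "summary") <- list(
    lines_read = read, encoded = encoded, rejected = length(errors),
    errors = if (length(errors)) do.call(rbind, errors) else NULL)
  kb
}

#' Encode already-parsed rules into a knowledge base
#'
#' Programmatic counterpart of [translate()] for rules produced by
#' [mine_decision_rules()] / [mine_action_rules()].
#'
#' @param rules List of rule objects.
#' @param kind `"diagnosis"` or `"treatment"`.
#' @param kb Knowledge base to extend.
#' @param provenance Provenance string recorded on each rule.
#' @param vocab Attribute vocabulary.
#' @return The extended `trt_kb`.
#' @export
encode_rules <- function(rules, kind = c("diagnosis", "treatment"), kb = kb_new(),
                         provenance = "mined", vocab = trt_vocabulary()) {
  kind <- match.arg(kind)
  tmp <- tempfile(fileext = ".rules")
  on.exit(unlink(tmp))
  writeLines(vapply(rules, serialize_rule, character(1)), tmp)
  kb <- translate(tmp, kind, kb, vocab)
  for (i in seq_along(kb$rules)) {
    if (startsWith(kb$rules[[i]]$provenance, basename(tmp))) {
      kb$rules[[i]]$provenance <- sub(basename(tmp), provenance,
                                      kb$rules[[i]]$provenance, fixed = TRUE)
    }
  }
  kb
}

# --- JSON Lines persistence ------------------------------------------------

#' Save / load a knowledge base as JSON Lines
#'
#' One JSON object per line: a header line carrying the version tag followed
#' by one line per encoded rule (id, kind, cedents, consequent, confidence,
#' support, gain, explanation, provenance). `load_kb(save_kb(kb))`
#' reproduces the knowledge base; a corrupt or invalid line raises a load
#' error naming the line.
#'
#' @param kb A `trt_kb`.
#' @param path File path (conventionally `.jsonl`).
#' @return `save_kb()` invisibly returns `path`; `load_kb()` returns the
#'   `trt_kb`.
#' @export
save_kb <- function(kb, path) {
  stopifnot(inherits(kb, "trt_kb"))
  lines <- c(
    jsonlite::toJSON(list(type = "kb_header", version = kb$version,
                          n_rules = length(kb$rules)), auto_unbox = TRUE),
    vapply(kb$rules, function(er) {
      rec <- list(id = er$id, kind = er$kind, version = kb$version)
      r <- er$rule
      if (er$kind == "diagnosis") {
        rec$cedents <- lapply(r$cedents, cedent_to_list)
        rec$consequent <- r$category
      } else {
        rec$stable <- lapply(r$stable, cedent_to_list)
        rec$flexible <- lapply(r$flexible, cedent_to_list)
        rec$consequent <- "Ch(better)"
        rec$gain <- r$gain
        rec$before_support <- r$before_support
        rec$before_confidence <- r$before_confidence
      }
      rec$confidence <- r$confidence
      rec$support <- r$support
      rec$explanation <- er$explanation
      rec$provenance <- er$provenance
      jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null", digits = NA)
    }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

cedent_to_list <- function(ced) {
  list(attr = ced$attr, op = ced$op,
       value = if (is.numeric(ced$value)) ced$value else as.character(ced$value),
       value2 = if (is.null(ced$value2)) NULL
                else if (is.numeric(ced$value2)) ced$value2 else as.character(ced$value2),
       eq_form = ced$eq_form)
}

cedent_from_list <- function(x) {
  cedent(x$attr, x$op, x$value, x$value2,
         eq_form = if (is.null(x$eq_form)) "literal" else x$eq_form)
}

#' @rdname save_kb
#' @param expected_version If non-`NULL`, a differing version tag in the
#'   file triggers a warning.
#' @export
load_kb <- function(path, expected_version = NULL) {
  if (!file.exists(path)) stop("knowledge base file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(kb_new())
  parse_line <- function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
             error = function(e) stop("corrupt knowledge base line ", i, ": ",
                                      conditionMessage(e), call. = FALSE))
  }
  first <- parse_line(1)
  has_header <- identical(first$type, "kb_header")
  version <- if (has_header) first$version else "1"
  kb <- kb_new(version)
  if (!is.null(expected_version) && !identical(version, expected_version)) {
    warning("knowledge base version mismatch: file has '", version,
            "', expected '", expected_version, "'")
  }
  rule_lines <- if (has_header) seq_along(lines)[-1] else seq_along(lines)
  for (i in rule_lines) {
    rec <- parse_line(i)
    ok <- tryCatch({
      r <- if (identical(rec$kind, "diagnosis")) {
        decision_rule(lapply(rec$cedents, cedent_from_list), rec$consequent,
                      null_na(rec$confidence), null_na(rec$support, NA_integer_))
      } else if (identical(rec$kind, "treatment")) {
        action_rule(lapply(rec$stable, cedent_from_list),
                    lapply(rec$flexible, cedent_from_list),
                    null_na(rec$confidence),
                    support = null_na(rec$support, NA_integer_),
                    gain = null_na(rec$gain),
                    before_support = null_na(rec$before_support, NA_integer_),
                    before_confidence = null_na(rec$before_confidence))
      } else stop("unknown rule kind: ", rec$kind)
      kb$rules[[length(kb$rules) + 1L]] <- encoded_rule(
        rec$id, rec$kind, r, rec$explanation, rec$provenance)
      TRUE
    }, error = function(e) e)
    if (inherits(ok, "error")) {
      stop("invalid knowledge base line ", i, ": ", conditionMessage(ok), call. = FALSE)
    }
  }
  kb
}

null_na <- function(x, default = NA_real_) {
  if (is.null(x)) default else x
}
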