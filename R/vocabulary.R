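#' Controlled attribute vocabulary
#'
#' Every attribute that can appear in a cohort table, a fact set or a rule is
#' described by one row of the vocabulary: its name, kind (`stable` patient
#' context, `flexible` treatment/state, or `decision` outcome), data type,
#' units, value domain and display phrases used when explanations are
#' generated. The default vocabulary ships as a CSV config file under
#' `inst/extdata/vocabulary.csv` and covers demographics, tinnitus background
#' flags, audiometry (pure-tone thresholds and loudness discomfort levels per
#' ear and frequency), structured-interview 0-10 Likert scores, medications,
#' treatment descriptors and outcome change metrics.
#'
#' @param path Path to a vocabulary CSV. Defaults to the file shipped with
#'   the package.
#' @return A data frame with class `trt_vocabulary` and columns
#'   `name`, `kind`, `dtype`, `units`, `domain`, `phrase`, `value_phrases`.
#' @export
#' @examples
#' vocab <- trt_vocabulary()
#' vocab[vocab$name == "LL3", ]
trt_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    cached <- .trt_env$vocab
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "vocabulary.csv", package = "trtcds")
  }
  v <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = character())
  required <- c("name", "kind", "dtype", "units", "domain", "phrase", "value_phrases")
  missing <- setdiff(required, names(v))
  if (length(missing)) {
    stop("vocabulary file lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad_kind <- setdiff(unique(v$kind), c("stable", "flexible", "decision"))
  if (length(bad_kind)) stop("unknown attribute kind: ", paste(bad_kind, collapse = ", "))
  bad_dtype <- setdiff(
    unique(v$dtype),
    c("numeric", "ordinal_0_10", "binary", "categorical", "interval_label")
  )
  if (length(bad_dtype)) stop("unknown dtype: ", paste(bad_dtype, collapse = ", "))
  if (anyDuplicated(v$name)) {
    stop("duplicate vocabulary entries: ",
         paste(unique(v$name[duplicated(v$name)]), collapse = ", "))
  }
  decision_ok <- c("ChTsc", "PerChTsc", "ChTaw", "PerChTaw", "Ch")
  bad_dec <- setdiff(v$name[v$kind == "decision"], decision_ok)
  if (length(bad_dec)) {
    stop("kind 'decision' is reserved for treatment-outcome attributes; got: ",
         paste(bad_dec, collapse = ", "))
  }
  class(v) <- c("trt_vocabulary", "data.frame")
  if (is.null(.trt_env$vocab) &&
      identical(path, system.file("extdata", "vocabulary.csv", package = "trtcds"))) {
    .trt_env$vocab <- v
  }
  v
}

.trt_env <- new.env(parent = emptyenv())

vocab_entry <- function(attr, vocab = trt_vocabulary()) {
  i <- match(attr, vocab$name)
  if (is.na(i)) stop("unknown attribute: '", attr, "'", call. = FALSE)
  vocab[i, , drop = FALSE]
}

vocab_has <- function(attr, vocab = trt_vocabulary()) attr %in% vocab$name

#' @rdname trt_vocabulary
#' @param attr Attribute name.
#' @param vocab Vocabulary data frame.
#' @return `vocab_dtype()` / `vocab_kind()` return a single string.
#' @export
vocab_dtype <- function(attr, vocab = trt_vocabulary()) vocab_entry(attr, vocab)$dtype

#' @rdname trt_vocabulary
#' @export
vocab_kind <- function(attr, vocab = trt_vocabulary()) vocab_entry(attr, vocab)$kind

# Parse the packed domain column: "a:b" numeric range, "x|y|z" level set, "" open.
vocab_domain <- function(attr, vocab = trt_vocabulary()) {
  d <- vocab_entry(attr, vocab)$domain
  if (!nzchar(d)) return(NULL)
  if (grepl("^-?[0-9.]+:-?[0-9.]+$", d)) {
    parts <- as.numeric(strsplit(d, ":", fixed = TRUE)[[1]])
    return(list(type = "range", min = parts[1], max = parts[2]))
  }
  list(type = "levels", levels = strsplit(d, "|", fixed = TRUE)[[1]])
}

# Human phrase for an attribute; falls back (flagged via attribute) to the raw name.
vocab_phrase <- function(attr, vocab = trt_vocabulary()) {
  e <- vocab_entry(attr, vocab)
  if (nzchar(e$phrase)) e$phrase else structure(attr, fallback = TRUE)
}

# Optional per-value phrase, e.g. G: m -> "a male". NULL when absent.
vocab_value_phrase <- function(attr, value, vocab = trt_vocabulary()) {
  vp <- vocab_entry(attr, vocab)$value_phrases
  if (!nzchar(vp)) return(NULL)
  pairs <- strsplit(strsplit(vp, "|", fixed = TRUE)[[1]], "=", fixed = TRUE)
  for (p in pairs) {
    if (length(p) == 2 && identical(p[1], as.character(value))) return(p[2])
  }
  NULL
}

# Normalise a binary value to "yes"/"no"; anything else is returned unchanged.
norm_binary <- function(x) {
  x <- as.character(x)
  out <- x
  out[x %in% c("1", "TRUE", "true", "yes", "y", "Y")] <- "yes"
  out[x %in% c("0", "FALSE", "false", "no", "n", "N")] <- "no"
  out
}

# Validate one scalar against the vocabulary domain. Returns NULL when valid,
# otherwise a message. NA (missing) is always valid.
validate_value <- function(attr, value, vocab = trt_vocabulary()) {
  if (is.na(value)) return(NULL)
  e <- vocab_entry(attr, vocab)
  if (e$dtype == "binary") {
    if (!norm_binary(value) %in% c("yes", "no")) {
      return(sprintf("attribute '%s': '%s' is not a binary yes/no value", attr, value))
    }
    return(NULL)
  }
  dom <- vocab_domain(attr, vocab)
  if (is.null(dom)) return(NULL)
  if (dom$type == "range") {
    x <- suppressWarnings(as.numeric(value))
    if (is.na(x)) {
      return(sprintf("attribute '%s': '%s' is not numeric", attr, value))
    }
    if (x < dom$min || x > dom$max) {
      return(sprintf("attribute '%s': value %s outside range [%s,%s]",
                     attr, value, fmt_num(dom$min), fmt_num(dom$max)))
    }
    return(NULL)
  }
  if (!as.character(value) %in% dom$levels) {
    return(sprintf("attribute '%s': '%s' not among allowed values {%s}",
                   attr, value, paste(dom$levels, collapse = ", ")))
  }
  NULL
}

#' TRT category labels
#'
#' The five TRT treatment-protocol categories in fixed order: C0 (tinnitus a
#' minimal problem), C1 (significant tinnitus), C2 (tinnitus with significant
#' hearing loss), C3 (hyperacusis-dominant) and C4 (prolonged exacerbation).
#'
#' @return Character vector `c("C0","C1","C2","C3","C4")`.
#' @export
trt_categories <- function() c("C0", "C1", "C2", "C3", "C4")

# Render a number the way rule text does: no scientific notation, no
# trailing zeros ("0.5", "3000", "66.667").
fmt_num <- function(x) {
  vapply(x, function(xi) format(xi, scientific = FALSE, trim = TRUE, drop0trailing = TRUE),
         character(1))
}
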