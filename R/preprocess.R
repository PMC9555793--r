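#' Score the Tinnitus Handicap Inventory
#'
#' Standard THI arithmetic over the 25 categorical items: "yes" scores 4,
#' "sometimes" 2 and "no" 0, for a total of 0-100. Items may be missing; the
#' total then sums the answered items only and is flagged incomplete.
#'
#' @param item_responses Character vector of exactly 25 responses, each one
#'   of `"yes"`, `"sometimes"`, `"no"` or `NA`.
#' @return A list with `total` (0-100) and `complete` (logical).
#' @export
#' @examples
#' score_thi(rep("no", 25))$total        # 0
#' score_thi(rep("yes", 25))$total       # 100
score_thi <- function(item_responses) {
  if (length(item_responses) != 25) {
    stop("THI has 25 items; got ", length(item_responses))
  }
  weights <- c(yes = 4, sometimes = 2, no = 0)
  known <- is.na(item_responses) | item_responses %in% names(weights)
  if (!all(known)) {
    stop("unknown THI response token(s): ",
         paste(unique(item_responses[!known]), collapse = ", "))
  }
  answered <- !is.na(item_responses)
  list(total = sum(weights[item_responses[answered]]),
       complete = all(answered))
}

#' Change metrics between consecutive visits
#'
#' The treatment-progress metrics: `ch` is previous minus current score, so a
#' positive value is a clinical improvement (the THI decreases when the
#' patient improves), and `per_ch` is `ch` as a percent of the previous
#' score. The THI total score is the primary source; when it is missing at
#' either visit the 0-10 tinnitus awareness score is used instead.
#'
#' @param prev_total,curr_total THI totals at the previous/current visit
#'   (0-100 or `NA`).
#' @param prev_taw,curr_taw Tinnitus awareness at the previous/current visit
#'   (0-10 or `NA`).
#' @return A list of class `trt_change`: `ch`, `per_ch` (`NA` with
#'   `per_ch_defined = FALSE` when the previous score is 0), `source`
#'   (`"THI"` or `"Taw"`).
#' @export
#' @examples
#' change_metrics(50, 30)                 # ch 20, per_ch 40, source THI
#' change_metrics(NA, NA, 8, 4)           # falls back to awareness
change_metrics <- function(prev_total, curr_total, prev_taw = NA, curr_taw = NA) {
  if (!is.na(prev_total) && !is.na(curr_total)) {
    prev <- prev_total; curr <- curr_total; source <- "THI"
  } else if (!is.na(prev_taw) && !is.na(curr_taw)) {
    prev <- prev_taw; curr <- curr_taw; source <- "Taw"
  } else {
    stop("no complete score pair: need both previous and current THI totals, ",
         "or both previous and current awareness scores")
  }
  ch <- prev - curr
  if (prev > 0) {
    per_ch <- 100 * ch / prev
    defined <- TRUE
  } else {
    per_ch <- NA_real_
    defined <- FALSE
  }
  structure(list(ch = ch, per_ch = per_ch, per_ch_defined = defined, source = source),
            class = "trt_change")
}

#' Label a visit-to-visit outcome
#'
#' @param metrics A `trt_change` from [change_metrics()], or a bare numeric
#'   `ch` value.
#' @param threshold Score points required to call a change "better"/"worse";
#'   defaults to 1 (any decrease in THI counts as improvement).
#' @return `"better"`, `"same"` or `"worse"`.
#' @export
label_outcome <- function(metrics, threshold = 1) {
  stopifnot(threshold > 0)
  ch <- if (inherits(metrics, "trt_change")) metrics$ch else metrics
  if (is.na(ch)) stop("change metric undefined")
  if (ch >= threshold) "better" else if (ch <= -threshold) "worse" else "same"
}

#' Impute missing THI totals along a visit sequence
#'
#' Interior gaps are filled by linear interpolation between the nearest
#' observed visits (on the visit-ordinal axis); leading/trailing gaps take
#' the nearest observed value. Observed values are never altered and every
#' imputed cell is flagged, so downstream analyses can drop or weight them.
#'
#' @param totals Numeric vector of THI totals with `NA` gaps, ordered by
#'   visit.
#' @param visit_no Optional visit ordinals (defaults to `seq_along(totals)`).
#' @return List with `totals` (completed) and `imputed` (logical flags).
#' @export
impute_total_score <- function(totals, visit_no = seq_along(totals)) {
  stopifnot(length(totals) == length(visit_no))
  obs <- !is.na(totals)
  if (!any(obs)) stop("cannot impute an all-missing score sequence")
  if (all(obs)) return(list(totals = totals, imputed = rep(FALSE, length(totals))))
  filled <- totals
  if (sum(obs) == 1) {
    filled[!obs] <- totals[obs]
  } else {
    filled[!obs] <- stats::approx(visit_no[obs], totals[obs], xout = visit_no[!obs],
                                  method = "linear", rule = 2)$y
  }
  list(totals = filled, imputed = !obs)
}

#' Extract tinnitus background flags from an etiology description
#'
#' Maps a free-text etiology field (plus optional structured hints) to the
#' binary background flags used throughout the rule base: STI
#' (stress-induced), NTI (noise-induced), HLTI (hearing-loss-induced), DETI
#' (depression-related), AATI (auto-accident-related), OTI (surgery-related)
#' and OMTI (other medical condition). Several flags may co-occur; absent
#' evidence yields 0.
#'
#' @param etiology Free-text etiology description (may be `NA` or empty).
#' @param t_side Logical/binary: is tinnitus a medication side effect?
#' @return Named integer vector of 0/1 flags including `T_side`.
#' @export
#' @examples
#' extract_background_flags("noise exposure")["NTI"]   # 1
extract_background_flags <- function(etiology, t_side = FALSE) {
  flags <- c(STI = 0L, NTI = 0L, HLTI = 0L, DETI = 0L, AATI = 0L, OTI = 0L,
             OMTI = 0L, T_side = 0L)
  if (isTRUE(t_side) || identical(norm_binary(t_side), "yes")) flags["T_side"] <- 1L
  if (is.na(etiology) || !nzchar(trimws(etiology))) return(flags)
  e <- tolower(etiology)
  if (grepl("stress|anxiet", e)) flags["STI"] <- 1L
  if (grepl("noise|acoustic trauma|loud", e)) flags["NTI"] <- 1L
  if (grepl("hearing loss|presbycusis", e)) flags["HLTI"] <- 1L
  if (grepl("depress", e)) flags["DETI"] <- 1L
  if (grepl("car accident|auto accident|whiplash|car crash", e)) flags["AATI"] <- 1L
  if (grepl("surgery|operation|ear surgery", e)) flags["OTI"] <- 1L
  if (grepl("medical|infection|meniere|otosclerosis|hypertension|diabetes", e)) {
    flags["OMTI"] <- 1L
  }
  flags
}

#' Equal-width discretization with half-open interval labels
#'
#' Bins a numeric value into equidistant half-open intervals `[a;b)` anchored
#' at `origin` and renders the label exactly as `"<a;b)"`; a value equal to a
#' boundary belongs to the next (upper) bin. [parse_interval()] inverts the
#' rendering, so bins and labels are in bijection.
#'
#' @param value Numeric value(s) to bin.
#' @param origin Left edge of the bin grid.
#' @param width Bin width (> 0).
#' @param range Optional length-2 numeric: values outside it are an error.
#' @return Character label(s) of the form `"<a;b)"`.
#' @export
#' @examples
#' discretize(17, 0, 5)   # "<15;20)"
#' discretize(20, 0, 5)   # "<20;25)" (half-open boundary)
discretize <- function(value, origin = 0, width, range = NULL) {
  stopifnot(is.numeric(value), width > 0)
  if (!is.null(range)) {
    out <- !is.na(value) & (value < range[1] | value > range[2])
    if (any(out)) {
      stop("value ", fmt_num(value[out][1]), " outside configured range [",
           fmt_num(range[1]), ",", fmt_num(range[2]), "]")
    }
  }
  k <- floor((value - origin) / width)
  a <- origin + k * width
  b <- a + width
  ifelse(is.na(value), NA_character_, render_interval(a, b))
}

render_interval <- function(a, b) paste0("<", fmt_num(a), ";", fmt_num(b), ")")

#' @rdname discretize
#' @param label An interval label `"<a;b)"`.
#' @return `parse_interval()` returns `c(a, b)`.
#' @export
parse_interval <- function(label) {
  m <- regmatches(label, regexec("^<\\s*(-?[0-9.]+)\\s*;\\s*(-?[0-9.]+)\\s*\\)$", label))[[1]]
  if (length(m) != 3) stop("malformed interval label: '", label, "'")
  out <- as.numeric(m[2:3])
  if (!out[1] < out[2]) stop("empty interval: '", label, "'")
  out
}

is_interval_label <- function(x) {
  grepl("^<\\s*-?[0-9.]+\\s*;\\s*-?[0-9.]+\\s*\\)$", x)
}

#' Chi-square feature ranking
#'
#' Ranks attributes by the raw chi-square statistic of the attribute-by-class
#' contingency table (no continuity correction, no p-value), the standard
#' filter-style ranking for categorical features. All-zero rows/columns are
#' dropped before the statistic is computed; a degenerate table (fewer than
#' two attribute levels or class levels co-occurring) scores 0.
#'
#' @param table Data frame of categorical/discretized attributes.
#' @param class_attr Name of the (categorical) class column.
#' @return Data frame of class `trt_feature_ranking` with columns
#'   `attribute`, `chi_square`, sorted by decreasing statistic, ties broken
#'   by attribute name.
#' @export
chi2_rank <- function(table, class_attr) {
  if (!class_attr %in% names(table)) stop("unknown class attribute: ", class_attr)
  cls <- as.character(table[[class_attr]])
  if (length(unique(cls[!is.na(cls)])) < 2) {
    stop("class attribute is constant; ranking undefined")
  }
  attrs <- setdiff(names(table), class_attr)
  score <- vapply(attrs, function(a) chi2_stat(table[[a]], cls), numeric(1))
  out <- data.frame(attribute = attrs, chi_square = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$chi_square, out$attribute), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trt_feature_ranking", "data.frame")
  out
}

chi2_stat <- function(x, cls) {
  keep <- !is.na(x) & !is.na(cls)
  tab <- table(as.character(x[keep]), cls[keep])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
  unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic)
}

#' Build a mining-ready feature table from a cohort
#'
#' Flattens the patient table into discretized/categorical attributes:
#' numeric audiometry is binned with width-5 dB intervals, 0-10 Likert
#' scores with width-0.5 intervals and age with width-10 bins by default;
#' per-attribute widths can be overridden. Binary flags and categorical
#' columns pass through. The LDL no-response sentinel 999 is kept as its own
#' level `"999"` rather than binned.
#'
#' @param cohort A `trt_cohort`.
#' @param class Optional vector of class labels (e.g. latent categories),
#'   added as column `Cat`.
#' @param widths Named numeric vector of per-attribute bin width overrides.
#' @param origins Named numeric vector of per-attribute bin origin overrides
#'   (default origin 0).
#' @param vocab Attribute vocabulary.
#' @return A data frame of character columns, one row per patient.
#' @export
feature_table <- function(cohort, class = NULL, widths = NULL, origins = NULL,
                          vocab = trt_vocabulary()) {
  pat <- cohort$patients
  out <- data.frame(row.names = seq_len(nrow(pat)))
  for (col in setdiff(names(pat), c("patient_id", "state"))) {
    if (!vocab_has(col, vocab)) next
    dt <- vocab_dtype(col, vocab)
    x <- pat[[col]]
    if (dt %in% c("binary", "categorical")) {
      out[[col]] <- as.character(x)
    } else if (dt %in% c("numeric", "ordinal_0_10")) {
      w <- if (!is.null(widths) && col %in% names(widths)) widths[[col]]
           else if (dt == "ordinal_0_10") 0.5
           else if (col == "age") 10
           else 5
      o <- if (!is.null(origins) && col %in% names(origins)) origins[[col]] else 0
      lab <- ifelse(!is.na(x) & x == 999, "999", discretize(x, o, w))
      out[[col]] <- lab
    }
  }
  if (!is.null(class)) {
    stopifnot(length(class) == nrow(pat))
    out$Cat <- as.character(class)
  }
  out
}
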