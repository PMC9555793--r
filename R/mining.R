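#' Mining thresholds
#'
#' @param min_support Minimum relative support as a fraction of objects in
#'   (0, 1]; converted to an absolute count by ceiling. Stored rule support
#'   stays an absolute count. Default 0.01 (1%).
#' @param min_confidence Minimum confidence in percent, default 80.
#' @param max_antecedent_length Maximum number of cedents in an antecedent
#'   (for action rules: in the stable context).
#' @return List of class `trt_thresholds`.
#' @export
mining_thresholds <- function(min_support = 0.01, min_confidence = 80,
                              max_antecedent_length = 3) {
  stopifnot(min_support > 0, min_support <= 1,
            min_confidence > 0, min_confidence <= 100,
            max_antecedent_length >= 1)
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 max_antecedent_length = max_antecedent_length),
            class = "trt_thresholds")
}

#' Mine decision rules from a discretized attribute table
#'
#' Level-wise (Apriori-style) enumeration of conjunctions of
#' attribute-equals-value cedents, with support-based pruning: an antecedent
#' qualifies when its support (rows matched) reaches
#' `ceiling(min_support * N)`, and a rule is emitted when its confidence for
#' some category value reaches `min_confidence`. The result is exactly the
#' set an exhaustive enumeration over all conjunctions up to
#' `max_antecedent_length` would produce, sorted by confidence (desc),
#' support (desc), then canonical antecedent text.
#'
#' @param table Data frame of categorical/discretized columns.
#' @param target_attr Name of the categorical target column.
#' @param thresholds A [mining_thresholds()].
#' @param vocab Attribute vocabulary (used to type emitted cedents).
#' @return List of `trt_decision_rule`s.
#' @export
mine_decision_rules <- function(table, target_attr = "Cat",
                                thresholds = mining_thresholds(),
                                vocab = trt_vocabulary()) {
  if (!nrow(table)) stop("empty table")
  if (!target_attr %in% names(table)) stop("unknown target attribute: ", target_attr)
  cls <- as.character(table[[target_attr]])
  cls_levels <- sort(unique(cls[!is.na(cls)]))
  if (length(cls_levels) < 2) stop("target attribute is constant; nothing to mine")
  n <- nrow(table)
  minsup <- ceiling(thresholds$min_support * n)

  attrs <- setdiff(names(table), target_attr)
  items <- list()   # each: list(attr, value, match = logical vector)
  for (a in attrs) {
    vals <- as.character(table[[a]])
    for (v in sort(unique(vals[!is.na(vals)]))) {
      m <- !is.na(vals) & vals == v
      if (sum(m) >= minsup) items[[length(items) + 1]] <- list(attr = a, value = v, match = m)
    }
  }
  if (!length(items)) return(list())
  item_attr <- vapply(items, `[[`, character(1), "attr")

  rules <- list()
  emit <- function(idx, match) {
    support <- sum(match)
    for (cv in cls_levels) {
      joint <- sum(match & !is.na(cls) & cls == cv)
      conf <- 100 * joint / support
      if (conf >= thresholds$min_confidence) {
        ceds <- lapply(idx, function(i) item_cedent(items[[i]], vocab))
        rules[[length(rules) + 1]] <<- decision_rule(ceds, cv, conf, support)
      }
    }
  }

  # level 1
  frontier <- lapply(seq_along(items), function(i) list(idx = i, match = items[[i]]$match))
  for (nd in frontier) emit(nd$idx, nd$match)
  k <- 1
  while (k < thresholds$max_antecedent_length && length(frontier) > 1) {
    nxt <- list()
    keys <- vapply(frontier, function(nd) paste(nd$idx, collapse = ","), character(1))
    freq_keys <- new.env(parent = emptyenv())
    for (key in keys) assign(key, TRUE, envir = freq_keys)
    for (i in seq_len(length(frontier) - 1)) {
      for (j in seq((i + 1), length(frontier))) {
        a <- frontier[[i]]$idx; b <- frontier[[j]]$idx
        # apriori join: share the first k-1 items
        if (k > 1 && !identical(a[-k], b[-k])) next
        cand <- sort(unique(c(a, b)))
        if (length(cand) != k + 1) next
        if (anyDuplicated(item_attr[cand])) next   # one value per attribute
        # all k-subsets frequent
        ok <- all(vapply(seq_along(cand), function(d) {
          exists(paste(cand[-d], collapse = ","), envir = freq_keys)
        }, logical(1)))
        if (!ok) next
        m <- frontier[[i]]$match & items[[setdiff(cand, frontier[[i]]$idx)]]$match
        if (sum(m) >= minsup) nxt[[length(nxt) + 1]] <- list(idx = cand, match = m)
      }
    }
    # dedupe candidates generated from different joins
    if (length(nxt)) {
      keys <- vapply(nxt, function(nd) paste(nd$idx, collapse = ","), character(1))
      nxt <- nxt[!duplicated(keys)]
      for (nd in nxt) emit(nd$idx, nd$match)
    }
    frontier <- nxt
    k <- k + 1
  }
  sort_rules(rules)
}

item_cedent <- function(item, vocab) {
  v <- item$value
  if (vocab_has(item$attr, vocab) &&
      vocab_dtype(item$attr, vocab) %in% c("numeric", "ordinal_0_10") &&
      is_interval_label(v)) {
    ab <- parse_interval(v)
    cedent(item$attr, "interval", ab[1], ab[2])
  } else {
    cedent(item$attr, "eq", v)
  }
}

sort_rules <- function(rules) {
  if (!length(rules)) return(rules)
  conf <- vapply(rules, `[[`, numeric(1), "confidence")
  sup <- vapply(rules, function(r) {
    s <- r$support
    if (is.na(s)) -Inf else as.numeric(s)
  }, numeric(1))
  canon <- vapply(rules, canonical_rule, character(1))
  rules[order(-conf, -sup, canon, method = "radix")]
}

#' Mine treatment action rules from a visit-pair table
#'
#' The input has one row per consecutive visit pair: stable context columns,
#' one `<attr>_before` / `<attr>_after` column pair per flexible attribute,
#' an outcome label column and a percent-change column. For every stable
#' context omega (a conjunction of stable attribute values, up to
#' `max_antecedent_length` of them, empty allowed), every non-empty set of
#' flexible attributes (up to `max_flexible`) and every realized pair of
#' from/to value assignments with `from != to` per attribute, the two
#' classification rules are evaluated:
#'
#' * after-rule `(omega & after == to) => better`: support and confidence
#'   over pairs matching omega whose after-state equals the to-values; must
#'   meet both thresholds. Its confidence is the rule's composite
#'   confidence.
#' * before-rule `(omega & before == from) => not better`: support over
#'   pairs matching omega whose before-state equals the from-values (must
#'   meet the support threshold); its confidence is computed over the subset
#'   of those pairs that *stayed* in the from-state (the counterfactual) and
#'   must meet the confidence threshold whenever that subset is non-empty
#'   (`NA` otherwise, e.g. under full compliance).
#'
#' Expected gain is the mean of the percent-change column over the
#' after-rule's supporting rows. Output is deduplicated and sorted by
#' composite confidence (desc) then gain (desc).
#'
#' @param pairs Visit-pair data frame.
#' @param stable_attrs Stable context column names.
#' @param flexible_attrs Flexible attribute base names (columns
#'   `<name>_before`, `<name>_after` must exist).
#' @param thresholds A [mining_thresholds()].
#' @param outcome_attr Outcome label column (default `"outcome"`).
#' @param positive Label counting as the desired effect (default
#'   `"better"`).
#' @param gain_attr Percent-change column (default `"per_ch"`).
#' @param max_flexible Maximum number of attributes changed together.
#' @param vocab Attribute vocabulary.
#' @return List of `trt_action_rule`s.
#' @export
mine_action_rules <- function(pairs, stable_attrs, flexible_attrs,
                              thresholds = mining_thresholds(),
                              outcome_attr = "outcome", positive = "better",
                              gain_attr = "per_ch", max_flexible = 1,
                              vocab = trt_vocabulary()) {
  if (!length(flexible_attrs)) stop("empty flexible attribute set")
  if (!nrow(pairs)) stop("no visit pairs")
  if (length(intersect(stable_attrs, flexible_attrs))) {
    stop("stable and flexible attribute sets must be disjoint")
  }
  need <- c(stable_attrs, paste0(flexible_attrs, "_before"),
            paste0(flexible_attrs, "_after"), outcome_attr)
  missing_cols <- setdiff(need, names(pairs))
  if (length(missing_cols)) stop("pair table lacks column(s): ",
                                 paste(missing_cols, collapse = ", "))
  n <- nrow(pairs)
  minsup <- ceiling(thresholds$min_support * n)
  out <- as.character(pairs[[outcome_attr]])
  is_pos <- !is.na(out) & out == positive
  gain_col <- if (gain_attr %in% names(pairs)) as.numeric(pairs[[gain_attr]]) else rep(NA_real_, n)

  # stable context candidates: realized value combos per attribute subset
  omega_list <- list(list(attrs = character(0), vals = character(0),
                          match = rep(TRUE, n)))
  max_stable <- min(thresholds$max_antecedent_length, length(stable_attrs))
  if (max_stable >= 1) {
    for (k in seq_len(max_stable)) {
      for (sub in combn_list(stable_attrs, k)) {
        combos <- unique(pairs[, sub, drop = FALSE])
        for (r in seq_len(nrow(combos))) {
          vals <- as.character(unlist(combos[r, , drop = TRUE]))
          if (anyNA(vals)) next
          m <- rep(TRUE, n)
          for (d in seq_along(sub)) {
            col <- as.character(pairs[[sub[d]]])
            m <- m & !is.na(col) & col == vals[d]
          }
          if (sum(m) >= minsup) {
            omega_list[[length(omega_list) + 1]] <-
              list(attrs = sub, vals = vals, match = m)
          }
        }
      }
    }
  }

  rules <- list()
  for (om in omega_list) {
    for (k in seq_len(min(max_flexible, length(flexible_attrs)))) {
      for (fsub in combn_list(flexible_attrs, k)) {
        before <- lapply(fsub, function(f) as.character(pairs[[paste0(f, "_before")]]))
        after <- lapply(fsub, function(f) as.character(pairs[[paste0(f, "_after")]]))
        from_combos <- unique_combos(before, om$match)
        to_combos <- unique_combos(after, om$match)
        for (fi in seq_len(nrow(from_combos))) {
          from <- as.character(unlist(from_combos[fi, , drop = TRUE]))
          m_before <- om$match
          for (d in seq_along(fsub)) {
            m_before <- m_before & !is.na(before[[d]]) & before[[d]] == from[d]
          }
          sup_b <- sum(m_before)
          if (sup_b < minsup) next
          m_stay <- m_before
          for (d in seq_along(fsub)) {
            m_stay <- m_stay & !is.na(after[[d]]) & after[[d]] == from[d]
          }
          conf_b <- if (sum(m_stay)) 100 * sum(m_stay & !is_pos) / sum(m_stay) else NA_real_
          if (!is.na(conf_b) && conf_b < thresholds$min_confidence) next
          for (ti in seq_len(nrow(to_combos))) {
            to <- as.character(unlist(to_combos[ti, , drop = TRUE]))
            if (any(to == from)) next   # every listed attribute must change
            m_after <- om$match
            for (d in seq_along(fsub)) {
              m_after <- m_after & !is.na(after[[d]]) & after[[d]] == to[d]
            }
            sup_a <- sum(m_after)
            if (sup_a < minsup) next
            conf_a <- 100 * sum(m_after & is_pos) / sup_a
            if (conf_a < thresholds$min_confidence) next
            gain <- if (all(is.na(gain_col[m_after]))) NA_real_
                    else mean(gain_col[m_after], na.rm = TRUE)
            stable_ceds <- mapply(function(a, v) {
              if (vocab_has(a, vocab) &&
                  vocab_dtype(a, vocab) %in% c("numeric", "ordinal_0_10") &&
                  is_interval_label(v)) {
                ab <- parse_interval(v)
                cedent(a, "interval", ab[1], ab[2])
              } else cedent(a, "eq", v)
            }, om$attrs, om$vals, SIMPLIFY = FALSE)
            flex_ceds <- mapply(function(a, f, t) cedent(a, "change", f, t),
                                fsub, from, to, SIMPLIFY = FALSE)
            rules[[length(rules) + 1]] <- action_rule(
              stable = stable_ceds, flexible = flex_ceds,
              confidence = conf_a, support = sup_a, gain = gain,
              before_support = sup_b, before_confidence = conf_b,
              after_support = sup_a, after_confidence = conf_a)
          }
        }
      }
    }
  }
  if (!length(rules)) return(rules)
  rules <- rules[!duplicated(vapply(rules, canonical_rule, character(1)))]
  conf <- vapply(rules, `[[`, numeric(1), "confidence")
  gain <- vapply(rules, function(r) if (is.na(r$gain)) -Inf else r$gain, numeric(1))
  canon <- vapply(rules, canonical_rule, character(1))
  rules[order(-conf, -gain, canon, method = "radix")]
}

combn_list <- function(x, k) {
  if (k > length(x)) return(list())
  utils::combn(x, k, simplify = FALSE)
}

unique_combos <- function(cols, mask) {
  df <- as.data.frame(lapply(cols, function(c) c[mask]), stringsAsFactors = FALSE,
                      col.names = paste0("v", seq_along(cols)))
  df <- unique(df)
  df[stats::complete.cases(df), , drop = FALSE]
}
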