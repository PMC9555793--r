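# Independent oracles and random-case generators used across the suite.
# These deliberately re-derive support/confidence/matching by direct counting
# and exhaustive enumeration, without touching the package's mining or
# matching internals.

# --- brute-force decision-rule miner --------------------------------------

bf_decision_key <- function(attrs, vals, category, sup, conf) {
  lhs <- paste(sort(paste0(attrs, "=", vals)), collapse = "&")
  paste0(lhs, "=>", category, "|", sup, "|", round(conf, 8))
}

bf_decision_rules <- function(table, target, min_support, min_confidence, max_len) {
  n <- nrow(table)
  minsup <- ceiling(min_support * n)
  attrs <- setdiff(names(table), target)
  cls <- as.character(table[[target]])
  cls_levels <- sort(unique(cls[!is.na(cls)]))
  keys <- character(0)
  for (k in seq_len(max_len)) {
    if (k > length(attrs)) break
    for (sub in utils::combn(attrs, k, simplify = FALSE)) {
      vals <- lapply(sub, function(a) {
        v <- as.character(table[[a]])
        sort(unique(v[!is.na(v)]))
      })
      grid <- expand.grid(vals, stringsAsFactors = FALSE)
      for (g in seq_len(nrow(grid))) {
        m <- rep(TRUE, n)
        for (d in seq_along(sub)) {
          col <- as.character(table[[sub[d]]])
          m <- m & !is.na(col) & col == grid[g, d]
        }
        sup <- sum(m)
        if (sup < minsup) next
        for (cv in cls_levels) {
          conf <- 100 * sum(m & !is.na(cls) & cls == cv) / sup
          if (conf >= min_confidence) {
            keys <- c(keys, bf_decision_key(sub, unlist(grid[g, ]), cv, sup, conf))
          }
        }
      }
    }
  }
  sort(keys)
}

# Key for a mined trt_decision_rule, in the same format as bf_decision_key.
mined_decision_key <- function(rule) {
  vals <- vapply(rule$cedents, function(ced) {
    if (ced$op == "interval") trtcds:::render_interval(ced$value, ced$value2)
    else as.character(ced$value)
  }, character(1))
  attrs <- vapply(rule$cedents, `[[`, character(1), "attr")
  bf_decision_key(attrs, vals, rule$category, rule$support, rule$confidence)
}

# --- brute-force action-rule miner ----------------------------------------

bf_action_key <- function(st_attrs, st_vals, f_attrs, from, to, sup, conf, gain) {
  om <- paste(sort(paste0(st_attrs, "=", st_vals)), collapse = "&")
  fl <- paste(sort(paste0(f_attrs, ":", from, "->", to)), collapse = "&")
  paste0(om, "|", fl, "|", sup, "|", round(conf, 8), "|",
         if (is.na(gain)) "NA" else round(gain, 8))
}

bf_action_rules <- function(pairs, stable_attrs, flexible_attrs,
                            min_support, min_confidence, max_stable,
                            max_flexible = 1, positive = "better") {
  n <- nrow(pairs)
  minsup <- ceiling(min_support * n)
  is_pos <- !is.na(pairs$outcome) & pairs$outcome == positive
  gain_col <- if ("per_ch" %in% names(pairs)) as.numeric(pairs$per_ch) else rep(NA_real_, n)
  keys <- character(0)

  omega_sets <- list(list(attrs = character(0), vals = character(0)))
  for (k in seq_len(min(max_stable, length(stable_attrs)))) {
    for (sub in utils::combn(stable_attrs, k, simplify = FALSE)) {
      vals <- lapply(sub, function(a) {
        v <- as.character(pairs[[a]]); sort(unique(v[!is.na(v)]))
      })
      grid <- expand.grid(vals, stringsAsFactors = FALSE)
      for (g in seq_len(nrow(grid))) {
        omega_sets[[length(omega_sets) + 1]] <-
          list(attrs = sub, vals = as.character(unlist(grid[g, ])))
      }
    }
  }
  for (om in omega_sets) {
    m_om <- rep(TRUE, n)
    for (d in seq_along(om$attrs)) {
      col <- as.character(pairs[[om$attrs[d]]])
      m_om <- m_om & !is.na(col) & col == om$vals[d]
    }
    for (k in seq_len(min(max_flexible, length(flexible_attrs)))) {
      for (fsub in utils::combn(flexible_attrs, k, simplify = FALSE)) {
        before <- lapply(fsub, function(f) as.character(pairs[[paste0(f, "_before")]]))
        after <- lapply(fsub, function(f) as.character(pairs[[paste0(f, "_after")]]))
        dom <- lapply(seq_along(fsub), function(d) {
          v <- c(before[[d]], after[[d]]); sort(unique(v[!is.na(v)]))
        })
        from_grid <- expand.grid(dom, stringsAsFactors = FALSE)
        to_grid <- from_grid
        for (fi in seq_len(nrow(from_grid))) {
          from <- as.character(unlist(from_grid[fi, ]))
          m_b <- m_om
          for (d in seq_along(fsub)) {
            m_b <- m_b & !is.na(before[[d]]) & before[[d]] == from[d]
          }
          if (sum(m_b) < minsup) next
          m_stay <- m_b
          for (d in seq_along(fsub)) {
            m_stay <- m_stay & !is.na(after[[d]]) & after[[d]] == from[d]
          }
          conf_b <- if (sum(m_stay)) 100 * sum(m_stay & !is_pos) / sum(m_stay) else NA_real_
          if (!is.na(conf_b) && conf_b < min_confidence) next
          for (ti in seq_len(nrow(to_grid))) {
            to <- as.character(unlist(to_grid[ti, ]))
            if (any(to == from)) next
            m_a <- m_om
            for (d in seq_along(fsub)) {
              m_a <- m_a & !is.na(after[[d]]) & after[[d]] == to[d]
            }
            sup_a <- sum(m_a)
            if (sup_a < minsup) next
            conf_a <- 100 * sum(m_a & is_pos) / sup_a
            if (conf_a < min_confidence) next
            gain <- if (all(is.na(gain_col[m_a]))) NA_real_
                    else mean(gain_col[m_a], na.rm = TRUE)
            keys <- c(keys, bf_action_key(om$attrs, om$vals, fsub, from, to,
                                          sup_a, conf_a, gain))
          }
        }
      }
    }
  }
  sort(unique(keys))
}

mined_action_key <- function(rule) {
  st_attrs <- vapply(rule$stable, `[[`, character(1), "attr")
  st_vals <- vapply(rule$stable, function(c) as.character(c$value), character(1))
  f_attrs <- vapply(rule$flexible, `[[`, character(1), "attr")
  from <- vapply(rule$flexible, function(c) as.character(c$value), character(1))
  to <- vapply(rule$flexible, function(c) as.character(c$value2), character(1))
  bf_action_key(st_attrs, st_vals, f_attrs, from, to,
                rule$support, rule$confidence, rule$gain)
}

# --- random generators -----------------------------------------------------

random_mining_table <- function(n_rows, n_attrs, n_vals = 3, n_classes = 3) {
  tab <- as.data.frame(
    lapply(seq_len(n_attrs), function(i) {
      sample(letters[seq_len(n_vals)], n_rows, replace = TRUE)
    }), col.names = paste0("X", seq_len(n_attrs)), stringsAsFactors = FALSE)
  tab$Cat <- sample(trt_categories()[seq_len(n_classes)], n_rows, replace = TRUE)
  tab
}

random_pair_table <- function(n_rows) {
  data.frame(
    S1 = sample(c("u", "v"), n_rows, replace = TRUE),
    S2 = sample(c("p", "q"), n_rows, replace = TRUE),
    F1_before = sample(c("a", "b", "c"), n_rows, replace = TRUE),
    F1_after = sample(c("a", "b", "c"), n_rows, replace = TRUE),
    per_ch = round(stats::rnorm(n_rows, 0, 20), 1),
    outcome = sample(c("better", "not-better"), n_rows, replace = TRUE),
    stringsAsFactors = FALSE)
}

# --- independent fact matcher (for the inference contract) ----------------

oracle_cedent_holds <- function(op, value, value2, fact) {
  if (is.null(fact) || is.na(fact)) return(FALSE)
  fn <- suppressWarnings(as.numeric(fact))
  switch(op,
    eq = as.character(fact) == as.character(value),
    ge = !is.na(fn) && fn >= value,
    le = !is.na(fn) && fn <= value,
    gt = !is.na(fn) && fn > value,
    lt = !is.na(fn) && fn < value,
    interval = !is.na(fn) && fn >= value && fn < value2,
    change = as.character(fact) == as.character(value))
}

oracle_rule_matches <- function(rule, facts) {
  ceds <- if (inherits(rule, "trt_decision_rule")) rule$cedents
          else c(rule$stable, rule$flexible)
  all(vapply(ceds, function(c) {
    oracle_cedent_holds(c$op, c$value, c$value2, facts[[c$attr]])
  }, logical(1)))
}

# Random KB + facts over real vocabulary attributes (numeric + categorical).
random_kb_and_facts <- function(n_rules = 15) {
  num_attrs <- c("R3", "L2", "R6", "LL3", "LR8", "T_An", "H_An", "age")
  cat_attrs <- list(G = c("m", "f"), Ins = c("GHH", "GHS", "SG", "HA"),
                    NTI = c("yes", "no"), E14 = c("yes", "no"))
  rand_cedent <- function() {
    if (stats::runif(1) < 0.6) {
      a <- sample(num_attrs, 1)
      v <- sample(0:100, 1)
      op <- sample(c("ge", "le", "gt", "lt", "interval"), 1)
      if (op == "interval") cedent(a, "interval", v, v + sample(5:20, 1))
      else cedent(a, op, v)
    } else {
      a <- sample(names(cat_attrs), 1)
      cedent(a, "eq", sample(cat_attrs[[a]], 1))
    }
  }
  kb <- kb_new()
  for (i in seq_len(n_rules)) {
    if (stats::runif(1) < 0.5) {
      r <- decision_rule(lapply(seq_len(sample(1:3, 1)), function(j) rand_cedent()),
                         sample(trt_categories(), 1),
                         sample(50:100, 1), sample(1:50, 1))
      kb$rules[[length(kb$rules) + 1]] <- trtcds:::encoded_rule(
        sprintf("d-%04d", i), "diagnosis", r, "x", "random")
    } else {
      fa <- sample(c("Ins", "FU"), 1)
      lv <- if (fa == "Ins") c("GHH", "GHS", "SG", "HA") else c("A", "C", "T", "E")
      ft <- sample(lv, 2)
      r <- action_rule(lapply(seq_len(sample(0:2, 1)), function(j) rand_cedent()),
                       list(cedent(fa, "change", ft[1], ft[2])),
                       sample(50:100, 1), gain = round(stats::runif(1, 1, 50), 1))
      kb$rules[[length(kb$rules) + 1]] <- trtcds:::encoded_rule(
        sprintf("t-%04d", i), "treatment", r, "x", "random")
    }
  }
  facts <- list()
  for (a in sample(num_attrs, sample(3:6, 1))) facts[[a]] <- sample(0:100, 1)
  for (a in sample(names(cat_attrs), sample(1:3, 1))) {
    facts[[a]] <- sample(cat_attrs[[a]], 1)
  }
  list(kb = kb, facts = as_facts(facts))
}

# --- random dialect rules (for parser round-trips) -------------------------

random_dialect_rule <- function(i) {
  num_attrs <- c("R3", "L2", "R6", "L4", "LL3", "LR8", "Mix_RSL", "treat", "age")
  rand_pred <- function() {
    a <- sample(num_attrs, 1)
    v <- sample(0:120, 1)
    switch(sample(5, 1),
           paste0(a, "(>=", v, ")"),
           paste0(a, "(<=", v, ")"),
           paste0(a, "(>", v, ")"),
           paste0(a, "(<", v, ")"),
           paste0(a, "(<", v, ";", v + sample(c(5, 10, 0.5), 1), "))"))
  }
  if (i %% 2 == 0) {
    n_ced <- sample(1:3, 1)
    ceds <- c(paste0("age(>=", i %% 90 + 1, ")"),
              if (n_ced > 1) replicate(n_ced - 1, rand_pred()))
    paste0(paste(ceds, collapse = " & "), " => Category(", sample(0:4, 1),
           ") | conf=", sample(1:100, 1))
  } else {
    stable <- if (stats::runif(1) < 0.8) paste0("G(", sample(c("m", "f"), 1), ") ") else ""
    ft <- sample(c("GHH", "GHS", "SG", "HA", "V"), 2)
    paste0(stable, ": (Ins(", ft[1], "->", ft[2], ") & treat(<", i, ";", i + 2,
           ")-><", i + 2, ";", i + 4, "))) => Ch(better) | conf=",
           sample(1:100, 1), " ; gain=", round(stats::runif(1, -10, 50), 1))
  }
}
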