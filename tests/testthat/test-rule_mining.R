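test_that("rule stats count support and confidence by the antecedent-matching definition", {
  set.seed(5)
  # construct a table where exactly 17 rows match the antecedent, 16 the class
  tab <- data.frame(A = c(rep("a", 17), rep("b", 13)),
                    Cat = c(rep("C1", 16), "C2", rep("C1", 13)),
                    stringsAsFactors = FALSE)
  r <- decision_rule(list(cedent("A", "eq", "a")), "C1", 50)
  s <- rule_stats(r, tab)
  expect_equal(s$support, 17)
  expect_equal(round(s$confidence, 1), 94.1)
  # full match -> 100%
  r2 <- decision_rule(list(cedent("A", "eq", "b")), "C1", 50)
  expect_equal(rule_stats(r2, tab)$confidence, 100)
  # empty antecedent match -> undefined confidence
  r3 <- decision_rule(list(cedent("A", "eq", "zzz")), "C1", 50)
  expect_error(rule_stats(r3, tab), "no rows")
})

test_that("a perfectly determining attribute yields its single-cedent rule at 100%", {
  tab <- data.frame(A = rep(c("a", "b"), 6),
                    B = sample(c("x", "y"), 12, replace = TRUE),
                    Cat = rep(c("C1", "C2"), 6), stringsAsFactors = FALSE)
  rules <- mine_decision_rules(tab, "Cat", mining_thresholds(0.05, 100, 1))
  keys <- vapply(rules, function(r) serialize_rule(r), character(1))
  expect_true("A(a) => Category(1) | conf=100 ; sup=6" %in% keys)
  expect_true("A(b) => Category(2) | conf=100 ; sup=6" %in% keys)
  expect_true(all(vapply(rules, `[[`, numeric(1), "confidence") == 100))
})

test_that("mined decision rules equal exhaustive enumeration on random tables", {
  set.seed(101)
  for (trial in 1:25) {
    tab <- random_mining_table(sample(20:50, 1), sample(2:6, 1),
                               n_vals = sample(2:3, 1))
    th <- mining_thresholds(stats::runif(1, 0.03, 0.1), sample(c(60, 80, 100), 1), 2)
    mined <- mine_decision_rules(tab, "Cat", th)
    expect_identical(sort(vapply(mined, mined_decision_key, character(1))),
                     bf_decision_rules(tab, "Cat", th$min_support,
                                       th$min_confidence, 2))
  }
})

test_that("label noise on every antecedent kills 100%-confidence rules", {
  set.seed(3)
  tab <- random_mining_table(40, 3, n_vals = 2, n_classes = 2)
  # guarantee noise: duplicate the table with flipped labels
  flipped <- tab
  flipped$Cat <- ifelse(tab$Cat == "C0", "C1", "C0")
  noisy <- rbind(tab, flipped)
  expect_identical(mine_decision_rules(noisy, "Cat", mining_thresholds(0.02, 100, 2)),
                   list())
})

test_that("support is anti-monotone and emitted stats re-verify exactly", {
  set.seed(17)
  for (trial in 1:10) {
    tab <- random_mining_table(40, 4)
    rules <- mine_decision_rules(tab, "Cat", mining_thresholds(0.05, 50, 3))
    for (r in rules) {
      s <- rule_stats(r, tab)
      expect_identical(s$support, r$support)
      expect_equal(s$confidence, r$confidence)
      if (length(r$cedents) > 1) {
        shorter <- decision_rule(r$cedents[-1], r$category, r$confidence)
        expect_lte(r$support, rule_stats(shorter, tab)$support)
      }
    }
  }
})

test_that("a uniformly improving mixing-point adjustment is mined at 100% confidence", {
  # every sound-generator pair that moves the mixing point from <11;12) to
  # <9;10) improves; pairs that keep it do not
  pairs <- data.frame(
    Ins = c(rep("SG", 30), rep("HA", 10)),
    Mix_RSL_before = c(rep("<11;12)", 30), rep("<11;12)", 10)),
    Mix_RSL_after = c(rep("<9;10)", 20), rep("<11;12)", 10), rep("<11;12)", 10)),
    per_ch = c(rep(42, 20), rep(-5, 10), rep(-2, 10)),
    outcome = c(rep("better", 20), rep("not-better", 20)),
    stringsAsFactors = FALSE)
  rules <- mine_action_rules(pairs, stable_attrs = "Ins", flexible_attrs = "Mix_RSL",
                             thresholds = mining_thresholds(0.05, 80, 1))
  keys <- vapply(rules, serialize_rule, character(1))
  expect_true(
    "Ins(SG) : (Mix_RSL(<11;12)-><9;10))) => Ch(better) | conf=100 ; sup=20 ; gain=42"
    %in% keys)
})

test_that("action mining returns nothing when flexible attributes never change", {
  pairs <- data.frame(S1 = rep(c("u", "v"), 10),
                      F1_before = rep("a", 20), F1_after = rep("a", 20),
                      per_ch = 0, outcome = rep("not-better", 20),
                      stringsAsFactors = FALSE)
  expect_identical(mine_action_rules(pairs, "S1", "F1",
                                     mining_thresholds(0.05, 50, 1)), list())
  expect_error(mine_action_rules(pairs, "S1", character(0)), "empty flexible")
  expect_error(mine_action_rules(pairs[0, ], "S1", "F1"), "no visit pairs")
})

test_that("mined action rules equal exhaustive enumeration on random pair tables", {
  set.seed(202)
  for (trial in 1:15) {
    pairs <- random_pair_table(sample(25:50, 1))
    th <- mining_thresholds(stats::runif(1, 0.04, 0.1), sample(c(40, 60, 80), 1), 2)
    mined <- mine_action_rules(pairs, c("S1", "S2"), "F1", th)
    expect_identical(sort(vapply(mined, mined_action_key, character(1))),
                     bf_action_rules(pairs, c("S1", "S2"), "F1",
                                     th$min_support, th$min_confidence, 2))
  }
})

test_that("every action rule decomposes into threshold-satisfying classification rules", {
  set.seed(9)
  pairs <- random_pair_table(60)
  th <- mining_thresholds(0.05, 50, 2)
  for (r in mine_action_rules(pairs, c("S1", "S2"), "F1", th)) {
    minsup <- ceiling(th$min_support * nrow(pairs))
    expect_gte(r$after_support, minsup)
    expect_gte(r$after_confidence, th$min_confidence)
    expect_gte(r$before_support, minsup)
    if (!is.na(r$before_confidence)) {
      expect_gte(r$before_confidence, th$min_confidence)
    }
    expect_equal(r$confidence, r$after_confidence)
  }
})

test_that("the Naive Bayes baseline reproduces hand-computed smoothed posteriors", {
  tab <- data.frame(F1 = c("a", "a", "a", "b", "b", "b", "b", "a"),
                    F2 = c("x", "x", "y", "x", "y", "y", "x", "y"),
                    Cat = c(rep("C1", 4), rep("C2", 4)), stringsAsFactors = FALSE)
  m <- fit_naive_bayes(tab, "Cat", smoothing = 1)
  p <- predict_category(m, list(F1 = "a", F2 = "x"))
  # priors 1/2; P(a|C1)=P(x|C1)=(3+1)/(4+2); P(a|C2)=P(x|C2)=(1+1)/(4+2)
  expect_equal(unname(p$posterior["C1"]), 0.8, tolerance = 1e-12)
  expect_equal(p$category, "C1")
  expect_equal(sum(p$posterior), 1)
})

test_that("Naive Bayes handles degenerate and uninformative inputs", {
  # single training class -> always that class, posterior 1
  m1 <- fit_naive_bayes(data.frame(F1 = c("a", "b"), Cat = "C2"), "Cat")
  expect_equal(predict_category(m1, list(F1 = "a")),
               list(category = "C2", posterior = c(C2 = 1), prior_only = FALSE))
  # symmetric attribute -> 0.5/0.5, tie broken by category order
  tab <- data.frame(F1 = c("a", "b", "a", "b"), Cat = c("C1", "C1", "C2", "C2"),
                    stringsAsFactors = FALSE)
  p <- predict_category(fit_naive_bayes(tab, "Cat"), list(F1 = "a"))
  expect_equal(unname(p$posterior), c(0.5, 0.5))
  expect_equal(p$category, "C1")
  # empty case -> argmax of priors, flagged
  tab2 <- data.frame(F1 = c("a", "a", "b"), Cat = c("C2", "C2", "C4"),
                     stringsAsFactors = FALSE)
  p2 <- predict_category(fit_naive_bayes(tab2, "Cat"), list())
  expect_true(p2$prior_only)
  expect_equal(p2$category, "C2")
  # unseen level is treated as missing, never a failure
  p3 <- predict_category(fit_naive_bayes(tab2, "Cat"), list(F1 = "unseen"))
  expect_true(p3$prior_only)
})
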