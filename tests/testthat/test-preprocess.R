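test_that("THI scoring matches direct summation and flags incompleteness", {
  expect_equal(score_thi(rep("no", 25)), list(total = 0, complete = TRUE))
  expect_equal(score_thi(rep("yes", 25)), list(total = 100, complete = TRUE))
  resp <- c(rep("yes", 10), rep("sometimes", 5), rep("no", 10))
  expect_equal(score_thi(resp)$total, 10 * 4 + 5 * 2)   # 50
  partial <- replace(resp, 3, NA)
  out <- score_thi(partial)
  expect_false(out$complete)
  expect_equal(out$total, 50 - 4)
  expect_error(score_thi(rep("no", 24)), "25 items")
  expect_error(score_thi(c(rep("no", 24), "maybe")), "unknown THI response")
})

test_that("THI scoring is monotone in item escalation", {
  set.seed(41)
  for (i in 1:25) {
    resp <- sample(c("no", "sometimes", "yes"), 25, replace = TRUE)
    base <- score_thi(resp)$total
    up <- resp
    j <- sample(which(up != "yes"), 1)
    up[j] <- if (up[j] == "no") "sometimes" else "yes"
    expect_gte(score_thi(up)$total, base)
  }
})

test_that("change metrics use previous-minus-current with awareness fallback", {
  m <- change_metrics(50, 50)
  expect_equal(m$ch, 0); expect_equal(m$per_ch, 0)
  m <- change_metrics(50, 30)
  expect_equal(m$ch, 20); expect_equal(m$per_ch, 40); expect_equal(m$source, "THI")
  # awareness fallback when a THI total is missing at either visit
  m <- change_metrics(NA, NA, prev_taw = 8, curr_taw = 4)
  expect_equal(m$ch, 4); expect_equal(m$source, "Taw")
  # per_ch undefined for a zero previous score
  m <- change_metrics(0, 0)
  expect_false(m$per_ch_defined); expect_true(is.na(m$per_ch))
  expect_error(change_metrics(50, NA, 8, NA), "no complete score pair")
})

test_that("outcome labelling splits better/same/worse at the threshold", {
  expect_equal(label_outcome(20, 1), "better")
  expect_equal(label_outcome(0, 1), "same")
  expect_equal(label_outcome(-5, 1), "worse")
  expect_equal(label_outcome(change_metrics(50, 46), threshold = 5), "same")
})

test_that("imputation interpolates interior gaps and carries edges, idempotently", {
  expect_equal(impute_total_score(c(40, NA, 20)),
               list(totals = c(40, 30, 20), imputed = c(FALSE, TRUE, FALSE)))
  expect_equal(impute_total_score(c(NA, 60, 80))$totals, c(60, 60, 80))
  # observed values never altered; no missing -> identity
  x <- c(10, 20, 30)
  expect_equal(impute_total_score(x), list(totals = x, imputed = rep(FALSE, 3)))
  # idempotent
  once <- impute_total_score(c(80, NA, NA, 20, NA))
  expect_equal(impute_total_score(once$totals)$totals, once$totals)
  # ordinal spacing respected
  expect_equal(impute_total_score(c(40, NA, 20), visit_no = c(0, 3, 4))$totals[2],
               40 + (20 - 40) * 3 / 4)
  expect_error(impute_total_score(c(NA, NA)), "all-missing")
})

test_that("background flags map etiologies to binary indicators", {
  f <- extract_background_flags("noise exposure")
  expect_equal(unname(f["NTI"]), 1L); expect_equal(sum(f), 1L)
  f <- extract_background_flags("stress-related")
  expect_equal(unname(f["STI"]), 1L)
  expect_equal(sum(extract_background_flags("")), 0L)
  expect_equal(sum(extract_background_flags(NA)), 0L)
  f <- extract_background_flags("noise exposure after ear surgery", t_side = TRUE)
  expect_equal(unname(f[c("NTI", "OTI", "T_side")]), c(1L, 1L, 1L))
})

test_that("discretization renders half-open equal-width bins", {
  expect_equal(discretize(17, 0, 5), "<15;20)")
  expect_equal(discretize(20, 0, 5), "<20;25)")   # boundary joins the upper bin
  expect_equal(discretize(0.5, 0, 0.5), "<0.5;1)")
  expect_equal(discretize(7, 6, 2), "<6;8)")
  expect_error(discretize(-1, 0, 5, range = c(0, 120)), "outside configured range")
})

test_that("interval rendering and parsing are mutually inverse on printed labels", {
  labels <- c("<15;20)", "<0;0.5)", "<6;8)", "<0;2.5)", "<1.5;3.5)", "<85;91)",
              "<11;12)", "<9;10)", "<3000;3150)", "<5;6)", "<2800;3000)",
              "<2670;2800)", "<22;52)", "<9;14)")
  for (lab in labels) {
    ab <- parse_interval(lab)
    expect_identical(trtcds:::render_interval(ab[1], ab[2]), lab)
    # the midpoint discretizes back into the same bin
    mid <- (ab[1] + ab[2]) / 2
    expect_identical(discretize(mid, origin = ab[1], width = ab[2] - ab[1]), lab)
  }
  expect_error(parse_interval("<15;20"), "malformed")
  expect_error(parse_interval("<20;15)"), "empty interval|malformed")
})

test_that("chi-square ranking reproduces the closed-form statistic and ordering", {
  # [[10,0],[0,10]]: all expected counts are 5, statistic = 4 * (5^2/5) = 20
  tab <- data.frame(A = rep(c("a", "b"), each = 10),
                    Cat = rep(c("C1", "C2"), each = 10),
                    stringsAsFactors = FALSE)
  expect_equal(chi2_rank(tab, "Cat")$chi_square, 20)
  # constant attribute carries no association
  tab$B <- "z"
  rk <- chi2_rank(tab, "Cat")
  expect_equal(rk$chi_square[rk$attribute == "B"], 0)
  # planted class-linked attribute outranks independent noise
  set.seed(7)
  n <- 200
  cls <- sample(c("C1", "C2"), n, replace = TRUE)
  tab2 <- data.frame(linked = cls, noise = sample(c("a", "b"), n, replace = TRUE),
                     Cat = cls, stringsAsFactors = FALSE)
  rk2 <- chi2_rank(tab2, "Cat")
  expect_equal(rk2$attribute[1], "linked")
  expect_gt(rk2$chi_square[1], rk2$chi_square[2])
  expect_error(chi2_rank(data.frame(A = c("a", "b"), Cat = "C1"), "Cat"), "constant")
})

test_that("chi-square ranking is invariant under row permutation", {
  set.seed(11)
  tab <- random_mining_table(60, 4)
  perm <- sample(nrow(tab))
  expect_equal(chi2_rank(tab, "Cat"), chi2_rank(tab[perm, ], "Cat"))
})
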