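#' Specification for a synthetic TRT cohort
#'
#' Describes the statistical structure the mining pipeline assumes:
#' a mixture over the five TRT categories, per-category signatures
#' (age, etiology-flag probabilities, audiometric threshold/LDL levels,
#' interview-score levels), planted decision rules (a cedent conjunction
#' whose satisfiers carry the target category at a target confidence) and
#' planted treatment effects (a stable context plus a flexible change whose
#' takers improve at a target rate). All randomness is fixed by `seed`.
#'
#' The defaults mirror the scale of a multi-year clinic registry
#' (~555 patients, 3-8 visits each, ~3,000 visits) with the classical
#' category signatures: C2 patients are elderly with elevated pure-tone
#' thresholds (hearing loss), C3 patients are young (30-38) with depressed
#' loudness discomfort levels (hyperacusis) and noise/stress backgrounds,
#' C1 patients are middle-aged with high tinnitus scores and
#' depression-related background. Distributional parameters are package
#' choices, documented in the methods vignette; none are estimates from
#' clinical data.
#'
#' @param n_patients Number of patients.
#' @param visit_range Integer range of visits per patient.
#' @param mixture Named probabilities over C0..C4 (normalised to sum 1).
#' @param planted_rules List of planted decision rules; each a list with
#'   `cedents` (list of [cedent()]s), `category`, `confidence` (percent) and
#'   `exposure` (probability a target-category patient satisfies the
#'   cedents).
#' @param planted_actions List of planted treatment effects; each a list
#'   with `stable` (named list of required stable values), `attr`, `from`,
#'   `to`, `rate` (percent improving when the action is taken), `gain_mean`,
#'   `gain_sd` (percent-change distribution of the improvement) and
#'   `compliance` (probability an eligible pair takes the action).
#' @param noise_mean,noise_sd Percent-change distribution between visits
#'   when no planted action applies (slightly negative drift: untreated
#'   scores rarely improve).
#' @param ldl_sentinel_prob Probability an LDL measurement is the
#'   no-response sentinel 999.
#' @param outcome_threshold Score points defining "better" (see
#'   [label_outcome()]).
#' @param seed Integer seed fixing all randomness.
#' @return A validated list of class `trt_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 555,
                        visit_range = c(3L, 8L),
                        mixture = c(C0 = 0.12, C1 = 0.30, C2 = 0.28,
                                    C3 = 0.18, C4 = 0.12),
                        planted_rules = default_planted_rules(),
                        planted_actions = default_planted_actions(),
                        noise_mean = -8, noise_sd = 8,
                        ldl_sentinel_prob = 0.01,
                        outcome_threshold = 1,
                        seed = 1L) {
  stopifnot(n_patients >= 1, length(visit_range) == 2, visit_range[1] >= 1,
            visit_range[2] >= visit_range[1])
  if (!all(trt_categories() %in% names(mixture))) {
    stop("mixture must name all five categories C0..C4")
  }
  mixture <- mixture[trt_categories()]
  if (any(mixture < 0) || sum(mixture) <= 0) stop("invalid category mixture")
  mixture <- mixture / sum(mixture)
  for (pr in planted_rules) {
    if (is.na(pr$confidence) || pr$confidence <= 0 || pr$confidence > 100) {
      stop("planted rule confidence must lie in (0,100]")
    }
    attrs <- vapply(pr$cedents, `[[`, character(1), "attr")
    if (anyDuplicated(attrs)) stop("infeasible planted rule: repeated cedent attribute")
  }
  if (length(planted_rules) > 1) {
    all_attrs <- unlist(lapply(planted_rules, function(pr)
      vapply(pr$cedents, `[[`, character(1), "attr")))
    if (anyDuplicated(all_attrs)) {
      stop("infeasible spec: planted rules share cedent attributes")
    }
  }
  for (pa in planted_actions) {
    if (pa$rate <= 0 || pa$rate > 100) stop("planted action rate must lie in (0,100]")
    if (pa$compliance < 0 || pa$compliance > 1) stop("compliance must lie in [0,1]")
  }
  structure(list(n_patients = as.integer(n_patients),
                 visit_range = as.integer(visit_range), mixture = mixture,
                 planted_rules = planted_rules, planted_actions = planted_actions,
                 noise_mean = noise_mean, noise_sd = noise_sd,
                 ldl_sentinel_prob = ldl_sentinel_prob,
                 outcome_threshold = outcome_threshold,
                 seed = as.integer(seed)),
            class = "trt_cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_planted_rules <- function() {
  list(list(cedents = list(cedent("L2", "ge", 50), cedent("R6", "le", 75)),
            category = "C2", confidence = 87, exposure = 0.8))
}

#' @rdname cohort_spec
#' @export
default_planted_actions <- function() {
  list(list(stable = list(G = "m", NTI = "yes"),
            attr = "Ins", from = "GHH", to = "GHS",
            rate = 80, gain_mean = 40, gain_sd = 12, compliance = 0.9))
}

cat_params <- list(
  C0 = list(age = c(45, 12), thr = c(18, 8), ldl = c(98, 8),
            t_pr = c(2, 1.5), h_pr = c(1, 1), hl_pr = c(1, 1), thi = c(18, 10),
            flags = c(STI = .10, NTI = .10, HLTI = .05, DETI = .05, AATI = .05,
                      OTI = .05, OMTI = .05)),
  C1 = list(age = c(50, 8), thr = c(22, 9), ldl = c(95, 9),
            t_pr = c(8, 1.2), h_pr = c(1, 1), hl_pr = c(1.5, 1), thi = c(55, 14),
            flags = c(STI = .30, NTI = .20, HLTI = .05, DETI = .40, AATI = .05,
                      OTI = .05, OMTI = .10)),
  C2 = list(age = c(70, 8), thr = c(55, 12), ldl = c(92, 10),
            t_pr = c(6, 1.5), h_pr = c(1.5, 1), hl_pr = c(8, 1.2), thi = c(50, 15),
            flags = c(STI = .05, NTI = .15, HLTI = .70, DETI = .10, AATI = .05,
                      OTI = .05, OMTI = .25)),
  C3 = list(age = c(34, 3), thr = c(20, 8), ldl = c(68, 8),
            t_pr = c(1.5, 1), h_pr = c(8, 1), hl_pr = c(1, 1), thi = c(45, 15),
            flags = c(STI = .35, NTI = .45, HLTI = .05, DETI = .10, AATI = .05,
                      OTI = .10, OMTI = .05)),
  C4 = list(age = c(45, 10), thr = c(30, 12), ldl = c(72, 10),
            t_pr = c(8, 1.2), h_pr = c(7, 1.5), hl_pr = c(2, 1.5), thi = c(68, 12),
            flags = c(STI = .25, NTI = .30, HLTI = .10, DETI = .20, AATI = .10,
                      OTI = .10, OMTI = .10))
)

rnorm_clamped <- function(n, mean, sd, lo, hi, round_to = 1) {
  x <- stats::rnorm(n, mean, sd)
  x <- pmin(pmax(x, lo), hi)
  round(x / round_to) * round_to
}

#' Generate a synthetic cohort
#'
#' Deterministic given the spec (including its seed): each patient draws a
#' latent category from the mixture, then demographics, background flags,
#' audiometry (pure-tone thresholds and LDLs per ear and frequency, with a
#' small no-response 999 sentinel rate on LDLs) and interview scores from
#' that category's signature. Planted decision rules are imposed by
#' construction: a patient satisfies the planted cedents with a
#' category-dependent probability calibrated so that the empirical rule
#' confidence matches the planted target in expectation; non-satisfiers have
#' one cedent broken explicitly. Visit sequences carry THI totals whose
#' drift follows the spec's noise distribution.
#'
#' @param spec A [cohort_spec()].
#' @return A `trt_cohort`; attribute `"truth"` holds the latent categories
#'   and the spec (ground truth for evaluation only).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "trt_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  cats <- sample(trt_categories(), n, replace = TRUE, prob = spec$mixture)

  pat <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                    stringsAsFactors = FALSE)
  pat$G <- sample(c("m", "f"), n, replace = TRUE)
  pat$age <- NA_real_
  flag_names <- c("STI", "NTI", "HLTI", "DETI", "AATI", "OTI", "OMTI")
  for (f in flag_names) pat[[f]] <- NA_character_
  thr_cols <- c(paste0("R", c(1, 2, 3, 4, 6, 8, 12)), paste0("L", c(1, 2, 3, 4, 6, 8, 12)))
  ldl_cols <- c(paste0("LR", 1:8), paste0("LL", 1:8))
  for (col in c(thr_cols, ldl_cols)) pat[[col]] <- NA_real_
  int_cols <- c("T_pr", "H_pr", "HL_pr", "T_An", "T_Sv", "H_An", "H_Sv", "H_EffLife")
  for (col in int_cols) pat[[col]] <- NA_real_

  for (ct in trt_categories()) {
    idx <- which(cats == ct)
    if (!length(idx)) next
    p <- cat_params[[ct]]
    m <- length(idx)
    pat$age[idx] <- rnorm_clamped(m, p$age[1], p$age[2], 18, 90)
    for (f in flag_names) {
      pat[[f]][idx] <- ifelse(stats::runif(m) < p$flags[[f]], "yes", "no")
    }
    for (col in thr_cols) pat[[col]][idx] <- rnorm_clamped(m, p$thr[1], p$thr[2], -10, 110)
    for (col in ldl_cols) {
      v <- rnorm_clamped(m, p$ldl[1], p$ldl[2], 30, 120)
      v[stats::runif(m) < spec$ldl_sentinel_prob] <- 999
      pat[[col]][idx] <- v
    }
    pat$T_pr[idx] <- rnorm_clamped(m, p$t_pr[1], p$t_pr[2], 0, 10, 0.5)
    pat$H_pr[idx] <- rnorm_clamped(m, p$h_pr[1], p$h_pr[2], 0, 10, 0.5)
    pat$HL_pr[idx] <- rnorm_clamped(m, p$hl_pr[1], p$hl_pr[2], 0, 10, 0.5)
    pat$T_An[idx] <- rnorm_clamped(m, p$t_pr[1], 1.5, 0, 10, 0.5)
    pat$T_Sv[idx] <- rnorm_clamped(m, p$t_pr[1], 1.5, 0, 10, 0.5)
    pat$H_An[idx] <- rnorm_clamped(m, p$h_pr[1], 1.2, 0, 10, 0.5)
    pat$H_Sv[idx] <- rnorm_clamped(m, p$h_pr[1], 1.2, 0, 10, 0.5)
    pat$H_EffLife[idx] <- rnorm_clamped(m, p$h_pr[1], 1.5, 0, 10, 0.5)
  }
  pat$AgeInd <- pmax(18, pat$age - round(stats::runif(n, 1, 15)))
  pat$AgeBeg <- pmin(pat$age, pat$AgeInd + round(stats::runif(n, 0, 5)))
  pat$DTI <- pat$age - pat$AgeInd

  # impose planted decision rules
  for (pr in spec$planted_rules) {
    pi_t <- spec$mixture[[pr$category]]
    s_t <- pr$exposure
    conf <- pr$confidence / 100
    s_o <- min(1, pi_t * s_t * (1 - conf) / (conf * max(1 - pi_t, 1e-9)))
    sat_prob <- ifelse(cats == pr$category, s_t, s_o)
    sat <- stats::runif(n) < sat_prob
    for (i in seq_len(n)) {
      if (sat[i]) {
        for (ced in pr$cedents) pat[[ced$attr]][i] <- force_cedent_value(ced)
      } else {
        ced <- pr$cedents[[sample.int(length(pr$cedents), 1)]]
        pat[[ced$attr]][i] <- break_cedent_value(ced)
      }
    }
  }

  # visit sequences with THI trajectories and treatment descriptors
  n_visits <- sample(seq(spec$visit_range[1], spec$visit_range[2]), n, replace = TRUE)
  vis_list <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_visits[i]
    p <- cat_params[[cats[i]]]
    thi <- numeric(k)
    thi[1] <- rnorm_clamped(1, p$thi[1], p$thi[2], 0, 100)
    if (k > 1) {
      for (v in 2:k) {
        per_ch <- stats::rnorm(1, spec$noise_mean / 2, spec$noise_sd)
        thi[v] <- round(min(100, max(0, thi[v - 1] * (1 - per_ch / 100))))
      }
    }
    ins0 <- sample(c("GHH", "GHS", "GHI", "SG", "HA", "V", "none"), 1,
                   prob = c(.25, .1, .1, .2, .2, .05, .1))
    vis_list[[i]] <- data.frame(
      patient_id = pat$patient_id[i],
      visit_no = seq_len(k) - 1L,
      Tsc = thi,
      Taw = rnorm_clamped(k, thi[1] / 10, 1, 0, 10, 0.5),
      Ins = ins0,
      FU = sample(c("A", "C", "T", "E", "0"), k, replace = TRUE,
                  prob = c(.4, .3, .15, .1, .05)),
      Mix_RSL = rnorm_clamped(k, 11, 2, 0, 30),
      Freq_LE = rnorm_clamped(k, 3000, 400, 1000, 6000, 10),
      treat = round(seq(0, by = 6, length.out = k) + stats::runif(k, 0, 3)),
      stringsAsFactors = FALSE)
  }
  vis <- do.call(rbind, vis_list)
  rownames(vis) <- NULL

  cohort <- new_cohort(pat, vis)
  attr(cohort, "truth") <- list(category = stats::setNames(cats, pat$patient_id),
                                spec = spec)
  cohort
}

# Draw a value satisfying / violating one planted cedent.
force_cedent_value <- function(ced) {
  switch(ced$op,
    ge = round(stats::runif(1, as.numeric(ced$value), as.numeric(ced$value) + 40)),
    le = round(stats::runif(1, max(as.numeric(ced$value) - 40, -10), as.numeric(ced$value))),
    gt = round(stats::runif(1, as.numeric(ced$value) + 1, as.numeric(ced$value) + 40)),
    lt = round(stats::runif(1, max(as.numeric(ced$value) - 40, -10),
                            as.numeric(ced$value) - 1)),
    interval = {
      a <- ced$value; b <- ced$value2
      min(b - 1e-6, round(stats::runif(1, a, b), 1))
    },
    eq = ced$value,
    stop("cannot plant cedent op: ", ced$op)
  )
}

break_cedent_value <- function(ced) {
  switch(ced$op,
    ge = round(stats::runif(1, max(as.numeric(ced$value) - 40, -10),
                            as.numeric(ced$value) - 1)),
    le = round(stats::runif(1, as.numeric(ced$value) + 1, as.numeric(ced$value) + 40)),
    gt = as.numeric(ced$value),
    lt = as.numeric(ced$value),
    interval = round(ced$value2 + stats::runif(1, 0, 20)),
    eq = paste0("not_", ced$value),
    stop("cannot break cedent op: ", ced$op)
  )
}

#' Generate a visit-pair table for action-rule mining
#'
#' One row per (simulated) consecutive visit pair: stable patient facts, the
#' flexible treatment attribute before and after, and the outcome of the
#' transition (`per_ch`, `ch` and the better/same/worse label). When a
#' planted effect's stable context holds, the before-state matches its
#' from-state and the (per-pair) compliance draw succeeds, the flexible
#' value switches to the to-state and the pair improves with the planted
#' rate — the improvement drawn from the planted gain distribution,
#' otherwise from the noise distribution (both truncated to agree with the
#' drawn outcome). All other pairs churn instruments rarely and follow the
#' noise distribution.
#'
#' @param spec A [cohort_spec()] with at least one planted action (use
#'   `planted_actions = list()` for a pure-noise null table).
#' @param n_pairs Number of visit pairs.
#' @param compliance Optional override of every planted action's
#'   compliance.
#' @param churn Probability an instrument changes for reasons unrelated to
#'   any planted effect.
#' @param seed Optional seed override (defaults to `spec$seed + 1`).
#' @return Data frame with columns `G`, `NTI`, `OMTI`, `T_side`,
#'   `Ins_before`, `Ins_after`, `prev_thi`, `per_ch`, `ch`, `outcome`.
#' @export
generate_visit_pairs <- function(spec = cohort_spec(), n_pairs = 500,
                                 compliance = NULL, churn = 0.01, seed = NULL) {
  stopifnot(inherits(spec, "trt_cohort_spec"))
  set.seed(if (is.null(seed)) spec$seed + 1L else as.integer(seed))
  n <- as.integer(n_pairs)
  df <- data.frame(
    G = sample(c("m", "f"), n, replace = TRUE),
    NTI = sample(c("yes", "no"), n, replace = TRUE, prob = c(.5, .5)),
    OMTI = sample(c("yes", "no"), n, replace = TRUE, prob = c(.15, .85)),
    T_side = sample(c("yes", "no"), n, replace = TRUE, prob = c(.1, .9)),
    Ins_before = sample(c("GHH", "GHS", "GHI", "SG", "HA", "V"), n, replace = TRUE,
                        prob = c(.40, .005, .095, .2, .2, .1)),
    stringsAsFactors = FALSE)
  df$Ins_after <- df$Ins_before
  df$prev_thi <- rnorm_clamped(n, 45, 15, 5, 100)
  per_ch <- stats::rnorm(n, spec$noise_mean, spec$noise_sd)
  treated <- rep(FALSE, n)

  for (pa in spec$planted_actions) {
    comp <- if (is.null(compliance)) pa$compliance else compliance
    eligible <- df$Ins_before == pa$from
    for (sa in names(pa$stable)) eligible <- eligible & df[[sa]] == pa$stable[[sa]]
    takes <- eligible & stats::runif(n) < comp
    df$Ins_after[takes] <- pa$to
    improves <- takes & stats::runif(n) < pa$rate / 100
    # truncate draws so the drawn outcome matches the intended label
    thr_pct <- 100 * spec$outcome_threshold / df$prev_thi
    per_ch[improves] <- truncated_normal(sum(improves), pa$gain_mean, pa$gain_sd,
                                         lower = thr_pct[improves])
    fail <- takes & !improves
    per_ch[fail] <- truncated_normal(sum(fail), spec$noise_mean, spec$noise_sd,
                                     upper = thr_pct[fail])
    treated <- treated | takes
  }
  churned <- !treated & stats::runif(n) < churn
  if (any(churned)) {
    levels_all <- c("GHH", "GHS", "GHI", "SG", "HA", "V")
    df$Ins_after[churned] <- vapply(df$Ins_before[churned], function(b) {
      sample(setdiff(levels_all, b), 1)
    }, character(1))
  }
  df$per_ch <- round(per_ch, 1)
  df$ch <- round(df$prev_thi * df$per_ch / 100)
  df$outcome <- vapply(df$ch, function(ch) {
    lab <- label_outcome(ch, spec$outcome_threshold)
    if (lab == "better") "better" else "not-better"
  }, character(1))
  df
}

# Inverse-CDF truncated normal draw (vectorised bounds).
truncated_normal <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (!n) return(numeric(0))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, pmin(plo, phi - 1e-12), phi)
  stats::qnorm(u, mean, sd)
}
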