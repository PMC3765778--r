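test_that("initial state reflects diagnosis flags", {
  p <- as.list(ref_profile())
  expect_equal(initial_state(c(p, diabetes = 0, previous_mi = 0)), "WELL")
  expect_equal(initial_state(c(p, diabetes = 1, previous_mi = 0)), "T2D")
  expect_equal(initial_state(c(p, diabetes = 0, previous_mi = 1)), "CVD")
  expect_equal(initial_state(c(p, diabetes = 1, previous_mi = 1)), "T2D_CVD")
})

test_that("annual transition probabilities match the competing-risks form", {
  # single hazard, no competition: p = 1 - exp(-h), closed form
  tp <- toy_params(h0 = list(cvd_onset = 0.02))
  pr <- annual_transition_probs("WELL", ref_profile(), 55, "M", tp)
  expect_equal(sum(pr), 1)
  expect_equal(unname(pr["CVD"]), 1 - exp(-0.02))
  expect_equal(unname(pr["WELL"]), exp(-0.02))
  # doubling the hazard strictly increases the probability
  tp2 <- toy_params(h0 = list(cvd_onset = 0.04))
  pr2 <- annual_transition_probs("WELL", ref_profile(), 55, "M", tp2)
  expect_gt(pr2["CVD"], pr["CVD"])
  expect_equal(unname(pr2["CVD"]), 1 - exp(-0.04))
  # competing hazards: total exit 1 - exp(-H), apportioned by hazard
  tp3 <- toy_params(h0 = list(cvd_onset = 0.03, t2d_onset = 0.01),
                    other = 0.01)
  pr3 <- annual_transition_probs("WELL", ref_profile(), 55, "M", tp3)
  H <- 0.05
  expect_equal(unname(pr3["CVD"]), (1 - exp(-H)) * 0.03 / H)
  expect_equal(unname(pr3["T2D"]), (1 - exp(-H)) * 0.01 / H)
  expect_equal(unname(pr3["DEAD_OTHER"]), (1 - exp(-H)) * 0.01 / H)
  expect_equal(sum(pr3), 1)
})

test_that("the reference profile is hazard-neutral", {
  params <- test_params()
  pr_ref <- annual_transition_probs("WELL", params$reference_profile, 60,
                                    "F", params)
  p0 <- params
  p0$coef[] <- 0
  pr_0 <- annual_transition_probs("WELL", ref_profile(waist = 120, fg = 9),
                                  60, "F", p0)
  expect_equal(pr_ref, pr_0)
})

test_that("probabilities are valid across profiles, ages and states", {
  params <- test_cal_params()
  set.seed(9)
  for (i in 1:25) {
    prof <- ref_profile() * stats::runif(9, 0.7, 1.4)
    prof["smoker"] <- stats::rbinom(1, 1, 0.3)
    age <- stats::runif(1, 35, 84)
    st <- sample(metscea:::STATES[1:5], 1)
    pr <- annual_transition_probs(st, prof, age, sample(c("M", "F"), 1),
                                  params)
    expect_true(all(pr >= 0 & pr <= 1))
    expect_equal(sum(pr), 1)
  }
})

test_that("zero hazards give the discounted-QoL closed form", {
  tp <- toy_params()
  g <- toy_group(age = 80)
  e <- cohort_expectation(g, "start", params = tp, discount_rate = 0)
  expect_equal(e$qaly, 5)       # 5 cycles, weight 1, no discounting
  expect_equal(e$yll, 0)
  expect_equal(e$surv_85, 1)
  led <- simulate_individual(ref_profile(), NULL, age0 = 80, sex = "M",
                             params = tp, seed = 4, discount_rate = 0)
  expect_equal(led$qaly_disc, 5)
  expect_equal(led$yll, 0)
  # discounting reduces accrual per the closed form
  e3 <- cohort_expectation(g, "start", params = tp, discount_rate = 0.03)
  expect_equal(e3$qaly, sum(1.03^-(1:5)))
})

test_that("a constant-hazard two-state chain matches brute-force enumeration", {
  h <- 0.1
  tp <- toy_params(other = h)
  g <- toy_group(age = 75)
  e <- cohort_expectation(g, "start", params = tp, discount_rate = 0)
  p <- 1 - exp(-h)
  Tn <- 10
  # independent oracle: enumerate survival and death-time distributions
  qaly_oracle <- sum((1 - p)^(1:Tn))
  yll_oracle <- sum((1 - p)^(0:(Tn - 1)) * p * (Tn - (1:Tn)))
  expect_equal(e$qaly, qaly_oracle)
  expect_equal(e$yll, yll_oracle)
  expect_equal(e$surv_85, (1 - p)^Tn)
})

test_that("forced death mid-simulation yields the years-of-life-lost gap", {
  # overwhelming disease mortality from the start state at age 70
  tp <- toy_params(h0 = list(cvd_onset = 1e9))
  # CVD state carries overwhelming death hazard too
  tp$h0$M[, "cvd_death"] <- 1e9
  tp$h0$F[, "cvd_death"] <- 1e9
  led <- simulate_individual(ref_profile(), NULL, age0 = 70, sex = "M",
                             params = tp, seed = 1)
  # dies of CVD at 72 at the latest (onset cycle 1, death cycle 2)
  expect_true(led$yll >= 13)
  expect_equal(led$death_age + led$yll, 85)
  # path is constant after absorption
  path <- led$state_path[[1]]
  first_dead <- which(path %in% c("DEAD_DISEASE", "DEAD_OTHER"))[1]
  expect_true(all(path[first_dead:length(path)] == path[first_dead]))
})

test_that("microsimulation converges to the cohort expectation", {
  params <- test_cal_params()
  g <- test_groups()$F_high
  sim <- run_microsim(g, "start", params = params, n_reps = 4000, seed = 21)
  e <- cohort_expectation(g, "start", params = params)
  key <- c(qaly_disc = "qaly", yll = "yll", cost_societal = "cost_societal",
           cost_healthcare = "cost_healthcare")
  for (k in names(key)) {
    expect_lt(abs(sim$means[[k]] - e[[key[[k]]]]), 3 * sim$mc_se[[k]] + 1e-9)
  }
})

test_that("raised blood pressure cannot improve expected outcomes", {
  params <- test_cal_params()
  g <- toy_group(age = 55, sex = "M")
  g2 <- g
  g2$profile_start <- ref_profile(sbp = 145)  # +20 mmHg
  g2$profile_12m <- g2$profile_start
  e1 <- cohort_expectation(g, "start", params = params)
  e2 <- cohort_expectation(g2, "start", params = params)
  expect_lte(e2$qaly, e1$qaly)
  expect_gte(e2$yll, e1$yll)
})

test_that("identical seeds reproduce the microsimulation exactly", {
  params <- test_cal_params()
  g <- test_groups()$M_medium
  a <- run_microsim(g, "12m", params = params, n_reps = 500, seed = 5)
  b <- run_microsim(g, "12m", params = params, n_reps = 500, seed = 5)
  expect_identical(a$means, b$means)
  expect_identical(a$ledgers, b$ledgers)
})

test_that("a fixed-seed individual life course is reproducible (snapshot)", {
  params <- test_params()  # uncalibrated shipped defaults
  led <- simulate_individual(ref_profile(sbp = 150, fg = 7.0),
                             ref_profile(sbp = 140, fg = 6.4),
                             age0 = 55, sex = "M", scenario = "base",
                             params = params, seed = 2024)
  led2 <- simulate_individual(ref_profile(sbp = 150, fg = 7.0),
                              ref_profile(sbp = 140, fg = 6.4),
                              age0 = 55, sex = "M", scenario = "base",
                              params = params, seed = 2024)
  expect_identical(led$qaly_disc, led2$qaly_disc)
  expect_identical(led$state_path, led2$state_path)
})

test_that("hazard calibration lands all groups in the target YLL window", {
  params <- test_cal_params()
  cal <- attr(params, "calibration")
  expect_true(all(cal$yll >= 4 & cal$yll <= 9.7))
  # already-feasible parameters are returned unscaled
  again <- calibrate_baseline_hazards(params, test_groups())
  expect_equal(attr(again, "calibration")$factor, 1, tolerance = 1e-6)
  # scaling all hazards up increases YLL (monotonicity used by the search)
  up <- params; up$hazard_scale <- params$hazard_scale * 2
  g <- test_groups()$M_high
  expect_gt(cohort_expectation(g, "start", params = up)$yll,
            cohort_expectation(g, "start", params = params)$yll)
  # infeasible window errors with diagnostics
  expect_error(
    calibrate_baseline_hazards(params, test_groups(),
                               yll_range = c(9.69, 9.7)),
    "no common factor")
})

test_that("risk ordering: worse profiles lose more life-years", {
  params <- test_cal_params()
  groups <- test_groups()
  yll <- vapply(groups, function(g)
    cohort_expectation(g, "start", params = params)$yll, numeric(1))
  # within sex, the high-risk group exceeds both lower groups (the low and
  # medium groups differ in mean age, so only high is age-robust);
  expect_gt(yll[["M_high"]], yll[["M_medium"]])
  expect_gt(yll[["M_high"]], yll[["M_low"]])
  expect_gt(yll[["F_high"]], yll[["F_medium"]])
  expect_gt(yll[["F_high"]], yll[["F_low"]])
  expect_gt(yll[["F_medium"]], yll[["F_low"]])
  # at a common starting age the ordering is monotone in risk level
  yll_55 <- vapply(groups, function(g) {
    g$age <- 55
    cohort_expectation(g, "start", params = params)$yll
  }, numeric(1))
  for (sx in c("M", "F")) {
    expect_gt(yll_55[[paste0(sx, "_medium")]], yll_55[[paste0(sx, "_low")]])
    expect_gt(yll_55[[paste0(sx, "_high")]], yll_55[[paste0(sx, "_medium")]])
  }
})
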