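# ---- hazard machinery -------------------------------------------------------

# per-individual, per-transition proportional-hazards multipliers
# X: n x length(HAZ_FIELDS) matrix of covariate values
hazard_multipliers <- function(X, params) {
  exp(sweep(X, 2, params$reference_profile, "-") %*% t(params$coef))
}

# profile list/vector -> covariate row in canonical order
profile_row <- function(profile) {
  p <- unlist(profile)
  out <- stats::setNames(numeric(length(HAZ_FIELDS)), HAZ_FIELDS)
  out[HAZ_FIELDS] <- vapply(HAZ_FIELDS, function(f) {
    if (f %in% names(p)) as.numeric(p[[f]]) else if (f == "smoker") 0 else
      stop("profile is missing field: ", f, call. = FALSE)
  }, numeric(1))
  out
}

# transitions leaving each alive state (row indices into TRANSITIONS)
out_transitions <- function() {
  lapply(stats::setNames(STATES[1:5], STATES[1:5]), function(s) {
    which(TRANSITIONS$from == s)
  })
}

#' Annual transition probabilities from one state
#'
#' Competing-risks conversion of annual hazards to probabilities: each
#' permitted disease transition has hazard h = h0(age, sex) * exp(sum of
#' beta_j (x_j - ref_j)) (scaled by the calibration factor), other-cause death
#' uses the life table, the total exit probability is 1 - exp(-H) apportioned
#' by cause-specific hazard, and the self-loop takes the remainder.
#'
#' @param state an alive state label (`WELL`, `T2D`, `T2D_COMPL`, `CVD`,
#'   `T2D_CVD`)
#' @param profile risk-factor profile (named vector or [risk_profile()])
#' @param age current age, years
#' @param sex `"M"` or `"F"`
#' @param params a [load_model_params()] list
#' @return named probability vector over the seven states (sums to 1)
#' @export
annual_transition_probs <- function(state, profile, age, sex, params) {
  stopifnot(state %in% STATES[1:5], sex %in% c("M", "F"))
  if (age >= params$termination_age) {
    stop("annual_transition_probs: age must be below the termination age",
         call. = FALSE)
  }
  X <- matrix(profile_row(profile), nrow = 1,
              dimnames = list(NULL, HAZ_FIELDS))
  mult <- hazard_multipliers(X, params)[1, ]
  b <- band_index(age, params)
  ks <- which(TRANSITIONS$from == state)
  h <- params$h0[[sex]][b, ks] * mult[ks] * params$hazard_scale
  h_other <- params$other_cause[[sex]][b]
  H <- sum(h) + h_other
  p <- stats::setNames(numeric(7), STATES)
  if (H > 0) {
    p_move <- 1 - exp(-H)
    p[TRANSITIONS$to[ks]] <- p_move * h / H
    p["DEAD_OTHER"] <- p_move * h_other / H
  }
  p[state] <- 1 - sum(p)
  p
}

#' Initial health state from diagnosis flags
#'
#' @param profile a profile carrying `diabetes` and `previous_mi` flags
#' @return a state label: `T2D`, `CVD`, `T2D_CVD` or `WELL`
#' @export
initial_state <- function(profile) {
  t2d <- isTRUE(as.logical(profile$diabetes)) ||
    (is.numeric(profile$diabetes) && profile$diabetes >= 1)
  mi <- isTRUE(as.logical(profile$previous_mi)) ||
    (is.numeric(profile$previous_mi) && profile$previous_mi >= 1)
  if (t2d && mi) "T2D_CVD" else if (t2d) "T2D" else if (mi) "CVD" else "WELL"
}

# ---- the vectorized engine --------------------------------------------------

# Simulate state paths for n individuals.
#   Xs, X12: n x 9 covariate matrices (X12 may be NULL -> no intervention arm)
#   ages: length-n starting ages; sex: length-n "M"/"F"
#   s0: length-n initial state indices
#   U: n x Tmax uniforms (common random numbers when shared across arms)
# Returns an n x (Tmax + 1) integer state matrix (column 1 = cycle 0).
microsim_paths <- function(Xs, X12, ages, sex, s0, scenario, params, U) {
  n <- nrow(Xs)
  term <- params$termination_age
  Tind <- pmax(0, floor(term - ages))
  Tmax <- max(Tind)
  stopifnot(ncol(U) >= Tmax)
  A <- hazard_multipliers(Xs, params)
  B <- if (is.null(X12)) NULL else exp((X12 - Xs) %*% t(params$coef))
  outs <- out_transitions()
  male <- sex == "M"
  S <- matrix(NA_integer_, n, Tmax + 1)
  S[, 1] <- s0
  state <- s0
  scale <- params$hazard_scale
  for (t in seq_len(Tmax)) {
    w <- if (is.null(B)) 0 else sustainability_weight(t, scenario)
    mult <- if (is.null(B) || w == 0) A else A * B^w
    age_t <- ages + (t - 1)
    b <- band_index(age_t, params)
    active <- which(state <= 5L & t <= Tind)
    nxt <- state
    if (length(active) > 0) {
      h_other <- numeric(n)
      h_other[male] <- params$other_cause$M[b[male]]
      h_other[!male] <- params$other_cause$F[b[!male]]
      for (si in 1:5) {
        idx <- active[state[active] == si]
        if (length(idx) == 0) next
        ks <- outs[[si]]
        h0m <- matrix(0, length(idx), length(ks))
        im <- male[idx]
        h0m[im, ] <- params$h0$M[b[idx][im], ks, drop = FALSE]
        h0m[!im, ] <- params$h0$F[b[idx][!im], ks, drop = FALSE]
        h <- h0m * mult[idx, ks, drop = FALSE] * scale
        H <- rowSums(h) + h_other[idx]
        p_move <- ifelse(H > 0, 1 - exp(-H), 0)
        # columns: each permitted target, other-cause death; remainder stays
        pm <- cbind(h, h_other[idx]) * (p_move / pmax(H, 1e-300))
        cum <- t(apply(pm, 1, cumsum))
        if (length(idx) == 1) cum <- matrix(cum, nrow = 1)
        u <- U[idx, t]
        pick <- rowSums(u > cum) + 1L  # 1..K_s targets, K_s+1 other, else stay
        targets <- c(match(TRANSITIONS$to[ks], STATES), 7L)
        moved <- pick <= length(targets)
        nxt[idx[moved]] <- targets[pick[moved]]
      }
    }
    state <- nxt
    S[, t + 1] <- state
  }
  S
}

# discounted accrual over simulated paths -> one-row-per-individual ledgers
accrue_ledgers <- function(S, ages, params, discount_rate = 0.03) {
  n <- nrow(S)
  Tmax <- ncol(S) - 1
  term <- params$termination_age
  Tind <- pmax(0, floor(term - ages))
  qaly <- numeric(n); cost_s <- numeric(n); cost_h <- numeric(n)
  death_age <- rep(NA_real_, n)
  mult <- c(params$qol_multipliers, DEAD_DISEASE = 0, DEAD_OTHER = 0)
  cs <- params$state_costs["societal", STATES]
  ch <- params$state_costs["healthcare", STATES]
  for (t in seq_len(Tmax)) {
    st <- S[, t + 1]
    active <- t <= Tind
    alive <- active & st <= 5L
    df <- (1 + discount_rate)^(-t)
    if (any(alive)) {
      q <- qol_at_age(ages[alive] + t, params) * mult[st[alive]]
      qaly[alive] <- qaly[alive] + q * df
      cost_s[alive] <- cost_s[alive] + cs[st[alive]] * df
      cost_h[alive] <- cost_h[alive] + ch[st[alive]] * df
    }
    died_now <- active & st >= 6L & (S[, t] <= 5L)
    death_age[died_now] <- ages[died_now] + t
  }
  yll <- ifelse(is.na(death_age), 0, pmax(0, term - death_age))
  tibble::tibble(qaly_disc = qaly, cost_societal = cost_s,
                 cost_healthcare = cost_h, death_age = death_age, yll = yll)
}

# ---- user-facing simulation wrappers ---------------------------------------

sim_output <- function(ledgers, seed, n_reps, S = NULL, ages = NULL) {
  means <- vapply(ledgers[c("qaly_disc", "cost_societal", "cost_healthcare",
                            "yll")], mean, numeric(1))
  ses <- vapply(ledgers[c("qaly_disc", "cost_societal", "cost_healthcare",
                          "yll")], function(x) stats::sd(x) / sqrt(length(x)),
                numeric(1))
  structure(list(ledgers = ledgers, means = means, mc_se = ses,
                 seed = seed, n_reps = n_reps, states = S, ages = ages),
            class = "sim_output")
}

# uniforms for n individuals over Tmax cycles plus 2 initial-state draws,
# derived from a single master seed (rows act as per-individual substreams)
draw_uniforms <- function(n, Tmax, seed) {
  set.seed(as.integer(seed %% 2147483647))
  list(U = matrix(stats::runif(n * Tmax), n, Tmax),
       U0 = matrix(stats::runif(n * 2), n, 2))
}

group_matrices <- function(group, n_reps, U0) {
  Xs <- matrix(rep(profile_row(group$profile_start), each = n_reps),
               nrow = n_reps, dimnames = list(NULL, HAZ_FIELDS))
  X12 <- matrix(rep(profile_row(group$profile_12m), each = n_reps),
                nrow = n_reps, dimnames = list(NULL, HAZ_FIELDS))
  t2d <- U0[, 1] < group$p_t2d
  mi <- U0[, 2] < group$p_mi
  s0 <- ifelse(t2d & mi, 5L, ifelse(t2d, 2L, ifelse(mi, 4L, 1L)))
  list(Xs = Xs, X12 = X12, s0 = s0)
}

#' Run the microsimulation for one group and arm
#'
#' Simulates `n_reps` individuals sharing the group's mean risk-factor
#' profile, starting at the group's mean baseline age (the same starting age
#' is used for both arms so age effects cancel), until age 85 or death. The
#' `start` arm keeps start levels throughout; the `12m` arm follows the
#' sustainability trajectory towards the 12-month levels. Initial states are
#' drawn from the group's diagnosed-diabetes and previous-MI rates; the
#' smoking rate enters the hazards as a fractional covariate.
#'
#' @param group a group object (one row of [summarize_groups()] passed through
#'   internally, or a list with `profile_start`, `profile_12m`, `age`, `sex`,
#'   `p_t2d`, `p_mi`)
#' @param arm `"start"` or `"12m"`
#' @param scenario a [sustainability_scenario()] or its name
#' @param params a [load_model_params()] list
#' @param n_reps number of simulated individuals (study default 10,000)
#' @param seed master seed for the per-individual random streams
#' @param discount_rate annual discount rate for QALYs and costs
#' @return a `sim_output` list: per-individual `ledgers`, `means`, Monte-Carlo
#'   standard errors `mc_se`, and the state paths
#' @export
run_microsim <- function(group, arm = c("start", "12m"), scenario = "base",
                         params = load_model_params(), n_reps = 10000,
                         seed = 1, discount_rate = 0.03) {
  arm <- match.arg(arm)
  stopifnot(n_reps >= 1)
  Tmax <- max(1, floor(params$termination_age - group$age))
  ru <- draw_uniforms(n_reps, Tmax, seed)
  gm <- group_matrices(group, n_reps, ru$U0)
  X12 <- if (arm == "12m") gm$X12 else NULL
  ages <- rep(group$age, n_reps)
  S <- microsim_paths(gm$Xs, X12, ages, rep(group$sex, n_reps), gm$s0,
                      scenario, params, ru$U)
  led <- accrue_ledgers(S, ages, params, discount_rate)
  sim_output(led, seed, n_reps, S, ages)
}

#' Simulate both arms of one group under common random numbers
#'
#' The two arms share the per-individual random streams and initial-state
#' draws, so with a null intervention effect the paired difference is exactly
#' zero and Monte-Carlo noise largely cancels in the deltas.
#'
#' @inheritParams run_microsim
#' @param crn share random streams across arms (`TRUE` by default)
#' @return list with `start` and `m12` sim outputs plus `delta`, a one-row
#'   tibble of paired mean differences (12m - start for QALYs, start - 12m
#'   for costs, i.e. future savings) with standard errors
#' @export
run_group_pair <- function(group, scenario = "base",
                           params = load_model_params(), n_reps = 10000,
                           seed = 1, discount_rate = 0.03, crn = TRUE) {
  Tmax <- max(1, floor(params$termination_age - group$age))
  ru <- draw_uniforms(n_reps, Tmax, seed)
  gm <- group_matrices(group, n_reps, ru$U0)
  ages <- rep(group$age, n_reps)
  sexv <- rep(group$sex, n_reps)
  S0 <- microsim_paths(gm$Xs, NULL, ages, sexv, gm$s0, scenario, params, ru$U)
  ru2 <- if (crn) ru else draw_uniforms(n_reps, Tmax, seed + 777)
  S1 <- microsim_paths(gm$Xs, gm$X12, ages, sexv, gm$s0, scenario, params,
                       ru2$U)
  led0 <- accrue_ledgers(S0, ages, params, discount_rate)
  led1 <- accrue_ledgers(S1, ages, params, discount_rate)
  pair_outputs(led0, led1, seed, n_reps, group, S0, S1, ages)
}

pair_outputs <- function(led0, led1, seed, n_reps, group = NULL,
                         S0 = NULL, S1 = NULL, ages = NULL) {
  d_q <- led1$qaly_disc - led0$qaly_disc
  d_cs <- led0$cost_societal - led1$cost_societal
  d_ch <- led0$cost_healthcare - led1$cost_healthcare
  d_yll <- led1$yll - led0$yll
  se <- function(x) stats::sd(x) / sqrt(length(x))
  delta <- tibble::tibble(
    delta_qaly = mean(d_q), delta_qaly_se = se(d_q),
    saving_societal = mean(d_cs), saving_societal_se = se(d_cs),
    saving_healthcare = mean(d_ch), saving_healthcare_se = se(d_ch),
    delta_yll = mean(d_yll), delta_yll_se = se(d_yll)
  )
  list(start = sim_output(led0, seed, n_reps, S0, ages),
       m12 = sim_output(led1, seed, n_reps, S1, ages),
       delta = delta, group = group)
}

#' Simulate one individual life course
#'
#' Thin single-individual wrapper around the simulation engine; the ledger
#' records the per-cycle state path, death age (if any), discounted QALYs and
#' costs, and years of life lost before the termination age.
#'
#' @param start_profile,m12_profile profiles; pass `m12_profile = NULL` for
#'   the comparator arm
#' @param age0 starting age (must be below the termination age)
#' @param sex `"M"` or `"F"`
#' @inheritParams run_microsim
#' @return a one-row ledger tibble with the state path as a list column
#' @export
simulate_individual <- function(start_profile, m12_profile = NULL, age0, sex,
                                scenario = "base",
                                params = load_model_params(), seed = 1,
                                discount_rate = 0.03) {
  stopifnot(age0 < params$termination_age)
  Tmax <- max(1, floor(params$termination_age - age0))
  ru <- draw_uniforms(1, Tmax, seed)
  Xs <- matrix(profile_row(start_profile), nrow = 1,
               dimnames = list(NULL, HAZ_FIELDS))
  X12 <- if (is.null(m12_profile)) NULL else
    matrix(profile_row(m12_profile), nrow = 1,
           dimnames = list(NULL, HAZ_FIELDS))
  s0 <- match(initial_state(as.list(start_profile)), STATES)
  S <- microsim_paths(Xs, X12, age0, sex, s0, scenario, params, ru$U)
  led <- accrue_ledgers(S, age0, params, discount_rate)
  led$state_path <- list(STATES[S[1, ]])
  led
}

#' Run both arms on individually sampled patients
#'
#' Implements the individual-characteristics stratification modes: `n_reps`
#' patients are drawn with replacement from the cohort and simulated with
#' their own risk-factor profiles, ages (and sex), under common random
#' numbers across arms. Initial states follow each patient's own diagnosis
#' flags.
#'
#' @param cohort an included, stratified cohort with `_start` and `_12m`
#'   profile columns
#' @inheritParams run_microsim
#' @return as [run_group_pair()]
#' @export
run_individual_pair <- function(cohort, scenario = "base",
                                params = load_model_params(), n_reps = 10000,
                                seed = 1, discount_rate = 0.03) {
  keep <- stats::complete.cases(cohort[paste0(RF_FIELDS, "_12m")])
  cohort <- cohort[keep, , drop = FALSE]
  set.seed(as.integer((seed + 13) %% 2147483647))
  pick <- sample.int(nrow(cohort), n_reps, replace = TRUE)
  sub <- cohort[pick, ]
  Xs <- as.matrix(sub[paste0(RF_FIELDS, "_start")])
  X12 <- as.matrix(sub[paste0(RF_FIELDS, "_12m")])
  colnames(Xs) <- colnames(X12) <- RF_FIELDS
  Xs <- cbind(Xs, smoker = sub$smoker)
  X12 <- cbind(X12, smoker = sub$smoker)
  s0 <- ifelse(sub$diabetes >= 1 & sub$previous_mi >= 1, 5L,
               ifelse(sub$diabetes >= 1, 2L,
                      ifelse(sub$previous_mi >= 1, 4L, 1L)))
  ages <- as.numeric(sub$age)
  Tmax <- max(1, floor(params$termination_age - min(ages)))
  ru <- draw_uniforms(n_reps, Tmax, seed)
  S0 <- microsim_paths(Xs, NULL, ages, sub$sex, s0, scenario, params, ru$U)
  S1 <- microsim_paths(Xs, X12, ages, sub$sex, s0, scenario, params, ru$U)
  led0 <- accrue_ledgers(S0, ages, params, discount_rate)
  led1 <- accrue_ledgers(S1, ages, params, discount_rate)
  pair_outputs(led0, led1, seed, n_reps, NULL, S0, S1, ages)
}
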