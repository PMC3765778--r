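# one-cycle 7x7 transition matrix for a scalar covariate profile
transition_matrix <- function(mult, age, sex, params) {
  P <- diag(7)
  dimnames(P) <- list(STATES, STATES)
  b <- band_index(age, params)
  h_other <- params$other_cause[[sex]][b]
  for (si in 1:5) {
    ks <- which(TRANSITIONS$from == STATES[si])
    h <- params$h0[[sex]][b, ks] * mult[ks] * params$hazard_scale
    H <- sum(h) + h_other
    if (H <= 0) next
    p_move <- 1 - exp(-H)
    row <- numeric(7)
    row[match(TRANSITIONS$to[ks], STATES)] <- p_move * h / H
    row[7] <- row[7] + p_move * h_other / H
    row[si] <- 1 - sum(row)
    P[si, ] <- row
  }
  P
}

#' Deterministic cohort expectation of the microsimulation
#'
#' Propagates state-occupancy probabilities forward through the same
#' per-cycle transition matrices the microsimulation samples from, yielding
#' the exact expectation the microsimulation converges to: expected
#' discounted QALYs and costs, and expected years of life lost before the
#' termination age. Used as an independent oracle for the stochastic engine
#' and for fast calibration.
#'
#' @inheritParams run_microsim
#' @param arm `"start"` or `"12m"`
#' @return named list: `qaly`, `yll`, `cost_societal`, `cost_healthcare`,
#'   and `surv_85` (probability of reaching the termination age)
#' @export
cohort_expectation <- function(group, arm = c("start", "12m"),
                               scenario = "base",
                               params = load_model_params(),
                               discount_rate = 0.03) {
  arm <- match.arg(arm)
  Xs <- matrix(profile_row(group$profile_start), nrow = 1,
               dimnames = list(NULL, HAZ_FIELDS))
  A <- hazard_multipliers(Xs, params)[1, ]
  B <- if (arm == "12m") {
    X12 <- matrix(profile_row(group$profile_12m), nrow = 1,
                  dimnames = list(NULL, HAZ_FIELDS))
    exp((X12 - Xs) %*% t(params$coef))[1, ]
  } else NULL
  occ <- numeric(7)
  pt <- group$p_t2d %||% 0
  pm <- group$p_mi %||% 0
  occ[1] <- (1 - pt) * (1 - pm)
  occ[2] <- pt * (1 - pm)
  occ[4] <- (1 - pt) * pm
  occ[5] <- pt * pm
  age0 <- group$age
  Tn <- max(1, floor(params$termination_age - age0))
  mult_state <- c(params$qol_multipliers, 0, 0)
  cs <- params$state_costs["societal", ]
  ch <- params$state_costs["healthcare", ]
  qaly <- 0; cost_s <- 0; cost_h <- 0; yll <- 0
  for (t in seq_len(Tn)) {
    w <- if (is.null(B)) 0 else sustainability_weight(t, scenario)
    mult <- if (is.null(B) || w == 0) A else A * B^w
    P <- transition_matrix(mult, age0 + t - 1, group$sex, params)
    dead_before <- occ[6] + occ[7]
    occ <- as.numeric(occ %*% P)
    df <- (1 + discount_rate)^(-t)
    alive <- occ[1:5]
    qaly <- qaly + sum(alive * mult_state[1:5]) * qol_at_age(age0 + t, params) * df
    cost_s <- cost_s + sum(alive * cs[1:5]) * df
    cost_h <- cost_h + sum(alive * ch[1:5]) * df
    died_now <- (occ[6] + occ[7]) - dead_before
    yll <- yll + died_now * max(0, params$termination_age - (age0 + t))
  }
  list(qaly = qaly, yll = yll, cost_societal = cost_s, cost_healthcare = cost_h,
       surv_85 = sum(occ[1:5]))
}

#' Calibrate baseline disease hazards to a target YLL range
#'
#' Scales all disease transition hazards by a common multiplicative factor so
#' the expected years of life lost (start-arm, deterministic expectation)
#' across the supplied groups fall inside the target range: bisection finds
#' the factor placing the minimum group YLL at the lower bound and the factor
#' placing the maximum at the upper bound; any factor between the two is
#' admissible and the one closest to 1 is returned (so an already-feasible
#' parameter set is left untouched, factor 1.0). Errors with diagnostics when
#' no common factor can satisfy both ends (the search does not bracket).
#'
#' @param params a [load_model_params()] list
#' @param groups list of group objects (see [run_microsim()])
#' @param yll_range admissible `[min, max]` for every group's expected YLL,
#'   years before the termination age
#' @param discount_rate passed through to the expectation (YLL itself is
#'   undiscounted)
#' @param factor_bounds search interval for the common factor
#' @return `params` with `hazard_scale` multiplied by the calibrated factor
#'   and an attribute `calibration` holding the factor and per-group YLL
#' @export
calibrate_baseline_hazards <- function(params, groups, yll_range = c(4, 9.7),
                                       discount_rate = 0.03,
                                       factor_bounds = c(0.02, 50)) {
  stopifnot(length(yll_range) == 2, all(yll_range > 0),
            yll_range[1] < yll_range[2])
  yll_at <- function(s) {
    p <- params
    p$hazard_scale <- params$hazard_scale * s
    vapply(groups, function(g) {
      cohort_expectation(g, arm = "start", params = p,
                         discount_rate = discount_rate)$yll
    }, numeric(1))
  }
  # YLL is monotone increasing in s (more disease -> earlier death)
  y_lb <- yll_at(factor_bounds[1]); y_ub <- yll_at(factor_bounds[2])
  bisect <- function(target, stat, side) {
    lo <- factor_bounds[1]; hi <- factor_bounds[2]
    for (i in 1:60) {
      mid <- sqrt(lo * hi)
      if (stat(yll_at(mid)) - target > 0) hi <- mid else lo <- mid
      if (hi / lo < 1.0002) break
    }
    if (side == "above") hi else lo  # stay strictly on the feasible side
  }
  # smallest factor with min-group YLL at the lower bound
  s_lo <- if (min(y_lb) >= yll_range[1]) factor_bounds[1]
          else if (min(y_ub) < yll_range[1]) NULL
          else bisect(yll_range[1], min, "above")
  # largest factor with max-group YLL at the upper bound
  s_hi <- if (max(y_ub) <= yll_range[2]) factor_bounds[2]
          else if (max(y_lb) > yll_range[2]) NULL
          else bisect(yll_range[2], max, "below")
  if (is.null(s_lo) || is.null(s_hi) || s_lo > s_hi) {
    stop("calibrate_baseline_hazards: no common factor places all group YLL ",
         "in [", yll_range[1], ", ", yll_range[2], "]; YLL at factor ",
         factor_bounds[1], ": [", paste(round(y_lb, 2), collapse = ", "),
         "], at factor ", factor_bounds[2], ": [",
         paste(round(y_ub, 2), collapse = ", "), "]",
         if (!is.null(s_lo) && !is.null(s_hi))
           paste0("; lower-bound factor ", round(s_lo, 3),
                  " exceeds upper-bound factor ", round(s_hi, 3)),
         call. = FALSE)
  }
  # keep the parameter set as close to its shipped values as the window
  # allows: no rescaling when the targets are already met
  s <- min(max(1, s_lo), s_hi)
  out <- params
  out$hazard_scale <- params$hazard_scale * s
  attr(out, "calibration") <- list(
    factor = s, factor_feasible = c(s_lo, s_hi),
    yll = stats::setNames(yll_at(s),
                          vapply(groups, function(g)
                            paste(g$sex, g$level, sep = "_"), character(1)))
  )
  out
}
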