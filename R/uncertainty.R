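#' A named configuration delta for scenario analysis
#'
#' A scenario is the base configuration plus named overrides: the discount
#' rate, the sustainability assumption, an alternative parameter file, or the
#' stratification mode. Stratification modes: `risk_groups` (the base 3x2
#' grouping), `gender_average` (per-sex mean profiles), `gender_individual`
#' (per sex, patients drawn with their own characteristics) and `individual`
#' (no grouping, own characteristics including sex).
#'
#' @param name scenario label
#' @param discount_rate,sustainability,params_file,stratification overrides;
#'   `NULL` keeps the base setting
#' @return list with class `"scenario_spec"`
#' @export
scenario_spec <- function(name, discount_rate = NULL, sustainability = NULL,
                          params_file = NULL,
                          stratification = NULL) {
  if (!is.null(stratification)) {
    stratification <- match.arg(stratification,
                                c("risk_groups", "gender_average",
                                  "gender_individual", "individual"))
  }
  structure(list(name = name, discount_rate = discount_rate,
                 sustainability = sustainability, params_file = params_file,
                 stratification = stratification),
            class = "scenario_spec")
}

# the study's standard scenario battery
default_scenarios <- function() {
  list(
    scenario_spec("base"),
    scenario_spec("discount_0", discount_rate = 0),
    scenario_spec("discount_5", discount_rate = 0.05),
    scenario_spec("sustainability_low", sustainability = "low"),
    scenario_spec("sustainability_high", sustainability = "high"),
    scenario_spec("strat_gender_average", stratification = "gender_average"),
    scenario_spec("strat_gender_individual",
                  stratification = "gender_individual"),
    scenario_spec("strat_individual", stratification = "individual")
  )
}

# per-sex average groups for the gender_average stratification mode
gender_average_groups <- function(cohort) {
  cohort$risk_group <- factor("all", levels = c("all"))
  summ <- cohort |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(
      n = dplyr::n(), mean_age = mean(.data$age),
      p_smoker = mean(.data$smoker), p_diabetes = mean(.data$diabetes),
      p_mi = mean(.data$previous_mi),
      dplyr::across(dplyr::ends_with("_start") | dplyr::ends_with("_12m"),
                    mean),
      .groups = "drop")
  summ$risk_group <- "all"
  lapply(seq_len(nrow(summ)), function(i) group_from_summary(summ[i, ]))
}

#' Run deterministic scenario analyses
#'
#' Re-evaluates the cost-effectiveness table under each scenario: overrides
#' are applied to the base configuration, group-mode scenarios re-simulate
#' each (risk level x sex) cell, and the stratification scenarios replace the
#' grouping itself (per-sex averages, or 10,000 patients drawn stochastically
#' from the cohort with their own characteristics).
#'
#' @param groups list of group objects (the base stratification)
#' @param cohort the included, stratified cohort (needed for the
#'   individual-characteristics modes)
#' @param params a [load_model_params()] list (calibrated)
#' @param scenarios list of [scenario_spec()]s; defaults to the study battery
#' @param cost a [program_cost()]
#' @param n_reps,seed,discount_rate,scenario base-case simulation settings
#' @return tibble of CEA rows with a `scenario` column
#' @export
run_scenarios <- function(groups, cohort, params,
                          scenarios = default_scenarios(),
                          cost = program_cost(), n_reps = 10000, seed = 1,
                          discount_rate = 0.03, scenario = "base") {
  out <- list()
  for (sc in scenarios) {
    known <- c("name", "discount_rate", "sustainability", "params_file",
               "stratification")
    bad <- setdiff(names(sc), known)
    if (length(bad) > 0) stop("run_scenarios: unknown override key(s): ",
                              paste(bad, collapse = ", "), call. = FALSE)
    r <- sc$discount_rate %||% discount_rate
    sust <- sc$sustainability %||% scenario
    p <- if (!is.null(sc$params_file)) load_model_params(sc$params_file) else
      params
    strat <- sc$stratification %||% "risk_groups"
    tab <- if (strat == "risk_groups") {
      pairs <- lapply(groups, run_group_pair, scenario = sust, params = p,
                      n_reps = n_reps, seed = seed, discount_rate = r)
      names(pairs) <- vapply(groups, function(g)
        paste(g$sex, g$level, sep = "_"), character(1))
      cea_table(pairs, cost)
    } else if (strat == "gender_average") {
      ga <- gender_average_groups(cohort)
      pairs <- lapply(ga, run_group_pair, scenario = sust, params = p,
                      n_reps = n_reps, seed = seed, discount_rate = r)
      names(pairs) <- vapply(ga, function(g) paste0(g$sex, "_all"),
                             character(1))
      cea_table(pairs, cost)
    } else if (strat == "gender_individual") {
      tabs <- lapply(c("M", "F"), function(sx) {
        pr <- run_individual_pair(cohort[cohort$sex == sx, ],
                                  scenario = sust, params = p,
                                  n_reps = n_reps, seed = seed,
                                  discount_rate = r)
        cea_table(stats::setNames(list(pr), paste0(sx, "_individual")), cost)
      })
      dplyr::bind_rows(tabs)
    } else {
      pr <- run_individual_pair(cohort, scenario = sust, params = p,
                                n_reps = n_reps, seed = seed,
                                discount_rate = r)
      cea_table(list(all_individual = pr), cost)
    }
    tab$scenario <- sc$name
    out[[length(out) + 1]] <- tab
  }
  dplyr::bind_rows(out) |> dplyr::relocate("scenario")
}

#' Bootstrap probabilistic sensitivity analysis
#'
#' Draws `n_draws` bootstrap replicates of `replicate_size` individuals with
#' replacement from the paired per-individual ledgers (the same indices are
#' used in both arms, matching the common-random-numbers pairing), and
#' returns the cloud of (delta cost, delta QALY) points for the
#' cost-effectiveness plane. The per-patient program cost is added to each
#' replicate's cost difference by default.
#'
#' @param pair a [run_group_pair()] / [run_individual_pair()] output
#' @param cost a [program_cost()]
#' @param perspective `"societal"` or `"healthcare"`
#' @param replicate_size individuals per replicate (study: 1,000)
#' @param n_draws bootstrap draws (study: 1,000)
#' @param seed RNG seed
#' @param include_program_cost add the program cost to each delta-cost value
#' @param identity replace resampling by the identity (degenerate bootstrap:
#'   every draw is the full-sample point estimate)
#' @return tibble with `draw`, `delta_cost_eur`, `delta_qaly`
#' @export
bootstrap_ce <- function(pair, cost = program_cost(),
                         perspective = c("societal", "healthcare"),
                         replicate_size = 1000, n_draws = 1000, seed = 1,
                         include_program_cost = TRUE, identity = FALSE) {
  perspective <- match.arg(perspective)
  l0 <- pair$start$ledgers; l1 <- pair$m12$ledgers
  if (is.null(l0) || is.null(l1) || nrow(l0) != nrow(l1)) {
    stop("bootstrap_ce: paired per-individual ledgers required", call. = FALSE)
  }
  n <- nrow(l0)
  if (replicate_size > n) {
    stop("bootstrap_ce: replicate_size exceeds the number of simulated ",
         "individuals", call. = FALSE)
  }
  ck <- paste0("cost_", perspective)
  d_cost <- l1[[ck]] - l0[[ck]]
  d_qaly <- l1$qaly_disc - l0$qaly_disc
  add <- if (include_program_cost) cost[[perspective]] else 0
  if (identity) {
    return(tibble::tibble(draw = seq_len(n_draws),
                          delta_cost_eur = mean(d_cost) + add,
                          delta_qaly = mean(d_qaly)))
  }
  set.seed(as.integer(seed %% 2147483647))
  idx <- matrix(sample.int(n, replicate_size * n_draws, replace = TRUE),
                nrow = replicate_size)
  tibble::tibble(
    draw = seq_len(n_draws),
    delta_cost_eur = colMeans(matrix(d_cost[idx], nrow = replicate_size)) + add,
    delta_qaly = colMeans(matrix(d_qaly[idx], nrow = replicate_size))
  )
}

#' Summarize a cost-effectiveness plane point cloud
#'
#' Quadrant shares (QALY gain/loss x cost increase/decrease), the share of
#' cost-saving points, and the cost-effectiveness acceptability value at a
#' willingness-to-pay threshold (share of points with delta cost <= threshold
#' x delta QALY).
#'
#' @param points a [bootstrap_ce()] tibble
#' @param wtp willingness-to-pay threshold, EUR/QALY
#' @return named list of proportions; quadrant shares sum to 1
#' @export
ce_plane_summary <- function(points, wtp = 50000) {
  if (is.null(points) || nrow(points) == 0) {
    stop("ce_plane_summary: empty point cloud", call. = FALSE)
  }
  dq <- points$delta_qaly; dc <- points$delta_cost_eur
  list(
    n = nrow(points),
    share_ne = mean(dq > 0 & dc >= 0),
    share_se = mean(dq > 0 & dc < 0),
    share_nw = mean(dq <= 0 & dc >= 0),
    share_sw = mean(dq <= 0 & dc < 0),
    share_cost_saving = mean(dc < 0),
    ceac = mean(dc <= wtp * dq),
    mean_delta_cost = mean(dc),
    mean_delta_qaly = mean(dq)
  )
}
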