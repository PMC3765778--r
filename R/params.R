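# health-state labels, fixed order; 6/7 are absorbing
STATES <- c("WELL", "T2D", "T2D_COMPL", "CVD", "T2D_CVD",
            "DEAD_DISEASE", "DEAD_OTHER")

# disease transitions (other-cause death WELL..T2D_CVD -> DEAD_OTHER is
# implicit and driven by the life table, not by these)
TRANSITIONS <- data.frame(
  name = c("t2d_onset", "cvd_onset", "t2d_compl", "t2d_cvd_onset",
           "t2d_death", "compl_cvd", "compl_death", "cvd_t2d",
           "cvd_death", "t2d_cvd_death"),
  from = c("WELL", "WELL", "T2D", "T2D", "T2D", "T2D_COMPL", "T2D_COMPL",
           "CVD", "CVD", "T2D_CVD"),
  to = c("T2D", "CVD", "T2D_COMPL", "T2D_CVD", "DEAD_DISEASE", "T2D_CVD",
         "DEAD_DISEASE", "T2D_CVD", "DEAD_DISEASE", "DEAD_DISEASE"),
  stringsAsFactors = FALSE
)

#' Load (or build) the disease-model parameter set
#'
#' The risk engine is fully configurable: age-banded annual baseline hazards
#' per transition and sex, proportional-hazards log-hazard-ratio coefficients
#' per unit of each risk factor (centred at a reference profile), an age/sex
#' other-cause mortality life table, age-indexed population quality-of-life
#' weights, per-state utility multipliers, and per-state annual costs by
#' perspective. The default file shipped with the package is a documented,
#' plausibility-oriented parameterization inspired by published CVD/T2D risk
#' scores; it is meant to be calibrated with
#' [calibrate_baseline_hazards()] and can be replaced wholesale.
#'
#' @param path YAML parameter file; defaults to the shipped set
#' @return a validated parameter list with class `"model_params"`
#' @export
#' @examples
#' params <- load_model_params()
#' params$termination_age
load_model_params <- function(path = system.file("extdata", "model_params.yaml",
                                                 package = "metscea")) {
  raw <- yaml::read_yaml(path)
  K <- nrow(TRANSITIONS)
  bands <- as.numeric(raw$age_band_starts)
  nb <- length(bands)
  get_h0 <- function(sex) {
    m <- sapply(TRANSITIONS$name, function(tr) {
      v <- as.numeric(raw$baseline_hazards[[tr]][[sex]])
      if (length(v) != nb) stop("baseline hazard table for ", tr, "/", sex,
                                " must have ", nb, " age bands", call. = FALSE)
      v
    })
    if (any(m < 0)) stop("load_model_params: negative baseline hazard in ",
                         sex, " table", call. = FALSE)
    m
  }
  coef <- matrix(0, K, length(HAZ_FIELDS),
                 dimnames = list(TRANSITIONS$name, HAZ_FIELDS))
  for (tr in names(raw$coefficients)) {
    if (!tr %in% TRANSITIONS$name) stop("unknown transition in coefficients: ",
                                        tr, call. = FALSE)
    for (f in names(raw$coefficients[[tr]])) {
      coef[tr, f] <- as.numeric(raw$coefficients[[tr]][[f]])
    }
  }
  ref <- stats::setNames(as.numeric(raw$reference_profile[HAZ_FIELDS]),
                         HAZ_FIELDS)
  other <- lapply(c(M = "M", F = "F"), function(sx) {
    v <- as.numeric(raw$other_cause_mortality[[sx]])
    if (any(v < 0)) stop("negative other-cause hazard", call. = FALSE)
    v
  })
  qol <- as.numeric(raw$qol_population)
  if (any(qol < 0 | qol > 1)) stop("population QoL weights must be in [0,1]",
                                   call. = FALSE)
  mult <- stats::setNames(as.numeric(raw$qol_multipliers[STATES[1:5]]),
                          STATES[1:5])
  if (any(mult <= 0 | mult > 1)) stop("QoL multipliers must be in (0,1]",
                                      call. = FALSE)
  cost_vec <- function(lst) {
    vapply(STATES, function(s) as.numeric(lst[[s]] %||% 0), numeric(1))
  }
  cost <- rbind(societal = cost_vec(raw$state_costs$societal),
                healthcare = cost_vec(raw$state_costs$healthcare))
  if (any(cost["societal", ] < cost["healthcare", ])) {
    stop("societal state costs must be >= healthcare state costs",
         call. = FALSE)
  }
  structure(list(
    age_band_starts = bands,
    h0 = list(M = get_h0("M"), F = get_h0("F")),
    coef = coef,
    reference_profile = ref,
    other_cause = other,
    qol_population = qol,
    qol_multipliers = mult,
    state_costs = cost,
    termination_age = as.numeric(raw$termination_age %||% 85),
    cycle_length = as.numeric(raw$cycle_length %||% 1),
    hazard_scale = as.numeric(raw$hazard_scale %||% 1)
  ), class = "model_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# age -> band row index (clamped to the table range)
band_index <- function(age, params) {
  pmin(pmax(findInterval(age, params$age_band_starts), 1),
       length(params$age_band_starts))
}

# population QoL weight at (continuous) age
qol_at_age <- function(age, params) {
  params$qol_population[band_index(age, params)]
}
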