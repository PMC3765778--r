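# shared, lazily built objects (expensive steps computed once per run)
.cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, force(expr), envir = .cache)
  get(name, envir = .cache)
}

test_fixtures <- function() cached("fx", load_fixture_tables())
test_spec <- function() cached("spec", cohort_spec(test_fixtures()))
test_cohort <- function() {
  cached("cohort", suppressMessages(generate_cohort(test_spec(), seed = 101)))
}
test_included <- function() {
  cached("included",
         stratify_cohort(apply_inclusion_filter(test_cohort())$included))
}
test_groups <- function() {
  cached("groups", {
    summ <- summarize_groups(test_included())
    g <- lapply(seq_len(nrow(summ)),
                function(i) metscea:::group_from_summary(summ[i, ]))
    names(g) <- vapply(g, function(x) paste(x$sex, x$level, sep = "_"),
                       character(1))
    g
  })
}
test_params <- function() cached("params", load_model_params())
test_cal_params <- function() {
  cached("cal", calibrate_baseline_hazards(test_params(), test_groups()))
}

# a reference-level profile (all proportional-hazards multipliers = 1)
ref_profile <- function(...) {
  p <- c(waist = 94, bmi = 27, fg = 5.3, tg = 1.5, hdl = 1.3, chol = 5.0,
         sbp = 125, dbp = 80, smoker = 0)
  over <- c(...)
  p[names(over)] <- over
  p
}

# minimal hand-built parameter set: single age band, hazards/costs set
# explicitly, QoL weight 1 everywhere unless overridden
toy_params <- function(h0 = list(), other = 0, qol = 1,
                       mult = c(WELL = 1, T2D = 1, T2D_COMPL = 1, CVD = 1,
                                T2D_CVD = 1),
                       cost_societal = numeric(0),
                       cost_healthcare = numeric(0),
                       coef = NULL, termination_age = 85) {
  tr <- metscea:::TRANSITIONS
  states <- metscea:::STATES
  K <- nrow(tr)
  h0m <- matrix(0, 1, K, dimnames = list(NULL, tr$name))
  for (nm in names(h0)) h0m[, nm] <- h0[[nm]]
  if (is.null(coef)) {
    coef <- matrix(0, K, length(metscea:::HAZ_FIELDS),
                   dimnames = list(tr$name, metscea:::HAZ_FIELDS))
  }
  cs <- ch <- stats::setNames(numeric(7), states)
  cs[names(cost_societal)] <- cost_societal
  ch[names(cost_healthcare)] <- cost_healthcare
  structure(list(
    age_band_starts = 0,
    h0 = list(M = h0m, F = h0m),
    coef = coef,
    reference_profile = ref_profile(),
    other_cause = list(M = other, F = other),
    qol_population = qol,
    qol_multipliers = mult,
    state_costs = rbind(societal = cs, healthcare = ch),
    termination_age = termination_age,
    cycle_length = 1,
    hazard_scale = 1
  ), class = "model_params")
}

toy_group <- function(profile = ref_profile(), age = 55, sex = "M",
                      p_t2d = 0, p_mi = 0, m12 = profile, level = "high") {
  list(sex = sex, level = level, n = 1, age = age,
       profile_start = profile, profile_12m = m12,
       p_t2d = p_t2d, p_mi = p_mi)
}
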