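#' Sustainability scenarios for intervention effects
#'
#' How long the risk-factor improvements measured at 12 months persist beyond
#' the follow-up. The base assumption keeps the 12-month levels for a second
#' year, then lets them decay linearly back to start levels by the 5th year.
#' `low` keeps the effect for the first year only (start levels from year 2);
#' `high` keeps the 12-month levels for life. `custom` takes the two year
#' parameters directly.
#'
#' @param name one of `"base"`, `"low"`, `"high"`, `"custom"`
#' @param full_effect_years last cycle with the full effect (custom only)
#' @param washout_end_year first cycle with zero effect (custom only); must
#'   exceed `full_effect_years`
#' @return list with class `"sustainability_scenario"`
#' @export
#' @examples
#' sustainability_scenario("base")
#' sustainability_scenario("custom", full_effect_years = 3, washout_end_year = 8)
sustainability_scenario <- function(name = c("base", "low", "high", "custom"),
                                    full_effect_years = NULL,
                                    washout_end_year = NULL) {
  name <- match.arg(name)
  par <- switch(name,
    base = list(full = 2, end = 5),
    low  = list(full = 1, end = 2),
    high = list(full = Inf, end = Inf),
    custom = {
      if (is.null(full_effect_years) || is.null(washout_end_year) ||
          washout_end_year <= full_effect_years) {
        stop("custom scenario needs washout_end_year > full_effect_years",
             call. = FALSE)
      }
      list(full = full_effect_years, end = washout_end_year)
    })
  structure(list(name = name, full_effect_years = par$full,
                 washout_end_year = par$end),
            class = "sustainability_scenario")
}

as_scenario <- function(x) {
  if (inherits(x, "sustainability_scenario")) x else sustainability_scenario(x)
}

#' Intervention-effect weight at a model cycle
#'
#' Weight w(t) in `[0, 1]` multiplying the 12-month improvement at integer
#' cycle t (cycle 1 = first year after the baseline measurement): 1 while the
#' effect is fully retained, 0 from the washout end, linear in between.
#'
#' @param t_years cycle index (integer >= 1); vectorized
#' @param scenario a [sustainability_scenario()] or its name
#' @return numeric weight(s) in `[0, 1]`
#' @export
#' @examples
#' sustainability_weight(1:6, "base")  # 1 1 2/3 1/3 0 0
sustainability_weight <- function(t_years, scenario = "base") {
  sc <- as_scenario(scenario)
  if (any(t_years < 1)) {
    stop("sustainability_weight: cycle index must be >= 1", call. = FALSE)
  }
  if (is.infinite(sc$full_effect_years)) return(rep(1, length(t_years)))
  w <- ifelse(t_years <= sc$full_effect_years, 1,
              ifelse(t_years >= sc$washout_end_year, 0,
                     (sc$washout_end_year - t_years) /
                       (sc$washout_end_year - sc$full_effect_years)))
  pmin(1, pmax(0, w))
}

#' Effective risk-factor profile at a model cycle
#'
#' Interpolates every continuous field between the start and 12-month
#' profiles: x(t) = x_start + w(t) * (x_12m - x_start). Binary fields
#' (smoking, diagnoses) are taken from the start profile; no 12-month change
#' is modelled for them.
#'
#' @param start,m12 field-compatible profiles (named vectors or
#'   [risk_profile()] lists)
#' @param t cycle index >= 1
#' @inheritParams sustainability_weight
#' @return a named numeric vector over the continuous fields (plus `smoker`
#'   when present in `start`)
#' @export
profile_at_cycle <- function(start, m12, t, scenario = "base") {
  w <- sustainability_weight(t, scenario)
  s <- unlist(start[intersect(names(start), HAZ_FIELDS)])
  m <- unlist(m12[intersect(names(m12), HAZ_FIELDS)])
  out <- s
  shared <- intersect(names(s), names(m))
  cont <- setdiff(shared, "smoker")
  out[cont] <- s[cont] + w * (m[cont] - s[cont])
  out
}
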