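#' Discounting
#'
#' Annual discounting of costs and QALYs at rate r: the factor applied to a
#' quantity accruing t years from baseline is (1 + r)^(-t). The study default
#' is 3% per year, with 0% and 5% as sensitivity settings.
#'
#' @param rate annual discount rate (proportion, >= 0)
#' @return list with class `"discount_spec"`
#' @export
discount_spec <- function(rate = 0.03) {
  if (!is.numeric(rate) || rate < 0) {
    stop("discount_spec: rate must be >= 0", call. = FALSE)
  }
  structure(list(rate = rate), class = "discount_spec")
}

#' @rdname discount_spec
#' @param t time in years (>= 0); vectorized
#' @param spec a [discount_spec()] or a bare rate
#' @export
#' @examples
#' discount_factor(10, discount_spec(0.03))  # 1.03^-10 = 0.74409...
discount_factor <- function(t, spec = discount_spec()) {
  r <- if (inherits(spec, "discount_spec")) spec$rate else spec
  if (any(t < 0)) stop("discount_factor: t must be >= 0", call. = FALSE)
  (1 + r)^(-t)
}

#' Convert Swedish krona to euro
#'
#' @param amount_sek amount in SEK (2012 price level)
#' @param rate_sek_per_eur exchange rate; the study's 2012 rate is 8.71
#' @return amount in EUR
#' @export
#' @examples
#' sek_to_eur(871)  # 100
sek_to_eur <- function(amount_sek, rate_sek_per_eur = 8.71) {
  stopifnot(rate_sek_per_eur > 0)
  amount_sek / rate_sek_per_eur
}

#' Per-patient program cost
#'
#' The study's per-patient intervention costs in EUR 2012: 2,810 from the
#' societal perspective and 2,300 from the healthcare perspective. The
#' published cost-per-QALY rows from the healthcare perspective are
#' arithmetically consistent with approximately 2,258.5; setting
#' `table5_consistent = TRUE` uses that implied value instead of the printed
#' figure.
#'
#' @param societal,healthcare per-patient cost by perspective, EUR
#' @param table5_consistent use the healthcare cost implied by the published
#'   results table rather than the printed rounded figure
#' @return named list with class `"program_cost"`
#' @export
program_cost <- function(societal = 2810, healthcare = 2300,
                         table5_consistent = FALSE) {
  if (table5_consistent) healthcare <- 2258.5
  if (societal < healthcare) {
    stop("program_cost: societal cost must be >= healthcare cost",
         call. = FALSE)
  }
  stopifnot(societal > 0, healthcare > 0)
  structure(list(societal = societal, healthcare = healthcare),
            class = "program_cost")
}

#' Per-patient program cost from itemized resource use
#'
#' Values resource-use lines with the unit-value table: wage lines are
#' inflated by an overhead share (office space, equipment); patient time and
#' fee lines count only under the societal perspective; the total is divided
#' by the number of participating patients. Patient time is valued at a
#' leisure rate (35% of the average wage in the source table).
#'
#' @param items data frame with columns `resource` and `units`
#' @param unit_values the resource valuation table (`table3` fixture format:
#'   `resource`, `value_eur`, `is_wage`, `societal_only`)
#' @param wage_overhead overhead share added to wage lines
#' @param perspective `"societal"` or `"healthcare"`
#' @param n_patients divisor for the per-patient figure
#' @return per-patient cost in EUR
#' @export
program_cost_from_items <- function(items,
                                    unit_values = load_fixture_tables()$table3,
                                    wage_overhead = 0.20,
                                    perspective = c("societal", "healthcare"),
                                    n_patients = 1) {
  perspective <- match.arg(perspective)
  idx <- match(items$resource, unit_values$resource)
  if (anyNA(idx)) {
    stop("program_cost_from_items: unknown resource(s): ",
         paste(items$resource[is.na(idx)], collapse = ", "),
         "; known resources: ",
         paste(unit_values$resource, collapse = ", "), call. = FALSE)
  }
  v <- unit_values[idx, ]
  line <- items$units * v$value_eur * ifelse(v$is_wage, 1 + wage_overhead, 1)
  if (perspective == "healthcare") line[v$societal_only] <- 0
  sum(line) / n_patients
}

#' Net cost against the do-nothing comparator
#'
#' The comparator is assumed to carry zero costs and zero health effects, so
#' the net cost is the per-patient program cost minus the future (lifetime,
#' discounted) cost saving the program induces. A positive saving means
#' future costs fall.
#'
#' @param program_cost per-patient program cost, EUR
#' @param future_cost_saving per-patient discounted future cost decrease, EUR
#' @return net cost, EUR
#' @export
#' @examples
#' net_cost(2810, 2446)  # 364
net_cost <- function(program_cost, future_cost_saving) {
  program_cost - future_cost_saving
}

#' ICER verdict on the incremental cost-effectiveness plane
#'
#' Positive QALY gain with positive net cost gives an ICER (reported to whole
#' EUR); positive gain at zero or negative net cost is cost-saving (printed
#' `"<0"` in the study's notation); a QALY loss is dominated (printed `"-"`);
#' zero QALY change with a non-zero cost leaves the ratio undefined.
#'
#' @param net_cost net cost vs do-nothing, EUR
#' @param delta_qaly incremental QALYs
#' @return list with `verdict` (`"icer"`, `"cost_saving"`, `"dominated"` or
#'   `"undefined"`) and `icer` (EUR/QALY, `NA` unless verdict is `"icer"`)
#' @export
#' @examples
#' icer(469, 0.13)    # 3608 EUR/QALY
#' icer(-153, 0.14)   # cost-saving
#' icer(1229, -0.004) # dominated
icer <- function(net_cost, delta_qaly) {
  if (delta_qaly > 0 && net_cost > 0) {
    list(verdict = "icer", icer = round(net_cost / delta_qaly))
  } else if (delta_qaly > 0) {
    list(verdict = "cost_saving", icer = NA_real_)
  } else if (delta_qaly < 0) {
    list(verdict = "dominated", icer = NA_real_)
  } else {
    list(verdict = if (net_cost == 0) "zero" else "undefined",
         icer = NA_real_)
  }
}

#' Assemble the cost-effectiveness table
#'
#' Builds one row per group and perspective from paired simulation outputs
#' (see [run_group_pair()]): incremental QALYs are the paired mean difference
#' (12m - start), future savings the paired mean cost difference
#' (start - 12m), the net cost adds the program cost, and the ICER verdict is
#' attached. Alternatively `from_fixture` accepts the published future-cost
#' table so the CEA arithmetic can be reproduced without simulation.
#'
#' @param pairs named list of [run_group_pair()] outputs (names like
#'   `"M_low"`), or `NULL` when `from_fixture` is given
#' @param cost a [program_cost()]
#' @param perspectives character subset of `c("societal", "healthcare")`
#' @param from_fixture optional `table4`-format tibble (`sex`, `level`,
#'   `measure` in `yll/qaly/cost_societal/cost_healthcare`, `start`, `m12`,
#'   `diff`)
#' @return tibble with `sex`, `level`, `perspective`, `delta_qaly`,
#'   `future_saving`, `net_cost`, `verdict`, `icer`
#' @export
cea_table <- function(pairs = NULL, cost = program_cost(),
                      perspectives = c("societal", "healthcare"),
                      from_fixture = NULL) {
  rows <- list()
  if (!is.null(from_fixture)) {
    t4 <- from_fixture
    combos <- unique(t4[c("sex", "level")])
    for (i in seq_len(nrow(combos))) {
      sx <- combos$sex[i]; lv <- combos$level[i]
      pick <- function(ms, col) {
        t4[[col]][t4$sex == sx & t4$level == lv & t4$measure == ms]
      }
      dq <- pick("qaly", "diff")
      for (persp in perspectives) {
        saving <- -pick(paste0("cost_", persp), "diff")
        nc <- net_cost(cost[[persp]], saving)
        v <- icer(nc, dq)
        rows[[length(rows) + 1]] <- tibble::tibble(
          sex = sx, level = lv, perspective = persp, delta_qaly = dq,
          future_saving = saving, net_cost = nc, verdict = v$verdict,
          icer = v$icer)
      }
    }
  } else {
    if (is.null(names(pairs)) || any(!nzchar(names(pairs)))) {
      stop("cea_table: pairs must be a named list", call. = FALSE)
    }
    for (nm in names(pairs)) {
      pr <- pairs[[nm]]
      if (is.null(pr$delta)) stop("cea_table: missing arm pair for group ",
                                  nm, call. = FALSE)
      g <- pr$group
      sx <- if (!is.null(g)) g$sex else sub("_.*", "", nm)
      lv <- if (!is.null(g)) g$level else sub("^[^_]*_", "", nm)
      for (persp in perspectives) {
        saving <- pr$delta[[paste0("saving_", persp)]]
        nc <- net_cost(cost[[persp]], saving)
        v <- icer(nc, pr$delta$delta_qaly)
        rows[[length(rows) + 1]] <- tibble::tibble(
          sex = sx, level = lv, perspective = persp,
          delta_qaly = pr$delta$delta_qaly, future_saving = saving,
          net_cost = nc, verdict = v$verdict, icer = v$icer)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Format a CEA table in the study's notation
#'
#' Cost-saving cells print `"<0"` and dominated cells `"-"`, matching the
#' published table conventions; ICERs are whole EUR.
#'
#' @param tab a [cea_table()] result
#' @return tibble with character `net_cost` and `cost_per_qaly` columns
#' @export
format_cea <- function(tab) {
  tibble::tibble(
    sex = tab$sex, level = tab$level, perspective = tab$perspective,
    qalys = round(tab$delta_qaly, 2),
    net_cost = ifelse(tab$verdict == "cost_saving", "<0",
                      as.character(round(tab$net_cost))),
    cost_per_qaly = dplyr::case_when(
      tab$verdict == "icer" ~ as.character(tab$icer),
      tab$verdict == "cost_saving" ~ "<0",
      tab$verdict == "dominated" ~ "-",
      TRUE ~ "n/a")
  )
}
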