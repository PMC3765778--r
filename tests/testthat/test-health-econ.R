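test_that("discounting follows (1+r)^-t", {
  expect_equal(discount_factor(0, discount_spec(0.03)), 1)
  expect_equal(discount_factor(10, discount_spec(0)), 1)
  expect_equal(discount_factor(10, discount_spec(0.03)), 0.74409,
               tolerance = 1e-5)
  expect_equal(discount_factor(10, 0.03), 1.03^-10)
  # strictly decreasing for r > 0, identity at r = 0
  t <- 0:30
  expect_true(all(diff(discount_factor(t, 0.05)) < 0))
  expect_true(all(discount_factor(t, 0) == 1))
  expect_error(discount_factor(-1, 0.03), ">= 0")
  expect_error(discount_spec(-0.01), ">= 0")
})

test_that("currency conversion uses the configured exchange rate", {
  expect_equal(sek_to_eur(8.71), 1)
  expect_equal(sek_to_eur(0), 0)
  expect_equal(sek_to_eur(871), 100)
  expect_equal(sek_to_eur(100, rate_sek_per_eur = 10), 10)
})

test_that("itemized program costing applies overheads and perspectives", {
  uv <- test_fixtures()$table3
  # wage lines carry the 20% overhead
  gp <- data.frame(resource = "general_practitioner", units = 1)
  expect_equal(program_cost_from_items(gp, uv), 54 * 1.2)
  # patient time is valued only under the societal perspective
  pt <- data.frame(resource = "time", units = 1)
  expect_equal(program_cost_from_items(pt, uv, perspective = "societal"), 6)
  expect_equal(program_cost_from_items(pt, uv, perspective = "healthcare"), 0)
  # empty item lists cost nothing; unknown resources are rejected with the
  # catalogue in the message
  empty <- data.frame(resource = character(0), units = numeric(0))
  expect_equal(program_cost_from_items(empty, uv), 0)
  expect_error(program_cost_from_items(
    data.frame(resource = "helicopter", units = 1), uv),
    "unknown resource.*helicopter")
  # per-patient division
  mix <- data.frame(resource = c("general_practitioner", "lunch"),
                    units = c(10, 20))
  expect_equal(program_cost_from_items(mix, uv, n_patients = 4),
               (10 * 54 * 1.2 + 20 * 9) / 4)
})

test_that("net costs and ICER verdicts reproduce the published arithmetic", {
  expect_equal(net_cost(2810, 2446), 364)
  expect_equal(net_cost(2810, 2963), -153)
  expect_equal(net_cost(0, 0), 0)
  expect_equal(icer(469, 0.13), list(verdict = "icer", icer = 3608))
  expect_equal(icer(-153, 0.14)$verdict, "cost_saving")
  expect_equal(icer(1229, -0.004)$verdict, "dominated")
  expect_equal(icer(100, 0)$verdict, "undefined")
  expect_true(is.na(icer(100, 0)$icer))
})

test_that("the verdict partition is exhaustive and mutually exclusive", {
  grid <- expand.grid(nc = c(-100, 0, 250), dq = c(-0.1, 0, 0.2))
  verdicts <- mapply(function(nc, dq) icer(nc, dq)$verdict, grid$nc, grid$dq)
  expect_true(all(verdicts %in%
                    c("icer", "cost_saving", "dominated", "undefined",
                      "zero")))
  expect_equal(sum(verdicts == "icer"), 1)        # nc>0, dq>0
  expect_equal(sum(verdicts == "cost_saving"), 2) # nc<=0, dq>0
  expect_equal(sum(verdicts == "dominated"), 3)   # dq<0
})

test_that("the CEA table built from the reference tables matches print", {
  fx <- test_fixtures()
  tab <- cea_table(cost = program_cost(), from_fixture = fx$table4)
  row <- function(sx, lv, p) {
    tab[tab$sex == sx & tab$level == lv & tab$perspective == p, ]
  }
  ml <- row("M", "low", "societal")
  expect_equal(ml$delta_qaly, 0.05)
  expect_equal(ml$net_cost, 364)
  fm <- row("F", "medium", "societal")
  expect_equal(fm$net_cost, 469)
  expect_equal(fm$icer, 3608)
  # women high societal: 2810 - 1354 = 1456, documented +-1 EUR vs print
  fh <- row("F", "high", "societal")
  expect_equal(fh$net_cost, 1456)
  expect_lte(abs(fh$net_cost - 1455), 1)
  # men medium and high societal are cost-saving
  expect_equal(row("M", "medium", "societal")$verdict, "cost_saving")
  expect_equal(row("M", "high", "societal")$verdict, "cost_saving")
  # perspective bookkeeping: components sum exactly
  for (i in seq(1, nrow(tab), by = 2)) {
    soc <- tab[i, ]; hc <- tab[i + 1, ]
    expect_equal(soc$net_cost - hc$net_cost,
                 (2810 - 2300) - (soc$future_saving - hc$future_saving))
  }
})

test_that("formatted output uses the study's cell notation", {
  fx <- test_fixtures()
  tab <- cea_table(cost = program_cost(), from_fixture = fx$table4)
  fmt <- format_cea(tab)
  expect_equal(
    fmt$net_cost[fmt$sex == "M" & fmt$level == "medium" &
                   fmt$perspective == "societal"], "<0")
  # a QALY-losing pair renders as dominated ("-")
  pr <- list(delta = tibble::tibble(delta_qaly = -0.004,
                                    saving_societal = 1581,
                                    saving_healthcare = 1200),
             group = NULL)
  fmt2 <- format_cea(cea_table(list(M_low = pr), program_cost()))
  expect_equal(fmt2$cost_per_qaly, c("-", "-"))
  expect_equal(fmt2$sex, c("M", "M"))
  expect_equal(fmt2$level, c("low", "low"))
})

test_that("program cost configuration enforces perspective ordering", {
  pc <- program_cost()
  expect_equal(pc$societal, 2810)
  expect_equal(pc$healthcare, 2300)
  expect_equal(program_cost(table5_consistent = TRUE)$healthcare, 2258.5)
  expect_error(program_cost(societal = 2000, healthcare = 2300), ">=")
})
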