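land <- land_fixture()

test_that("health gains follow the static model per stratum", {
  expect_equal(unname(health_gains(land$strata, land$policy)),
               c(128, 96, 64, 32, 0))
  # null intervention
  p0 <- land$policy; p0$effectiveness <- 0
  expect_equal(unname(health_gains(land$strata, p0)), rep(0, 5))
  # random scenarios equal the one-line elementwise oracle
  for (seed in c(7, 21)) {
    sc <- generate_synthetic_scenario(seed, 4, burden = "pro_poor")
    s <- sc$strata; p <- sc$policy
    oracle <- p$effectiveness * (p$cov_policy - p$cov_baseline) *
      s$case_fatality * s$incidence * s$population
    expect_equal(unname(health_gains(s, p)), oracle)
  }
  # total-coverage semantics multiply by cov_policy instead of the increment
  expect_equal(unname(health_gains(land$strata, land$policy, coverage = "total")),
               0.8 * 0.6 * 0.2 * c(8000, 6000, 4000, 2000, 0))
  # disinvestment warns and goes negative, not an error
  pd <- suppressWarnings(ecea_policy("d", 0.6, 0.5, 0.8, 10))
  expect_warning(g <- health_gains(land$strata, pd), "disinvestment")
  expect_true(all(g <= 0))
})

test_that("private expenditures and their aversion reproduce the worked example", {
  expect_equal(unname(private_expenditures(land$strata)),
               c(320000, 240000, 160000, 80000, 0))
  expect_equal(unname(private_expenditures_averted(land$strata, land$policy)),
               c(320000, 240000, 160000, 80000, 0))
  # zero per-case cost gives zero
  s0 <- land$strata; s0$c_dm <- 0; s0$c_dnm <- 0
  expect_equal(unname(private_expenditures(s0)), rep(0, 5))
  # the optional indirect cost adds c_i per paying case
  si <- land$strata; si$c_i <- 50
  expect_equal(unname(private_expenditures(si, include_indirect = TRUE)),
               unname(caseload(si)) * 0.4 * 150)
  expect_equal(private_expenditures(si), private_expenditures(land$strata))
  # crowd-out scaling and the coverage-literal convention
  ph <- land$policy; ph$crowd_out <- 0
  expect_equal(unname(private_expenditures_averted(land$strata, ph)), rep(0, 5))
  pc <- land$policy; pc$pe_convention <- "coverage"
  expect_equal(unname(private_expenditures_averted(land$strata, pc)),
               0.6 * c(320000, 240000, 160000, 80000, 0))
})

test_that("net costs price the costed caseload and net out offsets", {
  expect_equal(unname(net_costs(land$strata, land$policy)),
               c(400000, 300000, 200000, 100000, 0))
  p0 <- land$policy; p0$unit_cost <- 0
  expect_equal(unname(net_costs(land$strata, p0)), rep(0, 5))
  # cov_costing defaults to cov_policy
  pd <- land$policy; pd$cov_costing <- NULL
  expect_equal(unname(net_costs(land$strata, pd)),
               0.6 * unname(caseload(land$strata)) * 100)
  # preventive offsets, against a direct arithmetic oracle
  pp <- land$policy; pp$cost_offsets <- 25
  oracle <- 0.5 * unname(caseload(land$strata)) * 100 -
    25 * 0.8 * 0.1 * unname(caseload(land$strata))
  expect_equal(unname(net_costs(land$strata, pp)), oracle)
})

test_that("ICERs divide totals and flag degenerate denominators", {
  ic <- icers(1e6, 320, 3200)
  expect_equal(ic$icer_frp, 312.5)
  expect_equal(ic$icer_frp_rounded, 313)
  expect_equal(ic$icer_health, 3125)
  expect_equal(unname(ic$status), c("ok", "ok"))
  ic0 <- icers(1e6, 320, 0)
  expect_true(is.na(ic0$icer_frp))
  expect_identical(ic0$status[["frp"]], "undefined")
  icn <- icers(1e6, -5, 10)
  expect_identical(icn$status[["health"]], "dominated")
  expect_true(is.na(icn$icer_health))
})

test_that("per-budget scaling is linear and identity at the total cost", {
  res <- run_ecea(land)
  s1m <- per_budget_scaling(res, 1e6)
  expect_equal(s1m$totals$health_gains, 320) # C_total is exactly $1M
  s100k <- per_budget_scaling(res, 1e5)
  expect_equal(s100k$totals$health_gains, 32)
  expect_equal(s100k$totals$frp_benefit, s1m$totals$frp_benefit / 10)
  ident <- per_budget_scaling(res, res$totals$net_cost)
  expect_equal(ident$totals, res$totals)
  bad <- res; bad$totals$net_cost <- 0
  expect_error(per_budget_scaling(bad, 1e5), "positive")
})

test_that("engine is linear in population and invariant to stratum order", {
  sc <- generate_synthetic_scenario(5, 5, burden = "pro_poor")
  res <- run_ecea(sc)
  doubled <- sc; doubled$strata$population <- 2 * sc$strata$population
  res2 <- run_ecea(doubled)
  for (f in names(res$totals))
    expect_equal(res2$totals[[f]], 2 * res$totals[[f]])
  expect_equal(res2$icer$icer_health, res$icer$icer_health)
  expect_equal(res2$icer$icer_frp, res$icer$icer_frp)
  # permutation invariance of totals
  perm <- sc
  ord <- c(3, 1, 5, 2, 4)
  perm$strata <- sc$strata[ord, ]
  perm$policy$cov_baseline <- bc_test(sc$policy$cov_baseline, 5)[ord]
  perm$policy$cov_policy <- bc_test(sc$policy$cov_policy, 5)[ord]
  perm$policy$effectiveness <- bc_test(sc$policy$effectiveness, 5)[ord]
  expect_equal(run_ecea(perm)$totals, res$totals)
})

test_that("zero-incidence strata contribute zeros to every panel", {
  res <- run_ecea(land)
  v_row <- res$strata_table[res$strata_table$label == "V", ]
  for (f in c("caseload", "health_gains", "cases_averted", "pe_baseline",
              "pe_averted", "frp_benefit", "net_cost"))
    expect_identical(v_row[[f]], 0)
})
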