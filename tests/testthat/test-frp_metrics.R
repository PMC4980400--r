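land <- land_fixture()

test_that("certainty equivalent matches direct evaluation and its limits", {
  # frozen oracle value: direct power-form evaluation at y=1000, c=100,
  # p=0.1, r=3 gives 988.473986...
  expect_equal(certainty_equivalent(1000, 0.1, 100, 3), 988.4739855,
               tolerance = 1e-7)
  expect_equal(certainty_equivalent(1000, 0.1, 100, 3),
               oracle_ce(1000, 0.1, 100, 3))
  # boundary cases: no risk, certain loss, free care
  expect_identical(certainty_equivalent(1000, 0, 100, 3), 1000)
  expect_identical(certainty_equivalent(1000, 1, 100, 3), 900)
  expect_identical(certainty_equivalent(1000, 0.5, 0, 3), 1000)
  # log-utility limit at r = 1
  expect_equal(certainty_equivalent(1000, 0.1, 100, 1),
               exp(0.1 * log(900) + 0.9 * log(1000)))
  # domain error when the loss exhausts income
  expect_error(certainty_equivalent(90, 0.5, 100, 3), "nonpositive net income")
  # stable at large risk aversion where the naive power form overflows
  expect_true(is.finite(certainty_equivalent(1000, 0.1, 100, 60)))
  expect_lt(certainty_equivalent(1000, 0.1, 100, 60), 1000)
})

test_that("risk premium is non-negative, zero only at degenerate gambles, and monotone", {
  expect_equal(risk_premium(1000, 0.1, 100, 3), 1.5260145, tolerance = 1e-6)
  expect_equal(risk_premium(1000, 0.1, 100, 3),
               oracle_premium(1000, 0.1, 100, 3))
  expect_identical(risk_premium(1000, 0, 100, 3), 0)
  expect_identical(risk_premium(1000, 1, 100, 3), 0)
  expect_identical(risk_premium(1000, 0.5, 0, 3), 0)
  # property sweep: 1e4 random valid gambles, premium always >= 0
  withr::local_seed(99)
  n <- 1e4
  y <- stats::runif(n, 50, 1e5)
  cost <- stats::runif(n) * 0.95 * y
  p <- stats::runif(n)
  r <- stats::runif(n, 0.2, 8)
  prem <- risk_premium(y, p, cost, r)
  expect_true(all(prem >= 0))
  expect_equal(prem, mapply(oracle_premium, y, p, cost, r), tolerance = 1e-8)
  # strictly increasing in r and in cost on fixed grids
  prem_r <- risk_premium(1000, 0.1, 100, c(1, 2, 3, 4))
  expect_true(all(diff(prem_r) > 0))
  prem_c <- risk_premium(1000, 0.1, c(50, 100, 200, 400, 800), 3)
  expect_true(all(diff(prem_c) > 0))
  # continuity at r = 1: power-form values at r = 1 +/- 1e-4 bracket the log form
  lo <- risk_premium(1000, 0.1, 100, 1 - 1e-4)
  hi <- risk_premium(1000, 0.1, 100, 1 + 1e-4)
  mid <- risk_premium(1000, 0.1, 100, 1)
  expect_true(lo <= mid && mid <= hi)
})

test_that("catastrophic counting follows the strict threshold inequality", {
  # single-individual realizations
  expect_equal(catastrophic_cases(300, 100, 0.1), 1)   # 100 > 30
  expect_equal(catastrophic_cases(300, 0, 0.1), 0)     # free care never counts
  expect_equal(catastrophic_cases(1000, 100, 0.1), 0)  # boundary 100 > 100 is FALSE
  # Land point incomes: all 8,000 paying cases at Th = 0.1, none at Th = 0.4
  sc <- land
  sc$frp <- frp_config("catastrophic", threshold = 0.1)
  out <- catastrophic_cases_averted(sc)
  expect_equal(unname(out$per_stratum), c(3200, 2400, 1600, 800, 0))
  expect_equal(out$total, 8000)
  sc$frp <- frp_config("catastrophic", threshold = 0.4)
  expect_equal(catastrophic_cases_averted(sc)$total, 0)  # 100 <= 120 at y=300
  # no crowd-out, no aversion
  sc$frp <- frp_config("catastrophic", threshold = 0.1)
  sc$policy$crowd_out <- 0
  expect_equal(catastrophic_cases_averted(sc)$total, 0)
  # partial crowd-out against the enumeration oracle
  sc$policy$crowd_out <- 0.5
  s <- sc$strata
  paying <- unname(caseload(s)) * s$care_seeking
  pre <- oracle_catastrophic(s$income, paying, 100, 0.1)
  post <- oracle_catastrophic(s$income, paying, 50, 0.1)
  expect_equal(catastrophic_cases_averted(sc)$total, pre - post)
})

test_that("poverty counting reproduces the Land worked example under both readings", {
  # only the middle quintile (y=640) straddles Pl=600 after a $100 payment
  out <- poverty_cases_averted(land)  # fixture's affected fraction: 0.8
  expect_equal(unname(out$per_stratum), c(0, 0, 3200, 0, 0))
  expect_equal(out$total, 3200)
  # the paying-fraction reading gives 0.40 x 4000
  expect_equal(poverty_cases_averted(land, affected_fraction = 0.4)$total, 1600)
  # zero cost, nothing to avert
  sc <- land; sc$strata$c_dm <- 0
  expect_equal(poverty_cases_averted(sc)$total, 0)
  # individuals already below the line never count: poorest quintile at
  # y=300 < 600 contributes nothing even with large costs
  sc <- land; sc$strata$c_dm[1] <- 250
  expect_equal(unname(poverty_cases_averted(sc)$per_stratum)[1], 0)
  # strict inequalities: y == Pl is not a case
  sc <- land; sc$strata$income[3] <- 600
  expect_equal(poverty_cases_averted(sc)$total, 0)
  # enumeration oracle on a synthetic point-income scenario
  sc2 <- toy_scenario("poverty", affected_fraction = 0.6)
  s <- sc2$strata
  oracle <- oracle_poverty(s$income, unname(caseload(s)) * 0.6,
                           s$c_dm + s$c_dnm, 450)
  expect_equal(poverty_cases_averted(sc2)$total, oracle)
})

test_that("counting metrics on a Gamma income model match Monte-Carlo enumeration", {
  model <- gamma_from_mean_gini(640, 0.3)
  strata <- tibble::tibble(
    label = "all", population = 2e6, income = 640,
    incidence = 0.002, case_fatality = 0.2, care_seeking = 0.4,
    c_dm = 100, c_dnm = 0)
  policy <- ecea_policy("upf", 0.5, 0.6, 0.8, 100, crowd_out = 1)
  paying <- 2e6 * 0.002 * 0.4
  withr::local_seed(42)
  draws <- stats::rgamma(2e5, shape = model$shape, scale = model$scale)
  # catastrophic, Th = 0.2
  sc <- ecea_scenario(strata, policy,
                      frp = frp_config("catastrophic", threshold = 0.2),
                      income_model = model)
  got <- catastrophic_cases_averted(sc)$total
  mc <- paying * mean(100 > draws * 0.2)  # crowd_out 1: post count is 0
  expect_lt(abs(got - mc) / mc, 0.01)
  # poverty, Pl = 600
  sc$frp <- frp_config("poverty", poverty_line = 600, affected_fraction = 0.4)
  got_p <- poverty_cases_averted(sc)$total
  mc_p <- paying * mean(draws > 600 & draws - 100 < 600)
  expect_lt(abs(got_p - mc_p) / mc_p, 0.01)
})

test_that("population insurance value aggregates per-stratum premiums", {
  sc <- land
  sc$frp <- frp_config("insurance", risk_aversion = 3, poverty_line = 600)
  out <- insurance_value_population(sc)
  # full crowd-out: population value equals the total pre-policy premium,
  # checked against the per-stratum enumeration oracle
  s <- sc$strata
  p_event <- s$incidence * s$care_seeking
  oracle <- sum(s$population *
                  mapply(oracle_premium, s$income, p_event, 100, 3))
  expect_equal(out$total, oracle)
  expect_equal(unname(out$post), rep(0, 5))
  # no crowd-out, no value
  sc$policy$crowd_out <- 0
  expect_equal(insurance_value_population(sc)$total, 0)
  # benefit monotone in crowd-out
  vals <- vapply(c(0, 0.3, 0.7, 1), function(w) {
    sc$policy$crowd_out <- w
    insurance_value_population(sc)$total
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # prevention mode reduces the event probability and adds value on top of
  # a pure cost-side policy with partial crowd-out
  sc$policy$crowd_out <- 0.5
  base <- insurance_value_population(sc)$total
  sc$frp$prevention <- TRUE
  expect_gt(insurance_value_population(sc)$total, base)
  # incomes at or below the cost are a domain error naming the stratum
  bad <- land
  bad$frp <- frp_config("insurance")
  bad$strata$c_dm[1] <- 300
  expect_error(insurance_value_population(bad), "'I'")
})

test_that("every FRP metric weakly increases with crowd-out", {
  for (metric in c("catastrophic", "poverty", "insurance")) {
    sc <- toy_scenario(metric, affected_fraction = 0.5)
    vals <- vapply(seq(0, 1, by = 0.25), function(w) {
      sc$policy$crowd_out <- w
      frp_benefit(sc)$total
    }, numeric(1))
    expect_true(all(diff(vals) >= 0))
    expect_true(all(vals >= 0))
  }
})
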