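#' Certainty equivalent of the illness-cost gamble under CRRA utility
#'
#' An individual with annual income `y` faces an out-of-pocket cost `cost`
#' with probability `p` (the product of incidence and the paying fraction).
#' Under constant-relative-risk-aversion utility
#' \eqn{w(y) = y^{1-r}/(1-r)} (for `r != 1`), the certainty equivalent is
#' \deqn{y^* = [p (y-c)^{1-r} + (1-p) y^{1-r}]^{1/(1-r)},}
#' and for `r = 1` the logarithmic limit
#' \eqn{y^* = \exp(p \log(y-c) + (1-p)\log y)}. Evaluation goes through
#' logs so large `r` neither overflows nor underflows.
#'
#' @param y income, money per person-year (must exceed `cost` whenever
#'   `p > 0` and `cost > 0`).
#' @param p event probability in \[0, 1\].
#' @param cost out-of-pocket cost, money (>= 0).
#' @param r coefficient of relative risk aversion (> 0; default 3).
#' @return the certainty-equivalent income (vectorized over the inputs).
#' @examples
#' certainty_equivalent(1000, p = 0.1, cost = 100, r = 3)
#' @export
certainty_equivalent <- function(y, p, cost, r = 3) {
  k <- max(length(y), length(p), length(cost), length(r))
  y <- rep_len(as.numeric(y), k); p <- rep_len(as.numeric(p), k)
  cost <- rep_len(as.numeric(cost), k); r <- rep_len(as.numeric(r), k)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (any(cost < 0)) stop("cost must be >= 0", call. = FALSE)
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  out <- numeric(k)
  trivial <- p == 0 | cost == 0
  certain <- p == 1 & !trivial
  out[trivial] <- y[trivial]
  out[certain] <- y[certain] - cost[certain]
  i <- !trivial & !certain
  if (any(i)) {
    if (any(y[i] <= cost[i]))
      stop("utility undefined at nonpositive net income (income <= cost)",
           call. = FALSE)
    yi <- y[i]; pi <- p[i]; ci <- cost[i]; ri <- r[i]
    # log-utility limit of CRRA at r = 1
    ce <- ifelse(ri == 1,
                 exp(pi * log(yi - ci) + (1 - pi) * log(yi)),
                 {
                   a <- (1 - ri) * log(yi - ci)
                   b <- (1 - ri) * log(yi)
                   m <- pmax(a, b)
                   lse <- m + log(pi * exp(a - m) + (1 - pi) * exp(b - m))
                   exp(lse / (1 - ri))
                 })
    out[i] <- ce
  }
  out
}

#' Money-metric value of insurance (risk premium)
#'
#' The expected income under the gamble is
#' \eqn{E(y) = p(y - c) + (1 - p)y}; the risk premium is
#' \eqn{E(y) - y^*} with \eqn{y^*} the [certainty_equivalent()]. By Jensen's
#' inequality it is non-negative everywhere in the valid domain, exactly
#' zero when `p` is 0 or 1 or `cost` is 0, and increases with risk aversion
#' `r` and with `cost`.
#'
#' @inheritParams certainty_equivalent
#' @return the risk premium, money per person-year (vectorized).
#' @export
risk_premium <- function(y, p, cost, r = 3) {
  ey <- p * (y - cost) + (1 - p) * y
  prem <- ey - certainty_equivalent(y, p, cost, r)
  # degenerate gambles carry no risk: exactly zero, no float dust
  prem[p == 0 | p == 1 | cost == 0] <- 0
  # elsewhere the premium is mathematically >= 0; snap round-off at 0
  ifelse(prem < 0 & prem > -1e-9 * pmax(ey, 1), 0, prem)
}

# Expected count of catastrophic cases among `cases` paying cases whose
# incomes follow the (equal-probability) grid `income`: cost strictly
# exceeding threshold * income.
#' Expected catastrophic health-cost cases
#'
#' A case is catastrophic when the out-of-pocket cost strictly exceeds
#' `threshold` times income. Given an equal-probability income grid (a
#' single point income is the degenerate grid) and a number of paying
#' cases, returns the expected count `cases * P(cost > y * threshold)`.
#'
#' @param income numeric vector of equal-probability incomes.
#' @param cost out-of-pocket cost per paying case.
#' @param threshold catastrophic threshold as a fraction of income (> 0).
#' @param cases number of paying cases represented (default 1, giving the
#'   probability itself).
#' @return expected number of catastrophic cases (a real).
#' @export
catastrophic_cases <- function(income, cost, threshold, cases = 1) {
  stopifnot(threshold > 0)
  cases * mean(cost > income * threshold)
}

poverty_cases <- function(income, cost, poverty_line, cases = 1) {
  # strict inequalities: boundary incomes are not cases, and individuals
  # already below the line never count
  cases * mean(income > poverty_line & income - cost < poverty_line)
}

frp_outcome <- function(metric, per_stratum, pre = NULL, post = NULL) {
  structure(list(metric = metric,
                 per_stratum = per_stratum,
                 total = sum(per_stratum),
                 pre = pre, post = post),
            class = "ecea_frp_outcome")
}

#' @export
print.ecea_frp_outcome <- function(x, ...) {
  unit <- if (x$metric == "insurance") "money" else "cases"
  cat(sprintf("FRP metric '%s': total benefit %.6g (%s)\n",
              x$metric, x$total, unit))
  print(x$per_stratum)
  invisible(x)
}

# Per-stratum out-of-pocket cost before/after the policy: crowd-out scales
# down the cost faced by paying cases.
post_policy_cost <- function(cost, policy, n) {
  cost * (1 - policy_field(policy, "crowd_out", n))
}

#' Catastrophic health-cost cases averted by a policy
#'
#' Counts expected catastrophic cases (out-of-pocket cost strictly above
#' `threshold` times income) before and after the policy, integrating over
#' each stratum's income grid, and returns the difference. The policy
#' multiplies paying cases' costs by `1 - crowd_out`.
#'
#' @param scenario an `ecea_scenario` whose `frp$metric` settings supply the
#'   threshold and integration resolution.
#' @return an `ecea_frp_outcome` with per-stratum and total cases averted
#'   plus the pre-/post-policy counts.
#' @export
catastrophic_cases_averted <- function(scenario) {
  s <- scenario$strata
  policy <- the_policy(scenario)
  th <- scenario$frp$threshold
  n <- nrow(s)
  grids <- stratum_income_grids(scenario)
  paying <- caseload(s) * s$care_seeking
  cost <- s$c_dm + s$c_dnm
  cost_post <- post_policy_cost(cost, policy, n)
  pre <- post <- numeric(n)
  for (i in seq_len(n)) {
    pre[i] <- catastrophic_cases(grids[[i]], cost[i], th, paying[i])
    post[i] <- if (cost_post[i] > 0)
      catastrophic_cases(grids[[i]], cost_post[i], th, paying[i]) else 0
  }
  names(pre) <- names(post) <- s$label
  frp_outcome("catastrophic", pre - post, pre, post)
}

#' Poverty cases averted by a policy
#'
#' A poverty case is an individual with income strictly above the poverty
#' line whose income net of the out-of-pocket payment falls strictly below
#' it. Counts expected cases before and after the policy (costs scaled by
#' `1 - crowd_out`) over each stratum's income grid. The exposed caseload
#' per stratum is `caseload * affected_fraction` where the fraction comes
#' from `frp$affected_fraction`, falling back to the stratum's
#' `care_seeking`.
#'
#' @inheritParams catastrophic_cases_averted
#' @param affected_fraction optional override of the exposed-case fraction.
#' @return an `ecea_frp_outcome` (expected counts; rounding is left to
#'   reporting).
#' @export
poverty_cases_averted <- function(scenario, affected_fraction = NULL) {
  s <- scenario$strata
  policy <- the_policy(scenario)
  pl <- scenario$frp$poverty_line
  if (is.null(pl) || pl <= 0)
    stop("poverty metric requires frp poverty_line > 0", call. = FALSE)
  n <- nrow(s)
  frac <- affected_fraction %||% scenario$frp$affected_fraction %||% s$care_seeking
  frac <- bc(frac, n, "affected_fraction")
  grids <- stratum_income_grids(scenario)
  exposed <- caseload(s) * frac
  cost <- s$c_dm + s$c_dnm
  cost_post <- post_policy_cost(cost, policy, n)
  pre <- post <- numeric(n)
  for (i in seq_len(n)) {
    pre[i] <- poverty_cases(grids[[i]], cost[i], pl, exposed[i])
    post[i] <- if (cost_post[i] > 0)
      poverty_cases(grids[[i]], cost_post[i], pl, exposed[i]) else 0
  }
  names(pre) <- names(post) <- s$label
  frp_outcome("poverty", pre - post, pre, post)
}

#' Population money-metric insurance value of a policy
#'
#' For every individual (each stratum's income grid point), the risk
#' premium of the illness-cost gamble is computed before the policy
#' (probability `incidence * care_seeking`, cost `c_dm + c_dnm`) and after
#' (cost scaled by `1 - crowd_out`; with `frp$prevention = TRUE` the event
#' probability is additionally scaled by `1 - effectiveness * coverage
#' increment`). The policy's insurance value is the population-weighted sum
#' of the premium reductions.
#'
#' @inheritParams catastrophic_cases_averted
#' @return an `ecea_frp_outcome` with per-stratum money values; `pre` and
#'   `post` hold the population premiums before and after.
#' @export
insurance_value_population <- function(scenario) {
  s <- scenario$strata
  policy <- the_policy(scenario)
  r <- scenario$frp$risk_aversion
  n <- nrow(s)
  grids <- stratum_income_grids(scenario)
  p_event <- s$incidence * s$care_seeking
  cost <- s$c_dm + s$c_dnm
  cost_post <- post_policy_cost(cost, policy, n)
  p_post <- if (scenario$frp$prevention)
    p_event * pmax(0, 1 - policy_field(policy, "effectiveness", n) *
                     coverage_delta(policy, n))
  else p_event
  pre <- post <- numeric(n)
  for (i in seq_len(n)) {
    g <- grids[[i]]
    if (p_event[i] > 0 && cost[i] > 0 && any(g <= cost[i]))
      stop(sprintf("stratum '%s': income at or below out-of-pocket cost; insurance metric undefined",
                   s$label[i]), call. = FALSE)
    pre[i] <- s$population[i] * mean(risk_premium(g, p_event[i], cost[i], r))
    post[i] <- s$population[i] * mean(risk_premium(g, p_post[i], cost_post[i], r))
  }
  names(pre) <- names(post) <- s$label
  frp_outcome("insurance", pre - post, pre, post)
}

#' Financial-risk-protection benefit of a scenario
#'
#' Dispatches to the metric selected in the scenario's [frp_config()]:
#' catastrophic cases averted, poverty cases averted, or the population
#' insurance value.
#'
#' @inheritParams catastrophic_cases_averted
#' @return an `ecea_frp_outcome`.
#' @export
frp_benefit <- function(scenario) {
  switch(scenario$frp$metric,
         catastrophic = catastrophic_cases_averted(scenario),
         poverty = poverty_cases_averted(scenario),
         insurance = insurance_value_population(scenario))
}
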