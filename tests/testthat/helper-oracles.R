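# Independent oracles used across the suite. These deliberately recompute
# quantities by brute force or simulation, not by calling the package's own
# code paths.

# Sample Gini from draws via the sorted-index identity, equivalent to the
# mean absolute pairwise difference divided by twice the mean.
mc_gini <- function(x) {
  n <- length(x)
  x <- sort(x)
  2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
}

# Direct evaluation of the CRRA certainty equivalent (naive power form).
oracle_ce <- function(y, p, cost, r) {
  if (r == 1) exp(p * log(y - cost) + (1 - p) * log(y))
  else (p * (y - cost)^(1 - r) + (1 - p) * y^(1 - r))^(1 / (1 - r))
}
oracle_premium <- function(y, p, cost, r) {
  p * (y - cost) + (1 - p) * y - oracle_ce(y, p, cost, r)
}

# Brute-force expected counting-metric cases over a set of point incomes
# (one income per stratum), given per-stratum paying-case counts.
oracle_catastrophic <- function(incomes, cases, cost, th) {
  sum(cases * as.numeric(cost > incomes * th))
}
oracle_poverty <- function(incomes, cases, cost, pl) {
  sum(cases * as.numeric(incomes > pl & incomes - cost < pl))
}

bc_test <- function(x, n) if (length(x) == 1) rep(x, n) else x

# A small fully-valid hand-built scenario distinct from the packaged one.
toy_scenario <- function(metric = "catastrophic", ...) {
  strata <- tibble::tibble(
    label = c("a", "b", "c"),
    population = c(1e5, 2e5, 3e5),
    income = c(400, 900, 2000),
    incidence = c(0.01, 0.005, 0.002),
    case_fatality = 0.1,
    care_seeking = 0.5,
    c_dm = 80, c_dnm = 20, c_i = 0)
  policy <- ecea_policy("toy", cov_baseline = 0.3, cov_policy = 0.5,
                        effectiveness = 0.7, unit_cost = 50, crowd_out = 1)
  ecea_scenario(strata, policy,
                frp = frp_config(metric, threshold = 0.2, poverty_line = 450,
                                 ...),
                name = "toy")
}
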