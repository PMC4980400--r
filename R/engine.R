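#' Expected annual caseload per stratum
#'
#' @param strata the strata table of an `ecea_scenario`.
#' @return numeric vector, `incidence * population`, named by stratum label.
#' @export
caseload <- function(strata) {
  stats::setNames(strata$incidence * strata$population, strata$label)
}

policy_field <- function(policy, field, n) bc(policy[[field]], n, field)

# Coverage increment that drives health gains: the default "delta" semantics
# use the increase cov_policy - cov_baseline; "total" uses cov_policy.
coverage_delta <- function(policy, n, coverage = c("delta", "total")) {
  coverage <- match.arg(coverage)
  cp <- policy_field(policy, "cov_policy", n)
  if (coverage == "total") cp
  else cp - policy_field(policy, "cov_baseline", n)
}

#' Per-stratum health gains (deaths averted)
#'
#' Under the static disease model, deaths averted in stratum k are
#' `effectiveness * coverage-increment * case_fatality * caseload`, where
#' the caseload is `incidence * population`. The default coverage semantics
#' use the coverage increase `cov_policy - cov_baseline`; `coverage =
#' "total"` instead applies the full post-policy coverage.
#'
#' @param strata strata table.
#' @param policy an [ecea_policy()].
#' @param coverage `"delta"` (default) or `"total"`.
#' @return numeric vector of expected deaths averted per stratum (exact
#'   reals; no rounding). Negative values, with a warning, under
#'   disinvestment (coverage reduction).
#' @examples
#' land <- land_fixture()
#' health_gains(land$strata, land$policy)  # 128 96 64 32 0
#' @export
health_gains <- function(strata, policy, coverage = c("delta", "total")) {
  n <- nrow(strata)
  dcov <- coverage_delta(policy, n, coverage)
  if (any(dcov < 0))
    warning("negative coverage increment: health gains are negative (disinvestment)",
            call. = FALSE)
  eff <- policy_field(policy, "effectiveness", n)
  stats::setNames(eff * dcov * strata$case_fatality * caseload(strata),
                  strata$label)
}

#' Per-stratum disease cases averted
#'
#' `effectiveness * coverage-increment * caseload`; the case-level analogue
#' of [health_gains()] (no case-fatality factor), used for preventive cost
#' offsets.
#'
#' @inheritParams health_gains
#' @return numeric vector of expected cases averted per stratum.
#' @export
cases_averted <- function(strata, policy, coverage = c("delta", "total")) {
  n <- nrow(strata)
  eff <- policy_field(policy, "effectiveness", n)
  stats::setNames(eff * coverage_delta(policy, n, coverage) * caseload(strata),
                  strata$label)
}

#' Baseline private out-of-pocket expenditures per stratum
#'
#' Annual private expenditures in stratum k:
#' `incidence * population * care_seeking * (c_dm + c_dnm)`. Indirect costs
#' `c_i` are excluded by default and added per paying case when
#' `include_indirect = TRUE`.
#'
#' @param strata strata table.
#' @param include_indirect include `c_i` in the per-case cost (default
#'   `FALSE`).
#' @return numeric vector, money per stratum per year.
#' @export
private_expenditures <- function(strata, include_indirect = FALSE) {
  cost <- strata$c_dm + strata$c_dnm + if (include_indirect) strata$c_i else 0
  stats::setNames(caseload(strata) * strata$care_seeking * cost, strata$label)
}

#' Private expenditures averted by the policy
#'
#' Under the default `"crowd_out"` convention the policy removes
#' `crowd_out` times the baseline private expenditures (full public finance
#' with `crowd_out = 1` averts them all). Under the `"coverage"` convention
#' it averts `cov_policy` times the baseline. The convention is carried on
#' the policy (`pe_convention`).
#'
#' @inheritParams private_expenditures
#' @param policy an [ecea_policy()].
#' @return numeric vector, money averted per stratum per year.
#' @examples
#' land <- land_fixture()
#' private_expenditures_averted(land$strata, land$policy)  # total $800,000
#' @export
private_expenditures_averted <- function(strata, policy,
                                         include_indirect = FALSE) {
  n <- nrow(strata)
  pe <- private_expenditures(strata, include_indirect)
  mult <- switch(policy$pe_convention,
                 crowd_out = policy_field(policy, "crowd_out", n),
                 coverage = policy_field(policy, "cov_policy", n))
  pe * mult
}

#' Net implementer costs per stratum
#'
#' The policy maker finances treatment for the costed caseload at
#' `unit_cost` per case; preventive savings (`cost_offsets` per averted
#' case) are netted out. The costed caseload is `cov_costing * caseload`,
#' where `cov_costing` defaults to the post-policy coverage but can be set
#' separately (the Land example prices coverage of 50% of cases while the
#' policy coverage is 60%).
#'
#' @inheritParams health_gains
#' @return numeric vector, money per stratum per year.
#' @examples
#' land <- land_fixture()
#' net_costs(land$strata, land$policy)  # total $1,000,000
#' @export
net_costs <- function(strata, policy) {
  n <- nrow(strata)
  cov_cost <- policy$cov_costing %||% policy$cov_policy
  covered <- bc(cov_cost, n, "cov_costing") * caseload(strata)
  gross <- covered * policy_field(policy, "unit_cost", n)
  offsets <- policy_field(policy, "cost_offsets", n) *
    cases_averted(strata, policy)
  stats::setNames(gross - offsets, strata$label)
}

#' Incremental cost-effectiveness ratios
#'
#' `icer_health = C_total / deaths averted`; `icer_frp = C_total / FRP
#' benefit` — the price of one unit of financial risk protection. A zero
#' denominator yields status `"undefined"`, a negative one `"dominated"`;
#' the ratio is then `NA`, never infinity.
#'
#' @param total_cost total net implementer cost.
#' @param total_health total deaths averted.
#' @param total_frp total FRP benefit.
#' @return a list with `icer_health`, `icer_frp`, their half-up roundings to
#'   whole currency units (`icer_health_rounded`, `icer_frp_rounded`) and
#'   per-ratio `status` (`"ok"`, `"undefined"`, `"dominated"`).
#' @export
icers <- function(total_cost, total_health, total_frp) {
  one <- function(denom) {
    if (denom == 0) list(value = NA_real_, status = "undefined")
    else if (denom < 0) list(value = NA_real_, status = "dominated")
    else list(value = total_cost / denom, status = "ok")
  }
  h <- one(total_health); f <- one(total_frp)
  list(icer_health = h$value,
       icer_frp = f$value,
       icer_health_rounded = if (is.na(h$value)) NA_real_ else round_half_up(h$value),
       icer_frp_rounded = if (is.na(f$value)) NA_real_ else round_half_up(f$value),
       status = c(health = h$status, frp = f$status))
}

#' Rescale ECEA outcomes to a budget
#'
#' Multiplies every outcome panel of a result by `budget / C_total`,
#' preserving the stratum disaggregation, so outcomes read as "per $X
#' spent". ICERs are scale-invariant and unchanged.
#'
#' @param result an `ecea_result` from [run_ecea()].
#' @param budget money; must be used with a result whose total net cost is
#'   strictly positive.
#' @return a new `ecea_result` with scaled panels and the `budget` recorded.
#' @export
per_budget_scaling <- function(result, budget) {
  stopifnot(inherits(result, "ecea_result"))
  C <- result$totals$net_cost
  if (C <= 0)
    stop("per-budget scaling requires a positive total net cost", call. = FALSE)
  f <- budget / C
  cols <- c("health_gains", "cases_averted", "pe_baseline", "pe_averted",
            "frp_benefit", "net_cost")
  out <- result
  out$strata_table[cols] <- lapply(result$strata_table[cols], function(x) x * f)
  out$totals <- lapply(result$totals, function(x) x * f)
  out$budget <- budget
  out
}
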