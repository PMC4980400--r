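#' Run a full extended cost-effectiveness analysis
#'
#' Orchestrates the four outcome panels for a scenario: per-stratum health
#' gains, private expenditures averted, financial-risk-protection benefit
#' (per the scenario's FRP metric), and net implementer costs; then derives
#' totals, ICERs and, optionally, per-budget scalings.
#'
#' @param scenario a validated `ecea_scenario` holding a single policy.
#' @param coverage coverage semantics for health gains: `"delta"` (default,
#'   the coverage increase) or `"total"`.
#' @param budget optional money amount; when given, the returned result is
#'   additionally rescaled so outcomes read per `budget` spent (see
#'   [per_budget_scaling()]) and stored in `$scaled`.
#' @param include_indirect include indirect costs `c_i` in private
#'   expenditures (default `FALSE`).
#' @param quiet suppress the INFO log of panel totals (default `TRUE`).
#' @return an object of class `ecea_result`: `strata_table` (a tibble with
#'   one row per stratum), `totals`, `icer`, `frp` (the full
#'   `ecea_frp_outcome`), and metadata (`policy_name`, `frp_metric`,
#'   `currency`, `scaled`).
#' @examples
#' res <- run_ecea(land_fixture())
#' res$totals$health_gains  # 320 deaths averted
#' @export
run_ecea <- function(scenario, coverage = c("delta", "total"), budget = NULL,
                     include_indirect = FALSE, quiet = TRUE) {
  validate_scenario(scenario)
  coverage <- match.arg(coverage)
  policy <- the_policy(scenario)
  s <- scenario$strata

  bh <- health_gains(s, policy, coverage)
  ca <- cases_averted(s, policy, coverage)
  pe0 <- private_expenditures(s, include_indirect)
  peav <- private_expenditures_averted(s, policy, include_indirect)
  frp <- frp_benefit(scenario)
  nc <- net_costs(s, policy)

  tab <- tibble::tibble(
    label = s$label,
    population = s$population,
    caseload = unname(caseload(s)),
    health_gains = unname(bh),
    cases_averted = unname(ca),
    pe_baseline = unname(pe0),
    pe_averted = unname(peav),
    frp_benefit = unname(frp$per_stratum),
    net_cost = unname(nc))
  totals <- list(
    health_gains = sum(bh), cases_averted = sum(ca),
    pe_baseline = sum(pe0), pe_averted = sum(peav),
    frp_benefit = frp$total, net_cost = sum(nc))
  icer <- icers(totals$net_cost, totals$health_gains, totals$frp_benefit)

  if (!quiet) {
    message(sprintf(
      "[ecea] '%s' | deaths averted %.6g | PE averted %.6g | FRP (%s) %.6g | net cost %.6g",
      policy$name, totals$health_gains, totals$pe_averted,
      scenario$frp$metric, totals$frp_benefit, totals$net_cost))
  }

  res <- structure(
    list(scenario_name = scenario$name, policy_name = policy$name,
         frp_metric = scenario$frp$metric, currency = scenario$currency,
         strata_table = tab, totals = totals, icer = icer, frp = frp,
         coverage = coverage, budget = NULL),
    class = "ecea_result")
  res$scaled <- if (!is.null(budget)) per_budget_scaling(res, budget) else NULL
  res
}

#' Four-panel dashboard table
#'
#' The per-stratum outcome table with a TOTAL row appended, in the fixed
#' column order written by [write_outputs()].
#'
#' @param result an `ecea_result`.
#' @return a tibble with one row per stratum plus `TOTAL`.
#' @export
dashboard_table <- function(result) {
  stopifnot(inherits(result, "ecea_result"))
  tab <- result$strata_table
  total <- tibble::tibble(
    label = "TOTAL",
    population = sum(tab$population),
    caseload = sum(tab$caseload),
    health_gains = result$totals$health_gains,
    cases_averted = result$totals$cases_averted,
    pe_baseline = result$totals$pe_baseline,
    pe_averted = result$totals$pe_averted,
    frp_benefit = result$totals$frp_benefit,
    net_cost = result$totals$net_cost)
  rbind(tab, total)
}

#' @export
print.ecea_result <- function(x, ...) {
  cat(sprintf("ECEA result: scenario '%s', policy '%s' (%s)\n",
              x$scenario_name, x$policy_name, x$currency))
  cat(sprintf("  FRP metric: %s%s\n", x$frp_metric,
              if (!is.null(x$budget))
                sprintf(" | scaled to budget %.6g", x$budget) else ""))
  print(as.data.frame(dashboard_table(x)), row.names = FALSE, digits = 6)
  ic <- x$icer
  fmt1 <- function(v, s) if (s == "ok") sprintf("%.2f", v) else s
  cat(sprintf("  ICER: %s per death averted | %s per FRP unit\n",
              fmt1(ic$icer_health, ic$status[["health"]]),
              fmt1(ic$icer_frp, ic$status[["frp"]])))
  invisible(x)
}

#' Compare policies on per-budget efficiency
#'
#' Runs each scenario (or each policy of a multi-policy scenario) and
#' normalizes its outcomes to a shared budget, one row per policy, for
#' side-by-side 'efficient purchase' comparison of health gains and
#' financial risk protection. No ranking is imposed.
#'
#' @param scenarios a list of `ecea_scenario` objects (each holding one
#'   policy), or a single scenario whose `policy` is a list of policies.
#' @param budget money amount every row is normalized to.
#' @param ... passed to [run_ecea()].
#' @return a tibble with one row per policy: per-budget deaths averted,
#'   private expenditures averted and FRP benefit, the ICERs, and a status
#'   column flagging undefined/dominated ratios.
#' @export
compare_policies <- function(scenarios, budget, ...) {
  if (inherits(scenarios, "ecea_scenario")) {
    pols <- scenario_policies(scenarios)
    scenarios <- lapply(pols, function(p) { s <- scenarios; s$policy <- p; s })
  }
  stopifnot(is.list(scenarios), length(scenarios) >= 2)
  cur <- unique(vapply(scenarios, function(s) s$currency, character(1)))
  if (length(cur) != 1)
    stop("scenarios use inconsistent currencies: ",
         paste(cur, collapse = ", "), call. = FALSE)
  rows <- lapply(scenarios, function(sc) {
    res <- run_ecea(sc, ...)
    C <- res$totals$net_cost
    f <- if (C > 0) budget / C else NA_real_
    tibble::tibble(
      policy = res$policy_name,
      frp_metric = res$frp_metric,
      budget = budget,
      deaths_averted_per_budget = res$totals$health_gains * f,
      pe_averted_per_budget = res$totals$pe_averted * f,
      frp_benefit_per_budget = res$totals$frp_benefit * f,
      icer_health = res$icer$icer_health,
      icer_frp = res$icer$icer_frp,
      status = paste0("health:", res$icer$status[["health"]],
                      ",frp:", res$icer$status[["frp"]]))
  })
  do.call(rbind, rows)
}

#' Write machine-readable ECEA outputs
#'
#' Writes the per-stratum dashboard (with TOTAL row) as CSV in a fixed
#' column order, and a JSON summary holding the totals, ICERs (unrounded
#' and rounded to the nearest currency unit, half-up), metric metadata and
#' package version. Output is byte-stable for identical inputs. Currency
#' symbols are never embedded in numeric cells.
#'
#' @param result an `ecea_result`.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written (`csv`, `json`).
#' @export
write_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "ecea_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(out_dir, "ecea_strata.csv")
  json_path <- file.path(out_dir, "ecea_summary.json")
  tab <- dashboard_table(result)
  utils::write.csv(as.data.frame(tab), csv_path, row.names = FALSE)
  summary <- list(
    scenario = result$scenario_name,
    policy = result$policy_name,
    frp_metric = result$frp_metric,
    currency = result$currency,
    coverage_semantics = result$coverage,
    totals = result$totals,
    icer = list(health = result$icer$icer_health,
                frp = result$icer$icer_frp,
                health_rounded = result$icer$icer_health_rounded,
                frp_rounded = result$icer$icer_frp_rounded,
                status = as.list(result$icer$status)),
    version = as.character(utils::packageVersion("ecea")))
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(list(csv = csv_path, json = json_path))
}
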