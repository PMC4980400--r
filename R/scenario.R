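#' Define a health-policy instrument
#'
#' A policy raises intervention coverage from `cov_baseline` to `cov_policy`
#' in every stratum (per-stratum vectors allowed), with a given effectiveness
#' against the modelled outcome, a unit cost per covered case from the
#' implementer's perspective, and a crowd-out fraction giving the share of
#' private out-of-pocket payments removed among covered cases.
#'
#' Two conventions for private expenditures averted are supported. The
#' default, `pe_convention = "crowd_out"`, removes `crowd_out` times the
#' baseline private expenditures (full public finance crowds out all payers
#' when `crowd_out = 1`). The alternative `"coverage"` convention instead
#' averts `cov_policy` times the baseline private expenditures.
#'
#' @param name policy label.
#' @param cov_baseline pre-policy coverage, probability in \[0,1\], scalar or
#'   one value per stratum.
#' @param cov_policy post-policy coverage, probability in \[0,1\].
#' @param effectiveness intervention effectiveness, probability in \[0,1\].
#' @param unit_cost implementer cost per covered case (money, >= 0).
#' @param crowd_out fraction of private payments removed among covered
#'   cases, in \[0,1\]; default 1.
#' @param cov_costing coverage fraction the implementer actually pays for,
#'   in \[0,1\]; defaults to `cov_policy`. Exposed separately because a
#'   financing policy may price a different share of the caseload than the
#'   coverage level driving health gains.
#' @param cost_offsets implementer savings per averted case (money, >= 0);
#'   default 0 (treatment policies); set > 0 for preventive interventions.
#' @param pe_convention `"crowd_out"` (default) or `"coverage"`; see Details.
#' @return an object of class `ecea_policy`.
#' @examples
#' ecea_policy("upf", cov_baseline = 0.5, cov_policy = 0.6,
#'             effectiveness = 0.8, unit_cost = 100)
#' @export
ecea_policy <- function(name, cov_baseline, cov_policy, effectiveness,
                        unit_cost, crowd_out = 1, cov_costing = NULL,
                        cost_offsets = 0,
                        pe_convention = c("crowd_out", "coverage")) {
  pe_convention <- match.arg(pe_convention)
  p <- structure(
    list(name = as.character(name),
         cov_baseline = as.numeric(cov_baseline),
         cov_policy = as.numeric(cov_policy),
         effectiveness = as.numeric(effectiveness),
         unit_cost = as.numeric(unit_cost),
         crowd_out = as.numeric(crowd_out),
         cov_costing = if (is.null(cov_costing)) NULL else as.numeric(cov_costing),
         cost_offsets = as.numeric(cost_offsets),
         pe_convention = pe_convention),
    class = "ecea_policy")
  validate_policy(p)
  p
}

validate_policy <- function(p) {
  stopifnot(inherits(p, "ecea_policy"))
  for (f in c("cov_baseline", "cov_policy", "effectiveness", "crowd_out",
              "cov_costing")) {
    v <- p[[f]]
    if (is.null(v)) next
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      stop(sprintf("policy '%s': field '%s' must lie in [0, 1]", p$name, f),
           call. = FALSE)
  }
  if (any(p$unit_cost < 0) || any(p$cost_offsets < 0))
    stop(sprintf("policy '%s': unit_cost and cost_offsets must be >= 0",
                 p$name), call. = FALSE)
  # disinvestment (coverage reduction) is allowed but flagged
  if (any(p$cov_policy < p$cov_baseline))
    warning(sprintf("policy '%s': cov_policy < cov_baseline (disinvestment scenario)",
                    p$name), call. = FALSE)
  invisible(p)
}

#' Financial-risk-protection settings
#'
#' Chooses and parameterizes the FRP metric: `"catastrophic"` counts cases
#' whose out-of-pocket cost strictly exceeds `threshold` times income;
#' `"poverty"` counts cases pushed strictly below `poverty_line` by the
#' out-of-pocket payment (individuals already below the line never count);
#' `"insurance"` values the policy as the population sum of CRRA risk
#' premiums removed.
#'
#' @param metric one of `"poverty"`, `"catastrophic"`, `"insurance"`.
#' @param threshold catastrophic threshold as a fraction of annual income
#'   (default 0.1); used by the catastrophic metric.
#' @param poverty_line money per person-year; required by the poverty metric.
#' @param risk_aversion Arrow-Pratt coefficient of relative risk aversion
#'   (r > 0; default 3); used by the insurance metric.
#' @param affected_fraction fraction of a stratum's caseload exposed to the
#'   out-of-pocket payment when counting poverty cases. `NULL` (default)
#'   falls back to each stratum's `care_seeking` fraction.
#' @param n_grid number of equal-probability income points used to integrate
#'   over a continuous income model (default 10000).
#' @param prevention if `TRUE`, the insurance metric lets the policy reduce
#'   the event probability by effectiveness times the coverage increase
#'   (preventive interventions) in addition to crowding out costs.
#' @return an object of class `ecea_frp_config`.
#' @export
frp_config <- function(metric = c("poverty", "catastrophic", "insurance"),
                       threshold = 0.1, poverty_line = NULL,
                       risk_aversion = 3, affected_fraction = NULL,
                       n_grid = 10000, prevention = FALSE) {
  metric <- match.arg(metric)
  if (metric == "catastrophic" && (!is.numeric(threshold) || threshold <= 0))
    stop("catastrophic metric requires threshold > 0", call. = FALSE)
  if (metric == "poverty" &&
      (is.null(poverty_line) || !is.numeric(poverty_line) || poverty_line <= 0))
    stop("poverty metric requires poverty_line > 0", call. = FALSE)
  if (!is.numeric(risk_aversion) || risk_aversion <= 0)
    stop("risk_aversion must be > 0", call. = FALSE)
  if (!is.null(affected_fraction) &&
      (affected_fraction < 0 || affected_fraction > 1))
    stop("affected_fraction must lie in [0, 1]", call. = FALSE)
  structure(
    list(metric = metric, threshold = as.numeric(threshold),
         poverty_line = if (is.null(poverty_line)) NULL else as.numeric(poverty_line),
         risk_aversion = as.numeric(risk_aversion),
         affected_fraction = affected_fraction,
         n_grid = as.integer(n_grid), prevention = isTRUE(prevention)),
    class = "ecea_frp_config")
}

stratum_fields <- c("label", "population", "income", "incidence",
                    "case_fatality", "care_seeking", "c_dm", "c_dnm", "c_i")

#' Assemble an ECEA scenario
#'
#' Binds population strata, a policy, FRP settings, and an optional income
#' model into a validated scenario object. Scalar stratum parameters are
#' broadcast to all strata.
#'
#' @param strata a data frame with one row per stratum and columns `label`,
#'   `population` (persons), `income` (money per person-year), `incidence`
#'   (disease events per person-year), `case_fatality` (probability),
#'   `care_seeking` (probability of incurring private payment given a case),
#'   `c_dm` and `c_dnm` (out-of-pocket direct medical and non-medical cost
#'   per treated case), and optionally `c_i` (indirect cost per case,
#'   default 0). Scalar columns are recycled across strata.
#' @param policy an [ecea_policy()], or a list of them for comparisons.
#' @param frp an [frp_config()].
#' @param income_model optional [income_gamma()] or other income model used
#'   for within-population income variation; when `NULL`, strata carry point
#'   incomes.
#' @param currency currency label (default `"USD"`).
#' @param name scenario label.
#' @return an object of class `ecea_scenario`. All incomes, incidences and
#'   costs are annual.
#' @export
ecea_scenario <- function(strata, policy, frp = frp_config(metric = "catastrophic"),
                          income_model = NULL, currency = "USD",
                          name = "scenario") {
  strata <- as.data.frame(strata, stringsAsFactors = FALSE)
  if (nrow(strata) == 0) stop("at least one stratum is required", call. = FALSE)
  if (is.null(strata$c_i)) strata$c_i <- 0
  missing_cols <- setdiff(stratum_fields, names(strata))
  if (length(missing_cols) > 0)
    stop("strata missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  n <- nrow(strata)
  strata$label <- as.character(strata$label)
  for (f in setdiff(stratum_fields, "label"))
    strata[[f]] <- bc(strata[[f]], n, f)
  strata <- tibble::as_tibble(strata[stratum_fields])
  sc <- structure(
    list(name = as.character(name), strata = strata, policy = policy,
         frp = frp, income_model = income_model,
         currency = as.character(currency)),
    class = "ecea_scenario")
  validate_scenario(sc)
}

#' Validate an ECEA scenario
#'
#' Checks every invariant of the scenario data model: positive populations,
#' probabilities in \[0,1\], non-negative costs and incidences, unique
#' stratum labels, policy field lengths compatible with the number of
#' strata. Errors name the offending field and stratum.
#'
#' @param scenario an `ecea_scenario`.
#' @return the scenario, invisibly, if valid; otherwise an error.
#' @export
validate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "ecea_scenario"))
  s <- scenario$strata
  if (anyDuplicated(s$label))
    stop("stratum labels must be unique", call. = FALSE)
  check <- function(field, ok, what) {
    bad <- which(!ok)
    if (length(bad) > 0)
      stop(sprintf("stratum '%s': field '%s' %s", s$label[bad[1]], field, what),
           call. = FALSE)
  }
  check("population", s$population > 0, "must be > 0")
  check("incidence", s$incidence >= 0, "must be >= 0")
  check("income", s$income > 0, "must be > 0")
  for (f in c("case_fatality", "care_seeking"))
    check(f, s[[f]] >= 0 & s[[f]] <= 1, "must lie in [0, 1]")
  for (f in c("c_dm", "c_dnm", "c_i"))
    check(f, s[[f]] >= 0, "must be >= 0")
  pols <- scenario_policies(scenario)
  for (p in pols) {
    validate_policy(p)
    for (f in c("cov_baseline", "cov_policy", "effectiveness"))
      bc(p[[f]], nrow(s), f)  # errors on incompatible length
  }
  if (!inherits(scenario$frp, "ecea_frp_config"))
    stop("scenario 'frp' must be an frp_config()", call. = FALSE)
  if (!is.null(scenario$income_model) &&
      !inherits(scenario$income_model, "ecea_income_model"))
    stop("scenario 'income_model' must be an income model object", call. = FALSE)
  invisible(scenario)
}

scenario_policies <- function(scenario) {
  if (inherits(scenario$policy, "ecea_policy")) list(scenario$policy)
  else scenario$policy
}

# Select the single active policy of a scenario.
the_policy <- function(scenario) {
  pols <- scenario_policies(scenario)
  if (length(pols) != 1)
    stop("scenario holds ", length(pols),
         " policies; select one (e.g. scenario$policy <- scenario$policy[[i]])",
         call. = FALSE)
  pols[[1]]
}

#' @export
print.ecea_scenario <- function(x, ...) {
  cat(sprintf("ECEA scenario '%s' (%s, annual)\n", x$name, x$currency))
  cat(sprintf("  %d strata, total population %s\n", nrow(x$strata),
              format(sum(x$strata$population), big.mark = ",")))
  pols <- scenario_policies(x)
  for (p in pols)
    cat(sprintf("  policy '%s': coverage %s -> %s, effectiveness %s\n",
                p$name, paste(unique(p$cov_baseline), collapse = "/"),
                paste(unique(p$cov_policy), collapse = "/"),
                paste(unique(p$effectiveness), collapse = "/")))
  cat(sprintf("  FRP metric: %s\n", x$frp$metric))
  if (!is.null(x$income_model))
    cat(sprintf("  income model: %s\n", x$income_model$family))
  invisible(x)
}

# ---- scenario files ---------------------------------------------------------

#' Load a scenario from a YAML or JSON file
#'
#' Reads a scenario configuration: a `strata` list (one mapping per stratum),
#' an optional `strata_defaults` mapping applied to every stratum, a `policy`
#' mapping (or `policies` list), an `frp` mapping, and an optional
#' `income_model` mapping. Incidence may be given as `incidence` (events per
#' person-year) or `incidence_per_100k`; it is stored canonically per
#' person-year. Scalars broadcast to all strata.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated `ecea_scenario`.
#' @seealso [write_scenario()], [land_fixture()]
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  cfg <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    else yaml::read_yaml(path),
    error = function(e)
      stop(sprintf("failed to parse '%s': %s", path, conditionMessage(e)),
           call. = FALSE))
  scenario_from_config(cfg)
}

scenario_from_config <- function(cfg) {
  if (is.null(cfg$strata) || length(cfg$strata) == 0)
    stop("scenario config requires a non-empty 'strata' list", call. = FALSE)
  defaults <- cfg$strata_defaults
  rows <- lapply(cfg$strata, function(st) {
    st <- utils::modifyList(as.list(defaults %||% list()), as.list(st))
    if (!is.null(st$incidence_per_100k)) {
      st$incidence <- as.numeric(st$incidence_per_100k) / 1e5
      st$incidence_per_100k <- NULL
    }
    st
  })
  all_names <- unique(unlist(lapply(rows, names)))
  strata <- as.data.frame(
    lapply(stats::setNames(all_names, all_names), function(nm)
      vapply(rows, function(r) {
        v <- r[[nm]]
        if (is.null(v)) NA_real_ else if (nm == "label") NA_real_ else as.numeric(v)
      }, numeric(1))))
  strata$label <- vapply(rows, function(r)
    as.character(r$label %||% NA_character_), character(1))
  if (anyNA(strata$label))
    strata$label <- ifelse(is.na(strata$label),
                           paste0("stratum_", seq_len(nrow(strata))),
                           strata$label)

  pol_cfgs <- if (!is.null(cfg$policies)) cfg$policies else list(cfg$policy)
  policies <- lapply(pol_cfgs, function(pc) {
    if (is.null(pc)) stop("scenario config requires a 'policy' mapping",
                          call. = FALSE)
    ecea_policy(
      name = pc$name %||% "policy",
      cov_baseline = unlist(pc$cov_baseline),
      cov_policy = unlist(pc$cov_policy),
      effectiveness = unlist(pc$effectiveness),
      unit_cost = pc$unit_cost %||% 0,
      crowd_out = pc$crowd_out %||% 1,
      cov_costing = pc$cov_costing,
      cost_offsets = pc$cost_offsets %||% 0,
      pe_convention = pc$pe_convention %||% "crowd_out")
  })
  policy <- if (length(policies) == 1) policies[[1]] else policies

  fc <- cfg$frp %||% list()
  frp <- frp_config(
    metric = fc$metric %||% "catastrophic",
    threshold = fc$threshold %||% 0.1,
    poverty_line = fc$poverty_line,
    risk_aversion = fc$risk_aversion %||% 3,
    affected_fraction = fc$affected_fraction,
    n_grid = fc$n_grid %||% 10000,
    prevention = isTRUE(fc$prevention))

  im <- NULL
  if (!is.null(cfg$income_model)) {
    ic <- cfg$income_model
    im <- switch(ic$family %||% "gamma",
      gamma = income_gamma(mean = ic$mean, gini = ic$gini),
      point = income_point(ic$mean),
      empirical = income_empirical(unlist(ic$values)),
      stop("unknown income model family: ", ic$family, call. = FALSE))
  }

  ecea_scenario(strata = strata, policy = policy, frp = frp,
                income_model = im, currency = cfg$currency %||% "USD",
                name = cfg$name %||% "scenario")
}

#' Write a scenario to a YAML or JSON file
#'
#' Serializes a scenario in the canonical form read back by
#' [load_scenario()] (incidence per person-year). Round-trips to an equal
#' scenario.
#'
#' @param scenario an `ecea_scenario`.
#' @param path output path; `.json` selects JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  validate_scenario(scenario)
  s <- scenario$strata
  cfg <- list(
    name = scenario$name,
    currency = scenario$currency,
    strata = lapply(seq_len(nrow(s)), function(i) as.list(s[i, ])),
    frp = Filter(Negate(is.null), unclass(scenario$frp)))
  pols <- scenario_policies(scenario)
  pol_cfg <- lapply(pols, function(p) Filter(Negate(is.null), unclass(p)))
  if (length(pols) == 1) cfg$policy <- pol_cfg[[1]] else cfg$policies <- pol_cfg
  if (!is.null(scenario$income_model)) {
    m <- scenario$income_model
    cfg$income_model <- switch(m$family,
      gamma = list(family = "gamma", mean = m$mean, gini = m$gini),
      point = list(family = "point", mean = m$mean),
      empirical = list(family = "empirical", values = m$values))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else
    yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
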