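---
title: "Extended cost-effectiveness analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended cost-effectiveness analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecea)
```

## The problem

Conventional cost-effectiveness analysis values a health policy by one
number: health gained per dollar spent. Real financing decisions — which
services to put in a publicly financed benefits package, whom to target —
also turn on who gains and on how much illness-related impoverishment the
policy prevents. Extended cost-effectiveness analysis (ECEA) answers both
by evaluating a policy in four panels, each disaggregated across population
strata (typically income quintiles):

1. health gains (deaths averted here);
2. private out-of-pocket expenditures averted;
3. financial risk protection (FRP) afforded;
4. net cost to the implementer.

This package is the ECEA arithmetic as a reusable engine: scenarios are
declared in YAML/JSON (or built in code), and `run_ecea()` produces the
four panels, totals, ICERs and per-budget scalings.

## The static disease and cost model

Each stratum $k$ carries a population $P_k$, an annual disease incidence
$i_k$, a case-fatality probability, a fraction $u_k$ of cases paying out of
pocket, and per-case out-of-pocket costs $c_{DM,k} + c_{DNM,k}$ (direct
medical plus non-medical; indirect costs $c_{I,k}$ are carried but excluded
from the arithmetic unless explicitly switched on, since most published
analyses omit them for data reasons). A policy raises coverage from
$\mathrm{Cov}_0$ to $\mathrm{Cov}_1$ with effectiveness $\mathrm{Eff}$.
With caseload $N_k = i_k P_k$:

* deaths averted: $B_{H,k} = \mathrm{Eff}\,\Delta\mathrm{Cov}\,\cdot
  \mathrm{CFR}_k \cdot N_k$;
* baseline private expenditures: $PE_k = N_k u_k (c_{DM,k}+c_{DNM,k})$;
* private expenditures averted: $PE_{av,k} = w \cdot PE_k$ under the
  default crowd-out convention ($w$ = crowd-out fraction), or
  $\mathrm{Cov}_1 \cdot PE_k$ under the coverage-literal convention;
* net implementer cost: $C_k = \mathrm{Cov}_{cost} \cdot N_k \cdot
  \text{unit cost} - \text{offsets} \cdot \text{cases averted}$.

All quantities are expected values over one year, kept as exact reals;
rounding happens only at the reporting layer.

### Two coverage semantics, two conventions

Two places in the canonical tutorial example use coverage inconsistently,
and we expose each as an explicit switch rather than silently picking one:

* **Health gains** can be driven by the coverage *increase*
  $\Delta\mathrm{Cov}$ (default, the incremental reading) or by total
  post-policy coverage (`coverage = "total"`). The incremental reading is
  the default because a policy evaluation is a comparison against the
  status quo.
* **Costing** prices `cov_costing` of the caseload, defaulting to the
  post-policy coverage. The packaged Land example prices 50% of cases while
  policy coverage is 60%; the fixture therefore sets `cov_costing = 0.5`.
* **Expenditures averted** default to the crowd-out convention (universal
  public finance with $w = 1$ removes every payer's out-of-pocket cost);
  the coverage-literal convention ($\mathrm{Cov}_1 \cdot PE_k$) is
  available as `pe_convention = "coverage"` on the policy.

## Financial risk protection

Three alternative metrics, selected in `frp_config()`. All compare the
pre-policy state with a post-policy state in which paying cases face costs
scaled by $1 - w$.

**Catastrophic health costs.** A case is catastrophic when the
out-of-pocket cost strictly exceeds a threshold share of annual income,
$c > y \cdot Th$ (default $Th = 0.1$). The benefit is expected cases
before minus after.

**Poverty cases.** A case is counted when income is strictly above the
poverty line before the payment and strictly below it after:
$y > Pl$ and $y - c < Pl$. Individuals already below the line never
count. Ties break toward "not a case" — the inequalities are strict by
construction. Counts are expected (real-valued) numbers of cases;
probability-weighted integrals are not integers, and rounding is left to
reports.

**Money-metric value of insurance.** A risk-averse individual with CRRA
utility $w(y) = y^{1-r}/(1-r)$ faces the gamble of paying $c$ with
probability $p = i_k u_k$. Expected income is $E(y) = p(y-c) + (1-p)y$,
the certainty equivalent is
$y^* = [p (y-c)^{1-r} + (1-p) y^{1-r}]^{1/(1-r)}$, and the risk premium
$E(y) - y^*$ is the money value of removing the risk. The population value
of the policy sums premium reductions over all individuals. The default
$r = 3$ is the conventional high-risk-aversion choice; opinions in the
literature diverge, so it is a config parameter. At $r = 1$ the power form
is undefined and we use its logarithmic limit
$y^* = \exp(p\ln(y-c) + (1-p)\ln y)$, so the premium is continuous in $r$;
evaluation goes through logs so large $r$ neither overflows nor
underflows. The premium requires $y > c$; violations raise a domain error
naming the stratum. Optionally (`prevention = TRUE`) the policy also
scales the event probability by $1 - \mathrm{Eff}\,\Delta\mathrm{Cov}$,
appropriate for preventive interventions.

### The exposed-case fraction for poverty counting

The canonical worked example counts 3,200 poverty cases averted in a
middle quintile with 4,000 cases — an exposed fraction of 0.8, although
its expenditure arithmetic uses a paying fraction of 0.4. The tutorial
source does not reconcile the two, so the fraction is an explicit
parameter (`affected_fraction` in `frp_config()`, falling back to each
stratum's `care_seeking`). The packaged fixture documents both readings:
0.8 reproduces the canonical 3,200 cases and the \$313 ICER; 0.4 yields
1,600.

## The income model

FRP metrics scale costs by income, so they need an income distribution.
Strata may carry point incomes (the fixture does), or a Gamma
distribution for the whole population can be attached. The Gamma family
is convenient because its Gini coefficient has the closed form
$G(a) = \Gamma(a + 1/2)\,/\,(\Gamma(a+1)\sqrt{\pi})$, strictly decreasing
in the shape $a$ — so mean income plus a Gini (both routinely published)
pin down both parameters. `gamma_from_mean_gini()` inverts $G$ by a
bracketed root-find on the log scale (machine-precision tolerance; the
recovered Gini matches the input to 1e-8), and sets scale = mean/shape.
The exponential case $a = 1$, Gini exactly $1/2$, is a useful check.

Integration over income uses `discretize()`: $n$ equal-probability slices
represented by their *conditional means*, computed from the Gamma partial
expectation $E[Y\,1\{Y \le q\}] = \mu F_{a+1}(q)$. Conditional means
rather than midpoints preserve the distribution mean exactly
(telescoping), which keeps expected counts unbiased. The default
resolution $n = 10{,}000$ makes the slice-discretization error on a
counting probability at most $10^{-4}$ in absolute terms, negligible next
to the parameter uncertainty of any real scenario; it is a config value
(`n_grid`). `quantile_slice_means()` is the same construction at the
stratum scale, mapping a national distribution onto quintiles.

## Efficiency ratios and reporting

Totals over strata give the health ICER $C/B_H$ and the financial
protection ICER $\mathrm{ICER}_{FRP} = C/B_{FRP}$ — the price of one unit
of FRP. A zero denominator is reported as status `"undefined"` (never
infinity); a negative one as `"dominated"`. ICERs are reported unrounded
and rounded half-up to whole currency units (half-up, not banker's
rounding, so \$312.50 reports as \$313). `per_budget_scaling()` rescales
every panel by `budget / C_total` for "per \$1 million spent"-style
comparisons, and `compare_policies()` tabulates several policies at a
shared budget without imposing a ranking.

## The worked example

```{r land}
land <- land_fixture()
res <- run_ecea(land)
res
```

Five quintiles of 2 million people; TB incidence 400/300/200/100/0 per
100,000 gives caseloads 8,000/6,000/4,000/2,000/0. Coverage rises 50% to
60% with 80% effective treatment and 20% case fatality: 128/96/64/32/0
deaths averted, 320 in total, 40% in the poorest quintile. The 40% of
cases paying \$100 out of pocket are fully crowded out: \$800,000 averted.
Costing 50% of cases at \$100 totals \$1,000,000. Only the middle quintile
(income \$640 against a \$600 poverty line) can be impoverished by the
\$100 payment; with the documented 0.8 exposed fraction, 3,200 poverty
cases are averted, and the FRP ICER is \$1,000,000 / 3,200 = \$312.50,
reported as \$313.

## The synthetic-scenario generator

`generate_synthetic_scenario()` draws internally consistent test
scenarios: incomes are Gamma slice means (mean U(500, 5000), Gini
U(0.25, 0.55) — low- and middle-income country magnitudes where ECEA is
most used), incidence U(50, 500) per 100,000 with a uniform, pro-poor
(incidence falling with income rank) or pro-rich gradient, case fatality
U(0.02, 0.3), care seeking U(0.2, 0.9), and a coverage-expansion policy.
Out-of-pocket costs are capped below 40% of the poorest stratum's income
so the CRRA domain $y > c$ always holds. Generation is deterministic for
a fixed seed.

What the generator emulates is the *structure* of an ECEA input — monotone
income gradients, socially patterned burden, a single-period static
policy. What it does not emulate: correlated parameter uncertainty,
household (rather than individual) budgets, multi-year dynamics, or
behavioural responses to the policy. Tests passing on generated scenarios
therefore certify the arithmetic and its invariants (linearity in
population, permutation invariance, oracle equivalence of the counting
metrics), not the realism of any particular country scenario.

## Numerical choices and limitations

* Strict inequalities at the catastrophic threshold and poverty line;
  boundary individuals are not cases.
* Expected counts are reals throughout; reports round.
* The Gini root-find brackets $[10^{-8}, \infty)$ by doubling and solves
  to machine precision; calibration is verified to 1e-8 and rejected
  otherwise.
* Degenerate gambles ($p \in \{0, 1\}$ or $c = 0$) return a risk premium
  of exactly zero, bypassing float round-off.
* Single-period analysis: no discounting, no disease transmission
  dynamics, no herd effects. Disinvestment (coverage reductions) is
  allowed with a warning and produces negative gains rather than an
  error.
* Probabilistic sensitivity analysis is out of scope; the engine is
  deterministic, and uncertainty propagation is left to the caller
  (re-run over parameter draws).

Test suites and the acceptance script run the packaged five-stratum
example, property sweeps of $10^4$ random gambles, and Monte-Carlo
cross-checks at 200,000 draws — all problem sizes chosen to exercise the
asymptotics of the estimators while completing in seconds.
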