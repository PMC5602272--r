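---
title: "Benchmarking municipal primary care with output-oriented BCC DEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking municipal primary care with output-oriented BCC DEA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcdea)
```

## The evaluation design

`pcdea` operationalizes a municipal primary-care efficiency evaluation:
every municipality is a decision-making unit (DMU) described by resource
inputs and care products, and is benchmarked against the empirical
best-practice frontier formed by convex combinations of its peers. Two
companion models are built in. The **health-actions model** relates the
primary-care workforce and equipped basic health units (physicians,
nurses, units with a vaccination room, units with sonar/Pinard) to the
volume of care delivered (home visits, prenatal appointments, nursing
appointments, third doses of tetra/pentavalent vaccine). The
**outcomes model** relates physicians, nurses and basic health units to
two more-is-better outcomes: the percentage of live births with normal
weight and the percentage of hospitalizations *not* due to
primary-care-sensitive conditions. Avoidable hospitalizations are the
classic marker of primary-care failure, so their complement enters as a
product to maximize.

Because a municipality with too few physicians could look "efficient"
simply by producing adequately with almost nothing, both models append
**control products**: per-capita rates (physicians, nurses, units per
1,000 inhabitants) and equipment percentages. A unit with deficient
inputs then carries low control outputs and cannot reach the frontier
through scarcity alone. Controls are omitted in stratum 1 (up to 5,000
inhabitants), where per-capita staffing is structurally high and the
control would be uninformative.

## The envelopment model

For DMU 0 with inputs $x_0 \in \mathbb{R}^m$ and outputs
$y_0 \in \mathbb{R}^s$ among $n$ peers, phase 1 solves

$$\max_{\phi,\lambda} \phi \quad \text{s.t.}\quad
X^\top\lambda \le x_0,\qquad
Y^\top\lambda \ge \phi\, y_0,\qquad
\mathbf{1}^\top\lambda = 1,\qquad \lambda \ge 0 .$$

The convexity constraint $\mathbf{1}^\top\lambda = 1$ imposes variable
returns to scale (the BCC technology); the orientation is toward
products because the design question is "how much more could be
delivered with the resources already in place", the natural reading when
resources are fixed in the short run. The efficiency score is $1/\phi$.
Phase 2 fixes $\phi^\*$ and maximizes the sum of input and output
slacks. Envelopment problems are routinely degenerate, with many
alternative optimal bases; taking intensity weights from the
maximal-slack optimum makes reference sets (the peers with
$\lambda_j > \lambda_{tol}$) deterministic, which matters because the
classification below counts how often each efficient unit appears as a
peer.

Conventions worth stating:

* **Efficiency** means *radial* efficiency, $\phi \le 1 + \varepsilon$
  with $\varepsilon = 10^{-6}$; zero-slack (Pareto–Koopmans) status is
  computed and reported (`pareto_efficient`) but does not drive the
  headline categories.
* **Reference sets** are the support of the phase-2 $\lambda$, plus the
  DMU itself whenever it is radially efficient. The self-inclusion
  covers the degenerate weakly-efficient case (radially efficient but
  dominated), where the maximal-slack optimum puts no weight on the DMU
  itself; without it an efficient DMU could have an empty reference
  role, which the classification logic assumes cannot happen.
* **Headline expansion is radial only.** The equiproportional target
  $\phi\, y_0$ is what the aggregate expansion report is built from;
  slack-augmented shortfalls are a separate column, never folded in.
* **Numerical scaling.** Input and output columns are scaled to unit
  maximum before the LP and slacks unscaled afterwards. The models mix
  raw counts ($\sim 10^5$) with rates ($\sim 0.5$); without scaling the
  tableau is ill-conditioned.
* **The solver** is an in-package two-phase primal simplex with Bland's
  rule (entering variable = lowest eligible index), which cannot cycle
  on the degenerate bases these programs produce. The problems are
  small — at most a few hundred columns and ~15 rows — so a dense
  tableau is appropriate. The test suite cross-checks it against an
  independent LP implementation and against a brute-force
  $\lambda$-simplex grid search.

## Preprocessing

The stage order is fixed: exclusions → derived products → percentile
trim → stratification. Re-running the chain on its own output is a
no-op, and every stage conserves records (retained + excluded = input).

1. **Participation**: non-participants of the national quality program
   are removed (`non_pmaq`).
2. **Coverage**: primary-care coverage strictly below 80% excludes a
   record; exactly 80% is retained (the published rule reads "less
   than").
3. **Consistency**: a record missing any field the active model needs,
   violating a structural invariant (e.g. more equipped units than
   units), or carrying a zero denominator for a derived product is
   routed to `inconsistent` rather than crashing a later stage.
4. **Zero inputs**: for the health-actions model a record with *any*
   zero input is removed — a zero input row makes the DMU trivially
   non-comparable in the envelopment LP (nothing can dominate it on
   that input, and its own products are typically zero too). For the
   outcomes model only the all-zero case is removed. The published rule
   says "zero inputs" without resolving any/all; this package fixes the
   reading per model as above.
5. **Percentile trim**: the 5th and 95th percentiles of each model's
   per-capita rates are computed once, on the pooled retained sample
   (no distinction of size), with linear interpolation between order
   statistics (quantile type 7 — the source states no convention, so
   one is fixed for reproducibility). A record strictly outside the
   band in *any* listed variable is eliminated; boundary values stay.
   Trim rates are per 1,000 inhabitants; the base cancels out of the
   percentile comparison, so this choice cannot change which records
   are trimmed.
6. **Stratification**: five population classes (≤5k, 5–10k, 10–20k,
   20–50k, 50–100k); municipalities above 100,000 inhabitants are
   dropped with a note, as too few exist per class to support a
   frontier of their own. A stratum should hold at least
   $3\,(m + s)$ DMUs (`check_dmu_rule()`); below that the frontier
   over-fits and most units come out efficient by construction. The
   check warns and never aborts.

## Classification and reporting

Within each stratum, a DMU is `inefficient` ($\phi > 1$),
`efficient_self_only` (efficient, a peer only to itself), or
`efficient_multi_reference` (efficient and a peer to at least one other
DMU — the benchmarks whose practice can plausibly transfer). Crossing
the two models on the municipalities retained in both yields six joint
categories — the unordered pairs over the three single-model
categories. Percentages are rounded to one decimal, half away from
zero, matching the convention of published national tables (R's
`round()` rounds half to even and would disagree on exact halves).

The aggregate expansion report computes, per raw product (controls are
a modelling device and are excluded), the shortfall
$\sum_{\text{inefficient}} (\phi_i - 1) y_i$ and expresses it as a
percentage of total observed production over **all** retained DMUs.
A national evaluation that quotes a single percentage next to an
absolute national count is only coherent with this pooled denominator;
the restricted (inefficient-only) denominator remains available via
`denominator = "inefficient"` for sensitivity analysis.

The correlation screen uses Spearman rank correlation between each
input and each output: count indicators are heavily right-skewed, so a
rank method is the defensible default, and a positive, significant
input–product association is the precondition for interpreting the
frontier as a production relationship at all.

## The synthetic generator

No public accession exists for the municipal microdata the design was
built around, so the package ships a generator
(`generate_municipalities()`) that emulates the *structure* the method
assumes rather than any real joint distribution. Populations are
uniform within each stratum's bounds; staffing and units are Poisson
with per-capita rates (≈0.45 physicians and nurses, ≈0.32 units per
1,000 inhabitants — magnitudes consistent with published descriptive
tables); equipped units are binomial thinnings. Raw products follow

$$y = u \cdot g(x)\cdot e^{\varepsilon},\qquad
g_p(x) = A_p \prod_i x_i^{\beta_{pi}},\qquad \sum_i \beta_{pi} \le 1,$$

with true efficiency $u \sim \mathrm{Beta}(5,2)$ (mean 0.71) applied
multiplicatively to outputs — matching the model's output orientation —
and 5% lognormal noise. Row sums of the elasticities at most 1 keep
$g$ concave, hence the planted technology is consistent with a VRS
frontier. A configurable share of units (default 10%) is exactly
efficient: $u = 1$, zero noise. Outcome percentages are generated near
their observed national magnitudes (≈92% normal-weight births, ≈65–70%
non-primary-care-sensitive hospitalizations) with a mild dependence on
$u$. Exclusion cases — non-participants, low coverage, a zero input, a
ten-fold home-visit rate — are planted on disjoint subsets so each
pipeline stage fires on known records. Everything is reproducible from
the seed.

Defaults are 200 municipalities per stratum: large enough that every
stratum passes the DMU adequacy rule for both models, small enough that
a full two-model pipeline runs in seconds.

What the generator does *not* emulate: spatial or regional correlation,
reporting artefacts, the real covariance between staffing and
population, or the true 2012 joint distribution beyond order-of-
magnitude means. Passing recovery tests therefore show that the
*method* recovers a planted frontier of the assumed form — not that
real municipal data satisfy those assumptions.

## The recovery experiment

`recovery_experiment()` generates municipalities, runs the
health-actions preprocessing, estimates per-stratum frontiers, and
compares scores with the planted truth. Two figures summarize it: the
Spearman correlation between true $u$ and the DEA score over all
retained municipalities, and the share of planted exactly-efficient
units found on the frontier ($\phi \le 1 + 10^{-4}$).

The frontiers here are evaluated on the **raw products only** (controls
omitted in every stratum). The planted inefficiency multiplies raw
products; control products are a device of the real evaluation design
and are orthogonal to $u$ by construction. Including them adds up to
eight output dimensions unrelated to the planted signal, and in
8–12-dimensional output spaces with ~150 DMUs per stratum the radial
score compresses toward 1 for most units — the well-known
dimensionality effect that the DMU adequacy rule guards against. The
planted-efficient units are still recovered perfectly in that setting,
but rank recovery of $u$ is attenuated for reasons that have nothing to
do with solver correctness. The raw-product frontier is therefore the
meaningful target for validating recovery. With the default
configuration the experiment yields a Spearman correlation around
0.86 and 100% of planted-efficient units recovered (the acceptance
script recomputes both).

## Numerical choices and degenerate inputs

* Tolerances: $\varepsilon_{\text{eff}} = 10^{-6}$ on $\phi$ and
  $\lambda_{tol} = 10^{-6}$ for reference membership. The packaged
  software used in the original evaluation documents no tolerances;
  these are conventional magnitudes for double-precision simplex.
* A stratum where a DMU has no strictly positive input or no strictly
  positive output is rejected at construction — such a DMU has an
  unbounded or meaningless expansion problem.
* A constant column makes a correlation pair undefined (`NA`), never an
  error; a zero pooled denominator makes an expansion percentage
  undefined (`NA`), never 0.
* Ties in the percentile trim are resolved by the strict-inequality
  rule: values exactly at a threshold are retained.
* LP ties across alternative optima are resolved by the phase-2
  maximal-slack objective; within the simplex, Bland's rule breaks
  entering/leaving ties by lowest index.

## Problem sizes used in the tests

The suite exercises: analytic 1–3-DMU instances solved by hand; 100
random instances with up to 4 DMUs checked against a 0.01-step
$\lambda$-simplex grid oracle (with a 10× local refinement pass), plus
5- and 6-DMU instances at coarser grids with tolerances tied to the
step — a 0.01 grid over a 6-simplex has $\sim 10^{10}$ points and is
not enumerable, so coarse steps are the honest brute-force design at
those sizes; a 50-DMU frontier cross-checked against an independent LP
implementation; and full recovery runs at 200 municipalities per
stratum. These sizes were chosen so the whole suite runs in about a
minute while every check retains its discriminating power.

## Known limitations

* No bootstrap or second-stage inference on scores; DEA scores are
  descriptive benchmarks here, and their sampling noise is not
  quantified.
* Only the BCC output-oriented envelopment form is provided — no CCR,
  input orientation, super-efficiency, or multiplier duals.
* The exact score list of the original national evaluation is not
  reproducible: it depends on restricted microdata and on the
  undocumented tolerances of the packaged software used there. The
  package instead reproduces the evaluation's *arithmetic* on published
  aggregate counts and validates the method on synthetic data with
  known truth.
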