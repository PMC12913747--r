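---
title: "A long-term cost-utility model of sinus surgery for chronic rhinosinusitis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A long-term cost-utility model of sinus surgery for chronic rhinosinusitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinucost)
```

## The decision problem

Chronic rhinosinusitis (CRS) is a prevalent inflammatory sinonasal
disease with a large quality-of-life and economic burden. Two management
strategies are compared over a 33-year horizon:

* **Medical management** — ongoing otolaryngologic medical therapy
  (irrigations, topical steroids, antibiotics as needed), at a flat
  annual cost.
* **Endoscopic sinus surgery (ESS)** — index surgery with its
  perioperative risks, followed by postoperative medical management,
  annual revision-surgery risk, and state-dependent annual costs.

The comparison is a cost-utility analysis: each strategy accumulates
costs (USD) and quality-adjusted life years (QALYs), and the headline
statistic is the incremental cost-effectiveness ratio

$$\mathrm{ICER} = \frac{C_{\mathrm{ESS}} - C_{\mathrm{med}}}{E_{\mathrm{ESS}} - E_{\mathrm{med}}}\quad[\$/\mathrm{QALY}],$$

read against a willingness-to-pay (WTP) threshold $\lambda$ (the
conventional US benchmark being \$50,000/QALY).

## Model structure

### Perioperative decision tree

Surgical patients first traverse a chance tree: death at surgery
(`pDeath`), an intraoperative complication (`pIntraOpComp`, priced as
the incremental cost `cESSMajorComp`), and a postoperative node in
which a complication (`pPostOpComp`) is an infection, an epistaxis
(managed conservatively or in the OR) or a CSF leak (likewise), with
the three type probabilities conditional on a complication occurring.
Intra- and postoperative complications are modelled as sequential
independent nodes — a survivor can incur both — which yields 13
terminal outcomes (1 death + 2 × 6 survivor paths). Every path carries
the surgery cost `cESS`; the death path adds `cDeath` and never enters
the Markov model. The tree assigns no utility decrements of its own:
effectiveness differences arise entirely in the Markov states.

### Ten-state Markov model

Living health is discretized into ten utility-decile states (state 1 =
EQ-5D utility 0–0.099, …, state 10 = 0.9–1, top bin closed), plus an
absorbing Dead state. Each state carries

* a representative utility, by default the bin midpoint (0.05, …,
  0.95) — the within-bin placement is unidentified once utilities are
  binned; and
* an annual cost from the ladder `cMarkov1..cMarkov10`, attached in the
  *healthiest-cheapest* orientation (`cMarkov1` = \$1,167/yr to state
  10, `cMarkov10` = \$3,336/yr to state 1). Sicker patients plausibly
  incur more cost, and this orientation reconciles the surgical arm's
  published annual cost residual. The reverse orientation is one
  argument away (`state_costs(..., "sickest_cheapest")`).

The medical arm instead accrues the flat `cMedical` (\$772/yr); both
rules, or their sum, are configurable per strategy.

Cycle 1 uses the arm's year-0→1 transition matrix; all later cycles use
its steady-phase matrix. Rewards accrue on the **post-transition**
occupancy of each cycle — the entrance wave is the measurement that
places a patient, not a lived model year — and cycle $t$ is discounted
by $(1+r)^{-(t-1)}$ with no half-cycle correction (annual accrual
matches the per-year framing of the state costs).

Revision ESS occurs with probability `pRevisionESS` (0.041/yr) in every
cycle of the surgical arm and adds a full perioperative-tree traversal
cost. The death branch of that traversal is *priced* (its path carries
`cESS + cDeath`) but does not move occupancy to Dead: this keeps
revision risk a pure cost load, so raising it increases costs strictly
while leaving QALYs untouched, and keeps the cohort recursion and the
microsimulation exactly consistent. At the published magnitudes the
approximation is ~4 × 10⁻⁶ of annual death mass.

There is no background all-cause mortality by default — the only route
to Dead is surgical death — because the source analysis lists no
life-table input; a per-cycle mortality vector hook
(`background_mortality`) is provided.

### Discounting default

Both discount rates default to **0**. The published totals this
scenario reconstructs are demonstrably undiscounted: 22.61 QALYs over
33 annual cycles is impossible under 3%/yr discounting (whose ceiling
is $\sum_{t=1}^{33} 1.03^{-(t-1)} \approx 21.39$ even at perfect
utility), and the medical arm's published \$26,990 total sits at the
undiscounted $33 \times \$772 = \$25,476$ rather than the discounted
\$16.5k. For policy-grade analyses set
`model_config(discount_rate_costs = 0.03, discount_rate_qalys = 0.03)`.

## Data inputs and the bundled scenario

`crs_fixture()` assembles a complete runnable scenario:

* **Parameter table** (`model_parameters.csv`) — published probability
  and cost estimates. Complementary branch groups are proportionally
  renormalized at load when within 0.002 of summing to 1 (the printed
  intraoperative pair sums to 0.9999); larger deviations are errors.
  The ten Markov state costs are published with standard errors equal
  to their means; taken at face value these imply shape-1 (exponential)
  gamma PSA distributions, which the package retains as printed but
  flags with a warning (see the PSA note below).
* **Year-0→1 transition matrices** for both arms, transcribed as
  printed. The two printed matrices are identical — almost certainly a
  typesetting duplication, but the true surgical-arm dynamics are
  unrecoverable, so the transcription is used for both arms and for all
  surgical cycles. Nonzero rows are renormalized from rounding drift
  (one printed row sums to 1.01).
* **Synthetic components**, provenance-flagged in their file names and
  headers, for inputs that were never published: the entrance
  distribution (0.08/0.13/0.08/0.29/0.42 over states 5,7,8,9,10), the
  medical arm's steady-phase matrix, and the EQ-5D tariff.

The synthetic medical steady-phase matrix is the minimal structure that
separates the arms' long-run utilities: a near-tridiagonal decline with
stay 0.70 / down-one 0.20 / up-one 0.10 (edges 0.90/0.10 and
0.80/0.20). Under it the medical cohort drifts downward about one bin
per decade after its initial (published-matrix) improvement.

### Unobserved states

Rows of an estimated transition matrix with no observed subjects stay
all-zero, and the engine *refuses* to evolve a cohort into such a state
rather than inventing dynamics. The published matrices leave state 6
unobserved while state 5 (which holds entrance mass) feeds it, so the
surgical arm as printed cannot run. The fixture resolves this with
`patch_unobserved_rows()`: unobserved origins become self-loops (an
occupant of an unobserved state stays put) — the minimal assumption,
recorded on the matrix object and reversible via
`crs_fixture(patch_unobserved = FALSE)`.

## EQ-5D scoring and estimation

`score_eq5d()` implements an additive tariff: utility
$= 1 - \text{intercept} - \sum \text{decrements}$, clamped at the
tariff floor. The bundled tariff is a clearly-labelled synthetic
stand-in (anchor 1.0, floor −0.11) because the published algorithm
behind the source utilities is not identified; any published value set
loads from CSV. `bin_huv()` maps utilities to states with half-open
decile bins and a closed top bin; negative utilities clamp into state 1
with a warning. `estimate_transitions()` and `estimate_entrance()`
recover matrices and entrance vectors from longitudinal panels by
direct counting, retaining origin counts.

## Evaluation engines

`run_cohort()` is the deterministic recursion (expectation over the
tree, then matrix–vector propagation with an occupancy trace that must
conserve mass to 10⁻¹⁰). `run_microsim()` simulates seeded individual
trajectories — sampled tree outcome, state path and revision events —
and converges to the cohort values; the suite checks agreement within
3 Monte-Carlo standard errors at n = 20,000.

## Sensitivity analysis

`run_psa()` is a second-order PSA: each of 10,000 draws samples every
uncertain parameter jointly and independently (beta for probabilities,
gamma for costs, moment-matched from the published mean/SE),
renormalizes complementary groups per draw (logged, never silently
clamped), rebuilds the tree, and re-evaluates both arms with
`run_cohort()`. Transition matrices are held fixed because no origin
counts were published to support Dirichlet resampling; a
pseudo-count-driven Dirichlet option exists behind the
`dirichlet_counts` argument. First-order (microsimulation) noise is
deliberately not mixed into the CEAC, which conventionally summarizes
parameter uncertainty.

`ceac()` evaluates net monetary benefit
$\lambda\,\Delta E - \Delta C > 0$ on a WTP grid (ties count as not
cost-effective); `quadrant_summary()` reports the ICER-plane quadrant
fractions (I: costlier & more effective; II: dominated; IV: dominant);
`one_way_sa()` sweeps a single parameter.

**A note on the PSA spread.** Because the state-cost SEs equal their
means, the incremental cost carries a standard deviation near \$32k
around a mean of ≈\$41k. At $\lambda = \$50{,}000$/QALY surgery is
cost-effective in essentially 100% of draws, but at
$\lambda = \$10{,}000$ the attainable certainty is ≈86–87% — no
reading of the published distributional inputs reaches the ≥99% figure
reported at that threshold. The package reports what the inputs imply.

## Worked example

```{r base-case}
fx <- crs_fixture()
res <- evaluate_fixture(fx)
res$comparison
```

```{r one-way}
one_way_sa("cESS", 10500, 21000, steps = 3,
           reference = fx$medical, comparator = fx$surgical,
           params = fx$params, config = fx$config)
```

```{r psa, eval = FALSE}
samples <- run_psa(fx$medical, fx$surgical, fx$params,
                   config = fx$config, seed = 1, n = 10000)
ceac(samples, wtp_grid = c(10000, 50000))
quadrant_summary(samples, wtp = 50000)
```

The reconciliation targets are tolerant by design: the published
base-case totals depend on unprinted inputs, and the printed results
are internally inconsistent (the printed totals give
$36{,}305.83 / 9.13 \approx \$3{,}976.5$/QALY against a printed ICER of
\$4,367.68/QALY — irreconcilable by rounding; `compute_icer()` with
`reported_icer` surfaces both). The fixture lands within ±50% of the
published base-case and one-way ICERs, in plane quadrant I and below
\$10,000/QALY.

## Synthetic cohorts

`generate_panel()` draws per-subject state paths from configurable
entrance vectors and matrices (defaults: 96 surgical subjects over 5
annual waves, 48 medical over 2, mirroring the source cohorts) and
emits utilities uniformly within the occupied bin — the only
defensible placement once utilities are binned.
`generate_eq5d_responses()` inverts the tariff by enumerating all 243
response profiles and picking, per record, the profile whose score is
nearest within the same bin. The generator/estimator closure (matrix
recovery to max-abs ≤ 0.02) is checked on seed-averaged estimates at
5,000 subjects per arm, since a single cell at ~500 subjects/origin
still carries binomial noise up to ~0.018.

What the generator does *not* emulate: demographic covariates and
matching structure, attrition and intermediate missing waves, tariff
heterogeneity, or any treatment switching. Passing tests therefore
demonstrate internal consistency of the pipeline, not fidelity of the
synthetic dynamics to real CRS cohorts.

## Numerical choices and problem sizes

Tolerances: chance-node closure and enumeration sums at 10⁻¹²;
occupancy conservation at 10⁻¹⁰; moment round-trips at 10⁻⁹;
row-stochastic renormalization accepts pre-normalization drift up to
0.02. Statistical checks run at fixed seeds: 10⁶ draws for tree path
frequencies, 20,000 individuals for cohort–microsimulation agreement,
10,000 PSA draws, 12 × 5,000 subjects for matrix recovery — sizes at
which each check resolves its target comfortably while the whole suite
runs in a few minutes.

## Known limitations

* The cycle-1 improvement matrix is applied to *both* arms (as
  printed), which likely flatters the medical arm; the published
  medical QALY total (13.48) is far below what any dynamics consistent
  with the printed matrices produce (≈23 undiscounted), so the absolute
  arm totals should not be over-read — the incremental comparison is
  the meaningful output.
* No background mortality, treatment switching, biologic-therapy arm,
  or polyp-stratified sub-models.
* The bundled tariff, entrance vector and medical steady-phase matrix
  are synthetic stand-ins; conclusions about real cohorts require the
  corresponding real inputs.
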