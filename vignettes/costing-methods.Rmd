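---
title: "Costing methods: ledger model, allocation, replication scenarios and scale curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boostercost)
```

# The costing problem

`boostercost` implements ingredient-based micro-costing for a brief
alcohol-counselling intervention delivered to persons with HIV in
southwestern Uganda, whose booster sessions came in three delivery modes:
approximately monthly live calls from a counselor, or twice-weekly
automated two-way SMS or IVR dialogues. The package answers two kinds of
question:

1. **What did each delivery mode actually cost?** — observed cost tables
   per arm and per participant, stratified by time period, resource class
   and cost level.
2. **What would replication cost at another scale, under another
   operator?** — four hypothetical scenario models and per-participant
   cost curves over enrolment size.

All analysis is in US dollars; local-currency amounts convert at a fixed
study exchange rate (default 3690 UGX/USD, the rate in force at the start
of data collection).

# The ledger model

A ledger row is one cost ingredient with four stratification axes:

* `phase`: `start_up` (consumed before implementation) vs
  `implementation`. The schema enforces that start-up items are capital
  (fixed) costs — in this costing framework, everything consumed before
  operations is a one-time investment.
* `resource_class`: `capital` vs `recurring`, assessed over a one-year
  horizon; per-participant costs accrue over the three-month intervention
  window.
* `level`: `intervention` (does not vary as the programme grows — office
  infrastructure, oversight salaries, software, IT support), `counselor`
  (scales with the number of counselors — furniture, phones, recording
  equipment, counselor time), `participant` (scales per head — workbooks,
  phone credit, messaging charges).
* `arm`: `live`, `sms`, `ivr`, or `shared` for pre-allocation pools.

Categories come from a closed vocabulary (`cost_categories()`); unknown
values are rejected at validation with the offending row numbers, so a bad
file can be repaired line by line. Amounts are carried at full precision
everywhere; rounding (half-up, at cents for money and two decimals for
percentages) happens only at presentation. This order of operations is
load-bearing: the published per-participant table is the overall table
divided by recipients and *then* rounded, and several cells (e.g. office
consumables at \$1,980/160 = \$12.375 → \$12.38) distinguish half-up from
banker's rounding.

## The packaged fixtures and a one-cent wrinkle

The observed cost tables ship as one ledger file per arm
(`load_observed_fixture()`), with exactly one line item per published
category cell — no finer breakdown was published, and inventing one would
be unfalsifiable. In the published tables the block subtotals are each one
cent away from the sum of their own leaf cells (every arm; e.g. the
live-arm leaves sum to \$23,082.93 against a printed total of
\$23,082.92). The package always computes subtotals and totals from the
line items. That convention is not arbitrary: it reproduces the published
per-participant table cell-for-cell, including the participant-level SMS
subtotal (\$756.18/40 = \$18.90, where the printed subtotal \$756.19 would
round to \$18.91). One published per-participant cell — SMS hardware,
printed with four decimals as \$1.5466 — disagrees with its own division
(\$61.48/40 = \$1.537 → \$1.54) and is treated as a typesetting artifact;
the package reports \$1.54.

```{r fixtures}
s <- summarize_arm(load_observed_fixture("live"), "live")
s$total
per_participant(s, recipients(participant_flow(), "live"))$total
```

Recipient counts come from the participant flow: each arm's recipients are
those randomized to it plus wait-list control participants who chose it
(160 live, 40 SMS, 61 IVR). The participant inadvertently randomized twice
is counted once.

# Allocation of shared costs

Costs incurred jointly (counselor salaries, oversight time) are allocated
to arms by relative staff effort, per standard costing practice, with two
rules:

* **Research effort is removed before normalization**, not treated as a
  fourth arm — time spent adapting the intervention or running the trial
  is not an intervention delivery cost.
* **Weights are computed per staff-role pool** (counselors separately from
  oversight staff), because the two groups' effort profiles differ: the
  counselor basis is time on in-person sessions and live booster calls,
  while other staff are allocated on general effort distribution.

Hours logged against `shared` carry no arm information and are excluded
from the weights. An arm with zero effort receives weight zero; only a
pool with *no* intervention effort at all is an error (an unallocatable
pool). Allocation conserves amounts at full precision and preserves all
other strata, and allocating an already arm-specific ledger is a no-op.

# Aggregation

`summarize_arm()` groups an allocated ledger into (phase, level, category)
cells with percentage shares of the arm total; `per_participant()` divides
by recipients and rounds. Percentage shares in the per-participant table
are *copied* from the arm-level table rather than recomputed from the
rounded per-head amounts — the published tables print identical
compositions, and recomputation from rounded cents would drift. Cells are
ordered deterministically (phase, then level, then the canonical category
order), so exported reports are bit-reproducible; `summary_table()` /
`export_summary()` render either table as delimited text or JSON with a
rounding switch.

# Replication scenarios

The scenario engine re-prices an observed arm for arbitrary enrolment
under four models: operator ∈ {NGO, MOH} × staffing ∈ {stand-alone,
integrated}.

* **Staffing.** Stand-alone programmes hire dedicated counselors in whole
  FTEs: `⌈n / capacity⌉`. Integrated programmes pay existing staff
  fractionally: `n / capacity`. This single difference produces the
  sawtooth-vs-smooth contrast in the scale curves, with jumps exactly
  equal to one counselor's annual loaded cost (salary plus per-counselor
  overhead) at multiples of capacity.
* **Operator.** NGO programmes pay trial-level salaries; MOH programmes
  pay MOH scales and do not pay for site rental, utilities or "luxury"
  items.

## Parameter defaults and their provenance

The source analysis published no scenario parameter values, so the package
treats them as configuration with documented placeholder defaults, chosen
once:

| parameter | default | rationale |
|---|---|---|
| counselor hourly rate | \$4/h (loaded) | ≈ \$7,000/yr at full time, a plausible loaded NGO counselor cost in the study setting; drives capacity derivation |
| annual productive hours | 1,760 h/FTE/yr | 220 working days × 8 h |
| counselor capacity | derived: `floor(annual hours / per-participant hours)` | per-participant counselor hours are inferred from the arm's own effort accounting (observed counselor time cost ÷ hourly rate ÷ n); the least arbitrary default, and overridable |
| NGO oversight salary | the arm's observed allocated oversight outlay | "paid as in the observed trial" |
| MOH salary scale | 0.6 × NGO | placeholder ratio; no MOH scale was published |
| MOH exclusions | intervention-level `office_consumables` | this ledger vocabulary has no separate rental/utilities/luxury lines; consumables is the closest stand-in |

The derived capacities on the packaged templates are 122 (live), 183
(SMS) and 169 (IVR) participants per counselor-year — the live arm needs
more counselor time per participant because its boosters are
counselor-delivered calls.

## Connectivity: fixed or usage-based?

The observed tables class connectivity as an intervention-level (fixed)
recurring cost, and `scenario_spec()` follows that by default
(`scale_connectivity = FALSE`). But the technology arms' connectivity is
dominated by per-session messaging and call charges (the observed SMS
connectivity is ≈\$92 per participant over three months of twice-weekly
sessions), which plainly scales with enrolment. The package surfaces this
ambiguity as a flag rather than hiding it:

* `replication_scenarios()` — the n-at-scale replication grid — switches
  usage-based connectivity **on** for the SMS/IVR templates. With fixed
  connectivity, spreading the technology arms' programme-level costs over
  1000 participants would make them *cheaper* than the live arm, which
  contradicts the source's own finding that technology delivery costs
  2.5–3× more per participant at that scale; the usage-based reading is
  the one consistent with it.
* The economy-of-scale crossover analysis uses the **fixed** default with
  start-up amortized over participants: there the question is precisely
  how the technology arms' larger one-time and programme-level costs thin
  out with scale, letting IVR catch up with live.

Relatedly, the source describes replication as excluding start-up costs
yet presents its scale-up figures broken out by start-up vs
implementation, and explains the live/IVR convergence by start-up
amortization. Both behaviours are reachable (`include_startup`), with the
defaults above; neither is asserted as the single truth.

## Self-consistency (identity) scenarios

`identity_scenario()` builds the scenario whose parameters are read off
the observed arm itself, as an arithmetic round-trip check on the engine.
With integrated staffing the natural parameters — capacity at the exact
observed participants-per-FTE, salaries at observed rates — reproduce the
observed arm total exactly. Stand-alone staffing cannot represent the
observed fractional counselor effort with whole FTEs, so its identity
variant solves salaries and overhead from the observed counselor outlay at
ceiling staffing; this checks the stand-alone arithmetic, not a forecast.

# Economy-of-scale curves

`cost_curve()` sweeps enrolment over a grid (default: every multiple of 40
from 40 to 3200 — the analysis range, with a step fine enough to resolve
the sawtooth at plausible capacities) and records total/n. The closed-form
asymptote (participant-level unit cost + loaded counselor cost / capacity
+ usage-based connectivity rate if enabled) bounds every curve point from
below and equals the numerical large-n limit. `find_crossover()` reports
the first grid size where the sign of the difference between two curves
departs from its sign at the grid start, with exact ties resolving to that
size; crossovers are reported at grid resolution, with no interpolation,
since the underlying step functions make interpolated precision spurious.
One-time start-up costs are amortized per participant (divided by n), not
over calendar time; this is the amortization basis implemented and flagged
here.

```{r curves}
tpls <- observed_templates()
live <- cost_curve(
  tpls$live, canonical_scenarios(tpls$live, 1, include_startup = TRUE)$ngo_integrated
)
ivr <- cost_curve(
  tpls$ivr, canonical_scenarios(tpls$ivr, 1, include_startup = TRUE)$ngo_integrated
)
find_crossover(live, ivr)
```

# The synthetic-data generator

`synthetic_spec()` + `generate_ledger()` / `generate_effort_log()` emit
random but structurally valid datasets with *recorded ground truth*:
amounts drawn uniformly within per-category ranges and rounded to cents at
generation (so cent-exact conservation assertions are meaningful);
implementation items emitted as shared pools with a configurable
probability; effort logs whose per-arm hours are exactly proportional to
the same arm weights the ledger's ground truth uses (both generators draw
the weights first from the same seed). Seeded determinism is part of the
public contract. Default amount ranges and recipient counts (160/40/61)
are calibrated to the observed trial's orders of magnitude.

What the generator emulates: the stratification structure, shared-cost
pools, effort-log shape, and the arithmetic path from raw ledgers to
per-participant tables. What it does not emulate: realistic price
distributions, correlated costs across categories, missing or malformed
records, or real effort measurement error. Passing the round-trip
properties therefore certifies the pipeline's bookkeeping — conservation,
allocation, aggregation — on clean data, not robustness to messy field
data.

# Numerical choices

* Half-up rounding with a representation-error guard
  (`round_half_up()`); applied at presentation only.
* Allocation and aggregation are plain sums of full-precision doubles;
  conservation tests use 1e-9 tolerances (well under a cent at these
  magnitudes).
* Weights must sum to 1 within 1e-9; zero-effort arms get weight 0; an
  all-zero pool is an error rather than NaN weights.
* `n = 0` programmes are priced (fixed costs only) but their
  per-participant cost is an error, not `Inf`.
* Test-suite problem sizes: synthetic round-trip properties run over 100
  seeds of 3-arm, 14-item-per-arm ledgers; curve properties use the full
  40–3200 grid. All are desk-scale arithmetic.

# Limitations

* The scenario parameters (MOH scale, hourly rate, capacity derivation)
  are placeholders; scenario *orderings* (integrated ≤ stand-alone, MOH ≤
  NGO at lower salaries, step structure) are robust to them, but absolute
  scenario totals are only as good as the configuration.
* Cost-effectiveness is out of scope (the underlying trial found no
  significant efficacy differences), as are RCT outcomes, acceptability,
  and general accounting features (depreciation, inflation, discounting),
  none of which the source costing uses.
* Fixtures encode published, already-allocated arm costs; the raw effort
  logs and pre-allocation ledgers were not published, so study-true
  allocation inputs cannot be packaged — only synthetic ones.
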