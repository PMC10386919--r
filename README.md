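# boostercost

Micro-costing and scale-up modelling for brief counselling interventions
whose booster sessions are delivered by phone — live counselor calls,
two-way SMS, or interactive voice response (IVR).

Technology-delivered booster sessions are attractive for alcohol-reduction
and similar counselling programmes in low-income settings because they can
be automated and delivered at high frequency. Whether they are actually
cheaper than live counselor calls is an empirical costing question: the
technology arms carry large one-time software investments and usage-driven
connectivity charges, while the live arm carries counselor time that grows
with every participant. `boostercost` implements the ingredient-based
(micro-)costing pipeline used to answer that question for a three-arm trial
among persons with HIV in southwestern Uganda, and generalises its
replication and economy-of-scale analysis into reusable, property-tested
code for health-economics and implementation-science researchers.

## The costing model

Every cost line item is stratified along four axes:

* **phase** — consumed before (`start_up`) or during (`implementation`)
  programme operation; start-up costs are capital (fixed) by construction;
* **resource class** — `capital` vs `recurring`;
* **level** — whether the cost is driven by the programme as a whole
  (`intervention`), by the number of counselors (`counselor`), or by the
  number of participants (`participant`);
* **arm** — `live`, `sms`, `ivr`, or `shared` before allocation.

Shared costs are allocated to arms by staff effort: for a staff pool *p*
with intervention hours *h(p, a)* in arm *a* (research hours removed),

    w(a) = h(p, a) / Σₐ h(p, a),

and each shared item of amount *C* contributes *w(a)·C* to arm *a*. The
per-arm cost table sums items into (phase, level, category) cells with
percentage composition, and the per-participant table divides by the number
of recipients *n* (randomized plus wait-list uptake), rounding half-up to
cents only at presentation.

Replication scenarios re-price an observed arm for arbitrary enrolment *n*
under operator ∈ {NGO, MOH} × staffing ∈ {stand-alone, integrated}:

    total(n) = startup·[include_startup]
             + intervention-level recurring (operator exclusions, re-priced oversight)
             + FTE(n) · (counselor salary + overhead)
             + n · participant-level unit cost,

where FTE(n) = ⌈n / capacity⌉ for stand-alone programmes (whole counselors
are hired as enrolment exceeds capacity) and n / capacity for integrated
ones. Economy-of-scale curves plot total(n)/n over a 40–3200 enrolment
grid; stand-alone staffing makes them sawtoothed, and every curve is
bounded below by the closed-form asymptote
`unit cost + loaded counselor cost / capacity`.

## Worked example

The package ships the trial's observed cost tables as plain-text ledgers.
Reproducing the SMS arm's per-participant table (n = 40 recipients: 31
randomized plus 9 wait-list):

```r
library(boostercost)

ledger <- load_observed_fixture("sms")
s <- summarize_arm(ledger, "sms")
per_participant(s, recipients(participant_flow(), "sms"))
#> Per-participant cost summary, arm = sms (n = 40)
#>   start_up       intervention $     114.69   36.67%
#>     hardware                   $       1.54    0.49%
#>     software                   $     101.06   32.31%
#>     training                   $       1.53    0.49%
#>     office_equipment           $      10.57    3.38%
#>   implementation intervention $     138.66   44.33%
#>     staff_salaries             $      46.24   14.78%
#>     connectivity               $      91.90   29.38%
#>     office_consumables         $       0.52    0.17%
#>   implementation counselor    $      40.54   12.96%
#>     office_equipment           $       1.63    0.52%
#>     office_consumables         $       0.46    0.15%
#>     counselor_time             $      38.46   12.29%
#>   implementation participant  $      18.90    6.04%
#>     printed_material           $      11.49    3.67%
#>     phone_credit_counselor     $       0.08    0.03%
#>     phone_credit_participant   $       7.33    2.34%
#>     sms_charges                $       0.00    0.00%
#>   Total                       $     312.79  100.00%
```

$312.79 per participant, dominated by the one-time SMS software build
($101.06) and usage-driven connectivity ($91.90) — against $144.27 for the
live-call arm and $315.45 for IVR. Re-pricing the live-call arm for a
1000-participant replication under the four scenario models:

```r
scenario_grid(observed_templates()$live, n = 1000)
#>         scenario   total per_participant counselors_required
#> 1 ngo_standalone 88069.6         88.0696             9.00000
#> 2 ngo_integrated 82202.6         82.2026             8.19672
#> 3 moh_standalone 57781.6         57.7816             9.00000
#> 4 moh_integrated 54176.7         54.1767             8.19672
```

An MOH-integrated programme is cheapest ($54.18 per participant); the
live-call arm is the cheapest delivery mode at this scale under every
scenario. Economy-of-scale curves and crossovers:

```r
tpl <- observed_templates()
spec <- function(t) canonical_scenarios(t, 1, include_startup = TRUE)$ngo_integrated
live <- cost_curve(tpl$live, spec(tpl$live))
ivr  <- cost_curve(tpl$ivr,  spec(tpl$ivr))
find_crossover(live, ivr) # 280 — IVR catches up with live as start-up amortizes
plot_cost_curves(list(live, ivr))
```

A seeded generator emits structurally valid synthetic ledgers and effort
logs with recorded ground truth (`synthetic_spec()`, `generate_ledger()`,
`generate_effort_log()`); `inst/scripts/generate_synthetic.R` materializes
them as files from the command line.

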