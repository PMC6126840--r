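---
title: "Auditing WHO modified partographs: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing WHO modified partographs: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partoaudit)
```

## The problem this package addresses

At first-level maternity facilities in many low-resource settings, a single
health worker monitors labour with the WHO *modified* partograph: a one-page
chart of the active phase (from 4 cm cervical dilatation) recording foetal
observations (heart rate, liquor, moulding), labour progress (dilatation,
descent of the head, contractions) and maternal observations (blood
pressure, pulse, temperature, urine). The chart exists to trigger a
decision: when it shows an abnormal labour, the woman should be referred to
a facility with emergency obstetric care.

`partoaudit` turns the retrospective audit of such registers into a
reproducible pipeline. Given three flat tables — intrapartum case records,
long-format partograph observations, and a referral register — it answers
three questions:

1. **Did the partographs show an indication of abnormal labour?** A
   rule-based classifier applies four referral-indication definitions
   (foetal distress, prolonged labour, obstructed labour, pre-eclampsia).
2. **Were the partographs charted adequately?** A completeness audit scores
   each component against its WHO monitoring interval and compares the
   abnormal and no-indication groups with a pooled two-proportion z-test.
3. **Were flagged cases actually referred?** Referral-register linkage with
   a scope filter, assembled into a cohort flow report.

Because facility registers are rarely shareable, the package also contains a
labour-cohort simulator with known ground truth; every pipeline stage is
tested against it.

## Alert- and action-line geometry

The modified partograph plots dilatation against time. The *alert line*
starts at the active-phase anchor — here defined as the first plotted
dilatation of at least 4 cm — and rises at 1 cm per hour; the *action line*
runs parallel, 4 hours to its right:

$$t_{\mathrm{alert}}(d) = t_0 + 60\,(d - d_0), \qquad
  t_{\mathrm{action}}(d) = t_{\mathrm{alert}}(d) + 240 \quad
  \text{(minutes, } d \ge d_0\text{)}.$$

Design choices, all exposed as configuration:

* **Anchor at the first plot $\ge 4$ cm, not at admission.** Field
  partographs anchor the printed alert line where active-phase charting
  starts; for women admitted earlier than 4 cm there is no universally
  stated convention, so the first active-phase plot is used.
* **"Right of the alert line" is strict** ($t > t_{\mathrm{alert}}$): a
  point *on* the line is normal progress. **"Reaches the action line" is
  inclusive** ($t \ge t_{\mathrm{action}}$): touching the line already
  demands action.
* **Charted regression is ignored by the line tests.** Cervical dilatation
  cannot decrease; a plot below the anchor dilatation is a charting error
  and is logged rather than classified.
* All line arithmetic is in integer minutes; no floating point is involved.

## The four abnormal-labour rules

| Condition | Rule |
|---|---|
| Foetal distress | FHR $< 120$ or $> 160$ bpm on at least two observations, **or** meconium-stained liquor (`M`) |
| Prolonged labour | any dilatation plot right of the alert line or reaching the action line |
| Obstructed labour | moderate/severe contractions **and** (`+++` moulding **or** a descent plateau) |
| Pre-eclampsia | a BP pair with SBP $> 140$ or DBP $> 90$ mmHg **and** albuminuria |

Where the printed definitions leave room, the defaults take the most
literal reading and a switch exposes the alternative:

* **FHR boundaries are excluded** (120 and 160 are "less than"/"more than"
  violations only strictly beyond them), and the two violating observations
  **need not be consecutive**; `fhr_require_consecutive = TRUE` gives the
  stricter reading. Violations in opposite directions both count, since the
  criterion is a single disjunction.
* **"Moderate or severe" contractions** map to the WHO shading convention
  for contraction duration: 20–40 s and > 40 s.
* **A descent plateau** is the minimal operational reading: at least
  `descent_plateau_min_obs` (default 2) consecutive descent observations
  with no decrease in fifths palpable. No extra value condition is imposed:
  an earlier candidate refinement (ignoring plateaus at 0/5, i.e. an
  engaged head) was rejected because it breaks the classifier's
  monotonicity guarantee — under the pure rule, adding an observation can
  only switch flags from false to true.
* **Pre-eclampsia needs no repeat reading**: one qualifying BP pair
  suffices (only the FHR rule states a repetition requirement), and
  **trace albuminuria does not count** by default (clinical convention
  treats trace as negative); `include_trace_albumin = TRUE` reverses this.
  BP is evaluated on *pairs* — an `sbp` and `dbp` sharing a time point —
  because the two thresholds are tested jointly on one measurement.

Two caveats on the invariants. Permutation invariance holds for real
partographs (one plot per grid cell); if a file contains two different
values for the same component at the same minute, their relative order is
taken from the file. Monotonicity likewise presumes a physically valid
cervicograph: inserting a *backdated* high dilatation plot can re-anchor
the alert line and change the classification, which is why the property is
stated (and tested) for trajectory-consistent additions.

## The completeness rule

A component is "appropriately recorded" when it has **at least two
plottings at the required interval**: half-hourly for FHR, contractions and
pulse; two-hourly for temperature, urine volume and urine albumin;
four-hourly for liquor, moulding, dilatation, descent and blood pressure.
That phrase admits two readings, both implemented:

* `lenient` (default): at least one *adjacent pair* of observations within
  the interval — the most literal reading of "at least two plotting at the
  time interval";
* `strict`: *every* adjacent gap within the interval.

The blood-pressure interval is genuinely ambiguous in circulation —
monitoring protocols say four-hourly while some partograph forms print
half-hourly — so it defaults to 240 min, is configurable
(`interval_schedule(bp_interval_min = 30)`), and the choice is recorded in
the audit log. Labours shorter than an interval get no exemption: one
plotting is never "appropriate", which may understate completeness for
women admitted near full dilatation (a known limitation of this audit
design). Percentages are rounded half-up to one decimal.

Group comparison uses the pooled two-sided two-proportion z-test without
continuity correction,

$$z = \frac{\hat p_1 - \hat p_2}
  {\sqrt{\hat p(1-\hat p)\left(\tfrac1{n_1}+\tfrac1{n_2}\right)}},
  \qquad \hat p = \frac{x_1 + x_2}{n_1 + n_2},$$

whose square equals the 1-df chi-square statistic on the same 2×2 table
(cross-checked in the tests against `prop.test(correct = FALSE)`). When the
pooled proportion is 0 or 1 the statistic is undefined; the result is
marked *degenerate* and printed as a dash. No multiple-testing correction
is applied across components: each row is reported as its own unadjusted
comparison, matching standard practice in completeness audits.

## Flow, linkage and reporting

Cases arriving above 8 cm are near or at full dilatation, where a
partograph no longer informs decisions; eligibility is therefore
dilatation **$\le 8$ cm, inclusive**. Referral linkage is one-to-one by
case id: duplicate referral rows for one case collapse to the earliest
event (logged), referrals matching no case are logged orphans excluded from
counts, and rows without a case id are women referred at initial assessment
without admission — they contribute only to that flow node, with no
imputation of their characteristics. Referral reasons outside partograph
scope (maternal general illness, postpartum haemorrhage, retained placenta,
and neonatal reasons) are retained but marked, and never counted as
referred cases in the audit. Age bands in the background tables are 15–19,
20–24, 25–29, 30+, with an explicit "no information recorded" category —
missingness is always a reported category, never silently dropped.

## The simulator: what it emulates, and what it does not

`simulate_cohort()` draws, per admitted case: facility, age (truncated
normal, mean 24.9, sd 4.5 years), parity, membrane status, and arrival
dilatation from a categorical distribution whose default puts 55.3% of mass
at 8 cm or less. Active-phase dilatation is linear at a per-case rate:
truncated normal with mean 1.2 and sd 0.3 cm/h on $[1, 2]$ for cases not
drawn prolonged, and a fixed 0.4 cm/h for prolonged cases. The truncation
is load-bearing, not cosmetic: with whole-centimetre plotting (the floor of
the trajectory) on the four-hourly grid plus a delivery examination, a rate
of at least 1 cm/h makes every plotted point provably on or left of the
alert line, while 0.4 cm/h makes the first post-anchor plot provably right
of it. The rule engine therefore recovers the drawn conditions *exactly*
under full charting, so prevalence-recovery tests measure only binomial
sampling error. The upper truncation at 2 cm/h keeps every labour at least
an hour long, so each component can receive its two plottings.

The four conditions are drawn independently per case (a case may carry
several), with default prevalences 6.8%, 3.1%, 0.6% and 0.6% — chosen so
roughly 11% of cases carry at least one indication, with foetal distress
the most common and prolonged labour second, the mix typical of first-level
facility audits. Condition signatures are constructed, not hoped for: two
consecutive out-of-range FHR values (105 or 175 bpm) or meconium for
distress; elevated BP pairs (150–170/95–105) with albuminuria throughout
labour for pre-eclampsia; moderate/severe contractions with `+++` moulding
or a constant-descent plateau for obstruction. Cases *not* drawn with a
condition are kept clean by construction: FHR clamped inside (120, 160), BP
clamped below thresholds, and descent charted strictly decreasing, with
charting stopping once the head is engaged — the clinically sensible
behaviour that also prevents spurious plateaus.

Observation times snap to the component's schedule grid (30/120/240 min
from admission) plus a delivery examination. Charting dropout is an
independent per-due-interval Bernoulli per component (`sbp`/`dbp` pairs and
the contraction frequency/duration cell share draws), with default
probabilities spanning the realistic range from near-complete urine-albumin
charting (0.95) to near-absent pulse charting (0.08). Thinning uses common
random numbers drawn after all values in a fixed order, so lowering any
probability deterministically removes observations and completeness is
monotone in dropout — the property the tests exercise. Referral behaviour
follows ground truth with a compliance probability (default 0.07, the low
compliance typical of the setting), plus out-of-scope referral noise and a
stream of referrals without admission (default rate 0.292 per admitted
case).

Reproducibility: one root seed, per-case substreams derived by counter, so
the same parameters and seed give byte-identical register files.

What the simulator deliberately does **not** emulate: physiological labour
curves (Friedman-style acceleration), correlated or bursty charting dropout
(provider-absence runs), retrospective chart completion, dependence between
conditions, or transfer-time geography. Tests passing on simulated cohorts
therefore demonstrate the pipeline's correctness under the stated
generative model, not the behaviour of any real register set.

`make_reference_cohort()` is the complementary fixture: a fully
deterministic cohort (no random draws) whose audited flow is 1548 presented
/ 1198 admitted / 350 referred without admission / 663 eligible / 648 with
partograph / 71 flagged / 5 in-scope referrals / 1 referred with a charted
indication, and whose 71 flagged partographs split 44 foetal distress + 20
prolonged + 4 obstructed + 3 pre-eclampsia. Only the two largest shares of
that split (62% and 28%) are pinned by the audit margins it reproduces; the
zero-overlap split is the simplest completion and is asserted nowhere
except in this fixture's own documentation.

## Numerical and degenerate-input conventions

* Time is integer minutes since admission; file timestamps are ISO-8601,
  converted at load. Percentages round half *up* (away from zero) at one
  decimal, matching register-summary convention rather than banker's
  rounding.
* An empty partograph classifies as all-false; a partograph whose
  dilatation never reaches 4 cm has no line geometry, classifies as not
  prolonged, and is tallied in the audit log.
* Loaders never silently drop rows: rows in = rows accepted + rows
  rejected, with every reject enumerated by row number and reason.
  Duplicate case ids and admitted referrals without a case id are hard
  errors (they corrupt one-to-one linkage); everything else is a row-level
  reject.

## Problem sizes used by the test suite

Unit and property tests run on cohorts of 40–150 simulated cases and on
1000 randomly generated small partographs (at most 20 observations) checked
against an independent brute-force implementation of the four rules.
Parameter-recovery tests simulate 2000 cases per condition at prevalence
0.11 under full charting, over three fixed seeds, and require the
rule-engine estimate within two binomial standard errors. The acceptance
script audits the deterministic reference cohort and one seeded simulation
of 8000 fully charted cases; the larger size keeps the recovered-prevalence
estimate's sampling error near 0.35 percentage points.
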