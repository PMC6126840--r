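# partoaudit

Rule-based audit of WHO modified partographs from facility registers.

At first-level maternity facilities, the WHO modified partograph charts the
active phase of labour — foetal heart rate, liquor, moulding, cervical
dilatation, descent of the head, contractions, and maternal vitals — and is
meant to trigger referral when labour turns abnormal. Auditing how the tool
is actually used requires three linked register tables: intrapartum case
records (one row per admitted woman), long-format partograph observations
(one row per plotted value), and the referral register. `partoaudit` is for
maternal-health researchers and programme evaluators who need that audit to
be reproducible: strict CSV schemas in, a classed audit object and
machine-readable report out.

## What it computes

**Alert/action-line geometry.** The alert line is anchored at the first
plotted dilatation ≥ 4 cm and rises 1 cm/h; the action line is 4 h to its
right:

    t_alert(d)  = t0 + 60 (d − d0)        [minutes, d ≥ d0]
    t_action(d) = t_alert(d) + 240

"Right of the alert line" is strict (`t > t_alert`); "reaches the action
line" is inclusive (`t ≥ t_action`).

**Four abnormal-labour rules**, each flag backed by the triggering
observations as evidence:

| condition | rule |
|---|---|
| foetal distress | FHR < 120 or > 160 bpm on ≥ 2 observations, or meconium-stained liquor |
| prolonged labour | dilatation right of the alert line or reaching the action line |
| obstructed labour | moderate/severe contractions AND (+++ moulding OR descent plateau) |
| pre-eclampsia | BP pair with SBP > 140 or DBP > 90 mmHg AND albuminuria |

**Charting completeness** per component — at least two plottings at the WHO
interval (half-hourly FHR/contractions/pulse, two-hourly temperature/urine,
four-hourly liquor/moulding/dilatation/descent/BP) — compared between
abnormal and no-indication groups with the pooled two-proportion z-test

    z = (p̂1 − p̂2) / sqrt( p̂ (1 − p̂) (1/n1 + 1/n2) ),   p̂ = (x1 + x2)/(n1 + n2)

whose square is the 1-df chi-square statistic without continuity correction.

**Cohort flow**: presented → admitted → eligible (≤ 8 cm on arrival) →
partograph initiated → abnormal indication → referred, with referral-scope
filtering (postpartum/neonatal/general-illness reasons are not
partograph-based referrals) and background characteristic tables.

A built-in simulator (`simulate_cohort()`) generates all three registers
with known ground truth, and `make_reference_cohort()` is a deterministic
audit fixture with fixed flow counts.

## Worked example

```r
library(partoaudit)

sim <- simulate_cohort(sim_params(n_cases = 300, seed = 42))
audit <- partograph_audit(sim$cases, sim$observations, sim$referrals)
audit
```

```
Partograph audit
Cohort flow
  presented in labour                           394
  admitted for childbirth                       300 (76.1%)
  referred without admission                     94 (23.9%)
  eligible (dilatation <= 8 cm)                 171 (57.0%)
  partograph initiated                          168 (98.2%)
  indication of abnormal labour                  10 (6.0%)
  in-scope referrals among partograph cases       0
  referred with charted indication                0

Completeness (% appropriately recorded; p: abnormal vs no indication)
  fhr                 30 min   overall  85.1  abnormal  90.0  none  84.8  p 0.655
  contraction_freq    30 min   overall  97.6  abnormal 100.0  none  97.5  p 0.611
  pulse               30 min   overall   4.2  abnormal  20.0  none   3.2  p 0.010
  temperature        120 min   overall  42.9  abnormal  60.0  none  41.8  p 0.259
  urine_volume       120 min   overall  46.4  abnormal  80.0  none  44.3  p 0.028
  urine_albumin      120 min   overall  93.5  abnormal 100.0  none  93.0  p 0.388
  liquor             240 min   overall  53.6  abnormal  70.0  none  52.5  p 0.283
  moulding           240 min   overall  10.1  abnormal  10.0  none  10.1  p 0.990
  dilatation         240 min   overall  76.8  abnormal  90.0  none  75.9  p 0.307
  descent            240 min   overall  72.0  abnormal 100.0  none  70.3  p 0.042
  bp                 240 min   overall  63.7  abnormal  70.0  none  63.3  p 0.669
```

Of 300 admitted cases, 171 arrived in the chartable range (≤ 8 cm), a
partograph was started for 168, and the rule engine flagged 10 of them —
6.0% — as carrying an indication of abnormal labour. The completeness rows
read like a register audit: urine albumin is charted almost always (93.5%),
maternal pulse almost never (4.2%), and the p-column tests whether flagged
partographs were charted more completely than unflagged ones.
`summary(audit)` adds the per-condition breakdown and the audit log;
`write_report(audit, "report/")` emits `report.json`, `report.md`,
`flags.csv` and `completeness_table.csv`. Single cases can be inspected
with `plot(audit$partographs[[1]])`, which draws the cervicograph against
the alert and action lines.

A thin command-line wrapper is installed at
`inst/scripts/partoaudit.R` (subcommands `simulate`, `classify`, `audit`).

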