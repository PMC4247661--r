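---
title: "Wear-time algorithms, cut-point summaries and the simulated mail protocol"
author: "actiwear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wear-time algorithms, cut-point summaries and the simulated mail protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actiwear)
```

## The problem

Hip-worn accelerometers such as the ActiGraph GT3X+ record triaxial
"activity counts" integrated into 60-second epochs. Before any
physical-activity metric can be computed, each epoch must be classified as
*worn* or *not worn*: sedentary behaviour and monitor-off time both look
like near-zero counts, so the two are disentangled either by participant
self-report (a monitor log with dates and on/off times) or by automated
zero-run algorithms. In mail-based cohort studies the monitor records for
one to several days **in postal transit** on each side of the wear period;
handling vibration registers intermittent nonzero counts, which zero-run
algorithms can misread as wear. This package implements the full processing
grid needed to study these choices — five wear-time methods crossed with two
count signals — plus the agreement statistics to compare them, and a
synthetic cohort generator with ground truth so every stage is testable at
desk scale.

## Count signals

Each epoch carries counts from the vertical (`axis1`), anterior–posterior
(`axis2`) and medio-lateral (`axis3`) axes. Analyses use either the vertical
axis alone or the vector magnitude

$$\mathrm{VM}_k = \sqrt{a_{1k}^2 + a_{2k}^2 + a_{3k}^2}.$$

`compute_vm()` keeps the VM as an unrounded real number and every threshold
below compares against that real value: rounding to integers would move
epochs sitting exactly at a cut-point (e.g. VM 199.6) across classes, and no
rounding convention is part of any published rule. Only 60-s epochs are
accepted, and input series must be contiguous — a gap in the timestamps is a
hard error rather than an implicit zero-fill, because the non-wear rules are
run-length based and silently fabricated zeros would fabricate non-wear.

## Non-wear detection rules

Both automated rules scan for sustained spans of zero counts; they differ in
window length and in how interruptions are tolerated.

**Troiano (NHANES) rule** — non-wear is a maximal span of zero-count epochs
with total length ≥ 60 min. Runs of 1–2 consecutive epochs with counts
strictly between 0 and the spike tolerance (100 cpm vertical; 200 cpm VM, in
line with the VM sedentary cut-point) may interrupt the span; any epoch at
or above the tolerance, or any nonzero run of ≥ 3 epochs, terminates it.
Spans begin and end on zero epochs, and tolerated interruption epochs inside
a qualifying span count as non-wear. The published phrase "1–2 minutes" is
ambiguous about whether it caps each interruption or all interruptions
together; consistent with the NHANES reference implementation we allow any
number of separate 1–2 min interruptions by default, and expose
`max_interruption_runs` so the stricter reading (cap the number of runs) is
testable. Under the strict cap, qualifying sub-spans can overlap, so the
implementation marks the union of all qualifying windows.

**Choi rule** — non-wear is a maximal span of zero-count epochs with total
length ≥ 90 min, allowing nonzero interruption runs of ≤ 2 epochs (any
magnitude — there is no count cap) when the interruption is flanked by ≥ 30
consecutive zero-count minutes. The original description says "either up or
downstream", but the validated form of the rule requires the flank on
*both* sides; we default to the conjunctive rule (`flank_mode = "both"`) and
provide `"either"` as a toggle. The same criteria are applied unchanged to
VM input.

Two structural consequences are worth knowing. First, spans are detected on
the full continuous record with no day-boundary reset — mail-transit spans
legitimately cross midnight — and minutes are attributed to calendar days
afterwards (`wear_minutes()`, midnight split, epoch owned by the date
containing its start). Second, a qualifying span may begin at the first
epoch or end at the last one; Choi's interruption flanks, however, must
exist within the record. Note an asymmetry between the rules: a sequence
with no zero run ≥ 30 min can never produce Choi non-wear, but Troiano can
chain many short zero runs through tolerated interruptions (e.g. 29 zeros,
2 low-count epochs, 29 zeros, … accumulates past 60 min), so no analogous
guarantee holds for Troiano unless interruptions are suppressed.

**Reference oracle.** `oracle_nonwear()` is a second, independent
implementation of both contracts — a sequential epoch-by-epoch span scan,
deliberately simple, sharing no code with the run-length production path.
The test suite checks epoch-for-epoch agreement on 1,000 block-structured
random sequences of 2,880 epochs per rule and axis variant, plus hand-built
boundary cases.

## Monitor logs

A log day records the date, wake time, monitor-on time, monitor-off time
and bed time, any component of which may be missing — most commonly the
AM/PM indicator. `impute_meridiem()` resolves missing indicators with a
deterministic rule sequence, never overwriting a recorded value:

1. *Default windows*: wake/on default to AM for hours 4–11; off/bed default
   to PM for hours 5–11 and to AM for hour 12 (12 AM = midnight, 12 PM =
   noon).
2. *Ordering*: a remaining on-time indicator is chosen so that on ≥ wake; an
   off-time indicator so that off ≤ bed and off > on — but only when exactly
   one choice satisfies every applicable constraint.
3. Anything else stays missing; contradictions are flagged in the audit
   table along with every imputed value.

These rules are this package's own operationalization of "reasoned
assumptions" imputation; they are kept behind a single function precisely so
an alternative rule set can be swapped in.

Two wear-mask constructions use the log. The **detailed log**
(`detailed_log_mask()`) marks epochs in `[on, off)` on each day with a
complete date + on + off; half-open intervals mean abutting days never
double-count an epoch, off-times are owned by their log date (a log asks for
same-day times; day-level accounting needs an unambiguous owner), and a day
with any unresolved component contributes no wear. The **limited log**
(`limited_log_restrict()`) uses only the *dates*: an algorithm mask is
forced to non-wear on every date absent from the log, which is exactly what
removes mail-transit days. The operation never increases wear and is
idempotent; a log with no usable dates at all is a refusal, mirroring the
exclusion of participants who return no log.

## Intensity classification and summaries

Worn epochs are partitioned with standard adult hip cut-points:

| axis | sedentary | light | MVPA |
|------|-----------|-------|------|
| vertical | < 100 cpm | 100–1951 | ≥ 1952 |
| vector magnitude | < 200 cpm | 200–2689.99… | ≥ 2690 |

The classification is `sedentary if c <` lower, `MVPA if c ≥` upper, light
otherwise, so sedentary + light + MVPA = wear holds as an exact integer
identity for every day — a conservation property the tests enforce
everywhere. Published variants of the VM thresholds disagree in minor ways
(a light lower bound of 150 would leave a 150–200 gap; an MVPA bound of 2691
would leave a one-count hole), so we pin the gapless pair (200, 2690); both
constants are config-overridable.

A day is **valid** with ≥ 600 min (10 h) of wear within the calendar date.
Subject summaries average daily metrics over valid days only and carry the
≥ 1 and ≥ 4 valid-day eligibility flags; cohort summaries report medians and
interquartile ranges across subjects with ≥ 1 valid day, percentages against
the eligible cohort size, and the percentage of subjects with **more than 7
valid days** — for a 7-day protocol, a direct diagnostic of mail noise.
Quantiles use linear interpolation between closest ranks (R type 7); the
convention matters for cross-implementation agreement and is fixed rather
than configurable. Cohort medians are medians of subject-level means over
valid days (the alternative — pooling all person-days — weights subjects by
their number of valid days and is not implemented).

## Method agreement

`wilcoxon_signed_rank()` compares a paired metric between the vertical and
VM signals within a wear method. Conventions are pinned: zero differences
dropped, tied absolute differences mid-ranked, exact two-sided p computed
from the full distribution of the positive-rank sum whenever ≤ 25 non-zero
differences remain (a counting recursion over doubled mid-ranks, so ties are
exact too), and otherwise a continuity-corrected normal approximation with
the usual tie-corrected variance. The 25-pair switch point keeps enumeration
cheap where it is exact and the approximation accurate where it is used.
`bland_altman()` reports mean bias and 95% limits of agreement
(bias ± 1.96 × SD of the paired differences, n − 1 denominator).
`run_grid()` drives the full 5 × 2 grid over a cohort, recording per-subject
exclusions (e.g. no usable log dates) rather than failing, and is
deterministic given inputs and configuration.

## The synthetic cohort

`simulate_cohort()` emulates the mail protocol end to end; its defaults are
the study conditions the rest of the package is tested under.

* **Schedule**: 7 true wear days, preceded and followed by 1–3 in-transit
  days; daily on ≈ 07:00 ± 45 min, off ≈ 21:00 ± 60 min (clamped to
  04:00–11:59 and 17:00–23:59), giving ~14 h daily wear; with probability
  0.15 a 30–90 min midday removal gap.
* **Worn counts**: an intensity mixture (sedentary 0.689, light 0.300, MVPA
  0.011) chosen so the truth-mask vertical-axis composition lands near 600
  sedentary / 280 light / 9 MVPA min per day, the magnitudes reported for
  older women in mail-based cohorts. Sedentary epochs are 0 cpm with
  probability 0.45, otherwise uniform 1–99; light uniform 100–1951; MVPA
  uniform 1952–5500.
* **Lateral axes**: axis2 and axis3 are axis1 times independent log-normal
  ratios whose location depends on the vertical band — elevated (median 1.6)
  below 100 cpm, 0.55 in the light band, 0.60 in the MVPA band. Activities
  of daily living involve relatively more anterior–posterior and
  medio-lateral motion than locomotion does, and this mechanism (not fiat)
  reproduces the reported contrast directions: VM cut-points reclassify part
  of vertical-axis sedentary time as light and part of light as MVPA, so
  sedentary(VM) < sedentary(vertical) and MVPA(VM) > MVPA(vertical) for
  essentially every subject.
* **Mail noise**: each in-transit day carries Poisson(16) bursts of 1–30 min
  of uniform 1–500 cpm counts over a zero baseline — sparse, low-magnitude
  vibration rather than continuous activity. Bursts this frequent leave most
  inter-burst gaps below the Choi 90-min window but let many exceed the
  Troiano 60-min window, which is what makes Choi-alone inflate valid days
  more than Troiano-alone, with the limited-log hybrids at exactly zero
  (a log never lists more than the 7 wear dates). No quantitative
  description of in-mail count magnitudes exists to calibrate against, so
  these are free parameters fixed once to reproduce that qualitative
  ordering.
* **Logs**: true dates; reported times are the true times plus N(0, 5 min)
  noise; wake 15–60 min before on, bed 15–90 min after off. Missingness is
  then injected per day index at the per-day rates observed in a 7,650-log
  mail cohort (dates 0.03–2.2%, times 1.4–4.3%, AM/PM 19.3–23.4%); the AM/PM
  injection skips a field whose clock time was already removed, since an
  indicator without a time is unobservable.
* **Reproducibility**: one master seed draws a substream seed per subject,
  so subject *k* is byte-identical in any cohort of size ≥ *k*.

What the generator does **not** model: gait or raw 30 Hz acceleration,
weekday/seasonal structure, within-day autocorrelation of activity (worn
epochs are i.i.d. given class), monitor clock drift, or multi-interval wear
days (the log format carries one on/off pair per day). Passing tests
therefore demonstrate that the *pipeline machinery* is correct under a
realistic schedule/composition/noise model — not that any particular
real-cohort estimate is reproduced.

## Problem sizes and numerical choices

The shipped tests run the oracle battery at 1,000 × 2,880 epochs per rule
variant, and the end-to-end checks on a 200-subject default cohort
(~3 million epochs through all five methods and both axes) — sizes chosen so
the whole suite completes in a few minutes on one core while keeping every
stochastic check well-powered. Degenerate inputs are pinned by tests:
empty series, all-zero and all-active records, spans touching record edges,
interruptions at span edges, logs with no dates, cohorts with zero-variance
differences (degenerate signed-rank p = 1; Bland–Altman limits collapse to
the bias). `scripts/acceptance.R` re-runs the default study from scratch
under a caller-supplied seed and writes every headline quantity as JSON.

## Known limitations

* The AM/PM imputation scheme is a normative re-specification; studies using
  different "reasoned assumptions" will recover slightly different samples.
* The Troiano/Choi readings above resolve genuine ambiguities in the
  published prose; the toggles (`max_interruption_runs`, `flank_mode`)
  exist so either reading can be reproduced, but defaults follow the
  reference implementations.
* Timestamps are timezone-naive local time; daylight-saving transitions are
  out of scope.
* Cohort-scale numbers from any real study are population statistics; the
  simulator targets their *structure* (orderings, directions, rough
  magnitudes), not their values.
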