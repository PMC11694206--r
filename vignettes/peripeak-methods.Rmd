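---
title: "Peri-peak speed dynamics: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peri-peak speed dynamics: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peripeak)
```

## The problem

Elite team-sport players are monitored in competition with 10 Hz GNSS
units that report speed (km/h) against time (ms). Sprint *tests* start
players from a standing position, but match sprints rarely do: players
reach their match peak speed from a rolling ("flying") start, and they
leave it by decelerating hard. `peripeak` reconstructs that peri-peak
story from raw speed traces: it validates each player-match peak speed,
cuts the 20-second window around it (10 s either side at 0.1 s
resolution), and quantifies the per-second speed dynamics with paired
mean differences and magnitude-banded effect sizes, plus between-position
peak-speed comparisons.

The pipeline is organised in five stages, each an exported function
family: trace I/O (`read_trace()`, `validate_grid()`), filtering and peak
validation (`filter_speeds()`, `find_match_peak()`), windowing
(`extract_window()`, `per_second_profile()`, `speed_changes_01s()`),
effect statistics (`paired_mean_diff()`, `independent_mean_diff()`,
`classify_effect_size()`), and reporting (`run_pipeline()`,
`write_report()`). A synthetic trace generator (`simulate_trace()`,
`simulate_cohort()`) provides seeded, ground-truthed data, since real
club monitoring records are proprietary.

## Peak validity: the corroborating-effort rule

Raw GNSS speed occasionally spikes implausibly. Two filters guard the
peak:

1. **Plausibility cap.** Samples above 44.45 km/h (faster than any human)
   are marked missing. Nothing is interpolated — an interpolated value
   could fabricate a peak.
2. **Corroboration.** A candidate peak `v` only counts if *another
   effort* reached at least `v − 1` km/h in the same match. We
   operationalise "another effort" as: an observed sample at or above
   `v − 1` such that speed was observed *below* `v − 1` somewhere between
   it and the candidate. Equivalently, the corroborating sample must lie
   outside the candidate's own contiguous super-`(v − 1)` run. This is
   the weakest reading that stops a sprint's own samples from vouching
   for it while imposing no arbitrary time gap. Missing samples do not
   close a run: only observed sub-reference speed separates efforts, so a
   dropped sample cannot manufacture corroboration.

Candidates are the maxima of super-threshold bouts (maximal contiguous
runs of samples at or above the 25.2 km/h sprint threshold), examined in
descending order. If the global maximum fails corroboration it is
*demoted*, not fatal: the next-highest bout maximum is tested with the
margin recomputed for it. A single spurious spike therefore never voids a
whole player-match. The returned peak must itself exceed 25.2 km/h; a
match with no corroborated super-threshold effort has no match peak
(`NULL`, logged by the pipeline).

Two consequences worth knowing:

* The corroborating sample is **not** required to exceed 25.2 km/h
  itself, only `v − 1`; the published rule constrains the margin, not the
  corroborator's absolute speed.
* Validity is **not monotone** in the margin in general: widening the
  margin lowers the corroboration bar (an effort 1.5 km/h below the
  maximum corroborates at margin 2 but not at margin 1) and
  simultaneously widens the run a corroborator must escape. Both
  behaviours are exercised in the test suite.

Sprints are additionally typed `explosive`/`leading` by whether any of
the five samples (0.5 s) before the first super-threshold sample lie in
the 19.8–25.2 km/h high-speed-running band (band edges inclusive).

## The peri-peak window

`extract_window()` takes the 201 slots at offsets −100..+100 deciseconds
from the peak, aligned to the trace's own 100 ms grid anchored at the
peak sample — no resampling. A slot is matched to the sample nearest its
nominal time within ±10 ms (device jitter tolerance; anything larger is a
gap). Slots beyond the trace boundaries, at gaps, or at filtered samples
are missing; the window always has exactly 201 slots, so late-match peaks
are retained with truncated tails rather than discarded, which would bias
the post-peak profile. If the global maximum was rejected as
uncorroborated noise and the validated peak's window overlaps it, any
slot faster than the validated peak is masked — by the validity rule it
is noise, and masking preserves the invariant that the peak slot is the
window maximum.

Per-second reduction has two modes. The default `instant` takes the
sample *at* each integer-second offset, reading the timeline as 21
instantaneous speeds. `block_mean` averages the ten 0.1 s slots of the
second-long block on the peak side of each offset (blocks mirrored about
the peak), for users who read "1-second interval" as an average. The two
agree exactly on constant windows; `instant` is the default because the
per-second contrasts below compare *registered speeds at* one-second
marks. In `instant` mode a value is unavailable when its slot is missing;
in `block_mean` mode only when all ten slots are.

`speed_changes_01s()` returns the 200 consecutive 0.1 s deltas; on
gap-free windows they telescope exactly to the end-to-start speed
difference, an identity the tests assert.

## Effect statistics

Consecutive one-second offsets are compared **within** player-match
windows: for each of the 18 consecutive pairs (10–9 s before … 2–1 s
before, then — the peak itself excluded — 1–2 s after … 9–10 s after),
`paired_mean_diff()` reports

* the mean paired difference with a t-based 95% CI
  (`mean(b − a) ± t₀.₉₇₅,ₙ₋₁ · SD(b − a)/√n`), and
* Cohen's *d* standardised by the **average condition SD**,
  `s_av = √((SD(a)² + SD(b)²)/2)` — the estimation-statistics convention
  for paired designs — not by the SD of the differences. With highly
  correlated adjacent seconds the difference SD is far smaller than the
  condition SDs, and standardising by it would inflate *d* several-fold;
  published per-second effect sizes are only consistent with the
  condition-SD standardiser.

The CI for *d* uses the common paired-design normal approximation
`var(d) = (1/n + d²/(2n)) · 2(1 − r)`, with `r` the between-condition
correlation (taken 0 when a condition is constant). The approximation is
documented rather than exact; reconstruction of published *d* intervals
is therefore approximate by design and is not asserted anywhere.

Magnitude bands for |d|: trivial < 0.2 ≤ small < 0.6 ≤ moderate < 1.2 ≤
large < 2.0 ≤ very large < 4.0 ≤ extremely large, with band edges
belonging to the larger band. If the CI spans zero the effect is
**unclear** regardless of |d|; an endpoint exactly at zero counts as
spanning (the conservative reading). No multiple-testing adjustment is
applied across the 18 contrasts, mirroring standard practice in this
literature; the contrasts are descriptive, not confirmatory.

Between-position peak-speed comparisons use `independent_mean_diff()`:
equal-variance pooled-t intervals by default (the two-independent-groups
convention of estimation-statistics software), Welch optionally; *d*
standardised by the pooled SD with the usual
`SE(d)² = (n₁+n₂)/(n₁n₂) + d²/(2(n₁+n₂−2))` approximation. The pairwise
table reports `mean(pos2) − mean(pos1)` in the fixed CD, FB, CM, WM, FW
order, so a negative cell means the first-listed position is faster.

Degenerate inputs are handled explicitly: a zero-variance difference
yields a zero-width mean CI; a zero `s_av` yields `d = 0`; identical
vectors classify as unclear (zero-width CI touching zero); fewer than two
complete pairs, or groups under two values, are errors.

## Reference tables and reconciliation

`reference_tables()` ships published position-stratified summaries of 90
player-match windows from one elite squad over six matches: per-second
means ± SD by position, the pooled consecutive-interval differences, and
the pairwise position comparisons. They serve as reconciliation oracles:
`pooled_position_means()` pools position means n-weighted
(`Σnᵢmᵢ/Σnᵢ`), and for every **pre-peak** consecutive pair the difference
of pooled means reproduces the published pooled paired difference. The
published means are printed at 2 decimals, so each pooled mean carries up
to ±0.005 input-rounding error and each difference up to ±0.01; agreement
is asserted at that propagation bound. The **post-peak** rows of the
published paired-difference table do not reconcile with the published
per-second means by any aggregation we could derive (the reconstruction
gives ≈ −6.46 where −6.55 is printed at 1–2 s after the peak), most
plausibly because truncated windows enter the two tables with different
`n`; post-peak reconciliation is therefore documented as a limitation and
not asserted. Likewise one published pairwise cell (CD–FB 2.50) differs
from the difference of the printed peak means (2.53), presumably computed
pre-rounding; only the cells that reconcile exactly are asserted.

## The synthetic generator

`simulate_trace()` builds a ~90-minute 10 Hz trace as:

* **Locomotor baseline** — a semi-Markov process over
  stand/walk/jog/run states (mean speeds 0.3/5/9/14 km/h, geometric
  dwell times with means 5/8/6/3 s), smoothed toward each state's target
  with a 1 s time constant. Only the marginal speed distribution matters
  for testing, so dwell distributions are deliberately simple.
* **Sprint events** — 6 per trace, one per equal segment of the match
  with jitter, kept 15 s clear of the trace edges. Each trace draws one
  target match peak from the position's normal distribution (means/SDs
  per position: CD 29.11 ± 1.64 … FB 31.64 ± 1.94 km/h), redrawn below a
  26.5 km/h floor so every trace has a validly detectable peak;
  `expected_peak_mean()` gives the resulting truncated-normal mean,
  which is what detection should recover on average. A second sprint is
  always placed within 0.5 km/h of the target (guaranteeing
  corroboration), remaining sprints sit lower.
* **Sprint shape** — mono-exponential in speed: a rise from a flying
  start (`N(9, 2)` km/h) over 6 s with time constant `tau_acc_s = 2.5` s,
  normalised so the apex sample equals the drawn peak exactly, then a
  mirrored decay over 8 s with `tau_dec_s = 2.0 < tau_acc_s` to a
  non-zero post-sprint floor — players slow down faster than they speed
  up, but do not stop. Because speed approaches the apex asymptotically
  and leaves it geometrically, the largest 0.1 s changes occur
  immediately around the peak, as real traces show. Short 3 s linear
  lead-in/lead-out ramps blend each sprint into the baseline so insertion
  creates no artificial jumps.
* **Heterogeneity** — the post-sprint floor is drawn per sprint
  (`N(7, 2.5)` km/h, clamped) and both time constants share a per-sprint
  log-normal multiplier (`sdlog = 0.25`). Without this, every simulated
  decay would be identical and the between-window SD mid-recovery would
  collapse to the noise floor; with it, the cohort reproduces the
  characteristic variance funnel — speed variability shrinking as the
  peak approaches.
* **Artifacts** — i.i.d. Gaussian observation noise (SD 0.15 km/h,
  clamped at 0), 2 implausible spikes per trace (45.5–60 km/h) placed
  clear of sprint neighbourhoods, and optional gap injection (runs of
  2–10 dropped samples), all recorded in the ground truth.

`simulate_cohort()` derives per-trace seeds deterministically from the
master seed and the player/match identifiers, so cohorts are bitwise
reproducible and roster edits do not reshuffle unrelated traces.
`default_roster()` encodes the reference cohort geometry: 20 players
(4 CD, 3 FB, 5 CM, 5 WM, 3 FW) over 6 matches with a fixed absence
pattern thinning 120 player-matches to the 90 observed windows
(20/10/19/24/17 by position).

**What the generator does not emulate.** GNSS noise is white here but
autocorrelated in real devices; sprint counts and timing ignore match
context (halves, stoppages, score line, opponent); there is no
within-player repeatability structure linking a player's matches; the
locomotor baseline has no tactical structure; and sprint shape is a
smooth two-parameter curve, not stride-resolved kinematics. Passing
tests on simulated cohorts therefore validate the *pipeline's
bookkeeping and statistics* — detection, windowing, aggregation,
inference — under known ground truth; they do not certify the generator
as a model of soccer locomotion.

## Numerical and design choices

* Time is integer milliseconds from session start; halves or sessions
  are separate traces (no wall-clock alignment is attempted, and whether
  windows may span stoppages is left to the data supplier — the package
  analyses whatever grid it is given).
* Grid tolerance ±10 ms around the nominal 100 ms spacing; larger
  deviations are reported as gaps by `validate_grid()` and never
  repaired at the I/O layer.
* CSV dialect is fixed (`t_ms,v_kmh`; metadata
  `player_id,match_id,position`) and written by the shortest
  round-trippable decimal representation; reading uses a
  correctly-rounded parser so write → read is bit-identical.
* Bout segmentation uses ≥ threshold for run membership; peak validity
  uses > threshold for the candidate, matching the strict "> 25.2"
  sprint definition.
* Tables are emitted at full precision; rounding to the conventional 2
  decimals is left to display.

Problem sizes used by the test and acceptance runs — chosen to estimate
each property comfortably: one 90-trace full-length cohort (the reference
cohort geometry), 1,000 random 5-second traces against a brute-force
peak-detection oracle, and 1,000 Monte-Carlo replicates (n = 90 pairs)
for CI coverage.

## Limitations

Real club GNSS records are proprietary, so no test compares pipeline
output on real traces against the published tables; the package instead
(a) reconciles the published summary tables internally, and (b) validates
every algorithmic step against ground-truthed synthetic data and
independent oracles. The paired-*d* CI is a normal approximation; an
exact noncentral-t interval could be added behind the same interface.
Sprint typing is reported per bout but plays no role in peak validity,
and acceleration/deceleration *magnitudes* (m/s²) are deliberately out of
scope — the pipeline is speed-only, in km/h, end to end.
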