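---
title: "Scoring Y-maze spontaneous alternation from pose tracks: methods and design"
author: "ymazer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring Y-maze spontaneous alternation from pose tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ymazer)
```

This vignette is the package's account of its models and the choices behind
them: what each stage assumes, which tunables matter and why their defaults
are what they are, what the synthetic agent does and does not emulate, and
where the design was genuinely open.

## From pixels to normalized arm coordinates

A session is a 30 Hz stream of five tracked body parts (nose, both ears,
neck, tail base), each with a tracking likelihood. The **head point** is the
arithmetic mean of nose, ears and neck; the **tail-base point** is used as
tracked. Frames where any contributing part falls below the likelihood floor
(default 0.6, a common operating point for pose estimators; set 0 to
disable) are linearly interpolated from the neighbouring good frames, and
interpolation runs longer than 0.5 s are flagged rather than trusted
silently. The analysis window is 465 s (7 min 45 s) from the first frame;
frame times come from the configured frame rate, not from timestamp columns.

Maze calibration is a center point, three arm-end points (labelled A, B, C
counterclockwise) and the physical arm length (36 cm default). Validity
requires the arm axes to be pairwise 120° ± 10° and the three pixel arm
lengths to agree within 10%. Each frame's point is assigned to the arm whose
axis has the largest cosine similarity with the vector from the center —
angular sectors partition the plane with no dead zones, including the
central triangle — and its **normalized position** is the distance from the
center divided by that arm's own pixel length. Positions above 1 are kept
and flagged, not clipped: tracking jitter regularly places a nose beyond the
nominal arm end, and clipping would bias occupancy near the wall. Exact
center points and sector ties inherit the previous frame's arm (arm A at the
start); these choices only affect frames that carry no positional evidence
either way.

## The center-zone boundary

Pooled over animals, occupancy of the normalized position is high near the
center and falls to a steady "transit" level along the proximal arm; the
position where it settles is a behaviorally defined center-zone boundary.
`detectCenterBoundary()` codifies this: smooth the pooled histogram with a
centered moving average (default 5 bins), and return the left edge of the
first run of `k = 5` bins at or beyond `pMin = 0.05` whose forward
differences stay below 10% of the smoothed density range per bin. If no such
plateau exists the function warns and returns the fixed convention 0.25.

Two practical notes. First, the tolerance is *per bin*, so the detector's
sensitivity depends on the bin width: at very fine bins (0.01) almost any
smooth decay has per-bin steps below 10% of the range and the plateau is
called too early; bin widths of 0.02–0.03 make the knee steep enough per bin
to localize. Second, analysis defaults to the fixed boundary 0.25 — the
detector is there to *verify* that convention on a given dataset (and the
package's own tests verify it recovers a synthetic agent's programmed
center-dwell radius to within 0.05 at bin width 0.03), not to silently move
the goalposts per cohort.

## Visits, sufficiency, and choices

Single-point zone tests chatter when an animal bobs at a border. The visit
state machine therefore requires **both** the head and the tail base:

* entry into arm *a*: first frame with head position > boundary AND
  tail-base position > boundary AND both assigned to the same arm *a*;
* exit: first frame with both positions ≤ boundary (any arm).

Strict `>` on entry and `≤` on exit give a half-open convention so a frame
exactly on the boundary cannot be double-counted. While in an arm, the
running maxima of head and tail-base positions are tracked over frames
assigned to that arm; a visit is **sufficient** at threshold `T` when both
maxima reach `T` — each point at *any* time during the visit, simultaneity
not required, which is the weakest reading consistent with "both crossed".
Entry requires both points in the *same* arm because that is the only
reading that yields a well-defined visited arm. A session ending mid-visit
closes the visit at the last frame and marks it censored; censored visits
count toward visit numbers but their exit times are excluded from recency
statistics.

Choices are scored from the third sufficient visit: correct if the current
arm differs from both of the last two visited arms (which themselves
differ), incorrect if it matches one of them, neutral if the last two arms
were the same. The alternation rate is correct/(correct+incorrect); neutral
choices are excluded from both sides. The sweep recomputes every metric on
the sufficient subsequence of each threshold (0.25–0.70 in 0.01 steps for
inference; up to 1.0 for exploration), including the arm-choice bias — the
bias is a property of the realized choice sequence, which changes with the
threshold.

## Chance level and recency

The turning bias `|n_CW/(n_CW + n_CCW) − 1/2|` (computed on directional
transitions; same-arm reentries carry no direction) can produce alternation
without memory. The chance model is the minimal generative model consistent
with that single number: independent clockwise steps with probability
`q = 0.5 + bias` on the three-arm ring. Monte-Carlo simulation (default
1000 iterations, scored by the same classifier as real data) gives the
chance band as the mean and 2.5/97.5 percentiles; the closed form
`q² + (1 − q)²` (a step is correct exactly when it repeats the previous
direction) serves as an independent oracle, and the package's tests hold the
simulation to within three standard errors of it. Chance bands can be
computed per threshold from each session's own `n` and bias (the default) or
once from cohort means; both are supported because the aggregation level is
a genuine free choice.

Recency statistics quantify *why* a choice failed: for each scored,
non-reentry choice with both candidate arms previously exited,
`timeSinceBExit = t_entry − t_B` and
`diffRecency = (t_B − t_A)/(t_entry − t_B)`, where `t_B` is the exit of the
second-last visited arm (the incorrect candidate) and `t_A` the latest prior
exit of the correct candidate. The quantity is dimensionless: shifting all
timestamps, or dilating time uniformly, leaves it unchanged. A zero or
negative denominator is impossible in a well-formed visit sequence (an
intervening visit separates the entry from that exit), so the function fails
loudly rather than returning nonsense.

## Cohort comparison

Sweep curves are compared with a cluster-based permutation test: pointwise
two-sided Welch t statistics; candidate clusters are maximal runs with
pointwise `p < 0.05`; the cluster statistic is the sum of |t|; the null is
the maximum cluster mass over random relabelings of subjects (default
10,000; the tests use 1000 where many repeats are needed); cluster
`p = (1 + #{null ≥ observed}) / (1 + n_perm)`. Welch is the default
everywhere (cohort sizes are typically unequal) with Student available.
Missing values drop a subject at that threshold only. The formulation —
max-sum-|t|, cluster-forming α = 0.05 — is the field's standard one; both
knobs are arguments because the choice is conventional, not principled.

## The synthetic agent

The generator exists to give every pipeline stage a controllable ground
truth; it is deliberately minimal rather than biomechanically realistic.

**Kinematics.** The head runs along arm axes at constant speed (12 cm/s;
with ~3 s mean center dwells and ~2 s arm-end dwells this yields ≈ 35–45
entries in a 465 s session, a realistic tempo for an adult mouse), dwells
are exponential, and the tail base follows the head's path delayed by
`bodyLength/speed` (body length 5 cm ≈ head-to-tail-base of an adult
mouse). The arm-end dwell has a 0.5 s minimum (a shifted exponential with
the mean preserved): a physical turnaround occupies nonzero time, and the
minimum guarantees that the window during which head and tail base are both
beyond any crossed line spans many frames — without it, a shallow visit with
a near-zero turnaround can put both points beyond the boundary for less than
one frame, which no frame-based detector (and no definition of "visit" worth
defending) can register. Nose, ears and neck are placed symmetrically around
the head so their mean is exactly the head point; all parts carry
likelihood 1; optional iid Gaussian jitter (in arm-length units) is added to
every coordinate. Visit depths are a mixture: full visits
(uniform 0.85–1.0) with probability 0.85 — mice reach the distal arm on the
large majority of entries — else shallow (uniform 0.30–0.70).

**Choice process.** With probability `alternationFidelity` (default 0.5,
which with the default turning bias 0.1 gives an expected alternation rate
of 0.76, in the range of healthy group-housed mice) the agent consults its
memory; otherwise it steps clockwise with probability `0.5 + turningBias`.
With `memoryHalflife = Inf` the memory consult always picks the correct arm,
and the expected rate has the closed form
`m + (1 − m)(q² + (1 − q)²)` used by the parameter-recovery tests. With a
finite half-life the consult uses two decaying traces,
`w_X = 2^(−(t − exit_X)/halflife)`: the second-last arm's trace is retrieved
with probability `w_B` (so the correct-choice probability decays toward
chance with the time since that exit); retrieving only `B` yields a correct
avoidance; retrieving only `A` yields a deliberate wrong entry (A seems
recent, B forgotten); retrieving both ranks them, misranked with probability
`0.5 · 2^(−(t_B − t_A)/halflife) · (1 − w_B)` — a degraded trace confuses
close recencies. A plain one-trace decay (scaling the correct-choice
probability by `2^(−Δt/halflife)` alone) was measured during development to
produce *no* recency signature: it modulates only the denominator of
`diffRecency`, and choice-sequence structure cancels the effect. The
two-trace form reduces exactly to the one-trace law when the correct arm's
trace is negligible, and concentrates errors at small recency differences,
which is the behavioral signature of decaying spatial memory. Agents whose
alternation is mostly memory-driven with traces decaying on the scale of the
inter-visit interval (fidelity 0.9, half-life 10 s) express the signature
most strongly and are what the recency tests simulate; an agent with a
half-life far below the inter-visit interval is effectively amnesic — its
errors come from the memoryless fallback and carry almost no signature.

**What the agent does not emulate.** Wall-following, grooming and rearing
bouts, head-scanning at borders, structured tracking dropouts, per-animal
speed/size variation, and — notably — the empirical tendency of intact mice
to *increase* their measured correct rate as the threshold rises. The
agent's internal choice sequence includes its shallow visits, so filtering
them out re-scores choices against a different reference and pushes the rate
slightly toward chance; in real mice the opposite happens, presumably
because shallow pokes are not registered as visits by the animal either.
Passing tests therefore demonstrate that the *pipeline* measures what the
generator programmed — recovery of visit sequences, rates, biases, decay
contrasts — not that the generator reproduces every empirical curve shape.

## Numerical choices and degenerate inputs

* Entry `>` / exit `≤` at the boundary; maxima tracked only on frames
  assigned to the visited arm.
* Projection ties and center points inherit the previous frame's arm.
* Sessions shorter than the analysis window are analyzed whole, with a
  warning.
* An all-neutral (or too-short) sufficient subsequence yields `NA`
  alternation rate, which propagates as a missing value and drops that
  subject at that threshold in cohort curves.
* The occupancy detector treats a numerically flat profile (range below
  1e-12 of its level) as plateau-from-the-start and returns `pMin`.
* Chance simulation, cluster permutations, and the generator all take
  explicit seeds and run on a local RNG stream, leaving the caller's RNG
  state untouched.

## Problem sizes in the test suite

The suite validates visit recovery on 50 noiseless and 50 noise-added
(σ = 0.01 arm lengths) rendered sessions; classification against a
brute-force oracle on 1000 random sequences; chance rates at 1000
iterations; parameter recovery on cohorts of 24 full-depth agents at three
fidelities; cluster-test calibration on 200 null cohort pairs (12 vs 12,
1000 permutations each) with a planted long- vs short-half-life contrast
(24 vs 24) in 20 repeats; and the recency signature on 20 cohorts of 12
decaying agents. These sizes were chosen so each check has the statistical
resolution it needs (binomial or permutation error well below the asserted
tolerance) while the whole suite stays comfortably runnable on a laptop.

## Known limitations

* CSV pose tracks only (no HDF5), one animal per session.
* The boundary detector's tolerance is relative to the density range per
  bin, so its resolution is tied to the bin width; use it at 0.02–0.03 bin
  widths, or keep the fixed 0.25 convention.
* Travel distance uses the head point (configurable upstream of the call by
  supplying a different track) and is inflated by tracking jitter on noisy
  data — compare cohorts only at matched noise levels.
* The cluster permutation test assumes exchangeable subjects under the
  null; it is not a substitute for mixed models when sessions are repeated
  within animal.
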