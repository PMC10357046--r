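---
title: "Mining association rules for ambient ADL detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining association rules for ambient ADL detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adlminer)
```

## The problem and the model

Homes of older adults living independently can be instrumented with a
small set of ambient sensors: magnetic contacts on doors, cupboards and
drawers; smart plugs on the kettle, toaster and microwave; passive
infrared motion sensors; and multi-channel ("6-in-1") environmental
sensors whose humidity channel signals bathing. The goal is to turn the
resulting activation stream into occurrences of four activities of daily
living (ADLs) — eating/drinking, dressing, bathing and leaving the house
— with almost no training data: a participant can only be asked a few
times, during short recall interviews, *when* they last ate, dressed,
bathed or went out.

`adlminer` treats this as association rule mining over sliding-window
transactions:

* Each window is an **order-independent item set**. Activity sensors are
  activated in no fixed order (kettle before crockery in the morning,
  the reverse in the afternoon), so sequence information is deliberately
  discarded.
* A rule is `antecedent (sensor items) ⇒ consequent (one ADL label)`,
  scored by **support** (fraction of mining-database windows containing
  antecedent and label together) and **confidence** (that support
  divided by the support of the antecedent alone).
* Detection is **any-rule-fires subset matching** per window, run
  independently per ADL.

The approach assumes each ADL has a roughly stable sensor signature that
fits inside its window length, and that item tokens mean the same thing
across homes. The second assumption is what makes pooling work: tokens
are location-canonical (`fridge_door`, `presence:bathroom`), never
device serials, so rules mined from annotated participants apply
verbatim to a new home.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| window size, eating/drinking and bathing | 60 | min | long enough to span a meal or a bath plus its humidity response |
| window size, dressing and leaving house | 30 | min | short, burst-like activities; a longer window dilutes confidence |
| stride | 5 | min | dense enough that an occurrence is never straddled by consecutive windows of its size |
| `min_support` | 0.15 | fraction | on a 1:1 positive/negative mining database this admits items appearing in ≳30% of positives |
| `min_confidence` | 0.5 | fraction | a rule must be right more often than wrong on its own antecedent |
| `max_antecedent_size` | 4 | items | bounds level-wise apriori growth; rules stay readable |
| `negative_sampling_ratio` | 1 | per positive | see *Mining database composition* below |
| `humidity_rise_threshold` | 10 | %RH | half the simulated bath amplitude; above baseline jitter |

All are configurable (`window_spec()`, `mining_params()`); the defaults
are the package's reference configuration and the ones its acceptance
checks use.

## The mining database — an explicit design choice

Support and confidence need a population of windows to be computed over,
and that population is genuinely open to choice. Using *all* windows
makes `min_support = 0.15` unattainable for any activity occupying a few
percent of the day; using *positives only* makes confidence vacuously 1.
The package therefore builds, per ADL: all labelled-positive windows
(with the ADL label injected as an item) plus a seeded, equal-sized
sample of unlabelled windows drawn without replacement. Pooling
concatenates the per-participant databases (each with its own negative
sample, on a participant-offset seed) before mining once. Empty windows
are retained as negatives — they are what makes confidence informative.

Whether `min_support` applies to the antecedent alone or to the full
itemset including the label is another free choice; the package applies
it to the full itemset, the standard apriori reading, so every emitted
rule's joint support is itself above threshold.

Dominated rules — an antecedent superset whose confidence does not
exceed that of a kept subset rule — are pruned in (size, lexicographic)
scan order. Because domination is transitive through the kept set, this
equals pruning against all candidate rules; the suite checks that
equivalence against an exhaustive enumerator.

## Windowing: numerical conventions

* All intervals are half-open `[start, end)`; an event exactly at a
  window's end belongs to the next window only. This prevents
  double-counting on edges and gives exact closed-form window counts
  (`(1440 − W)/stride + 1` per day).
* The stride grid is anchored at local midnight of each logging day
  (UTC by convention) and windows never cross midnight. Day-anchoring
  keeps per-day counts interpretable in the day-oriented reports; the
  cost is a blind spot of at most one window length around midnight,
  far from the scheduled activities modelled here.
* `humidity_rise:<room>` is present when `max − first` reading within
  the window reaches the threshold; a window with fewer than two
  readings never carries it. "First minus max" rather than a slope fit
  keeps the item cheap, monotone in the rise, and — importantly —
  sensitive to the sampling interval, reproducing the known failure
  mode where 10-min humidity sampling starves bathing detection.
* Ties among rules firing on the same window resolve to the first rule
  in the stable (ADL, antecedent size, lexicographic) order, so
  detection output is a deterministic function of its inputs.
* On firing, the scan advances past the window's end rather than by one
  stride. The alternative (stride advance) emits a run of overlapping
  detections per occurrence; advance-past-window makes detection counts
  readable as occurrence counts. Within-ADL overlaps are thus
  impossible by construction; cross-ADL overlaps are allowed, since the
  four detectors run independently.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates, per participant: scheduled daily
occurrences (three meals at 08:00/13:00/18:30 with 25 min jitter SD,
dressing ~08:30, bathing 0.8/day ~21:00, leaving 0.9/day ~10:00);
signature sensor activations placed uniformly within each occurrence,
each sensor firing independently with its configured probability;
homogeneous Poisson background noise per sensor (0.05 events/h); door
callers (0.5/day) who open the front door with no departure; a bathroom
humidity series (baseline 50 %RH, bath rise 20 %RH with 30-min
exponential relaxation, sampled every minute); and briefing annotations
— the truth records of two randomly chosen days, jittered ±10 min
uniformly, modelling imperfect recall. Where no published value exists
for a generative knob (activation probabilities, durations, noise and
caller rates are not reported for real deployments), the defaults were
chosen once as plausible for an instrumented single-occupancy home and
are documented rather than fitted.

Each (participant, component) pair draws from its own seeded RNG
substream, so changing one knob — say the caller rate — changes *only*
caller events, leaving routines, noise and annotations bit-identical.
This is what makes the failure-mode probes well-posed comparisons.

The generator deliberately omits: multi-occupancy and visitors beyond
door callers, appliance usage unrelated to any ADL (TV, washing
machine), seasonal or weekday structure, sensor dropout and clock drift,
and annotation *errors* beyond timestamp jitter (no mislabelled ADLs).
Passing tests on this generator therefore demonstrate that the
machinery recovers the structure it assumes — not that real homes
satisfy those assumptions.

A consequence worth stating plainly: with scheduled activities plus
background noise, the mined single-item rules are *correct* (high
confidence on the mining database) yet fire on every stray activation,
so detection recall is near-perfect while precision is low, and callers
inflate leaving-house counts without touching ground truth. The
package's evaluation functions exist precisely to measure these
phenomena rather than hide them; the simulated routine even reproduces a
cross-activity confound (dressing scheduled inside breakfast windows
pulls kitchen items into dressing rules).

## Evaluation conventions

A truth record matches a detection of the same ADL when its timestamp
falls inside the detection interval; matching is greedy, one-to-one, in
time order, per participant. Greedy matching on interval-point
containment is within a small margin of the optimal bipartite matching
(checked against an exact matching oracle in the suite) and is
deterministic. Precision with zero detections is undefined and is
reported as 0 with an explicit flag. Day-normalisation follows
`raw × reference_days / logging_days` with `reference_days = "max"`
resolving to the cohort's longest logging duration; the per-day rate is
also emitted so either normalisation reading is available. The
core-sensor score is the unweighted mean of rule presence (fraction of
rules containing the item) and fire share (fraction of detections whose
firing rule contains it); both criteria are natural, no weighting is
published, and the mean keeps the two on equal footing.

## Problem sizes

The reference configuration used throughout the tests and the
acceptance script is 5 participants × 28 days with annotations on
2 days each — large enough that each ADL accumulates tens of positive
windows when pooled, small enough that the full pipeline (≈200k events,
≈8k windows per participant and ADL) runs in well under a minute per
cohort. Mining-oracle checks run on 50 random databases of ≤10 items
and ≤40 transactions, where exhaustive enumeration over all 2¹⁰
itemsets is exact and instant.

## Known limitations

* Rule antecedents are conjunctions only; an ADL whose signature is a
  disjunction is representable only as several rules, which the miner
  does produce but at correspondingly lower per-rule support.
* No post-processing suppresses noise-driven detections; precision is
  whatever the rules deliver. A duration or count filter would be a
  natural extension but is out of scope.
* Day-anchored windows cannot detect activities spanning midnight.
* The humidity-rise item compares first and maximum reading; a bath
  already in progress at window start can mask the rise.
* Leave-one-out evaluation measures transfer between *statistically
  identical* simulated homes; transfer across genuinely heterogeneous
  routines can only be weaker.
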