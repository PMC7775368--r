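---
title: "Spatio-temporal behavioral dynamics in a modified open field: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal behavioral dynamics in a modified open field: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mofs)
```

## The experimental system

`mofs` analyses rodent movement in a *modified open-field system*: a
square arena (100 × 100 cm by default) with a floor-level water dispenser
whose location is the experimental variable — at the centre of the arena in
a first phase, next to a wall in a second. Water is delivered
non-contingently on a time-based schedule: fixed time (FT, one drop every
30 s) or variable time (VT, exponentially varying intervals with a 30-s
mean), each drop staying available for 3 s. A texturized patch 5.5 cm from
the dispenser signals its location. Tracking yields the animal's centre of
mass every 0.2 s as (x, y) coordinates in cm; sessions last 20 min and each
condition runs for 20 daily sessions.

The scientific question is eco-behavioral: does the *location* of the water
source, not just the schedule, reorganise the spatial dynamics of behavior?
With the dispenser at the centre, two functionally distinct segments exist
(safe periphery, intermittent water at the centre) and a back-and-forth
travel pattern emerges; with the dispenser at a wall both segments collapse
onto the periphery and displacement contracts. The package quantifies this
with a fixed battery of per-session measures.

## Coordinate and zone conventions

All positions live in the arena frame: origin at one corner, x rightward,
y upward, cm units. The arena is tiled exactly by a 10 × 10 `zone_grid`;
regions are indexed 0-based and row-major (region 0 contains the origin,
region 99 the opposite corner). Cells are half-open on their lower-left
edges with the last row/column closed, so every point of the closed arena
belongs to exactly one region — a requirement for reproducible occupancy
and recurrence analyses. The outer ring of cells (36 of 100) is the
operational "peripheral" zone used to quantify thigmotaxis.

## The measured quantities

For each session the package computes:

* **Occupancy map** — accumulated dwell time per region; each frame
  contributes exactly one sampling period to exactly one region, so dwell
  counts conserve the frame count exactly (conservation is checked in
  integer frame units to avoid floating-point ambiguity).
* **Relative distance to the dispenser** — per-frame distance divided by
  the maximum possible distance for that dispenser placement (the farthest
  point of a rectangle from an interior point is a corner). The series is
  smoothed by a trailing moving average of 200 frames (40 s at 0.2-s
  sampling); at the session start the window shrinks to the frames
  available. A trailing window was chosen because it is causal; the
  alignment does not affect any of the session-level contrasts.
* **Delivery moments** — the animal's position at the first frame at or
  after each delivery onset, plus the derived *delivery-proximity rate*
  (fraction of deliveries with the animal within 5 cm of the dispenser at
  onset).
* **Recurrence plot** — the binary matrix over time pairs indicating
  whether the animal occupied the same region at both times, computed at
  full frame resolution by default with a stride option for plotting, and
  summarised by the off-diagonal recurrence rate. The underlying notion of
  recurrence is lag-free: the full cross-time matrix contains the lag-1
  comparison as its first off-diagonal.
* **Entropy index** — Shannon entropy (natural log, nats) of the
  occupancy distribution, optionally normalised by `log(n_regions)` so
  grids of different size are comparable. Entropy is computed on occupancy
  rather than on region transitions, the minimal reading of "variation of
  displacement patterns"; a transition-entropy variant
  (`transition_entropy()`) is provided for sensitivity analyses.
* **Divergence index** — Kullback–Leibler divergence between the
  occupancy distributions of consecutive sessions, direction
  D(earlier ‖ later), with a Jensen–Shannon option when a symmetric index
  is wanted. Both maps receive an additive pseudocount of one sampling
  period (0.2 s) per region before renormalising; this keeps the
  divergence finite when a region visited in one session is empty in the
  other and is negligible against a 1200-s session.
* **Path length** — summed frame-to-frame displacement, a measure of the
  vigor (as opposed to the direction) of movement.

## The synthetic rat agent

No public tracking data accompany the study design, so the package ships a
seeded generative agent whose purpose is to reproduce the *qualitative*
structure of the reported behavior, making every analysis testable
end-to-end. It is a discrete-time correlated random walk at the sampling
period:

* Heading receives Gaussian turn noise (SD 0.6 rad per step) and is
  biased by a drift vector
  `w_wall · u_wall + λ · w_disp · g(t) · u_disp`.
* **Thigmotaxis**: `u_wall` points toward the nearest wall whenever the
  agent is more than 5 cm from every wall, and vanishes inside that wall
  band. The band matters: attraction all the way to the wall pins the
  agent into corners, whereas with the band it slides along the perimeter,
  which is what rats do. Default weight `w_wall = 0.45`.
* **Schedule-driven approach**: `u_disp` points to the dispenser, gated
  by `g(t)` — equal to 1 while water is available, and under FT schedules
  also during the 5 s before each onset (temporal anticipation of the
  predictable schedule; under VT only availability-triggered approach
  applies), and a small baseline `g0 = 0.06` otherwise. Default weight
  `w_disp = 1.6`.
* **Learning** `λ` is the product of two saturating components:
  across-session schedule learning `1 − exp(−(s−1)/learn_tau)` with
  `learn_tau = 5` sessions, carried over when the dispenser moves (session
  indices continue across conditions), and location re-acquisition
  `1 − exp(−s_c/loc_tau)` with `loc_tau = 3` sessions of the current
  condition. The second component is faster because the patch signals the
  new location; it is what lets approach accuracy keep improving after the
  dispenser moves, as observed, while the first component produces the
  emergence of centre-directed travel "around session 10" of the first
  phase.
* Step length is `max(0, N(12, 6)) cm/s × 0.2 s`; positions reflect
  specularly off the walls. While water is available and the agent is
  within 5 cm of the dispenser it holds position (drinking) until the
  window closes. Every session starts at the same entry corner, 5 cm from
  both walls, with a random heading — animals are introduced at the same
  point each day, and a varying start would spuriously inflate
  between-session divergence in early, purely thigmotactic sessions.

VT inter-delivery intervals are truncated-exponential
(bounds `[mean/5, 3·mean]`, inverse-CDF sampling), the memoryless law used
in operant practice, truncated to avoid degenerate near-zero and very long
intervals; user-supplied onset lists are accepted anywhere a
`delivery_log` is.

Defaults were calibrated once against the qualitative targets — strong
early peripheral occupancy (share > 0.9 in session 1), emergence of
back-and-forth travel late in the centre phase, contraction to the
dispenser wall in the wall phase, a divergence spike at the phase
transition, and near-constant path length across conditions — and then
frozen. What passing these checks shows is that the *analysis battery*
discriminates the patterns it was designed to discriminate; the agent is
not a fitted model of any individual rat, models no individual differences
beyond seed variation (a non-adapting animal can be emulated by setting
`w_disp = 0`), and omits grooming, rearing and speed differences between
zones.

## Determinism and seeds

Every stochastic component takes an explicit seed. `simulate_experiment()`
derives per-session seeds from one master seed by stable integer hashing
(kept below 2³¹), so runs are reproducible session-by-session and
independent of evaluation order; FT schedules are deterministic and
seed-independent. Two `run_full()` calls with the same configuration are
bit-identical.

## Numerical choices and degenerate inputs

* Region assignment uses `floor(x · n/width)` clamped to the last index,
  matching the half-open/closed-edge convention exactly at boundaries.
* Occupancy conservation is asserted on integer frame counts; dwell times
  are counts × sampling period.
* Zero-length availability, empty delivery logs, single-frame
  trajectories, and zero speed are all defined (the agent simply never
  moves at zero speed; an empty schedule yields an empty delivery table).
* Tracking gaps are repaired by linear interpolation up to a configurable
  maximum gap (default 5 frames); longer gaps are an error, not silently
  interpolated, because long unobserved excursions cannot be
  reconstructed. Convexity of the arena guarantees interpolated points are
  in bounds.
* Wall reflection is applied iteratively, so even step lengths exceeding
  the arena size cannot escape it.

## Problem sizes

Analyses run at the study's native scale (6,000 frames per 20-min
session; full-resolution recurrence matrices are 6,000 × 6,000). The
package's own test battery and the bundled acceptance script exercise the
full pipeline on scaled-down sessions (1–5 min) with the study's layout
(3 subjects, 20 sessions per condition, FT 30 s), which preserves every
qualitative contrast while keeping a complete run in seconds; the vignette
and README examples use the same scale.

## Known limitations

* The agent's learning is phenomenological (two exponential factors), not
  a reinforcement-learning model; it reproduces group-level patterns, not
  acquisition curves of individual animals.
* Entropy and divergence are computed on occupancy distributions; analyses
  of *sequential* structure beyond the recurrence plot (determinism or
  laminarity lines, velocity-per-zone) are out of scope.
* The recurrence matrix at full resolution costs O(n²) memory
  (~140 MB at 6,000 frames); use `frame_stride` when plotting many
  sessions.
* Inferential statistics are deliberately absent: the battery is
  descriptive, and condition contrasts are reported as per-subject
  comparisons.
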