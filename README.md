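# mofs

Spatio-temporal analysis of behavioral dynamics in a **modified open-field
system** (MOFS): a square arena with a floor-level water dispenser whose
location — centre of the arena vs. next to a wall — is the experimental
variable, while water is delivered non-contingently on fixed-time (FT) or
variable-time (VT) schedules.

The package is for behavioral scientists studying the spatial dimension of
the behavioral continuum under time-based schedules. It implements the
standard analysis battery for such experiments and a seeded agent-based
simulator so the whole pipeline can be exercised, tested and taught without
animal data.

## What it computes

Given tracking trajectories (one (x, y) fix every 0.2 s, cm units) and a
water-delivery log per session:

- **Occupancy maps** — accumulated dwell time per cell of a 10 × 10 zone
  grid tiling the arena.
- **Relative distance to the dispenser** — per-frame distance d(t) to the
  dispenser divided by the maximum possible distance for that placement,
  in [0, 1], smoothed by a trailing 200-frame (40-s) moving average.
- **Delivery moments** — the animal's position at the first frame at or
  after each delivery onset, and the *delivery-proximity rate* (fraction of
  deliveries with the animal within 5 cm of the dispenser at onset).
- **Categorical recurrence plots** — the binary matrix
  R(i, j) = 1 iff the animal occupied the same grid region at frames i and
  j, with an off-diagonal recurrence-rate summary.
- **Entropy index** — Shannon entropy of the occupancy distribution,
  H = −Σₖ pₖ ln pₖ with pₖ the fraction of session time in region k
  (0 = all time in one region; ln 100 ≈ 4.605 = uniform over the grid).
- **Divergence index** — Kullback–Leibler divergence
  D(P ‖ Q) = Σₖ pₖ ln(pₖ/qₖ) between the occupancy distributions of
  consecutive sessions (pseudocount-regularised): near 0 for stable
  behavior, elevated when the dispenser location changes.
- **Path length** — total distance travelled per session (movement vigor).

The simulator is a correlated random walk with thigmotaxis (wall
attraction), schedule-gated dispenser approach, drinking holds, and
across-session learning; it reproduces the qualitative condition contrasts
(centre vs. wall dispenser) that motivate the battery. See the methods
vignette (`vignettes/mofs-methods.Rmd`) for the model and every numerical
choice.

## Worked example

Simulate one mid-training session with the dispenser at the centre under an
FT 30-s schedule, then compute its metrics:

```r
library(mofs)
arena <- make_arena("center")           # 100 x 100 cm, dispenser (50, 50)
grid  <- zone_grid(arena)               # 10 x 10 regions
sched <- generate_schedule("FT", mean_interval = 30, session_length = 1200)
sess  <- simulate_session(arena, grid, agent_params(), sched,
                          session_index = 15, seed = 42)
session_metrics(sess)
```

which prints (columns transposed):

```
entropy                  4.223
normalized_entropy       0.917
divergence_from_previous NA        # first session analysed, no predecessor
mean_relative_distance   0.540
path_length              12142.1   # cm over the 20-min session
n_deliveries             39        # FT 30 s in 1200 s with 3-s availability
delivery_proximity_rate  0.846
```

By session 15 the agent has learned the schedule: entropy is high
(displacement spread widely over the grid, 91.7 % of the uniform maximum)
because it commutes between the safe periphery and the central dispenser;
84.6 % of deliveries find it within 5 cm of the dispenser; and the mean
relative distance (0.54) sits between the wall (≈ 0.7) and the dispenser
(0). In session 1 the same code gives near-zero proximity and ≈ 0.79 mean
relative distance — pure thigmotaxis.

A full study layout (two experiments FT/VT, 3 subjects each, 20 sessions
per condition, centre then wall) runs with:

```r
bundle <- run_full(default_config(master_seed = 1), out_dir = "out")
bundle$metrics        # one row per (subject, experiment, condition, session)
```

and `plot_routes()`, `plot_occupancy()`, `plot_recurrence()`,
`plot_distance_series()` and `plot_metric_series()` draw the standard
panels. A thin command-line wrapper with `simulate`, `analyze` and `run`
subcommands is installed at `inst/cli/mofs`.

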