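# effcomm

Tools for studying how observers detect *communicative* action — movement
produced to convey a message — as opposed to *world-directed* action aimed
at changing the physical environment. The package is written for
computational cognitive scientists working on action understanding: it
provides the full modelling and analysis chain for 2-D moving-dot
paradigms, from stimulus generation through Bayesian goal inference to the
statistics that link model output to Likert judgments.

## The account

Observers expect world-directed agents to move **efficiently**. A movement
therefore signals communicativeness to the extent that it efficiently
reveals that no world-directed goal could have produced it.

Two operationalisations are implemented:

**Rarity.** For a path `p` with traveled distance `d(p)` and straight-line
start-to-end distance `d*(p)`,

    r(p) = 1 − d*(p) / d(p),

which is 0 for maximally efficient paths and 1 for any closed path.
Repetition is the limiting case: retracing a movement adds distance without
displacement, pushing `r` to 1.

**Inverse planning.** A noisy-rational observer scores the probability that
observed steps `a` were produced in pursuit of some world-directed goal `g`
in arena `W`:

    p(W | a) ∝ Σ_{g ∈ G} p(a | g) p(g | W),

with a uniform prior over a lattice `G` of candidate goal locations and a
per-step Boltzmann policy `p(a | s, g) ∝ exp(−β (|a| + cost(s + a, g)))`,
where `cost` is the obstacle-avoiding cost-to-go. The per-frame log marginal
likelihood `ℓ_t` traces how quickly the movement reveals itself; the
**communicativeness score** is `−ℓ_T` at the final frame. Unlike rarity,
this observer distinguishes inefficiencies that are consistent with
world-directed goals (zig-zagging toward a target, detouring around a lake)
from movement that no goal explains.

The path space chains 16 motion primitives (4 cardinals, 4 diagonals, 8
quarter-circle arcs); paths are canonicalized under the 8 square symmetries,
classified into eight movement classes (A–H), and assembled into the three
standard stimulus designs (23-path rarity gradient; 21 repetition variants
equated for distance traveled; 12 bordered/unbordered pairs). A synthetic
Likert-judgment generator and the full statistical surface (percentile
bootstrap CIs, linear calibration, exclusion permutation test, per-class
discrepancies) complete the chain.

## Worked example

```r
library(effcomm)

p_zig  <- path_spec(c(0, 1, 0, 1))    # N, E, N, E zig-zag
p_loop <- path_spec(c(8, 10, 12, 14)) # four arcs tracing a circle
rarity(p_zig)    # 0.2928932  (inefficient, but goal-consistent)
rarity(p_loop)   # 1          (returns to its origin)

tr_zig  <- compose_path(p_zig)        # 12 frame steps
tr_loop <- compose_path(p_loop)
w <- world_for(list(tr_zig, tr_loop)) # shared arena, goal lattice at 0.5

world_directedness_curve(w, tr_loop)
#> <world-directedness curve: 12 steps, final loglik -34.915, score 34.915>
communicativeness_score(tr_zig, w)    # 30.7727
communicativeness_score(tr_loop, w)   # 34.91539
```

The zig-zag is inefficient (rarity 0.29) yet stays plausible under
north-east goals, so the observer penalises it far less than the closed
loop, which no world-directed goal explains: the loop's higher score means
it more strongly reveals a communicative origin. The curve's 12 values are
the per-frame log marginal likelihoods; plotting them shows *when* a path
gives itself away.

## The analysis workflow

The numbered scripts under `analysis/` run the full study chain and write
tables under `results/` (optionally pass a seed as the first argument):

| script | what it does |
|---|---|
| `01_path_space.R` | enumerates the canonical 4-primitive space, reports counts per chaining convention and class composition |
| `02_build_stimuli.R` | builds the three stimulus sets, writes specs + rendered trajectories |
| `03_model_scores.R` | world-directedness curves and scores for the 23-path set |
| `04_judgments_analysis.R` | synthetic judgments; rarity and model correlations with bootstrap CIs; calibration; class discrepancies; exclusion permutation test; slope recovery |
| `05_repetition_and_borders.R` | model scores and rating trends across 0/1/2 repetitions; bordered vs unbordered score comparison |

`vignettes/efficient-communication.Rmd` documents the model, its
parameters, the numerical choices, and what the synthetic generator does
and does not emulate.

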