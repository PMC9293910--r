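---
title: "Detecting communicative action from movement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting communicative action from movement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

People move either to change the physical world (reach a place, fetch an
object) or to communicate (wave, nod, beckon). An observer watching a dot
trace a path on a screen readily judges whether the movement "is trying to
tell me something". This package implements a computational account of that
judgment: observers expect world-directed action to be *efficient*, so a
movement signals communicativeness to the extent that it efficiently reveals
that no world-directed goal could explain it.

The package provides four layers, each usable on its own:

1. a **generative path space**: 2-D trajectories chained from sixteen motion
   primitives, with symmetry-aware enumeration and an eight-way movement
   classification;
2. a **rarity statistic** for paths;
3. an **inverse-planning observer** that scores how strongly a trajectory
   reveals the absence of a world-directed goal, in open arenas or arenas
   with obstacles;
4. a **statistical pipeline** (bootstrap correlations, linear calibration,
   permutation tests, per-class discrepancies) linking model output to
   Likert communicativeness judgments, together with a synthetic-judgment
   generator so the whole chain runs end-to-end without human data.

## The path space

Paths are chains of primitives drawn from a fixed alphabet of sixteen: four
unit cardinal segments, four diagonal segments of length $\sqrt{2}$, and
eight quarter-circle arcs of radius 1 (length $\pi/2$), parameterised by
start tangent (N/E/S/W) and turn direction (CW/CCW). All sixteen live on a
common unit grid, so four-primitive paths span comparable extents. A path is
rendered into frames by subdividing each primitive into equal arc-length
sub-steps — three per primitive by default, so four-primitive paths are
scored over twelve frame steps.

```{r}
library(effcomm)
list_primitives()
tr <- compose_path(path_spec(c(0, 4, 8, 1)))   # N, NE, arc, E
plot(tr)
```

Two paths are *the same shape* when one is a rotation or reflection of the
other (the eight square symmetries). Each symmetry maps primitives to
primitives, so it acts on a path as a permutation of ids;
`canonicalize()` picks the lexicographically least sequence in the orbit as
the representative, a stable key independent of rendering. Path reversal is
*not* part of the equivalence: a path and its reverse are distinct stimuli
(they differ in how beliefs unfold over time), and nothing in the design
requires conflating them.

### How many four-primitive shapes are there?

With all $16^4$ sequences admissible, Burnside's lemma gives the canonical
count exactly: rotations fix no primitive, and each of the four reflections
fixes exactly two, so the count is $(16^4 + 4\cdot 2^4)/8 = 8200$, which
`enumerate_path_space(4)` reproduces. Alternative chaining conventions are
built in for comparison — forbidding immediate retraces gives
$(16\cdot 15^3 + 8)/8 = 6751$ classes, and requiring tangent continuity
gives 42. A widely used description of this stimulus family cites roughly
half the all-combinations count ("4520 unique paths"); no convention we
derived reproduces that number, and under the stated equivalence the count
is provably at least $16^4/8 > 8000$. The enumerator therefore reports
counts per convention rather than forcing a target, and the stimulus
builders depend only on the canonical space, not on its exact size.

### Movement classes

The eight a-priori movement classes describe how (in)efficiently a path
travels: **A** maximally efficient; **B** retraces itself back to its
origin; **C** moves toward multiple quadrants; **D** moves toward only one
quadrant; **E** partially retraces itself; **F** self-intersects without
closing; **G** repeats a two-segment pattern; **H** closes without
retracing. Informal class descriptions overlap (a closed path may also
self-intersect), so `classify_path()` applies formal predicates in a fixed
precedence order — A, B, G, H, E, F, D, C, first match wins — making the
partition total and deterministic. Self-intersection is decided on the
rendered polyline with eight chords per quarter-arc; quadrant membership
uses closed quadrants and excludes the origin. Classification is invariant
under all eight symmetries (verified property-style in the test suite).

## Rarity

For a path $p$ with total traveled distance $d(p)$ and straight-line
start-to-end distance $d^*(p)$,

$$r(p) \;=\; 1 - \frac{d^*(p)}{d(p)} \in [0, 1].$$

$r = 0$ exactly for straight chains (the movements expected under a
world-directed goal), $r = 1$ for any path that returns to its start.
Because every symmetry is an isometry, rarity is symmetry-invariant, and it
is unchanged by uniform rescaling of a path.

## The inverse-planning observer

The observer inverts a noisy-rational model of world-directed action. Given
an arena $W$ with a lattice $G$ of candidate goal locations (uniform prior),
the probability that observed actions $a$ are world-directed is

$$p(W \mid a) \;\propto\; \sum_{g \in G} p(a \mid g)\, p(g \mid W)\, p(W),$$

with a single fixed world per evaluation, so $p(W)$ drops out. The step
likelihood is a Boltzmann policy: at state $s$ the agent chooses among a
candidate set $A(s)$ — the observed step plus $K - 1$ same-length steps at
uniformly spaced headings, minus blocked ones — with

$$p(a \mid s, g) \;\propto\; \exp\!\big(-\beta\,(|a| + \mathrm{cost}(s + a, g))\big),$$

where $\mathrm{cost}$ is the obstacle-avoiding cost-to-go.
`world_directedness_curve()` accumulates the per-step log-likelihoods per
goal and marginalises with log-sum-exp, giving the per-frame log marginal
likelihood $\ell_t$ that the movement so far is world-directed; the
communicativeness score is $s = -\ell_T$ at the final frame. $\ell_t$ is
non-increasing, so the *shape* of the curve shows how quickly a movement
reveals itself.

Parameters, defaults, and why:

| parameter | default | units | role |
|---|---|---|---|
| `beta` | 2 | 1/arena-unit | rationality; 0 = uniform steps, large = shortest-path planner |
| `n_headings` | 16 | — | candidate steps per state |
| `frames_per_primitive` | 3 | — | scored steps per primitive |
| `goal_spacing` | 0.5 | arena units | goal-lattice pitch |
| `grid_resolution` | 0.1 | arena units | navigation-grid pitch |
| `log_floor` | −745 | log prob | per-step underflow floor |

`beta = 2` makes the observer sensitive to goal direction at the default
step lengths (1/3 to ~0.52 arena units) without saturating: straight
four-primitive paths score well below closed loops, while the class
ordering remains graded. The defaults give 12 scored steps for the standard
stimuli, and scores on the order of 25–35 nats.

Exact supplementary settings behind the published account of this model are
not available, so the likelihood form, `beta`, `n_headings` and the lattice
pitches are explicit configuration with the defaults above; the package's
claims rest on properties that hold across this family (closed forms at
`beta = 0`, monotone curves, oracle equivalence, ordering effects), not on
one tuned parameterisation. An open modelling question is whether the
reported curves are raw marginals or posteriors against an explicit
non-world-directed alternative; the package exposes the raw marginal
$\ell_t$, and a two-hypothesis posterior can be formed from it directly if
needed (the score is monotone in either construction).

### Worlds, cost-to-go, and numerical choices

Arena bounds default to the trajectory bounding box padded by one unit, so
goals "beyond" the movement are representable. In an obstacle-free world
the cost-to-go is the exact Euclidean distance. With obstacles, cost is the
shortest path on an 8-connected grid of pitch `h` (diagonal cost
$h\sqrt 2$), which overestimates Euclidean lengths by at most ~8–9%; a
goal unreachable on the grid has infinite cost. Distance fields are
computed per goal by Dijkstra (via `igraph`) and cached. Log-space
accumulation uses log-sum-exp; per-step log-probabilities are floored at
−745 to keep sums finite.

Bordered ("lake") worlds are built as a distance buffer around the rendered
polyline: points at distance in `(margin, margin + width]` of the path are
impassable, leaving a corridor of half-width `margin = 0.4` flanked by
lakes of thickness `width = 2`. A buffer with round joins (rather than
miter-join polygon offsetting) stays well-defined for the self-intersecting
and closed paths in the stimulus set; construction fails loudly if the
corridor pinches shut. When comparing bordered and unbordered scores the
package evaluates both with the grid cost (`cost_method = "grid"`), so the
comparison never mixes discretized and exact geometry.

Blocking an alternative step, or removing a goal, can only concentrate the
policy on what remains, so corridors lower communicativeness scores; the
test suite verifies `score(bordered) <= score(unbordered)` on every
bordered pair, and the analysis scripts additionally show the drop is
larger for rarer paths.

## Stimulus builders

* `build_study1_set(seed)` — the two maximally efficient canonical paths
  (class A: the straight cardinal and straight diagonal chains are the only
  rarity-0 canonical paths) plus three random paths from each remaining
  class: 23 paths spanning the rarity range.
* `build_study2_set()` — seven two-primitive basic movements, each with a
  one-repetition (out-and-back, then rotated 90° CCW and reflected over the
  x-axis) and a two-repetition version (two cycles, rotated 180°), all 21
  rescaled to the same total traveled distance (that of the longest
  unscaled item, since only the equality is specified). Basics never have a
  second primitive retracing the first, and are chosen deterministically to
  span the rarity range of the two-primitive space; already-closed basics
  are excluded because repetition could not add rarity to them.
* `build_study3_set(study1_set, ratings, seed)` — one random path per
  class, plus four random paths with mean rating ≥ 4.25; each of the 12
  emitted unbordered and bordered (with `make_bordered_world()`).

Each builder records its seed; the same seed reproduces the same set
exactly. The published stimulus selections used unknown seeds, so the
builders reproduce the *construction*, not the particular random draws.

## Synthetic judgments

`simulate_judgments()` emulates the Likert (1–7) rating design: with
standardized predictor $z$ (rarity or model score),

$$\text{rating} = \mathrm{clamp}\big(\mathrm{round}(a + b\,z + u_p +
\varepsilon),\, 1,\, 7\big),\qquad u_p \sim N(0, \tau^2),\;
\varepsilon \sim N(0, \sigma^2),$$

with defaults $a = 4$, $b = 1.2$, $\tau = 0.5$, $\sigma = 1$, 30
participants. The rounded-and-clamped Gaussian link is a deliberate
simplification (an ordered-logit would be more realistic but adds nothing
for pipeline testing). What the generator does *not* emulate: systematic
rater disagreement with the predictor (real per-path means deviate from any
monotone function of rarity far more than averaging noise suggests),
response styles, order effects, or missingness. Consequently synthetic
correlations are cleaner than published ones (≈0.99 at the defaults versus
≈0.8 in real ratings); passing tests show the pipeline recovers what the
generator put in, not that the model explains human raters.

Two quantitative consequences of the discrete link matter for testing.
First, rounding-and-clamping attenuates the recoverable slope by ~3% at the
defaults. Second, for parameter recovery the confidence interval must
reflect the design: ratings vary over *two* random factors, participants
and paths. `recover_linking_slope()` therefore bootstraps both factors
(resampling participants and paths independently — the classic
subjects-and-items argument); a participant-only bootstrap understates the
uncertainty of a slope defined over a path population and breaks nominal
coverage once the small attenuation is in play.

## Statistics

Effect sizes are reported with percentile-bootstrap confidence intervals,
resampling paths (the unit of the correlation), 10,000 resamples by
default. Model scores are put on the Likert scale by OLS
(`calibrate_linear()`), and per-class discrepancies are means of
(calibrated prediction − mean rating), positive when the model rates the
class as more communicative than raters do.

The permutation test for "excluding these paths raises the correlation"
draws random equal-size exclusions as its null (exhaustively enumerated
when there are at most `n_perm` subsets), with the add-one estimator
$p = (1 + \#\{\Delta r_{\text{null}} \ge \Delta r_{\text{obs}}\})/(n_{\text{perm}} + 1)$.
What is permuted is the *identity of the excluded subset*, which directly
targets the claim being tested; the published account does not state its
scheme, and this is the most direct one.

## What the tests compute, and at what sizes

Property-style suites cover: symmetry invariance of rarity, length and
class (1000 and 150 sampled specs); canonicalization against a
rendered-coordinate orbit oracle (exhaustive for one- and two-primitive
paths, 200 sampled orbits for four); Burnside and transfer-matrix count
oracles; planner closed forms at `beta = 0`, curve monotonicity,
brute-force goal-enumeration equality (25-goal lattice, tolerance 1e-8),
straight-vs-loop and repetition orderings, and the bordered inequality on
all 12 pairs. Statistical calibration runs at reduced-but-stable sizes
chosen to keep the default suite fast: CI coverage with 500 replications of
1000 resamples, null permutation calibration with 200 replications of 299
permutations, power at 10,000 permutations, slope recovery with 100
replications of 500 crossed resamples. These sizes are the package's
standing choices and are the same ones the reported numbers come from.

## Known limitations

* The observer has no explicit communicative-agent model: the score is a
  deficit of world-directedness, not a likelihood ratio between two
  generative accounts.
* Goals are locations only — no subgoals, hidden constraints,
  information-seeking, or incompetence, so inefficiencies those processes
  produce are (correctly, under this model) scored as rare.
* Grid cost-to-go inherits 8-connected anisotropy; comparisons across
  worlds should use a common `cost_method`.
* The synthetic generator is a pipeline test harness, not a rater model;
  quantitative agreement with human effect sizes is out of its scope.
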