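---
title: "Quantifying mobile-bearing dislocation risk with a motion planner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mobile-bearing dislocation risk with a motion planner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bearingrrt)
```

## The problem

Domed lateral unicompartmental knee replacements interpose a fully mobile
polyethylene bearing between a spherically domed tibial component (with a
raised wall on its medial edge) and a spherical femoral condyle. Because the
bearing is held only by congruence and soft-tissue tension, it can escape —
dislocate — when the lateral compartment is distracted. The clinically
dominant mode is medial, with the bearing riding over the tibial wall.

`bearingrrt` treats this as a rigid-body motion-planning problem. The
femoral and tibial components form a static *environment*; the bearing is a
free-flying *robot* with a six-degree-of-freedom pose (translation plus unit
quaternion). For a given relative placement of the components —
a mediolateral (ML) translation and a vertical distraction — a
rapidly-exploring random tree (RRT) searches for a collision-free path from
the seated position to a *goal region* outside the implant on the chosen
side. If the bearing's volume centroid enters the goal region, that
configuration dislocates. The **Distraction to Dislocation (DD)** for an ML
translation is the smallest vertical distraction at which an escape path
exists; risk is summarised as DD versus ML per direction (medial, lateral,
anterior, posterior).

## The synthetic implant

Real implant CAD geometry is proprietary, so the package generates a
parametric stand-in (`implant_params()`, `make_tibial()`, `make_bearing()`,
`make_femoral()`) that reproduces the essential features: a flat tibial
plateau with a centred spherical dome and a raised anteroposterior wall on
the medial edge; a biconcave bearing whose inferior concavity is congruent
with the dome and whose superior concavity is congruent with the femoral
sphere; and a spherical femoral condyle segment. Meshes are built as closed
surfaces of revolution and boxes; watertightness is asserted by a
boundary-edge check.

The frame convention is millimetres with +x lateral, +y anterior,
+z superior and the plateau top at z = 0. ML translation is applied to the
femoral component along +x — away from the medial wall — and the bearing's
seated start follows it, so ML equals the bearing-to-wall distance, the
quantity a surgeon controls at implantation. Seating congruent spheres at an
ML offset necessarily overlaps the dome slightly; the valid-start correction
(`find_valid_start()`) lifts the bearing in 0.01 mm steps until it is free
(up to 3 mm — the analytic overlap reaches ≈2.3 mm at ML 6 with the default
geometry). At low distraction and large offset no free seating exists at
all; such configurations are recorded as `invalid_start` and treated as
non-dislocating, which matches their physical meaning.

Default dimensions (all overridable) are chosen at plausible lateral-UKR
scale: dome radius 25 mm with a 2 mm apex, 50 × 30 mm plateau, 5 mm wall,
18 mm bearing with 4 mm minimum thickness, 24 mm femoral sphere radius. Two
geometric facts motivated the defaults, both visible in closed form before
any planning. First, congruence forces the dome apex to be at least the
bearing's inferior sagitta (1.68 mm here), else the seated rim sinks below
the plateau. Second, the binding constraint for a medial escape should be
the *corner gap* between the wall top and the femoral sphere, whose width
grows strongly as the femoral component translates laterally — this is what
makes medial DD fall with ML, the qualitative signature of the clinically
observed mechanism. A bearing wide relative to the plateau instead gets pinched
between the dome flank and the femoral sphere over its lateral rim, a
squeeze that is ML-independent and would flatten the trend; the 18 mm
default avoids that regime. What the generator does *not* emulate: the real
components' anatomic, non-axisymmetric shapes, polyethylene compliance, and
any soft-tissue restraint beyond two rigid walls. Absolute DD values
therefore characterise the synthetic implant only; the qualitative
ML dependence, and everything upstream of geometry (planner, sweep,
statistics), is what tests on this generator can and do establish.

## Collision checking

Collision queries (`collision_world()`, `in_collision()`, `motion_valid()`,
`signed_clearance()`) run on axis-aligned-bounding-box trees over both
meshes. Touching counts as colliding: any triangle pair within 1e-6 mm
reports a collision (congruent surfaces in contact are therefore "in
collision", which is exactly why the smart start exists). Exact
triangle-triangle distances are only computed for pairs that survive three
conservative rejections (box overlap inflated by the tolerance, a
supporting-plane separation certificate, and a separating-axis test with
margin); a ray-parity containment test catches a robot buried wholly inside
a solid. Swept motions interpolate linearly in translation and by shortest
arc spherically in rotation, sampled so that spacing along the combined arc
(translation plus `rotation_weight` × rotation angle) never exceeds the
collision resolution — stricter than sampling the translation arc alone,
because a pure rotation of an 18 mm disc can sweep its rim millimetres.
Interior samples skip the containment ray: a solid thicker than the
resolution cannot be entered between samples without a detected surface
crossing.

The production collision resolution of 0.0001 mm is available but costs
12 500 checks per 1.25 mm step; the package default is 0.01 mm, and the test
suite uses 0.1–0.15 mm with coarse (3 mm target edge) meshes. The validity
properties checked in the tests (symmetry, conservativeness under
refinement, agreement with a brute-force all-pairs oracle) are
resolution-independent.

## The planner

`rrt_once()` is a standard RRT with goal biasing: with probability
`goal_bias` (default 0.05) the sampled pose places the centroid in the goal
box, otherwise uniformly in the bounding box, with a random orientation; the
nearest tree node under the weighted metric (translation distance +
5 mm/rad × rotation angle) is extended by one 1.25 mm step; the node is kept
if the swept motion is valid. Orientation sampling is uniform over SO(3) by
default, with an optional tilt cap (`max_tilt_deg`) — the physical bearing
cannot somersault between congruent surfaces, and capping tilt at 45–60°
concentrates samples on reachable attitudes; the implant test sweeps use
60°. Budgets are either wall-clock seconds (production parity; the reference
schedules ship as `planner_preset("testing")`, 270 s × 10 attempts
escalating to 405 s × 25, and `planner_preset("smart-search")`,
180 s × 10 → 270 s × 25) or iteration counts, which make every run exactly
reproducible: all randomness flows from one 64-bit mixed seed per
(configuration, phase, attempt) via `derive_seed()`.

`plan_with_attempts()` restarts the tree up to `attempts` times;
`validate_path()` re-checks every returned path independently against the
collision module and the goal test.

## The smart sweep

`smart_sweep()` implements directional searching with conditional budget
ramp-up: for each ML (ascending), distractions are tested from the most
likely to dislocate (maximum) down to the least likely; a failure under the
initial budget is re-searched once with the extended budget; a confirmed
failure (or an unseatable start) fixes DD at that ML as the smallest
dislocating distraction and the sweep advances, skipping the remaining lower
levels under the monotonicity assumption. `early_exit = FALSE` audits that
assumption by evaluating the full grid, and doubles as the brute-force
reference against which the efficiency property (strictly fewer planner
invocations whenever any level fails) is counted exactly. The arithmetic
behind the efficiency claim is exposed as `theoretical_max_time()`
(brute force: configurations × time × attempts) and `optimised_max_time()`
(dislocations beyond one per ML at the initial budget plus one extended
search per ML).

A false `no_dislocation` from RRT randomness is mitigated exactly once, by
the extended re-search — not by extra retries — so a reported DD can sit one
grid step above the true threshold when a marginal level is missed; the
acceptance checks therefore use one-grid-step tolerances throughout.

## Scene regions

The search bounding box constrains the bearing centroid: implant bounds
padded by 1.5 bearing diameters on the dislocation side and 0.5 elsewhere,
floored just below the plateau top (so the bearing cannot dive under the
tibial plate). For medial/lateral runs the transverse (anteroposterior) axis
is additionally clamped to ± one bearing radius: the spherical condyle ends
~20 mm from its centre and an unconstrained planner otherwise escapes around
its anterior edge through space that the femur and soft tissue occupy in
vivo — the bounding box's purpose is precisely to keep the search in the
physically meaningful region. Anterior/posterior runs instead gain a rigid
lateral wall mesh standing in for the lateral soft tissues, without which
the bearing dislocates anteriorly via the lateral space. The goal region is
a slab one bearing-diameter deep just outside the plateau edge on the
dislocation side, spanning the clamped transverse range and the full box
height; dislocation triggers when the centroid crosses into it (boundary
inclusive). Subtle "lodged above the wall" poses that never leave the
implant footprint are thus not counted — refining the goal region is the
natural lever if they should be.

## Agreement statistics

`icc_consistency_k()` computes the two-way random-effects, consistency,
average-measures intraclass correlation ICC(C,k) for k = 2 from the ANOVA
mean squares, `ICC = (MS_subjects − MS_error) / MS_subjects`, with the 95%
interval from F-distribution bounds (`1 − 1/F_L` with
`F_L = F_obs / F_{0.975}(n−1, n−1)`, and symmetrically for the upper bound).
Consistency-type agreement deliberately ignores a fixed offset between
methods. `bland_altman()` reports the mean and sample (n−1) SD of paired
differences and the ±1.96 SD limits. `compare_sweeps()` joins two DD-by-ML
tables on ML (erroring on mismatched keys, dropping MLs where either method
found no dislocation in range) and reports both summaries; in the original
validation design one table comes from the planner and one from a mechanical
rig.

## Numerical choices and degenerate inputs

Touch tolerance 1e-6 mm; boundary poses count as in-goal; quaternions are
normalised on construction and compared up to sign; slerp falls back to
normalised lerp within ~1.8° of alignment; zero-length motions are valid iff
their single pose is free. A zero wall height drops the wall mesh rather
than emitting a degenerate box. ICC on constant, identical ratings is
undefined and reported as `NA` with a warning; perfect non-constant
agreement short-circuits to ICC 1 before the infinite F statistic. Binary
STL stores float32, so round-trips through it are exact only to float32
precision; ASCII output carries 9 significant digits.

## Problem sizes used by the tests

The suite and `scripts/acceptance.R` run the implant at 3 mm mesh
resolution (≈400-face bearing, ≈1000-face environment), 0.15 mm collision
resolution, iteration budgets of 3000 × 4 attempts escalating to
10000 × 10, a distraction grid of 0–8 mm by 1 mm and ML ∈ {0, 3, 6} mm;
oracle-scene checks use 0.25 mm grids. These sizes were chosen so the full
suite completes on one CPU core in well under half an hour while keeping the
marginal-level flakiness of RRT below the one-grid-step tolerances.

## Known limitations

Axisymmetric synthetic geometry (no anatomic condyle; lateral ≈
anteroposterior behaviour is more symmetric than in the real implant);
rigid bodies only; a single rigid wall stands in for all lateral soft
tissue; DD is resolved only to the distraction grid; RRT gives a
probabilistic, one-sided answer (a found path is definitive, a missed one
is not), mitigated but not eliminated by the extended re-search.
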