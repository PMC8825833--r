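# bearingrrt

Mobile-bearing dislocation analysis for unicompartmental knee replacement
(UKR) by sampling-based motion planning.

In domed lateral UKR a fully mobile polyethylene bearing sits unconstrained
between a spherically domed tibial component (with a raised medial wall) and
a spherical femoral condyle. When the lateral compartment distracts, the
bearing can escape — dislocate — most often medially over the wall.
`bearingrrt` quantifies that risk *in silico*: the implant components form a
static environment, the bearing is a free-flying rigid body, and a
rapidly-exploring random tree (RRT) searches for a collision-free escape
path for every relative placement of the components. The package is for
biomechanics and implant-design researchers who want dislocation risk as a
function of surgical placement without a physical rig.

## Method in brief

For a dislocation direction *d* ∈ {medial, lateral, anterior, posterior}
and a configuration (*ml*, *v*) — mediolateral femoral translation and
vertical distraction, both in mm — build a scene: tibial mesh at the
origin, femoral mesh translated by (*ml*, 0, *v*), bearing seated
congruently, a bounding box limiting the search, and a goal region outside
the implant on side *d*. A configuration **dislocates** iff RRT finds a
path of collision-checked motions whose final pose puts the bearing
centroid in the goal region. The **Distraction to Dislocation** is

&nbsp;&nbsp;&nbsp;&nbsp;DD(*ml*) = min { *v* : (*ml*, *v*) dislocates },

estimated by the *smart sweep*: for each *ml*, test *v* from the most
dislocation-prone (maximum) downward; re-search any failure once with an
extended budget (time × attempts ramp-up); stop the column on a confirmed
failure. Agreement between two DD tables (e.g. planner vs mechanical rig)
is summarised by the two-way random-effects consistency ICC for mean
ratings, ICC(C,2) = (MS_subjects − MS_error)/MS_subjects with an
F-distribution 95% CI, and by Bland–Altman mean ± SD of differences.

Proprietary implant CAD models are replaced by a parametric synthetic
implant generator (`implant_params()`, `make_tibial()`, `make_bearing()`,
`make_femoral()`), plus an analytic ball-over-wall *oracle scene* whose
escape clearance is known in closed form,
`max(0, ball_d + wall_h − gap0)` — the test bench for the whole pipeline.

## Worked example

Sweep the analytic oracle scene (closed-form DD = 4 + 2 − 4 = 2 mm) and
check the planner recovers it:

```r
library(bearingrrt)
res <- cmd_oracle_test(gap0 = 4, wall_h = 2, ball_d = 4, v_max = 5, seed = 1)
#> oracle: closed-form DD 2.00 mm; swept DD 2.00, 2.00 mm; max |error| 0.00 mm
res$dd
#>   ml_mm dd_mm
#> 1     0     2
#> 2     2     2
```

The sweep descended from 5 mm, found escape paths down to exactly 2 mm at
both ML positions, and confirmed the failure below it — matching the closed
form with zero grid error. The same machinery runs on the synthetic
implant:

```r
cfg <- run_config(list(
  directions = c("medial", "lateral"),
  grid = list(v_max = 8, v_step = 1, ml_max = 6, ml_step = 3),
  planner = list(initial  = list(max_iterations = 3000,  attempts = 4),
                 extended = list(max_iterations = 10000, attempts = 10),
                 collision_resolution = 0.15, max_tilt_deg = 60,
                 goal_bias = 0.1),
  mesh_resolution = 3, seed = 1, output_dir = "out"))
cmd_sweep(cfg)   # CSVs, a DD-vs-ML plot and a reproducibility manifest
```

On the default synthetic implant medial DD falls as the components
translate laterally away from the wall (e.g. 5 mm at ML 0 to 4 mm at ML 6
on the 1 mm test grid), while lateral/anterior/posterior DD are
ML-independent — the directional signature that makes medial dislocation
the clinically dominant mode. `enumerate_grid(grid_spec())` has 825 rows
(33 distractions × 25 ML values);
`theoretical_max_time(825, 405, 25)` = 8 353 125 s of brute-force testing
versus `optimised_max_time(410, 25, 180, 10, 405, 25)` = 946 125 s for the
smart sweep.

A shell front-end wrapping these functions is installed at
`inst/cli/bearingrrt.R` (`generate`, `sweep`, `compare`, `oracle-test`).

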