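# Scene construction: one planning problem per (direction, configuration).
#
# The femoral component is translated by (+ml, 0, +v) from its congruent rest
# pose; +x points laterally, so increasing ML moves the femoral component --
# and the bearing seated congruently beneath it -- away from the medial wall,
# making ML the bearing-to-wall distance. The bearing's nominal start is
# seated on the dome at the femoral ML offset, flush against the wall at
# ML = 0; sliding it laterally along the (spherical) dome while keeping its
# seat height produces the minor congruent-surface overlaps that the
# valid-start correction resolves by lifting.

DIRECTIONS <- c("medial", "lateral", "anterior", "posterior")

direction_axis <- function(direction) {
  switch(direction,
         medial = c(-1, 0, 0), lateral = c(1, 0, 0),
         anterior = c(0, 1, 0), posterior = c(0, -1, 0),
         stop(sprintf("unknown direction '%s' (use one of %s)", direction,
                      paste(DIRECTIONS, collapse = ", "))))
}

#' One grid point of the sweep
#'
#' @param ml_translation mediolateral femoral translation (mm, lateral
#'   positive, i.e. bearing distance from the medial wall).
#' @param vertical_distraction vertical femoral lift (mm).
#' @return an object of class `configuration`.
#' @export
configuration <- function(ml_translation, vertical_distraction) {
  stopifnot(is.numeric(ml_translation), is.numeric(vertical_distraction),
            length(ml_translation) == 1L, length(vertical_distraction) == 1L)
  structure(list(ml_translation = ml_translation,
                 vertical_distraction = vertical_distraction),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("configuration: ML %.2f mm, distraction %.2f mm\n",
              x$ml_translation, x$vertical_distraction))
  invisible(x)
}

#' Scene construction options
#'
#' Bounding-box and goal-region sizing, in units of the bearing diameter, and
#' the touch tolerance used by collision queries.
#'
#' @param pad_escape bbox padding beyond the implant bounds on the
#'   dislocation side (x bearing diameter).
#' @param pad_other bbox padding on the remaining sides (x bearing diameter).
#' @param goal_depth depth of the goal slab just outside the plateau edge
#'   (x bearing diameter).
#' @param bbox_z_lo lower z limit for the bearing centroid (mm); slightly
#'   below the plateau top, preventing unphysical paths beneath the tibial
#'   plate.
#' @param track_half_width half-width (mm) of the centroid's allowed
#'   transverse excursion for medial/lateral runs; `NULL` uses the bearing
#'   radius. This keeps the search in the relevant region under the femoral
#'   condyle: without it the planner escapes around the anterior/posterior
#'   end of the condyle, which in vivo is blocked by the femur and soft
#'   tissue.
#' @param touch_eps collision touch tolerance (mm).
#' @export
scene_options <- function(pad_escape = 1.5, pad_other = 0.5, goal_depth = 1,
                          bbox_z_lo = -2, track_half_width = NULL,
                          touch_eps = 1e-6) {
  list(pad_escape = pad_escape, pad_other = pad_other, goal_depth = goal_depth,
       bbox_z_lo = bbox_z_lo, track_half_width = track_half_width,
       touch_eps = touch_eps)
}

#' Build one planning scene for the synthetic implant
#'
#' Places the tibial component at the origin, the femoral component at its
#' congruent rest pose translated by `(ml, 0, v)`, seats the bearing
#' congruently on the dome flush against the medial wall at ML 0 (following
#' the femoral ML offset), and defines the search bounding box and the goal
#' region on the dislocation side. For anterior/posterior runs a lateral wall
#' is appended to the environment, standing in for the lateral soft tissues.
#'
#' @param direction one of `"medial"`, `"lateral"`, `"anterior"`,
#'   `"posterior"`.
#' @param config a [configuration()].
#' @param params an [implant_params()].
#' @param opts a [scene_options()] list.
#' @return an object of class `scene`.
#' @export
build_scene <- function(direction, config, params = implant_params(),
                        opts = scene_options()) {
  stopifnot(inherits(config, "configuration"),
            inherits(params, "implant_params"))
  src <- implant_scene_source(params, opts)
  src(direction, config)
}

#' Reusable scene factory for the synthetic implant
#'
#' Meshes the implant once and returns a function
#' `(direction, configuration) -> scene`, so a grid sweep does not re-mesh
#' per configuration. [build_scene()] is this factory applied once.
#'
#' @inheritParams build_scene
#' @return a function `(direction, config)` returning a [build_scene()] scene.
#' @export
implant_scene_source <- function(params = implant_params(),
                                 opts = scene_options()) {
  d <- implant_derived(params)
  tib <- make_tibial(params)
  fem <- make_femoral(params)
  bear <- make_bearing(params)
  W <- params$plateau_width_ML
  L <- params$plateau_length_AP
  diam <- params$bearing_outer_diameter

  function(direction, config) {
    axis <- direction_axis(direction)
    ml <- config$ml_translation
    v <- config$vertical_distraction
    x0 <- d$flush_x + ml
    fem_w <- mesh_translate(fem, c(x0, 0, d$fem_centre_z + v))
    env <- list(tib, fem_w)
    if (direction %in% c("anterior", "posterior")) {
      fem_top <- d$fem_centre_z + v - params$femoral_sphere_radius +
        d$fem_segment_height
      lat_wall <- box_mesh(c(W / 2, -L, -EMBED),
                           c(W / 2 + params$wall_thickness, L, fem_top + 2),
                           name = "lateral_wall")
      env <- c(env, list(lat_wall))
    }
    eb <- Reduce(function(acc, m) {
      b <- mesh_bounds(m)
      rbind(pmin(acc[1, ], b[1, ]), pmax(acc[2, ], b[2, ]))
    }, env, init = rbind(rep(Inf, 3), rep(-Inf, 3)))
    bbox <- rbind(lo = eb[1, ] - opts$pad_other * diam,
                  hi = eb[2, ] + opts$pad_other * diam)
    esc <- which(axis != 0)
    if (axis[esc] > 0) {
      bbox["hi", esc] <- eb[2, esc] + opts$pad_escape * diam
    } else {
      bbox["lo", esc] <- eb[1, esc] - opts$pad_escape * diam
    }
    bbox["lo", 3] <- opts$bbox_z_lo
    if (direction %in% c("medial", "lateral")) {
      th <- opts$track_half_width %||% (diam / 2)
      bbox["lo", 2] <- max(bbox["lo", 2], -th)
      bbox["hi", 2] <- min(bbox["hi", 2], th)
    }
    # goal: a slab just outside the plateau edge on the dislocation side,
    # spanning the bearing track transversely and the full bbox height
    plat <- rbind(c(-W / 2, -L / 2), c(W / 2, L / 2))  # cols: x, y
    goal <- bbox
    edge <- if (axis[esc] > 0) plat[2, esc] else plat[1, esc]
    if (axis[esc] > 0) {
      goal["lo", esc] <- edge + 0.05
    } else {
      goal["hi", esc] <- edge - 0.05
    }
    tr <- 3 - esc  # the other horizontal axis
    goal["lo", tr] <- max(plat[1, tr], bbox["lo", tr])
    goal["hi", tr] <- min(plat[2, tr], bbox["hi", tr])
    start <- pose(t = c(x0, 0, d$seat_z))
    structure(list(direction = direction, environment = env, robot = bear,
                   bbox = bbox, goal = goal, start = start, config = config,
                   params = params, opts = opts,
                   cache = new.env(parent = emptyenv())),
              class = "scene")
  }
}

#' Scene factory for the analytic ball-over-wall oracle
#'
#' Wraps [make_oracle_scene()] as a `(direction, configuration) -> scene`
#' factory in which the vertical distraction lifts the ceiling plate. The
#' escape direction is +x regardless of the `direction` label; ML translation
#' has no effect on the geometry, so the closed-form answer is
#' ML-independent.
#'
#' @inheritParams make_oracle_scene
#' @param touch_eps collision touch tolerance (mm).
#' @return a function `(direction, config)` returning a [build_scene()] scene, with the
#'   closed-form DD attached as attribute `closed_form_dd`.
#' @export
oracle_scene_source <- function(gap0, wall_h, ball_d, mesh_resolution = 0.8,
                                touch_eps = 1e-6) {
  base <- make_oracle_scene(gap0, wall_h, ball_d,
                            mesh_resolution = mesh_resolution)
  dims <- base$dims
  r <- ball_d / 2
  src <- function(direction, config) {
    v <- config$vertical_distraction
    env <- oracle_environment(dims, v)
    bbox <- rbind(lo = c(dims$x_min + r, -dims$y_half + r, 0),
                  hi = c(dims$x_max, dims$y_half - r, dims$gap0 + v))
    goal <- bbox
    goal["lo", 1] <- dims$x_wall + dims$wall_t + 0.25
    structure(list(direction = direction, environment = env,
                   robot = base$robot, bbox = bbox, goal = goal,
                   start = pose(t = c(0, 0, r)), config = config,
                   params = NULL,
                   opts = list(touch_eps = touch_eps),
                   cache = new.env(parent = emptyenv())),
            class = "scene")
  }
  attr(src, "closed_form_dd") <- base$closed_form_dd
  src
}

#' Minimal free-space scene
#'
#' A ball robot in an empty (or user-supplied) environment with a goal slab
#' a short distance along +x: the simplest non-trivial planning problem,
#' used for planner reliability checks and demonstrations.
#'
#' @param goal_distance distance from the start to the near goal face (mm).
#' @param environment optional list of obstacle [tri_mesh()]es.
#' @param ball_radius robot ball radius (mm).
#' @return a [build_scene()] scene.
#' @export
free_space_scene <- function(goal_distance = 10, environment = list(),
                             ball_radius = 1) {
  prof <- arc_profile(ball_radius, 0, 0, -pi / 2, pi / 2, ball_radius / 3)
  ball <- revolve_mesh(prof, segments_around(ball_radius, ball_radius / 3),
                       name = "ball")
  structure(list(
    direction = "lateral", environment = environment, robot = ball,
    bbox = rbind(lo = c(-5, -8, -8), hi = c(goal_distance + 6, 8, 8)),
    goal = rbind(lo = c(goal_distance, -8, -8),
                 hi = c(goal_distance + 6, 8, 8)),
    start = pose(), config = configuration(0, 0), params = NULL,
    opts = list(touch_eps = 1e-6),
    cache = new.env(parent = emptyenv())), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("scene: direction %s, %d environment mesh(es), robot '%s'\n",
              x$direction, length(x$environment), x$robot$name))
  if (!is.null(x$config)) print(x$config)
  cat(sprintf("  bbox x [%.1f, %.1f] y [%.1f, %.1f] z [%.1f, %.1f] mm\n",
              x$bbox[1, 1], x$bbox[2, 1], x$bbox[1, 2], x$bbox[2, 2],
              x$bbox[1, 3], x$bbox[2, 3]))
  invisible(x)
}

# collision world for a scene, cached on the scene object
scene_world <- function(scene) {
  w <- scene$cache$world
  if (is.null(w)) {
    w <- collision_world(scene$environment, scene$robot,
                         touch_eps = scene$opts$touch_eps)
    scene$cache$world <- w
  }
  w
}

scene_centroid <- function(scene) {
  cc <- scene$cache$centroid
  if (is.null(cc)) {
    cc <- mesh_centroid(scene$robot)
    scene$cache$centroid <- cc
  }
  cc
}

#' Correct the start pose for minor surface overlaps
#'
#' The congruent nominal start usually touches (or slightly penetrates) the
#' dome when the bearing is translated mediolaterally. This lifts the bearing
#' vertically in `lift_step` increments until collision-free, up to
#' `max_correction`, returning the first free pose (the minimal lift on the
#' `lift_step` grid).
#'
#' @param scene a [build_scene()] scene.
#' @param max_correction maximum total lift (mm).
#' @param lift_step lift increment (mm).
#' @return the corrected [pose()], or `NULL` when no collision-free pose is
#'   found within `max_correction` (an "invalid start": recorded by the
#'   sweep, not an error).
#' @export
find_valid_start <- function(scene, max_correction = 3, lift_step = 0.01) {
  stopifnot(inherits(scene, "scene"), max_correction > 0, lift_step > 0)
  world <- scene_world(scene)
  n <- floor(max_correction / lift_step + 1e-9)
  for (k in 0:n) {
    p <- pose(t = scene$start$t + c(0, 0, k * lift_step), q = scene$start$q)
    if (!in_collision(world, p)) return(p)
  }
  NULL
}

#' Has the bearing dislocated at a pose?
#'
#' @param scene a [build_scene()] scene.
#' @param pose a [pose()].
#' @return `TRUE` iff the robot's volume centroid, transformed by `pose`,
#'   lies inside the scene's goal box (boundary inclusive).
#' @export
in_goal <- function(scene, pose) {
  stopifnot(inherits(scene, "scene"), inherits(pose, "pose"))
  cw <- transform_points(pose, scene_centroid(scene))
  all(cw >= scene$goal[1, ] & cw <= scene$goal[2, ])
}
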