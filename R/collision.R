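#' Build a collision world
#'
#' Packages the static environment meshes and the movable robot mesh into an
#' acceleration structure for pose collision queries. Queries are pure: no
#' state is mutated between calls.
#'
#' Touching counts as colliding: any pair of surface triangles within
#' `touch_eps` (default 1e-6 mm) reports a collision, so congruent implant
#' surfaces in grazing contact are "in collision" and must be separated by
#' the valid-start correction before planning.
#'
#' @param environment a [tri_mesh()] or list of them (static obstacles).
#' @param robot the movable [tri_mesh()] in its local frame.
#' @param touch_eps touch tolerance in mm.
#' @return an object of class `collision_world`.
#' @export
collision_world <- function(environment, robot, touch_eps = 1e-6) {
  if (inherits(environment, "tri_mesh")) environment <- list(environment)
  stopifnot(all(vapply(environment, inherits, logical(1), "tri_mesh")),
            inherits(robot, "tri_mesh"), touch_eps >= 0)
  w <- structure(list(environment = environment, robot = robot,
                      touch_eps = touch_eps, cache = new.env(parent = emptyenv())),
                 class = "collision_world")
  w
}

#' @export
print.collision_world <- function(x, ...) {
  cat(sprintf("collision_world: %d environment mesh(es) (%d faces), robot '%s' (%d faces)\n",
              length(x$environment),
              sum(vapply(x$environment, function(m) nrow(m$faces), integer(1))),
              x$robot$name, nrow(x$robot$faces)))
  invisible(x)
}

# lazily (re)build the C++ acceleration structure; external pointers do not
# survive serialisation, so rebuild whenever the pointer is gone
world_ptr <- function(world) {
  p <- world$cache$ptr
  if (is.null(p) || !cpp_world_ok(p)) {
    p <- cpp_world_build(
      lapply(world$environment, function(m) list(vertices = m$vertices,
                                                 faces = m$faces)),
      world$robot$vertices, world$robot$faces, world$touch_eps)
    world$cache$ptr <- p
  }
  p
}

#' Is the robot in collision at a pose?
#'
#' @param world a [collision_world()].
#' @param pose a [pose()] placing the robot.
#' @return `TRUE` iff the robot surface intersects (or touches, within the
#'   world's touch tolerance) any environment surface, or the robot is buried
#'   inside an environment solid.
#' @export
in_collision <- function(world, pose) {
  stopifnot(inherits(world, "collision_world"), inherits(pose, "pose"))
  cpp_collide(world_ptr(world), pose$t, pose$q)
}

#' Is a swept motion between two poses collision-free?
#'
#' Interpolates linearly in translation and spherical-linearly in rotation,
#' sampling at spacing at most `resolution` along the combined arc
#' (translation distance plus `rotation_weight` times the rotation angle),
#' with at least the two endpoints, and checks every sample.
#'
#' @param world a [collision_world()].
#' @param pose_a,pose_b endpoint [pose()]s.
#' @param resolution maximum sample spacing (mm); must be positive.
#' @param rotation_weight metric weight converting rotation (rad) to mm.
#' @return `TRUE` iff every sampled pose is collision-free.
#' @export
motion_valid <- function(world, pose_a, pose_b, resolution,
                         rotation_weight = 5) {
  stopifnot(inherits(world, "collision_world"),
            inherits(pose_a, "pose"), inherits(pose_b, "pose"))
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0) {
    stop("parameter 'resolution' must be positive")
  }
  cpp_motion_valid(world_ptr(world), pose_a$t, pose_a$q, pose_b$t, pose_b$q,
                   resolution, rotation_weight)
}

#' Signed clearance of the robot at a pose
#'
#' @param world a [collision_world()].
#' @param pose a [pose()].
#' @return minimum surface separation (mm) when collision-free; `0` at
#'   grazing contact; the negated penetration-depth estimate (deepest buried
#'   vertex's distance to the opposing surface) when colliding.
#' @export
signed_clearance <- function(world, pose) {
  stopifnot(inherits(world, "collision_world"), inherits(pose, "pose"))
  cpp_clearance(world_ptr(world), pose$t, pose$q)
}

#' Deterministically derive a planner seed
#'
#' Stable 64-bit mixing of a master seed with integer indices (attempt
#' number, grid indices, ...), identical across platforms. Used so that every
#' (configuration, attempt) pair plans with its own reproducible stream.
#'
#' @param master numeric master seed.
#' @param ... integer indices to mix in.
#' @return a numeric seed (53-bit integer value).
#' @export
derive_seed <- function(master, ...) {
  idx <- as.integer(c(...))
  cpp_mix_seed(as.numeric(master), idx)
}
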