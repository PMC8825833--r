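# Parametric synthetic implant geometry.
#
# Local frame convention used throughout the package: millimetres, +x lateral
# (away from the raised medial wall), +y anterior, +z superior, tibial plateau
# top at z = 0. The medial wall therefore sits on the -x edge of the plateau,
# and increasing mediolateral (ML) translation moves the femoral component --
# and with it the bearing's seated start -- away from the wall, i.e. ML equals
# the bearing-to-wall distance.

# plate below the plateau top and embedding depth for merged sub-solids
PLATE_THICKNESS <- 5
EMBED <- 0.5

#' Parameters of the synthetic implant
#'
#' Dimensions (mm) of the parametric lateral-UKR-like implant used in place
#' of proprietary CAD component models. Congruence is built in: the bearing's
#' inferior concavity has radius `dome_radius` and its superior concavity has
#' radius `femoral_sphere_radius`.
#'
#' Defaults describe a plausible lateral unicompartmental implant. Two
#' constraints shape them: `dome_apex_height` must be at least the bearing's
#' inferior sagitta (`dome_radius - sqrt(dome_radius^2 -
#' (bearing_outer_diameter/2)^2)`, 1.68 mm at the defaults) or the seated
#' bearing rim would sink below the plateau; and the bearing must be narrow
#' relative to the plateau so that the binding constraint for a medial
#' escape is the wall-to-femoral corner gap (strongly dependent on ML
#' translation, which is what makes medial DD fall as the components move
#' laterally) rather than the ML-independent squeeze between the dome flank
#' and the femoral sphere over the bearing's lateral rim.
#'
#' @param dome_radius radius of the spherical tibial dome (mm).
#' @param dome_apex_height dome apex height above the plateau top (mm).
#' @param plateau_length_AP anteroposterior plateau length (mm).
#' @param plateau_width_ML mediolateral plateau width (mm).
#' @param wall_height raised medial wall height above the plateau (mm);
#'   0 drops the wall.
#' @param wall_thickness medial wall thickness (mm).
#' @param bearing_outer_diameter outer diameter of the mobile bearing (mm).
#' @param bearing_min_thickness bearing thickness at its thinnest (central)
#'   point (mm).
#' @param femoral_sphere_radius radius of the spherical femoral condyle (mm).
#' @param mesh_resolution target edge length for generated meshes (mm).
#' @return an object of class `implant_params`.
#' @export
implant_params <- function(dome_radius = 25,
                           dome_apex_height = 2,
                           plateau_length_AP = 50,
                           plateau_width_ML = 30,
                           wall_height = 5,
                           wall_thickness = 2,
                           bearing_outer_diameter = 18,
                           bearing_min_thickness = 4,
                           femoral_sphere_radius = 24,
                           mesh_resolution = 1.5) {
  p <- list(dome_radius = dome_radius,
            dome_apex_height = dome_apex_height,
            plateau_length_AP = plateau_length_AP,
            plateau_width_ML = plateau_width_ML,
            wall_height = wall_height,
            wall_thickness = wall_thickness,
            bearing_outer_diameter = bearing_outer_diameter,
            bearing_min_thickness = bearing_min_thickness,
            femoral_sphere_radius = femoral_sphere_radius,
            mesh_resolution = mesh_resolution)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("parameter '%s' must be a finite number", nm))
    }
    lo <- if (nm == "wall_height") 0 else .Machine$double.eps
    if (v < lo) stop(sprintf("parameter '%s' must be positive", nm))
  }
  r <- bearing_outer_diameter / 2
  if (r >= dome_radius) {
    stop("parameter 'bearing_outer_diameter' must be < 2 * dome_radius")
  }
  if (r >= femoral_sphere_radius) {
    stop("parameter 'bearing_outer_diameter' must be < 2 * femoral_sphere_radius")
  }
  structure(p, class = "implant_params")
}

#' @export
print.implant_params <- function(x, ...) {
  cat("implant_params (mm):\n")
  for (nm in names(x)) cat(sprintf("  %-24s %g\n", nm, x[[nm]]))
  invisible(x)
}

# quantities derived from the parameters; used by generators and scenarios
implant_derived <- function(params) {
  r <- params$bearing_outer_diameter / 2
  sag_inf <- params$dome_radius - sqrt(params$dome_radius^2 - r^2)
  sag_sup <- params$femoral_sphere_radius -
    sqrt(params$femoral_sphere_radius^2 - r^2)
  rim_height <- params$bearing_min_thickness + sag_inf + sag_sup
  dome_centre_z <- params$dome_apex_height - params$dome_radius
  # bearing local frame: rim bottom plane at z = 0; inferior concavity sphere
  # centre at z = -(dome_radius - sag_inf)
  seat_z <- dome_centre_z + (params$dome_radius - sag_inf)
  # superior concavity sphere centre, bearing local frame
  sup_centre_z <- rim_height + (params$femoral_sphere_radius - sag_sup)
  wall_inner_x <- -params$plateau_width_ML / 2 + params$wall_thickness
  flush_x <- wall_inner_x + r + 1e-3
  list(bearing_radius = r, sag_inf = sag_inf, sag_sup = sag_sup,
       rim_height = rim_height, dome_centre_z = dome_centre_z,
       seat_z = seat_z, sup_centre_z = sup_centre_z,
       fem_centre_z = seat_z + sup_centre_z,
       wall_inner_x = wall_inner_x, flush_x = flush_x,
       fem_segment_height = params$femoral_sphere_radius * 5 / 12)
}

# ----------------------------------------------------------- primitives

#' Axis-aligned box mesh
#'
#' @param lo,hi opposite corners (mm).
#' @param name mesh label.
#' @export
box_mesh <- function(lo, hi, name = "box") {
  lo <- as.numeric(lo)
  hi <- as.numeric(hi)
  if (any(hi <= lo)) stop("box corners must satisfy hi > lo on every axis")
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertex order from expand.grid: x fastest; faces wound outward
  f <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = lo
             c(5, 6, 7), c(6, 8, 7),   # z = hi
             c(1, 2, 5), c(2, 6, 5),   # y = lo
             c(3, 7, 4), c(4, 7, 8),   # y = hi
             c(1, 5, 3), c(3, 5, 7),   # x = lo
             c(2, 4, 6), c(4, 8, 6))   # x = hi
  tri_mesh(v, f, name = name)
}

# surface of revolution about the z axis from an (r, z) profile polyline.
# The profile must start and end on the axis (r = 0); the result is a closed,
# consistently wound solid.
revolve_mesh <- function(profile, n_seg, name = "solid") {
  r <- profile[, 1]
  z <- profile[, 2]
  np <- length(r)
  if (r[1] > 1e-9 || r[np] > 1e-9) stop("profile must start and end on the axis")
  on_axis <- r <= 1e-9
  theta <- seq(0, 2 * pi, length.out = n_seg + 1L)[-(n_seg + 1L)]
  verts <- matrix(0, 0, 3)
  ring_idx <- vector("list", np)
  for (i in seq_len(np)) {
    if (on_axis[i]) {
      verts <- rbind(verts, c(0, 0, z[i]))
      ring_idx[[i]] <- rep(nrow(verts), n_seg)
    } else {
      ring <- cbind(r[i] * cos(theta), r[i] * sin(theta), z[i])
      ring_idx[[i]] <- nrow(verts) + seq_len(n_seg)
      verts <- rbind(verts, ring)
    }
  }
  faces <- vector("list", np - 1L)
  nxt <- c(seq_len(n_seg)[-1], 1L)
  for (i in seq_len(np - 1L)) {
    a <- ring_idx[[i]]
    b <- ring_idx[[i + 1L]]
    if (on_axis[i] && on_axis[i + 1L]) stop("degenerate profile segment on axis")
    q1 <- cbind(a, a[nxt], b[nxt])
    q2 <- cbind(a, b[nxt], b)
    f <- rbind(q1, q2)
    keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
    faces[[i]] <- f[keep, , drop = FALSE]
  }
  mesh_orient_outward(tri_mesh(verts, do.call(rbind, faces), name = name))
}

# arc of a circle of radius R centred at (r = cr, z = cz), sampled between
# angles a0 and a1 (radians, measured in the (r, z) plane), at ~res spacing
arc_profile <- function(R, cr, cz, a0, a1, res) {
  n <- max(4L, ceiling(abs(a1 - a0) * R / res))
  a <- seq(a0, a1, length.out = n + 1L)
  cbind(cr + R * cos(a), cz + R * sin(a))
}

segments_around <- function(r_max, res) {
  max(16L, ceiling(2 * pi * r_max / res))
}

# ------------------------------------------------------- implant meshes

#' Generate the tibial component mesh
#'
#' Flat plateau slab with a centred spherical dome cap and a raised wall
#' running anteroposteriorly along the medial (-x) edge. The plateau top
#' defines z = 0. The result is a single closed surface (the slab, dome and
#' wall are closed sub-solids embedded into one another).
#'
#' @param params an [implant_params()].
#' @return a watertight [tri_mesh()] named `"tibial"`.
#' @export
make_tibial <- function(params = implant_params()) {
  stopifnot(inherits(params, "implant_params"))
  d <- implant_derived(params)
  W <- params$plateau_width_ML
  L <- params$plateau_length_AP
  res <- params$mesh_resolution
  plate <- box_mesh(c(-W / 2, -L / 2, -PLATE_THICKNESS), c(W / 2, L / 2, 0),
                    name = "plateau")
  # dome: spherical cap above z = 0 with a short embedded skirt below
  h <- params$dome_apex_height
  R <- params$dome_radius
  a_rim <- sqrt(2 * R * h - h^2)             # cap footprint radius at z = 0
  ang_rim <- asin(a_rim / R)
  cz <- d$dome_centre_z
  cap <- arc_profile(R, 0, cz, pi / 2 - ang_rim, pi / 2, res)
  prof <- rbind(c(0, -EMBED), c(a_rim, -EMBED), cap, c(0, h))
  # drop consecutive duplicates (arc start coincides with the skirt top)
  keep <- c(TRUE, rowSums(abs(diff(prof))) > 1e-9)
  dome <- revolve_mesh(prof[keep, , drop = FALSE],
                       segments_around(a_rim, res), name = "dome")
  parts <- list(plate, dome)
  if (params$wall_height > 0) {
    wall <- box_mesh(c(-W / 2, -L / 2, -EMBED),
                     c(d$wall_inner_x, L / 2, params$wall_height),
                     name = "wall")
    parts <- c(parts, list(wall))
  }
  m <- mesh_concat(parts, name = "tibial")
  stopifnot(mesh_min_face_area(m) > 1e-9)
  m
}

#' Generate the mobile-bearing mesh
#'
#' Biconcave disc in its own local frame: rim bottom plane at z = 0,
#' spherical inferior concavity of radius `dome_radius`, spherical superior
#' concavity of radius `femoral_sphere_radius`, outer cylindrical rim. This
#' is the "robot" the planner moves.
#'
#' @param params an [implant_params()].
#' @return a watertight [tri_mesh()] named `"bearing"`.
#' @export
make_bearing <- function(params = implant_params()) {
  stopifnot(inherits(params, "implant_params"))
  d <- implant_derived(params)
  res <- params$mesh_resolution
  r <- d$bearing_radius
  H <- d$rim_height
  if (params$bearing_min_thickness <= 0) {
    stop("parameter 'bearing_min_thickness' must be positive")
  }
  # inferior concavity: sphere radius R_inf centred on the axis below
  R_inf <- params$dome_radius
  c_inf <- -(R_inf - d$sag_inf)               # centre z, local frame
  ang_inf <- asin(r / R_inf)
  bot <- arc_profile(R_inf, 0, c_inf, pi / 2, pi / 2 - ang_inf, res)
  # superior concavity: sphere radius R_sup centred on the axis above
  R_sup <- params$femoral_sphere_radius
  c_sup <- H + (R_sup - d$sag_sup)
  ang_sup <- asin(r / R_sup)
  top <- arc_profile(R_sup, 0, c_sup, -pi / 2 + ang_sup, -pi / 2, res)
  n_rim <- max(2L, ceiling(H / res))
  rim <- cbind(r, seq(0, H, length.out = n_rim + 1L))
  prof <- rbind(bot, rim, top)
  keep <- c(TRUE, rowSums(abs(diff(prof))) > 1e-9)
  m <- revolve_mesh(prof[keep, , drop = FALSE], segments_around(r, res),
                    name = "bearing")
  stopifnot(mesh_min_face_area(m) > 1e-9)
  m
}

#' Generate the femoral component mesh
#'
#' Spherical condyle segment of radius `femoral_sphere_radius`, convex side
#' down, in a local frame with the sphere centre at the origin (lowest point
#' at `z = -femoral_sphere_radius`).
#'
#' @param params an [implant_params()].
#' @return a watertight [tri_mesh()] named `"femoral"`.
#' @export
make_femoral <- function(params = implant_params()) {
  stopifnot(inherits(params, "implant_params"))
  d <- implant_derived(params)
  res <- params$mesh_resolution
  R <- params$femoral_sphere_radius
  z_cut <- -R + d$fem_segment_height
  r_cut <- sqrt(R^2 - z_cut^2)
  ang_cut <- atan2(z_cut, r_cut)
  cap <- arc_profile(R, 0, 0, -pi / 2, ang_cut, res)
  prof <- rbind(cap, c(0, z_cut))
  keep <- c(TRUE, rowSums(abs(diff(prof))) > 1e-9)
  m <- revolve_mesh(prof[keep, , drop = FALSE], segments_around(r_cut, res),
                    name = "femoral")
  stopifnot(mesh_min_face_area(m) > 1e-9)
  m
}

# ------------------------------------------------------- oracle geometry

#' Analytic ball-over-wall oracle scene
#'
#' A test fixture with a closed-form answer: a spherical "bearing" of
#' diameter `ball_d` sits on a floor plate under a ceiling plate whose
#' underside is `gap0` above the floor; a wall of height `wall_h` blocks the
#' escape side (+x). The ceiling plays the femoral role and is lifted by the
#' vertical distraction. The ball escapes over the wall exactly when the
#' ceiling-to-wall gap admits it, so the extra distraction required is
#'
#'   `closed_form_dd = max(0, ball_d + wall_h - gap0)`.
#'
#' @param gap0 ceiling underside clearance above the floor at zero
#'   distraction (mm); `gap0 = ball_d` means the ceiling rests on the ball.
#' @param wall_h wall height above the floor (mm); 0 drops the wall.
#' @param ball_d ball diameter (mm).
#' @param mesh_resolution target edge length for the ball mesh (mm).
#' @return list with `environment` (floor, ceiling and, if `wall_h > 0`,
#'   wall meshes at zero distraction), `robot` (ball mesh, local frame
#'   centred at the origin), and `closed_form_dd` (mm).
#' @export
make_oracle_scene <- function(gap0, wall_h, ball_d, mesh_resolution = 0.8) {
  if (!is.numeric(gap0) || gap0 <= 0) stop("parameter 'gap0' must be positive")
  if (!is.numeric(wall_h) || wall_h < 0) stop("parameter 'wall_h' must be >= 0")
  if (!is.numeric(ball_d) || ball_d <= 0) stop("parameter 'ball_d' must be positive")
  dd <- max(0, ball_d + wall_h - gap0)
  dims <- oracle_dims(gap0, wall_h, ball_d)
  env <- oracle_environment(dims, v = 0)
  r <- ball_d / 2
  prof <- arc_profile(r, 0, 0, -pi / 2, pi / 2, mesh_resolution)
  ball <- revolve_mesh(prof, segments_around(r, mesh_resolution), name = "ball")
  list(environment = env, robot = ball, closed_form_dd = dd, dims = dims)
}

oracle_dims <- function(gap0, wall_h, ball_d) {
  list(gap0 = gap0, wall_h = wall_h, ball_d = ball_d,
       x_min = -2.5 * ball_d, x_wall = 1.25 * ball_d, wall_t = 1,
       x_max = 1.25 * ball_d + 1 + 2.5 * ball_d, y_half = 1.5 * ball_d)
}

oracle_environment <- function(dims, v) {
  floor <- box_mesh(c(dims$x_min, -dims$y_half, -1),
                    c(dims$x_wall + dims$wall_t, dims$y_half, 0),
                    name = "floor")
  ceiling <- box_mesh(c(dims$x_min, -dims$y_half, dims$gap0 + v),
                      c(dims$x_max, dims$y_half, dims$gap0 + v + 1),
                      name = "ceiling")
  env <- list(floor, ceiling)
  if (dims$wall_h > 0) {
    wall <- box_mesh(c(dims$x_wall, -dims$y_half, -EMBED),
                     c(dims$x_wall + dims$wall_t, dims$y_half, dims$wall_h),
                     name = "wall")
    env <- c(env, list(wall))
  }
  env
}
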