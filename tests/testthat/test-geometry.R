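params_coarse <- implant_params(mesh_resolution = 2.5)

test_that("generated implant components are closed watertight meshes", {
  for (maker in list(make_tibial, make_bearing, make_femoral)) {
    m <- maker(params_coarse)
    expect_true(is_watertight(m))
    expect_equal(mesh_boundary_edges(m), 0)
    expect_gt(bearingrrt:::mesh_min_face_area(m), 1e-9)
  }
})

test_that("tibial bounds follow the plateau and the tallest feature", {
  p <- params_coarse
  m <- make_tibial(p)
  b <- unname(rbind(apply(m$vertices, 2, min), apply(m$vertices, 2, max)))
  expect_equal(b[2, 1] - b[1, 1], p$plateau_width_ML, tolerance = 1e-9)
  expect_equal(b[2, 2] - b[1, 2], p$plateau_length_AP, tolerance = 1e-9)
  expect_equal(b[2, 3], max(p$wall_height, p$dome_apex_height), tolerance = 1e-9)
  expect_lt(b[1, 3], 0)
})

test_that("a zero wall height drops the wall to the plateau surface", {
  p <- implant_params(wall_height = 0, mesh_resolution = 2.5)
  m <- make_tibial(p)
  # medial-edge strip, away from the dome footprint
  strip <- m$vertices[m$vertices[, 1] < bearingrrt:::implant_derived(p)$wall_inner_x, ]
  expect_equal(max(strip[, 3]), 0, tolerance = 1e-9)
})

test_that("tibial mesh is mirror-symmetric about the AP midplane", {
  m <- make_tibial(params_coarse)
  v <- m$vertices
  mirrored <- v
  mirrored[, 2] <- -mirrored[, 2]
  key <- function(x) sort(paste(round(x[, 1], 6), round(x[, 2], 6),
                                round(x[, 3], 6)))
  expect_identical(key(v), key(mirrored))
})

test_that("bearing volume matches the cylinder-minus-caps closed form", {
  p <- params_coarse
  d <- bearingrrt:::implant_derived(p)
  cap_vol <- function(R, h) pi * h^2 * (3 * R - h) / 3
  analytic <- pi * d$bearing_radius^2 * d$rim_height -
    cap_vol(p$dome_radius, d$sag_inf) -
    cap_vol(p$femoral_sphere_radius, d$sag_sup)
  m <- make_bearing(p)
  expect_lt(abs(mesh_volume(m) - analytic) / analytic, 0.02)
})

test_that("bearing centre of mass lies on the symmetry axis", {
  cm <- mesh_centroid(make_bearing(params_coarse))
  expect_equal(cm[1], 0, tolerance = 1e-9)
  expect_equal(cm[2], 0, tolerance = 1e-9)
})

test_that("femoral lowest point touches the seated bearing top at rest", {
  p <- params_coarse
  d <- bearingrrt:::implant_derived(p)
  fem <- mesh_translate(make_femoral(p), c(0, 0, d$fem_centre_z))
  bear <- mesh_translate(make_bearing(p), c(0, 0, d$seat_z))
  fem_low <- min(fem$vertices[, 3])
  # bearing top surface at the axis (its deepest superior point)
  bear_axis_top <- max(bear$vertices[abs(bear$vertices[, 1]) < 1e-9 &
                                       abs(bear$vertices[, 2]) < 1e-9, 3])
  expect_equal(fem_low, bear_axis_top, tolerance = 1e-9)
})

test_that("halving the target edge length halves typical edge lengths", {
  p1 <- implant_params(mesh_resolution = 3)
  p2 <- implant_params(mesh_resolution = 1.5)
  e1 <- stats::median(mesh_edge_lengths(make_bearing(p1)))
  e2 <- stats::median(mesh_edge_lengths(make_bearing(p2)))
  expect_lt(abs(e1 / e2 - 2) / 2, 0.25)
})

test_that("invalid parameters are rejected naming the offending field", {
  expect_error(implant_params(dome_radius = -1), "dome_radius")
  expect_error(implant_params(bearing_min_thickness = 0),
               "bearing_min_thickness")
  expect_error(implant_params(bearing_outer_diameter = 60),
               "bearing_outer_diameter")
  expect_error(implant_params(wall_height = -0.1), "wall_height")
  expect_silent(implant_params(wall_height = 0))
})

test_that("oracle closed form matches its stated cases", {
  expect_equal(make_oracle_scene(4, 2, 4)$closed_form_dd, 2)
  expect_equal(make_oracle_scene(7, 2, 4)$closed_form_dd, 0)   # gap0 >= d + h
  expect_equal(make_oracle_scene(4, 0, 4)$closed_form_dd, 0)   # no wall
  expect_equal(make_oracle_scene(5, 2.5, 4)$closed_form_dd, 1.5)
  expect_error(make_oracle_scene(-1, 2, 4), "gap0")
  expect_error(make_oracle_scene(4, 2, 0), "ball_d")
})

test_that("oracle closed form agrees with a dense collision-grid sweep", {
  # brute-force oracle: for each distraction, flood-fill a translation grid
  # of collision-free ball centres; the escape exists iff start connects to
  # the far side of the wall
  gap0 <- 4; wall_h <- 2; ball_d <- 4
  src <- oracle_scene_source(gap0, wall_h, ball_d)
  escape_possible <- function(v) {
    sc <- src("lateral", configuration(0, v))
    w <- bearingrrt:::scene_world(sc)
    xs <- seq(0, sc$bbox[2, 1], by = 0.5)
    zs <- seq(ball_d / 2, sc$bbox[2, 3] + 0.26, by = 0.25)
    free <- outer(seq_along(xs), seq_along(zs), Vectorize(function(i, j) {
      !in_collision(w, pose(t = c(xs[i], 0, zs[j])))
    }))
    # BFS from the (corrected) start column to beyond the wall
    visited <- matrix(FALSE, nrow(free), ncol(free))
    q <- which(free[1, ])[1]
    if (is.na(q)) return(FALSE)
    frontier <- list(c(1L, q))
    visited[1, q] <- TRUE
    while (length(frontier) > 0) {
      cur <- frontier[[1]]; frontier <- frontier[-1]
      if (xs[cur[1]] > 1.25 * ball_d + 1) return(TRUE)
      for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        nb <- cur + d
        if (all(nb >= 1L) && nb[1] <= nrow(free) && nb[2] <= ncol(free) &&
            !visited[nb[1], nb[2]] && free[nb[1], nb[2]]) {
          visited[nb[1], nb[2]] <- TRUE
          frontier[[length(frontier) + 1L]] <- nb
        }
      }
    }
    FALSE
  }
  closed <- max(0, ball_d + wall_h - gap0)
  expect_false(escape_possible(closed - 0.5))
  expect_true(escape_possible(closed + 0.5))
})
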