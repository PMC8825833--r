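params_test <- implant_params(mesh_resolution = 3)

test_that("scene construction is deterministic", {
  a <- build_scene("medial", configuration(1.5, 2), params_test)
  b <- build_scene("medial", configuration(1.5, 2), params_test)
  for (f in c("environment", "robot", "bbox", "goal")) {
    expect_identical(a[[f]], b[[f]])
  }
  expect_identical(a$start$t, b$start$t)
})

test_that("anterior/posterior scenes gain the lateral wall", {
  cfg <- configuration(0, 2)
  expect_length(build_scene("medial", cfg, params_test)$environment, 2L)
  expect_length(build_scene("lateral", cfg, params_test)$environment, 2L)
  expect_length(build_scene("anterior", cfg, params_test)$environment, 3L)
  expect_length(build_scene("posterior", cfg, params_test)$environment, 3L)
  expect_error(build_scene("sideways", cfg, params_test), "unknown direction")
})

test_that("the goal region lies inside the bounding box, outside the implant", {
  for (dir in c("medial", "lateral", "anterior", "posterior")) {
    sc <- build_scene(dir, configuration(2, 3), params_test)
    expect_true(all(sc$goal[1, ] >= sc$bbox[1, ] - 1e-9))
    expect_true(all(sc$goal[2, ] <= sc$bbox[2, ] + 1e-9))
    expect_false(in_goal(sc, sc$start))
  }
  # medial goal sits strictly medial of the wall's outer face
  sc <- build_scene("medial", configuration(0, 0), params_test)
  expect_lt(sc$goal[2, 1], -params_test$plateau_width_ML / 2)
})

test_that("ML translation shifts the femoral component rigidly", {
  s0 <- build_scene("medial", configuration(0, 0), params_test)
  s2 <- build_scene("medial", configuration(2, 0), params_test)
  c0 <- mesh_centroid(s0$environment[[2]])
  c2 <- mesh_centroid(s2$environment[[2]])
  expect_equal(c2 - c0, c(2, 0, 0), tolerance = 1e-9)
  # and the distraction lifts it vertically
  s2v <- build_scene("medial", configuration(2, 1.25), params_test)
  expect_equal(mesh_centroid(s2v$environment[[2]]) - c2, c(0, 0, 1.25),
               tolerance = 1e-9)
})

test_that("a collision-free nominal start is returned unchanged", {
  sc <- fixture_free_scene()
  st <- find_valid_start(sc)
  expect_identical(st$t, sc$start$t)
})

test_that("start correction lifts by the analytic overlap, in one lift step", {
  # seat the bearing congruently, then sink it 0.05 mm into the dome
  sc <- build_scene("medial", configuration(0, 4), params_test)
  seated <- find_valid_start(sc)
  expect_false(is.null(seated))
  sunk <- sc
  sunk$start <- pose(t = seated$t - c(0, 0, 0.05), q = seated$q)
  lifted <- find_valid_start(sunk, lift_step = 0.01)
  lift <- lifted$t[3] - sunk$start$t[3]
  expect_gte(lift, 0.05 - 1e-9)
  expect_lte(lift, 0.06 + 1e-9)
})

test_that("start correction gives up beyond max_correction", {
  sc <- build_scene("medial", configuration(0, 4), params_test)
  sunk <- sc
  sunk$start <- pose(t = sc$start$t - c(0, 0, 2), q = sc$start$q)
  expect_null(find_valid_start(sunk, max_correction = 0.5))
})

test_that("start correction finds the minimal lift on the step grid", {
  sc <- build_scene("medial", configuration(3, 4), params_test)
  st <- find_valid_start(sc, lift_step = 0.02)
  expect_false(is.null(st))
  w <- bearingrrt:::scene_world(sc)
  # independent fine scan: every coarser-grid lift below the returned one
  # must collide
  lift <- st$t[3] - sc$start$t[3]
  ks <- seq(0, lift - 0.02 + 1e-12, by = 0.02)
  for (k in ks) {
    expect_true(in_collision(w, pose(t = sc$start$t + c(0, 0, k))))
  }
  expect_false(in_collision(w, st))
})

test_that("goal membership uses the volume centroid with inclusive bounds", {
  sc <- fixture_free_scene()
  ctr <- 0.5 * (sc$goal[1, ] + sc$goal[2, ])
  expect_true(in_goal(sc, pose(t = ctr)))
  on_face <- ctr
  on_face[1] <- sc$goal[1, 1]
  expect_true(in_goal(sc, pose(t = on_face)))            # boundary inclusive
  expect_false(in_goal(sc, pose(t = on_face - c(1e-6, 0, 0))))
})

test_that("every direction starts outside its goal at zero distraction", {
  for (dir in c("medial", "lateral", "anterior", "posterior")) {
    sc <- build_scene(dir, configuration(0, 0), params_test)
    expect_false(in_goal(sc, sc$start))
  }
})
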