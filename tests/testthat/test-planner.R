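test_that("planner settings enforce their invariants", {
  expect_error(planner_settings(), "exactly one")
  expect_error(planner_settings(max_iterations = 10, max_seconds = 1),
               "exactly one")
  expect_error(planner_settings(max_iterations = 10, goal_bias = 1),
               "goal_bias")
  expect_error(planner_settings(max_iterations = 10, attempts = 0),
               "attempts")
  expect_error(planner_settings(max_iterations = 10, step_length = 0),
               "step_length")
  s <- planner_settings(max_iterations = 10)
  expect_s3_class(s, "planner_settings")
})

test_that("reference budget presets carry the two schedules", {
  pr <- planner_preset("smart-search")
  expect_equal(pr$initial$max_seconds, 180)
  expect_equal(pr$initial$attempts, 10L)
  expect_equal(pr$extended$max_seconds, 270)
  expect_equal(pr$extended$attempts, 25L)
  pr <- planner_preset("testing")
  expect_equal(pr$initial$max_seconds, 270)
  expect_equal(pr$initial$attempts, 10L)
  expect_equal(pr$extended$max_seconds, 405)
  expect_equal(pr$extended$attempts, 25L)
})

test_that("a start already in the goal yields a single-pose path", {
  sc <- fixture_free_scene()
  sc$start <- pose(t = c(12, 0, 0))
  r <- rrt_once(sc, fixture_settings(), seed = 1)
  expect_identical(r$status, "dislocated")
  expect_length(r$path, 1L)
  expect_true(validate_path(sc, r$path, 0.1))
})

test_that("a colliding start reports invalid_start", {
  sc <- fixture_free_scene(environment = list(fixture_ball(1)))
  r <- rrt_once(sc, fixture_settings(), seed = 1)
  expect_identical(r$status, "invalid_start")
  expect_null(r$path)
})

test_that("open space is reached and the path re-validates", {
  sc <- fixture_free_scene()
  r <- plan_with_attempts(sc, fixture_settings(iters = 3000, attempts = 2))
  expect_identical(r$status, "dislocated")
  expect_true(validate_path(sc, r$path, 0.1))
  expect_true(in_goal(sc, r$path[[length(r$path)]]))
})

test_that("a sealed room admits no path and uses every attempt", {
  sc <- fixture_sealed_scene()
  s <- fixture_settings(iters = 400, attempts = 3)
  r <- plan_with_attempts(sc, s)
  expect_identical(r$status, "no_path_within_budget")
  expect_identical(r$attempts_used, 3L)
  expect_identical(r$samples_drawn, 1200L)
})

test_that("iteration-budget planning is deterministic in the master seed", {
  sc <- fixture_free_scene(environment = list(fixture_slab(c(4, -3, -8), c(5, 8, 8))))
  s <- fixture_settings(iters = 1500, attempts = 2, seed = 42)
  r1 <- plan_with_attempts(sc, s)
  r2 <- plan_with_attempts(sc, s)
  expect_identical(r1$status, r2$status)
  expect_identical(r1$samples_drawn, r2$samples_drawn)
  expect_identical(lapply(r1$path, `[[`, "t"), lapply(r2$path, `[[`, "t"))
  # a different seed explores differently
  s2 <- fixture_settings(iters = 1500, attempts = 2, seed = 43)
  r3 <- plan_with_attempts(sc, s2)
  expect_false(identical(r1$samples_drawn, r3$samples_drawn) &&
                 identical(lapply(r1$path, `[[`, "t"),
                           lapply(r3$path, `[[`, "t")))
})

test_that("every stored tree node hangs off the root", {
  sc <- fixture_free_scene()
  r <- rrt_once(sc, fixture_settings(iters = 800), seed = 3)
  par <- r$parents
  expect_identical(par[1], 0L)                      # root
  if (length(par) > 1) {
    idx <- seq_along(par)[-1]
    expect_true(all(par[idx] >= 1L & par[idx] < idx))  # parents precede
  }
})

test_that("corrupting a valid path breaks re-validation", {
  sc <- fixture_free_scene(environment = list(fixture_slab(c(20, -1, -1), c(21, 1, 1))))
  r <- plan_with_attempts(sc, fixture_settings(iters = 3000, attempts = 2))
  expect_identical(r$status, "dislocated")
  expect_true(validate_path(sc, r$path, 0.1))
  # waypoint moved into the obstacle
  bad <- r$path
  bad[[max(2L, length(bad) - 1L)]] <- pose(t = c(20.5, 0, 0))
  expect_false(validate_path(sc, bad, 0.1))
  # final pose pulled out of the goal
  bad2 <- r$path
  bad2[[length(bad2)]] <- pose(t = c(5, 0, 0))
  expect_false(validate_path(sc, bad2, 0.1))
  # path that does not start at the scene start
  bad3 <- r$path
  bad3[[1]] <- pose(t = sc$start$t + c(0.5, 0, 0))
  expect_false(validate_path(sc, bad3, 0.1))
})

test_that("success rate is monotone in the iteration budget", {
  src <- oracle_scene_source(5, 1.5, 4)      # closed-form DD = 0.5
  sc <- src("lateral", configuration(0, 1))  # narrow-ish but solvable
  st <- find_valid_start(sc)
  sc$start <- st
  rate <- function(iters) {
    ok <- 0L
    for (seed in 1:20) {
      r <- rrt_once(sc, fixture_settings(iters = iters), seed = seed)
      if (r$status == "dislocated") ok <- ok + 1L
    }
    ok / 20
  }
  r_small <- rate(60)
  r_large <- rate(240)
  expect_gte(r_large, r_small)
  expect_gt(r_large, 0.5)
})

test_that("planned paths round-trip through JSON export", {
  path <- list(pose(t = c(1, 2, 3)), pose(t = c(4, 5, 6),
                                          q = c(cos(0.3), 0, sin(0.3), 0)))
  f <- withr::local_tempfile(fileext = ".json")
  write_path_json(path, f)
  back <- read_path_json(f)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_equal(back[[i]]$t, path[[i]]$t, tolerance = 1e-12)
    expect_equal(back[[i]]$q, path[[i]]$q, tolerance = 1e-12)
  }
})
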