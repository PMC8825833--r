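test_that("grid enumeration is inclusive, row-major, and counts correctly", {
  g <- enumerate_grid(grid_spec())
  expect_identical(nrow(g), 825L)
  g33 <- enumerate_grid(grid_spec(ml_min = 2, ml_max = 2, ml_step = 0.25))
  expect_identical(nrow(g33), 33L)
  g1 <- enumerate_grid(grid_spec(v_min = 1, v_max = 1, v_step = 0.5,
                                 ml_min = 2, ml_max = 2, ml_step = 0.5))
  expect_identical(nrow(g1), 1L)
  # row-major: ml ascending, v ascending within ml; both endpoints included
  expect_equal(g$ml_mm[1], 0)
  expect_equal(g$v_mm[1:2], c(0, 0.25))
  expect_equal(g$v_mm[33], 8)
  expect_equal(g$ml_mm[nrow(g)], 6)
  expect_error(grid_spec(v_step = 0), "positive")
  expect_error(grid_spec(v_min = 2, v_max = 1), "non-empty")
})

oracle_sweep_settings <- function(seed = 1) {
  list(initial = planner_settings(collision_resolution = 0.1,
                                  max_iterations = 1200L, attempts = 3L,
                                  seed = seed),
       extended = planner_settings(collision_resolution = 0.1,
                                   max_iterations = 3000L, attempts = 6L,
                                   seed = seed))
}

test_that("sweeping the analytic oracle recovers its closed-form DD", {
  src <- oracle_scene_source(4, 1, 4)        # closed form 1
  s <- oracle_sweep_settings()
  res <- smart_sweep("lateral", grid_spec(v_max = 4, v_step = 0.25,
                                          ml_max = 2, ml_step = 2),
                     s$initial, s$extended, scene_source = src, seed = 5)
  closed <- attr(src, "closed_form_dd")
  expect_true(all(abs(res$dd$dd_mm - closed) <= 0.25 + 1e-9))
})

test_that("an unobstructed scene dislocates at the minimum distraction", {
  src <- oracle_scene_source(7, 0, 4)        # closed form 0, no wall
  s <- oracle_sweep_settings()
  res <- smart_sweep("lateral", grid_spec(v_max = 1, v_step = 0.5,
                                          ml_max = 0, ml_step = 1),
                     s$initial, s$extended, scene_source = src, seed = 2)
  expect_equal(res$dd$dd_mm, 0)
  expect_true(all(res$outcomes$outcome == "dislocated"))
})

test_that("an impossible scene reports no dislocation in range", {
  src <- oracle_scene_source(4, 30, 4)       # wall far above the range
  s <- oracle_sweep_settings()
  res <- smart_sweep("lateral", grid_spec(v_max = 1.5, v_step = 0.5,
                                          ml_max = 0, ml_step = 1),
                     s$initial, s$extended, scene_source = src, seed = 3)
  expect_true(is.na(res$dd$dd_mm))
  # only the top level is searched; the rest is skipped
  expect_identical(res$outcomes$outcome[res$outcomes$v_mm == 1.5],
                   "no_dislocation")
  expect_setequal(res$outcomes$outcome[res$outcomes$v_mm < 1.5], "skipped")
})

test_that("the sweep record is monotone: nothing above a DD failed", {
  src <- oracle_scene_source(4, 1, 4)
  s <- oracle_sweep_settings()
  res <- smart_sweep("lateral", grid_spec(v_max = 3, v_step = 0.25,
                                          ml_max = 2, ml_step = 2),
                     s$initial, s$extended, scene_source = src, seed = 5)
  for (i in seq_len(nrow(res$dd))) {
    dd <- res$dd$dd_mm[i]
    if (is.na(dd)) next
    above <- res$outcomes[res$outcomes$ml_mm == res$dd$ml_mm[i] &
                            res$outcomes$v_mm >= dd, ]
    expect_true(all(above$outcome %in% c("dislocated", "skipped")))
  }
})

test_that("early exit never plans more than the brute-force full grid", {
  # gap0 > ball_d so the bottom level has a valid start and must be planned
  src <- oracle_scene_source(5, 2, 4)
  spec <- grid_spec(v_max = 2, v_step = 0.5, ml_max = 2, ml_step = 2)
  s <- oracle_sweep_settings()
  smart <- smart_sweep("lateral", spec, s$initial, s$extended,
                       scene_source = src, seed = 5, early_exit = TRUE)
  brute <- smart_sweep("lateral", spec, s$initial, s$extended,
                       scene_source = src, seed = 5, early_exit = FALSE)
  # the scene has non-dislocating configurations, so the smart sweep must
  # save planner invocations, and both must agree on the DD
  expect_gt(sum(smart$outcomes$outcome == "no_dislocation"), 0)
  expect_lt(smart$counts$planner_calls, brute$counts$planner_calls)
  expect_equal(smart$dd$dd_mm, brute$dd$dd_mm)
})

test_that("a fixed master seed reproduces the sweep exactly", {
  src <- oracle_scene_source(4, 1, 4)
  spec <- grid_spec(v_max = 2, v_step = 1, ml_max = 0, ml_step = 1)
  s <- oracle_sweep_settings()
  r1 <- smart_sweep("lateral", spec, s$initial, s$extended,
                    scene_source = src, seed = 9)
  r2 <- smart_sweep("lateral", spec, s$initial, s$extended,
                    scene_source = src, seed = 9)
  expect_identical(r1$outcomes, r2$outcomes)
  expect_identical(r1$dd, r2$dd)
})

test_that("theoretical testing-time arithmetic reproduces its definition", {
  expect_equal(theoretical_max_time(825, 405, 25), 8353125)
  expect_equal(theoretical_max_time(0, 405, 25), 0)
  expect_equal(optimised_max_time(410, 25, 180, 10, 405, 25), 946125)
  expect_equal(optimised_max_time(25, 25, 180, 10, 405, 25), 25 * 405 * 25)
})

test_that("sweep CSVs round-trip through the writers and readers", {
  src <- oracle_scene_source(4, 1, 4)
  s <- oracle_sweep_settings()
  res <- smart_sweep("lateral", grid_spec(v_max = 2, v_step = 1,
                                          ml_max = 0, ml_step = 1),
                     s$initial, s$extended, scene_source = src, seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_sweep_csv(res, dir)
  expect_true(all(file.exists(paths)))
  summ <- read_sweep_summary(paths["summary"])
  expect_equal(summ$dd_mm, res$dd$dd_mm)
  detail <- utils::read.csv(paths["detail"])
  expect_identical(nrow(detail), nrow(res$outcomes))
  expect_error(read_sweep_summary(paths["detail"]), "lacks column")
})
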