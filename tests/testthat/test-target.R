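test_that("default task yields 840 samples with a 1 s static head", {
  tgt <- generate_target_trajectory(task_config(seed = 7))
  expect_equal(n_samples(tgt), 840)
  expect_true(all(tgt$x[1:60] == tgt$x[1]))
  expect_true(all(tgt$y[1:60] == tgt$y[1]))
  # both stop stages are static too
  st <- attr(tgt, "stages")
  for (s in c(3, 5)) {
    idx <- st$first[s]:st$last[s]
    expect_equal(diff(tgt$x[idx]), rep(0, length(idx) - 1))
    expect_equal(diff(tgt$y[idx]), rep(0, length(idx) - 1))
  }
})

test_that("motion stages advance at constant speed except at bounces", {
  for (seed in c(1, 7, 23)) {
    tgt <- generate_target_trajectory(task_config(seed = seed))
    d <- sqrt(diff(tgt$x)^2 + diff(tgt$y)^2)
    moving <- d > 0
    bounce_steps <- unique(c(attr(tgt, "bounces") - 1L, attr(tgt, "bounces")))
    plain <- setdiff(which(moving), bounce_steps)
    expect_true(all(abs(d[plain] - 250 / 60) < 1e-9))
    # bounds: never exits the screen
    expect_true(all(tgt$x >= 0 & tgt$x <= 1365 & tgt$y >= 0 & tgt$y <= 767))
  }
})

test_that("motion resumes in the same direction after the mid-task stop", {
  tgt <- generate_target_trajectory(task_config(seed = 5))
  st <- attr(tgt, "stages")
  b <- attr(tgt, "bounces")
  # last step of stage 2 not at a bounce, first step of stage 4 not at a bounce
  last2 <- c(tgt$x[st$last[2]] - tgt$x[st$last[2] - 1],
             tgt$y[st$last[2]] - tgt$y[st$last[2] - 1])
  first4 <- c(tgt$x[st$first[4]] - tgt$x[st$first[4] - 1],
              tgt$y[st$first[4]] - tgt$y[st$first[4] - 1])
  if (!any(b %in% c(st$last[2], st$first[4]))) {
    expect_equal(atan2(last2[2], last2[1]), atan2(first4[2], first4[1]),
                 tolerance = 1e-12)
  }
})

test_that("trajectories are reproducible for identical seeds and differ across seeds", {
  a <- generate_target_trajectory(task_config(seed = 99))
  b <- generate_target_trajectory(task_config(seed = 99))
  c_ <- generate_target_trajectory(task_config(seed = 100))
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_identical(attr(a, "bounces"), attr(b, "bounces"))
  expect_false(identical(a$x, c_$x))
})

test_that("reflect_step mirrors overshoot, preserves speed, and agrees with fine sub-stepping", {
  bounds <- c(0, 1365, 0, 767)
  # exiting by delta re-enters by delta with mirrored direction
  r <- reflect_step(c(10, 100), c(-20, 0), bounds)
  expect_equal(r$pos, c(10, 100))
  expect_equal(r$step, c(20, 0))
  expect_true(r$bounced)
  # step parallel to an edge, no crossing: unchanged
  r2 <- reflect_step(c(10, 0), c(5, 0), bounds)
  expect_equal(r2$pos, c(15, 0))
  expect_equal(r2$step, c(5, 0))
  expect_false(r2$bounced)
  # corner exit mirrors both components
  r3 <- reflect_step(c(2, 2), c(-5, -6), bounds)
  expect_equal(r3$pos, c(3, 4))
  expect_equal(r3$step, c(5, 6))

  # sub-stepping oracle: 1000 micro-steps with per-wall mirroring
  substep_oracle <- function(pos, step, bounds, k = 1000) {
    s <- step / k
    for (i in seq_len(k)) {
      p <- pos + s
      if (p[1] < bounds[1]) { p[1] <- 2 * bounds[1] - p[1]; s[1] <- -s[1] }
      if (p[1] > bounds[2]) { p[1] <- 2 * bounds[2] - p[1]; s[1] <- -s[1] }
      if (p[2] < bounds[3]) { p[2] <- 2 * bounds[3] - p[2]; s[2] <- -s[2] }
      if (p[2] > bounds[4]) { p[2] <- 2 * bounds[4] - p[2]; s[2] <- -s[2] }
      pos <- p
    }
    pos
  }
  set.seed(3)
  for (rep in 1:25) {
    pos <- c(runif(1, 0, 1365), runif(1, 0, 767))
    step <- runif(2, -60, 60)
    expect_equal(reflect_step(pos, step, bounds)$pos,
                 substep_oracle(pos, step, bounds), tolerance = 1e-6)
  }
  expect_error(reflect_step(c(5, 5), c(2000, 1000), bounds), "nonphysical")
  expect_error(reflect_step(c(-1, 5), c(1, 1), bounds), "inside")
})

test_that("bounce detection matches the generator log and handles simple shapes", {
  hits <- 0L
  for (seed in 1:10) {
    tgt <- generate_target_trajectory(task_config(seed = seed))
    expect_identical(find_bounce_points(tgt), attr(tgt, "bounces"))
    hits <- hits + length(attr(tgt, "bounces"))
  }
  expect_gt(hits, 0)  # the seeds exercise at least one edge hit
  # straight line: no bounces
  straight <- trajectory(seq(0, 99), seq(0, 99))
  expect_length(find_bounce_points(straight), 0)
  # triangle wave in x: one index per apex
  xs <- c(0:10, 9:0, 1:10)
  tri <- trajectory(xs, seq_along(xs))
  expect_identical(find_bounce_points(tri), c(11L, 21L))
})

test_that("straight segments partition the motion stages at bounces", {
  tgt <- generate_target_trajectory(task_config(seed = 7))
  segs <- straight_segments(tgt)
  st <- attr(tgt, "stages")
  expect_true(all(segs$first >= st$first[2]))
  expect_equal(nrow(segs), 2 + length(attr(tgt, "bounces")))
  # each target segment is exactly collinear: zero regression index vs itself
  r <- regression_direction_index(tgt, tgt, segs)
  expect_equal(r$delta_theta_regr, 0)
  expect_equal(r$n_segments, nrow(segs))
})

test_that("task config validates its inputs", {
  expect_error(task_config(speed_px_s = 0), "positive")
  expect_error(task_config(start_position = c(-5, 10)), "outside")
})
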