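test_that("lattice ball cardinalities match brute-force enumeration", {
  expect_identical(gauss_disk_cardinality(0), 1L)
  expect_identical(gauss_disk_cardinality(1), 5L)
  expect_identical(gauss_disk_cardinality(2), 13L)  # x^2 + y^2 <= 4
  set.seed(1)
  for (r in c(0.5, 1.7, 3, 7.9, 22.03)) {
    expect_identical(gauss_disk_cardinality(r),
                     brute_disk_intersection(c(0, 0), r, c(0, 0), r))
    # translation invariance of the count
    c0 <- c(sample(-50:50, 1), sample(-50:50, 1))
    expect_identical(brute_disk_intersection(c0, r, c0, r),
                     gauss_disk_cardinality(r))
  }
  expect_error(gauss_disk_cardinality(-1), "non-negative")
})

test_that("disk intersection counts agree with the lattice-scan oracle and are symmetric", {
  # nesting and disjointness
  expect_identical(disk_intersection_cardinality(c(0, 0), 5, c(0, 0), 2),
                   gauss_disk_cardinality(2))
  expect_identical(disk_intersection_cardinality(c(0, 0), 2, c(10, 0), 2), 0L)
  expect_identical(disk_intersection_cardinality(c(0, 0), 2, c(2, 0), 2),
                   brute_disk_intersection(c(0, 0), 2, c(2, 0), 2))
  set.seed(7)
  for (i in 1:30) {
    c1 <- c(sample(-10:10, 1), sample(-10:10, 1))
    c2 <- c(sample(-10:10, 1), sample(-10:10, 1))
    r1 <- runif(1, 0, 8); r2 <- runif(1, 0, 8)
    v <- disk_intersection_cardinality(c1, r1, c2, r2)
    expect_identical(v, brute_disk_intersection(c1, r1, c2, r2))
    expect_identical(v, disk_intersection_cardinality(c2, r2, c1, r1))
  }
})

test_that("colocality agrees with the brute-force lattice oracle on random cases", {
  geom <- screen_geometry()
  set.seed(42)
  # single-frame and 10-frame random cases, radii in pixels via ad-hoc geometry
  for (i in 1:50) {
    n <- sample(c(1, 10), 1)
    tx <- runif(n, 0, 100); ty <- runif(n, 0, 100)
    gx <- tx + rnorm(n, sd = 8); gy <- ty + rnorm(n, sd = 8)
    r1_mm <- runif(1, 0.5, 3); r2_mm <- runif(1, 0.3, 2)
    p <- colocality_params(r1_mm, r2_mm, geom)
    expect_equal(colocality(trajectory(tx, ty), trajectory(gx, gy), p),
                 brute_colocality(tx, ty, gx, gy, p$r1_px, p$r2_px),
                 tolerance = 1e-12)
  }
})

test_that("colocality hits its boundary values and monotonicity in r1", {
  tgt <- generate_target_trajectory(task_config(seed = 3))
  expect_equal(colocality(tgt, tgt, colocality_params(5, 2)), 1)
  # gaze displaced far beyond r1 + r2 everywhere: zero overlap
  far <- trajectory(tgt$x + 200, tgt$y, rate_hz = tgt$rate_hz)
  expect_equal(colocality(tgt, far, colocality_params(5, 2)), 0)
  # single-frame pair at lattice distance 2 with r1 = r2 = 2 px
  geom1 <- screen_geometry(diagonal_mm = sqrt(1366^2 + 768^2))  # 1 mm = 1 px
  p22 <- colocality_params(2, 2, geom1)
  expect_equal(colocality(trajectory(0, 0), trajectory(2, 0), p22),
               brute_disk_intersection(c(0, 0), 2, c(2, 0), 2) / 13)
  # monotone non-decreasing in r1
  gz <- simulate_gaze(tgt, impaired_profile(), seed = 9)
  cos_r1 <- vapply(c(5, 10, 15), function(r1)
    colocality(tgt, gz, colocality_params(r1, 2)), numeric(1))
  expect_true(all(diff(cos_r1) >= 0))
  expect_error(colocality(tgt, trajectory(1, 1)), "lengths differ")
})

test_that("colocality is invariant under joint translation and lattice rotation", {
  set.seed(5)
  tx <- runif(30, 0, 200); ty <- runif(30, 0, 200)
  gx <- tx + rnorm(30, sd = 10); gy <- ty + rnorm(30, sd = 10)
  p <- colocality_params(5, 2)
  base <- colocality(trajectory(tx, ty), trajectory(gx, gy), p)
  shift <- colocality(trajectory(tx + 37, ty - 12), trajectory(gx + 37, gy - 12), p)
  expect_equal(shift, base, tolerance = 1e-12)
  # 90 degree rotation of the lattice: (x, y) -> (-y, x)
  rot <- colocality(trajectory(-ty, tx), trajectory(-gy, gx), p)
  expect_equal(rot, base, tolerance = 1e-12)
})

test_that("step angles use atan2 and mask zero displacements", {
  tr <- trajectory(c(0, 1, 1, 1, 0), c(0, 0, 1, 1, 0))
  a <- step_angles(tr)
  expect_equal(a$theta[1], 0)
  expect_equal(a$theta[2], pi / 2)
  expect_false(a$moving[3])
  expect_true(is.na(a$theta[3]))
  expect_equal(a$theta[4], atan2(-1, -1))
})

test_that("sample direction index: coherence limits and uniform-scatter behaviour", {
  pair <- make_tracked_pair(seed_target = 1)
  expect_equal(sample_direction_index(pair$target, pair$target), 0)
  # constant angular offset: still perfectly coherent
  tgt <- pair$target
  rot <- 0.7
  gx <- tgt$x * cos(rot) - tgt$y * sin(rot)
  gy <- tgt$x * sin(rot) + tgt$y * cos(rot)
  expect_equal(sample_direction_index(tgt, trajectory(gx, gy)), 0,
               tolerance = 1e-12)
  # i.i.d. uniform angle differences at M = 10000: index is 1 within ~0.02
  # (resultant length is Rayleigh-ish with mean ~ sqrt(pi / (4 M)) ~ 0.0089)
  set.seed(8)
  m <- 10001
  th_o <- runif(m, -pi, pi)
  walk <- function(th) trajectory(cumsum(c(0, cos(th))), cumsum(c(0, sin(th))))
  expect_equal(sample_direction_index(walk(th_o), walk(runif(m, -pi, pi))), 1,
               tolerance = 0.02)
  # degenerate: no jointly moving steps
  still <- trajectory(rep(0, 10), rep(0, 10))
  expect_error(sample_direction_index(still, still), "direction index undefined")
})

test_that("regression direction index recovers constructed orientations", {
  # target along 0 rad, gaze exactly on a 0.3 rad line
  n <- 100
  tgt <- trajectory(seq_len(n), rep(5, n))
  segs <- data.frame(first = 1L, last = n)
  gaze <- trajectory(seq_len(n), 5 + tan(0.3) * seq_len(n))
  r <- regression_direction_index(tgt, gaze, segs)
  expect_equal(r$delta_theta_regr, 0.3, tolerance = 1e-9)
  # orientation folding: a 0.3 rad line and its pi-rotated twin are the same line
  gaze_rev <- trajectory(rev(gaze$x), rev(gaze$y))
  expect_equal(regression_direction_index(tgt, gaze_rev, segs)$delta_theta_regr,
               0.3, tolerance = 1e-9)
  # vertical target segment is well-defined under total least squares
  tgt_v <- trajectory(rep(3, n), seq_len(n))
  expect_equal(regression_direction_index(tgt_v, tgt_v, segs)$delta_theta_regr, 0)
  # coincident gaze points: skipped with a warning, then error when none left
  still <- trajectory(rep(1, n), rep(2, n))
  expect_warning(expect_error(
    regression_direction_index(tgt, still, segs), "no usable"),
    "coincide")
})

test_that("regression index stays small under isotropic noise on long segments", {
  # sigma = 2 px noise on a 300-sample straight segment barely tilts the fit
  n <- 300
  tgt <- trajectory(seq_len(n) * 4, seq_len(n) * 3)
  segs <- data.frame(first = 1L, last = n)
  ok <- 0L
  for (s in 1:100) {
    set.seed(s)
    gz <- trajectory(tgt$x + rnorm(n, sd = 2), tgt$y + rnorm(n, sd = 2))
    if (regression_direction_index(tgt, gz, segs)$delta_theta_regr < 0.05)
      ok <- ok + 1L
  }
  expect_gte(ok, 95)
})

test_that("Shoelace area: exact cases and the triangulation oracle", {
  expect_equal(shoelace_area(c(0, 1, 1, 0), c(0, 0, 1, 1))[["abs"]], 1)
  expect_equal(shoelace_area(c(0, 4, 0), c(0, 0, 3))[["abs"]], 6)
  expect_equal(shoelace_area(c(0, 1, 2), c(0, 1, 2))[["abs"]], 0)  # collinear
  # orientation flips the sign
  expect_equal(shoelace_area(c(0, 0, 1, 1), c(0, 1, 1, 0))[["signed"]], -1 *
               shoelace_area(c(0, 1, 1, 0), c(0, 0, 1, 1))[["signed"]])
  expect_error(shoelace_area(c(0, 1), c(0, 1)), "at least 3")

  set.seed(123)
  for (i in 1:1000) {
    p <- random_simple_polygon(sample(5:12, 1),
                               centre = runif(2, -20, 20),
                               r_range = sort(runif(2, 0.5, 15)))
    a <- shoelace_area(p$x, p$y)[["abs"]]
    expect_equal(a, triangulation_area(p$x, p$y, p$centre),
                 tolerance = 1e-9)
  }
})

test_that("polygon area index windows the trajectory and scales quadratically", {
  # straight line: zero for any window
  line <- trajectory(seq(0, 999), seq(0, 999) * 0.5)
  expect_equal(polygon_area_index(line, 15), 0)
  # unit square traced repeatedly, window = one cycle
  sq <- trajectory(rep(c(0, 1, 1, 0), 10), rep(c(0, 0, 1, 1), 10))
  expect_equal(polygon_area_index(sq, 4), 1)
  # oracle equivalence on a seeded random walk, including partial-window drop
  set.seed(21)
  rw <- trajectory(cumsum(rnorm(400)), cumsum(rnorm(400)))
  w <- 15
  k <- floor(400 / w)
  oracle <- mean(vapply(seq_len(k), function(j) {
    idx <- ((j - 1) * w + 1):(j * w)
    x <- rw$x[idx]; y <- rw$y[idx]
    abs(0.5 * sum(x * c(y[-1], y[1]) - y * c(x[-1], x[1])))
  }, numeric(1)))
  expect_equal(polygon_area_index(rw, w), oracle)
  # spatial scaling by s multiplies areas by s^2
  rw3 <- trajectory(rw$x * 3, rw$y * 3)
  expect_equal(polygon_area_index(rw3, w), 9 * polygon_area_index(rw, w))
  expect_error(polygon_area_index(trajectory(1:10, 1:10), 15), "fewer than")
})

test_that("cohort area normalisation maps the maximum to 1 and preserves order", {
  expect_equal(normalize_area_cohort(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(normalize_area_cohort(5), 1)
  set.seed(2)
  v <- runif(20, 0, 50)
  expect_identical(order(normalize_area_cohort(v)), order(v))
  expect_error(normalize_area_cohort(c(0, 0)), "all-zero")
})
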