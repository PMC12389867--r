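#' Configuration of the five-stage pursuit task
#'
#' The pursuit stimulus is a ball that (1) appears at the start position and
#' stays static for 1 s, (2) moves in a straight line in a random direction
#' for 5 s at constant speed, reflecting specularly off the screen edges,
#' (3) stops for 2 s, (4) resumes in the same direction it held when it
#' stopped for another 5 s (again bouncing), and (5) stops for a final 1 s.
#' At the 60 Hz analysis clock the default 14 s task yields exactly 840
#' samples.
#'
#' @param speed_px_s Target speed in pixels per second (default 250).
#' @param stage_durations_s Durations of the five stages in seconds
#'   (default `c(1, 5, 2, 5, 1)`).
#' @param rate_hz Sampling rate (default 60).
#' @param geometry A [screen_geometry()].
#' @param seed Integer seed for the random initial direction.
#' @param start_position Starting pixel position `c(x, y)`; defaults to the
#'   screen centre.
#' @param ball_radius_px Display radius of the target ball. Kept for
#'   completeness of the task description; reflection is computed at the ball
#'   centre and the radius does not affect bounce timing.
#'
#' @return An object of class `task_config`.
#' @export
task_config <- function(speed_px_s = 250,
                        stage_durations_s = c(1, 5, 2, 5, 1),
                        rate_hz = 60,
                        geometry = screen_geometry(),
                        seed = 1L,
                        start_position = NULL,
                        ball_radius_px = 20) {
  stopifnot(inherits(geometry, "screen_geometry"),
            length(stage_durations_s) == 5L)
  if (speed_px_s <= 0) stop("'speed_px_s' must be positive", call. = FALSE)
  if (any(stage_durations_s <= 0)) stop("stage durations must be positive", call. = FALSE)
  if (is.null(start_position))
    start_position <- c((geometry$width_px - 1) / 2, (geometry$height_px - 1) / 2)
  if (start_position[1] < 0 || start_position[1] > geometry$width_px - 1 ||
      start_position[2] < 0 || start_position[2] > geometry$height_px - 1)
    stop("start position lies outside the screen", call. = FALSE)
  structure(list(speed_px_s = speed_px_s,
                 stage_durations_s = stage_durations_s,
                 rate_hz = rate_hz,
                 geometry = geometry,
                 seed = as.integer(seed),
                 start_position = as.numeric(start_position),
                 ball_radius_px = ball_radius_px),
            class = "task_config")
}

#' Specular reflection of one motion step inside a rectangle
#'
#' Advances a position by one step vector, reflecting off the rectangle walls:
#' the overshoot beyond a wall re-enters mirrored (path length is preserved,
#' not clamped), the corresponding step component changes sign, and corner
#' exits reflect in both components. Repeated reflection handles steps that
#' cross a wall more than conceptually once, but a step longer than both
#' screen dimensions is rejected as nonphysical.
#'
#' @param pos Numeric `c(x, y)` inside `bounds`.
#' @param step Numeric `c(dx, dy)` displacement for this step.
#' @param bounds Numeric `c(xmin, xmax, ymin, ymax)` wall positions.
#' @return A list with `pos` (new position, inside bounds), `step` (the step
#'   vector with post-reflection signs) and `bounced` (logical).
#' @export
#' @examples
#' reflect_step(c(10, 100), c(-20, 0), c(0, 1365, 0, 767))
reflect_step <- function(pos, step, bounds) {
  stopifnot(length(pos) == 2L, length(step) == 2L, length(bounds) == 4L)
  w <- bounds[2] - bounds[1]; h <- bounds[4] - bounds[3]
  if (abs(step[1]) > w && abs(step[2]) > h)
    stop("step magnitude exceeds both screen dimensions; nonphysical", call. = FALSE)
  if (pos[1] < bounds[1] || pos[1] > bounds[2] ||
      pos[2] < bounds[3] || pos[2] > bounds[4])
    stop("'pos' must lie inside 'bounds'", call. = FALSE)
  p <- pos + step
  s <- step
  bounced <- FALSE
  for (iter in 1:8) {
    hit <- FALSE
    if (p[1] < bounds[1]) { p[1] <- 2 * bounds[1] - p[1]; s[1] <- -s[1]; hit <- TRUE }
    else if (p[1] > bounds[2]) { p[1] <- 2 * bounds[2] - p[1]; s[1] <- -s[1]; hit <- TRUE }
    if (p[2] < bounds[3]) { p[2] <- 2 * bounds[3] - p[2]; s[2] <- -s[2]; hit <- TRUE }
    else if (p[2] > bounds[4]) { p[2] <- 2 * bounds[4] - p[2]; s[2] <- -s[2]; hit <- TRUE }
    if (!hit) break
    bounced <- TRUE
  }
  list(pos = p, step = s, bounced = bounced)
}

#' Generate the five-stage bouncing-ball target trajectory
#'
#' Deterministic given the seed: the initial direction is drawn uniformly on
#' `[0, 2*pi)` from a seeded generator and everything else is exact
#' kinematics. Motion stages advance by `speed_px_s / rate_hz` pixels per step
#' along the current direction, with specular reflection at the walls
#' (`x` in `[0, width_px - 1]`, `y` in `[0, height_px - 1]`); static stages
#' repeat the last position. After the mid-task stop the ball resumes in the
#' direction it held when the stop began.
#'
#' The returned trajectory carries attributes used downstream:
#' `bounces` (sample indices of the first sample after each reflection),
#' `stages` (per-stage first/last sample index and a moving flag) and
#' `initial_direction` (radians).
#'
#' @param cfg A [task_config()].
#' @return A [trajectory()] with attributes `bounces`, `stages`,
#'   `initial_direction`.
#' @export
#' @examples
#' tgt <- generate_target_trajectory(task_config(seed = 7))
#' n_samples(tgt)          # 840
#' attr(tgt, "bounces")    # samples where the ball reflected
generate_target_trajectory <- function(cfg = task_config()) {
  stopifnot(inherits(cfg, "task_config"))
  g <- cfg$geometry
  bounds <- c(0, g$width_px - 1, 0, g$height_px - 1)
  n_stage <- round(cfg$rate_hz * cfg$stage_durations_s)
  n_total <- sum(n_stage)
  step_len <- cfg$speed_px_s / cfg$rate_hz

  theta0 <- with_seed(cfg$seed, stats::runif(1, 0, 2 * pi))
  dir_vec <- c(cos(theta0), sin(theta0)) * step_len

  x <- numeric(n_total); y <- numeric(n_total)
  bounces <- integer(0)
  pos <- cfg$start_position
  moving_stage <- c(FALSE, TRUE, FALSE, TRUE, FALSE)
  stage_start <- cumsum(c(1, n_stage))[1:5]
  stage_end <- cumsum(n_stage)

  idx <- 0L
  for (s in 1:5) {
    for (k in seq_len(n_stage[s])) {
      idx <- idx + 1L
      if (moving_stage[s]) {
        # every sample of a motion stage is the result of one step from the
        # previous sample, so the first moved position appears at the stage's
        # first sample
        r <- reflect_step(pos, dir_vec, bounds)
        pos <- r$pos
        dir_vec <- r$step
        if (r$bounced) bounces <- c(bounces, idx)
      }
      x[idx] <- pos[1]; y[idx] <- pos[2]
    }
  }

  traj <- trajectory(x, y, rate_hz = cfg$rate_hz)
  attr(traj, "bounces") <- bounces
  attr(traj, "stages") <- data.frame(stage = 1:5, first = stage_start,
                                     last = stage_end, moving = moving_stage)
  attr(traj, "initial_direction") <- theta0
  traj
}

#' Detect bounce points from a sampled trajectory
#'
#' A bounce is a change in motion direction between consecutive displacement
#' vectors. Because a reflection generally happens inside a sampling step, the
#' displacement of the reflecting step is a mixture of the old and new
#' directions, so a single physical bounce can produce direction changes at
#' two consecutive samples; runs of consecutive flagged samples are merged and
#' the last sample of the run is reported, which coincides with the
#' generator's logged bounce sample. Steps with zero displacement (stop/start
#' boundaries) are excluded, so stage transitions are not reported.
#'
#' @param traj A [trajectory()] with at least 3 samples.
#' @param tol_rad Minimum direction change (radians) to count (default 1e-6).
#' @return Integer sample indices, possibly empty.
#' @export
find_bounce_points <- function(traj, tol_rad = 1e-6) {
  stopifnot(inherits(traj, "spem_trajectory"))
  if (traj$n < 3L) stop("need at least 3 samples", call. = FALSE)
  dx <- diff(traj$x); dy <- diff(traj$y)
  nonzero <- (dx != 0 | dy != 0)
  ang <- atan2(dy, dx)
  m <- length(ang)
  # direction change between step i-1 and step i, attributed to sample i+... :
  # step i runs from sample i to sample i+1; a change between steps i-1 and i
  # pivots at sample i.
  flagged <- logical(traj$n)
  for (i in 2:m) {
    if (!nonzero[i - 1] || !nonzero[i]) next
    d <- abs(ang[i] - ang[i - 1])
    d <- min(d, 2 * pi - d)
    if (d > tol_rad) flagged[i] <- TRUE
  }
  idx <- which(flagged)
  if (length(idx) == 0L) return(integer(0))
  # A reflection inside step s->s+1 makes that step's displacement a mixture
  # of old and new directions, flagging pivots at both samples s and s+1; a
  # reflection exactly at a sample point flags only the arrival sample. In
  # both cases the last sample of a run of consecutive flags is the first
  # sample on the new line, which is what the generator logs.
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  unname(vapply(runs, function(r) r[length(r)], integer(1)))
}

#' Straight motion segments of a target trajectory
#'
#' Splits the motion stages into maximal straight segments delimited by stage
#' transitions and bounce points. For generator output the stage table and
#' logged bounces are used; for arbitrary trajectories the segments are
#' derived from zero-displacement runs and [find_bounce_points()].
#'
#' @param traj A target [trajectory()].
#' @return A data frame with columns `first` and `last`: inclusive sample
#'   index ranges within which the target moves along one straight line.
#' @export
straight_segments <- function(traj) {
  stopifnot(inherits(traj, "spem_trajectory"))
  stages <- attr(traj, "stages")
  bounces <- attr(traj, "bounces")
  if (is.null(stages)) {
    # generic path: motion = nonzero displacement
    dx <- diff(traj$x); dy <- diff(traj$y)
    moving <- (dx != 0 | dy != 0)
    r <- rle(moving)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    stages <- data.frame(first = starts, last = ends + 1L, moving = r$values)
    stages <- stages[stages$moving, c("first", "last"), drop = FALSE]
    bounces <- find_bounce_points(traj)
  } else {
    stages <- stages[stages$moving, c("first", "last"), drop = FALSE]
  }
  out <- list()
  for (i in seq_len(nrow(stages))) {
    a <- stages$first[i]; b <- stages$last[i]
    cuts <- sort(bounces[bounces > a & bounces <= b])
    # a bounce sample starts a new straight segment; the sample before it ends
    # the previous one
    starts <- c(a, cuts)
    ends <- c(cuts - 1L, b)
    out[[i]] <- data.frame(first = starts, last = ends)
  }
  res <- do.call(rbind, out)
  res[res$last > res$first, , drop = FALSE]
}
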