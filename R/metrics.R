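#' Lattice-ball cardinalities
#'
#' The colocality index lives on the integer pixel lattice: the closed ball
#' `B_r(x, y)` is the set of lattice points within Euclidean distance `r` of
#' the centre. Its cardinality is independent of (integer) centre by
#' translation invariance, so `gauss_disk_cardinality()` takes only the
#' radius. `disk_intersection_cardinality()` counts lattice points that lie in
#' two balls at once; it is symmetric in its two (centre, radius) arguments.
#'
#' @param radius_px Ball radius in pixels (real-valued, non-negative).
#' @return A lattice point count (integer-valued numeric).
#' @export
#' @examples
#' gauss_disk_cardinality(0)  # 1: the centre
#' gauss_disk_cardinality(1)  # 5: centre + 4-neighbourhood
#' gauss_disk_cardinality(2)  # 13
gauss_disk_cardinality <- function(radius_px) {
  if (length(radius_px) != 1L || is.na(radius_px) || radius_px < 0)
    stop("'radius_px' must be a single non-negative number", call. = FALSE)
  fr <- floor(radius_px)
  dx <- -fr:fr
  as.integer(sum(2 * floor(sqrt(pmax(radius_px^2 - dx^2, 0))) + 1))
}

# All lattice offsets within radius r of the origin, as an integer matrix.
disk_offsets <- function(radius_px) {
  fr <- as.integer(floor(radius_px))
  dx <- rep(-fr:fr, each = 2L * fr + 1L)
  dy <- rep(-fr:fr, times = 2L * fr + 1L)
  keep <- dx * dx + dy * dy <= radius_px^2
  cbind(dx = dx[keep], dy = dy[keep])
}

#' @rdname gauss_disk_cardinality
#' @param c1,c2 Integer lattice centres `c(x, y)`.
#' @param r1_px,r2_px Radii of the two balls in pixels.
#' @export
disk_intersection_cardinality <- function(c1, r1_px, c2, r2_px) {
  if (r1_px < 0 || r2_px < 0) stop("radii must be non-negative", call. = FALSE)
  # enumerate the smaller ball, test membership in the larger
  if (r2_px > r1_px) {
    tmp <- c1; c1 <- c2; c2 <- tmp
    tmpr <- r1_px; r1_px <- r2_px; r2_px <- tmpr
  }
  d2 <- sum((c1 - c2)^2)
  if (d2 > (r1_px + r2_px)^2) return(0L)
  off <- disk_offsets(r2_px)
  px <- off[, 1L] + c2[1]; py <- off[, 2L] + c2[2]
  as.integer(sum((px - c1[1])^2 + (py - c1[2])^2 <= r1_px^2))
}

#' Colocality parameters
#'
#' Radii of the target ball (`r1`) and gaze ball (`r2`), stated in millimetres
#' and converted to pixels through the screen geometry. The reference analysis
#' uses `r1` in {5, 10, 15} mm and `r2` in {2, 4, 8} mm.
#'
#' @param r1_mm Target-ball radius in mm.
#' @param r2_mm Gaze-ball radius in mm.
#' @param geometry A [screen_geometry()].
#' @return An object of class `colocality_params`.
#' @export
colocality_params <- function(r1_mm = 5, r2_mm = 2, geometry = screen_geometry()) {
  if (r1_mm <= 0 || r2_mm <= 0) stop("radii must be positive", call. = FALSE)
  structure(list(r1_mm = r1_mm, r2_mm = r2_mm, geometry = geometry,
                 r1_px = mm_to_px(r1_mm, geometry),
                 r2_px = mm_to_px(r2_mm, geometry)),
            class = "colocality_params")
}

#' Spatiotemporal colocality of two trajectories
#'
#' At each time point a ball of radius `r1` is drawn around the target
#' position and a ball of radius `r2` around the gaze position, both on the
#' integer pixel lattice (positions are snapped half-away-from-zero). The
#' index is the summed cardinality of the intersections divided by the summed
#' cardinality of the gaze balls:
#' \deqn{Co = \frac{\sum_t |B_{r1}(r_o(t)) \cap B_{r2}(r_g(t))|}{\sum_t |B_{r2}(r_g(t))|}.}
#' When `r2 <= r1`, `Co` is 1 exactly when every gaze ball is contained in its
#' paired target ball and 0 when the balls never meet. Balls are not clipped
#' at the screen edges: the gaze-ball cardinality in the denominator is
#' centre-independent, which the normalisation relies on.
#'
#' @param target,gaze [trajectory()] objects of equal length.
#' @param params A [colocality_params()].
#' @return The colocality in `[0, 1]` (for `r2 <= r1`).
#' @export
#' @examples
#' tgt <- generate_target_trajectory(task_config(seed = 3))
#' colocality(tgt, tgt)  # 1: identical trajectories, r2 < r1
colocality <- function(target, gaze, params = colocality_params()) {
  stopifnot(inherits(target, "spem_trajectory"), inherits(gaze, "spem_trajectory"),
            inherits(params, "colocality_params"))
  if (target$n != gaze$n)
    stop(sprintf("trajectory lengths differ: %d vs %d", target$n, gaze$n),
         call. = FALSE)
  r1 <- params$r1_px; r2 <- params$r2_px
  ddx <- round_half_away(target$x) - round_half_away(gaze$x)
  ddy <- round_half_away(target$y) - round_half_away(gaze$y)
  # the intersection count depends only on the integer centre offset, so
  # compute it once per distinct offset
  key <- paste(ddx, ddy, sep = ",")
  uk <- !duplicated(key)
  udx <- ddx[uk]; udy <- ddy[uk]
  off <- disk_offsets(r2)
  denom_each <- nrow(off)
  counts <- vapply(seq_along(udx), function(i) {
    d2 <- udx[i]^2 + udy[i]^2
    if (d2 > (r1 + r2)^2) return(0)
    if (sqrt(d2) + r2 <= r1) return(denom_each)  # gaze ball nested in target ball
    sum((off[, 1L] - udx[i])^2 + (off[, 2L] - udy[i])^2 <= r1^2)
  }, numeric(1))
  names(counts) <- key[uk]
  sum(counts[key]) / (denom_each * target$n)
}

#' Per-step motion angles of a trajectory
#'
#' The direction of each step, `atan2(y[t+1] - y[t], x[t+1] - x[t])`, in
#' `(-pi, pi]`, together with a mask of steps that actually move (a zero
#' displacement has no defined angle).
#'
#' @param traj A [trajectory()] with at least 2 samples.
#' @return A list with `theta` (length `n - 1`) and `moving` (logical mask;
#'   `theta` is `NA` where `moving` is `FALSE`).
#' @export
step_angles <- function(traj) {
  stopifnot(inherits(traj, "spem_trajectory"))
  if (traj$n < 2L) stop("need at least 2 samples", call. = FALSE)
  dx <- diff(traj$x); dy <- diff(traj$y)
  moving <- (dx != 0 | dy != 0)
  theta <- ifelse(moving, atan2(dy, dx), NA_real_)
  list(theta = theta, moving = moving)
}

#' Per-sample direction-difference index
#'
#' The circular coherence between target and gaze step directions: with
#' \eqn{\theta_o(t)} and \eqn{\theta_g(t)} the per-step angles, the index is
#' one minus the length of the mean resultant of the angle differences,
#' \deqn{\Delta\theta_{sample} = 1 - \left| \frac{1}{M} \sum_t
#'   e^{i(\theta_o(t) - \theta_g(t))} \right|,}
#' taken over the `M` steps where both trajectories have nonzero displacement
#' (a stationary target or gaze has no step direction). The modulus makes the
#' index real: 0 means perfectly coherent directions (any constant angular
#' offset included), values near 1 mean the difference angles scatter
#' uniformly around the circle. Note this is a coherence index, not a metric.
#'
#' @param target,gaze [trajectory()] objects of equal length (>= 2).
#' @return The index, in `[0, 2]` (at most 1 in expectation; values above 1
#'   require anti-phase structure).
#' @export
sample_direction_index <- function(target, gaze) {
  stopifnot(inherits(target, "spem_trajectory"), inherits(gaze, "spem_trajectory"))
  if (target$n != gaze$n)
    stop(sprintf("trajectory lengths differ: %d vs %d", target$n, gaze$n),
         call. = FALSE)
  ao <- step_angles(target); ag <- step_angles(gaze)
  valid <- ao$moving & ag$moving
  if (!any(valid))
    stop("no steps where both trajectories move; direction index undefined",
         call. = FALSE)
  z <- mean(exp(1i * (ao$theta[valid] - ag$theta[valid])))
  1 - Mod(z)
}

# Orientation (mod pi, in [0, pi)) of the principal axis of a 2-D point
# cloud: total-least-squares line fit. Returns NA when all points coincide.
tls_orientation <- function(x, y) {
  cx <- x - mean(x); cy <- y - mean(y)
  sxx <- sum(cx * cx); syy <- sum(cy * cy); sxy <- sum(cx * cy)
  if (sxx + syy == 0) return(NA_real_)
  # principal axis angle of the 2x2 scatter matrix
  ang <- 0.5 * atan2(2 * sxy, sxx - syy)
  ang %% pi
}

#' Regression-line direction-difference index
#'
#' For each straight segment of the target trajectory (delimited by bounces
#' and stage transitions), a line is fitted to the gaze positions over the
#' same samples and the acute angle between its orientation and the target
#' segment's orientation is taken; the index is the mean of these angles
#' across segments, in radians. Lines are fitted by total least squares
#' (principal axis), which is defined for vertical segments where an ordinary
#' regression of y on x is not; orientations are compared modulo `pi` and
#' folded into `[0, pi/2]` because a fitted line has an orientation but no
#' direction.
#'
#' @param target,gaze [trajectory()] objects of equal length.
#' @param segments Data frame with `first`/`last` sample indices of the
#'   straight target segments; defaults to [straight_segments()] of the
#'   target. Segments with fewer than 3 samples, or whose gaze points all
#'   coincide, are skipped (the latter with a warning).
#' @return A list with `delta_theta_regr` (mean acute orientation difference,
#'   radians), `per_segment` (the individual differences) and `n_segments`
#'   (number of segments used).
#' @export
regression_direction_index <- function(target, gaze,
                                       segments = straight_segments(target)) {
  stopifnot(inherits(target, "spem_trajectory"), inherits(gaze, "spem_trajectory"))
  if (target$n != gaze$n)
    stop(sprintf("trajectory lengths differ: %d vs %d", target$n, gaze$n),
         call. = FALSE)
  diffs <- numeric(0)
  for (i in seq_len(nrow(segments))) {
    idx <- segments$first[i]:segments$last[i]
    if (length(idx) < 3L) next
    th_o <- tls_orientation(target$x[idx], target$y[idx])
    th_g <- tls_orientation(gaze$x[idx], gaze$y[idx])
    if (is.na(th_o)) next
    if (is.na(th_g)) {
      warning(sprintf("segment %d-%d: all gaze points coincide; segment skipped",
                      segments$first[i], segments$last[i]), call. = FALSE)
      next
    }
    d <- abs(th_o - th_g) %% pi
    if (d > pi / 2) d <- pi - d
    diffs <- c(diffs, d)
  }
  if (length(diffs) == 0L)
    stop("no usable straight segments for the regression direction index",
         call. = FALSE)
  list(delta_theta_regr = mean(diffs), per_segment = diffs,
       n_segments = length(diffs))
}

#' Shoelace polygon area
#'
#' Signed area of the polygon with the given ordered vertices (closing
#' last-to-first): \deqn{A = \tfrac{1}{2}\sum_i (x_i y_{i+1} - y_i x_{i+1}).}
#' For self-intersecting polygons the signed contributions cancel by
#' orientation, which is the behaviour the windowed trajectory-area index
#' relies on.
#'
#' @param x,y Vertex coordinates in order (length >= 3).
#' @return Named numeric vector with `signed` and `abs` area.
#' @export
#' @examples
#' shoelace_area(c(0, 1, 1, 0), c(0, 0, 1, 1))  # unit square: abs area 1
shoelace_area <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("a polygon needs at least 3 vertices", call. = FALSE)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  a <- 0.5 * sum(x * yn - y * xn)
  c(signed = a, abs = abs(a))
}

#' Windowed polygon-area index of a trajectory
#'
#' The trajectory is cut into consecutive non-overlapping windows of
#' `window_n` samples (a trailing partial window is dropped); each window's
#' points, in temporal order and closed last-to-first, form a polygon whose
#' absolute Shoelace area is computed, and the mean over windows is returned.
#' A perfectly straight (or static) trajectory yields 0; deviations from
#' straight-line pursuit open up the polygons. At the 60 Hz clock the
#' reference window sizes n = 15, 30, 45, 60, 90 correspond to 250--1500 ms.
#'
#' @param traj A [trajectory()].
#' @param window_n Samples per window (the reference analysis uses 15--90).
#' @return Mean absolute polygon area in squared pixels.
#' @export
polygon_area_index <- function(traj, window_n = 15) {
  stopifnot(inherits(traj, "spem_trajectory"))
  if (window_n < 3L) stop("'window_n' must be at least 3", call. = FALSE)
  if (traj$n < window_n)
    stop(sprintf("trajectory has %d samples, fewer than window_n = %d",
                 traj$n, window_n), call. = FALSE)
  k <- floor(traj$n / window_n)
  areas <- vapply(seq_len(k), function(w) {
    idx <- ((w - 1L) * window_n + 1L):(w * window_n)
    shoelace_area(traj$x[idx], traj$y[idx])[["abs"]]
  }, numeric(1))
  mean(areas)
}

#' Cohort normalisation of polygon areas
#'
#' Per-window areas are reported in normalised units: each subject's mean area
#' (for a given window size) divided by the maximum across the whole cohort,
#' both groups pooled, so the largest subject maps to 1.
#'
#' @param values Non-negative per-subject mean areas for one window size.
#' @return `values / max(values)`, in `[0, 1]`.
#' @export
normalize_area_cohort <- function(values) {
  if (length(values) < 1L) stop("empty cohort", call. = FALSE)
  if (any(values < 0)) stop("areas must be non-negative", call. = FALSE)
  m <- max(values)
  if (m == 0) stop("all-zero cohort: normalisation undefined", call. = FALSE)
  values / m
}
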