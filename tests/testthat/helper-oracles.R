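# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration over a bounding box for
# lattice-ball counts, and a centroid-fan triangulation for polygon areas.

# exhaustive lattice scan: points within r1 of c1 AND r2 of c2
brute_disk_intersection <- function(c1, r1, c2, r2) {
  xs <- floor(min(c1[1] - r1, c2[1] - r2)):ceiling(max(c1[1] + r1, c2[1] + r2))
  ys <- floor(min(c1[2] - r1, c2[2] - r2)):ceiling(max(c1[2] + r1, c2[2] + r2))
  g <- expand.grid(x = xs, y = ys)
  sum((g$x - c1[1])^2 + (g$y - c1[2])^2 <= r1^2 &
      (g$x - c2[1])^2 + (g$y - c2[2])^2 <= r2^2)
}

# brute-force colocality: per-frame lattice scans, no memoisation
brute_colocality <- function(tx, ty, gx, gy, r1, r2) {
  tx <- round_half(tx); ty <- round_half(ty)
  gx <- round_half(gx); gy <- round_half(gy)
  num <- sum(vapply(seq_along(tx), function(t)
    brute_disk_intersection(c(tx[t], ty[t]), r1, c(gx[t], gy[t]), r2),
    numeric(1)))
  denom <- length(tx) * brute_disk_intersection(c(0, 0), r2, c(0, 0), r2)
  num / denom
}

round_half <- function(x) sign(x) * floor(abs(x) + 0.5)

# random star-shaped (hence simple) polygon: vertices at sorted angles around
# a centre, random radii. Angles are redrawn until every angular gap is < pi,
# which guarantees the centre lies inside the polygon so that the fan
# triangulation from it is exact.
random_simple_polygon <- function(n_vertices, centre = c(0, 0),
                                  r_range = c(1, 10)) {
  force(centre); force(r_range)
  repeat {
    ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
    gaps <- diff(c(ang, ang[1] + 2 * pi))
    if (max(gaps) < pi) break
  }
  rad <- stats::runif(n_vertices, r_range[1], r_range[2])
  list(x = centre[1] + rad * cos(ang), y = centre[2] + rad * sin(ang),
       centre = centre)
}

# centroid-fan triangulation area: valid for star-shaped polygons w.r.t. the
# generating centre (triangles are disjoint and cover the polygon)
triangulation_area <- function(x, y, centre) {
  n <- length(x)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(abs((x - centre[1]) * (yn - centre[2]) -
          (y - centre[2]) * (xn - centre[1])) / 2)
}

# quick paired target+gaze at 60 Hz for metric tests
make_tracked_pair <- function(seed_target = 1, profile = control_profile(),
                              seed_gaze = 2) {
  tgt <- generate_target_trajectory(task_config(seed = seed_target))
  list(target = tgt, gaze = simulate_gaze(tgt, profile, seed = seed_gaze))
}
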