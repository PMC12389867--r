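#' Synthetic gaze profile
#'
#' Parameters of the generative model used to emulate a subject tracking the
#' pursuit target. The model has three ingredients:
#'
#' * tracking noise: the gaze follows the target delayed by `lag_ms`, plus
#'   temporally correlated (AR(1), coefficient `jitter_ar`) isotropic Gaussian
#'   jitter with marginal SD `jitter_sd_px` per axis. The correlation mimics
#'   the smoothing a low-rate tracker plus linear-interpolation resampling
#'   imposes on measurement noise;
#' * attentional lapses: lapse episodes start as a Poisson process with rate
#'   `lapse_rate_per_s` and last an exponential time with mean
#'   `lapse_duration_s`; during a lapse the gaze decouples from the target and
#'   performs a directed random walk: each lapse draws a random heading and
#'   the gaze drifts `drift_sd_px` pixels per step along it, with isotropic
#'   Gaussian scatter of the same scale superimposed (an excursion towards
#'   some other part of the screen, rather than noise around the target);
#' * recovery: after a lapse the gaze closes a fraction `catchup_gain` of its
#'   positional error per step until it is back on target, then resumes
#'   normal tracking.
#'
#' With all noise scales and the lag at zero the simulated gaze reproduces the
#' target exactly.
#'
#' @param jitter_sd_px Marginal SD of tracking jitter, pixels per axis.
#' @param lag_ms Constant tracking delay, milliseconds.
#' @param lapse_rate_per_s Poisson rate of lapse onsets, 1/s.
#' @param lapse_duration_s Mean lapse duration, seconds (exponential).
#' @param drift_sd_px Random-walk step SD during lapses, pixels per axis.
#' @param catchup_gain Fraction of the positional error closed per step after
#'   a lapse, in (0, 1].
#' @param jitter_ar AR(1) coefficient of the jitter process, in [0, 1).
#' @return An object of class `gaze_profile`.
#' @seealso [control_profile()], [impaired_profile()] for the shipped
#'   defaults.
#' @export
gaze_profile <- function(jitter_sd_px = 0, lag_ms = 0, lapse_rate_per_s = 0,
                         lapse_duration_s = 1, drift_sd_px = 0,
                         catchup_gain = 0.5, jitter_ar = 0.9) {
  if (jitter_sd_px < 0 || lapse_rate_per_s < 0 || drift_sd_px < 0 ||
      lag_ms < 0 || lapse_duration_s < 0)
    stop("noise scales, lag and durations must be non-negative", call. = FALSE)
  if (catchup_gain <= 0 || catchup_gain > 1)
    stop("'catchup_gain' must be in (0, 1]", call. = FALSE)
  if (jitter_ar < 0 || jitter_ar >= 1)
    stop("'jitter_ar' must be in [0, 1)", call. = FALSE)
  structure(list(jitter_sd_px = jitter_sd_px, lag_ms = lag_ms,
                 lapse_rate_per_s = lapse_rate_per_s,
                 lapse_duration_s = lapse_duration_s,
                 drift_sd_px = drift_sd_px, catchup_gain = catchup_gain,
                 jitter_ar = jitter_ar),
            class = "gaze_profile")
}

#' Default simulation profiles
#'
#' Calibration constants of the simulator, not claims about any real cohort:
#' `control_profile()` emulates attentive pursuit (small correlated jitter,
#' short lag, rare lapses) and `impaired_profile()` emulates degraded pursuit
#' (larger jitter, longer lag, frequent lapses with drift and slow recovery).
#' The scales were chosen once so that, on the default task, simulated group
#' means of the headline indices fall near the reference cohort's values and
#' all four index families differ between groups in the same direction as in
#' that cohort.
#'
#' @return A [gaze_profile()].
#' @export
control_profile <- function() {
  gaze_profile(jitter_sd_px = 4, lag_ms = 30, lapse_rate_per_s = 0.02,
               lapse_duration_s = 0.5, drift_sd_px = 2, catchup_gain = 0.5,
               jitter_ar = 0)
}

#' @rdname control_profile
#' @export
impaired_profile <- function() {
  gaze_profile(jitter_sd_px = 5, lag_ms = 30, lapse_rate_per_s = 0.35,
               lapse_duration_s = 0.6, drift_sd_px = 18, catchup_gain = 0.5,
               jitter_ar = 0)
}

#' Simulate a gaze trajectory tracking a target
#'
#' Applies the [gaze_profile()] model to a target trajectory: lagged tracking
#' with correlated jitter, Poisson/exponential attentional lapses with
#' random-walk drift, and proportional catch-up after each lapse. The
#' simulation is fully determined by the seed.
#'
#' @param target A [trajectory()] (typically [generate_target_trajectory()]
#'   output at 60 Hz).
#' @param profile A [gaze_profile()].
#' @param seed Integer seed.
#' @return A [trajectory()] of the same length and rate as `target`.
#' @export
#' @examples
#' tgt <- generate_target_trajectory(task_config(seed = 2))
#' g <- simulate_gaze(tgt, control_profile(), seed = 11)
#' colocality(tgt, g)
simulate_gaze <- function(target, profile, seed = 1L) {
  stopifnot(inherits(target, "spem_trajectory"), inherits(profile, "gaze_profile"))
  n <- target$n
  rate <- target$rate_hz
  lag_samples <- profile$lag_ms / 1000 * rate
  # lagged target by fractional-index linear interpolation, clamped at start
  ti <- pmax(seq_len(n) - lag_samples, 1)
  lo <- floor(ti); hi <- ceiling(ti); w <- ti - lo
  tx <- target$x[lo] * (1 - w) + target$x[hi] * w
  ty <- target$y[lo] * (1 - w) + target$y[hi] * w

  with_seed(seed, {
    # AR(1) jitter with marginal SD jitter_sd_px per axis
    rho <- profile$jitter_ar
    innov_sd <- profile$jitter_sd_px * sqrt(1 - rho^2)
    jx <- numeric(n); jy <- numeric(n)
    ex <- stats::rnorm(n); ey <- stats::rnorm(n)
    jx[1] <- profile$jitter_sd_px * ex[1]
    jy[1] <- profile$jitter_sd_px * ey[1]
    if (n > 1) for (t in 2:n) {
      jx[t] <- rho * jx[t - 1] + innov_sd * ex[t]
      jy[t] <- rho * jy[t - 1] + innov_sd * ey[t]
    }

    p_onset <- profile$lapse_rate_per_s / rate
    onset_u <- stats::runif(n)
    dur_draw <- stats::rexp(n, rate = 1 / max(profile$lapse_duration_s, 1e-12))
    dx <- stats::rnorm(n); dy <- stats::rnorm(n)

    heading_u <- stats::runif(n, 0, 2 * pi)

    gx <- numeric(n); gy <- numeric(n)
    state <- "track"            # track | lapse | catchup
    lapse_left <- 0
    hx <- 0; hy <- 0            # per-lapse drift heading
    gx[1] <- tx[1] + jx[1]; gy[1] <- ty[1] + jy[1]
    for (t in 2:n) {
      if (state == "track" && p_onset > 0 && onset_u[t] < p_onset) {
        state <- "lapse"
        lapse_left <- max(1, round(dur_draw[t] * rate))
        hx <- cos(heading_u[t]); hy <- sin(heading_u[t])
      }
      if (state == "lapse") {
        gx[t] <- gx[t - 1] + profile$drift_sd_px * (hx + dx[t])
        gy[t] <- gy[t - 1] + profile$drift_sd_px * (hy + dy[t])
        lapse_left <- lapse_left - 1
        if (lapse_left <= 0) state <- "catchup"
      } else if (state == "catchup") {
        gx[t] <- gx[t - 1] + profile$catchup_gain * (tx[t] - gx[t - 1])
        gy[t] <- gy[t - 1] + profile$catchup_gain * (ty[t] - gy[t - 1])
        err <- sqrt((gx[t] - tx[t])^2 + (gy[t] - ty[t])^2)
        if (err < max(2, profile$jitter_sd_px)) state <- "track"
      } else {
        gx[t] <- tx[t] + jx[t]
        gy[t] <- ty[t] + jy[t]
      }
    }
    trajectory(gx, gy, rate_hz = rate)
  })
}

# canonical labels for index columns of a cohort table
index_key <- function(index, param) {
  ifelse(index == "colocality", paste0("co_", gsub("/", "_", param)),
  ifelse(index == "area", paste0("area_", param), index))
}

#' Simulate a two-group cohort and compute all indices
#'
#' Generates `n_per_group` subjects per profile (each with its own seeded
#' target realisation, mirroring per-session stimulus randomness), simulates
#' their gaze, and computes the full index set: colocality over the `r1` x
#' `r2` grid, both direction indices, and cohort-normalised polygon areas for
#' each window size.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param control,impaired [gaze_profile()]s for the two groups.
#' @param seed Master seed; all per-subject seeds derive from it.
#' @param r1_mm,r2_mm Colocality radius grids in mm (all pairs are computed).
#' @param windows_n Polygon-area window sizes in samples.
#' @param cfg Base [task_config()]; each subject gets a derived seed.
#' @param labels Group labels, impaired first (defaults `c("SZ", "CNT")`).
#' @return A `cohort_table` data frame with columns `subject_id`, `group`,
#'   `index`, `param`, `key`, `value`.
#' @export
make_cohort <- function(n_per_group = 9,
                        control = control_profile(),
                        impaired = impaired_profile(),
                        seed = 1L,
                        r1_mm = c(5, 10, 15),
                        r2_mm = c(2, 4, 8),
                        windows_n = c(15, 30, 45, 60, 90),
                        cfg = task_config(),
                        labels = c("SZ", "CNT")) {
  if (n_per_group < 2) stop("'n_per_group' must be at least 2", call. = FALSE)
  n_tot <- 2L * n_per_group
  seeds <- derive_seeds(seed, 2L * n_tot)
  geometry <- cfg$geometry
  rate <- cfg$rate_hz

  subjects <- data.frame(
    subject_id = sprintf("%s%02d", rep(c("S", "C"), each = n_per_group),
                         rep(seq_len(n_per_group), 2)),
    group = rep(labels, each = n_per_group),
    stringsAsFactors = FALSE
  )
  profiles <- c(rep(list(impaired), n_per_group), rep(list(control), n_per_group))

  rows <- list()
  raw_area <- matrix(NA_real_, nrow = n_tot, ncol = length(windows_n))
  for (i in seq_len(n_tot)) {
    cfg_i <- cfg; cfg_i$seed <- seeds[2L * i - 1L]
    tgt <- generate_target_trajectory(cfg_i)
    gz <- simulate_gaze(tgt, profiles[[i]], seed = seeds[2L * i])
    segs <- straight_segments(tgt)
    for (r1 in r1_mm) for (r2 in r2_mm) {
      co <- colocality(tgt, gz, colocality_params(r1, r2, geometry))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subjects$subject_id[i], group = subjects$group[i],
        index = "colocality", param = sprintf("%g/%g", r1, r2), value = co)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = subjects$subject_id[i], group = subjects$group[i],
      index = "dtheta_sample", param = NA_character_,
      value = sample_direction_index(tgt, gz))
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = subjects$subject_id[i], group = subjects$group[i],
      index = "dtheta_regr", param = NA_character_,
      value = regression_direction_index(tgt, gz, segs)$delta_theta_regr)
    for (j in seq_along(windows_n))
      raw_area[i, j] <- polygon_area_index(gz, windows_n[j])
  }
  # normalised areas: divide by the cohort maximum per window size
  for (j in seq_along(windows_n)) {
    nv <- normalize_area_cohort(raw_area[, j])
    ms <- round(windows_n[j] / rate * 1000)
    for (i in seq_len(n_tot)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subjects$subject_id[i], group = subjects$group[i],
        index = "area", param = as.character(ms), value = nv[i])
    }
  }
  tab <- do.call(rbind, rows)
  tab$key <- index_key(tab$index, tab$param)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
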