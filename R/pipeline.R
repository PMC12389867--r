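#' Configuration for a full synthetic run
#'
#' Bundles every knob of the end-to-end synthetic pipeline: task geometry,
#' index parameter grids, statistics level and classifier settings. All
#' randomness derives from the single `seed` passed to
#' [run_full_synthetic()].
#'
#' @param n_per_group Subjects per group.
#' @param control,impaired [gaze_profile()]s for the two groups.
#' @param cfg Base [task_config()].
#' @param r1_mm,r2_mm Colocality radius grids (mm).
#' @param windows_n Polygon-area windows (samples, within 15--90 by default).
#' @param alpha Significance level for the group comparisons.
#' @param features Classifier feature keys.
#' @param grid Hyperparameter grid values for C and sigma.
#' @param B_perm,B_boot Permutation and bootstrap replicate counts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_per_group = 9,
                       control = control_profile(),
                       impaired = impaired_profile(),
                       cfg = task_config(),
                       r1_mm = c(5, 10, 15),
                       r2_mm = c(2, 4, 8),
                       windows_n = c(15, 30, 45, 60, 90),
                       alpha = 0.05,
                       features = c("co_5_2", "dtheta_regr", "area_250"),
                       grid = seq(0.1, 5, by = 0.1),
                       B_perm = 1000,
                       B_boot = 1000) {
  stopifnot(all(r1_mm > 0), all(r2_mm > 0), all(windows_n >= 3))
  structure(list(n_per_group = n_per_group, control = control,
                 impaired = impaired, cfg = cfg, r1_mm = r1_mm, r2_mm = r2_mm,
                 windows_n = windows_n, alpha = alpha, features = features,
                 grid = grid, B_perm = B_perm, B_boot = B_boot),
            class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Chains every stage on simulated data with a single master seed: target
#' generation and gaze simulation for a two-group cohort, all trajectory
#' indices, group statistics, and the SVM evaluation harness (grid search,
#' permutation test, bootstrap CIs). Rerunning with the same seed reproduces
#' every number exactly.
#'
#' @param config A [run_config()].
#' @param seed Master seed.
#' @return A list with `cohort` (the index table), `comparisons` (group
#'   statistics), `classifier` (grid search, permutation and bootstrap
#'   results), `underpowered` flag (`TRUE` when `n_per_group < 5`), and
#'   `provenance` (config, seed, package version).
#' @export
run_full_synthetic <- function(config = run_config(), seed = 1L) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(seed, 3L)
  cohort <- tryCatch(
    make_cohort(n_per_group = config$n_per_group, control = config$control,
                impaired = config$impaired, seed = seeds[1],
                r1_mm = config$r1_mm, r2_mm = config$r2_mm,
                windows_n = config$windows_n, cfg = config$cfg),
    error = function(e) stop("cohort simulation stage: ", conditionMessage(e),
                             call. = FALSE))
  comparisons <- tryCatch(
    summarize_cohort(cohort, alpha = config$alpha),
    error = function(e) stop("group statistics stage: ", conditionMessage(e),
                             call. = FALSE))
  classifier <- tryCatch({
    fm <- feature_matrix(cohort, features = config$features)
    gs <- grid_search(fm$x, fm$y, C_grid = config$grid,
                      sigma_grid = config$grid)
    ev <- loocv_evaluate(fm$x, fm$y, gs$sigma, gs$C)
    perm <- permutation_test(fm$x, fm$y, gs$sigma, gs$C, B = config$B_perm,
                             seed = seeds[2])
    boot <- bootstrap_ci(fm$x, fm$y, gs$sigma, gs$C, B = config$B_boot,
                         seed = seeds[3])
    list(best_C = gs$C, best_sigma = gs$sigma,
         accuracy = ev$accuracy, sensitivity = ev$sensitivity,
         specificity = ev$specificity,
         permutation_p = perm$p_value, bootstrap = boot)
  }, error = function(e) stop("classification stage: ", conditionMessage(e),
                              call. = FALSE))
  list(cohort = cohort,
       comparisons = comparisons,
       classifier = classifier,
       underpowered = config$n_per_group < 5,
       provenance = list(seed = seed, derived_seeds = seeds, config = config,
                         package_version = as.character(utils::packageVersion("spemtrack"))))
}
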