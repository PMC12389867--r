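#' Feature matrix from a cohort table
#'
#' Pivots a long cohort table into the per-subject feature matrix used by the
#' classifier. The default three features are the most discriminative column
#' of each index family: colocality at r1 = 5 mm / r2 = 2 mm, the
#' regression-line direction index, and the normalised polygon area at 250 ms.
#' All indices already lie in a common 0--1-ish range, so no feature scaling
#' is applied anywhere in the harness.
#'
#' @param table A cohort table (from [make_cohort()] or [reference_cohort()]).
#' @param features Character vector of index keys (see the `key` column).
#' @param positive Label of the positive (patient) class, default `"SZ"`.
#' @return A list with `x` (numeric matrix, subjects x features), `y` (factor
#'   with the positive class as first level) and `subject_id`.
#' @export
feature_matrix <- function(table,
                           features = c("co_5_2", "dtheta_regr", "area_250"),
                           positive = "SZ") {
  stopifnot(is.data.frame(table),
            all(c("subject_id", "group", "key", "value") %in% names(table)))
  missing_f <- setdiff(features, unique(table$key))
  if (length(missing_f) > 0L)
    stop("features not present in table: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  sub <- table[table$key %in% features, c("subject_id", "group", "key", "value")]
  wide <- stats::reshape(sub, direction = "wide", idvar = c("subject_id", "group"),
                         timevar = "key")
  names(wide) <- sub("^value\\.", "", names(wide))
  x <- as.matrix(wide[, features, drop = FALSE])
  if (anyNA(x)) stop("missing feature values", call. = FALSE)
  rownames(x) <- wide$subject_id
  neg <- setdiff(unique(wide$group), positive)
  if (length(neg) != 1L) stop("expected exactly two groups", call. = FALSE)
  list(x = x, y = factor(wide$group, levels = c(positive, neg)),
       subject_id = wide$subject_id)
}

# one Gaussian-kernel soft-margin SVM fit + prediction of held-out rows.
# kernel: k(u, v) = exp(-||u - v||^2 / (2 sigma^2)), i.e. gamma = 1/(2 sigma^2)
svm_predict_heldout <- function(x_train, y_train, x_test, sigma, C) {
  fit <- e1071::svm(x = x_train, y = y_train, scale = FALSE,
                    type = "C-classification", kernel = "radial",
                    gamma = 1 / (2 * sigma^2), cost = C)
  stats::predict(fit, x_test)
}

#' Leave-one-out evaluation of a Gaussian-kernel SVM
#'
#' Each subject is predicted by an SVM trained on all the others, with fixed
#' hyperparameters; the fit is deterministic, so the result is too. Accuracy
#' is the fraction of correct held-out predictions, sensitivity the recall of
#' the positive (first-level, patient) class and specificity the recall of
#' the control class.
#'
#' @param x Numeric feature matrix (subjects x features).
#' @param y Factor of class labels, positive class first level; both classes
#'   must appear in every training fold, so each class needs >= 2 members.
#' @param sigma Gaussian kernel width (> 0).
#' @param C Soft-margin cost (> 0).
#' @return A list with `accuracy`, `sensitivity`, `specificity` and
#'   `predicted` (the held-out predictions).
#' @export
loocv_evaluate <- function(x, y, sigma, C) {
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (sigma <= 0 || C <= 0) stop("'sigma' and 'C' must be positive", call. = FALSE)
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("need exactly two classes", call. = FALSE)
  if (any(table(y) < 2L))
    stop("each class needs at least 2 members (a training fold would otherwise lose a class)",
         call. = FALSE)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n))
    pred[i] <- svm_predict_heldout(x[-i, , drop = FALSE], y[-i],
                                   x[i, , drop = FALSE], sigma, C)
  pos <- levels(y)[1]; negl <- levels(y)[2]
  list(accuracy = mean(pred == y),
       sensitivity = mean(pred[y == pos] == pos),
       specificity = mean(pred[y == negl] == negl),
       predicted = pred)
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates LOOCV accuracy on every (C, sigma) pair of a regular grid
#' (default 0.1 to 5.0 in steps of 0.1, i.e. 50 x 50 = 2500 fits) and returns
#' the maximiser. Ties are broken towards the smallest C, then the smallest
#' sigma, so the result is deterministic.
#'
#' @param x,y As in [loocv_evaluate()].
#' @param C_grid,sigma_grid Candidate values.
#' @return A list with `C`, `sigma`, `accuracy` (the best LOOCV accuracy) and
#'   `grid` (data frame of all evaluations).
#' @export
grid_search <- function(x, y, C_grid = seq(0.1, 5, by = 0.1),
                        sigma_grid = seq(0.1, 5, by = 0.1)) {
  grid <- expand.grid(C = C_grid, sigma = sigma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i)
    loocv_evaluate(x, y, grid$sigma[i], grid$C[i])$accuracy, numeric(1))
  best_acc <- max(grid$accuracy)
  cand <- grid[grid$accuracy == best_acc, ]
  cand <- cand[order(cand$C, cand$sigma), ]
  list(C = cand$C[1], sigma = cand$sigma[1], accuracy = best_acc, grid = grid)
}

#' Permutation test of classifier performance
#'
#' Builds the null distribution of LOOCV accuracy by refitting under
#' label permutations: for each of `B` seeded permutations the labels are
#' shuffled, the LOOCV accuracy recomputed, and the p-value estimated as
#' \deqn{p = \frac{1 + \#\{\hat\Theta_b \ge \hat\Theta_{true}\}}{1 + B},}
#' so the smallest attainable p is `1 / (B + 1)`. Hyperparameters are held
#' fixed at the values selected on the original labels; re-running the grid
#' search inside every permutation is available via `regrid = TRUE` but is
#' 2500x slower (neither choice is exactly conservative: fixed
#' hyperparameters ignore selection variability, per-permutation search gives
#' the null its own optimism).
#'
#' @param x,y As in [loocv_evaluate()].
#' @param sigma,C Hyperparameters selected on the original labels.
#' @param B Number of permutations (default 1000).
#' @param seed Seed for the permutations.
#' @param regrid If `TRUE`, rerun [grid_search()] on each permuted dataset.
#' @return A list with `p_value`, `theta_true` and `theta_null` (the `B`
#'   permuted accuracies).
#' @export
permutation_test <- function(x, y, sigma, C, B = 1000, seed = 1L,
                             regrid = FALSE) {
  if (B < 1) stop("'B' must be at least 1", call. = FALSE)
  theta_true <- loocv_evaluate(x, y, sigma, C)$accuracy
  theta_null <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      yb <- sample(y)
      if (regrid) grid_search(x, yb)$accuracy
      else loocv_evaluate(x, yb, sigma, C)$accuracy
    }, numeric(1))
  })
  list(p_value = (1 + sum(theta_null >= theta_true)) / (1 + B),
       theta_true = theta_true, theta_null = theta_null)
}

#' Bootstrap confidence intervals for classifier performance
#'
#' Resamples the subjects with replacement `B` times, recomputes the LOOCV
#' metrics on each resample with fixed hyperparameters, and reports the
#' bootstrap mean and the 95 percent percentile interval
#' `[2.5 percent, 97.5 percent]` for accuracy, sensitivity and specificity.
#' Resamples in which either class has fewer than 2 members are redrawn
#' (LOOCV needs both classes in every training fold); this conditions the
#' bootstrap distribution on evaluable resamples.
#'
#' @param x,y As in [loocv_evaluate()].
#' @param sigma,C Fixed hyperparameters.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Seed for the resampling.
#' @return A list of per-metric results: each has `mean`, `ci` (length-2
#'   vector) and the `B` resampled values.
#' @export
bootstrap_ci <- function(x, y, sigma, C, B = 1000, seed = 1L) {
  if (B < 2) stop("'B' must be at least 2", call. = FALSE)
  n <- nrow(x)
  res <- with_seed(seed, {
    acc <- sen <- spe <- numeric(B)
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (all(table(y[idx]) >= 2) && nlevels(droplevels(y[idx])) == 2L) break
      }
      ev <- loocv_evaluate(x[idx, , drop = FALSE], y[idx], sigma, C)
      acc[b] <- ev$accuracy; sen[b] <- ev$sensitivity; spe[b] <- ev$specificity
    }
    list(acc = acc, sen = sen, spe = spe)
  })
  summarise <- function(v) list(mean = mean(v),
                                ci = unname(stats::quantile(v, c(0.025, 0.975))),
                                values = v)
  list(accuracy = summarise(res$acc),
       sensitivity = summarise(res$sen),
       specificity = summarise(res$spe),
       B = B)
}
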