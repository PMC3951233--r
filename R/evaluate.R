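# Model evaluation: R (as printed, the 1 - SSE/SST form), RMSE, NRMSE,
# random train/test splitting, split-homogeneity tests, and repeated
# random sub-sampling validation.

#' Prediction R statistic (1 - SSE/SST form)
#'
#' Computes `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)` -- the
#' coefficient-of-determination form, reported here under the name the
#' field uses for it, R.  It equals 1 for perfect prediction, 0 when
#' predicting the observed mean, and can be negative for predictions
#' worse than the mean.  No square root is taken.
#'
#' @param y_obs Observed values (length >= 2, not constant).
#' @param y_pred Predicted values, same length.
#' @return The scalar statistic.
#' @seealso [pearson_r()] for the ordinary product-moment correlation.
#' @export
r_squared <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 2L)
  sst <- sum((y_obs - mean(y_obs))^2)
  if (sst == 0) stop("y_obs is constant: R is undefined (zero denominator)")
  1 - sum((y_obs - y_pred)^2) / sst
}

#' Pearson correlation of observed and predicted values
#'
#' Reported alongside [r_squared()] because published QSPkR tables do
#' not always distinguish the two.
#'
#' @inheritParams r_squared
#' @return Product-moment correlation coefficient.
#' @export
pearson_r <- function(y_obs, y_pred) stats::cor(y_obs, y_pred)

#' Root-mean-square error
#'
#' @inheritParams r_squared
#' @return `sqrt(mean((y_obs - y_pred)^2))`, in the units of the
#'   inputs; symmetric in its arguments.
#' @export
rmse <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred))
  if (length(y_obs) == 0L) stop("empty input")
  sqrt(mean((y_obs - y_pred)^2))
}

#' Normalized root-mean-square error
#'
#' Divides an RMSE by the observed range of the target, giving a
#' dimensionless error comparable across pharmacokinetic parameters
#' with different units.
#'
#' @param rmse_value An RMSE in original units.
#' @param scale Observed range: `c(min, max)` or a one-row data frame
#'   with `min`/`max` columns.
#' @return `rmse_value / (max - min)`.
#' @export
nrmse <- function(rmse_value, scale) {
  s <- scale_bounds(scale)
  if (s[2L] <= s[1L]) stop("constant scale: NRMSE undefined")
  rmse_value / (s[2L] - s[1L])
}

#' Random train/test split
#'
#' Uniformly random partition of `n_compounds` indices into a training
#' set of size `n_train` and a test set of the remainder (the reference
#' protocol allocates 33 of 39 compounds to training and 6 to testing).
#'
#' @param n_compounds Total number of compounds.
#' @param n_train Training-set size, strictly between 0 and
#'   `n_compounds`.
#' @param seed Optional integer seed.
#' @return An object of class `qspkr_split`: list with sorted integer
#'   vectors `train` and `test`.
#' @export
split_train_test <- function(n_compounds, n_train, seed = NULL) {
  n_compounds <- as.integer(n_compounds); n_train <- as.integer(n_train)
  if (n_train <= 0L || n_train >= n_compounds)
    stop("n_train must be strictly between 0 and n_compounds")
  if (!is.null(seed)) set.seed(seed)
  tr <- sort(sample.int(n_compounds, n_train))
  structure(list(train = tr, test = setdiff(seq_len(n_compounds), tr)),
            class = "qspkr_split")
}

#' Split-homogeneity tests
#'
#' Checks that a random train/test split did not produce groups with
#' different pharmacokinetic-value distributions: a Levene-type test of
#' variance homogeneity (Brown-Forsythe, median-centered, via
#' `car::leveneTest`) and a two-sample t-test of location (Welch by
#' default, appropriate for the unequal 33/6 group sizes).
#'
#' @param train_values,test_values Numeric PK values of the two groups
#'   (each length >= 2, not both constant).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return List with `levene_p`, `ttest_p`, `levene_statistic`,
#'   `t_statistic`.
#' @export
homogeneity_tests <- function(train_values, test_values, var_equal = FALSE) {
  if (length(train_values) < 2L || length(test_values) < 2L)
    stop("both groups need at least two values")
  values <- c(train_values, test_values)
  if (stats::sd(values) == 0) stop("all values identical: tests undefined")
  grp <- factor(rep(c("train", "test"), c(length(train_values),
                                          length(test_values))))
  lev <- car::leveneTest(values, grp, center = stats::median)
  tt <- stats::t.test(train_values, test_values, var.equal = var_equal)
  list(levene_p = lev[["Pr(>F)"]][1L],
       levene_statistic = lev[["F value"]][1L],
       ttest_p = tt$p.value,
       t_statistic = unname(tt$statistic))
}

# Train on one split, predict the test fold, report metrics on the
# original PK scale (and normalized scale for reference).
evaluate_split <- function(data, selected, split, ann_ctl) {
  Xs <- data$X[, selected, drop = FALSE]
  model <- init_network(length(selected), ann_ctl)
  model <- train_ann(model, Xs[split$train, , drop = FALSE],
                     data$dp[split$train], ann_ctl)
  pred_norm <- ann_forward(model, Xs[split$test, , drop = FALSE])
  obs_norm <- data$dp[split$test]
  pred <- denormalize(pred_norm, data$scale_pk)
  obs <- denormalize(obs_norm, data$scale_pk)
  hom <- homogeneity_tests(denormalize(data$dp[split$train], data$scale_pk), obs)
  rm <- rmse(obs, pred)
  list(model = model,
       metrics = data.frame(
         R = r_squared(obs, pred),
         pearson_r = pearson_r(obs, pred),
         RMSE = rm,
         NRMSE = nrmse(rm, data$scale_pk),
         RMSE_normalized = rmse(obs_norm, pred_norm),
         levene_p = hom$levene_p,
         ttest_p = hom$ttest_p),
       predictions = data.frame(compound = data$compound_ids[split$test],
                                observed = obs, predicted = pred))
}

#' Repeated random sub-sampling validation
#'
#' Repeats the reference validation protocol: randomly split the
#' compounds (33 train / 6 test for 39 compounds; the same 33:6
#' proportion otherwise), train a fresh network on the training fold's
#' selected descriptors, predict the held-out fold, map predictions
#' back to original units, and score with R, RMSE and NRMSE.  Per-split
#' homogeneity (Levene and t-test p-values) is reported with each
#' repeat.  Aggregate metrics pool the predicted/observed pairs of all
#' repeats.
#'
#' @param data A `qspkr_dataset`.
#' @param selected Integer indices of the descriptors used as network
#'   inputs (typically [run_ga()]`$selected`).
#' @param ann_ctl An [ann_control()] object for the per-repeat
#'   networks.
#' @param n_repeats Number of random splits (default 10; use 1 for a
#'   single-split evaluation).
#' @param n_train Training-fold size; default `round(33/39 * n)`.
#' @param seed Optional integer seed; repeat `i` uses `seed + i` for
#'   its split and network initialization.
#' @return An object of class `qspkr_validation`: list with `per_repeat`
#'   (data frame of per-split metrics), `aggregate` (pooled R,
#'   pearson_r, RMSE, NRMSE plus mean and sd of per-repeat metrics),
#'   `predictions` (all predicted/observed pairs, original units),
#'   `selected`, `n_train`, `n_repeats`, `seed`.
#' @export
repeated_subsampling_validation <- function(data, selected,
                                            ann_ctl = ann_control(),
                                            n_repeats = 10L,
                                            n_train = NULL,
                                            seed = NULL) {
  stopifnot(inherits(data, "qspkr_dataset"), n_repeats >= 1L)
  n <- nrow(data$X)
  selected <- as.integer(selected)
  if (any(selected < 1L | selected > ncol(data$X)))
    stop("selected descriptor index out of range")
  if (is.null(n_train)) n_train <- round(33 / 39 * n)
  n_train <- max(1L, min(n - 1L, as.integer(n_train)))
  reps <- vector("list", n_repeats)
  preds <- vector("list", n_repeats)
  for (i in seq_len(n_repeats)) {
    rep_seed <- if (is.null(seed)) NULL else seed + i
    split <- split_train_test(n, n_train, rep_seed)
    ctl <- ann_ctl
    ctl$seed <- rep_seed
    ev <- evaluate_split(data, selected, split, ctl)
    reps[[i]] <- cbind(data.frame(repeat_id = i), ev$metrics)
    preds[[i]] <- cbind(data.frame(repeat_id = i), ev$predictions)
  }
  per_repeat <- do.call(rbind, reps)
  predictions <- do.call(rbind, preds)
  pooled_rmse <- rmse(predictions$observed, predictions$predicted)
  aggregate <- list(
    R = r_squared(predictions$observed, predictions$predicted),
    pearson_r = pearson_r(predictions$observed, predictions$predicted),
    RMSE = pooled_rmse,
    NRMSE = nrmse(pooled_rmse, data$scale_pk),
    mean = colMeans(per_repeat[-1L]),
    sd = vapply(per_repeat[-1L], stats::sd, numeric(1)))
  structure(list(per_repeat = per_repeat, aggregate = aggregate,
                 predictions = predictions, selected = selected,
                 n_train = n_train, n_test = n - n_train,
                 n_repeats = n_repeats, seed = seed,
                 pk_name = data$pk_name, pk_unit = data$pk_unit),
            class = "qspkr_validation")
}

#' @export
print.qspkr_validation <- function(x, ...) {
  cat(sprintf(
    "<qspkr_validation> %d repeats of a %d/%d train/test split (%s)\n",
    x$n_repeats, x$n_train, x$n_test, x$pk_name))
  cat(sprintf("  pooled test metrics: R = %.3f, RMSE = %.4g %s, NRMSE = %.3f\n",
              x$aggregate$R, x$aggregate$RMSE,
              if (is.na(x$pk_unit)) "" else x$pk_unit, x$aggregate$NRMSE))
  invisible(x)
}
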