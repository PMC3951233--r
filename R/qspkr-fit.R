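# The user-facing model: GA descriptor selection + neural-network
# regression + repeated sub-sampling validation, in one fit.

#' Fit a QSPkR model
#'
#' Runs the full modelling procedure on one pharmacokinetic parameter:
#' min-max normalization of descriptors and PK values to the unit
#' interval, genetic-algorithm selection of at most
#' `ga$gene_limit` descriptors under the award/penalty pairwise
#' fitness, repeated random sub-sampling validation (33/6 splits for 39
#' compounds) of a Levenberg-Marquardt-trained three-layer network, and
#' a final network trained on all compounds for prediction.
#'
#' @param descriptors Either a `qspkr_dataset` (already normalized, as
#'   returned by [minmax_normalize()] or [generate_dataset()]`$data`),
#'   a `qspkr_raw` table, or a numeric matrix/data frame (compounds x
#'   descriptors, original units).
#' @param pk Pharmacokinetic values: a one-column `qspkr_raw` table or
#'   a numeric vector.  Ignored (must be missing) when `descriptors`
#'   is already a `qspkr_dataset`.
#' @param ga A [ga_control()] object.
#' @param ann An [ann_control()] object.
#' @param n_repeats Validation repeats (default 10).
#' @param n_train Training-fold size (default: the 33/39 proportion).
#' @param seed Integer seed driving every stochastic stage.  Stage
#'   seeds are derived as `seed * 101 + stage` (stage 1 = GA, 2 =
#'   validation, 3 = final network), so stages can be reproduced in
#'   isolation; explicit seeds inside `ga`/`ann` take precedence.
#' @return An object of class `qspkr`: list with `data`, `selection`
#'   (a `qspkr_ga`), `validation` (a `qspkr_validation`), `final_model`
#'   (a `qspkr_ann` trained on all compounds), `seed` and `call`.
#' @examples
#' synth <- generate_dataset(synthetic_spec(n_compounds = 30,
#'   n_descriptors = 60, n_informative = 5, seed = 1))
#' fit <- qspkr(synth$data, n_repeats = 2, seed = 1)
#' print(fit)
#' head(predict(fit, synth$raw$descriptors))
#' @export
qspkr <- function(descriptors, pk,
                  ga = ga_control(), ann = ann_control(),
                  n_repeats = 10L, n_train = NULL, seed = 1L) {
  cl <- match.call()
  data <- if (inherits(descriptors, "qspkr_dataset")) {
    if (!missing(pk)) stop("pk must not be given when descriptors is a qspkr_dataset")
    descriptors
  } else {
    raw_x <- as_qspkr_raw(descriptors, "descriptor")
    raw_pk <- as_qspkr_raw_pk(pk, raw_x$compound_ids)
    minmax_normalize(raw_x, raw_pk)
  }
  seed <- as.integer(seed)
  if (is.null(ga$seed)) ga$seed <- derive_seed(seed, 1L)
  sel <- run_ga(data, ga)
  if (length(sel$selected) == 0L)
    stop("the genetic algorithm selected no descriptors")
  val <- repeated_subsampling_validation(data, sel$selected, ann,
                                         n_repeats = n_repeats,
                                         n_train = n_train,
                                         seed = derive_seed(seed, 2L))
  final_ctl <- ann
  if (is.null(final_ctl$seed)) final_ctl$seed <- derive_seed(seed, 3L)
  final <- init_network(length(sel$selected), final_ctl)
  final <- train_ann(final, data$X[, sel$selected, drop = FALSE], data$dp,
                     final_ctl)
  structure(list(data = data, selection = sel, validation = val,
                 final_model = final, seed = seed, call = cl),
            class = "qspkr")
}

# deterministic per-stage seeds below 2^31
derive_seed <- function(seed, stage) {
  (abs(as.integer(seed)) %% 21000000L) * 101L + as.integer(stage)
}

as_qspkr_raw <- function(x, what) {
  if (inherits(x, "qspkr_raw")) return(x)
  x <- as.matrix(x)
  ids <- rownames(x) %||% sprintf("compound_%02d", seq_len(nrow(x)))
  cols <- colnames(x) %||% sprintf("%s_%04d", what, seq_len(ncol(x)))
  new_qspkr_raw(ids, cols, x)
}

as_qspkr_raw_pk <- function(pk, ids) {
  if (inherits(pk, "qspkr_raw")) return(pk)
  pk <- as.numeric(pk)
  if (length(pk) != length(ids))
    stop("pk length does not match the number of compounds")
  new_qspkr_raw(ids, "pk", matrix(pk, ncol = 1L))
}

#' @export
print.qspkr <- function(x, ...) {
  cat("QSPkR model (GA descriptor selection + LM-trained neural network)\n")
  cat(sprintf("  data: %d compounds x %d descriptors; parameter %s [%s]\n",
              nrow(x$data$X), ncol(x$data$X), x$data$pk_name, x$data$pk_unit))
  cat(sprintf("  selected descriptors (%d, %s termination): %s\n",
              length(x$selection$selected), x$selection$termination,
              paste(x$selection$selected_names, collapse = ", ")))
  cat(sprintf(
    "  validation (%d x %d/%d splits): R = %.3f, RMSE = %.4g, NRMSE = %.3f\n",
    x$validation$n_repeats, x$validation$n_train, x$validation$n_test,
    x$validation$aggregate$R, x$validation$aggregate$RMSE,
    x$validation$aggregate$NRMSE))
  invisible(x)
}

#' @export
summary.qspkr <- function(object, ...) {
  structure(list(fit = object,
                 selected = data.frame(
                   index = object$selection$selected,
                   name = object$selection$selected_names),
                 per_repeat = object$validation$per_repeat,
                 aggregate = object$validation$aggregate),
            class = "summary.qspkr")
}

#' @export
print.summary.qspkr <- function(x, ...) {
  print(x$fit)
  cat("\nPer-repeat validation metrics:\n")
  print(x$per_repeat, row.names = FALSE, digits = 4)
  cat("\nMean +/- sd over repeats:\n")
  m <- x$aggregate$mean; s <- x$aggregate$sd
  for (nm in c("R", "pearson_r", "RMSE", "NRMSE"))
    cat(sprintf("  %-10s %8.4f +/- %.4f\n", nm, m[[nm]], s[[nm]]))
  invisible(x)
}

#' @export
coef.qspkr <- function(object, ...) {
  m <- object$final_model
  H <- m$control$n_hidden
  nm <- c(sprintf("W1[%s]", outer(seq_len(H), object$selection$selected_names,
                                  paste, sep = ",")),
          sprintf("b1[%d]", seq_len(H)),
          sprintf("w2[%d]", seq_len(H)), "b2")
  stats::setNames(pack_params(m), nm)
}

#' Predict pharmacokinetic values for new compounds
#'
#' Normalizes the new descriptor values with the scale learned at fit
#' time, runs the final network on the selected descriptors, and maps
#' the result back to original units.
#'
#' @param object A fitted `qspkr` model.
#' @param newdata A `qspkr_raw` table, matrix or data frame.  Columns
#'   are matched to the selected descriptors by name when column names
#'   are present; otherwise the matrix must contain all original
#'   descriptor columns in order.
#' @param ... Unused.
#' @return Numeric vector of predictions in the PK parameter's
#'   original units.
#' @export
predict.qspkr <- function(object, newdata, ...) {
  if (missing(newdata)) return(fitted(object))
  X <- if (inherits(newdata, "qspkr_raw")) newdata$values else as.matrix(newdata)
  sel <- object$selection$selected
  names_sel <- object$selection$selected_names
  Xs <- if (!is.null(colnames(X)) && all(names_sel %in% colnames(X))) {
    X[, names_sel, drop = FALSE]
  } else if (ncol(X) == ncol(object$data$X)) {
    X[, sel, drop = FALSE]
  } else {
    stop("newdata must carry the selected descriptor columns by name, ",
         "or all ", ncol(object$data$X), " original descriptor columns")
  }
  sc <- object$data$scale_x[sel, ]
  rng <- pmax(sc$max - sc$min, 1)  # constant columns were never selectable
  Xn <- sweep(sweep(Xs, 2L, sc$min), 2L, rng, "/")
  denormalize(ann_forward(object$final_model, Xn), object$data$scale_pk)
}

#' @export
fitted.qspkr <- function(object, ...) {
  sel <- object$selection$selected
  denormalize(ann_forward(object$final_model,
                          object$data$X[, sel, drop = FALSE]),
              object$data$scale_pk)
}

#' @export
residuals.qspkr <- function(object, ...) {
  denormalize(object$data$dp, object$data$scale_pk) - fitted(object)
}

#' Predicted-versus-observed plot
#'
#' Plots the pooled held-out predictions from the validation repeats
#' against the observed values, with the identity line; points from
#' the final all-data fit are overlaid in grey.
#'
#' @param x A fitted `qspkr` model.
#' @param ... Passed to `plot()`.
#' @export
plot.qspkr <- function(x, ...) {
  p <- x$validation$predictions
  unit <- if (is.na(x$data$pk_unit)) "" else paste0(" [", x$data$pk_unit, "]")
  graphics::plot(p$observed, p$predicted,
                 xlab = paste0("observed ", x$data$pk_name, unit),
                 ylab = paste0("predicted ", x$data$pk_name, unit),
                 main = sprintf("Held-out predictions (%d repeats), R = %.3f",
                                x$validation$n_repeats,
                                x$validation$aggregate$R), ...)
  graphics::points(denormalize(x$data$dp, x$data$scale_pk), fitted(x),
                   col = "grey60", pch = 3)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
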