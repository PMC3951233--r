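# Three-layer feed-forward network (inputs -> hidden -> single output,
# bias in each layer) trained by Levenberg-Marquardt least squares on
# normalized targets.

#' Neural-network control parameters
#'
#' @param n_hidden Hidden-layer size (default 4; with tens of training
#'   compounds and at most 15 inputs, a small hidden layer limits
#'   overfitting).
#' @param epochs Number of training epochs; one epoch is one
#'   Levenberg-Marquardt update of the full batch, accepted or finally
#'   rejected (default 50).
#' @param activation_hidden Hidden activation: `"tanh"` (default) or
#'   `"logistic"`.
#' @param activation_output Output activation: `"logistic"` (default;
#'   targets are min-max normalized into `[0, 1]`) or `"linear"`.
#' @param lm_damping_init Initial damping `mu` (default 1e-3).
#' @param lm_damping_increase Factor applied to `mu` after a rejected
#'   step (default 10).
#' @param lm_damping_decrease Factor applied to `mu` after an accepted
#'   step (default 0.1).
#' @param lm_damping_max Training stops once `mu` exceeds this bound
#'   (default 1e10).
#' @param lm_max_retries Damping increases attempted within one epoch
#'   before the epoch is recorded as rejected (default 20).
#' @param weight_init_scale Half-width of the uniform weight
#'   initialization interval (default 0.5).
#' @param optimizer `"lm"` (Levenberg-Marquardt, default) or `"gd"`
#'   (plain batch gradient descent, secondary option).
#' @param learning_rate Step size for `optimizer = "gd"` (default 0.5).
#' @param seed Optional integer seed for weight initialization.
#' @return A validated list of class `qspkr_ann_control`.
#' @export
ann_control <- function(n_hidden = 4L,
                        epochs = 50L,
                        activation_hidden = c("tanh", "logistic"),
                        activation_output = c("logistic", "linear"),
                        lm_damping_init = 1e-3,
                        lm_damping_increase = 10,
                        lm_damping_decrease = 0.1,
                        lm_damping_max = 1e10,
                        lm_max_retries = 20L,
                        weight_init_scale = 0.5,
                        optimizer = c("lm", "gd"),
                        learning_rate = 0.5,
                        seed = NULL) {
  ctl <- list(n_hidden = as.integer(n_hidden),
              epochs = as.integer(epochs),
              activation_hidden = match.arg(activation_hidden),
              activation_output = match.arg(activation_output),
              lm_damping_init = lm_damping_init,
              lm_damping_increase = lm_damping_increase,
              lm_damping_decrease = lm_damping_decrease,
              lm_damping_max = lm_damping_max,
              lm_max_retries = as.integer(lm_max_retries),
              weight_init_scale = weight_init_scale,
              optimizer = match.arg(optimizer),
              learning_rate = learning_rate,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  stopifnot(ctl$n_hidden >= 1L, ctl$epochs >= 0L,
            ctl$lm_damping_init > 0, ctl$lm_damping_increase > 1,
            ctl$lm_damping_decrease > 0, ctl$lm_damping_decrease < 1,
            ctl$lm_max_retries >= 1L, ctl$weight_init_scale >= 0,
            ctl$learning_rate > 0)
  class(ctl) <- "qspkr_ann_control"
  ctl
}

activation <- function(name) {
  switch(name,
         tanh = list(f = tanh, df = function(z) 1 - tanh(z)^2),
         logistic = list(f = function(z) 1 / (1 + exp(-z)),
                         df = function(z) { s <- 1 / (1 + exp(-z)); s * (1 - s) }),
         linear = list(f = identity, df = function(z) rep(1, length(z))),
         stop("unknown activation: ", name))
}

#' Initialize a network
#'
#' Weights and biases are drawn independently and uniformly from
#' `[-weight_init_scale, +weight_init_scale]`.
#'
#' @param n_inputs Number of input neurons (selected descriptors).
#' @param control An [ann_control()] object; its `seed` (if non-NULL)
#'   makes the draw reproducible.
#' @return An object of class `qspkr_ann`: list with `W1` (n_hidden x
#'   n_inputs), `b1` (n_hidden), `w2` (n_hidden), `b2` (scalar), the
#'   control list, and an empty training `trace`.
#' @export
init_network <- function(n_inputs, control = ann_control()) {
  n_inputs <- as.integer(n_inputs)
  if (n_inputs < 1L) stop("n_inputs must be at least 1")
  if (!is.null(control$seed)) set.seed(control$seed)
  H <- control$n_hidden
  s <- control$weight_init_scale
  draw <- function(n) stats::runif(n, -s, s)
  structure(list(W1 = matrix(draw(H * n_inputs), H, n_inputs),
                 b1 = draw(H), w2 = draw(H), b2 = draw(1L),
                 n_inputs = n_inputs, control = control, trace = NULL),
            class = "qspkr_ann")
}

n_params <- function(model) length(model$W1) + length(model$b1) +
  length(model$w2) + 1L

#' @export
print.qspkr_ann <- function(x, ...) {
  cat(sprintf("<qspkr_ann> %d-%d-1 network (%d parameters, %s/%s)%s\n",
              x$n_inputs, x$control$n_hidden, n_params(x),
              x$control$activation_hidden, x$control$activation_output,
              if (is.null(x$trace)) ", untrained" else
                sprintf(", trained %d epochs, final SSE %.4g",
                        nrow(x$trace), x$trace$sse[nrow(x$trace)])))
  invisible(x)
}

pack_params <- function(model) c(as.vector(model$W1), model$b1, model$w2, model$b2)

unpack_params <- function(theta, model) {
  H <- model$control$n_hidden; p <- model$n_inputs
  model$W1 <- matrix(theta[seq_len(H * p)], H, p)
  off <- H * p
  model$b1 <- theta[off + seq_len(H)]; off <- off + H
  model$w2 <- theta[off + seq_len(H)]; off <- off + H
  model$b2 <- theta[off + 1L]
  model
}

#' Forward pass
#'
#' Computes `g_out(w2 . g_hid(W1 x + b1) + b2)` for each row of `X`.
#' Pure function: rows are independent and the model is not modified.
#'
#' @param model A `qspkr_ann`.
#' @param X Numeric matrix, one row per compound, `n_inputs` columns
#'   (normalized descriptor values).
#' @return Numeric vector of predictions in the output activation's
#'   range (`(0, 1)` for logistic).
#' @export
ann_forward <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_inputs)
    stop(sprintf("input has %d columns, network expects %d",
                 ncol(X), model$n_inputs))
  fh <- activation(model$control$activation_hidden)$f
  fo <- activation(model$control$activation_output)$f
  Z <- X %*% t(model$W1) + matrix(model$b1, nrow(X), length(model$b1),
                                  byrow = TRUE)
  A <- fh(Z) %*% model$w2 + model$b2
  as.numeric(fo(A))
}

#' @export
predict.qspkr_ann <- function(object, newdata, ...) ann_forward(object, newdata)

# Jacobian of predictions w.r.t. the packed parameter vector, plus the
# predictions themselves.  Derivatives follow the chain rule through
# the two layers (back-propagated deltas).
ann_jacobian <- function(model, X) {
  X <- as.matrix(X)
  n <- nrow(X); H <- model$control$n_hidden
  ah <- activation(model$control$activation_hidden)
  ao <- activation(model$control$activation_output)
  Z <- X %*% t(model$W1) + matrix(model$b1, n, H, byrow = TRUE)
  Hid <- ah$f(Z)
  A <- as.numeric(Hid %*% model$w2 + model$b2)
  yhat <- ao$f(A)
  gp <- ao$df(A)                     # dyhat/dA, length n
  dHid <- ah$df(Z)                   # n x H
  # columns ordered as pack_params: W1 (column-major), b1, w2, b2
  J <- matrix(0, n, n_params(model))
  delta <- dHid * (gp %o% model$w2)  # n x H
  for (j in seq_len(model$n_inputs))
    J[, (j - 1L) * H + seq_len(H)] <- delta * X[, j]
  off <- H * model$n_inputs
  J[, off + seq_len(H)] <- delta
  J[, off + H + seq_len(H)] <- Hid * gp
  J[, off + 2L * H + 1L] <- gp
  list(yhat = yhat, J = J)
}

#' Train a network
#'
#' With the default `"lm"` optimizer, each epoch computes the residual
#' vector `r = y - yhat` and its analytic Jacobian, solves the damped
#' normal equations `(J'J + mu I) step = J'r`, and accepts the step if
#' the sum of squared errors decreases (then `mu` shrinks); otherwise
#' `mu` grows and the step is retried up to `lm_max_retries` times.
#' The SSE over accepted steps is therefore non-increasing.  Training
#' stops after `epochs` epochs or when `mu` exceeds `lm_damping_max`.
#' With `optimizer = "gd"` each epoch takes one batch gradient-descent
#' step of size `learning_rate`.
#'
#' @param model An initialized `qspkr_ann`.
#' @param X Training inputs (rows = compounds, normalized to `[0, 1]`).
#' @param y Training targets in `[0, 1]`, one per row of `X`.
#' @param control Optional [ann_control()] overriding the model's.
#' @return The trained `qspkr_ann`; `$trace` is a data frame with one
#'   row per epoch (`epoch`, `sse`, `mu`, `accepted`).
#' @export
train_ann <- function(model, X, y, control = model$control) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  model$control <- control
  if (control$epochs == 0L) return(model)
  if (control$optimizer == "gd") return(train_gd(model, X, y, control))

  theta <- pack_params(model)
  mu <- control$lm_damping_init
  fwd <- ann_jacobian(model, X)
  sse <- sum((y - fwd$yhat)^2)
  if (!is.finite(sse)) stop("non-finite loss before epoch 1")
  trace <- vector("list", control$epochs)
  for (ep in seq_len(control$epochs)) {
    r <- y - fwd$yhat
    JtJ <- crossprod(fwd$J)
    Jtr <- as.numeric(crossprod(fwd$J, r))
    accepted <- FALSE
    for (try in seq_len(control$lm_max_retries)) {
      step <- tryCatch(solve(JtJ + diag(mu, nrow(JtJ)), Jtr),
                       error = function(e) NULL)
      if (!is.null(step)) {
        cand <- unpack_params(theta + step, model)
        cand_fwd <- ann_jacobian(cand, X)
        cand_sse <- sum((y - cand_fwd$yhat)^2)
        if (is.finite(cand_sse) && cand_sse < sse) {
          theta <- theta + step
          model <- cand
          fwd <- cand_fwd
          sse <- cand_sse
          mu <- mu * control$lm_damping_decrease
          accepted <- TRUE
          break
        }
      }
      mu <- mu * control$lm_damping_increase
      if (mu > control$lm_damping_max) break
    }
    if (!is.finite(sse)) stop("non-finite loss at epoch ", ep)
    trace[[ep]] <- data.frame(epoch = ep, sse = sse, mu = mu,
                              accepted = accepted)
    if (mu > control$lm_damping_max) break
  }
  model$trace <- do.call(rbind, trace[!vapply(trace, is.null, TRUE)])
  model
}

train_gd <- function(model, X, y, control) {
  trace <- vector("list", control$epochs)
  for (ep in seq_len(control$epochs)) {
    fwd <- ann_jacobian(model, X)
    r <- y - fwd$yhat
    sse <- sum(r^2)
    if (!is.finite(sse)) stop("non-finite loss at epoch ", ep)
    grad <- as.numeric(crossprod(fwd$J, r))  # d(SSE)/dtheta = -2 J'r; step along J'r
    theta <- pack_params(model) + control$learning_rate * grad
    model <- unpack_params(theta, model)
    trace[[ep]] <- data.frame(epoch = ep, sse = sse, mu = NA_real_,
                              accepted = TRUE)
  }
  model$trace <- do.call(rbind, trace)
  model
}

#' Check analytic derivatives against finite differences
#'
#' Compares the analytic Jacobian of the network output with central
#' finite differences at the model's current weights.
#'
#' @param model A `qspkr_ann`.
#' @param X Input matrix.
#' @param h Finite-difference step (default 1e-6).
#' @return Maximum deviation over all Jacobian entries, relative to
#'   `max(1, |finite-difference value|)` elementwise.
#' @export
analytic_gradient_check <- function(model, X, h = 1e-6) {
  X <- as.matrix(X)
  J <- ann_jacobian(model, X)$J
  theta <- pack_params(model)
  Jfd <- matrix(0, nrow(X), length(theta))
  for (k in seq_along(theta)) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    Jfd[, k] <- (ann_forward(unpack_params(tp, model), X) -
                 ann_forward(unpack_params(tm, model), X)) / (2 * h)
  }
  max(abs(J - Jfd) / pmax(1, abs(Jfd)))
}

#' Serialize a trained network to a JSON-ready list
#'
#' @param model A `qspkr_ann`.
#' @return A plain list (weights, shapes, control, trace) suitable for
#'   `jsonlite::write_json()`; invert with [ann_from_list()].
#' @export
ann_to_list <- function(model) {
  list(n_inputs = model$n_inputs,
       n_hidden = model$control$n_hidden,
       W1 = unclass(model$W1), b1 = model$b1, w2 = model$w2, b2 = model$b2,
       activation_hidden = model$control$activation_hidden,
       activation_output = model$control$activation_output,
       seed = model$control$seed,
       trace = model$trace)
}

#' Rebuild a network from its serialized form
#'
#' @param lst A list as produced by [ann_to_list()] (possibly
#'   round-tripped through JSON).
#' @return A `qspkr_ann`.
#' @export
ann_from_list <- function(lst) {
  ctl <- ann_control(n_hidden = lst$n_hidden,
                     activation_hidden = lst$activation_hidden,
                     activation_output = lst$activation_output,
                     seed = lst$seed)
  m <- init_network(lst$n_inputs, ctl)
  m$W1 <- matrix(as.numeric(unlist(lst$W1)), lst$n_hidden, lst$n_inputs)
  m$b1 <- as.numeric(lst$b1); m$w2 <- as.numeric(lst$w2)
  m$b2 <- as.numeric(lst$b2)
  m$trace <- if (!is.null(lst$trace)) as.data.frame(lst$trace) else NULL
  m
}
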