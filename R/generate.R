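# resolve either a fitted model or a bare (weights, config) pair
resolve_net <- function(object, config = NULL) {
  if (inherits(object, "sctrnn"))
    list(weights = object$weights, config = object$config)
  else if (inherits(object, "sctrnn_weights")) {
    if (is.null(config)) stop("a 'network_config' is required with raw weights")
    list(weights = object, config = config)
  } else stop("'object' must be an 'sctrnn' fit or an 'sctrnn_weights' set")
}

#' Closed-loop (proactive) trajectory generation
#'
#' Sets the recurrent state to the learned initial state of a class and
#' lets the network run on its own predictions: the readout of the initial
#' state is the first input and every subsequent input is the previous
#' predicted mean (the chi = 0 regime, prediction noise off).  The result
#' is deterministic.
#'
#' @param object an `sctrnn` fit, or an `sctrnn_weights` set (then `config`
#'   is required).
#' @param class_id which learned initial state to start from.
#' @param T number of generated steps.
#' @param config a [network_config()] when `object` is a raw weight set.
#' @return A list of class `generation_result` with `trajectory` (T x 2
#'   predicted means), `activations` (C x T context activations) and
#'   `variances` (T x 2 predicted variances).
#' @export
closed_loop_generate <- function(object, class_id, T = 75L, config = NULL) {
  net <- resolve_net(object, config)
  S <- nrow(net$weights$initial_states)
  if (class_id < 1L || class_id > S)
    stop("'class_id' must index one of the ", S, " learned initial states")
  res <- .sctrnn_generate_cpp(net$weights$initial_states[class_id, ],
                              net$weights$W_inp, net$weights$W_rec,
                              net$weights$W_out, net$weights$W_var,
                              net$config$tau, net$config$K,
                              net$config$variance_floor, as.integer(T))
  structure(res, class = "generation_result")
}

#' @export
print.generation_result <- function(x, ...) {
  cat("Closed-loop generation:", nrow(x$trajectory), "steps,",
      nrow(x$activations), "context neurons\n")
  invisible(x)
}

#' Infer an initial state for a target trajectory
#'
#' Recognition of a (possibly untrained) trajectory: with the network
#' weights frozen, only the initial state is optimized, by Adam on the
#' open-loop (chi = 1, noise off) prediction likelihood of the target.
#' The search starts from the mean of the learned initial states; with
#' `epochs = 0` that starting point is returned unchanged.  The distance
#' prior over initial states is not applied (it exists to separate classes
#' during training).
#'
#' @param object an `sctrnn` fit or `sctrnn_weights` (+ `config`).
#' @param target a T x 2 target trajectory, or a list of targets (each
#'   inferred independently, in one batch).
#' @param epochs number of Adam updates.
#' @param config required with raw weights.
#' @param control optimizer settings ([training_control()]); only the Adam
#'   fields are used.
#' @return For a single target, a list with `state` (length-C vector) and
#'   `nll` (per-epoch loss history); for a list of targets, `state` is a
#'   C x M matrix.
#' @export
infer_initial_state <- function(object, target, epochs = 5000L,
                                config = NULL, control = training_control()) {
  net <- resolve_net(object, config)
  single <- !is.list(target)
  targets <- if (single) list(as.matrix(target)) else lapply(target, as.matrix)
  C <- net$config$context_size
  M <- length(targets)
  start <- matrix(colMeans(net$weights$initial_states), C, M)
  if (epochs == 0L) {
    st <- if (single) drop(start[, 1L]) else start
    return(list(state = st, nll = numeric(0)))
  }
  T_ <- nrow(targets[[1]])
  X <- array(0, dim = c(net$config$input_size, M, T_))
  for (n in seq_len(M)) X[, n, ] <- t(targets[[n]])
  res <- .sctrnn_infer_cpp(X, start, net$weights$W_inp, net$weights$W_rec,
                           net$weights$W_out, net$weights$W_var,
                           net$config$tau, net$config$K,
                           net$config$variance_floor, as.integer(epochs),
                           control$learning_rate, control$beta1,
                           control$beta2, control$adam_eps)
  st <- if (single) drop(res$initial_states[, 1L]) else res$initial_states
  list(state = st, nll = res$nll)
}

#' One-step (reactive) prediction error from a given initial state
#'
#' Drives the network open-loop (chi = 1, noise off) with the target
#' trajectory, starting from `initial_state`, and returns the mean squared
#' one-step prediction error: each step's predicted mean against the next
#' target point.
#'
#' @param object an `sctrnn` fit or `sctrnn_weights` (+ `config`).
#' @param initial_state length-C recurrent state at t = 0.
#' @param target T x 2 target trajectory.
#' @param config required with raw weights.
#' @return Mean squared error (a single number).
#' @export
reactive_error <- function(object, initial_state, target, config = NULL) {
  net <- resolve_net(object, config)
  target <- as.matrix(target)
  w <- net$weights
  w$initial_states <- matrix(initial_state, nrow = 1L)
  tr <- forward_sequence(w, net$config, 1L, target, chi = 1, noise = FALSE)
  T_ <- nrow(target)
  prediction_mse(tr$y[-T_, , drop = FALSE], target[-1L, , drop = FALSE])
}
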