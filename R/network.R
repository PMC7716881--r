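#' Network hyperparameters
#'
#' Collects the architectural and developmental parameters of the S-CTRNN.
#'
#' @param context_size number of recurrent context neurons.
#' @param input_size,output_size dimensionality of the input and of the
#'   predicted mean/variance (2 for planar drawing).
#' @param tau leaky-integrator time constant (>= 1); the recurrent state
#'   decays with coefficient `1 - 1/tau` per step.
#' @param chi_train external-contribution parameter used during learning:
#'   the weight of the raw sensory input in the integrated input, in
#'   \[0.1, 1\].  A value of 0 would make the prediction error identically
#'   zero (the network would compare its prediction against itself), so
#'   values below 0.1 are rejected for training.
#' @param K aberrant-precision offset added inside the exponential of the
#'   variance readout; `K > 0` makes the network overestimate sensory noise,
#'   `K < 0` underestimate it.
#' @param v_dist variance of the distance prior that keeps the per-class
#'   initial states at a controlled spread around their mean.
#' @param variance_floor small constant added to the predicted variance so
#'   that it stays strictly positive.
#' @param noise_placement where the sampled prediction noise enters the
#'   integrated input: `"prediction"` attaches it to the prediction term
#'   (`chi*x + (1-chi)*(y + nu)`), so that `chi = 1` reproduces the raw
#'   input exactly; `"literal"` adds it unconditionally
#'   (`chi*x + (1-chi)*y + nu`).
#' @return A list of class `network_config`.
#' @export
network_config <- function(context_size = 70L, input_size = 2L,
                           output_size = 2L, tau = 2, chi_train = 1,
                           K = 0, v_dist = 10, variance_floor = 1e-5,
                           noise_placement = c("prediction", "literal")) {
  noise_placement <- match.arg(noise_placement)
  context_size <- as.integer(context_size)
  if (context_size < 1L) stop("'context_size' must be positive")
  if (tau < 1) stop("'tau' must be >= 1 so the leak coefficient is in [0, 1)")
  if (chi_train < 0.1 || chi_train > 1)
    stop("'chi_train' must lie in [0.1, 1]: chi_train = 0 yields a zero ",
         "prediction error and no learning")
  if (v_dist <= 0) stop("'v_dist' must be positive")
  if (variance_floor <= 0) stop("'variance_floor' must be positive")
  structure(list(context_size = context_size,
                 input_size = as.integer(input_size),
                 output_size = as.integer(output_size),
                 tau = tau, chi_train = chi_train, K = K, v_dist = v_dist,
                 variance_floor = variance_floor,
                 noise_placement = noise_placement),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat("S-CTRNN configuration\n")
  cat(sprintf("  context neurons: %d, tau: %g\n", x$context_size, x$tau))
  cat(sprintf("  chi_train: %g, K: %g, v_dist: %g\n",
              x$chi_train, x$K, x$v_dist))
  invisible(x)
}

#' Initialize network weights
#'
#' Draws all connection weights i.i.d. uniform in `[-scale, scale]` (small
#' random values) from the current R random stream and sets the per-class
#' initial states to zero, from where training moves them apart under the
#' distance prior.
#'
#' @param config a [network_config()].
#' @param n_classes number of trajectory classes (rows of `initial_states`).
#' @param scale half-width of the uniform initialization interval.
#' @return A list of class `sctrnn_weights` with matrices `W_inp` (C x I),
#'   `W_rec` (C x C), `W_out` (O x C), `W_var` (O x C) and `initial_states`
#'   (`n_classes` x C).
#' @export
init_weights <- function(config, n_classes, scale = 0.025) {
  C <- config$context_size
  I <- config$input_size
  O <- config$output_size
  u <- function(r, c) matrix(runif(r * c, -scale, scale), r, c)
  structure(list(W_inp = u(C, I), W_rec = u(C, C), W_out = u(O, C),
                 W_var = u(O, C),
                 initial_states = matrix(0, n_classes, C)),
            class = "sctrnn_weights")
}

check_weight_dims <- function(weights, config) {
  C <- config$context_size
  if (!identical(dim(weights$W_rec), c(C, C)) ||
      nrow(weights$W_inp) != C || ncol(weights$W_inp) != config$input_size ||
      ncol(weights$W_out) != C || nrow(weights$W_out) != config$output_size ||
      ncol(weights$W_var) != C || ncol(weights$initial_states) != C)
    stop("weight dimensions are inconsistent with the network configuration")
  invisible(TRUE)
}

#' One leaky-integrator update of the recurrent layer
#'
#' `u_rec <- (1 - 1/tau) * u_rec_prev + (1/tau) * (W_inp x + W_rec h_prev)`,
#' followed by `h <- tanh(u_rec)`.
#'
#' @param prev_state list with elements `u_rec` and `h` (length-C vectors).
#' @param x_in input vector of length `input_size`.
#' @param weights an [init_weights()] object.
#' @param config a [network_config()].
#' @return The updated state list.
#' @export
recurrent_step <- function(prev_state, x_in, weights, config) {
  if (length(x_in) != config$input_size ||
      length(prev_state$u_rec) != config$context_size)
    stop("dimension mismatch between state/input and configuration")
  leak <- 1 - 1 / config$tau
  u <- leak * prev_state$u_rec +
    (1 / config$tau) * drop(weights$W_inp %*% x_in +
                            weights$W_rec %*% prev_state$h)
  list(u_rec = u, h = tanh(u))
}

#' Mean and variance readout
#'
#' The predicted mean is `y = tanh(W_out h)`; the predicted variance is
#' `v = exp(W_var h + K) + variance_floor`, so `K` shifts the estimated
#' log-variance uniformly and the floor keeps `v` strictly positive.
#'
#' @param state a state list with element `h`.
#' @inheritParams recurrent_step
#' @return A list with vectors `y` and `v`.
#' @export
readout <- function(state, weights, config) {
  u_out <- drop(weights$W_out %*% state$h)
  u_var <- drop(weights$W_var %*% state$h)
  list(y = tanh(u_out),
       v = exp(u_var + config$K) + config$variance_floor)
}

#' Integrate sensory input with the network's own prediction
#'
#' The integrated input mixes the raw next input with the previous-step
#' prediction: `x' = chi * x_next + (1 - chi) * (y + nu)` with
#' `nu ~ N(0, v)` componentwise (placement `"prediction"`, the default), or
#' `x' = chi * x_next + (1 - chi) * y + nu` (placement `"literal"`).  With
#' `noise = FALSE` the perturbation `nu` is zero.
#'
#' @param x_next raw input vector for the next step.
#' @param y,v predicted mean and variance from the previous step.
#' @param chi mixing coefficient in \[0, 1\]; 1 = purely sensory (open
#'   loop), 0 = purely prior (closed loop).
#' @param noise logical; sample the Gaussian perturbation?
#' @param placement `"prediction"` or `"literal"` (see above).
#' @return The integrated input vector.
#' @export
integrate_input <- function(x_next, y, v, chi, noise = TRUE,
                            placement = c("prediction", "literal")) {
  placement <- match.arg(placement)
  if (!is.numeric(chi) || length(chi) != 1L || chi < 0 || chi > 1)
    stop("'chi' must be a single number in [0, 1]")
  if (length(x_next) != length(y))
    stop("input and prediction dimensionality differ")
  nu <- if (noise) rnorm(length(y), sd = sqrt(v)) else 0
  if (placement == "prediction")
    chi * x_next + (1 - chi) * (y + nu)
  else
    chi * x_next + (1 - chi) * y + nu
}

#' Run the network over a driving sequence
#'
#' Starts from the learned initial state of `class_id` and consumes, at each
#' step, the integrated input built from the driving point and the previous
#' step's prediction.  The first point is fed raw (no prediction exists at
#' t = 0).  With `chi = 1` and `noise = FALSE` this is deterministic
#' open-loop (reactive) processing.
#'
#' @param weights an [init_weights()]-style weight set.
#' @param config a [network_config()].
#' @param class_id which row of `initial_states` to start from.
#' @param driving T x `input_size` matrix of raw input points.
#' @param chi mixing coefficient (defaults to `config$chi_train`).
#' @param noise logical; sample prediction noise in the integrated input.
#' @return A list of class `forward_trace` with `x_in` (T x I integrated
#'   inputs), `h` (C x T context activations), `y`, `v` (T x O predicted
#'   means/variances) and `h0` (activation of the initial state).
#' @export
forward_sequence <- function(weights, config, class_id, driving,
                             chi = config$chi_train, noise = TRUE) {
  check_weight_dims(weights, config)
  driving <- as.matrix(driving)
  if (class_id < 1L || class_id > nrow(weights$initial_states))
    stop("'class_id' is out of range")
  if (!is.numeric(chi) || chi < 0 || chi > 1)
    stop("'chi' must lie in [0, 1]")
  X <- array(t(driving), dim = c(ncol(driving), 1L, nrow(driving)))
  res <- .sctrnn_forward_cpp(X, matrix(weights$initial_states[class_id, ]),
                             weights$W_inp, weights$W_rec, weights$W_out,
                             weights$W_var, config$tau, chi, config$K,
                             config$variance_floor,
                             noise && (chi < 1 ||
                                       config$noise_placement == "literal"),
                             config$noise_placement == "literal")
  structure(list(x_in = t(res$x_in[, 1L, ]), h = res$h[, 1L, ],
                 y = t(res$y[, 1L, ]), v = t(res$v[, 1L, ]),
                 h0 = drop(res$h0)),
            class = "forward_trace")
}

#' @export
print.forward_trace <- function(x, ...) {
  cat("S-CTRNN forward trace:", nrow(x$y), "steps,",
      nrow(x$h), "context neurons\n")
  invisible(x)
}
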