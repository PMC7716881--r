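#' Gaussian negative log-likelihood of a forward trace
#'
#' For every step t of the trace, the predicted mean `y_t` and variance
#' `v_t` are scored against the corresponding target row:
#' `sum_t sum_i [ ln(2 pi v_{t,i}) + (target_{t,i} - y_{t,i})^2 / (2 v_{t,i}) ]`.
#' During training the target of step t is the integrated input of step
#' t + 1, so callers align the trace and targets accordingly (see
#' [shifted_targets()]).
#'
#' @param trace a [forward_sequence()] trace, or any list with matrices `y`
#'   and `v` (steps x dimensions).
#' @param targets numeric matrix with as many rows as the trace has steps.
#' @return The summed negative log-likelihood (a single number).
#' @export
sequence_nll <- function(trace, targets) {
  y <- as.matrix(trace$y)
  v <- as.matrix(trace$v)
  targets <- as.matrix(targets)
  if (!identical(dim(y), dim(targets)))
    stop("trace and targets have different lengths or dimensionality")
  sum(log(2 * pi * v) + (targets - y)^2 / (2 * v))
}

#' Pair each trace step with the next integrated input
#'
#' Helper producing the (trace, target) alignment used by the training
#' loss: step t predicts the integrated input of step t + 1, so the last
#' step has no target and is dropped.
#'
#' @param trace a `forward_trace`.
#' @return A list with the trimmed `trace` (steps 1..T-1) and `targets`
#'   (integrated inputs 2..T).
#' @export
shifted_targets <- function(trace) {
  T_ <- nrow(trace$y)
  list(trace = list(y = trace$y[-T_, , drop = FALSE],
                    v = trace$v[-T_, , drop = FALSE]),
       targets = trace$x_in[-1L, , drop = FALSE])
}

#' Distance prior over the per-class initial states
#'
#' Gaussian likelihood that keeps the initial states at a controlled spread
#' around their componentwise mean:
#' `sum_s sum_i [ ln(2 pi v_dist) + (u0_si - mean_i)^2 / (2 v_dist) ]`.
#' The mean is recomputed from the current states, so the value is invariant
#' under a common translation of all states.
#'
#' @param initial_states S x C matrix (one row per class).
#' @param v_dist prior variance.
#' @return The summed negative log-likelihood.
#' @export
initial_state_nll <- function(initial_states, v_dist) {
  initial_states <- as.matrix(initial_states)
  if (v_dist <= 0) stop("'v_dist' must be positive")
  center <- colMeans(initial_states)
  dev <- sweep(initial_states, 2L, center)
  length(initial_states) * log(2 * pi * v_dist) + sum(dev^2) / (2 * v_dist)
}

#' Training control parameters
#'
#' @param max_epochs maximum number of training epochs.
#' @param check_interval convergence is assessed every this many epochs.
#' @param window number of epochs over which mean and standard deviation of
#'   the per-element loss are computed for the convergence rule.
#' @param mean_improve_threshold training stops when the windowed mean loss
#'   improves by less than this ...
#' @param std_threshold ... and fluctuates (sd) by less than this.
#' @param learning_rate,beta1,beta2,adam_eps Adam optimizer settings.
#' @return A list of class `training_control`.
#' @export
training_control <- function(max_epochs = 30000L, check_interval = 100L,
                             window = 500L, mean_improve_threshold = 0.001,
                             std_threshold = 0.05, learning_rate = 0.001,
                             beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  max_epochs <- as.integer(max_epochs)
  check_interval <- as.integer(check_interval)
  window <- as.integer(window)
  if (window < check_interval)
    stop("'window' must be at least 'check_interval'")
  if (learning_rate <= 0) stop("'learning_rate' must be positive")
  structure(list(max_epochs = max_epochs, check_interval = check_interval,
                 window = window,
                 mean_improve_threshold = mean_improve_threshold,
                 std_threshold = std_threshold,
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps),
            class = "training_control")
}

#' Convergence rule on a training loss history
#'
#' Compares the mean loss (batch-mean NLL per sequence) over the most recent
#' `window` epochs
#' with the mean over the window before: training has converged when the
#' improvement is below `mean_improve_threshold` and the fluctuation
#' (standard deviation over the last window) is below `std_threshold`.
#' With fewer than two full windows of history the answer is `FALSE`.
#'
#' @param nll_history numeric vector of per-epoch mean losses (or a
#'   `TrainingLog`-style data frame with column `nll`).
#' @param control a [training_control()].
#' @return `TRUE` or `FALSE`.
#' @export
check_convergence <- function(nll_history, control = training_control()) {
  if (is.data.frame(nll_history)) nll_history <- nll_history$nll
  w <- control$window
  n <- length(nll_history)
  if (n < 2L * w) return(FALSE)
  cur <- nll_history[(n - w + 1L):n]
  prev <- nll_history[(n - 2L * w + 1L):(n - w)]
  (mean(prev) - mean(cur)) < control$mean_improve_threshold &&
    sd(cur) < control$std_threshold
}
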