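#' Fit an S-CTRNN to a set of drawing trajectories
#'
#' Trains all connection weights and the per-class initial states by
#' minimizing the joint negative log-likelihood: the heteroscedastic
#' Gaussian prediction loss of each step's (mean, variance) readout against
#' the integrated input of the next step, plus the distance prior over the
#' initial states.  Optimization uses Adam on the full batch (all noisy
#' realizations of all classes) each epoch, and stops when the convergence
#' rule of [check_convergence()] fires or `control$max_epochs` is reached.
#'
#' The developmental parameters act during learning: `chi_train` mixes raw
#' sensory input with the network's own previous prediction at the input
#' layer (plus Gaussian noise of the predicted variance), and `K` offsets
#' the estimated log-variance, down-weighting (`K > 0`) or exaggerating
#' (`K < 0`) the precision-weighted prediction error.
#'
#' @param dataset a [build_dataset()] trajectory set.
#' @param config a [network_config()]; its `chi_train` and `K` define the
#'   learning condition.
#' @param control a [training_control()].
#' @param weights optional starting weights from [init_weights()] (e.g. to
#'   share one initialization across conditions); drawn fresh from the
#'   current RNG when `NULL`.
#' @return An object of class `sctrnn` with elements `weights`, `config`,
#'   `control`, `log` (data frame `epoch`, `nll`: batch-mean prediction NLL
#'   per sequence, the quantity the convergence rule watches), `epochs`,
#'   `converged`, `dataset` and `reference` (the
#'   first noisy realization of every class, the evaluation reference).
#' @examples
#' set.seed(42)
#' ts <- build_dataset(default_shape_specs(), repeats = 2)
#' fit <- sctrnn_fit(ts, config = network_config(context_size = 10),
#'                   control = training_control(max_epochs = 20))
#' fit$epochs
#' @export
sctrnn_fit <- function(dataset, config = network_config(),
                       control = training_control(), weights = NULL) {
  stopifnot(inherits(dataset, "trajectory_set"))
  n_classes <- length(dataset$clean)
  if (is.null(weights)) weights <- init_weights(config, n_classes)
  if (nrow(weights$initial_states) != n_classes)
    stop("'weights$initial_states' must have one row per trajectory class")
  check_weight_dims(weights, config)

  seqs <- list()
  cls <- integer(0)
  for (k in seq_len(n_classes)) {
    for (r in seq_along(dataset$noisy[[k]])) {
      seqs[[length(seqs) + 1L]] <- dataset$noisy[[k]][[r]]
      cls <- c(cls, k)
    }
  }
  T_ <- nrow(seqs[[1]])
  X <- array(0, dim = c(config$input_size, length(seqs), T_))
  for (n in seq_along(seqs)) X[, n, ] <- t(seqs[[n]])

  res <- .sctrnn_train_cpp(X, cls - 1L,
                           weights$W_inp, weights$W_rec, weights$W_out,
                           weights$W_var, t(weights$initial_states),
                           config$tau, config$chi_train, config$K,
                           config$variance_floor, config$v_dist,
                           config$noise_placement == "literal",
                           control$max_epochs, control$check_interval,
                           control$window, control$mean_improve_threshold,
                           control$std_threshold, control$learning_rate,
                           control$beta1, control$beta2, control$adam_eps)

  trained <- structure(list(W_inp = res$W_inp, W_rec = res$W_rec,
                            W_out = res$W_out, W_var = res$W_var,
                            initial_states = t(res$initial_states)),
                       class = "sctrnn_weights")
  structure(list(weights = trained, config = config, control = control,
                 log = data.frame(epoch = seq_along(res$nll),
                                  nll = res$nll),
                 epochs = res$epochs, converged = res$converged,
                 dataset = dataset,
                 reference = lapply(dataset$noisy, `[[`, 1L),
                 call = match.call()),
            class = "sctrnn")
}

#' Analytic loss gradients for one batch
#'
#' Computes the gradients of the joint training loss with respect to all
#' weight matrices and the initial states, without performing an update.
#' Integrated inputs and likelihood targets are treated as data (no
#' gradient flows through the input-mixing path), so with `noise = FALSE`
#' the gradients are exactly those of the deterministic loss and can be
#' verified against finite differences.
#'
#' @param weights,config as in [sctrnn_fit()].
#' @param sequences list of T x I driving matrices.
#' @param classes integer class index per sequence.
#' @param noise sample prediction noise in the integrated inputs?
#' @param init_prior include the initial-state distance prior?
#' @return A list with the loss components `nll_output`, `nll_init` and
#'   gradient matrices named like the weights.
#' @export
sctrnn_gradients <- function(weights, config, sequences, classes,
                             noise = FALSE, init_prior = TRUE) {
  T_ <- nrow(sequences[[1]])
  X <- array(0, dim = c(config$input_size, length(sequences), T_))
  for (n in seq_along(sequences)) X[, n, ] <- t(sequences[[n]])
  res <- .sctrnn_grads_cpp(X, as.integer(classes) - 1L,
                           weights$W_inp, weights$W_rec, weights$W_out,
                           weights$W_var, t(weights$initial_states),
                           config$tau, config$chi_train, config$K,
                           config$variance_floor, config$v_dist,
                           noise, config$noise_placement == "literal",
                           init_prior)
  res$initial_states <- t(res$initial_states)
  res
}

#' @export
print.sctrnn <- function(x, ...) {
  cat("S-CTRNN fit:", length(x$dataset$clean), "classes,",
      x$config$context_size, "context neurons\n")
  cat(sprintf("  chi_train = %g, K = %g\n", x$config$chi_train, x$config$K))
  cat(sprintf("  %d epochs (%s), final per-sequence NLL %.4f\n", x$epochs,
              if (isTRUE(x$converged)) "converged" else "epoch cap reached",
              x$log$nll[nrow(x$log)]))
  invisible(x)
}

#' @export
summary.sctrnn <- function(object, ...) {
  gen <- lapply(seq_along(object$dataset$clean), function(k)
    closed_loop_generate(object, k)$trajectory)
  mse <- vapply(seq_along(gen), function(k)
    prediction_mse(gen[[k]], object$reference[[k]]), numeric(1))
  out <- list(fit = object,
              per_class = data.frame(
                class = seq_along(gen),
                shape = object$dataset$specs$shape,
                position = object$dataset$specs$position,
                closed_loop_mse = mse),
              mean_mse = mean(mse))
  class(out) <- "summary.sctrnn"
  out
}

#' @export
print.summary.sctrnn <- function(x, ...) {
  print(x$fit)
  cat("\nClosed-loop reproduction error per class (vs first training",
      "realization):\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("\nMean closed-loop MSE: %.5f (noise floor of the default",
              x$mean_mse), "task: 0.004)\n")
  invisible(x)
}

#' @export
coef.sctrnn <- function(object, ...) object$weights

#' Generate trajectories from a fitted network
#'
#' `type = "closed"` performs proactive (closed-loop) generation: starting
#' from the learned initial state, the network's own predicted mean is fed
#' back as input.  `type = "open"` performs reactive one-step prediction
#' driven by `newdata` (default: the class's first training realization).
#'
#' @param object a fitted [sctrnn_fit()] model.
#' @param class_id trajectory class (row of the learned initial states).
#' @param type `"closed"` or `"open"`.
#' @param newdata driving sequence for open-loop prediction.
#' @param T number of generated steps (closed loop).
#' @param ... unused.
#' @return A T x 2 matrix of predicted means.
#' @export
predict.sctrnn <- function(object, class_id = 1L,
                           type = c("closed", "open"), newdata = NULL,
                           T = NULL, ...) {
  type <- match.arg(type)
  if (type == "closed") {
    if (is.null(T)) T <- nrow(object$dataset$clean[[1]])
    closed_loop_generate(object, class_id, T)$trajectory
  } else {
    if (is.null(newdata)) newdata <- object$reference[[class_id]]
    tr <- forward_sequence(object$weights, object$config, class_id,
                           newdata, chi = 1, noise = FALSE)
    tr$y
  }
}

#' @export
residuals.sctrnn <- function(object, ...) {
  lapply(seq_along(object$reference), function(k) {
    target <- object$reference[[k]]
    yhat <- predict(object, k, type = "open", newdata = target)
    T_ <- nrow(target)
    target[-1L, , drop = FALSE] - yhat[-T_, , drop = FALSE]
  })
}

#' Simulate noisy trajectories from a fitted network
#'
#' Runs closed-loop generation and adds Gaussian observation noise drawn
#' from the network's own predicted variance at every step -- the model's
#' account of what a noisy sensory observation of its drawing would look
#' like.
#'
#' @param object a fitted `sctrnn` model.
#' @param nsim number of simulated trajectories.
#' @param seed optional seed passed to [set.seed()].
#' @param class_id trajectory class.
#' @param T number of steps.
#' @param ... unused.
#' @return A list of `nsim` T x 2 matrices.
#' @export
simulate.sctrnn <- function(object, nsim = 1, seed = NULL, class_id = 1L,
                            T = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(T)) T <- nrow(object$dataset$clean[[1]])
  gen <- closed_loop_generate(object, class_id, T)
  lapply(seq_len(nsim), function(i)
    gen$trajectory + matrix(rnorm(length(gen$trajectory),
                                  sd = sqrt(as.vector(gen$variances))),
                            nrow = T))
}

#' @export
plot.sctrnn <- function(x, which = c("trajectories", "pca", "loss"), ...) {
  which <- match.arg(which)
  k <- length(x$dataset$clean)
  cols <- grDevices::hcl.colors(k, "Dark 3")
  if (which == "trajectories") {
    graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                   xlab = "x", ylab = "y",
                   main = "Closed-loop generation (lines) vs clean shapes")
    for (i in seq_len(k)) {
      graphics::points(x$dataset$clean[[i]], col = cols[i], pch = 16,
                       cex = 0.3)
      graphics::lines(closed_loop_generate(x, i)$trajectory, col = cols[i])
    }
  } else if (which == "pca") {
    acts <- lapply(seq_len(k), function(i)
      closed_loop_generate(x, i)$activations)
    emb <- pca_embed(acts)
    graphics::plot(emb$coords, col = rep(cols, each = ncol(acts[[1]])),
                   pch = 16, cex = 0.4, xlab = "PC1", ylab = "PC2",
                   main = sprintf("Context activations (PC1+2: %.0f%%)",
                                  100 * sum(emb$pc_explained[1:2])))
  } else {
    graphics::plot(x$log$epoch, x$log$nll, type = "l", xlab = "epoch",
                   ylab = "mean NLL per element", main = "Training loss")
  }
  invisible(x)
}
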