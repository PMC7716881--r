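# Deterministic seed fan-out: one master seed yields per-(trial, role,
# condition) sub-seeds.  Weight-initialization and dataset seeds depend only
# on the trial, so every parameter condition of a trial starts from the same
# initial weights and the same noisy dataset; the prediction-noise stream
# differs per condition.
derive_seed <- function(master, trial, role, cond = 0L) {
  role_id <- match(role, c("data", "weights", "noise", "infer"))
  as.integer((as.double(master) * 100003 + trial * 1009 +
                role_id * 101 + cond * 7919) %% 2147483647)
}

#' Configuration of a parameter-sweep experiment
#'
#' Describes one sweep over the external-contribution parameter (`chi`,
#' holding K = 0) or the aberrant-precision parameter (`K`, holding
#' chi_train = 1), with a number of independent trials per condition that
#' share initial weights across conditions.
#'
#' @param sweep `"chi"` or `"K"`.
#' @param chi_grid,K_grid parameter values of the sweep that is active.
#' @param n_trials independently initialized networks per condition.
#' @param holdout_class class left out of training (generalization
#'   experiment); `NULL` trains on all classes.
#' @param scale_factor multiplies the full-scale epoch budgets (30000
#'   training epochs, 5000 inference epochs) for desk-scale runs.
#' @param repeats noisy realizations per class in the training batch.
#' @param context_size recurrent layer size.
#' @param master_seed seed from which all per-trial seeds are derived.
#' @param learning_rate Adam step size used for every run of the sweep.
#' @param resample_data draw a fresh noisy dataset per trial (`TRUE`) or
#'   share one dataset across trials (`FALSE`, default `TRUE`).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(sweep = c("chi", "K"),
                              chi_grid = seq(0.1, 1, by = 0.1),
                              K_grid = c(-8, -4, -2, 0, 2, 4, 8),
                              n_trials = 10L, holdout_class = NULL,
                              scale_factor = 1, repeats = 50L,
                              context_size = 70L, master_seed = 1L,
                              learning_rate = 0.001, resample_data = TRUE) {
  sweep <- match.arg(sweep)
  if (scale_factor <= 0 || scale_factor > 1)
    stop("'scale_factor' must be in (0, 1]")
  structure(list(sweep = sweep, chi_grid = chi_grid, K_grid = K_grid,
                 n_trials = as.integer(n_trials),
                 holdout_class = holdout_class,
                 scale_factor = scale_factor, repeats = as.integer(repeats),
                 context_size = as.integer(context_size),
                 master_seed = as.integer(master_seed),
                 learning_rate = learning_rate,
                 max_epochs = max(200L, as.integer(round(30000 * scale_factor))),
                 infer_epochs = max(100L, as.integer(round(5000 * scale_factor))),
                 resample_data = isTRUE(resample_data)),
            class = "experiment_config")
}

conditions_of <- function(config) {
  if (config$sweep == "chi")
    data.frame(chi = config$chi_grid, K = 0)
  else
    data.frame(chi = 1, K = config$K_grid)
}

# train one (condition, trial) cell under the shared-seed scheme
train_cell <- function(config, cond_idx, trial, chi, K, n_classes_keep) {
  set.seed(derive_seed(config$master_seed,
                       if (config$resample_data) trial else 1L, "data"))
  dataset <- build_dataset(default_shape_specs(), repeats = config$repeats)
  if (!is.null(n_classes_keep))
    dataset <- subset_classes(dataset, n_classes_keep)
  net <- network_config(context_size = config$context_size,
                        chi_train = chi, K = K)
  set.seed(derive_seed(config$master_seed, trial, "weights"))
  w <- init_weights(net, length(dataset$clean))
  ctrl <- training_control(max_epochs = config$max_epochs,
                           learning_rate = config$learning_rate)
  set.seed(derive_seed(config$master_seed, trial, "noise", cond_idx))
  fit <- sctrnn_fit(dataset, config = net, control = ctrl, weights = w)
  fit
}

evaluate_representation <- function(fit) {
  k <- length(fit$dataset$clean)
  gens <- lapply(seq_len(k), function(i)
    closed_loop_generate(fit, i, T = nrow(fit$dataset$clean[[1]])))
  mse <- mean(vapply(seq_len(k), function(i)
    prediction_mse(gens[[i]]$trajectory, fit$reference[[i]]), numeric(1)))
  acts <- lapply(gens, `[[`, "activations")
  rep_m <- inner_outer(acts, fit$dataset$position_labels)
  emb <- pca_embed(acts)
  list(mse = mse, metrics = rep_m,
       pc_top2 = sum(emb$pc_explained[1:2]), activations = acts)
}

#' Experiment 1: behavior versus internal representation
#'
#' Trains `n_trials` networks per parameter condition on all eight
#' trajectory classes, then evaluates for each network the closed-loop
#' reproduction error (behavior), the DTW inner/outer distances and their
#' quotient (representation quality) and the PCA explained variance of the
#' context activations.  Diverged runs are recorded as failed and excluded
#' from the aggregates.
#'
#' @param config an [experiment_config()] without `holdout_class`.
#' @return An object of class `sctrnn_experiment` with per-cell `results`,
#'   condition-level `summary` and the `config`.
#' @export
run_experiment1 <- function(config = experiment_config()) {
  if (!is.null(config$holdout_class))
    stop("experiment 1 trains on all classes; use run_experiment2() for ",
         "the holdout design")
  conds <- conditions_of(config)
  rows <- list()
  for (ci in seq_len(nrow(conds))) {
    for (trial in seq_len(config$n_trials)) {
      row <- data.frame(chi = conds$chi[ci], K = conds$K[ci], trial = trial,
                        epochs = NA_integer_, converged = NA,
                        mse = NA_real_, inner = NA_real_, outer = NA_real_,
                        quotient = NA_real_, pc_top2 = NA_real_,
                        failed = FALSE)
      res <- tryCatch({
        fit <- train_cell(config, ci, trial, conds$chi[ci], conds$K[ci],
                          NULL)
        ev <- evaluate_representation(fit)
        row$epochs <- fit$epochs
        row$converged <- fit$converged
        row$mse <- ev$mse
        row$inner <- ev$metrics$inner_distance
        row$outer <- ev$metrics$outer_distance
        row$quotient <- ev$metrics$inner_outer_quotient
        row$pc_top2 <- ev$pc_top2
        row
      }, error = function(e) {
        row$failed <- TRUE
        attr(row, "message") <- conditionMessage(e)
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  results <- do.call(rbind, rows)
  new_experiment(results, config,
                 c("epochs", "mse", "inner", "outer", "quotient", "pc_top2"))
}

#' Experiment 2: generalization to a held-out trajectory
#'
#' Trains each network on seven of the eight classes (by default the
#' figure-eight at the bottom position is held out).  For every class --
#' trained and untrained alike -- an initial state is inferred from the
#' clean target with frozen weights, and the reactive (open-loop) one-step
#' prediction error from that state measures how well the network can
#' recognize and reproduce the trajectory.  The untrained-class error is
#' the generalization measure; representation quality is computed on the
#' trained classes, and the per-network Pearson correlation between the two
#' is reported.
#'
#' @param config an [experiment_config()]; `holdout_class` defaults to 8
#'   (bottom figure-eight).
#' @return An `sctrnn_experiment`; `results` additionally holds
#'   `trained_error` and `untrained_error`, and the object carries
#'   `correlation` (quotient vs untrained error across all networks).
#' @export
run_experiment2 <- function(config = experiment_config()) {
  holdout <- if (is.null(config$holdout_class)) 8L
             else as.integer(config$holdout_class)
  keep <- setdiff(1:8, holdout)
  conds <- conditions_of(config)
  rows <- list()
  for (ci in seq_len(nrow(conds))) {
    for (trial in seq_len(config$n_trials)) {
      row <- data.frame(chi = conds$chi[ci], K = conds$K[ci], trial = trial,
                        epochs = NA_integer_, converged = NA,
                        quotient = NA_real_, trained_error = NA_real_,
                        untrained_error = NA_real_, failed = FALSE)
      res <- tryCatch({
        fit <- train_cell(config, ci, trial, conds$chi[ci], conds$K[ci],
                          keep)
        ev <- evaluate_representation(fit)
        # recognize all eight clean targets by initial-state inference
        full_clean <- lapply(seq_len(nrow(default_shape_specs())),
                             function(i) make_shape(default_shape_specs()[i, ]))
        set.seed(derive_seed(config$master_seed, trial, "infer", ci))
        inf <- infer_initial_state(fit, full_clean,
                                   epochs = config$infer_epochs)
        errs <- vapply(1:8, function(i)
          reactive_error(fit, inf$state[, i], full_clean[[i]]), numeric(1))
        row$epochs <- fit$epochs
        row$converged <- fit$converged
        row$quotient <- ev$metrics$inner_outer_quotient
        row$trained_error <- mean(errs[keep])
        row$untrained_error <- errs[holdout]
        row
      }, error = function(e) {
        row$failed <- TRUE
        attr(row, "message") <- conditionMessage(e)
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  results <- do.call(rbind, rows)
  out <- new_experiment(results, config,
                        c("epochs", "quotient", "trained_error",
                          "untrained_error"))
  ok <- !results$failed
  if (sum(ok) >= 3L && sd(results$quotient[ok]) > 0)
    out$correlation <- quality_generalization_correlation(
      results$quotient[ok], results$untrained_error[ok])
  out
}

new_experiment <- function(results, config, measures) {
  ok <- results[!results$failed, , drop = FALSE]
  key <- interaction(ok$chi, ok$K, drop = TRUE)
  agg <- do.call(rbind, lapply(split(ok, key), function(d) {
    s <- data.frame(chi = d$chi[1L], K = d$K[1L], n = nrow(d))
    for (m in measures) {
      s[[paste0(m, "_mean")]] <- mean(d[[m]])
      s[[paste0(m, "_sd")]] <- if (nrow(d) > 1L) sd(d[[m]]) else NA_real_
    }
    s
  }))
  agg <- agg[order(agg$chi, agg$K), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(results = results, summary = agg, config = config),
            class = "sctrnn_experiment")
}

#' @export
print.sctrnn_experiment <- function(x, ...) {
  cat("S-CTRNN sweep over", x$config$sweep, "--", nrow(x$results),
      "runs (", sum(x$results$failed), "failed )\n")
  print(x$summary, row.names = FALSE, digits = 4)
  if (!is.null(x$correlation))
    cat(sprintf("quotient vs generalization error: r = %.3f (p = %.3f)\n",
                x$correlation$r, x$correlation$p))
  invisible(x)
}
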