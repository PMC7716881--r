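# one shared trained model for the generation/inference tests: two
# well-separated classes, moderate size, open-loop learning
trained_model <- local({
  set.seed(61)
  ts <- build_dataset(default_shape_specs()[c(1, 2), ], repeats = 4)
  cfg <- network_config(context_size = 25)
  sctrnn_fit(ts, config = cfg,
             control = training_control(max_epochs = 4000))
})

test_that("closed-loop generation is deterministic and bounded", {
  g1 <- closed_loop_generate(trained_model, 1)
  g2 <- closed_loop_generate(trained_model, 1)
  expect_identical(g1, g2)
  expect_equal(dim(g1$activations),
               c(trained_model$config$context_size, 75L))
  expect_equal(dim(g1$trajectory), c(75L, 2L))
  expect_true(all(abs(g1$trajectory) < 1))
  expect_error(closed_loop_generate(trained_model, 5), "initial states")
  # untrained random weights still give bounded output
  set.seed(62)
  cfg <- network_config(context_size = 12)
  w <- tiny_weights(cfg, 1, sd = 2)
  g3 <- closed_loop_generate(w, 1, T = 30, config = cfg)
  expect_true(all(abs(g3$trajectory) < 1))
})

test_that("closed-loop reproduction of a trained class reaches the noise floor", {
  g <- closed_loop_generate(trained_model, 1)
  mse <- prediction_mse(g$trajectory, trained_model$reference[[1]])
  # class 1 noise variance is 0.001; a converged network should be within
  # a small multiple of it
  expect_lt(mse, 0.005)
})

test_that("closed-loop generation settles toward a periodic orbit", {
  g <- closed_loop_generate(trained_model, 2)
  cyc <- function(i) g$trajectory[(25 * (i - 1) + 1):(25 * i), ]
  d12 <- prediction_mse(cyc(1), cyc(2))
  d23 <- prediction_mse(cyc(2), cyc(3))
  expect_lte(d23, d12)
})

test_that("inference with zero epochs returns the mean initial state", {
  target <- trained_model$dataset$clean[[1]]
  out <- infer_initial_state(trained_model, target, epochs = 0)
  expect_equal(out$state, colMeans(trained_model$weights$initial_states))
})

test_that("initial-state inference recovers a trained trajectory", {
  target <- trained_model$dataset$clean[[1]]
  inf <- infer_initial_state(trained_model, target, epochs = 600)
  err_inferred <- reactive_error(trained_model, inf$state, target)
  err_mean <- reactive_error(trained_model,
                             colMeans(trained_model$weights$initial_states),
                             target)
  # inference improves markedly on its uninformed starting point and ends
  # well below the task noise floor
  expect_lt(err_inferred, err_mean)
  expect_lt(err_inferred, 0.004)
  # inference loss trends down
  expect_lt(mean(tail(inf$nll, 100)), mean(head(inf$nll, 100)))
})

test_that("different targets yield distinct inferred states", {
  t1 <- trained_model$dataset$clean[[1]]
  t2 <- trained_model$dataset$clean[[2]]
  inf <- infer_initial_state(trained_model, list(t1, t2), epochs = 300)
  expect_equal(dim(inf$state), c(25L, 2L))
  expect_gt(sqrt(sum((inf$state[, 1] - inf$state[, 2])^2)), 0.1)
})

test_that("reactive error is zero for a perfect copier on constant input", {
  # network tuned to output exactly 0.5 whenever its input is 0.5:
  # tau = 1, no recurrence, and W_out solves tanh(m tanh(10 * 0.5)) = 0.5
  cfg <- network_config(context_size = 2, tau = 1)
  w <- init_weights(cfg, 1)
  w$W_rec[] <- 0
  w$W_inp <- diag(2) * 10
  w$W_out <- diag(2) * atanh(0.5) / tanh(5)
  const <- matrix(0.5, 20, 2)
  err <- reactive_error(w, rep(0, 2), const, config = cfg)
  expect_lt(err, 1e-12)
})

test_that("reactive error is invariant to permuting context neurons", {
  set.seed(63)
  cfg <- network_config(context_size = 7)
  w <- tiny_weights(cfg, 1)
  target <- make_shape(shape_spec("ellipse", "top", 0))
  e0 <- reactive_error(w, w$initial_states[1, ], target, config = cfg)
  p <- sample(7)
  wp <- w
  wp$W_inp <- w$W_inp[p, ]
  wp$W_rec <- w$W_rec[p, p]
  wp$W_out <- w$W_out[, p]
  wp$W_var <- w$W_var[, p]
  wp$initial_states <- w$initial_states[, p, drop = FALSE]
  ep <- reactive_error(wp, wp$initial_states[1, ], target, config = cfg)
  expect_equal(ep, e0, tolerance = 1e-12)
})

test_that("the fitted-model methods are coherent", {
  expect_s3_class(trained_model, "sctrnn")
  expect_output(print(trained_model), "S-CTRNN fit")
  w <- coef(trained_model)
  expect_s3_class(w, "sctrnn_weights")
  expect_equal(dim(w$W_rec), c(25L, 25L))
  # closed-loop predict equals the generator's trajectory
  expect_identical(predict(trained_model, 1, type = "closed"),
                   closed_loop_generate(trained_model, 1)$trajectory)
  # open-loop residuals have the one-step structure and a small magnitude
  r <- residuals(trained_model)
  expect_length(r, 2L)
  expect_equal(dim(r[[1]]), c(74L, 2L))
  expect_lt(mean(r[[1]]^2), 0.01)
  # simulate adds observation noise around the closed-loop trajectory
  sims <- simulate(trained_model, nsim = 2, seed = 64, class_id = 1)
  base <- closed_loop_generate(trained_model, 1)$trajectory
  expect_length(sims, 2L)
  expect_false(isTRUE(all.equal(sims[[1]], base)))
  expect_lt(prediction_mse(sims[[1]], base), 0.05)
  s <- summary(trained_model)
  expect_equal(nrow(s$per_class), 2L)
  expect_lt(s$mean_mse, 0.01)
})
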