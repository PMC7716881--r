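test_that("recurrent step implements the leaky integrator", {
  set.seed(21)
  cfg <- tiny_config(C = 4)
  w <- tiny_weights(cfg, 1)
  state <- list(u_rec = rnorm(4), h = tanh(rnorm(4)))
  x <- rnorm(2)
  # tau = 1: leak term vanishes
  cfg1 <- tiny_config(C = 4, tau = 1)
  s1 <- recurrent_step(state, x, w, cfg1)
  expect_equal(s1$u_rec, drop(w$W_inp %*% x + w$W_rec %*% state$h))
  # zero weights, tau = 2: pure leak halves the state
  w0 <- w
  w0$W_inp[] <- 0; w0$W_rec[] <- 0
  s2 <- recurrent_step(list(u_rec = rep(1, 4), h = rep(0, 4)), c(0, 0),
                       w0, cfg)
  expect_equal(s2$u_rec, rep(0.5, 4))
  # zero input and state is a fixed point
  s3 <- recurrent_step(list(u_rec = rep(0, 4), h = rep(0, 4)), c(0, 0),
                       w0, cfg)
  expect_equal(s3$h, rep(0, 4))
  expect_error(recurrent_step(state, c(1, 2, 3), w, cfg), "mismatch")
})

test_that("readout gives tanh means and floored exponential variances", {
  cfg <- tiny_config(C = 3)
  w <- init_weights(cfg, 1)
  w$W_out[] <- 0
  w$W_var[] <- 0
  out <- readout(list(h = rep(0.5, 3)), w, cfg)
  expect_equal(out$y, c(0, 0))
  expect_equal(out$v, rep(1 + 1e-5, 2))
  cfg2 <- tiny_config(C = 3, K = 2)
  out2 <- readout(list(h = rep(0.5, 3)), w, cfg2)
  expect_equal(out2$v, rep(exp(2) + 1e-5, 2))
  # v is strictly positive even for strongly negative K
  cfg3 <- tiny_config(C = 3, K = -50)
  out3 <- readout(list(h = rep(0.5, 3)), w, cfg3)
  expect_true(all(out3$v > 0))
})

test_that("input integration interpolates between sensation and prediction", {
  expect_equal(integrate_input(c(0.2, 0.2), c(0.4, 0.4), c(1, 1), chi = 0.5,
                               noise = FALSE), c(0.3, 0.3))
  # chi = 1 reproduces the raw input regardless of prediction and variance
  set.seed(22)
  expect_equal(integrate_input(c(0.7, -0.2), c(0, 0), c(5, 5), chi = 1,
                               noise = TRUE), c(0.7, -0.2))
  # chi = 0 with no noise returns the prediction
  expect_equal(integrate_input(c(1, 1), c(0.4, -0.4), c(0.1, 0.1), chi = 0,
                               noise = FALSE), c(0.4, -0.4))
  expect_error(integrate_input(c(0, 0), c(0, 0), c(1, 1), chi = 1.2),
               "\\[0, 1\\]")
  # literal placement adds noise even at chi = 1
  set.seed(23)
  lit <- integrate_input(c(0.5, 0.5), c(0, 0), c(0.01, 0.01), chi = 1,
                         noise = TRUE, placement = "literal")
  expect_false(isTRUE(all.equal(lit, c(0.5, 0.5))))
})

test_that("forward_sequence agrees with stepwise R composition", {
  set.seed(24)
  cfg <- tiny_config(C = 6, chi = 0.6)
  w <- tiny_weights(cfg, 2)
  driving <- matrix(rnorm(20, sd = 0.3), 10, 2)
  tr <- forward_sequence(w, cfg, 2, driving, chi = 0.6, noise = FALSE)
  # reference composition in R: first input raw, then mixed with the
  # previous step's readout
  state <- list(u_rec = w$initial_states[2, ],
                h = tanh(w$initial_states[2, ]))
  xin <- driving[1, ]
  for (t in 1:10) {
    state <- recurrent_step(state, xin, w, cfg)
    out <- readout(state, w, cfg)
    expect_equal(tr$h[, t], state$h, tolerance = 1e-12)
    expect_equal(tr$y[t, ], out$y, tolerance = 1e-12)
    expect_equal(tr$v[t, ], out$v, tolerance = 1e-12)
    expect_equal(tr$x_in[t, ], xin, tolerance = 1e-12)
    if (t < 10)
      xin <- integrate_input(driving[t + 1, ], out$y, out$v, 0.6,
                             noise = FALSE)
  }
})

test_that("open-loop traces are deterministic and follow the driving input", {
  set.seed(25)
  cfg <- tiny_config(C = 8)
  w <- tiny_weights(cfg, 1)
  driving <- matrix(rnorm(30, sd = 0.2), 15, 2)
  tr1 <- forward_sequence(w, cfg, 1, driving, chi = 1, noise = FALSE)
  tr2 <- forward_sequence(w, cfg, 1, driving, chi = 1, noise = FALSE)
  expect_identical(tr1, tr2)
  expect_equal(tr1$x_in, driving, ignore_attr = TRUE)
  expect_equal(nrow(tr1$y), 15L)
  # identical seeds give identical stochastic traces
  set.seed(99)
  a <- forward_sequence(w, cfg, 1, driving, chi = 0.3, noise = TRUE)
  set.seed(99)
  b <- forward_sequence(w, cfg, 1, driving, chi = 0.3, noise = TRUE)
  expect_identical(a, b)
  expect_error(forward_sequence(w, cfg, 3, driving), "out of range")
})

test_that("raising K rescales predicted variances by exp(delta K)", {
  set.seed(26)
  w <- tiny_weights(tiny_config(C = 6), 1)
  driving <- matrix(rnorm(20, sd = 0.2), 10, 2)
  v0 <- forward_sequence(w, tiny_config(C = 6, K = 0), 1, driving,
                         chi = 1, noise = FALSE)$v
  v1 <- forward_sequence(w, tiny_config(C = 6, K = 1), 1, driving,
                         chi = 1, noise = FALSE)$v
  expect_equal(v1 - 1e-5, exp(1) * (v0 - 1e-5), tolerance = 1e-12)
  expect_true(all(v0 > 0) && all(v1 > 0))
})

test_that("weights serialize to text bit-exactly", {
  set.seed(27)
  cfg <- tiny_config(C = 7)
  w <- tiny_weights(cfg, 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_weights(w, f, config = cfg)
  w2 <- read_weights(f)
  for (nm in names(w))
    expect_identical(unname(w[[nm]]), unname(w2[[nm]]))
  expect_true(file.exists(paste0(f, ".json")))
})

test_that("configuration guards reject unusable parameters", {
  expect_error(network_config(tau = 0.5), "tau")
  expect_error(network_config(chi_train = 0.05), "chi_train")
  expect_error(network_config(chi_train = 0), "no learning")
  expect_error(network_config(v_dist = 0), "v_dist")
})
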