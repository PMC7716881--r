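test_that("the default task has 8 classes with the documented noise levels", {
  specs <- default_shape_specs()
  expect_equal(nrow(specs), 8L)
  expect_equal(sort(unique(specs$shape)), c("eight", "ellipse"))
  expect_equal(as.integer(table(specs$position)), rep(2L, 4))
  expect_equal(specs$noise_variance,
               c(0.001, 0.001, 0.003, 0.003, 0.005, 0.005, 0.007, 0.007))
  expect_equal(mean(specs$noise_variance), 0.004)
})

test_that("clean shapes are periodic, bounded and centered at their position", {
  specs <- default_shape_specs()
  for (i in seq_len(nrow(specs))) {
    tr <- make_shape(specs[i, ])
    expect_equal(dim(tr), c(75L, 2L))
    expect_true(all(abs(tr) < 1))
    # cycle-periodic: point t equals point t + 25
    expect_equal(tr[1:50, ], tr[26:75, ])
    center <- colMeans(tr[1:25, ])
    expected <- switch(specs$position[i],
                       right = c(0.5, 0), left = c(-0.5, 0),
                       top = c(0, 0.5), bottom = c(0, -0.5))
    expect_equal(center, expected, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("same-position shapes share a bounding-box center, positions differ", {
  specs <- default_shape_specs()
  centers <- t(vapply(seq_len(nrow(specs)), function(i) {
    tr <- make_shape(specs[i, ])
    (apply(tr, 2, max) + apply(tr, 2, min)) / 2
  }, numeric(2)))
  # discrete sampling shifts box extrema by up to one step, hence the
  # coarse tolerance
  for (pos in unique(specs$position)) {
    idx <- which(specs$position == pos)
    expect_lt(max(abs(centers[idx[1], ] - centers[idx[2], ])), 0.01)
  }
  pos_centers <- unique(round(centers, 1))
  expect_equal(nrow(pos_centers), 4L)
  expect_true(min(dist(pos_centers)) > 0.5)
})

test_that("the figure-eight crosses its center twice per cycle", {
  tr <- make_shape(shape_spec("eight", "top", 0))
  cyc <- sweep(tr[1:25, ], 2, c(0, 0.5))
  # the vertical coordinate changes sign exactly twice per cycle (one pass
  # through the crossing per lobe); the path comes close to the center
  flips <- sum(diff(sign(cyc[, 2])) != 0)
  expect_equal(flips, 2L)
  expect_lt(min(sqrt(rowSums(cyc^2))), 0.1)
})

test_that("make_shape rejects unknown shapes and positions", {
  expect_error(shape_spec("triangle", "right", 0.001))
  expect_error(shape_spec("ellipse", "center", 0.001))
  expect_error(shape_spec("ellipse", "right", -0.1), "non-negative")
  expect_error(shape_spec("ellipse", "right", 0.001, cycles = 4,
                          n_steps = 75), "divisible")
})

test_that("corrupt adds noise of the requested variance and respects seeds", {
  tr <- make_shape(shape_spec("ellipse", "left", 0))
  expect_identical(corrupt(tr, 0), tr)
  expect_error(corrupt(tr, -1), "non-negative")
  set.seed(5)
  a <- corrupt(tr, 0.003)
  set.seed(5)
  b <- corrupt(tr, 0.003)
  expect_identical(a, b)
  # empirical variance converges to the nominal one
  set.seed(6)
  devs <- replicate(2000, corrupt(tr, 0.003) - tr)
  expect_equal(mean(devs^2), 0.003, tolerance = 0.1)
})

test_that("build_dataset produces the right batch structure and labels", {
  set.seed(9)
  ts <- build_dataset(default_shape_specs(), repeats = 50)
  expect_equal(length(ts$clean), 8L)
  expect_equal(sum(lengths(ts$noisy)), 400L)  # 8 classes x 50 realizations
  expect_equal(as.integer(table(ts$position_labels)), rep(2L, 4))
  expect_error(build_dataset(default_shape_specs()[0, ], repeats = 1))
  expect_error(build_dataset(default_shape_specs(), repeats = 0))
  # zero-variance specs give noisy == clean
  specs0 <- default_shape_specs()
  specs0$noise_variance <- 0
  ts0 <- build_dataset(specs0, repeats = 1)
  expect_identical(ts0$noisy[[3]][[1]], ts0$clean[[3]])
})

test_that("trajectory sets round-trip through CSV", {
  set.seed(10)
  ts <- build_dataset(default_shape_specs()[1:2, ], repeats = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(ts, f)
  d <- read_trajectories(f)
  expect_equal(nrow(d), 2L * (1L + 2L) * 75L)
  clean1 <- d[d$class == 1 & d$realization == 0, c("x", "y")]
  expect_equal(as.matrix(clean1), ts$clean[[1]], ignore_attr = TRUE)
})

test_that("subset_classes keeps geometry and relabels", {
  set.seed(11)
  ts <- build_dataset(default_shape_specs(), repeats = 2)
  sub <- subset_classes(ts, c(2, 5))
  expect_equal(length(sub$clean), 2L)
  expect_identical(sub$clean[[2]], ts$clean[[5]])
  expect_equal(sub$position_labels, ts$specs$position[c(2, 5)])
  expect_error(subset_classes(ts, 9))
})
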