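#' Specification of one drawing shape
#'
#' A shape specification describes one of the trajectory classes of the
#' drawing task: an ellipse or a figure-eight, placed at one of four
#' positions of the two-dimensional task space, drawn for a given number of
#' cycles over a given number of time steps, and observed under additive
#' Gaussian sensory noise of a given variance.
#'
#' @param shape `"ellipse"` or `"eight"`.
#' @param position `"right"`, `"left"`, `"top"` or `"bottom"`.
#' @param noise_variance non-negative variance of the additive Gaussian
#'   observation noise, in squared task-space units.
#' @param cycles number of repetitions of the shape within one trajectory.
#' @param n_steps number of time steps of the trajectory; must be divisible
#'   by `cycles`.
#' @return A one-row data frame of class `shape_spec`.
#' @seealso [default_shape_specs()], [make_shape()]
#' @export
shape_spec <- function(shape, position, noise_variance, cycles = 3L,
                       n_steps = 75L) {
  shape <- match.arg(shape, c("ellipse", "eight"))
  position <- match.arg(position, c("right", "left", "top", "bottom"))
  if (!is.numeric(noise_variance) || length(noise_variance) != 1L ||
      noise_variance < 0)
    stop("'noise_variance' must be a single non-negative number")
  cycles <- as.integer(cycles)
  n_steps <- as.integer(n_steps)
  if (cycles < 1L || n_steps < 1L)
    stop("'cycles' and 'n_steps' must be positive integers")
  if (n_steps %% cycles != 0L)
    stop("'n_steps' must be divisible by 'cycles'")
  out <- data.frame(shape = shape, position = position,
                    noise_variance = noise_variance,
                    cycles = cycles, n_steps = n_steps,
                    stringsAsFactors = FALSE)
  class(out) <- c("shape_spec", class(out))
  out
}

#' The default eight-class drawing task
#'
#' Returns the eight shape specifications of the drawing task: ellipses and
#' figure-eights at the four positions right, left, top and bottom.  The
#' observation-noise variances are 0.001 for the first two ellipses, 0.003
#' for the other two, 0.005 for the first two eights and 0.007 for the
#' remaining two, so that the task-average noise level is 0.004 -- the floor
#' below which no prediction error can fall.
#'
#' @param cycles,n_steps passed to every [shape_spec()].
#' @return A data frame with one row per trajectory class.
#' @export
default_shape_specs <- function(cycles = 3L, n_steps = 75L) {
  shapes <- rep(c("ellipse", "eight"), each = 4L)
  positions <- rep(c("right", "left", "top", "bottom"), times = 2L)
  vars <- c(0.001, 0.001, 0.003, 0.003, 0.005, 0.005, 0.007, 0.007)
  out <- do.call(rbind, Map(shape_spec, shapes, positions, vars,
                            MoreArgs = list(cycles = cycles,
                                            n_steps = n_steps)))
  rownames(out) <- NULL
  out
}

# center of each position in task space; radius 0.25 keeps every coordinate
# well inside the (-1, 1) range of the tanh readout
position_center <- function(position) {
  switch(position,
         right  = c(0.5, 0),
         left   = c(-0.5, 0),
         top    = c(0, 0.5),
         bottom = c(0, -0.5),
         stop("unknown position: ", position))
}

#' Generate the clean trajectory of one shape specification
#'
#' Draws the noise-free trajectory: an ellipse is parameterized as
#' `(0.25 cos(theta), 0.15 sin(theta))` and a figure-eight as the Lissajous
#' curve `(0.15 sin(2 theta), 0.25 sin(theta))`, both centered on the
#' position of the spec, traversed counter-clockwise with phase origin at
#' the rightmost point, and repeated `cycles` times over `n_steps` steps.
#'
#' @param spec a [shape_spec()] (or one row of [default_shape_specs()]).
#' @return An `n_steps` x 2 matrix of task-space coordinates, each strictly
#'   inside (-1, 1) and periodic with period `n_steps / cycles`.
#' @export
make_shape <- function(spec) {
  spec <- as.list(spec[1L, , drop = FALSE])
  n_steps <- as.integer(spec$n_steps)
  cycles <- as.integer(spec$cycles)
  if (n_steps %% cycles != 0L)
    stop("'n_steps' must be divisible by 'cycles'")
  period <- n_steps / cycles
  center <- position_center(spec$position)
  theta <- 2 * pi * (seq_len(n_steps) - 1L) / period
  xy <- switch(spec$shape,
               ellipse = cbind(0.25 * cos(theta), 0.15 * sin(theta)),
               eight = cbind(0.15 * sin(2 * (theta + pi / 4)),
                             0.25 * sin(theta + pi / 4)),
               stop("unknown shape: ", spec$shape))
  sweep(xy, 2L, center, "+")
}

#' Add Gaussian observation noise to a trajectory
#'
#' Perturbs every coordinate independently with zero-mean Gaussian noise of
#' the given variance, emulating sensory noise on the drawing input.  Uses
#' the current R random number stream, so results are reproducible under
#' [set.seed()].
#'
#' @param trajectory numeric matrix (time steps x dimensions).
#' @param variance non-negative noise variance.
#' @return A matrix of the same shape; the input is not modified.
#' @export
corrupt <- function(trajectory, variance) {
  trajectory <- as.matrix(trajectory)
  if (!is.numeric(variance) || length(variance) != 1L || is.na(variance) ||
      variance < 0)
    stop("'variance' must be a single non-negative number")
  if (variance == 0) return(trajectory)
  trajectory + matrix(rnorm(length(trajectory), sd = sqrt(variance)),
                      nrow = nrow(trajectory))
}

#' Build a training dataset of noisy drawing trajectories
#'
#' For every shape specification, generates the clean trajectory and
#' `repeats` independently corrupted realizations.  One training epoch of
#' [sctrnn_fit()] processes all realizations of all classes as a single
#' batch.
#'
#' @param specs data frame of shape specifications (default: the eight-class
#'   task of [default_shape_specs()]).
#' @param repeats number of noisy realizations per class.
#' @return An object of class `trajectory_set` with elements `specs`,
#'   `clean` (list of `n_steps` x 2 matrices), `noisy` (list of lists of
#'   realizations), `class_labels` and `position_labels`.
#' @examples
#' set.seed(1)
#' ts <- build_dataset(repeats = 2)
#' length(ts$clean)        # 8 classes
#' dim(ts$clean[[1]])      # 75 x 2
#' @export
build_dataset <- function(specs = default_shape_specs(), repeats = 50L) {
  if (is.null(specs) || nrow(specs) == 0L)
    stop("'specs' must contain at least one shape specification")
  repeats <- as.integer(repeats)
  if (repeats < 1L) stop("'repeats' must be >= 1")
  clean <- lapply(seq_len(nrow(specs)),
                  function(i) make_shape(specs[i, , drop = FALSE]))
  noisy <- lapply(seq_len(nrow(specs)), function(i) {
    lapply(seq_len(repeats),
           function(r) corrupt(clean[[i]], specs$noise_variance[i]))
  })
  structure(list(specs = specs, clean = clean, noisy = noisy,
                 class_labels = seq_len(nrow(specs)),
                 position_labels = specs$position,
                 repeats = repeats),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("Trajectory set:", length(x$clean), "classes x", x$repeats,
      "noisy realizations\n")
  cat("  steps:", nrow(x$clean[[1]]), " cycles:", x$specs$cycles[1], "\n")
  info <- paste0(x$specs$shape, "/", x$specs$position,
                 " (var ", format(x$specs$noise_variance), ")")
  cat(paste0("  [", seq_along(info), "] ", info, collapse = "\n"), "\n")
  invisible(x)
}

#' Keep only a subset of trajectory classes
#'
#' Used by the generalization experiment to hold one class out of training.
#'
#' @param x a `trajectory_set`.
#' @param keep integer indices of the classes to keep.
#' @return A `trajectory_set` with the selected classes, relabeled 1..k.
#' @export
subset_classes <- function(x, keep) {
  stopifnot(inherits(x, "trajectory_set"))
  keep <- as.integer(keep)
  if (any(keep < 1L | keep > length(x$clean)))
    stop("'keep' indexes classes out of range")
  structure(list(specs = x$specs[keep, , drop = FALSE],
                 clean = x$clean[keep],
                 noisy = x$noisy[keep],
                 class_labels = seq_along(keep),
                 position_labels = x$specs$position[keep],
                 repeats = x$repeats),
            class = "trajectory_set")
}

#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  rows <- list()
  for (k in seq_along(x$clean)) {
    tr <- x$clean[[k]]
    rows[[length(rows) + 1L]] <-
      data.frame(class = k, realization = 0L, t = seq_len(nrow(tr)),
                 x = tr[, 1L], y = tr[, 2L])
    for (r in seq_along(x$noisy[[k]])) {
      tr <- x$noisy[[k]][[r]]
      rows[[length(rows) + 1L]] <-
        data.frame(class = k, realization = r, t = seq_len(nrow(tr)),
                   x = tr[, 1L], y = tr[, 2L])
    }
  }
  do.call(rbind, rows)
}

#' Write/read a trajectory set as CSV
#'
#' Long format with columns `class, realization, t, x, y`; realization 0 is
#' the clean trajectory.
#'
#' @param x a `trajectory_set`.
#' @param file path to a CSV file.
#' @return `write_trajectories` returns `file` invisibly;
#'   `read_trajectories` returns the long-format data frame.
#' @export
write_trajectories <- function(x, file) {
  write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(file) {
  read.csv(file)
}
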