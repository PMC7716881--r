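#' Mean squared error between two trajectories
#'
#' Per-element mean of squared coordinate differences; the behavioral
#' performance measure for generated trajectories.  For the default task,
#' comparing against a noisy training realization cannot fall below the
#' average observation-noise variance of 0.004.
#'
#' @param generated,reference equally sized numeric matrices.
#' @return A single number.
#' @export
prediction_mse <- function(generated, reference) {
  generated <- as.matrix(generated)
  reference <- as.matrix(reference)
  if (!identical(dim(generated), dim(reference)))
    stop("'generated' and 'reference' must have identical dimensions")
  mean((generated - reference)^2)
}

#' Dynamic time warping distance
#'
#' Classic DTW between two multivariate sequences: Euclidean local cost,
#' unit steps (match, insertion, deletion), no warping window, and the raw
#' accumulated cost (no path-length normalization).  Symmetric in its
#' arguments and zero for identical sequences.
#'
#' @param a,b numeric matrices with one time point per row and equal
#'   numbers of columns (dimensions).
#' @return The accumulated warping cost.
#' @export
dtw_distance <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (ncol(a) != ncol(b))
    stop("sequences must have the same dimensionality")
  if (nrow(a) == 0L || nrow(b) == 0L) stop("sequences must be non-empty")
  .dtw_cpp(t(a), t(b))
}

#' Inner and outer distances of an internal representation
#'
#' Quantifies how well the recurrent layer separates trajectory classes by
#' position.  The DTW distances between the context-activation time courses
#' of classes at the *same* position are averaged into the inner distance;
#' distances between classes at *different* positions into the outer
#' distance.  Their quotient (inner / outer) is small when same-position
#' patterns are represented alike and different positions are kept apart --
#' the signature of a well-structured representation.
#'
#' @param activations list of C x T activation matrices, one per class
#'   (e.g. from [closed_loop_generate()]).
#' @param positions character/factor vector of per-class positions.
#' @return A list of class `representation_metrics` with `inner_distance`,
#'   `outer_distance`, `inner_outer_quotient` and the pair counts.
#' @export
inner_outer <- function(activations, positions) {
  k <- length(activations)
  if (k < 2L || length(positions) != k)
    stop("need at least two classes with one position label each")
  pairs <- utils::combn(k, 2L)
  same <- positions[pairs[1L, ]] == positions[pairs[2L, ]]
  if (!any(same))
    stop("no position is represented by more than one class: ",
         "inner distances are undefined")
  if (!any(!same))
    stop("all classes share one position: outer distances are undefined")
  d <- apply(pairs, 2L, function(p)
    dtw_distance(t(activations[[p[1L]]]), t(activations[[p[2L]]])))
  inner <- mean(d[same])
  outer <- mean(d[!same])
  structure(list(inner_distance = inner, outer_distance = outer,
                 inner_outer_quotient = inner / outer,
                 n_inner_pairs = sum(same), n_outer_pairs = sum(!same)),
            class = "representation_metrics")
}

#' @export
print.representation_metrics <- function(x, ...) {
  cat(sprintf("inner %.3f (%d pairs) / outer %.3f (%d pairs) = quotient %.4f\n",
              x$inner_distance, x$n_inner_pairs, x$outer_distance,
              x$n_outer_pairs, x$inner_outer_quotient))
  invisible(x)
}

#' Two-dimensional PCA embedding of context activations
#'
#' Pools per-time-step activation vectors (optionally across classes),
#' centers them and projects onto the top two principal components --
#' the low-dimensional view of the internal representation.
#'
#' @param activations a C x M matrix of pooled activations (columns are
#'   time-step samples), or a list of C x T matrices that are pooled.
#' @return A list with `coords` (M x 2 scores), `pc_explained`
#'   (explained-variance fraction of every component, summing to 1) and
#'   `class` (per-sample class index when a list was given).
#' @export
pca_embed <- function(activations) {
  cls <- NULL
  if (is.list(activations)) {
    cls <- rep(seq_along(activations),
               vapply(activations, ncol, integer(1)))
    activations <- do.call(cbind, activations)
  }
  if (ncol(activations) < 2L)
    stop("need at least two time-step samples for a PCA embedding")
  p <- prcomp(t(activations), center = TRUE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  list(coords = p$x[, 1:2, drop = FALSE], pc_explained = expl, class = cls)
}

#' Min-max quality normalization across conditions
#'
#' Rescales raw error-like values across parameter conditions to \[0, 1\]
#' and flips them (`1 - value`), so that larger means better.  Standard
#' deviations, when supplied, are rescaled by the same factor.
#'
#' @param values numeric vector (one value per condition).
#' @param sds optional standard deviations to rescale.
#' @return A numeric vector in \[0, 1\] (with attribute `"sds"` when given).
#' @export
normalize_quality <- function(values, sds = NULL) {
  rng <- range(values)
  if (diff(rng) == 0)
    stop("all values are equal: the normalization range is degenerate")
  out <- 1 - (values - rng[1L]) / diff(rng)
  if (!is.null(sds)) attr(out, "sds") <- sds / diff(rng)
  out
}

#' Correlation between representation quality and generalization
#'
#' Pearson correlation (with two-sided p-value) between per-network
#' inner-outer quotients and per-network generalization errors.
#'
#' @param quotients,generalization_errors paired numeric vectors (one entry
#'   per trained network).
#' @return A list with `r`, `p` and `n`.
#' @export
quality_generalization_correlation <- function(quotients,
                                               generalization_errors) {
  if (length(quotients) != length(generalization_errors) ||
      length(quotients) < 3L)
    stop("need at least three paired observations")
  if (sd(quotients) == 0 || sd(generalization_errors) == 0)
    stop("zero variance in one of the variables")
  ct <- cor.test(quotients, generalization_errors, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(quotients))
}
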