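#' Serialize network weights to a text file
#'
#' Writes all weight matrices and the initial states into one CSV (columns
#' `matrix, row, col, value`, values printed with 17 significant digits so
#' the round trip is bit-exact) next to a JSON metadata block holding the
#' network configuration.
#'
#' @param weights an `sctrnn_weights` set.
#' @param file path of the CSV to write; the metadata is written to
#'   `paste0(file, ".json")`.
#' @param config optional [network_config()] stored in the metadata.
#' @return `file`, invisibly.
#' @export
write_weights <- function(weights, file, config = NULL) {
  rows <- lapply(names(weights), function(nm) {
    m <- weights[[nm]]
    data.frame(matrix = nm,
               row = rep(seq_len(nrow(m)), times = ncol(m)),
               col = rep(seq_len(ncol(m)), each = nrow(m)),
               value = sprintf("%.17g", as.vector(m)))
  })
  write.csv(do.call(rbind, rows), file, row.names = FALSE, quote = FALSE)
  meta <- list(format = "sctrnn_weights/1")
  if (!is.null(config)) meta$config <- unclass(config)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_weights
#' @return `read_weights` returns the `sctrnn_weights` list.
#' @export
read_weights <- function(file) {
  d <- read.csv(file, colClasses = c("character", "integer", "integer",
                                     "character"))
  out <- lapply(split(d, d$matrix), function(g) {
    m <- matrix(0, max(g$row), max(g$col))
    m[cbind(g$row, g$col)] <- as.numeric(g$value)
    m
  })
  out <- out[c("W_inp", "W_rec", "W_out", "W_var", "initial_states")]
  class(out) <- "sctrnn_weights"
  out
}

#' Export a training log or experiment table to CSV
#'
#' @param x an `sctrnn` fit (writes the per-epoch loss log) or an
#'   `sctrnn_experiment` (writes the per-run results table).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_log <- function(x, file) {
  d <- if (inherits(x, "sctrnn")) x$log
       else if (inherits(x, "sctrnn_experiment")) x$results
       else stop("'x' must be an 'sctrnn' fit or an 'sctrnn_experiment'")
  write.csv(d, file, row.names = FALSE)
  invisible(file)
}
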