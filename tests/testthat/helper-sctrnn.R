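# small fixtures shared across test files

tiny_config <- function(C = 5L, chi = 1, K = 0, ...) {
  network_config(context_size = C, chi_train = chi, K = K, ...)
}

tiny_weights <- function(config, n_classes = 2L, sd = 0.3) {
  w <- init_weights(config, n_classes)
  for (nm in c("W_inp", "W_rec", "W_out", "W_var"))
    w[[nm]] <- matrix(rnorm(length(w[[nm]]), sd = sd), nrow(w[[nm]]))
  w$initial_states <- matrix(rnorm(n_classes * config$context_size,
                                   sd = 0.2), n_classes)
  w
}

random_sequences <- function(n, T_, d = 2, sd = 0.3) {
  lapply(seq_len(n), function(i) matrix(rnorm(T_ * d, sd = sd), T_, d))
}

# brute-force DTW: enumerate all monotone warping paths by dynamic
# programming written independently of the package's implementation
# (recursive with memoization on the full path lattice)
dtw_bruteforce <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  memo <- new.env()
  cost <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    if (i == 0 || j == 0) return(Inf)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- cost(i, j) + min(rec(i - 1, j - 1), rec(i - 1, j), rec(i, j - 1))
    memo[[key]] <- val
    val
  }
  rec(nrow(a), nrow(b))
}
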