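# Independent brute-force oracles used across tests.

# direct O(n^2) circular convolution: y[t] = sum_m h[m] x[(t - m) mod n]
direct_circ_conv <- function(x, h) {
  n <- length(x)
  hp <- c(h, numeric(n - length(h)))
  vapply(seq_len(n) - 1L, function(t) {
    sum(hp * x[((t - (seq_len(n) - 1L)) %% n) + 1L])
  }, numeric(1))
}

# full scattering of one window by direct convolution only
direct_scatter <- function(x, bank) {
  J <- bank$J
  S0 <- direct_circ_conv(x, bank$eta)
  U1 <- lapply(seq_len(J), function(j) abs(direct_circ_conv(x, bank$haar[[j]])))
  S1 <- lapply(U1, function(u) direct_circ_conv(u, bank$eta))
  U2 <- list(); S2 <- list()
  for (j1 in seq_len(J)) for (j2 in seq_len(J)) {
    if (j2 <= j1) next
    key <- paste0(j1, ".", j2)
    U2[[key]] <- abs(direct_circ_conv(U1[[j1]], bank$haar[[j2]]))
    S2[[key]] <- direct_circ_conv(U2[[key]], bank$eta)
  }
  list(S0 = S0, U1 = U1, S1 = S1, U2 = U2, S2 = S2)
}

# small defect-free simulated stream used by several io/cleaning tests
tiny_stream <- function(n_windows = 4, window_len = 32, seed = 11,
                        defects = defect_spec()) {
  generate_dataset(default_activity_models(), n_windows, window_len,
                   defects = defects, seed = seed)
}

# enumerate all non-empty masks of m bits as logical vectors
all_masks <- function(m) {
  lapply(seq_len(2^m - 1), function(code) as.logical(bitwAnd(code, 2^(seq_len(m) - 1))))
}
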