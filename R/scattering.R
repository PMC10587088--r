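# Symlet-4 scaling (low-pass) filter taps, standard published constants,
# normalized here to unit sum when the averaging filter is built.
SYM4_DEC_LO <- c(-0.07576571478927333, -0.02963552764599851,
                 0.49761866763201545,  0.80373875180591614,
                 0.29785779560527736, -0.09921954357684722,
                 -0.01260396726203783, 0.03222310060404270)

# dyadic upsampling: insert (factor - 1) zeros between taps
upsample_taps <- function(h, factor) {
  if (factor == 1) return(h)
  out <- numeric(length(h) * factor - (factor - 1))
  out[seq(1, length(out), by = factor)] <- h
  out
}

conv_full <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

# fold a filter modulo n (periodization for circular convolution)
periodize_taps <- function(h, n) {
  out <- numeric(min(n, length(h)))
  for (i in seq_along(h)) {
    j <- ((i - 1L) %% n) + 1L
    out[j] <- out[j] + h[i]
  }
  out
}

#' Build the Haar/Symlet scattering filter bank
#'
#' Band-pass filters are dyadically dilated Haar wavelets: at scale `j` the
#' filter is `2^(j-1)` taps of `+2^(-j/2)` followed by `2^(j-1)` taps of
#' `-2^(-j/2)` (unit l2 norm, zero mean). The low-pass averaging filter is
#' the Symlet-4 scaling filter cascaded (a-trous) to smoothing support
#' `2^J`, normalized to unit sum, and periodized to the window length since
#' all convolutions are circular.
#'
#' @param J Maximum dyadic scale; requires `2^J <= window_len`.
#' @param window_len Window length in samples.
#' @return Object of class `scattering_bank` with elements `haar` (list of
#'   J filters), `eta` (low-pass taps), `J`, `window_len`.
#' @export
build_filter_bank <- function(J, window_len) {
  if (2^J > window_len) {
    stop(sprintf("scale error: 2^J = %d exceeds window_len = %d; max feasible J is %d",
                 2^J, window_len, floor(log2(window_len))))
  }
  haar <- lapply(seq_len(J), function(j) {
    half <- 2^(j - 1)
    c(rep(2^(-j / 2), half), rep(-2^(-j / 2), half))
  })
  h0 <- SYM4_DEC_LO / sum(SYM4_DEC_LO)
  eta <- h0
  if (J > 1) {
    for (j in seq_len(J - 1)) eta <- conv_full(eta, upsample_taps(h0, 2^j))
  }
  eta <- periodize_taps(eta, window_len)
  structure(list(haar = haar, eta = eta, J = J, window_len = window_len),
            class = "scattering_bank")
}

# circular convolution y[n] = sum_m h[m] x[(n - m) mod N], via FFT
circ_conv <- function(x, h) {
  n <- length(x)
  hp <- c(h, numeric(n - length(h)))
  Re(stats::fft(stats::fft(x) * stats::fft(hp), inverse = TRUE)) / n
}

# batched circular convolution: X is (N x n_signals), returns same shape
circ_conv_mat <- function(X, h_fft) {
  n <- nrow(X)
  Re(stats::mvfft(stats::mvfft(X) * h_fft, inverse = TRUE)) / n
}

#' Scattering transform of a single window
#'
#' Order-2 wavelet scattering with circular convolutions: the zeroth order
#' is the low-pass average `S0 = x * eta`; first-order paths are
#' `U1[j] = |x * psi_j|`, `S1[j] = U1[j] * eta`; second-order paths (only
#' frequency-decreasing, `j2 > j1`) are `U2 = |U1[j1] * psi_j2|`,
#' `S2 = U2 * eta`.
#'
#' @param x Real-valued signal of length `bank$window_len`.
#' @param bank A [build_filter_bank()] object.
#' @return Object of class `scattering_coeffs`: `S0` (vector), `S1`
#'   (J x N matrix), `U1`, and `S2`, `U2` (lists indexed by path name
#'   `"j1.j2"`), plus `pooled`, the per-path time averages
#'   `(S0, S1[1..J], S2 paths)` in fixed order.
#' @export
scatter_window <- function(x, bank) {
  n <- bank$window_len
  if (length(x) != n) stop("size error: window length != bank window_len")
  S0 <- circ_conv(x, bank$eta)
  J <- bank$J
  U1 <- lapply(seq_len(J), function(j) abs(circ_conv(x, bank$haar[[j]])))
  S1 <- t(vapply(U1, function(u) circ_conv(u, bank$eta), numeric(n)))
  U2 <- list(); S2 <- list()
  for (j1 in seq_len(J)) {
    for (j2 in seq_len(J)) {
      if (j2 <= j1) next
      key <- paste0(j1, ".", j2)
      U2[[key]] <- abs(circ_conv(U1[[j1]], bank$haar[[j2]]))
      S2[[key]] <- circ_conv(U2[[key]], bank$eta)
    }
  }
  pooled <- c(mean(S0), rowMeans(S1),
              vapply(S2, mean, numeric(1)))
  names(pooled) <- c("S0", paste0("S1.", seq_len(J)),
                     if (length(S2)) paste0("S2.", names(S2)))
  structure(list(S0 = S0, S1 = S1, U1 = U1, U2 = U2, S2 = S2,
                 pooled = pooled),
            class = "scattering_coeffs")
}

scattering_path_names <- function(J) {
  s2 <- character(0)
  for (j1 in seq_len(J)) for (j2 in seq_len(J)) {
    if (j2 > j1) s2 <- c(s2, paste0("S2.", j1, ".", j2))
  }
  c("S0", paste0("S1.", seq_len(J)), s2)
}

#' Scattering feature matrix of a window set
#'
#' Per channel, the feature vector is the global time average of every
#' scattering path `(S0, S1 per scale, S2 per frequency-decreasing path)`;
#' the full vector concatenates channels, giving
#' `M = n_channels * (1 + J + J(J-1)/2)` features. Implemented with batched
#' FFT convolutions across windows.
#'
#' @param ws A [window_set()].
#' @param bank A [build_filter_bank()] compatible with the window length.
#' @return Numeric matrix (n_windows x M) with feature names
#'   `<channel>.<path>`; labels attached as attribute `labels`.
#' @export
extract_features <- function(ws, bank) {
  d <- dim(ws$windows)
  n_win <- d[1]; n_ch <- d[2]; len <- d[3]
  if (len != bank$window_len) stop("bank window_len does not match window set")
  J <- bank$J
  paths <- scattering_path_names(J)
  feat_names <- as.vector(t(outer(ws$channel_names, paths, paste, sep = ".")))
  out <- matrix(0, n_win, n_ch * length(paths),
                dimnames = list(NULL, feat_names))
  if (n_win == 0) return(out)
  eta_fft <- stats::fft(c(bank$eta, numeric(len - length(bank$eta))))
  haar_fft <- lapply(bank$haar, function(h) stats::fft(c(h, numeric(len - length(h)))))
  for (c_i in seq_len(n_ch)) {
    X <- t(ws$windows[, c_i, , drop = FALSE][, 1, ])   # len x n_win
    if (n_win == 1) X <- matrix(ws$windows[1, c_i, ], ncol = 1)
    cols <- paste0(ws$channel_names[c_i], ".", paths)
    out[, cols[1]] <- colMeans(circ_conv_mat(X, eta_fft))
    U1 <- lapply(seq_len(J), function(j) abs(circ_conv_mat(X, haar_fft[[j]])))
    for (j in seq_len(J)) {
      # time average of U1*eta equals mean(U1) because eta sums to 1
      out[, cols[1 + j]] <- colMeans(circ_conv_mat(U1[[j]], eta_fft))
    }
    p <- 1 + J
    for (j1 in seq_len(J)) for (j2 in seq_len(J)) {
      if (j2 <= j1) next
      p <- p + 1
      U2 <- abs(circ_conv_mat(U1[[j1]], haar_fft[[j2]]))
      out[, cols[p]] <- colMeans(circ_conv_mat(U2, eta_fft))
    }
  }
  attr(out, "labels") <- ws$labels
  out
}
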