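test_that("filter bank has Haar band-pass and unit-sum low-pass structure", {
  bank <- build_filter_bank(4, 64)
  expect_equal(bank$haar[[1]], c(1, -1) / sqrt(2), tolerance = 1e-12)
  for (j in 1:4) {
    expect_lt(abs(sum(bank$haar[[j]])), 1e-12)       # zero mean
    expect_equal(sum(bank$haar[[j]]^2), 1, tolerance = 1e-12)  # unit l2
    expect_lte(length(bank$haar[[j]]), 64)
  }
  expect_equal(sum(bank$eta), 1, tolerance = 1e-12)
  expect_lte(length(bank$eta), 64)
  # low-pass leaves constants untouched
  x <- rep(3.7, 64)
  expect_equal(harpipe:::circ_conv(x, bank$eta), x, tolerance = 1e-9)
  expect_error(build_filter_bank(7, 64), "max feasible J")
})

test_that("scattering agrees with a direct-convolution oracle on every path", {
  bank <- build_filter_bank(4, 64)
  set.seed(17)
  for (r in 1:50) {
    x <- rnorm(64)
    sc <- scatter_window(x, bank)
    oracle <- direct_scatter(x, bank)
    expect_equal(sc$S0, oracle$S0, tolerance = 1e-10)
    for (j in 1:4) {
      expect_equal(sc$U1[[j]], oracle$U1[[j]], tolerance = 1e-10)
      expect_equal(unname(sc$S1[j, ]), oracle$S1[[j]], tolerance = 1e-10)
    }
    for (key in names(oracle$S2)) {
      expect_equal(sc$U2[[key]], oracle$U2[[key]], tolerance = 1e-10)
      expect_equal(sc$S2[[key]], oracle$S2[[key]], tolerance = 1e-10)
    }
  }
})

test_that("constants are killed by band-pass and preserved by S0", {
  bank <- build_filter_bank(4, 64)
  sc <- scatter_window(rep(2.5, 64), bank)
  expect_equal(sc$S0, rep(2.5, 64), tolerance = 1e-10)
  for (j in 1:4) expect_equal(max(abs(sc$U1[[j]])), 0, tolerance = 1e-12)
  expect_true(all(vapply(sc$S2, function(s) max(abs(s)), numeric(1)) < 1e-12))
  # all U and S entries are non-negative for orders >= 1
  set.seed(2)
  sc2 <- scatter_window(rnorm(64), bank)
  expect_true(all(unlist(sc2$U1) >= 0))
  expect_true(all(unlist(sc2$U2) >= 0))
  expect_true(all(sc2$S1 >= -1e-12))
})

test_that("pooled features are exactly circular-shift invariant", {
  bank <- build_filter_bank(4, 64)
  set.seed(23)
  x <- rnorm(64)
  p0 <- scatter_window(x, bank)$pooled
  for (shift in c(1, 7, 31)) {
    xs <- c(x[(shift + 1):64], x[1:shift])
    expect_equal(scatter_window(xs, bank)$pooled, p0, tolerance = 1e-9)
  }
  # impulse at any position gives identical pooled features
  e1 <- numeric(64); e1[1] <- 1
  e2 <- numeric(64); e2[40] <- 1
  expect_equal(scatter_window(e1, bank)$pooled,
               scatter_window(e2, bank)$pooled, tolerance = 1e-9)
})

test_that("feature extraction has the path-count, homogeneity and zero contracts", {
  bank <- build_filter_bank(4, 64)
  set.seed(5)
  w <- array(rnorm(6 * 3 * 64), c(6, 3, 64))
  ws <- window_set(w, labels = rep(1:2, 3))
  f <- extract_features(ws, bank)
  expect_equal(ncol(f), 3 * (1 + 4 + 6))   # M = c (1 + J + J(J-1)/2)
  # matches the single-window transform
  p <- scatter_window(w[4, 2, ], bank)$pooled
  expect_equal(unname(f[4, 12:22]), unname(p), tolerance = 1e-12)

  zs <- window_set(array(0, c(2, 3, 64)), labels = c(1L, 1L))
  expect_true(all(extract_features(zs, bank) == 0))

  # positive scaling scales features linearly
  ws2 <- window_set(w * 3.5, labels = ws$labels)
  expect_equal(extract_features(ws2, bank), 3.5 * f, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("scattering is empirically non-expansive and energy decays with order", {
  bank <- build_filter_bank(4, 64)
  set.seed(31)
  lip <- 0
  for (i in 1:100) {
    a <- rnorm(64); b <- rnorm(64)
    pa <- scatter_window(a, bank)$pooled
    pb <- scatter_window(b, bank)$pooled
    lip <- max(lip, sqrt(sum((pa - pb)^2)) / sqrt(sum((a - b)^2)))
  }
  expect_lte(lip, 1.05)

  # mean second-order magnitude below first order on stochastic signals
  w <- array(rnorm(20 * 1 * 64), c(20, 1, 64))
  f <- extract_features(window_set(w, rep(1L, 20)), bank)
  s1 <- f[, grepl("S1", colnames(f))]
  s2 <- f[, grepl("S2", colnames(f))]
  expect_lt(mean(abs(s2)), mean(abs(s1)))
})
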