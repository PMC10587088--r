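test_that("network initialization is seeded, balanced and shares filters", {
  a <- init_network(16, 5, seed = 3)
  b <- init_network(16, 5, seed = 3)
  expect_identical(a$eps, b$eps)
  expect_identical(a$layers, b$layers)

  # n_lego = 1: every mask selects the single filter
  m1 <- init_network(16, 3, n_lego = 1, seed = 1)
  for (ly in m1$layers) expect_true(all(ly$mask == 1))

  # balanced round-robin: per-filter fragment counts differ by <= 1
  m2 <- init_network(37, 4, n_lego = 3, fragment_dim = 4, seed = 2)
  for (ly in m2$layers) {
    counts <- tabulate(as.vector(ly$mask), nbins = 3)
    expect_lte(max(counts) - min(counts), 1)
  }

  # parameter economy: conv parameters independent of fragment count
  small <- init_network(8, 2, n_lego = 4, fragment_dim = 4, kernel_len = 3)
  big <- init_network(400, 2, n_lego = 4, fragment_dim = 4, kernel_len = 3)
  expect_equal(lego_param_count(small), 4 * 4 * 3)
  expect_equal(lego_param_count(big), lego_param_count(small))
  expect_equal(length(small$eps), lego_param_count(small))
  expect_equal(length(big$eps), length(small$eps))

  expect_error(init_network(2, 2, fragment_dim = 4), "configuration error")
})

test_that("a zero head yields uniform probabilities and per-sample independence", {
  m <- init_network(10, 4, seed = 5)
  set.seed(5)
  x <- matrix(rnorm(6 * 10), 6)
  p <- forward_network(m, x)$probs
  expect_equal(p, matrix(0.25, 6, 4), tolerance = 1e-12, ignore_attr = TRUE)
  # duplicating a sample duplicates its row
  m$W <- matrix(rnorm(length(m$W)), nrow(m$W)); m$fitted <- TRUE
  x2 <- rbind(x, x[2, ])
  p2 <- forward_network(m, x2)$probs
  expect_equal(p2[7, ], p2[2, ], tolerance = 1e-12)
})

test_that("masked fragment sums reproduce a hand computation", {
  # input_dim 4, fragment_dim 2, kernel_len 1, one layer, 2 filters
  m <- init_network(4, 2, n_lego = 2, fragment_dim = 2, kernel_len = 1,
                    n_layers = 1, seed = 7, min_width = 1)
  x <- matrix(c(1, 2, 3, 4), 1)
  fwd <- harpipe:::lego_forward_cache(m, x)
  # layer: 2 fragments (1,2) and (3,4); mask[iota, phi] = ((iota+phi-2) %% 2)+1
  e1 <- m$eps[, 1, 1]; e2 <- m$eps[, 1, 2]
  g1 <- sum(c(1, 2) * e1) + sum(c(3, 4) * e2)   # slot 1: filters 1,2
  g2 <- sum(c(1, 2) * e2) + sum(c(3, 4) * e1)   # slot 2: filters 2,1
  expect_equal(unname(fwd$caches[[1]]$pre[1, ]), c(g1, g2), tolerance = 1e-12)
  expect_equal(unname(fwd$pool[1, ]), pmax(c(g1, g2), 0), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  m <- init_network(7, 3, n_lego = 2, fragment_dim = 3, kernel_len = 2,
                    n_layers = 2, seed = 5)
  set.seed(3)
  m$W <- matrix(rnorm(length(m$W), sd = 0.5), nrow(m$W))
  m$b <- rnorm(length(m$b), sd = 0.1)
  x <- matrix(rnorm(6 * 7), 6)
  y <- c(1, 2, 3, 1, 2, 3)
  yh <- harpipe:::one_hot(y, 1:3)
  fwd <- harpipe:::lego_forward_cache(m, x)
  gr <- harpipe:::lego_backward(m, fwd, yh)
  loss_of <- function(mm) {
    harpipe:::cross_entropy(harpipe:::lego_forward_cache(mm, x)$probs, yh)
  }
  h <- 1e-5
  check <- function(get, set, grad) {
    for (i in seq_along(get(m))) {
      mp <- set(m, i, h); mm2 <- set(m, i, -h)
      fd <- (loss_of(mp) - loss_of(mm2)) / (2 * h)
      expect_equal(grad[i], fd, tolerance = 1e-5)
    }
  }
  check(function(m) m$eps,
        function(m, i, d) { m$eps[i] <- m$eps[i] + d; m }, gr$deps)
  check(function(m) m$W,
        function(m, i, d) { m$W[i] <- m$W[i] + d; m }, gr$dW)
  check(function(m) m$b,
        function(m, i, d) { m$b[i] <- m$b[i] + d; m }, gr$db)
})

test_that("training is deterministic, monotone on a toy set and separable", {
  set.seed(9)
  x <- rbind(matrix(rnorm(10 * 4, -2), 10), matrix(rnorm(10 * 4, 2), 10))
  y <- rep(1:2, each = 10)
  cfg <- train_config(learning_rate = 0.05, epochs = 200, batch_size = 32,
                      seed = 1)
  net <- train_network(init_network(4, 2, fragment_dim = 2, seed = 2),
                       x, y, cfg)
  pred <- predict_network(net, x)
  expect_equal(mean(pred$labels == y), 1)
  # loss non-increasing after epoch 5 (allow <= 3 upticks)
  upticks <- sum(diff(net$loss_trace[-(1:4)]) > 1e-9)
  expect_lte(upticks, 3)

  net2 <- train_network(init_network(4, 2, fragment_dim = 2, seed = 2),
                        x, y, cfg)
  expect_identical(net$loss_trace, net2$loss_trace)
  expect_identical(net$eps, net2$eps)

  # zero-step limit: a vanishing learning rate freezes parameters
  tiny <- train_config(learning_rate = 1e-12, epochs = 3, batch_size = 32)
  net3 <- train_network(init_network(4, 2, fragment_dim = 2, seed = 2),
                        x, y, tiny)
  expect_equal(max(abs(diff(net3$loss_trace))), 0, tolerance = 1e-9)

  expect_error(train_network(init_network(4, 2, fragment_dim = 2),
                             x, rep(1L, 20)), ">= 2 classes")
})

test_that("prediction breaks ties toward the smaller class and counts add up", {
  m <- init_network(4, 2, fragment_dim = 2, seed = 1)
  expect_error(predict_network(m, matrix(0, 1, 4)), "not fitted")
  # zero head: exact tie -> smallest class
  p <- forward_network(m, matrix(rnorm(4), 1))
  expect_equal(p$labels, 1L)

  set.seed(11)
  x <- matrix(rnorm(30 * 4), 30)
  y <- sample(1:3, 30, replace = TRUE)
  m3 <- init_network(4, 3, fragment_dim = 2, seed = 2)
  m3$classes <- 1:3; m3$fitted <- TRUE
  pr <- predict_network(m3, x, y = y)
  for (i in seq_len(3)) {
    row <- pr$confusion[i, ]
    expect_equal(row$tp + row$tn + row$fp + row$fn, 30)
  }
})
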