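test_that("attack vector and norms follow the straight-line geometry", {
  expect_equal(attack_vector(c(1, 1), c(0, 0)), c(1, 1))
  expect_equal(attack_vector(c(0.3, 0.7), c(0.3, 0.7)), c(0, 0))
  expect_equal(sqrt(sum(attack_vector(c(1, 1), c(0, 0))^2)), sqrt(2),
               tolerance = 1e-9)
  expect_error(attack_vector(c(1, 2, 3), c(1, 2)), "dimension")
})

test_that("cruise destinations lie on the prey hyperplane exactly", {
  set.seed(1)
  # worked case beta = (1,1), prey = (1,1): s = 2
  cr <- cruise_vector(c(1, 1), c(1, 1), c(0.2, 0.2))
  expect_equal(sum(c(1, 1) * cr$A), 2, tolerance = 1e-12)
  # random cases: hyperplane identity and perpendicularity through prey
  for (i in 1:200) {
    m <- sample(2:8, 1)
    alpha <- rnorm(m); prey <- runif(m); pos <- runif(m)
    cr <- cruise_vector(alpha, prey, pos)
    expect_lte(abs(sum(alpha * cr$A) - cr$s), 1e-9)
    # (A - prey) is tangent to alpha
    expect_lte(abs(sum(alpha * (cr$A - prey))), 1e-9)
  }
  # degenerate: 1-D or zero attack vector falls back to a unit vector
  f1 <- cruise_vector(0.5, 0.3, 0.1)
  expect_true(f1$fallback)
  f2 <- cruise_vector(c(0, 0), c(0.5, 0.5), c(0.5, 0.5))
  expect_true(f2$fallback)
  expect_equal(sqrt(sum(f2$G^2)), 1, tolerance = 1e-12)
})

test_that("binomial step vectors have the stated support and moments", {
  set.seed(2)
  expect_true(all(binomial_random_vector(100, 10, 0) == 0))
  expect_true(all(binomial_random_vector(100, 10, 1) == 1))
  u <- binomial_random_vector(1e5, 10, 0.5)
  expect_true(all(u >= 0 & u <= 1))
  expect_lt(abs(mean(u) - 0.5), 0.005)
  expect_lt(abs(stats::var(u) - 0.025), 0.003)
})

test_that("propensity schedule interpolates linearly between its endpoints", {
  sch <- geo_schedule(iter_max = 100)
  expect_equal(propensity_schedule(sch, 0),
               c(k_attack = 0.5, k_cruise = 1))
  expect_equal(propensity_schedule(sch, 100),
               c(k_attack = 2, k_cruise = 0.5))
  expect_equal(propensity_schedule(sch, 50)[["k_attack"]], 1.25)
  expect_equal(propensity_schedule(geo_schedule(iter_max = 0), 0),
               c(k_attack = 0.5, k_cruise = 1))
  # attack rises while cruise falls
  ks <- sapply(0:100, function(i) propensity_schedule(sch, i))
  expect_true(all(diff(ks["k_attack", ]) > 0))
  expect_true(all(diff(ks["k_cruise", ]) < 0))
})

test_that("eagle steps are bounded and respect the unit box", {
  set.seed(3)
  for (i in 1:2000) {
    m <- sample(2:10, 1)
    e <- list(position = runif(m))
    ka <- runif(1, 0, 2); kc <- runif(1, 0, 2)
    e2 <- step_and_move(e, runif(m), ka, kc)
    expect_true(all(e2$position >= 0 & e2$position <= 1))
    # before clamping the step obeys the triangle inequality; verify via an
    # unclamped reconstruction is not possible here, so check the clamped
    # displacement which can only be shorter
    expect_lte(sqrt(sum((e2$position - e$position)^2)), ka + kc + 1e-9)
  }
})

test_that("the optimizer solves the 2-D sphere and keeps an elitist trace", {
  successes <- 0
  for (s in 1:10) {
    r <- geo_optimize(function(x) sum((x - 0.3)^2), dim = 2,
                      pop_size = 20, iter_max = 200, seed = s)
    if (r$best_f < 1e-3) successes <- successes + 1
    expect_true(all(diff(r$trace) <= 1e-12))  # minimizing: non-increasing
  }
  expect_gte(successes, 9)
})

test_that("feature selection finds a planted informative feature (M = 5)", {
  hits <- 0
  for (s in 1:10) {
    d <- generate_informative_feature_table(200, 5, 1, 3, 2, seed = s)
    xs <- scale(d$x); attr(xs, "scaled:center") <- NULL
    set.seed(s)
    fit <- make_wrapper_fitness(xs, d$y)
    # exhaustive 2^5 oracle: the informative feature is in the argmax subset
    best_f <- -Inf; best_mask <- NULL
    for (mk in all_masks(5)) {
      f <- fit(mk)
      if (f > best_f) { best_f <- f; best_mask <- mk }
    }
    expect_true(d$informative %in% which(best_mask))
    sel <- select_features(xs, d$y, fitness = fit, pop_size = 10,
                           iter_max = 50, seed = s)
    if (d$informative %in% which(sel$mask)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("selection is deterministic, elitist and never empty", {
  d <- generate_informative_feature_table(150, 8, 3, 2, 2, seed = 4)
  xs <- scale(d$x); attr(xs, "scaled:center") <- NULL
  a <- select_features(xs, d$y, pop_size = 10, iter_max = 30, seed = 9)
  b <- select_features(xs, d$y, pop_size = 10, iter_max = 30, seed = 9)
  expect_identical(a$mask, b$mask)
  expect_identical(a$trace, b$trace)
  expect_true(all(diff(a$trace) >= -1e-12))
  expect_gte(a$n_selected, 1)
  expect_equal(a$n_selected, sum(a$mask))

  expect_error(make_wrapper_fitness(xs, rep(1L, nrow(xs))), "single class")
  expect_error(select_features(xs, d$y, pop_size = 1), "pop_size")
})
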