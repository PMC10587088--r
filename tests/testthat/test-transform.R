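make_stream <- function(values, label = 1L, source = "s") {
  raw_record_set(data.frame(source_id = source,
                            timestamp = seq_along(values) - 1L,
                            ch_0 = values, label = label), 1,
                 stage = "cleaned")
}

test_that("integration merges sources by (source, timestamp) and conserves counts", {
  sim <- tiny_stream(n_windows = 2)
  cl <- clean_records(sim$records)
  one <- integrate_sources(list(cl))
  expect_equal(as.matrix(one[paste0("ch_", 0:2)]),
               as.matrix(cl[paste0("ch_", 0:2)]))

  a <- make_stream(1:5); b <- make_stream(6:12)
  b$source_id <- "t"; b$timestamp <- b$timestamp + 100L
  merged <- integrate_sources(list(raw_record_set(as.data.frame(b), 1), a))
  expect_equal(nrow(merged), 12)
  expect_equal(merged$ch_0, c(1:5, 6:12))  # s before t

  c3 <- make_stream(1:9); c3$source_id <- "u"
  m3 <- integrate_sources(list(a, raw_record_set(as.data.frame(b), 1),
                               raw_record_set(as.data.frame(c3), 1)))
  expect_equal(nrow(m3), 5 + 7 + 9)

  bad <- raw_record_set(data.frame(source_id = "v", timestamp = 0:2,
                                   ch_0 = 1:3, ch_1 = 4:6, label = 1L), 2)
  expect_error(integrate_sources(list(a, bad)), "schema mismatch")
})

test_that("histogram entropy matches closed forms", {
  expect_equal(channel_entropy(rep(1, 50), 8), 0)
  # uniform over 4 occupied bins
  v <- rep(c(0, 1, 2, 3), each = 25)
  expect_equal(channel_entropy(v, 4), log(4), tolerance = 1e-9)
  # two bins p = (0.25, 0.75)
  v2 <- c(rep(0, 25), rep(1, 75))
  expect_equal(channel_entropy(v2, 2), -(0.25 * log(0.25) + 0.75 * log(0.75)),
               tolerance = 1e-9)
  expect_equal(channel_entropy(v2, 2, c_boltz = 2),
               2 * channel_entropy(v2, 2), tolerance = 1e-12)
})

test_that("discretizer recovers separated clusters and picks k by silhouette", {
  s <- make_stream(c(0, 0, 10, 10))
  m <- fit_discretizer(s, candidate_ks = 2, seed = 1)
  expect_equal(sort(unlist(m$centroids)), c(0, 10), ignore_attr = TRUE)
  expect_equal(unname(m$inertia["2"]), 0, tolerance = 1e-9)

  expect_error(suppressWarnings(fit_discretizer(make_stream(rep(5, 20)),
                                                candidate_ks = c(2, 3))),
               "skipped")

  # 3 well-separated Gaussians: silhouette should choose k = 3
  hits <- 0
  for (sd_i in 1:10) {
    set.seed(sd_i)
    v <- c(rnorm(100, 0, 0.1), rnorm(100, 5, 0.1), rnorm(100, 10, 0.1))
    m3 <- suppressWarnings(fit_discretizer(make_stream(v),
                                           candidate_ks = 2:5, seed = sd_i))
    if (m3$k == 3) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("quantization projects onto centroids with the stated tie rule", {
  s <- make_stream(c(0.2, 1.4, 2.0, 3.0, 3.9, 10))
  model <- structure(list(centroids = list(ch_0 = c(2, 4, 8))),
                     class = "discretization_model")
  q <- discretize(s, model)
  # exact centroid unchanged; equidistant 3.0 -> smaller centroid 2
  expect_equal(q$ch_0, c(2, 2, 2, 2, 4, 8))
  expect_true(all(q$ch_0 %in% c(2, 4, 8)))
  # projection: applying twice changes nothing
  expect_equal(discretize(q, model)$ch_0, q$ch_0)
  expect_equal(attr(q, "stage"), "digital")
})

test_that("fitted inertia equals the quantization error on the training stream", {
  set.seed(4)
  v <- c(rnorm(150, 0), rnorm(150, 6))
  s <- make_stream(v)
  m <- fit_discretizer(s, candidate_ks = 2, seed = 2, max_fit_n = Inf)
  q <- discretize(s, m)
  sse <- sum((v - q$ch_0)^2)
  expect_equal(sse, unname(m$inertia["2"]), tolerance = 1e-6)

  # inertia non-increasing in k (best of restarts)
  m2 <- fit_discretizer(s, candidate_ks = 2:6, seed = 3, max_fit_n = Inf)
  expect_true(all(diff(m2$inertia) <= 1e-9))
})

test_that("discretization model survives a JSON round-trip", {
  s <- make_stream(c(rnorm(50), rnorm(50, 8)))
  m <- fit_discretizer(s, candidate_ks = 2:3, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_discretizer_json(m, path)
  m2 <- read_discretizer_json(path)
  expect_equal(m2$k, m$k)
  expect_equal(m2$centroids$ch_0, m$centroids$ch_0, tolerance = 1e-12)
})
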