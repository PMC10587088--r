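test_that("grouped mode matches the closed form and its limits", {
  expect_equal(grouped_mode(10, 10, 7, 3, 4), 10 + 10 * 4 / 7,
               tolerance = 1e-12)
  # symmetric neighbours put the mode at the bin midpoint
  expect_equal(grouped_mode(2, 4, 9, 5, 5), 4)
  # preceding frequency equal to modal: mode at the lower edge
  expect_equal(grouped_mode(3, 2, 6, 6, 1), 3)
  # result is always inside the modal bin
  for (i in 1:50) {
    set.seed(i)
    fm <- runif(1, 5, 10); fp <- runif(1, 0, fm); fs <- runif(1, 0, fm)
    if ((fm - fp) + (fm - fs) == 0) next
    m <- grouped_mode(1, 2, fm, fp, fs)
    expect_gte(m, 1); expect_lte(m, 3)
  }
  expect_error(grouped_mode(0, 1, 5, 5, 5), "degenerate")
  expect_error(grouped_mode(0, 0, 5, 1, 1), "width")
})

test_that("binning covers the range and finds the modal bin", {
  b <- fit_bins(c(1, 2, 2, 3), n_bins = 3, strategy = "equal-width")
  expect_equal(b$freq, c(1, 2, 1))
  expect_equal(b$modal_bin, 2L)

  # constant values collapse to a single bin whose mode is the constant
  b2 <- fit_bins(rep(4.2, 10), n_bins = 4)
  expect_equal(b2$mode_value, 4.2)

  # equal-frequency on a uniform grid gives near-equal counts
  b3 <- fit_bins(seq(0, 1, length.out = 64), n_bins = 8,
                 strategy = "equal-frequency")
  expect_lte(max(b3$freq) - min(b3$freq), 1)

  expect_warning(fit_bins(c(1, 1, 2, 2, 3), n_bins = 8), "distinct")
})

test_that("cleaning smooths, imputes with the grouped mode and dedups", {
  sim <- tiny_stream(n_windows = 6, seed = 5,
                     defects = defect_spec(0.05, 0.1, 0.02))
  gt <- sim$ground_truth
  cl <- clean_records(sim$records)
  expect_false(anyNA(cl[paste0("ch_", 0:2)]))
  expect_equal(attr(cl, "stage"), "cleaned")
  # record count = input minus exact-duplicate count from ground truth
  expect_equal(nrow(cl), nrow(sim$records) - sum(gt$defect == "duplicate"))

  # every imputed slot equals its channel's grouped mode
  models <- attr(cl, "cleaning_models")
  dd <- dedup_records(sim$records)
  for (cc in paste0("ch_", 0:2)) {
    miss <- which(is.na(dd[[cc]]))
    if (length(miss)) {
      expect_true(all(cl[[cc]][miss] == models[[cc]]$mode_value))
    }
  }

  # single-bin limit: every value becomes the channel mean
  sim0 <- tiny_stream(n_windows = 2, seed = 9)
  cl1 <- clean_records(sim0$records, n_bins = 1, strategy = "equal-width")
  expect_equal(cl1$ch_0, rep(mean(sim0$records$ch_0), nrow(cl1)),
               tolerance = 1e-12)

  expect_error(
    clean_records(raw_record_set(
      data.frame(source_id = "s", timestamp = 0:2, ch_0 = NA_real_,
                 label = 1L), 1)),
    "entirely missing")
})

test_that("cleaning is idempotent, bounded, and variance-reducing", {
  sim <- tiny_stream(n_windows = 6, seed = 13,
                     defects = defect_spec(0.03, 0.03, 0.03))
  cl <- clean_records(sim$records)
  models <- attr(cl, "cleaning_models")
  cl2 <- clean_records(cl, models = models)
  for (cc in paste0("ch_", 0:2)) {
    expect_equal(cl2[[cc]], cl[[cc]], tolerance = 1e-12)
    orig <- sim$records[[cc]][!is.na(sim$records[[cc]])]
    expect_gte(min(cl[[cc]]), min(orig))
    expect_lte(max(cl[[cc]]), max(orig))
  }
  # bin-mean smoothing cannot increase per-channel variance
  dd <- dedup_records(sim$records)
  cl3 <- clean_records(dd, models = fit_cleaning_models(dd))
  for (cc in paste0("ch_", 0:2)) {
    keep <- !is.na(dd[[cc]])
    expect_lte(stats::var(cl3[[cc]][keep]), stats::var(dd[[cc]][keep]) + 1e-12)
  }
})
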