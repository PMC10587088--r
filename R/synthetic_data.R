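#' Activity signal model
#'
#' Describes one activity class as a mixture of per-channel sinusoids with
#' additive Gaussian noise and a per-window constant drift offset. Windows
#' simulated from these models carry the periodic structure that a wavelet
#' scattering front end is designed to discriminate.
#'
#' @param class_id Integer class label, unique within a generator config.
#' @param name Activity name (e.g. "walking").
#' @param base_freqs List (one element per channel) of oscillation frequencies
#'   in cycles/sample; all must lie in (0, 0.5), i.e. below Nyquist. A single
#'   numeric vector is recycled across channels.
#' @param amplitudes Per-channel amplitude in sensor units (recycled).
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param drift Length-2 range of the per-window constant offset.
#' @return An object of class `activity_model`.
#' @export
activity_model <- function(class_id, name, base_freqs, amplitudes = 1,
                           noise_sd = 0.1, drift = c(0, 0)) {
  if (!is.list(base_freqs)) base_freqs <- list(base_freqs)
  fr <- unlist(base_freqs)
  if (any(fr <= 0) || any(fr >= 0.5)) {
    stop("base_freqs must lie strictly inside (0, 0.5) cycles/sample")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(drift) != 2 || drift[2] < drift[1]) {
    stop("drift must be an increasing length-2 range")
  }
  structure(list(class_id = as.integer(class_id), name = as.character(name),
                 base_freqs = base_freqs, amplitudes = amplitudes,
                 noise_sd = noise_sd, drift = drift),
            class = "activity_model")
}

#' Default five-activity model set
#'
#' Five activity classes (walking, blinking, standing, sitting, emergency)
#' over tri-axial accelerometer-like channels, with class-specific dominant
#' frequencies and amplitudes chosen to be spectrally distinct.
#'
#' @param n_channels Number of sensor channels (default 3, tri-axial).
#' @param noise_sd Additive noise standard deviation shared by all classes.
#' @param drift Per-window constant offset range shared by all classes.
#' @param amplitude_scale Multiplier on every class amplitude; values near 0
#'   collapse the class-conditional signal structure into the noise floor
#'   (useful as a separability control).
#' @return List of [activity_model()] objects.
#' @export
default_activity_models <- function(n_channels = 3, noise_sd = 0.1,
                                    drift = c(-0.2, 0.2),
                                    amplitude_scale = 1) {
  specs <- list(
    list(1L, "walking",   c(0.06, 0.12),  1.5),
    list(2L, "blinking",  c(0.30),        0.6),
    list(3L, "standing",  c(0.02),        0.3),
    list(4L, "sitting",   c(0.04, 0.20),  0.8),
    list(5L, "emergency", c(0.18, 0.40),  2.0)
  )
  lapply(specs, function(s) {
    freqs <- lapply(seq_len(n_channels), function(c_i) {
      # stagger frequencies slightly per channel so channels are not clones
      s[[3]] * (1 + 0.05 * (c_i - 1))
    })
    amps <- amplitude_scale * s[[4]] * (1 - 0.1 * (seq_len(n_channels) - 1))
    activity_model(s[[1]], s[[2]], freqs, amps, noise_sd = noise_sd,
                   drift = drift)
  })
}

#' Defect injection specification
#'
#' @param missing_rate Fraction of records receiving one missing channel value.
#' @param duplicate_rate Fraction of records followed by an inserted exact copy.
#' @param corrupt_rate Fraction of records receiving one spiked channel value.
#' @param corrupt_magnitude Multiplier applied to the corrupted value.
#' @return An object of class `defect_spec`.
#' @export
defect_spec <- function(missing_rate = 0, duplicate_rate = 0,
                        corrupt_rate = 0, corrupt_magnitude = 50) {
  rates <- c(missing_rate, duplicate_rate, corrupt_rate)
  if (any(rates < 0) || any(rates > 1)) stop("defect rates must lie in [0, 1]")
  if (sum(rates) > 1) stop("defect rates must sum to at most 1")
  structure(list(missing_rate = missing_rate, duplicate_rate = duplicate_rate,
                 corrupt_rate = corrupt_rate,
                 corrupt_magnitude = corrupt_magnitude),
            class = "defect_spec")
}

#' Construct a raw record set
#'
#' A raw record set is a data frame of timestamped multi-channel sensor
#' samples with columns `source_id`, `timestamp`, `ch_0` .. `ch_{k-1}`,
#' `label`. Missing entries are encoded as `NA` (flagged, never absent).
#'
#' @param df Data frame with the columns above.
#' @param n_channels Number of channel columns.
#' @param sample_rate Nominal sampling rate in Hz.
#' @param stage Processing stage tag: "raw", "cleaned", "integrated" or
#'   "digital".
#' @return Object of class `raw_record_set` (a data frame).
#' @export
raw_record_set <- function(df, n_channels, sample_rate = 1, stage = "raw") {
  need <- c("source_id", "timestamp", paste0("ch_", seq_len(n_channels) - 1L),
            "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- df[, need]
  for (src in split(df$timestamp, df$source_id)) {
    if (is.unsorted(src)) stop("timestamps must be non-decreasing per source")
  }
  structure(df, n_channels = as.integer(n_channels),
            sample_rate = sample_rate, stage = stage,
            class = c("raw_record_set", "data.frame"))
}

#' @export
print.raw_record_set <- function(x, ...) {
  cat(sprintf("<raw_record_set> %d records, %d channels, stage=%s\n",
              nrow(x), attr(x, "n_channels"), attr(x, "stage")))
  invisible(x)
}

channel_cols <- function(records) {
  paste0("ch_", seq_len(attr(records, "n_channels")) - 1L)
}

#' Generate a synthetic wearable-sensor dataset
#'
#' Simulates a labeled sensor stream as consecutive fixed-length windows,
#' one block of windows per activity class interleaved across classes, then
#' injects missing values, exact consecutive duplicates and multiplicative
#' corruption spikes at the requested rates. Every injected defect position
#' is recorded in the returned ground truth, so cleaning can be audited
#' exactly.
#'
#' @param models List of [activity_model()] objects (non-empty).
#' @param n_windows_per_class Number of windows simulated per class (>= 1).
#' @param window_len Window length in samples (>= 8).
#' @param n_channels Number of channels; must match the models.
#' @param defects A [defect_spec()].
#' @param seed Integer seed; equal (config, seed) gives identical output.
#' @return List with elements `records` (defected [raw_record_set()]),
#'   `clean` (the same stream before defect injection), `ground_truth`
#'   (data frame of `row`, `defect`, `channel` for every injected defect,
#'   rows indexing `records`), and `window_id` (per-record window index in
#'   `clean`).
#' @export
generate_dataset <- function(models, n_windows_per_class, window_len = 128,
                             n_channels = 3, defects = defect_spec(),
                             seed = 1) {
  if (length(models) == 0) stop("configuration error: empty model list")
  if (window_len < 8) stop("size error: window_len must be >= 8")
  if (n_windows_per_class < 1) stop("n_windows_per_class must be >= 1")
  set.seed(seed)
  tt <- seq_len(window_len) - 1L
  win_list <- list()
  lab_list <- integer(0)
  # interleave classes so the stream alternates activities window by window
  for (w in seq_len(n_windows_per_class)) {
    for (m in models) {
      freqs <- rep(m$base_freqs, length.out = n_channels)
      amps <- rep(m$amplitudes, length.out = n_channels)
      off <- stats::runif(1, m$drift[1], m$drift[2])
      win <- vapply(seq_len(n_channels), function(c_i) {
        f <- freqs[[c_i]]
        ph <- stats::runif(length(f), 0, 2 * pi)
        sig <- rowSums(vapply(seq_along(f), function(i) {
          (amps[c_i] / length(f)) * sin(2 * pi * f[i] * tt + ph[i])
        }, numeric(window_len)))
        sig + off + stats::rnorm(window_len, 0, m$noise_sd)
      }, numeric(window_len))
      win_list[[length(win_list) + 1L]] <- win
      lab_list <- c(lab_list, m$class_id)
    }
  }
  vals <- do.call(rbind, win_list)
  colnames(vals) <- paste0("ch_", seq_len(n_channels) - 1L)
  n_rec <- nrow(vals)
  clean_df <- data.frame(source_id = "sim",
                         timestamp = seq_len(n_rec) - 1L,
                         vals,
                         label = rep(lab_list, each = window_len),
                         stringsAsFactors = FALSE)
  clean <- raw_record_set(clean_df, n_channels, sample_rate = 1,
                          stage = "raw")
  window_id <- rep(seq_along(lab_list), each = window_len)

  # defect injection: each record draws at most one defect category
  u <- stats::runif(n_rec)
  p1 <- defects$missing_rate
  p2 <- p1 + defects$corrupt_rate
  p3 <- p2 + defects$duplicate_rate
  kind <- ifelse(u < p1, "missing", ifelse(u < p2, "corrupt",
                 ifelse(u < p3, "duplicate", "none")))
  chan <- ifelse(kind %in% c("missing", "corrupt"),
                 sample.int(n_channels, n_rec, replace = TRUE) - 1L, NA)
  out_df <- clean_df
  ch_cols <- paste0("ch_", seq_len(n_channels) - 1L)
  for (i in which(kind == "missing")) out_df[i, ch_cols[chan[i] + 1L]] <- NA
  for (i in which(kind == "corrupt")) {
    cc <- ch_cols[chan[i] + 1L]
    out_df[i, cc] <- out_df[i, cc] * defects$corrupt_magnitude
  }
  dup_at <- which(kind == "duplicate")
  if (length(dup_at)) {
    # insert an exact copy directly after each duplicated record
    reps <- rep(1L, n_rec)
    reps[dup_at] <- 2L
    idx <- rep(seq_len(n_rec), reps)
    out_df <- out_df[idx, , drop = FALSE]
    rownames(out_df) <- NULL
    # cumsum(reps) is each original's last copy: for duplicated records that
    # is the inserted copy, for all others the record itself
    new_pos <- cumsum(reps)
    gt_rows <- c(which(kind == "missing"), which(kind == "corrupt"))
    gt <- data.frame(
      row = c(new_pos[gt_rows], new_pos[dup_at]),
      defect = c(kind[gt_rows], rep("duplicate", length(dup_at))),
      channel = c(chan[gt_rows], rep(NA_integer_, length(dup_at))))
  } else {
    gt_rows <- which(kind != "none")
    gt <- data.frame(row = gt_rows, defect = kind[gt_rows],
                     channel = chan[gt_rows])
  }
  gt <- gt[order(gt$row), , drop = FALSE]
  rownames(gt) <- NULL
  records <- raw_record_set(out_df, n_channels, sample_rate = 1,
                            stage = "raw")
  list(records = records, clean = clean, ground_truth = gt,
       window_id = window_id)
}

#' Generate a feature table with planted informative columns
#'
#' Test harness for wrapper feature selection: standard-normal noise columns
#' plus a planted subset whose class-conditional means are shifted by a
#' stated standardized effect size (the between-adjacent-class shift equals
#' `effect_size` in units of the within-class standard deviation).
#'
#' @param n_samples Number of rows.
#' @param n_features Number of columns.
#' @param n_informative Number of planted informative columns
#'   (`<= n_features`).
#' @param effect_size Standardized mean shift between adjacent classes (> 0,
#'   or 0 for the null case).
#' @param n_classes Number of classes (labels `1..n_classes`, balanced).
#' @param seed Integer seed.
#' @return List with `x` (matrix), `y` (integer labels) and `informative`
#'   (sorted planted column indices).
#' @export
generate_informative_feature_table <- function(n_samples, n_features,
                                               n_informative, effect_size,
                                               n_classes = 2, seed = 1) {
  if (n_informative > n_features) {
    stop("configuration error: n_informative > n_features")
  }
  if (effect_size < 0) stop("effect_size must be >= 0")
  set.seed(seed)
  y <- sample(rep_len(seq_len(n_classes), n_samples))
  x <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
  informative <- sort(sample.int(n_features, n_informative))
  mu <- effect_size * (y - (n_classes + 1) / 2)  # centered class means
  for (j in informative) x[, j] <- x[, j] + mu
  colnames(x) <- paste0("f_", seq_len(n_features))
  list(x = x, y = as.integer(y), informative = informative)
}
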