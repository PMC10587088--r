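#' One-vs-rest confusion counts
#'
#' @param pred Predicted labels.
#' @param truth True labels.
#' @param classes Class set (default: sorted union).
#' @return Data frame with one row per class: `class`, `tp`, `tn`, `fp`,
#'   `fn`; each row sums to `length(truth)`.
#' @export
confusion_counts <- function(pred, truth, classes = NULL) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (is.null(classes)) classes <- sort(unique(c(pred, truth)))
  n <- length(truth)
  out <- data.frame(class = classes, tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (i in seq_along(classes)) {
    cl <- classes[i]
    out$tp[i] <- sum(pred == cl & truth == cl)
    out$fp[i] <- sum(pred == cl & truth != cl)
    out$fn[i] <- sum(pred != cl & truth == cl)
    out$tn[i] <- n - out$tp[i] - out$fp[i] - out$fn[i]
  }
  out
}

safe_ratio <- function(num, den) {
  flagged <- den == 0
  val <- ifelse(flagged, 0, num / ifelse(flagged, 1, den))
  list(value = val, undefined = flagged)
}

#' Classification metrics from confusion counts
#'
#' Per class (one-vs-rest): accuracy `(TP+TN)/n * 100`, precision
#' `TP/(TP+FP) * 100`, recall `TP/(TP+FN) * 100` and F-score, the harmonic
#' mean `2 P R / (P + R)`. Macro metrics average the per-class values.
#' Overall accuracy is the fraction of correctly labeled samples (for a
#' single binary row this equals the per-class accuracy). Zero-denominator
#' metrics are reported as 0 with the `undefined` flag set.
#'
#' @param counts Data frame from [confusion_counts()] (columns `tp`, `tn`,
#'   `fp`, `fn`; negative counts are an error).
#' @return Object of class `metric_report`: `per_class` data frame with
#'   `accuracy`, `precision`, `recall`, `f_score` (in percent) and
#'   `undefined` flags, plus `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f_score` scalars.
#' @export
compute_metrics <- function(counts) {
  need <- c("tp", "tn", "fp", "fn")
  if (!all(need %in% names(counts))) stop("counts must have tp/tn/fp/fn")
  if (any(unlist(counts[need]) < 0)) stop("validation error: negative counts")
  n <- counts$tp + counts$tn + counts$fp + counts$fn
  acc <- 100 * (counts$tp + counts$tn) / n
  prec <- safe_ratio(100 * counts$tp, counts$tp + counts$fp)
  rec <- safe_ratio(100 * counts$tp, counts$tp + counts$fn)
  f_den <- prec$value + rec$value
  f <- safe_ratio(2 * prec$value * rec$value, f_den)
  per_class <- data.frame(
    class = if (!is.null(counts$class)) counts$class else seq_len(nrow(counts)),
    accuracy = acc, precision = prec$value, recall = rec$value,
    f_score = f$value,
    undefined = prec$undefined | rec$undefined | f$undefined)
  overall <- if (nrow(counts) == 1) acc[1] else 100 * sum(counts$tp) / n[1]
  structure(list(per_class = per_class,
                 accuracy = overall,
                 macro_precision = mean(per_class$precision),
                 macro_recall = mean(per_class$recall),
                 macro_f_score = mean(per_class$f_score)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> accuracy %.3f%%, macro P %.3f%% R %.3f%% F %.3f%%\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f_score))
  invisible(x)
}

#' Stratified 80/20 train/test split
#'
#' Per class, `round(0.8 * n_class)` windows go to training (at least one
#' window is always kept on each side); the split is disjoint, exhaustive
#' and deterministic given the seed.
#'
#' @param labels Integer label vector (or a [window_set()], whose labels
#'   are used).
#' @param seed Integer seed.
#' @param train_frac Training fraction (default 0.8).
#' @return List with integer index vectors `train` and `test`.
#' @export
split_80_20 <- function(labels, seed = 1, train_frac = 0.8) {
  if (inherits(labels, "window_set")) labels <- labels$labels
  tab <- table(labels)
  if (any(tab < 2)) {
    stop("stratification error: class ",
         names(tab)[which(tab < 2)[1]], " has fewer than 2 windows")
  }
  set.seed(seed)
  train <- integer(0)
  for (cl in names(tab)) {
    ix <- which(labels == as.integer(cl))
    n_tr <- min(max(round(train_frac * length(ix)), 1L), length(ix) - 1L)
    train <- c(train, ix[sample.int(length(ix))][seq_len(n_tr)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Default pipeline configuration
#'
#' Nested list of every stage's parameters; any entry can be overridden by
#' the matching argument of [run_pipeline()] config, or by a YAML file with
#' the same structure.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @return Nested configuration list.
#' @export
har_config <- function(seed = 1) {
  list(
    data = list(n_windows_per_class = 200, window_len = 128, n_channels = 3,
                noise_sd = 0.1, drift = c(-0.2, 0.2), amplitude_scale = 1,
                missing_rate = 0.02, duplicate_rate = 0.02,
                corrupt_rate = 0.02, corrupt_magnitude = 50,
                path = NULL, decimate = 1),
    cleaning = list(n_bins = 16, strategy = "equal-frequency",
                    smoothing = "means"),
    transform = list(candidate_ks = c(4, 6, 8, 12, 16), n_init = 10,
                     c_boltz = 1, max_fit_n = 20000),
    scattering = list(J = 4),
    selection = list(pop_size = 20, iter_max = 100, threshold = 0.5,
                     omega = 0.01, n_trials = 10, prob = 0.5),
    classifier = list(n_lego = 4, fragment_dim = 4, kernel_len = 3,
                      n_layers = 2, learning_rate = 0.05, epochs = 200,
                      batch_size = 32),
    eval = list(train_frac = 0.8, permute_labels = FALSE),
    seed = seed
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' Entries present in the file override [har_config()] defaults.
#'
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  merge_config(har_config(), yaml::read_yaml(path))
}

# windows over record positions, tolerant of missing channel values; used
# to define the train/test membership before any model is fitted
provisional_windows <- function(records, window_len) {
  out <- list()
  for (sid in unique(records$source_id)) {
    ix <- which(records$source_id == sid)
    n_w <- length(ix) %/% window_len
    for (w in seq_len(n_w)) {
      sel <- ix[((w - 1) * window_len + 1):(w * window_len)]
      out[[length(out) + 1L]] <- list(rows = sel,
                                      label = majority_label(records$label[sel]))
    }
  }
  out
}

#' Run the end-to-end activity-recognition pipeline
#'
#' Stages, in order: simulate (or read) the raw stream; drop exact
#' consecutive duplicates; integrate sources; define the stratified 80/20
#' window split; fit the cleaning (binning/smoothing/imputation) models and
#' the discretizer on training records only and apply them to the whole
#' stream; segment into windows; extract scattering features; select
#' features by the eagle optimizer on the training split; fit the scatter
#' summary on the training split and normalize; train the Lego classifier;
#' evaluate on the held-out windows.
#'
#' @param config A configuration list from [har_config()] (possibly
#'   partially overridden), a YAML path, or `NULL` for defaults.
#' @param out_dir Optional directory for artifacts (feature CSV, model
#'   JSON, report JSON).
#' @return List with `report` (the [compute_metrics()] result plus split
#'   sizes, seed and config hash), `models` (all fitted stage models),
#'   `features`, `split`, `selection`, and `timing` (per-stage seconds,
#'   excluded from the report hash).
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- merge_config(har_config(), if (is.null(config)) list() else config)
  seed <- config$seed
  timing <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  # --- data ---------------------------------------------------------------
  if (!is.null(config$data$path)) {
    records <- read_raw_csv(config$data$path)
  } else {
    models <- default_activity_models(n_channels = config$data$n_channels,
                                      noise_sd = config$data$noise_sd,
                                      drift = config$data$drift,
                                      amplitude_scale = config$data$amplitude_scale)
    sim <- generate_dataset(models, config$data$n_windows_per_class,
                            window_len = config$data$window_len,
                            n_channels = config$data$n_channels,
                            defects = defect_spec(config$data$missing_rate,
                                                  config$data$duplicate_rate,
                                                  config$data$corrupt_rate,
                                                  config$data$corrupt_magnitude),
                            seed = seed)
    records <- sim$records
  }
  timing["data"] <- tic() - t0; t0 <- tic()

  # --- stateless cleaning steps + split definition ------------------------
  records <- dedup_records(records)
  records <- integrate_sources(list(records))
  if (config$data$decimate > 1) {
    records <- decimate_records(records, config$data$decimate)
  }
  wl <- config$data$window_len
  pw <- provisional_windows(records, wl)
  labels <- vapply(pw, `[[`, integer(1), "label")
  if (isTRUE(config$eval$permute_labels)) {
    set.seed(seed + 101L)
    perm <- sample(length(labels))
    labels <- labels[perm]
    for (i in seq_along(pw)) {
      records$label[pw[[i]]$rows] <- labels[i]
    }
  }
  split <- split_80_20(labels, seed = seed,
                       train_frac = config$eval$train_frac)
  train_rows <- unlist(lapply(pw[split$train], `[[`, "rows"))
  timing["split"] <- tic() - t0; t0 <- tic()

  # --- fitted cleaning + discretization (train records only) --------------
  train_records <- raw_record_set(as.data.frame(records)[train_rows, ],
                                  attr(records, "n_channels"),
                                  stage = attr(records, "stage"))
  cleaning_models <- fit_cleaning_models(train_records,
                                         n_bins = config$cleaning$n_bins,
                                         strategy = config$cleaning$strategy)
  cleaned <- clean_records(records, smoothing = config$cleaning$smoothing,
                           models = cleaning_models)
  timing["clean"] <- tic() - t0; t0 <- tic()
  train_cleaned <- raw_record_set(as.data.frame(cleaned)[train_rows, ],
                                  attr(cleaned, "n_channels"),
                                  stage = "cleaned")
  discretizer <- fit_discretizer(train_cleaned,
                                 candidate_ks = config$transform$candidate_ks,
                                 n_init = config$transform$n_init,
                                 seed = seed,
                                 c_boltz = config$transform$c_boltz,
                                 max_fit_n = config$transform$max_fit_n)
  digital <- discretize(cleaned, discretizer)
  timing["transform"] <- tic() - t0; t0 <- tic()

  # --- segmentation + scattering features ---------------------------------
  ws <- segment_stream(digital, wl, hop = wl)
  bank <- build_filter_bank(config$scattering$J, wl)
  feats <- extract_features(ws, bank)
  timing["features"] <- tic() - t0; t0 <- tic()

  # --- selection (train only, on z-scored features) -----------------------
  pre_summary <- scatter_summary(feats[split$train, , drop = FALSE])
  feats_std <- normalize_features(feats, pre_summary)
  sel <- select_features(feats_std[split$train, , drop = FALSE],
                         ws$labels[split$train],
                         pop_size = config$selection$pop_size,
                         iter_max = config$selection$iter_max,
                         threshold = config$selection$threshold,
                         omega = config$selection$omega,
                         seed = seed,
                         n_trials = config$selection$n_trials,
                         prob = config$selection$prob)
  timing["selection"] <- tic() - t0; t0 <- tic()

  # --- post-processing (scatter summary on train split) -------------------
  sel_cols <- which(sel$mask)
  summ <- scatter_summary(feats[split$train, sel_cols, drop = FALSE])
  x_train <- normalize_features(feats[split$train, sel_cols, drop = FALSE], summ)
  x_test <- normalize_features(feats[split$test, sel_cols, drop = FALSE], summ)
  timing["postprocess"] <- tic() - t0; t0 <- tic()

  # --- classifier ----------------------------------------------------------
  net <- init_network(length(sel_cols), n_classes = length(unique(ws$labels)),
                      n_lego = config$classifier$n_lego,
                      fragment_dim = min(config$classifier$fragment_dim,
                                         length(sel_cols)),
                      kernel_len = config$classifier$kernel_len,
                      n_layers = config$classifier$n_layers, seed = seed)
  net <- train_network(net, x_train, ws$labels[split$train],
                       config = train_config(
                         learning_rate = config$classifier$learning_rate,
                         epochs = config$classifier$epochs,
                         batch_size = config$classifier$batch_size,
                         seed = seed))
  pred <- predict_network(net, x_test, y = ws$labels[split$test])
  timing["classifier"] <- tic() - t0

  metrics <- compute_metrics(pred$confusion)
  report <- list(
    accuracy = metrics$accuracy,
    macro_precision = metrics$macro_precision,
    macro_recall = metrics$macro_recall,
    macro_f_score = metrics$macro_f_score,
    per_class = metrics$per_class,
    n_train = length(split$train), n_test = length(split$test),
    n_features = ncol(feats), n_selected = sel$n_selected,
    discretization_k = discretizer$k,
    seed = seed,
    config_hash = config_hash(config))
  result <- list(report = report, metrics = metrics,
                 models = list(cleaning = cleaning_models,
                               discretizer = discretizer,
                               bank = bank, pre_summary = pre_summary,
                               selection = sel, summary = summ,
                               classifier = net),
                 features = feats, split = split, window_labels = ws$labels,
                 predictions = pred, timing = timing)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

config_hash <- function(config) {
  # order-stable serialization; good enough for change detection
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  sum(utf8ToInt(as.character(s)) * (seq_len(nchar(as.character(s))) %% 997)) %% 1e9
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  feats <- result$features
  df <- data.frame(label = result$window_labels, feats, check.names = FALSE)
  utils::write.csv(df, file.path(out_dir, "features.csv"), row.names = FALSE)
  jsonlite::write_json(result$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(list(k = result$models$discretizer$k,
                            centroids = result$models$discretizer$centroids,
                            entropy = result$models$discretizer$entropy,
                            selected = result$models$selection$selected_names),
                       file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
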