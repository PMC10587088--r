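#' Mode of grouped (binned) data
#'
#' Estimates the mode of a binned value distribution from the modal bin and
#' its neighbours:
#' \deqn{M = l + t \frac{F^m - F^p}{(F^m - F^p) + (F^m - F^s)}}
#' where `l` and `t` are the modal bin's lower limit and width, and `F^m`,
#' `F^p`, `F^s` are the frequencies of the modal, preceding and succeeding
#' bins. The result always lies inside the modal bin, `[l, l + t]`.
#'
#' @param l Lower limit of the modal bin.
#' @param t Bin width (> 0).
#' @param f_m Modal bin frequency (must be >= both neighbours).
#' @param f_p Preceding bin frequency.
#' @param f_s Succeeding bin frequency.
#' @return The grouped mode, in sensor units.
#' @export
grouped_mode <- function(l, t, f_m, f_p, f_s) {
  if (t <= 0) stop("bin width t must be > 0")
  if (f_m < f_p || f_m < f_s) {
    stop("modal frequency must be >= neighbour frequencies")
  }
  denom <- (f_m - f_p) + (f_m - f_s)
  if (denom == 0) {
    stop(structure(class = c("harpipe_degenerate_mode", "error", "condition"),
                   list(message = "degenerate grouped mode: flat histogram around the modal bin",
                        call = sys.call())))
  }
  l + t * (f_m - f_p) / denom
}

#' Fit a per-channel binning model
#'
#' Partitions a channel's non-missing values into bins (equal-width or
#' equal-frequency), records per-bin frequencies and smoothing
#' representatives (mean, median and boundaries), and computes the channel
#' mode via [grouped_mode()] on the modal bin. A flat histogram around the
#' modal bin falls back to the modal bin midpoint, the symmetric limit of the
#' grouped-mode formula.
#'
#' @param values Numeric vector of non-missing channel values.
#' @param n_bins Number of bins (>= 1; a single bin smooths every value to
#'   one representative).
#' @param strategy `"equal-frequency"` (default) or `"equal-width"`.
#' @return An object of class `binning_model` with elements `edges`,
#'   `freq`, `means`, `medians`, `modal_bin`, `mode_value`.
#' @export
fit_bins <- function(values, n_bins = 16,
                     strategy = c("equal-frequency", "equal-width")) {
  strategy <- match.arg(strategy)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values to bin")
  if (n_bins < 1) stop("n_bins must be >= 1")
  distinct <- sort(unique(values))
  if (length(distinct) == 1) {
    # constant channel: single effective bin, mode is the constant
    return(structure(list(edges = c(distinct, distinct), freq = length(values),
                          means = distinct, medians = distinct,
                          modal_bin = 1L, mode_value = distinct,
                          strategy = strategy),
                     class = "binning_model"))
  }
  if (length(distinct) < n_bins) {
    warning(sprintf("only %d distinct values for %d bins; collapsing to distinct-value bins",
                    length(distinct), n_bins))
    mids <- (distinct[-1] + distinct[-length(distinct)]) / 2
    edges <- c(distinct[1], mids, distinct[length(distinct)])
  } else if (strategy == "equal-width") {
    edges <- seq(min(values), max(values), length.out = n_bins + 1L)
  } else {
    probs <- seq(0, 1, length.out = n_bins + 1L)
    edges <- unname(stats::quantile(values, probs, type = 7))
    edges <- unique(edges)
    if (length(edges) < 3) edges <- range(values)
  }
  nb <- length(edges) - 1L
  # bins are [edge_i, edge_{i+1}) with the last bin closed on the right
  bin_of <- findInterval(values, edges, rightmost.closed = TRUE,
                         all.inside = TRUE)
  freq <- tabulate(bin_of, nbins = nb)
  means <- vapply(seq_len(nb), function(b) {
    if (freq[b] == 0) (edges[b] + edges[b + 1]) / 2 else mean(values[bin_of == b])
  }, numeric(1))
  medians <- vapply(seq_len(nb), function(b) {
    if (freq[b] == 0) (edges[b] + edges[b + 1]) / 2 else stats::median(values[bin_of == b])
  }, numeric(1))
  modal_bin <- which.max(freq)
  f_m <- freq[modal_bin]
  f_p <- if (modal_bin > 1) freq[modal_bin - 1L] else 0
  f_s <- if (modal_bin < nb) freq[modal_bin + 1L] else 0
  l <- edges[modal_bin]; t_w <- edges[modal_bin + 1L] - edges[modal_bin]
  mode_value <- tryCatch(grouped_mode(l, t_w, f_m, f_p, f_s),
                         harpipe_degenerate_mode = function(e) l + t_w / 2)
  structure(list(edges = edges, freq = freq, means = means,
                 medians = medians, modal_bin = modal_bin,
                 mode_value = mode_value, strategy = strategy),
            class = "binning_model")
}

smooth_values <- function(values, model, smoothing) {
  edges <- model$edges
  nb <- max(length(edges) - 1L, 1L)
  out <- values
  nn <- !is.na(values)
  if (length(edges) == 2 && edges[1] == edges[2]) {
    out[nn] <- model$means[1]
  } else {
    # out-of-range values clamp into the terminal bins
    b <- findInterval(values[nn], edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
    rep_v <- switch(smoothing,
                    means = model$means,
                    medians = model$medians,
                    boundaries = NULL)
    if (smoothing == "boundaries") {
      lo <- edges[b]; hi <- edges[b + 1L]
      v <- values[nn]
      out[nn] <- ifelse(v - lo <= hi - v, lo, hi)
    } else {
      out[nn] <- rep_v[b]
    }
    # the channel mode is the channel's central representative and is left
    # invariant by smoothing, so imputation and smoothing commute and
    # cleaning is idempotent under a fixed model
    out[nn][values[nn] == model$mode_value] <- model$mode_value
  }
  out[!nn] <- model$mode_value  # impute missing with the grouped mode
  out
}

#' Fit MIBA cleaning models for every channel
#'
#' @param records A [raw_record_set()] (may contain defects).
#' @param n_bins Bins per channel.
#' @param strategy Binning strategy, see [fit_bins()].
#' @return List of `binning_model`, one per channel.
#' @export
fit_cleaning_models <- function(records, n_bins = 16,
                                strategy = c("equal-frequency", "equal-width")) {
  strategy <- match.arg(strategy)
  ch <- channel_cols(records)
  models <- list()
  for (cc in ch) {
    v <- records[[cc]]
    if (all(is.na(v))) stop("channel ", cc, " is entirely missing")
    models[[cc]] <- fit_bins(v, n_bins = n_bins, strategy = strategy)
  }
  models
}

#' Remove exact consecutive duplicate records
#'
#' A duplicate is a record identical to its predecessor in all channels,
#' timestamp and source (missing entries compare equal to missing).
#'
#' @param records A [raw_record_set()].
#' @return The record set with duplicate copies dropped.
#' @export
dedup_records <- function(records) {
  if (nrow(records) < 2) return(records)
  df <- as.data.frame(records)
  cols <- c("source_id", "timestamp", channel_cols(records))
  cur <- df[-1, cols, drop = FALSE]
  prev <- df[-nrow(df), cols, drop = FALSE]
  same <- rep(TRUE, nrow(cur))
  for (cc in cols) {
    a <- cur[[cc]]; b <- prev[[cc]]
    eq <- (a == b) | (is.na(a) & is.na(b))
    eq[is.na(eq)] <- FALSE
    same <- same & eq
  }
  keep <- c(TRUE, !same)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  raw_record_set(out, attr(records, "n_channels"),
                 sample_rate = attr(records, "sample_rate"),
                 stage = attr(records, "stage"))
}

#' Clean a record stream by mode-integrated binning
#'
#' Removes exact consecutive duplicates, smooths every non-missing value to
#' its bin's representative (bin means by default), and imputes every
#' missing value with the channel's grouped-data mode. The output carries no
#' missing flags.
#'
#' @param records A [raw_record_set()] with possible defects.
#' @param n_bins Bins per channel (default 16).
#' @param strategy Binning strategy (default equal-frequency).
#' @param smoothing `"means"` (default), `"medians"` or `"boundaries"`.
#' @param models Optional prefitted output of [fit_cleaning_models()]; when
#'   supplied (e.g. fitted on a training subset) no refitting occurs.
#' @return A cleaned [raw_record_set()] with attribute `stage = "cleaned"`
#'   and the fitted models attached as attribute `cleaning_models`.
#' @export
clean_records <- function(records, n_bins = 16,
                          strategy = c("equal-frequency", "equal-width"),
                          smoothing = c("means", "medians", "boundaries"),
                          models = NULL) {
  strategy <- match.arg(strategy)
  smoothing <- match.arg(smoothing)
  records <- dedup_records(records)
  if (is.null(models)) {
    models <- fit_cleaning_models(records, n_bins = n_bins, strategy = strategy)
  }
  df <- as.data.frame(records)
  for (cc in channel_cols(records)) {
    df[[cc]] <- smooth_values(df[[cc]], models[[cc]], smoothing)
  }
  out <- raw_record_set(df, attr(records, "n_channels"),
                        sample_rate = attr(records, "sample_rate"),
                        stage = "cleaned")
  attr(out, "cleaning_models") <- models
  out
}
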