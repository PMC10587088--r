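#' Construct a window set
#'
#' A window set holds fixed-length labeled signal windows as a 3-d array of
#' shape (n_windows, n_channels, window_len), the container consumed by the
#' scattering front end.
#'
#' @param windows Numeric array (n_windows x n_channels x window_len); no
#'   missing entries.
#' @param labels Integer label vector, length n_windows.
#' @param channel_names Optional channel names (default `ch_0`, ...).
#' @param provenance Optional data frame with per-window `source_id` and
#'   `start` index.
#' @param stage Processing stage tag.
#' @return Object of class `window_set`.
#' @export
window_set <- function(windows, labels, channel_names = NULL,
                       provenance = NULL, stage = "windows") {
  if (length(dim(windows)) != 3) stop("windows must be a 3-d array")
  if (dim(windows)[1] != length(labels)) {
    stop("labels length must equal the number of windows")
  }
  if (anyNA(windows)) stop("window set must contain no missing entries")
  if (is.null(channel_names)) {
    channel_names <- paste0("ch_", seq_len(dim(windows)[2]) - 1L)
  }
  structure(list(windows = windows, labels = as.integer(labels),
                 channel_names = channel_names, provenance = provenance,
                 stage = stage),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_set> %d windows x %d channels x %d samples, stage=%s\n",
              d[1], d[2], d[3], x$stage))
  invisible(x)
}

#' Read a raw sensor CSV
#'
#' Reads delimited sensor records with columns
#' `source_id,timestamp,ch_0..ch_{k-1},label`. Empty fields become flagged
#' missing values (`NA`); rows are never silently dropped.
#'
#' @param path File path.
#' @param channels Channel column names; default: every column starting with
#'   `ch_` in the header.
#' @param label_col Label column name.
#' @param valid_labels Optional integer set; any other label value is an
#'   error listing the offending values.
#' @return A [raw_record_set()].
#' @export
read_raw_csv <- function(path, channels = NULL, label_col = "label",
                         valid_labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(channels)) channels <- grep("^ch_", names(df), value = TRUE)
  if (length(channels) < 1) stop("schema must name at least one channel column")
  for (cc in channels) {
    v <- df[[cc]]
    if (is.character(v)) v[v == ""] <- NA
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(vn))
    if (length(bad)) {
      stop(sprintf("unparseable value in column %s at line %d: '%s'",
                   cc, bad[1] + 1L, v[bad[1]]))
    }
    df[[cc]] <- vn
  }
  if (!is.null(valid_labels)) {
    bad <- setdiff(unique(df[[label_col]][!is.na(df[[label_col]])]),
                   valid_labels)
    if (length(bad)) {
      stop("unknown label symbol(s): ", paste(bad, collapse = ", "))
    }
  }
  names(df)[names(df) == label_col] <- "label"
  df$label <- as.integer(df$label)
  raw_record_set(df, n_channels = length(channels), stage = "raw")
}

#' Write a raw record set as CSV
#'
#' Missing entries are written as empty fields.
#'
#' @param records A [raw_record_set()].
#' @param path Output file path.
#' @export
write_raw_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read a UCI-HAR-style fixed-width window layout
#'
#' Reads a directory of whitespace-delimited per-channel window files (one
#' row per window) plus a label file with one label per row, and stacks the
#' channels into a (n, c, window_len) window set.
#'
#' @param dir Directory path.
#' @param channel_files Channel file names within `dir`; default: every
#'   `*.txt` file except the label file, in sorted order.
#' @param label_file Label file name; default: the `*.txt` file whose name
#'   starts with `y` or `label`.
#' @return A [window_set()].
#' @export
read_ucihar_layout <- function(dir, channel_files = NULL, label_file = NULL) {
  files <- sort(list.files(dir, pattern = "\\.txt$"))
  if (is.null(label_file)) {
    label_file <- files[grepl("^(y|label)", files)][1]
    if (is.na(label_file)) stop("no label file (y*.txt or label*.txt) found")
  }
  if (is.null(channel_files)) channel_files <- setdiff(files, label_file)
  if (length(channel_files) < 1) stop("no channel files found")
  mats <- lapply(channel_files, function(f) {
    as.matrix(utils::read.table(file.path(dir, f)))
  })
  n <- nrow(mats[[1]])
  len <- ncol(mats[[1]])
  for (i in seq_along(mats)) {
    if (nrow(mats[[i]]) != n || ncol(mats[[i]]) != len) {
      stop(sprintf("structural error: %s has %d x %d rows/cols, expected %d x %d",
                   channel_files[i], nrow(mats[[i]]), ncol(mats[[i]]), n, len))
    }
  }
  labels <- utils::read.table(file.path(dir, label_file))[[1]]
  if (length(labels) != n) {
    stop(sprintf("structural error: %d labels for %d windows",
                 length(labels), n))
  }
  w <- array(0, dim = c(n, length(mats), len))
  for (c_i in seq_along(mats)) w[, c_i, ] <- mats[[c_i]]
  window_set(w, labels,
             channel_names = sub("\\.txt$", "", channel_files),
             stage = "windows")
}

#' Decimate a record stream by averaging
#'
#' Downsamples each source's stream by an integer factor, replacing each
#' block of `factor` consecutive samples by its per-channel mean (labels by
#' majority, ties toward the smaller class id). Used to harmonize collection
#' rates to a nominal 1 Hz before segmentation.
#'
#' @param records A defect-free [raw_record_set()].
#' @param factor Integer decimation factor (>= 1).
#' @return A [raw_record_set()] at `sample_rate / factor`.
#' @export
decimate_records <- function(records, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1) return(records)
  if (anyNA(records[channel_cols(records)])) {
    stop("records contain missing values; clean before decimating")
  }
  ch <- channel_cols(records)
  out <- lapply(split(seq_len(nrow(records)), records$source_id), function(ix) {
    n_blk <- length(ix) %/% factor
    if (n_blk == 0) return(NULL)
    ix <- ix[seq_len(n_blk * factor)]
    blk <- rep(seq_len(n_blk), each = factor)
    vals <- apply(as.matrix(records[ix, ch, drop = FALSE]), 2, function(v) {
      tapply(v, blk, mean)
    })
    vals <- matrix(vals, nrow = n_blk, dimnames = list(NULL, ch))
    labs <- vapply(split(records$label[ix], blk), majority_label, integer(1))
    data.frame(source_id = records$source_id[ix[1]],
               timestamp = tapply(records$timestamp[ix], blk, min),
               vals, label = labs, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(df) <- NULL
  raw_record_set(df, attr(records, "n_channels"),
                 sample_rate = attr(records, "sample_rate") / factor,
                 stage = attr(records, "stage"))
}

majority_label <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) return(NA_integer_)
  tab <- table(labels)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)  # tie broken toward the smaller class id
}

#' Segment a cleaned stream into labeled windows
#'
#' Slides half-open windows `[start, start + window_len)` along each source's
#' stream with the given hop. Window labels are the majority label of member
#' samples (ties toward the smaller class id). Trailing segments shorter
#' than `window_len` are discarded, never padded.
#'
#' @param records A cleaned, defect-free [raw_record_set()].
#' @param window_len Window length in samples.
#' @param hop Hop between window starts (>= 1); `hop = window_len` gives a
#'   non-overlapping tiling.
#' @return A [window_set()].
#' @export
segment_stream <- function(records, window_len, hop = window_len) {
  if (hop < 1) stop("hop must be >= 1")
  ch <- channel_cols(records)
  if (anyNA(records[ch])) {
    stop("records contain missing values; run cleaning before segmentation")
  }
  wins <- list(); labs <- integer(0); prov <- list()
  for (sid in unique(records$source_id)) {
    ix <- which(records$source_id == sid)
    n <- length(ix)
    starts <- seq(1L, n - window_len + 1L, by = hop)
    if (n < window_len) starts <- integer(0)
    for (s in starts) {
      sel <- ix[s:(s + window_len - 1L)]
      wins[[length(wins) + 1L]] <-
        t(as.matrix(records[sel, ch, drop = FALSE]))
      labs <- c(labs, majority_label(records$label[sel]))
      prov[[length(prov) + 1L]] <- data.frame(source_id = sid, start = s - 1L)
    }
  }
  if (!length(wins)) {
    w <- array(0, dim = c(0, length(ch), window_len))
    return(window_set(w, integer(0), channel_names = ch,
                      stage = attr(records, "stage")))
  }
  w <- array(0, dim = c(length(wins), length(ch), window_len))
  for (i in seq_along(wins)) w[i, , ] <- wins[[i]]
  window_set(w, labs, channel_names = ch,
             provenance = do.call(rbind, prov),
             stage = attr(records, "stage"))
}
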