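#' Integrate cleaned record streams from multiple sources
#'
#' Peer-to-peer merge: sources are concatenated and ordered by
#' `(source_id, timestamp)`; channel units can be harmonized by per-source
#' affine maps. The record count of the result is the sum of the inputs.
#'
#' @param sources List of cleaned [raw_record_set()] objects with identical
#'   channel schema.
#' @param affine Optional named list mapping `source_id` to `c(scale, shift)`
#'   applied to every channel of that source.
#' @return A single [raw_record_set()] with `stage = "integrated"`.
#' @export
integrate_sources <- function(sources, affine = NULL) {
  if (!length(sources)) stop("no sources to integrate")
  nch <- attr(sources[[1]], "n_channels")
  ch <- channel_cols(sources[[1]])
  for (s in sources) {
    if (attr(s, "n_channels") != nch ||
        !identical(channel_cols(s), ch)) {
      stop("schema mismatch: differing channels ",
           paste(union(setdiff(channel_cols(s), ch), setdiff(ch, channel_cols(s))),
                 collapse = ", "))
    }
  }
  dfs <- lapply(sources, function(s) {
    d <- as.data.frame(s)
    if (!is.null(affine) && !is.null(affine[[d$source_id[1]]])) {
      ab <- affine[[d$source_id[1]]]
      for (cc in ch) d[[cc]] <- ab[1] * d[[cc]] + ab[2]
    }
    d
  })
  df <- do.call(rbind, dfs)
  df <- df[order(df$source_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  raw_record_set(df, nch, sample_rate = attr(sources[[1]], "sample_rate"),
                 stage = "integrated")
}

#' Histogram entropy of a channel
#'
#' Shannon entropy (in nats) of the channel's value histogram, scaled by a
#' dimensionless constant: `E = C_boltz * sum_b -p_b log p_b`, empty bins
#' skipped. With `C_boltz = 1` this is pure Shannon entropy.
#'
#' @param values Non-empty numeric vector.
#' @param n_hist_bins Number of equal-width histogram bins (>= 1).
#' @param c_boltz Scale constant (default 1).
#' @return Entropy in nats (>= 0).
#' @export
channel_entropy <- function(values, n_hist_bins = 32, c_boltz = 1) {
  if (!length(values)) stop("values must be non-empty")
  if (n_hist_bins < 1) stop("n_hist_bins must be >= 1")
  values <- values[!is.na(values)]
  rng <- range(values)
  if (rng[1] == rng[2]) return(0)
  edges <- seq(rng[1], rng[2], length.out = n_hist_bins + 1L)
  b <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(b, nbins = n_hist_bins)
  p <- p[p > 0] / length(values)
  c_boltz * sum(-p * log(p))
}

farthest_point_centers <- function(v, k, first) {
  centers <- numeric(k)
  centers[1] <- first
  if (k > 1) {
    d <- abs(v - centers[1])
    for (i in 2:k) {
      centers[i] <- v[which.max(d)]
      d <- pmin(d, abs(v - centers[i]))
    }
  }
  centers
}

kmeans_1d <- function(v, k, n_init, max_iter = 300) {
  best <- NULL
  for (r in seq_len(n_init)) {
    init <- farthest_point_centers(v, k, v[sample.int(length(v), 1)])
    if (length(unique(init)) < k) next
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(v, centers = matrix(init, ncol = 1),
                                     iter.max = max_iter,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

# mean silhouette on (a subsample of) 1-D points with given cluster labels
mean_silhouette_1d <- function(v, cl, max_n = 1000) {
  if (length(v) > max_n) {
    ix <- sample.int(length(v), max_n)
    v <- v[ix]; cl <- cl[ix]
  }
  ks <- sort(unique(cl))
  if (length(ks) < 2) return(NA_real_)
  s <- numeric(length(v))
  groups <- split(v, cl)
  sizes <- vapply(groups, length, integer(1))
  for (i in seq_along(v)) {
    dmeans <- vapply(seq_along(ks), function(g) {
      gv <- groups[[g]]
      if (ks[g] == cl[i]) {
        if (sizes[g] <= 1) return(NA_real_)
        sum(abs(gv - v[i])) / (sizes[g] - 1)
      } else mean(abs(gv - v[i]))
    }, numeric(1))
    own <- which(ks == cl[i])
    a <- dmeans[own]
    b <- min(dmeans[-own])
    s[i] <- if (is.na(a)) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Fit the entropy / candidate-k / discretization model
#'
#' For every candidate cluster count k, each channel's (entropy-weighted)
#' values are clustered by 1-D k-means (Lloyd's algorithm with
#' farthest-point seeding and restarts); the chosen k maximizes the mean
#' silhouette across channels. The fitted model stores sorted per-channel
#' centroids for nearest-centroid quantization.
#'
#' @param stream A cleaned (and integrated) [raw_record_set()].
#' @param candidate_ks Candidate cluster counts (non-empty).
#' @param n_init Number of seeding restarts per (channel, k).
#' @param seed Integer seed.
#' @param c_boltz Entropy scale constant, see [channel_entropy()].
#' @param max_fit_n Per-channel subsample size used for fitting (the full
#'   stream is still quantized at transform time).
#' @return Object of class `discretization_model`.
#' @export
fit_discretizer <- function(stream, candidate_ks = c(4, 6, 8, 12, 16),
                            n_init = 10, seed = 1, c_boltz = 1,
                            max_fit_n = 20000) {
  if (!length(candidate_ks)) stop("candidate_ks must be non-empty")
  set.seed(seed)
  ch <- channel_cols(stream)
  ent <- vapply(ch, function(cc) channel_entropy(stream[[cc]], c_boltz = c_boltz),
                numeric(1))
  wts <- if (sum(ent) > 0) ent / sum(ent) else rep(1 / length(ch), length(ch))
  names(wts) <- ch
  vals <- lapply(ch, function(cc) {
    v <- stream[[cc]]
    if (length(v) > max_fit_n) v <- v[sample.int(length(v), max_fit_n)]
    v
  })
  names(vals) <- ch
  fits <- list()      # fits[[as.character(k)]][[cc]]
  sil <- inertia <- stats::setNames(rep(NA_real_, length(candidate_ks)),
                                    candidate_ks)
  for (k in sort(candidate_ks)) {
    per_ch <- list(); sil_ch <- iner_ch <- numeric(0); ok <- TRUE
    for (cc in ch) {
      v <- vals[[cc]] * wts[[cc]]   # entropy-weighted values
      if (length(unique(v)) < k) {
        warning(sprintf("candidate k=%d skipped: channel %s has fewer distinct values",
                        k, cc))
        ok <- FALSE
        break
      }
      fit <- kmeans_1d(v, k, n_init)
      if (is.null(fit)) { ok <- FALSE; break }
      per_ch[[cc]] <- fit
      sil_ch <- c(sil_ch, mean_silhouette_1d(v, fit$cluster))
      iner_ch <- c(iner_ch, fit$tot.withinss)
    }
    if (!ok) next
    fits[[as.character(k)]] <- per_ch
    sil[as.character(k)] <- mean(sil_ch, na.rm = TRUE)
    inertia[as.character(k)] <- sum(iner_ch)
  }
  if (!length(fits)) stop("all candidate k were skipped; channel(s) too degenerate")
  chosen <- as.integer(names(which.max(sil[!is.na(sil)])))
  centroids <- lapply(ch, function(cc) {
    # centroids back on the raw value scale
    sort(as.numeric(fits[[as.character(chosen)]][[cc]]$centers)) / wts[[cc]]
  })
  names(centroids) <- ch
  structure(list(entropy = ent, weights = wts, c_boltz = c_boltz,
                 k = chosen, centroids = centroids,
                 candidate_ks = sort(candidate_ks),
                 silhouette = sil, inertia = inertia),
            class = "discretization_model")
}

quantize_to_centroids <- function(v, centroids) {
  if (length(centroids) == 1) return(rep(centroids, length(v)))
  mids <- (centroids[-1] + centroids[-length(centroids)]) / 2
  # equidistant values go to the smaller centroid index
  idx <- findInterval(v, mids, left.open = TRUE) + 1L
  centroids[idx]
}

#' Quantize a stream onto fitted centroids
#'
#' Replaces every value by its nearest centroid (ties toward the smaller
#' centroid index), yielding the discretized "digital" stream.
#'
#' @param stream A cleaned, integrated [raw_record_set()].
#' @param model A fitted `discretization_model`.
#' @return A [raw_record_set()] with `stage = "digital"`.
#' @export
discretize <- function(stream, model) {
  ch <- channel_cols(stream)
  if (!all(ch %in% names(model$centroids))) {
    stop("model was fitted on a different channel schema")
  }
  df <- as.data.frame(stream)
  for (cc in ch) df[[cc]] <- quantize_to_centroids(df[[cc]], model$centroids[[cc]])
  raw_record_set(df, attr(stream, "n_channels"),
                 sample_rate = attr(stream, "sample_rate"),
                 stage = "digital")
}

#' Serialize a discretization model to JSON
#' @param model A `discretization_model`.
#' @param path Output path.
#' @export
write_discretizer_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a discretization model from JSON
#' @param path JSON path written by [write_discretizer_json()].
#' @export
read_discretizer_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$centroids <- lapply(m$centroids, as.numeric)
  structure(m, class = "discretization_model")
}
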