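#' Initialize a Lego-filter network
#'
#' A split-transform-merge classifier over a feature vector: each layer
#' splits its input into fragments of `fragment_dim` (zero-padding the
#' tail), maps every fragment through one of `n_lego` small shared filters
#' (each a `fragment_dim x kernel_len` matrix), sums the selected maps per
#' output slot, concatenates the slots and applies a ReLU. The single
#' filter bank is shared by all layers, so the convolutional parameter
#' count is exactly `n_lego * fragment_dim * kernel_len` regardless of the
#' fragment count. After the last layer each slot is average-pooled and a
#' dense softmax head (zero-initialized) produces class probabilities.
#'
#' The one-hot filter assignment masks are fixed at initialization by a
#' balanced round-robin of fragments over filters.
#'
#' @param input_dim Feature dimension (>= fragment_dim).
#' @param n_classes Number of classes.
#' @param n_lego Number of shared Lego filters (>= 1).
#' @param fragment_dim Fragment length.
#' @param kernel_len Filter output width.
#' @param n_layers Number of split-transform-merge layers.
#' @param seed Integer seed for the He-style Gaussian filter init.
#' @param min_width Minimum number of output slots per layer (default
#'   `2 * n_lego`): narrow inputs (few selected features) would otherwise
#'   collapse the merged representation below the class count.
#' @return Object of class `lego_classifier` (unfitted).
#' @export
init_network <- function(input_dim, n_classes, n_lego = 4, fragment_dim = 4,
                         kernel_len = 3, n_layers = 2, seed = 1,
                         min_width = 2 * n_lego) {
  if (n_lego < 1) stop("n_lego must be >= 1")
  if (fragment_dim < 1) stop("fragment_dim must be >= 1")
  if (input_dim < fragment_dim) {
    stop("configuration error: input_dim < fragment_dim")
  }
  set.seed(seed)
  eps <- array(stats::rnorm(fragment_dim * kernel_len * n_lego,
                            sd = sqrt(2 / fragment_dim)),
               dim = c(fragment_dim, kernel_len, n_lego))
  layers <- list()
  d <- input_dim
  for (l in seq_len(n_layers)) {
    n_frag <- ceiling(d / fragment_dim)
    n_out <- max(n_frag, min_width)
    # one-hot assignment: mask[iota, phi] names the filter for that pair,
    # round-robin so per-filter fragment counts differ by at most one
    mask <- outer(seq_len(n_out), seq_len(n_frag),
                  function(i, p) ((i + p - 2L) %% n_lego) + 1L)
    layers[[l]] <- list(in_dim = d, n_frag = n_frag, n_out = n_out,
                        mask = mask)
    d <- n_out * kernel_len
  }
  structure(list(eps = eps, layers = layers,
                 W = matrix(0, layers[[n_layers]]$n_out, n_classes),
                 b = numeric(n_classes),
                 input_dim = input_dim, n_classes = n_classes,
                 n_lego = n_lego, fragment_dim = fragment_dim,
                 kernel_len = kernel_len, n_layers = n_layers,
                 fitted = FALSE, seed = seed),
            class = "lego_classifier")
}

#' Convolutional parameter count of a Lego classifier
#'
#' `n_lego * fragment_dim * kernel_len`: independent of the number of
#' fragments, which is the parameter economy the shared-filter design buys.
#'
#' @param model A `lego_classifier`.
#' @export
lego_param_count <- function(model) {
  model$n_lego * model$fragment_dim * model$kernel_len
}

relu <- function(x) (x > 0) * x

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass; returns probs plus per-layer caches for backprop
lego_forward_cache <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$input_dim) stop("feature dimension mismatch")
  n <- nrow(x)
  fd <- model$fragment_dim; kl <- model$kernel_len
  caches <- list()
  a <- x
  for (l in seq_len(model$n_layers)) {
    ly <- model$layers[[l]]
    pad <- ly$n_frag * fd - ly$in_dim
    ap <- if (pad > 0) cbind(a, matrix(0, n, pad)) else a
    th <- vector("list", ly$n_frag)   # th[[phi]][[filter]] : n x kl
    frag <- vector("list", ly$n_frag)
    for (phi in seq_len(ly$n_frag)) {
      v <- ap[, ((phi - 1) * fd + 1):(phi * fd), drop = FALSE]
      frag[[phi]] <- v
      th[[phi]] <- lapply(seq_len(model$n_lego), function(f) {
        v %*% model$eps[, , f]
      })
    }
    pre <- matrix(0, n, ly$n_out * kl)
    for (io in seq_len(ly$n_out)) {
      g <- matrix(0, n, kl)
      for (phi in seq_len(ly$n_frag)) {
        g <- g + th[[phi]][[ly$mask[io, phi]]]
      }
      pre[, ((io - 1) * kl + 1):(io * kl)] <- g
    }
    act <- relu(pre)
    caches[[l]] <- list(frag = frag, pre = pre, pad = pad)
    a <- act
  }
  last <- model$layers[[model$n_layers]]
  # global average pool over kernel positions within each output slot
  pool <- matrix(0, n, last$n_out)
  for (io in seq_len(last$n_out)) {
    pool[, io] <- rowMeans(a[, ((io - 1) * kl + 1):(io * kl), drop = FALSE])
  }
  logits <- sweep(pool %*% model$W, 2, model$b, "+")
  probs <- softmax_rows(logits)
  list(probs = probs, pool = pool, act = a, caches = caches)
}

# gradient of mean cross-entropy w.r.t. eps, W, b
lego_backward <- function(model, fwd, y_onehot) {
  n <- nrow(y_onehot)
  kl <- model$kernel_len; fd <- model$fragment_dim
  dlogits <- (fwd$probs - y_onehot) / n
  dW <- crossprod(fwd$pool, dlogits)
  db <- colSums(dlogits)
  dpool <- dlogits %*% t(model$W)
  last <- model$layers[[model$n_layers]]
  dact <- matrix(0, n, last$n_out * kl)
  for (io in seq_len(last$n_out)) {
    dact[, ((io - 1) * kl + 1):(io * kl)] <- dpool[, io] / kl
  }
  deps <- array(0, dim = dim(model$eps))
  for (l in rev(seq_len(model$n_layers))) {
    ly <- model$layers[[l]]
    cache <- fwd$caches[[l]]
    dpre <- dact * (cache$pre > 0)
    dfrag <- vector("list", ly$n_frag)
    for (phi in seq_len(ly$n_frag)) dfrag[[phi]] <- matrix(0, n, fd)
    for (io in seq_len(ly$n_out)) {
      dg <- dpre[, ((io - 1) * kl + 1):(io * kl), drop = FALSE]
      for (phi in seq_len(ly$n_frag)) {
        f <- ly$mask[io, phi]
        deps[, , f] <- deps[, , f] + crossprod(cache$frag[[phi]], dg)
        dfrag[[phi]] <- dfrag[[phi]] + dg %*% t(model$eps[, , f])
      }
    }
    if (l > 1) {
      dap <- do.call(cbind, dfrag)
      dact <- dap[, seq_len(ly$in_dim), drop = FALSE]  # drop tail padding
    }
  }
  list(deps = deps, dW = dW, db = db)
}

cross_entropy <- function(probs, y_onehot) {
  -mean(log(rowSums(probs * y_onehot) + 1e-12))
}

one_hot <- function(y, classes) {
  m <- matrix(0, length(y), length(classes))
  m[cbind(seq_along(y), match(y, classes))] <- 1
  m
}

#' Training configuration for the Lego classifier
#'
#' @param learning_rate Explicit-Euler step size of the gradient flow (> 0).
#' @param epochs Number of passes over the training data (>= 1).
#' @param batch_size Mini-batch size.
#' @param seed Integer seed for shuffling.
#' @param patience Early-stop patience on validation loss (Inf disables).
#' @export
train_config <- function(learning_rate = 0.01, epochs = 300, batch_size = 32,
                         seed = 1, patience = Inf) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (epochs < 1) stop("epochs must be >= 1")
  list(learning_rate = learning_rate, epochs = epochs,
       batch_size = batch_size, seed = seed, patience = patience)
}

#' Train a Lego classifier by explicit-Euler gradient descent
#'
#' Minimizes mean cross-entropy by forward-Euler steps on the full
#' parameter gradient (the time-discretized gradient flow); mini-batches
#' are drawn in a seeded shuffled order each epoch, so training is
#' deterministic given (data, config, seed).
#'
#' @param model An [init_network()] classifier.
#' @param x Training feature matrix.
#' @param y Training labels (>= 2 classes).
#' @param config A [train_config()].
#' @param x_val,y_val Optional validation split for early stopping.
#' @return The fitted model with `loss_trace` (per-epoch train loss) and
#'   `val_loss_trace` attached.
#' @export
train_network <- function(model, x, y, config = train_config(),
                          x_val = NULL, y_val = NULL) {
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need >= 2 classes in train labels")
  model$classes <- classes
  x <- as.matrix(x)
  yh <- one_hot(y, classes)
  n <- nrow(x)
  set.seed(config$seed)
  loss_trace <- numeric(config$epochs)
  val_trace <- if (is.null(x_val)) NULL else numeric(config$epochs)
  best_val <- Inf; wait <- 0L
  lr <- config$learning_rate
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    bl <- 0; nb <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      ix <- ord[start:min(start + config$batch_size - 1, n)]
      fwd <- lego_forward_cache(model, x[ix, , drop = FALSE])
      loss <- cross_entropy(fwd$probs, yh[ix, , drop = FALSE])
      if (!is.finite(loss)) {
        stop("divergence: loss is not finite; reduce the learning rate")
      }
      gr <- lego_backward(model, fwd, yh[ix, , drop = FALSE])
      model$eps <- model$eps - lr * gr$deps
      model$W <- model$W - lr * gr$dW
      model$b <- model$b - lr * gr$db
      bl <- bl + loss; nb <- nb + 1
    }
    loss_trace[ep] <- bl / nb
    if (!is.null(x_val)) {
      vf <- lego_forward_cache(model, x_val)
      vl <- cross_entropy(vf$probs, one_hot(y_val, classes))
      val_trace[ep] <- vl
      if (vl < best_val - 1e-8) { best_val <- vl; wait <- 0L }
      else {
        wait <- wait + 1L
        if (wait >= config$patience) {
          loss_trace <- loss_trace[seq_len(ep)]
          val_trace <- val_trace[seq_len(ep)]
          break
        }
      }
    }
  }
  model$fitted <- TRUE
  model$loss_trace <- loss_trace
  model$val_loss_trace <- val_trace
  model
}

#' Class probabilities and hard labels from a Lego classifier
#'
#' Hard labels are the argmax class, ties broken toward the smaller class
#' id. When true labels are supplied, per-class one-vs-rest confusion
#' counts are attached.
#'
#' @param model A fitted `lego_classifier` (or unfitted, for
#'   [forward_network()] only).
#' @param x Feature matrix.
#' @param y Optional true labels for confusion counting.
#' @return Object of class `prediction_set`: `probs`, `labels`, and
#'   optionally `confusion` (see [confusion_counts()]).
#' @export
predict_network <- function(model, x, y = NULL) {
  if (!isTRUE(model$fitted)) stop("state error: model is not fitted")
  forward_network(model, x, y)
}

#' Forward pass of a Lego classifier (fitted or not)
#' @rdname predict_network
#' @export
forward_network <- function(model, x, y = NULL) {
  fwd <- lego_forward_cache(model, x)
  classes <- if (!is.null(model$classes)) model$classes
             else seq_len(model$n_classes)
  # which.max returns the first maximum: with ascending classes this is
  # the smaller class id on ties
  labels <- classes[apply(fwd$probs, 1, which.max)]
  out <- list(probs = fwd$probs, labels = labels)
  if (!is.null(y)) out$confusion <- confusion_counts(labels, y, classes)
  structure(out, class = "prediction_set")
}
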