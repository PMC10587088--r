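#' Attack vector of an eagle
#'
#' Straight-line vector from the eagle's position toward the remembered
#' prey (the best position in some eagle's memory).
#'
#' @param prey Prey position vector.
#' @param position Eagle position vector (same length).
#' @return `prey - position`.
#' @export
attack_vector <- function(prey, position) {
  if (length(prey) != length(position)) stop("dimension mismatch")
  prey - position
}

#' Cruise vector on the prey's tangent hyperplane
#'
#' The cruise direction is tangent to the attack direction: with normal
#' `beta = alpha` and hyperplane offset `s = sum(beta * prey)`, one
#' coordinate (chosen uniformly among nonzero `beta_j`) is solved so that
#' the random destination `A` satisfies `sum(beta * A) = s` exactly; the
#' cruise vector is `A - position`. A zero attack vector triggers a
#' pure-exploration fallback: a uniform random unit vector.
#'
#' @param alpha Attack vector.
#' @param prey Prey position (defines the hyperplane offset).
#' @param position Eagle position.
#' @return List with `G` (cruise vector), `A` (destination point), `s`
#'   (hyperplane offset) and `fallback` (logical).
#' @export
cruise_vector <- function(alpha, prey, position) {
  m <- length(alpha)
  nz <- which(alpha != 0)
  if (!length(nz) || m == 1) {
    g <- stats::rnorm(m)
    g <- g / sqrt(sum(g^2))
    return(list(G = g, A = position + g, s = NA_real_, fallback = TRUE))
  }
  s <- sum(alpha * prey)
  h <- nz[sample.int(length(nz), 1)]
  A <- stats::runif(m)
  A[h] <- (s - sum(alpha[-h] * A[-h])) / alpha[h]
  list(G = A - position, A = A, s = s, fallback = FALSE)
}

#' Normalized binomial random vector
#'
#' Each coordinate is an independent `Binomial(n_trials, prob) / n_trials`
#' draw, so values lie on `{0, 1/n_trials, ..., 1}` with mean `prob` and
#' variance `prob (1 - prob) / n_trials`.
#'
#' @param m Dimension.
#' @param n_trials Number of trials (>= 1).
#' @param prob Success probability in `[0, 1]`.
#' @return Numeric vector in `[0, 1]^m`.
#' @export
binomial_random_vector <- function(m, n_trials = 10, prob = 0.5) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (prob < 0 || prob > 1) stop("prob must lie in [0, 1]")
  stats::rbinom(m, n_trials, prob) / n_trials
}

#' Attack/cruise propensity schedule
#'
#' Linear interpolation between initial and final propensities: attack
#' rises and cruise falls as iterations progress, shifting the search from
#' exploration to exploitation.
#'
#' @param schedule List with `k_attack0`, `k_attack_max`, `k_cruise0`,
#'   `k_cruise_max`, `iter_max` (see [geo_schedule()]).
#' @param iter Iteration counter in `[0, iter_max]`.
#' @return Named vector `c(k_attack =, k_cruise =)`.
#' @export
propensity_schedule <- function(schedule, iter) {
  if (iter < 0 || iter > schedule$iter_max) stop("iter out of range")
  if (schedule$iter_max == 0) {
    return(c(k_attack = schedule$k_attack0, k_cruise = schedule$k_cruise0))
  }
  frac <- iter / schedule$iter_max
  ka <- schedule$k_attack0 +
    frac * abs(schedule$k_attack_max - schedule$k_attack0) *
    sign(schedule$k_attack_max - schedule$k_attack0)
  kc <- schedule$k_cruise0 +
    frac * abs(schedule$k_cruise_max - schedule$k_cruise0) *
    sign(schedule$k_cruise_max - schedule$k_cruise0)
  c(k_attack = ka, k_cruise = kc)
}

#' Construct a propensity schedule
#'
#' @param k_attack0,k_attack_max Initial and final attack propensity
#'   (defaults 0.5 rising to 2).
#' @param k_cruise0,k_cruise_max Initial and final cruise propensity
#'   (defaults 1 falling to 0.5).
#' @param iter_max Total number of iterations.
#' @export
geo_schedule <- function(k_attack0 = 0.5, k_attack_max = 2,
                         k_cruise0 = 1, k_cruise_max = 0.5, iter_max = 100) {
  list(k_attack0 = k_attack0, k_attack_max = k_attack_max,
       k_cruise0 = k_cruise0, k_cruise_max = k_cruise_max,
       iter_max = iter_max)
}

#' One eagle move
#'
#' Step `delta = R1 * k_attack * alpha/|alpha| + R2 * k_cruise * G/|G|`
#' with `R1`, `R2` fresh normalized-binomial vectors applied elementwise; a
#' zero attack or cruise vector contributes nothing. The new position is
#' the old position plus the step, clamped to `[0, 1]^m`.
#'
#' @param eagle List with at least `position`.
#' @param prey Prey position vector.
#' @param k_attack,k_cruise Current propensities.
#' @param n_trials,prob Binomial step parameters.
#' @return The eagle with updated `position`.
#' @export
step_and_move <- function(eagle, prey, k_attack, k_cruise,
                          n_trials = 10, prob = 0.5) {
  pos <- eagle$position
  m <- length(pos)
  alpha <- attack_vector(prey, pos)
  na <- sqrt(sum(alpha^2))
  cr <- cruise_vector(alpha, prey, pos)
  ng <- sqrt(sum(cr$G^2))
  r1 <- binomial_random_vector(m, n_trials, prob)
  r2 <- binomial_random_vector(m, n_trials, prob)
  delta <- numeric(m)
  if (na > 0) delta <- delta + r1 * k_attack * alpha / na
  if (ng > 0) delta <- delta + r2 * k_cruise * cr$G / ng
  eagle$position <- pmin(pmax(pos + delta, 0), 1)
  eagle
}

# shared GEO loop maximizing fitness_fn over [0,1]^m; returns population,
# global best and best-so-far trace
geo_run <- function(fitness_fn, m, pop_size, schedule, n_trials, prob) {
  eagles <- lapply(seq_len(pop_size), function(i) {
    pos <- stats::runif(m)
    list(position = pos, best_position = pos, best_fitness = fitness_fn(pos))
  })
  best_i <- which.max(vapply(eagles, `[[`, numeric(1), "best_fitness"))
  best <- eagles[[best_i]]
  trace <- numeric(schedule$iter_max)
  for (iter in seq_len(schedule$iter_max)) {
    k <- propensity_schedule(schedule, iter)
    for (i in seq_len(pop_size)) {
      # prey: uniform draw from the population's memory set
      prey <- eagles[[sample.int(pop_size, 1)]]$best_position
      eagles[[i]] <- step_and_move(eagles[[i]], prey,
                                   k[["k_attack"]], k[["k_cruise"]],
                                   n_trials, prob)
      f <- fitness_fn(eagles[[i]]$position)
      if (f > eagles[[i]]$best_fitness) {
        eagles[[i]]$best_fitness <- f
        eagles[[i]]$best_position <- eagles[[i]]$position
      }
      if (eagles[[i]]$best_fitness > best$best_fitness) best <- eagles[[i]]
    }
    trace[iter] <- best$best_fitness
  }
  list(best = best, trace = trace, eagles = eagles)
}

#' Golden Eagle optimization of a raw objective
#'
#' Minimizes (default) or maximizes `fn` over the unit box `[0, 1]^dim`
#' with binomial-distributed elementwise step factors.
#'
#' @param fn Objective taking a numeric vector.
#' @param dim Problem dimension.
#' @param pop_size Population size (>= 2).
#' @param iter_max Iterations.
#' @param seed Integer seed.
#' @param minimize Minimize (default) or maximize.
#' @param n_trials,prob Binomial step parameters.
#' @param schedule Optional [geo_schedule()]; `iter_max` overrides its count.
#' @return List with `best_x`, `best_f` (on the original objective scale)
#'   and `trace` of best-so-far objective values.
#' @export
geo_optimize <- function(fn, dim, pop_size = 20, iter_max = 200, seed = 1,
                         minimize = TRUE, n_trials = 10, prob = 0.5,
                         schedule = NULL) {
  if (pop_size < 2) stop("pop_size must be >= 2")
  set.seed(seed)
  if (is.null(schedule)) schedule <- geo_schedule(iter_max = iter_max)
  schedule$iter_max <- iter_max
  sgn <- if (minimize) -1 else 1
  res <- geo_run(function(x) sgn * fn(x), dim, pop_size, schedule,
                 n_trials, prob)
  list(best_x = res$best$best_position,
       best_f = sgn * res$best$best_fitness,
       trace = sgn * res$trace)
}

# stratified fold assignment: per class, cycle fold ids after a shuffle
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    ix <- which(y == cl)
    ix <- ix[sample.int(length(ix))]
    folds[ix] <- rep_len(seq_len(n_folds), length(ix))
  }
  folds
}

nearest_centroid_cv <- function(x, y, cols, folds) {
  if (!length(cols)) return(c(acc = NA_real_, margin = NA_real_))
  classes <- sort(unique(y))
  correct <- 0L
  marg <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f
    xm_tr <- x[tr, cols, drop = FALSE]
    xm_te <- x[!tr, cols, drop = FALSE]
    cent <- rowsum(xm_tr, y[tr]) / as.vector(table(factor(y[tr], classes)))
    # squared distances to each class centroid
    d2 <- outer(rowSums(xm_te^2), rep(1, length(classes))) -
      2 * xm_te %*% t(cent) +
      outer(rep(1, nrow(xm_te)), rowSums(cent^2))
    pred <- classes[apply(d2, 1, which.min)]
    correct <- correct + sum(pred == y[!tr])
    # relative margin between the true-class and best-other centroid
    d <- sqrt(pmax(d2, 0))
    own <- cbind(seq_len(nrow(d)), match(y[!tr], classes))
    d_true <- d[own]
    d[own] <- Inf
    d_other <- apply(d, 1, min)
    marg <- marg + sum((d_other - d_true) / (d_other + d_true + 1e-12))
  }
  c(acc = correct / length(y), margin = marg / length(y))
}

#' Default wrapper fitness: margin-augmented CV nearest-centroid accuracy
#'
#' Builds the fitness closure used by [select_features()]: stratified
#' 3-fold cross-validated accuracy of a nearest-centroid classifier on the
#' masked feature columns, plus `margin_weight` times the mean relative
#' centroid margin `(d_other - d_true)/(d_other + d_true)` of the held-out
#' samples, minus the sparsity penalty `omega * (n_selected / M)`. The
#' margin term keeps the objective informative once 0/1 accuracy
#' saturates, so discriminative features are still preferred over noise at
#' high accuracy; the penalty is kept at tie-breaking scale. Folds are
#' fixed when the closure is built, so the fitness is deterministic, and
#' results are cached by mask.
#'
#' @param x Feature matrix (standardized).
#' @param y Integer labels.
#' @param omega Sparsity penalty weight (default 0.01).
#' @param margin_weight Weight of the mean relative margin (default 0.1).
#' @param n_folds Number of CV folds (default 3).
#' @return Function `mask -> fitness` (empty masks give `-Inf`).
#' @export
make_wrapper_fitness <- function(x, y, omega = 0.01, margin_weight = 0.1,
                                 n_folds = 3) {
  if (length(unique(y)) < 2) stop("fitness error: labels contain a single class")
  folds <- stratified_folds(y, n_folds)
  m_total <- ncol(x)
  cache <- new.env(parent = emptyenv())
  function(mask) {
    cols <- which(mask)
    if (!length(cols)) return(-Inf)
    key <- paste(cols, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    r <- nearest_centroid_cv(x, y, cols, folds)
    f <- r[["acc"]] + margin_weight * r[["margin"]] -
      omega * length(cols) / m_total
    cache[[key]] <- f
    f
  }
}

#' Wrapper feature selection by binomial-step Golden Eagle optimization
#'
#' Eagle positions live in `[0, 1]^M` and decode to binary masks by
#' `x_j > threshold`. Each iteration every eagle picks a prey uniformly
#' from the population's memories, combines an attack step toward it with a
#' cruise step on the tangent hyperplane (elementwise binomial step
#' factors), and updates its memory elitistically; the best memory over the
#' whole run is returned.
#'
#' @param features Feature matrix (n x M), already standardized.
#' @param labels Integer labels (>= 2 classes).
#' @param fitness Optional fitness closure `mask -> numeric`; default
#'   [make_wrapper_fitness()] on `features`/`labels`.
#' @param pop_size Population size (>= 2, default 20).
#' @param iter_max Iterations (default 100).
#' @param threshold Mask decoding threshold (default 0.5).
#' @param omega Sparsity penalty weight for the default fitness.
#' @param seed Integer seed.
#' @param n_trials,prob Binomial step parameters.
#' @return Object of class `selection_result`: `mask` (logical length M),
#'   `n_selected`, `best_fitness`, `trace` (best-so-far per iteration),
#'   `selected_names`.
#' @export
select_features <- function(features, labels, fitness = NULL, pop_size = 20,
                            iter_max = 100, threshold = 0.5, omega = 0.01,
                            seed = 1, n_trials = 10, prob = 0.5) {
  if (pop_size < 2) stop("pop_size must be >= 2")
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f_", seq_len(ncol(features)))
  }
  set.seed(seed)
  if (is.null(fitness)) {
    fitness <- make_wrapper_fitness(features, labels, omega = omega)
  }
  m <- ncol(features)
  schedule <- geo_schedule(iter_max = iter_max)
  res <- geo_run(function(pos) fitness(pos > threshold), m, pop_size,
                 schedule, n_trials, prob)
  mask <- res$best$best_position > threshold
  if (!any(mask)) {
    # degenerate run where no memory decoded to a non-empty subset
    mask[which.max(res$best$best_position)] <- TRUE
  }
  structure(list(mask = mask, n_selected = sum(mask),
                 best_fitness = res$best$best_fitness,
                 trace = res$trace,
                 selected_names = colnames(features)[mask],
                 threshold = threshold, seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d/%d features, best fitness %.4f\n",
              x$n_selected, length(x$mask), x$best_fitness))
  invisible(x)
}
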