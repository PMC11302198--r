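#' Configuration of the informative-KNN point filter
#'
#' @param k_values Neighbour counts to enumerate; the default
#'   `c(3, 5, 7, 10)` with `M` running over `1..k` yields 25 (k, M)
#'   combinations.
#' @param bandwidth_rule `"median-heuristic"` (default; bandwidth = median
#'   pairwise squared distance of the standardized matrix) or `"literal"`
#'   (bandwidth 1, the textbook Gaussian kernel `exp(-||dx||^2)`, which
#'   underflows in high dimension and is kept for low-dimensional work and
#'   oracle checks).
#' @param standardize Per-feature z-scoring before distances (default
#'   `TRUE`); the kernel is scale-sensitive.
#' @param discard_fraction Fraction of points to discard, default 0.05.
#' @param scope `"all-points"` (default): the worst
#'   `round(discard_fraction * n)` points over the whole dataset are
#'   discarded. `"cg-only"`: only control points are candidates and the
#'   count is taken relative to the number of control points (the reading
#'   in which only unvetted controls are treated as potential outliers).
#' @return Object of class `iknn_config`.
#' @export
iknn_config <- function(k_values = c(3L, 5L, 7L, 10L),
                        bandwidth_rule = c("median-heuristic", "literal"),
                        standardize = TRUE,
                        discard_fraction = 0.05,
                        scope = c("all-points", "cg-only")) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  scope <- match.arg(scope)
  if (any(k_values < 1)) {
    stop_physioscreen("invalid_parameter", "every k must be >= 1")
  }
  if (discard_fraction < 0 || discard_fraction >= 1) {
    stop_physioscreen("invalid_parameter", "discard_fraction must lie in [0, 1)")
  }
  structure(list(k_values = as.integer(sort(k_values)),
                 bandwidth_rule = bandwidth_rule,
                 standardize = standardize,
                 discard_fraction = discard_fraction,
                 scope = scope),
            class = "iknn_config")
}

#' Gaussian kernel similarity between two points
#'
#' `exp(-||xi - xj||^2 / bandwidth)`; bandwidth 1 reproduces the literal
#' kernel `exp(-||dx||^2)`.
#'
#' @param xi,xj Numeric vectors of equal length.
#' @param bandwidth Positive scalar.
#' @return Similarity in `(0, 1]`.
#' @export
kernel_distance <- function(xi, xj, bandwidth = 1) {
  if (length(xi) != length(xj)) {
    stop_physioscreen("shape_error", "vectors must have equal dimension")
  }
  if (bandwidth <= 0) {
    stop_physioscreen("invalid_parameter", "bandwidth must be > 0")
  }
  exp(-sum((xi - xj)^2) / bandwidth)
}

#' Isolation weight of a candidate neighbour
#'
#' \eqn{\Lambda(x_j, x_i) = \prod_n (1 - d(x_j, x_n)(1 - \delta_{y_j, y_n}))}
#' over the k neighbours \eqn{x_n} of \eqn{x_i}: each neighbour with a label
#' different from \eqn{y_j} contributes a factor that shrinks towards zero
#' as it approaches \eqn{x_j}; same-label neighbours contribute factor 1.
#' \eqn{\Lambda} is therefore large when \eqn{x_j} is far from all
#' opposite-label members of the neighbourhood.
#'
#' @param xj Candidate neighbour (numeric vector).
#' @param yj Its label.
#' @param neighbors Matrix of the k neighbours of the query point (rows).
#' @param neighbor_labels Their labels.
#' @param bandwidth Kernel bandwidth.
#' @return Weight in `[0, 1]`.
#' @export
lambda_weight <- function(xj, yj, neighbors, neighbor_labels, bandwidth = 1) {
  d <- apply(neighbors, 1, kernel_distance, xi = xj, bandwidth = bandwidth)
  prod(1 - d * (neighbor_labels != yj))
}

# Squared Euclidean distance matrix.
sq_dist <- function(x) {
  s <- rowSums(x^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  d2
}

# Standardize + bandwidth resolution shared by the scoring entry points.
prepare_iknn <- function(x, config) {
  x <- as.matrix(x)
  if (config$standardize) {
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    sd[sd == 0] <- 1
    x <- sweep(sweep(x, 2, mu), 2, sd, "/")
  }
  d2 <- sq_dist(x)
  bw <- if (config$bandwidth_rule == "literal") 1 else {
    m <- stats::median(d2[upper.tri(d2)])
    if (!is.finite(m) || m <= 0) 1 else m
  }
  list(x = x, d2 = d2, kern = exp(-d2 / bw), bandwidth = bw)
}

# k nearest neighbours of point i (self excluded; ties by input order).
nearest_neighbors <- function(d2, i, k) {
  ord <- order(d2[i, ], seq_len(ncol(d2)))
  ord <- ord[ord != i]
  ord[seq_len(k)]
}

#' Informativeness of each neighbour of a point
#'
#' For query point \eqn{x_i} with k nearest neighbours, each neighbour
#' \eqn{x_j} receives
#' \deqn{P(x_j | x_i) = \frac{1}{C_i}\, d(x_j, x_i)^{\eta}\,
#'   \Lambda(x_j, x_i)^{1 - \eta}}
#' where \eqn{\eta} is the fraction of \eqn{x_i}'s k neighbours whose label
#' equals \eqn{y_j}, \eqn{d} is the Gaussian kernel similarity and
#' \eqn{C_i} normalizes the k values to sum to 1. If every unnormalized
#' mass is exactly zero the distribution falls back to uniform `1/k` with a
#' warning.
#'
#' @param i Index of the query point.
#' @param k Neighbour count (`1 <= k < n`).
#' @param x Numeric data matrix (rows = points).
#' @param y Label vector (two classes).
#' @param config An [iknn_config()].
#' @return Named numeric vector of probabilities over the k neighbour
#'   indices, summing to 1.
#' @export
informativeness <- function(i, k, x, y, config = iknn_config()) {
  prep <- prepare_iknn(x, config)
  n <- nrow(prep$x)
  if (k >= n) stop_physioscreen("invalid_parameter", "k must be < n")
  nb <- nearest_neighbors(prep$d2, i, k)
  p <- neighbor_probabilities(prep$kern, y, i, nb)
  stats::setNames(p, nb)
}

neighbor_probabilities <- function(kern, y, i, nb) {
  k <- length(nb)
  y_nb <- y[nb]
  unnorm <- numeric(k)
  for (jj in seq_len(k)) {
    j <- nb[jj]
    eta <- mean(y_nb == y[j])
    lam <- prod(1 - kern[j, nb] * (y_nb != y[j]))
    unnorm[jj] <- kern[j, i]^eta * lam^(1 - eta)
  }
  tot <- sum(unnorm)
  if (tot == 0) {
    warning("all informativeness masses are zero; falling back to uniform")
    return(rep(1 / k, k))
  }
  unnorm / tot
}

#' Mean informativeness scores over the (k, M) enumeration
#'
#' For every point and every pair (k, M) with `k` in `k_values` and `M` in
#' `1..k`, the k neighbours are ranked by informativeness, the labels of the
#' top M neighbours are majority-voted into a prediction, and the binary
#' score `s = 1` records disagreement with the point's own label. The mean
#' score `s_bar` over the enumeration (25 pairs by default) ranks points:
#' high `s_bar` marks a point as uninformative for its class. Vote ties
#' (even M with a split) are resolved by the label of the single most
#' informative neighbour; ranking ties are broken by neighbour distance
#' order.
#'
#' @param x Numeric matrix (rows = points).
#' @param y Label vector; exactly two classes must be present.
#' @param config An [iknn_config()].
#' @return Object of class `iknn_scores`: list with `s_bar` (numeric per
#'   point), `scores` (n x n_pairs 0/1 matrix, columns named `k<k>_M<M>`),
#'   `pairs` (data.frame of the enumeration), `bandwidth`, `config`.
#' @export
mean_informativeness_score <- function(x, y, config = iknn_config()) {
  x <- as.matrix(x)
  y <- as.vector(y)
  n <- nrow(x)
  if (length(unique(y)) < 2) {
    stop_physioscreen("degenerate_labels", "two classes are required")
  }
  if (n <= max(config$k_values)) {
    stop_physioscreen("invalid_parameter", "need more points than max(k_values)")
  }
  prep <- prepare_iknn(x, config)
  pairs <- do.call(rbind, lapply(config$k_values, function(k) {
    data.frame(k = k, M = seq_len(k))
  }))
  scores <- matrix(NA_real_, n, nrow(pairs),
                   dimnames = list(NULL, paste0("k", pairs$k, "_M", pairs$M)))
  for (i in seq_len(n)) {
    for (k in config$k_values) {
      nb <- nearest_neighbors(prep$d2, i, k)
      p <- neighbor_probabilities(prep$kern, y, i, nb)
      ord <- order(-p, seq_along(p))   # informativeness desc, stable
      ranked_labels <- y[nb][ord]
      for (M in seq_len(k)) {
        top <- ranked_labels[seq_len(M)]
        counts <- base::table(top)
        if (length(counts) > 1 && counts[1] == counts[2]) {
          vote <- ranked_labels[1]     # tie: most informative neighbour
        } else {
          vote <- names(counts)[which.max(counts)]
        }
        scores[i, paste0("k", k, "_M", M)] <- as.numeric(vote != y[i])
      }
    }
  }
  structure(list(s_bar = rowMeans(scores), scores = scores, pairs = pairs,
                 bandwidth = prep$bandwidth, config = config),
            class = "iknn_scores")
}

#' Discard the least informative points
#'
#' Ranks points by mean informativeness score `s_bar` (descending; ties by
#' stable input order) and discards the worst `round(discard_fraction * n)`
#' — over all points, or over the control points only under
#' `scope = "cg-only"` (with the count relative to the number of controls).
#' Refuses to empty a class.
#'
#' @param x Numeric matrix or a `pipeline_dataset`.
#' @param y Labels (ignored when `x` is a `pipeline_dataset`).
#' @param config An [iknn_config()].
#' @return Object of class `iknn_filter_result`: `retained`, `discarded`
#'   (integer index vectors partitioning the input), `s_bar`, `n_discard`,
#'   `config`.
#' @export
filter_points <- function(x, y = NULL, config = iknn_config()) {
  if (inherits(x, "pipeline_dataset")) {
    y <- as.character(x$y)
    x <- x$x
  }
  n <- nrow(x)
  scores <- mean_informativeness_score(x, y, config)
  s_bar <- scores$s_bar
  if (config$scope == "cg-only") {
    candidates <- which(y == "CG")
    n_discard <- round_half_up(config$discard_fraction * length(candidates))
  } else {
    candidates <- seq_len(n)
    n_discard <- round_half_up(config$discard_fraction * n)
  }
  ord <- candidates[order(-s_bar[candidates], seq_along(candidates))]
  discarded <- if (n_discard > 0) sort(ord[seq_len(n_discard)]) else integer(0)
  retained <- setdiff(seq_len(n), discarded)
  kept_classes <- unique(y[retained])
  if (length(kept_classes) < length(unique(y))) {
    stop_physioscreen("class_depletion", "discarding would empty a class")
  }
  structure(list(retained = retained, discarded = discarded,
                 s_bar = s_bar, n_discard = n_discard,
                 scores = scores, config = config),
            class = "iknn_filter_result")
}

#' @export
print.iknn_filter_result <- function(x, ...) {
  cat("Informative-KNN filter:", length(x$discarded), "of",
      length(x$s_bar), "points discarded (scope:", x$config$scope, ")\n")
  if (length(x$discarded)) {
    cat("  discarded indices:", paste(x$discarded, collapse = ", "), "\n")
  }
  invisible(x)
}
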