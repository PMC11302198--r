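# Independent brute-force oracle for the informative-KNN mean score:
# direct loops over the informativeness, weighting and voting definitions,
# sharing no code with the package implementation.
oracle_sbar <- function(x, y, k_values = c(3, 5, 7, 10),
                        bandwidth = NULL, standardize = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (standardize) {
    for (j in seq_len(ncol(x))) {
      s <- stats::sd(x[, j])
      if (s == 0) s <- 1
      x[, j] <- (x[, j] - mean(x[, j])) / s
    }
  }
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) d2[i, j] <- sum((x[i, ] - x[j, ])^2)
  }
  if (is.null(bandwidth)) bandwidth <- stats::median(d2[upper.tri(d2)])
  dk <- exp(-d2 / bandwidth)
  n_pairs <- sum(k_values)
  sbar <- numeric(n)
  for (i in seq_len(n)) {
    total <- 0
    for (k in k_values) {
      ord <- order(d2[i, ], seq_len(n))
      ord <- ord[ord != i]
      nb <- ord[seq_len(k)]
      p <- numeric(k)
      for (jj in seq_len(k)) {
        j <- nb[jj]
        eta <- sum(y[nb] == y[j]) / k
        lam <- 1
        for (nn in nb) if (y[nn] != y[j]) lam <- lam * (1 - dk[j, nn])
        p[jj] <- dk[j, i]^eta * lam^(1 - eta)
      }
      p <- if (sum(p) == 0) rep(1 / k, k) else p / sum(p)
      rk <- order(-p, seq_len(k))
      classes <- unique(y)
      for (M in seq_len(k)) {
        top <- y[nb][rk[seq_len(M)]]
        c1 <- sum(top == classes[1])
        c2 <- sum(top == classes[2])
        vote <- if (c1 > c2) classes[1] else if (c2 > c1) classes[2] else y[nb][rk[1]]
        total <- total + as.numeric(vote != y[i])
      }
    }
    sbar[i] <- total / n_pairs
  }
  sbar
}

# Two-class Gaussian benchmark with a fraction of label-flipped points.
make_flip_benchmark <- function(n_per_class = 100, separation = 3,
                                flip_fraction = 0.05, dim = 2) {
  x <- rbind(matrix(rnorm(n_per_class * dim), n_per_class),
             matrix(rnorm(n_per_class * dim, mean = separation), n_per_class))
  y <- rep(c("CG", "EG"), each = n_per_class)
  n_flip_per_class <- round(flip_fraction * n_per_class)
  flipped <- c(sample(seq_len(n_per_class), n_flip_per_class),
               n_per_class + sample(seq_len(n_per_class), n_flip_per_class))
  y[flipped] <- ifelse(y[flipped] == "CG", "EG", "CG")
  list(x = x, y = y, flipped = sort(flipped))
}

# Small cohort spec for fast screening tests.
small_spec <- function(seed, n_cg = 20, n_eg = 16,
                       features = c(EDA = 12L, HRV = 8L, ST = 4L), ...) {
  cohort_spec(n_cg = n_cg, n_eg = n_eg,
              n_features_per_modality = features,
              dropout = c(incomplete = 0L, unretrievable = 0L),
              dropout_by_group = c(CG = 0L, EG = 0L),
              seed = seed, ...)
}
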