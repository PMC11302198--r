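#' Relative median absolute deviation
#'
#' `rMAD(f) = med(|f - med(f)|) / |med(f)|`, a robust, scale-relative
#' dispersion statistic. When the median is zero the unnormalized MAD is
#' returned and flagged as degenerate (the relative form is undefined).
#' The denominator uses the absolute median so the statistic stays
#' nonnegative for negative-valued features.
#'
#' @param values Non-empty numeric vector.
#' @return Nonnegative scalar with attribute `degenerate` (logical).
#' @examples
#' rmad(c(1, 2, 3, 4, 5))  # 1/3
#' @export
rmad <- function(values) {
  if (!length(values)) stop_physioscreen("empty_input", "empty feature vector")
  m <- stats::median(values)
  mad0 <- stats::median(abs(values - m))
  if (m == 0) {
    structure(mad0, degenerate = TRUE)
  } else {
    structure(mad0 / abs(m), degenerate = FALSE)
  }
}

#' Relative interquartile range
#'
#' `rIQR(f) = |p75 - p25| / |p25|` with percentiles computed by linear
#' interpolation between order statistics ([stats::quantile()] type 7).
#' When the 25th percentile is zero the 75th percentile is used as the
#' denominator; when both are zero the statistic is 0 and flagged as
#' degenerate.
#'
#' @param values Non-empty numeric vector.
#' @return Nonnegative scalar with attribute `degenerate` (logical).
#' @examples
#' riqr(c(1, 2, 3, 4, 5))  # 1
#' @export
riqr <- function(values) {
  if (!length(values)) stop_physioscreen("empty_input", "empty feature vector")
  p <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  num <- abs(p[2] - p[1])
  den <- if (p[1] == 0) p[2] else p[1]
  if (den == 0) {
    structure(0, degenerate = TRUE)
  } else {
    structure(num / abs(den), degenerate = FALSE)
  }
}

#' Per-feature robust dispersion statistics
#'
#' @param x Numeric matrix (rows = data points) or a [feature_table].
#' @return `data.frame` of class `variance_stats`: `feature`, `rmad`,
#'   `riqr`, `rmad_degenerate`, `riqr_degenerate`.
#' @export
variance_stats <- function(x) {
  if (inherits(x, "feature_table")) x <- feature_matrix(x)
  x <- as.matrix(x)
  feats <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  rm_ <- lapply(seq_len(ncol(x)), function(j) rmad(x[, j]))
  ri_ <- lapply(seq_len(ncol(x)), function(j) riqr(x[, j]))
  out <- data.frame(
    feature = feats,
    rmad = vapply(rm_, as.numeric, numeric(1)),
    riqr = vapply(ri_, as.numeric, numeric(1)),
    rmad_degenerate = vapply(rm_, attr, logical(1), "degenerate"),
    riqr_degenerate = vapply(ri_, attr, logical(1), "degenerate"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("variance_stats", "data.frame")
  out
}

#' Low-variance feature mask from rMAD / rIQR lower bounds
#'
#' A feature is retained when `rmad >= theta_rmad` **and**
#' `riqr >= theta_riqr`, both statistics computed on the supplied rows
#' (training rows during cross-validation, so no test information leaks
#' into the mask).
#'
#' @param x Numeric matrix or [feature_table].
#' @param theta_rmad,theta_riqr Nonnegative lower-bound thresholds.
#' @return Object of class `feature_mask`: logical vector (named by
#'   feature) with attributes `theta_rmad`, `theta_riqr`, `stats`.
#' @export
apply_variance_thresholds <- function(x, theta_rmad = 0, theta_riqr = 0) {
  if (theta_rmad < 0 || theta_riqr < 0) {
    stop_physioscreen("invalid_parameter", "thresholds must be >= 0")
  }
  vs <- variance_stats(x)
  mask <- vs$rmad >= theta_rmad & vs$riqr >= theta_riqr
  names(mask) <- vs$feature
  if (!any(mask)) {
    stop_physioscreen("all_discarded", "thresholds would discard every feature")
  }
  structure(mask, theta_rmad = theta_rmad, theta_riqr = theta_riqr,
            stats = vs, class = "feature_mask")
}
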