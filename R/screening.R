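#' Within-group pairwise Wilcoxon significant-feature ratios
#'
#' First screening stage: within one group, for every pair of tests and
#' every feature, a two-sided Wilcoxon signed-rank test on the paired
#' per-participant values. Each matrix entry is the fraction of features
#' with \eqn{P \le \alpha}. A low ratio for a pair of tests indicates that
#' the pair is nearly exchangeable at the individual level and may be
#' bundled under a common label.
#'
#' Zero differences are dropped before ranking (the classic signed-rank
#' convention, as implemented by [stats::wilcox.test()]); a feature whose
#' paired differences are all zero is counted as non-significant.
#' P-values use the normal approximation with continuity correction.
#'
#' @param table A [feature_table].
#' @param group `"CG"` or `"EG"`.
#' @param alpha Significance cutoff (inclusive), default 0.1.
#' @return Object of class `pairwise_ratio_matrix`: a symmetric numeric
#'   matrix (tests x tests) with zero diagonal, plus attributes `group` and
#'   `alpha`.
#' @export
pairwise_within_group_ratio <- function(table, group, alpha = 0.1) {
  stopifnot(group %in% c("CG", "EG"))
  feats <- attr(table, "feature_names")
  tests <- attr(table, "test_labels")
  tests <- tests[tests %in% unique(table$test)]
  sub <- table[table$group == group, , drop = FALSE]
  if (!nrow(sub)) stop_physioscreen("insufficient_sample", "group absent")

  split_rows <- split(seq_len(nrow(sub)), sub$test)
  n_t <- length(tests)
  ratios <- matrix(0, n_t, n_t, dimnames = list(tests, tests))
  for (i in seq_len(n_t - 1)) {
    for (j in seq.int(i + 1, n_t)) {
      ri <- split_rows[[tests[i]]]
      rj <- split_rows[[tests[j]]]
      common <- intersect(sub$participant_id[ri], sub$participant_id[rj])
      if (length(common) < 5) {
        stop_physioscreen("insufficient_sample", sprintf(
          "fewer than 5 participants with both %s and %s", tests[i], tests[j]))
      }
      mi <- as.matrix(sub[ri[match(common, sub$participant_id[ri])], feats])
      mj <- as.matrix(sub[rj[match(common, sub$participant_id[rj])], feats])
      p <- vapply(seq_along(feats), function(f) {
        d <- mi[, f] - mj[, f]
        if (all(d == 0)) return(1)
        suppressWarnings(
          stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
      }, numeric(1))
      ratios[i, j] <- ratios[j, i] <- mean(p <= alpha)
    }
  }
  structure(ratios, group = group, alpha = alpha,
            class = c("pairwise_ratio_matrix", "matrix"))
}

#' The fixed test-bundling map
#'
#' Maps the three colour-word tests to bundle `C`, the two number tests to
#' `N` and the emotion test to `E`. This is the pipeline's default bundling;
#' [bundle_tests()] provides the data-driven alternative.
#'
#' @param test_labels Original test labels.
#' @param test_types Named map label -> type.
#' @return Named character vector (original label -> bundle label).
#' @export
bundle_map_default <- function(test_labels = c("C1", "C2", "C3", "N-S", "N-V", "E"),
                               test_types = c("C1" = "C", "C2" = "C", "C3" = "C",
                                              "N-S" = "N", "N-V" = "N", "E" = "E")) {
  stats::setNames(unname(test_types[test_labels]), test_labels)
}

#' Data-driven test bundling from pairwise ratio matrices
#'
#' Builds a graph on the test labels with an edge wherever the
#' significant-feature ratio is at most `tau` in *both* groups; bundles are
#' the connected components. A bundle is named by the shared test-type
#' prefix of its members when that prefix is unambiguous (single-valued
#' within the bundle and not used by another bundle), otherwise by the
#' concatenation of its member labels.
#'
#' @param cg,eg [pairwise_within_group_ratio()] matrices for the two groups.
#' @param tau Bundling threshold in `[0, 1]`.
#' @return A named character vector (original test label -> bundle label).
#' @export
bundle_tests <- function(cg, eg, tau = 0.2) {
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0 || tau > 1) {
    stop_physioscreen("invalid_parameter", "tau must lie in [0, 1]")
  }
  tests <- rownames(cg)
  if (!identical(sort(tests), sort(rownames(eg)))) {
    stop_physioscreen("invalid_parameter", "matrices must share test labels")
  }
  eg <- eg[tests, tests]
  n <- length(tests)
  # union-find over edges significant-ratio <= tau in both groups
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (cg[i, j] <= tau && eg[i, j] <= tau) {
        parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(tests, comp)
  prefixes <- vapply(groups, function(g) {
    p <- unique(test_type_prefix(g))
    if (length(p) == 1) p else NA_character_
  }, character(1))
  dup <- prefixes[!is.na(prefixes)]
  dup <- dup[duplicated(dup)]
  labels <- vapply(seq_along(groups), function(i) {
    p <- prefixes[i]
    if (!is.na(p) && !(p %in% dup)) p else paste(groups[[i]], collapse = "+")
  }, character(1))
  out <- character(n)
  names(out) <- tests
  for (i in seq_along(groups)) out[groups[[i]]] <- labels[i]
  out[tests]
}

#' Between-group Kolmogorov-Smirnov significant-feature ratios per bundle
#'
#' Second screening stage: for each bundle, the rows of its member tests are
#' pooled per group and treated as independent samples; per feature, a
#' two-sample two-sided KS test compares the CG and EG samples (asymptotic
#' p-values). Reported are the overall and per-modality fractions of
#' features with \eqn{P \le \alpha}, and the bundle attaining the maximal
#' overall ratio — the data subset passed on to the classifiers.
#'
#' @param table A [feature_table] containing both groups.
#' @param bundles Bundle map (named character vector); default the fixed map.
#' @param alpha Significance cutoff (inclusive), default 0.1.
#' @return Object of class `group_difference_report`: list with `overall`
#'   (named numeric per bundle), `by_modality` (bundle x modality matrix),
#'   `selected_bundle`, `alpha`, `n_features`.
#' @export
ks_between_group_ratio <- function(table, bundles = bundle_map_default(),
                                   alpha = 0.1) {
  feats <- attr(table, "feature_names")
  modality <- attr(table, "modality")
  if (length(unique(table$group)) < 2) {
    stop_physioscreen("insufficient_sample", "both groups required")
  }
  bundle_labels <- unique(unname(bundles))
  missing <- bundle_labels[!vapply(bundle_labels, function(b) {
    any(table$test %in% names(bundles)[bundles == b])
  }, logical(1))]
  if (length(missing)) {
    stop_physioscreen("missing_bundle",
                      paste("bundle(s) absent from table:",
                            paste(missing, collapse = ", ")))
  }
  mods <- unique(unname(modality[feats]))
  sig <- matrix(NA, length(bundle_labels), length(feats),
                dimnames = list(bundle_labels, feats))
  for (b in bundle_labels) {
    sub <- subset_bundle(table, bundles, b)
    cg <- feature_matrix(sub)[sub$group == "CG", , drop = FALSE]
    eg <- feature_matrix(sub)[sub$group == "EG", , drop = FALSE]
    p <- vapply(seq_along(feats), function(f) {
      suppressWarnings(
        stats::ks.test(cg[, f], eg[, f], exact = FALSE)$p.value)
    }, numeric(1))
    sig[b, ] <- p <= alpha
  }
  overall <- rowMeans(sig)
  by_modality <- vapply(mods, function(m) {
    rowMeans(sig[, modality[feats] == m, drop = FALSE])
  }, numeric(length(bundle_labels)))
  by_modality <- matrix(by_modality, nrow = length(bundle_labels),
                        dimnames = list(bundle_labels, mods))
  structure(list(
    overall = overall,
    by_modality = by_modality,
    selected_bundle = names(overall)[which.max(overall)],
    alpha = alpha,
    n_features = length(feats),
    n_features_by_modality = base::table(factor(modality[feats], levels = mods))
  ), class = "group_difference_report")
}

#' Demographic comparison of the two groups
#'
#' Pooled-variance two-sample t-test on age (degrees of freedom
#' \eqn{n_1 + n_2 - 2}) and a Pearson chi-square test with Yates continuity
#' correction on the 2x2 gender table, both two-sided.
#'
#' @param records A `participant_records` data frame (columns `group`,
#'   `age`, `gender`).
#' @return Object of class `demographics_summary`.
#' @export
demographic_comparison <- function(records) {
  g <- as.character(records$group)
  n <- table(factor(g, levels = c("CG", "EG")))
  if (any(n < 2)) {
    stop_physioscreen("insufficient_sample", "each group needs >= 2 members")
  }
  tt <- stats::t.test(age ~ group, data = records, var.equal = TRUE)
  gender_tab <- table(factor(records$gender, levels = c("M", "F")),
                      factor(g, levels = c("CG", "EG")))
  ct <- suppressWarnings(stats::chisq.test(gender_tab, correct = TRUE))
  structure(list(
    n = as.vector(n), groups = names(n),
    age_mean = tapply(records$age, g, mean)[c("CG", "EG")],
    age_sd = tapply(records$age, g, stats::sd)[c("CG", "EG")],
    t_statistic = unname(tt$statistic), t_df = unname(tt$parameter),
    p_age = tt$p.value,
    gender_table = gender_tab,
    chi_square = unname(ct$statistic), chi_df = unname(ct$parameter),
    p_gender = ct$p.value
  ), class = "demographics_summary")
}

#' @export
print.demographics_summary <- function(x, ...) {
  cat(sprintf("Age: %.2f +/- %.2f vs %.2f +/- %.2f, t(%d) = %.2f, P = %.2g\n",
              x$age_mean[1], x$age_sd[1], x$age_mean[2], x$age_sd[2],
              x$t_df, x$t_statistic, x$p_age))
  cat(sprintf("Gender (M/F): %d/%d vs %d/%d, chi-square(%d, %d) = %.4f, P = %.2g\n",
              x$gender_table["M", "CG"], x$gender_table["F", "CG"],
              x$gender_table["M", "EG"], x$gender_table["F", "EG"],
              x$chi_df, sum(x$n), x$chi_square, x$p_gender))
  invisible(x)
}

#' @export
print.group_difference_report <- function(x, ...) {
  cat("Between-group KS screening (P <=", x$alpha, "):\n")
  for (b in names(x$overall)) {
    cat(sprintf("  %s: %.1f%% of %d features significant\n",
                b, 100 * x$overall[b], x$n_features))
  }
  cat("Selected bundle:", x$selected_bundle, "\n")
  invisible(x)
}

#' Heatmap of a pairwise ratio matrix
#'
#' @param x A `pairwise_ratio_matrix`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.pairwise_ratio_matrix <- function(x, ...) {
  n <- nrow(x)
  m <- unclass(x)[, rev(seq_len(n)), drop = FALSE]
  graphics::image(seq_len(n), seq_len(n), m, zlim = c(0, 1),
                  axes = FALSE, xlab = "", ylab = "",
                  main = paste0("Significant-feature ratio (",
                                attr(x, "group"), ")"), ...)
  graphics::axis(1, seq_len(n), rownames(x), las = 2)
  graphics::axis(2, seq_len(n), rev(colnames(x)), las = 2)
  invisible(x)
}

#' Bar chart of between-group significant-feature ratios
#'
#' @param x A `group_difference_report`.
#' @param by_modality Plot per-modality bars instead of overall ones.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.group_difference_report <- function(x, by_modality = FALSE, ...) {
  if (by_modality) {
    graphics::barplot(t(x$by_modality) * 100, beside = TRUE,
                      legend.text = colnames(x$by_modality),
                      ylab = "% significant features", ...)
  } else {
    graphics::barplot(x$overall * 100, ylab = "% significant features", ...)
  }
  invisible(x)
}
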