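test_that("pairwise Wilcoxon matrix is symmetric with zero diagonal", {
  tab <- generate_cohort(small_spec(1))$table
  for (g in c("CG", "EG")) {
    m <- pairwise_within_group_ratio(tab, g)
    expect_equal(unname(diag(m)), rep(0, nrow(m)))
    expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("two tests with identical values give a zero ratio", {
  tab <- generate_cohort(small_spec(2))$table
  feats <- attr(tab, "feature_names")
  # overwrite C2 rows with C1 values, participant-aligned
  c1 <- tab[tab$test == "C1", ]
  idx <- which(tab$test == "C2")
  tab[idx, feats] <- c1[match(tab$participant_id[idx], c1$participant_id), feats]
  m <- pairwise_within_group_ratio(tab, "CG")
  expect_equal(m["C1", "C2"], 0)
})

test_that("cross-type ratios dominate same-type ratios when type shifts are large", {
  for (seed in 1:10) {
    tab <- generate_cohort(small_spec(seed, type_shift_scale = 3,
                                      within_type_noise = 1))$table
    for (g in c("CG", "EG")) {
      m <- pairwise_within_group_ratio(tab, g)
      same <- c(m["C1", "C2"], m["C1", "C3"], m["C2", "C3"], m["N-S", "N-V"])
      cross <- c(m["C1", "N-S"], m["C1", "E"], m["N-S", "E"], m["C3", "N-V"])
      expect_gt(min(cross), max(same))
    }
  }
})

test_that("insufficient paired participants is an error", {
  tab <- generate_cohort(small_spec(1, n_cg = 4, n_eg = 6))$table
  expect_error(pairwise_within_group_ratio(tab, "CG"),
               class = "insufficient_sample")
})

make_ratio_matrix <- function(tests, same, cross, group = "CG") {
  types <- physioscreen:::test_type_prefix(tests)
  m <- outer(types, types, function(a, b) ifelse(a == b, same, cross))
  diag(m) <- 0
  dimnames(m) <- list(tests, tests)
  structure(m, group = group, alpha = 0.1,
            class = c("pairwise_ratio_matrix", "matrix"))
}

test_that("bundling with the study-like ratio pattern recovers C/N/E", {
  tests <- c("C1", "C2", "C3", "N-S", "N-V", "E")
  cg <- make_ratio_matrix(tests, same = 0.05, cross = 0.5)
  eg <- make_ratio_matrix(tests, same = 0.05, cross = 0.5, group = "EG")
  b <- bundle_tests(cg, eg, tau = 0.2)
  expect_equal(b, c("C1" = "C", "C2" = "C", "C3" = "C",
                    "N-S" = "N", "N-V" = "N", "E" = "E"))
})

test_that("tau = 0 with no zero off-diagonal entries bundles nothing", {
  tests <- c("C1", "C2", "N-S")
  cg <- make_ratio_matrix(tests, same = 0.02, cross = 0.4)
  eg <- make_ratio_matrix(tests, same = 0.03, cross = 0.4, group = "EG")
  b <- bundle_tests(cg, eg, tau = 0)
  expect_equal(length(unique(b)), 3)
})

test_that("bundling is invariant to test-label permutation", {
  tests <- c("C1", "C2", "C3", "N-S", "N-V", "E")
  cg <- make_ratio_matrix(tests, same = 0.05, cross = 0.5)
  eg <- make_ratio_matrix(tests, same = 0.08, cross = 0.6, group = "EG")
  ref <- bundle_tests(cg, eg, 0.2)
  set.seed(4)
  for (r in 1:5) {
    p <- sample(tests)
    b <- bundle_tests(cg[p, p], eg[p, p], 0.2)
    expect_equal(b[tests], ref[tests])
  }
  expect_error(bundle_tests(cg, eg, tau = 1.5), class = "invalid_parameter")
})

test_that("bundles with a shared ambiguous prefix fall back to concatenated labels", {
  tests <- c("C1", "C2", "C3")
  # only C1-C2 bundle; C3 separate -> two components with prefix "C"
  m <- matrix(0.5, 3, 3, dimnames = list(tests, tests))
  diag(m) <- 0
  m["C1", "C2"] <- m["C2", "C1"] <- 0.05
  cg <- structure(m, group = "CG", alpha = 0.1,
                  class = c("pairwise_ratio_matrix", "matrix"))
  eg <- structure(m, group = "EG", alpha = 0.1,
                  class = c("pairwise_ratio_matrix", "matrix"))
  b <- bundle_tests(cg, eg, 0.2)
  expect_equal(unname(b["C1"]), unname(b["C2"]))
  expect_false(b["C1"] == b["C3"])
  expect_true(grepl("\\+", b["C1"]))
})

test_that("KS ratios: equal samples give zero, overall is the weighted modality mean", {
  tab <- generate_cohort(small_spec(6, n_cg = 18, n_eg = 18))$table
  feats <- attr(tab, "feature_names")
  # make EG rows literally equal to CG rows feature-wise
  cg_rows <- which(tab$group == "CG")
  eg_rows <- which(tab$group == "EG")
  tab[eg_rows, feats] <- tab[cg_rows, feats]
  gd <- ks_between_group_ratio(tab, bundle_map_default())
  expect_equal(unname(gd$overall), rep(0, 3))

  tab2 <- generate_cohort(small_spec(7))$table
  gd2 <- ks_between_group_ratio(tab2, bundle_map_default())
  counts <- as.vector(gd2$n_features_by_modality[colnames(gd2$by_modality)])
  weighted <- as.vector(gd2$by_modality %*% counts) / sum(counts)
  expect_equal(unname(gd2$overall), weighted)
})

test_that("KS significant ratios are 0 at alpha = 0 and non-decreasing in alpha", {
  tab <- generate_cohort(small_spec(8))$table
  r0 <- ks_between_group_ratio(tab, alpha = 0)
  expect_equal(unname(r0$overall), rep(0, 3))
  alphas <- c(0.01, 0.05, 0.1, 0.5)
  ratios <- sapply(alphas, function(a)
    ks_between_group_ratio(tab, alpha = a)$overall)
  for (b in rownames(ratios)) {
    expect_true(all(diff(ratios[b, ]) >= 0))
  }
})

test_that("KS ratios are invariant under strictly monotone feature transforms", {
  tab <- generate_cohort(small_spec(10))$table
  ref <- ks_between_group_ratio(tab)
  tab$EDA_f1 <- exp(tab$EDA_f1)
  tab$HRV_f2 <- tab$HRV_f2^3
  tab$ST_f1 <- atan(tab$ST_f1)
  trans <- ks_between_group_ratio(tab)
  expect_equal(trans$overall, ref$overall)
  expect_equal(trans$by_modality, ref$by_modality)
})

test_that("a bundle absent from the table raises a missing-bundle error", {
  tab <- generate_cohort(small_spec(1))$table
  tab <- tab[tab$test != "E", ]
  expect_error(ks_between_group_ratio(tab, bundle_map_default()),
               class = "missing_bundle")
})

test_that("demographic comparison matches the pooled-variance formula", {
  set.seed(31)
  rec <- data.frame(
    group = rep(c("CG", "EG"), c(25, 18)),
    age = c(rnorm(25, 36, 10), rnorm(18, 33, 11)),
    gender = sample(c("M", "F"), 43, replace = TRUE)
  )
  d <- demographic_comparison(rec)
  a1 <- rec$age[rec$group == "CG"]
  a2 <- rec$age[rec$group == "EG"]
  sp2 <- ((length(a1) - 1) * var(a1) + (length(a2) - 1) * var(a2)) /
    (length(a1) + length(a2) - 2)
  t_oracle <- (mean(a1) - mean(a2)) / sqrt(sp2 * (1 / length(a1) + 1 / length(a2)))
  expect_equal(d$t_statistic, t_oracle)
  expect_equal(d$t_df, length(a1) + length(a2) - 2)
  expect_equal(d$chi_df, 1)

  # identical age vectors in both groups give t = 0 exactly
  rec2 <- data.frame(group = rep(c("CG", "EG"), each = 10),
                     age = rep(seq(20, 47, 3), 2),
                     gender = rep(c("M", "F"), 10))
  expect_equal(demographic_comparison(rec2)$t_statistic, 0)

  expect_error(demographic_comparison(data.frame(
    group = c("CG", "EG", "EG"), age = c(30, 31, 32),
    gender = c("M", "F", "M"))), class = "insufficient_sample")
})
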