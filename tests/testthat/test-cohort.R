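test_that("default spec reproduces recruitment bookkeeping and table shape", {
  cohort <- generate_cohort(cohort_spec(seed = 11))
  rec <- cohort$records
  expect_equal(nrow(rec), 95)
  expect_equal(sum(!rec$completed), 4)
  expect_equal(sum(rec$completed & !rec$data_retrievable), 15)
  analyzed <- rec$completed & rec$data_retrievable
  expect_equal(sum(analyzed), 76)
  expect_equal(as.vector(table(rec$group[analyzed])), c(44, 32))
  expect_equal(anyDuplicated(rec$participant_id), 0)

  tab <- cohort$table
  feats <- attr(tab, "feature_names")
  expect_equal(nrow(tab), 76 * 6)
  expect_equal(length(feats), 191)
  expect_equal(as.vector(table(attr(tab, "modality")[feats])[c("EDA", "HRV", "ST")]),
               c(103, 77, 11))
  # fusion order is EDA block, then HRV, then ST
  expect_equal(feats[1], "EDA_f1")
  expect_equal(feats[104], "HRV_f1")
  expect_equal(feats[191], "ST_f11")
  # exactly one row per (analyzed participant, test); no dropouts present
  expect_true(all(table(tab$participant_id) == 6))
  expect_true(all(tab$participant_id %in% rec$participant_id[analyzed]))
  expect_false(anyNA(feature_matrix(tab)))
})

test_that("generation is bit-identical for a repeated spec and seed", {
  spec <- cohort_spec(seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$table, b$table)
  expect_identical(a$records, b$records)
})

test_that("planted truth uses round-half-up counts and is contained in the feature set", {
  spec <- cohort_spec(seed = 5)
  truth <- planted_truth(spec)
  expect_equal(length(truth$N), 99)   # round(0.52 * 191)
  expect_equal(length(truth$C), 20)   # round(0.104 * 191)
  expect_equal(length(truth$E), 7)    # round(0.036 * 191)
  feats <- feature_names(spec)
  for (ty in names(truth)) expect_true(all(truth[[ty]] %in% feats))

  null_spec <- cohort_spec(effect_fraction = c(C = 0, N = 0, E = 0), seed = 5)
  expect_true(all(lengths(planted_truth(null_spec)) == 0))
})

test_that("planted effects shift EG means on exactly the truth features", {
  spec <- small_spec(3, n_cg = 60, n_eg = 60, effect_size = 2,
                     subject_scale = 0, type_shift_scale = 0)
  truth <- planted_truth(spec)
  tab <- generate_cohort(spec)$table
  n_rows <- tab[tab$test %in% c("N-S", "N-V"), ]
  m <- feature_matrix(n_rows)
  gap <- colMeans(m[n_rows$group == "EG", , drop = FALSE]) -
    colMeans(m[n_rows$group == "CG", , drop = FALSE])
  in_truth <- colnames(m) %in% truth$N
  expect_gt(min(gap[in_truth]), 1)    # planted shift is 2 residual sds
  expect_lt(max(abs(gap[!in_truth])), 1)
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(n_cg = -1), class = "invalid_spec")
  expect_error(cohort_spec(test_labels = c("C1", "C1")), class = "invalid_spec")
  expect_error(cohort_spec(effect_fraction = c(C = 1.2, N = 0.5, E = 0)),
               class = "invalid_spec")
  expect_error(cohort_spec(n_eg = 0), class = "invalid_spec")
  expect_error(cohort_spec(within_type_noise = -0.1), class = "invalid_spec")
  expect_silent(cohort_spec(n_eg = 0, effect_fraction = c(C = 0, N = 0, E = 0)))
})

test_that("a null spec yields feature values with no group or test structure", {
  # effect-free, no subject or type effects: every row is iid noise, so a
  # same-type and a cross-type pair behave identically under the Wilcoxon
  # screen (both at the nominal level).
  spec <- small_spec(9, n_cg = 30, n_eg = 20,
                     effect_fraction = c(C = 0, N = 0, E = 0),
                     subject_scale = 0, type_shift_scale = 0)
  tab <- generate_cohort(spec)$table
  cg <- pairwise_within_group_ratio(tab, "CG")
  off_diag <- cg[upper.tri(cg)]
  expect_true(all(off_diag < 0.5))   # nowhere near the shifted-type regime
  expect_true(all(diag(cg) == 0))
})
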