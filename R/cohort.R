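#' Specification of a synthetic case-control cohort
#'
#' Parameterizes the generative model used by [generate_cohort()]. The
#' defaults emulate a 76-participant adult case-control study (44 controls,
#' 32 cases) in which each participant completes six cognitive stress tests
#' (three colour-word, two number, one emotion variant) while a wrist-worn
#' sensor records electrodermal activity (EDA), heart rate variability (HRV)
#' and skin temperature (ST), summarized as 103 + 77 + 11 = 191 features per
#' (participant, test).
#'
#' The generated value for participant \eqn{i}, feature \eqn{f}, test \eqn{t}
#' of type \eqn{T} is
#' \deqn{x = \mu_f + a_i + b_{f,T} + \Delta\, z_{f,T}\, 1[\mathrm{EG}] +
#'   \epsilon_{i,f,t}}
#' with per-participant random effect \eqn{a_i \sim N(0,
#' \mathrm{subject\_scale}^2)}, per-(feature, test-type) offset
#' \eqn{b_{f,T} \sim N(0, \mathrm{type\_shift\_scale}^2)} shared by all
#' same-type tests, planted indicator \eqn{z_{f,T} \in \{0,1\}} for exactly
#' `round(effect_fraction[T] * n_features)` features, group shift
#' \eqn{\Delta = \mathrm{effect\_size} \times \mathrm{within\_type\_noise}}
#' (i.e. `effect_size` is expressed in units of the residual standard
#' deviation), and residual \eqn{\epsilon \sim N(0,
#' \mathrm{within\_type\_noise}^2)}.
#'
#' Same-type tests are therefore nearly exchangeable at the individual level
#' (paired differences have mean zero), different-type tests are shifted
#' through \eqn{b_{f,T}}, and group effects are concentrated in the test type
#' with the largest `effect_fraction` (the number tests by default, carrying
#' 52\% of features versus 10.4\% for colour-word and 3.6\% for emotion).
#'
#' @param n_cg,n_eg Number of control (CG) / experimental (EG) participants
#'   with complete, retrievable data.
#' @param n_features_per_modality Named integer vector, features per
#'   modality block; the fused dimension is their sum (default 191).
#' @param test_labels Ordered test labels.
#' @param test_types Named character vector mapping each test label to its
#'   type.
#' @param effect_fraction Named numeric vector (by test type) giving the
#'   fraction of features carrying a group effect.
#' @param effect_size Standardized group mean shift for affected features,
#'   in units of `within_type_noise`.
#' @param type_shift_scale Standard deviation of the per-(feature, type)
#'   offsets that separate different test types.
#' @param subject_scale Standard deviation of the per-participant random
#'   effect.
#' @param within_type_noise Residual standard deviation distinguishing
#'   same-type tests.
#' @param dropout Named integer vector `c(incomplete =, unretrievable =)`:
#'   participants who did not finish the protocol or whose data could not be
#'   retrieved. They are generated and flagged, never silently omitted, so
#'   recruitment bookkeeping (95 enrolled, 4 incomplete, 15 unretrievable,
#'   76 analyzed by default) is reproducible.
#' @param dropout_by_group Named integer vector `c(CG =, EG =)` allocating
#'   the dropout total to the two groups (defaults 14 and 5, so 58 CG and
#'   37 EG are enrolled).
#' @param age_params List with per-group `c(mean =, sd =)` of age in years;
#'   ages are truncated at 18.
#' @param gender_params Named numeric vector, per-group male fraction.
#' @param seed Integer seed; every random draw of the generator is governed
#'   by it.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [planted_truth()]
#' @export
cohort_spec <- function(n_cg = 44L, n_eg = 32L,
                        n_features_per_modality = c(EDA = 103L, HRV = 77L, ST = 11L),
                        test_labels = c("C1", "C2", "C3", "N-S", "N-V", "E"),
                        test_types = c("C1" = "C", "C2" = "C", "C3" = "C",
                                       "N-S" = "N", "N-V" = "N", "E" = "E"),
                        effect_fraction = c(C = 0.104, N = 0.52, E = 0.036),
                        effect_size = 1.5,
                        type_shift_scale = 1,
                        subject_scale = 0.5,
                        within_type_noise = 1,
                        dropout = c(incomplete = 4L, unretrievable = 15L),
                        dropout_by_group = c(CG = 14L, EG = 5L),
                        age_params = list(CG = c(mean = 35.18, sd = 11.14),
                                          EG = c(mean = 32.58, sd = 11.39)),
                        gender_params = c(CG = 32 / 58, EG = 24 / 37),
                        seed = 1L) {
  spec <- structure(list(
    n_cg = as.integer(n_cg), n_eg = as.integer(n_eg),
    n_features_per_modality = n_features_per_modality,
    test_labels = test_labels, test_types = test_types,
    effect_fraction = effect_fraction, effect_size = effect_size,
    type_shift_scale = type_shift_scale, subject_scale = subject_scale,
    within_type_noise = within_type_noise,
    dropout = dropout, dropout_by_group = dropout_by_group,
    age_params = age_params, gender_params = gender_params,
    seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  counts <- c(spec$n_cg, spec$n_eg, spec$n_features_per_modality,
              spec$dropout, spec$dropout_by_group)
  if (any(counts < 0)) {
    stop_physioscreen("invalid_spec", "all counts must be >= 0")
  }
  if (anyDuplicated(spec$test_labels)) {
    stop_physioscreen("invalid_spec", "duplicate test labels")
  }
  if (!all(spec$test_labels %in% names(spec$test_types))) {
    stop_physioscreen("invalid_spec", "every test label needs a test type")
  }
  if (any(spec$effect_fraction < 0 | spec$effect_fraction > 1)) {
    stop_physioscreen("invalid_spec", "effect fractions must lie in [0, 1]")
  }
  scales <- c(spec$effect_size, spec$type_shift_scale, spec$subject_scale,
              spec$within_type_noise)
  if (any(scales < 0)) {
    stop_physioscreen("invalid_spec", "scale parameters must be >= 0")
  }
  if (any(spec$effect_fraction > 0) && (spec$n_cg <= 0 || spec$n_eg <= 0)) {
    stop_physioscreen("invalid_spec",
                      "group effects require both group sizes to be positive")
  }
  if (sum(spec$dropout) != sum(spec$dropout_by_group)) {
    stop_physioscreen("invalid_spec",
                      "dropout counts and their group allocation disagree")
  }
  invisible(spec)
}

#' Feature names of a cohort spec, partitioned by modality
#' @param spec A [cohort_spec()].
#' @return Character vector `<modality>_f<k>` in fusion (concatenation) order.
#' @export
feature_names <- function(spec) {
  unlist(lapply(names(spec$n_features_per_modality), function(m) {
    paste0(m, "_f", seq_len(spec$n_features_per_modality[[m]]))
  }), use.names = FALSE)
}

#' Planted ground truth of a synthetic cohort
#'
#' Returns, per test type, the exact set of features carrying a group effect
#' (`z = 1`) that [generate_cohort()] plants for the same spec and seed.
#' The count per type is `round(effect_fraction * n_features)` under
#' round-half-up; the member features are drawn uniformly without
#' replacement under the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return Named list (by test type) of character vectors of feature names.
#' @export
planted_truth <- function(spec) {
  validate_cohort_spec(spec)
  feats <- feature_names(spec)
  n_feat <- length(feats)
  types <- unique(unname(spec$test_types[spec$test_labels]))
  set.seed(spec$seed)
  out <- lapply(types, function(ty) {
    frac <- if (ty %in% names(spec$effect_fraction)) spec$effect_fraction[[ty]] else 0
    n_aff <- round_half_up(frac * n_feat)
    if (n_aff == 0) return(character(0))
    sort_by_index <- sample.int(n_feat, n_aff)
    feats[sort(sort_by_index)]
  })
  names(out) <- types
  out
}

#' Generate a synthetic labeled cohort
#'
#' Draws participant records (demographics plus completion / retrievability
#' flags) and a fused multimodal feature table under the generative model
#' described in [cohort_spec()]. Incomplete or unretrievable participants
#' appear in the records but contribute no feature rows.
#'
#' @param spec A [cohort_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{records}{`data.frame` of class `participant_records`:
#'       `participant_id`, `group`, `age`, `gender`, `completed`,
#'       `data_retrievable`.}
#'     \item{table}{[feature_table] with one row per (analyzed participant,
#'       test) and one column per feature, plus `participant_id`, `group`,
#'       `test` id columns.}
#'   }
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 7))
#' nrow(cohort$table)            # 76 participants x 6 tests
#' sum(!cohort$records$completed)
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  truth <- planted_truth(spec)  # seeds the RNG; later draws continue from it
  feats <- feature_names(spec)
  n_feat <- length(feats)
  modality <- rep(names(spec$n_features_per_modality),
                  times = spec$n_features_per_modality)

  n_enrolled <- c(CG = spec$n_cg + unname(spec$dropout_by_group["CG"]),
                  EG = spec$n_eg + unname(spec$dropout_by_group["EG"]))
  n_total <- sum(n_enrolled)
  ids <- sprintf("P%03d", seq_len(n_total))
  group <- factor(rep(c("CG", "EG"), n_enrolled), levels = c("CG", "EG"))

  age <- numeric(n_total)
  gender <- character(n_total)
  for (g in c("CG", "EG")) {
    sel <- group == g
    ap <- spec$age_params[[g]]
    age[sel] <- rnorm_trunc(sum(sel), ap[["mean"]], ap[["sd"]], lower = 18)
    gender[sel] <- ifelse(stats::runif(sum(sel)) < spec$gender_params[[g]],
                          "M", "F")
  }

  # Dropout allocation: the last dropout_by_group[g] participants of each
  # group drop out; across that pool the first `incomplete` are flagged as
  # not having completed, the remainder as unretrievable.
  dropped <- logical(n_total)
  for (g in c("CG", "EG")) {
    idx <- which(group == g)
    n_drop <- unname(spec$dropout_by_group[g])
    if (n_drop > 0) dropped[idx[seq.int(length(idx) - n_drop + 1, length(idx))]] <- TRUE
  }
  completed <- rep(TRUE, n_total)
  retrievable <- rep(TRUE, n_total)
  drop_idx <- which(dropped)
  n_inc <- unname(spec$dropout["incomplete"])
  completed[drop_idx[seq_len(min(n_inc, length(drop_idx)))]] <- FALSE
  if (length(drop_idx) > n_inc) {
    retrievable[drop_idx[seq.int(n_inc + 1, length(drop_idx))]] <- FALSE
  }

  records <- data.frame(
    participant_id = ids, group = group, age = age, gender = gender,
    completed = completed, data_retrievable = retrievable,
    stringsAsFactors = FALSE
  )
  class(records) <- c("participant_records", "data.frame")

  analyzed <- completed & retrievable
  an_ids <- ids[analyzed]
  an_group <- group[analyzed]
  n_an <- length(an_ids)

  mu <- stats::rnorm(n_feat)                       # per-feature baseline
  a <- stats::rnorm(n_an, 0, spec$subject_scale)   # per-participant effect
  types <- unique(unname(spec$test_types[spec$test_labels]))
  b <- matrix(stats::rnorm(n_feat * length(types), 0, spec$type_shift_scale),
              n_feat, length(types), dimnames = list(feats, types))
  delta <- spec$effect_size * spec$within_type_noise

  rows <- vector("list", length(spec$test_labels))
  for (ti in seq_along(spec$test_labels)) {
    tl <- spec$test_labels[ti]
    ty <- unname(spec$test_types[tl])
    z <- as.numeric(feats %in% truth[[ty]])
    eps <- matrix(stats::rnorm(n_an * n_feat, 0, spec$within_type_noise),
                  n_an, n_feat)
    m <- matrix(mu, n_an, n_feat, byrow = TRUE) +
      matrix(a, n_an, n_feat) +
      matrix(b[, ty], n_an, n_feat, byrow = TRUE) +
      outer(as.numeric(an_group == "EG"), delta * z) +
      eps
    colnames(m) <- feats
    rows[[ti]] <- data.frame(
      participant_id = an_ids, group = an_group, test = tl, m,
      stringsAsFactors = FALSE, check.names = FALSE
    )
  }
  table <- do.call(rbind, rows)
  ord <- order(match(table$participant_id, an_ids),
               match(table$test, spec$test_labels))
  table <- table[ord, , drop = FALSE]
  rownames(table) <- NULL
  table <- new_feature_table(table, feature_names = feats,
                             modality = stats::setNames(modality, feats),
                             test_labels = spec$test_labels,
                             test_types = spec$test_types)
  list(records = records, table = table)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:",
      x$n_cg, "CG +", x$n_eg, "EG analyzed participants;",
      sum(x$dropout), "dropouts;",
      sum(x$n_features_per_modality), "features (",
      paste(names(x$n_features_per_modality), x$n_features_per_modality,
            sep = ":", collapse = ", "), ")\n")
  cat("  tests:", paste(x$test_labels, collapse = ", "), "\n")
  cat("  effect fractions:",
      paste(names(x$effect_fraction), x$effect_fraction, sep = "=",
            collapse = ", "),
      " effect size:", x$effect_size, "\n")
  invisible(x)
}
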