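#' Labeled multimodal feature tables
#'
#' A `feature_table` is a `data.frame` with identifier columns
#' `participant_id`, `group` (factor, `CG`/`EG`), `test`, followed by one
#' numeric column per feature. Feature columns are ordered as the
#' concatenation of the modality blocks (fusion by concatenation), and the
#' order is identical across rows by construction. Attributes:
#' `feature_names` (ordered), `modality` (named map feature -> modality),
#' `test_labels`, `test_types`.
#'
#' @name feature_table
NULL

new_feature_table <- function(df, feature_names, modality, test_labels,
                              test_types) {
  structure(df,
            feature_names = feature_names,
            modality = modality,
            test_labels = test_labels,
            test_types = test_types,
            class = c("feature_table", "data.frame"))
}

validate_feature_table <- function(table) {
  feats <- attr(table, "feature_names")
  id_cols <- c("participant_id", "group", "test")
  missing_cols <- setdiff(c(id_cols, feats), names(table))
  if (length(missing_cols)) {
    stop_physioscreen("schema_error",
                      paste("missing columns:",
                            paste(utils::head(missing_cols, 5), collapse = ", ")))
  }
  bad_test <- setdiff(unique(table$test), attr(table, "test_labels"))
  if (length(bad_test)) {
    stop_physioscreen("schema_error",
                      paste("unknown test label(s):",
                            paste(bad_test, collapse = ", ")))
  }
  bad_group <- setdiff(unique(as.character(table$group)), c("CG", "EG"))
  if (length(bad_group)) {
    stop_physioscreen("schema_error",
                      paste("unknown group label(s):",
                            paste(bad_group, collapse = ", ")))
  }
  key <- paste(table$participant_id, table$test)
  if (anyDuplicated(key)) {
    stop_physioscreen("schema_error",
                      paste("duplicate (participant, test) row:",
                            key[which(duplicated(key))[1]]))
  }
  vals <- as.matrix(table[, feats, drop = FALSE])
  if (anyNA(vals)) {
    stop_physioscreen("schema_error", "missing feature values")
  }
  invisible(table)
}

#' Extract the numeric feature matrix of a table
#'
#' @param table A [feature_table].
#' @param signal_set `"fusion"` for all modalities, or a subset of the
#'   modality names (e.g. `"EDA"`, `c("EDA", "HRV")`).
#' @return Numeric matrix, rows aligned with `table`.
#' @export
feature_matrix <- function(table, signal_set = "fusion") {
  feats <- select_features(table, signal_set)
  m <- as.matrix(table[, feats, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

select_features <- function(table, signal_set = "fusion") {
  feats <- attr(table, "feature_names")
  if (identical(signal_set, "fusion")) return(feats)
  modality <- attr(table, "modality")
  unknown <- setdiff(signal_set, unique(modality))
  if (length(unknown)) {
    stop_physioscreen("schema_error",
                      paste("unknown modality:", paste(unknown, collapse = ", ")))
  }
  feats[modality[feats] %in% signal_set]
}

#' Restrict a feature table to the tests of one bundle
#'
#' @param table A [feature_table].
#' @param bundles A bundle map (named character vector, original test ->
#'   bundle label), e.g. [bundle_map_default()].
#' @param bundle Bundle label to keep.
#' @return A [feature_table] containing only rows of the bundle's tests.
#' @export
subset_bundle <- function(table, bundles, bundle) {
  members <- names(bundles)[bundles == bundle]
  if (!length(members) || !any(table$test %in% members)) {
    stop_physioscreen("missing_bundle",
                      paste("bundle", bundle, "has no rows in the table"))
  }
  out <- table[table$test %in% members, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a classification dataset from a feature table
#'
#' Builds the labeled matrix the decision pipeline and the point filter
#' operate on: one data point per (participant, test) row of the selected
#' bundle, restricted to the requested signal set.
#'
#' @inheritParams subset_bundle
#' @inheritParams feature_matrix
#' @return List of class `pipeline_dataset`: `x` (matrix), `y` (factor
#'   `CG`/`EG`), `participant_id`, `test`, `signal_set`, `bundle`.
#' @export
as_pipeline_dataset <- function(table, bundles = bundle_map_default(),
                                bundle = "N", signal_set = "fusion") {
  sub <- subset_bundle(table, bundles, bundle)
  structure(list(
    x = feature_matrix(sub, signal_set),
    y = factor(as.character(sub$group), levels = c("CG", "EG")),
    participant_id = sub$participant_id,
    test = sub$test,
    signal_set = signal_set,
    bundle = bundle
  ), class = "pipeline_dataset")
}

#' @export
print.feature_table <- function(x, ...) {
  feats <- attr(x, "feature_names")
  cat("Feature table:", length(unique(x$participant_id)), "participants x",
      length(unique(x$test)), "tests,", length(feats), "features\n")
  cat("  groups:", paste(names(table(x$group)), table(x$group),
                         sep = "=", collapse = ", "), "(rows)\n")
  invisible(x)
}
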