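#' Write / read a feature table as delimited text
#'
#' Tab-separated values preceded by a single schema header line recording
#' the modality block sizes and the test-label vocabulary, e.g.
#' `#schema feature_table; modalities=EDA:103,HRV:77,ST:11; tests=C1,...`.
#' Values are written with 17 significant digits so the round trip is
#' lossless. Reading validates the schema: unknown test or group labels,
#' duplicate (participant, test) rows and missing feature columns are
#' schema errors naming the offender.
#'
#' @param table A [feature_table].
#' @param path File path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a [feature_table].
#' @export
write_feature_table <- function(table, path) {
  feats <- attr(table, "feature_names")
  modality <- attr(table, "modality")
  blocks <- rle(unname(modality[feats]))
  header <- paste0(
    "#schema feature_table; modalities=",
    paste(blocks$values, blocks$lengths, sep = ":", collapse = ","),
    "; tests=", paste(attr(table, "test_labels"), collapse = ","),
    "; types=", paste(names(attr(table, "test_types")),
                      attr(table, "test_types"), sep = ":", collapse = ","))
  out <- as.data.frame(table)
  for (f in feats) out[[f]] <- formatC(out[[f]], digits = 17, format = "g")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#schema feature_table")) {
    stop_physioscreen("schema_error", "missing feature_table schema header")
  }
  fields <- strsplit(sub("^#schema feature_table; ", "", header), "; ")[[1]]
  get_field <- function(name) {
    v <- fields[startsWith(fields, paste0(name, "="))]
    if (!length(v)) stop_physioscreen("schema_error",
                                      paste("schema header lacks", name))
    sub(paste0("^", name, "="), "", v)
  }
  blocks <- strsplit(strsplit(get_field("modalities"), ",")[[1]], ":")
  mod_names <- vapply(blocks, `[`, character(1), 1)
  mod_sizes <- as.integer(vapply(blocks, `[`, character(1), 2))
  test_labels <- strsplit(get_field("tests"), ",")[[1]]
  type_pairs <- strsplit(strsplit(get_field("types"), ",")[[1]], ":")
  test_types <- stats::setNames(vapply(type_pairs, `[`, character(1), 2),
                                vapply(type_pairs, `[`, character(1), 1))
  df <- utils::read.delim(path, skip = 1, check.names = FALSE,
                          stringsAsFactors = FALSE)
  feats <- unlist(mapply(function(m, n) paste0(m, "_f", seq_len(n)),
                         mod_names, mod_sizes, SIMPLIFY = FALSE),
                  use.names = FALSE)
  df$group <- factor(df$group, levels = c("CG", "EG"))
  tab <- new_feature_table(
    df, feature_names = feats,
    modality = stats::setNames(rep(mod_names, mod_sizes), feats),
    test_labels = test_labels, test_types = test_types)
  validate_feature_table(tab)
  tab
}

#' Write / read participant records as delimited text
#' @param records A `participant_records` data frame.
#' @param path File path.
#' @export
write_participant_records <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#schema participant_records", con)
  utils::write.table(as.data.frame(records), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_participant_records
#' @export
read_participant_records <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#schema participant_records")) {
    stop_physioscreen("schema_error", "missing participant_records header")
  }
  df <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE)
  df$group <- factor(df$group, levels = c("CG", "EG"))
  class(df) <- c("participant_records", "data.frame")
  df
}

#' Bundled reference classification metrics
#'
#' Loads the package's bundled table of published classification metrics
#' from a reference adult-ADHD wearable case-control study: accuracy,
#' sensitivity and specificity (in percent) for the LR, RF, KNN and SVM
#' models on the EDA, HRV, ST and fusion datasets, for both the original
#' and the point-filtered (reduced) dataset — 96 values in total. These
#' drive the balanced-accuracy comparison analyses without requiring the
#' (unavailable) raw study data.
#'
#' @return List with `original` and `reduced`: `data.frame`s with columns
#'   `signal_set`, `classifier`, `accuracy`, `sensitivity`, `specificity`
#'   (percent).
#' @export
load_printed_metrics <- function() {
  path <- system.file("extdata", "reference_metrics.csv",
                      package = "physioscreen")
  if (!nzchar(path)) {
    stop_physioscreen("integrity_error", "bundled metrics fixture not found")
  }
  if (unname(tools::md5sum(path)) != reference_metrics_md5) {
    stop_physioscreen("integrity_error", "metrics fixture checksum mismatch")
  }
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  pivot <- function(col) {
    wide <- stats::reshape(
      long[, c("signal_set", "classifier", "metric", col)],
      idvar = c("signal_set", "classifier"), timevar = "metric",
      direction = "wide")
    names(wide) <- sub(paste0("^", col, "\\."), "", names(wide))
    rownames(wide) <- NULL
    wide
  }
  list(original = pivot("original"), reduced = pivot("reduced"))
}

reference_metrics_md5 <- "203d6495ac8158c6e18bc0a20e7efb94"

#' Run the full decision pipeline end to end
#'
#' Executes simulate -> within-group screening and bundling -> between-group
#' selection -> per-signal-set i-KNN filtering -> full-versus-reduced
#' Monte-Carlo evaluation -> balanced-accuracy comparison, writing every
#' intermediate as delimited text under `out_dir` and returning a manifest
#' with checksums. Reruns with the same spec and settings reproduce
#' identical artifacts.
#'
#' @param spec A [cohort_spec()] (its seed governs the simulation); or
#'   `table`/`records` may be supplied directly instead.
#' @param out_dir Output directory (created if needed).
#' @param table,records Optional pre-existing [feature_table] and
#'   participant records; exactly one of `spec` or `table` must be given.
#' @param alpha Significance cutoff for both screening stages.
#' @param tau Bundling threshold for the data-driven rule.
#' @param bundling `"fixed"` (default: the C/N/E map) or `"data-driven"`.
#' @param iknn An [iknn_config()].
#' @param classifiers Classifier names to evaluate.
#' @param signal_sets Signal sets to evaluate (default the three modalities
#'   and their fusion).
#' @param n_folds,test_fraction,seed CV settings (see [pipeline_config()]).
#' @param stages Subset of `c("screen", "evaluate")`; screening alone skips
#'   the classifier stage.
#' @return Object of class `run_manifest`: config echo, package version,
#'   output paths with md5 checksums, timing, and the in-memory `results`.
#' @export
run_full_pipeline <- function(spec = cohort_spec(), out_dir = tempfile("physioscreen_run_"),
                              table = NULL, records = NULL,
                              alpha = 0.1, tau = 0.2,
                              bundling = c("fixed", "data-driven"),
                              iknn = iknn_config(),
                              classifiers = c("LR", "RF", "KNN", "SVM"),
                              signal_sets = c("EDA", "HRV", "ST", "fusion"),
                              n_folds = 100L, test_fraction = 0.3, seed = 1L,
                              stages = c("screen", "evaluate")) {
  bundling <- match.arg(bundling)
  t0 <- Sys.time()
  if (is.null(table) == is.null(spec)) {
    stop_physioscreen("invalid_config",
                      "exactly one of spec or table must be supplied")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(table)) {
    cohort <- generate_cohort(spec)
    table <- cohort$table
    records <- cohort$records
  }
  outputs <- character(0)
  emit <- function(obj, name, writer = utils::write.table) {
    p <- file.path(out_dir, name)
    if (is.function(writer)) writer(obj, p)
    outputs <<- c(outputs, p)
    p
  }
  emit(table, "feature_table.tsv", write_feature_table)
  if (!is.null(records)) {
    emit(records, "participant_records.tsv", write_participant_records)
  }

  results <- list()
  if ("screen" %in% stages) {
    cg <- pairwise_within_group_ratio(table, "CG", alpha)
    eg <- pairwise_within_group_ratio(table, "EG", alpha)
    bundles <- if (bundling == "fixed") {
      bundle_map_default(attr(table, "test_labels"), attr(table, "test_types"))
    } else {
      bundle_tests(cg, eg, tau)
    }
    gd <- ks_between_group_ratio(table, bundles, alpha)
    results$pairwise <- list(CG = cg, EG = eg)
    results$bundles <- bundles
    results$group_difference <- gd
    emit(NULL, "pairwise_cg.tsv", function(o, p)
      utils::write.table(as.data.frame(unclass(cg)), p, sep = "\t", quote = FALSE))
    emit(NULL, "pairwise_eg.tsv", function(o, p)
      utils::write.table(as.data.frame(unclass(eg)), p, sep = "\t", quote = FALSE))
    emit(NULL, "group_difference.tsv", function(o, p)
      utils::write.table(
        data.frame(bundle = names(gd$overall), overall = gd$overall,
                   as.data.frame(gd$by_modality)),
        p, sep = "\t", quote = FALSE, row.names = FALSE))
  } else {
    bundles <- bundle_map_default(attr(table, "test_labels"),
                                  attr(table, "test_types"))
  }

  if ("evaluate" %in% stages) {
    selected <- if (!is.null(results$group_difference)) {
      results$group_difference$selected_bundle
    } else "N"
    summaries <- list()
    for (ss in signal_sets) {
      ds <- as_pipeline_dataset(table, bundles, selected, ss)
      filt <- filter_points(ds, config = iknn)
      emit(NULL, paste0("sbar_", ss, ".tsv"), function(o, p)
        utils::write.table(
          data.frame(participant_id = ds$participant_id, test = ds$test,
                     s_bar = filt$s_bar,
                     discarded = seq_along(filt$s_bar) %in% filt$discarded),
          p, sep = "\t", quote = FALSE, row.names = FALSE))
      ds_red <- ds
      ds_red$x <- ds$x[filt$retained, , drop = FALSE]
      ds_red$y <- ds$y[filt$retained]
      for (cl in classifiers) {
        for (variant in c("full", "reduced")) {
          cfg <- pipeline_config(classifier = cl, n_folds = n_folds,
                                 test_fraction = test_fraction, seed = seed,
                                 variant = variant, signal_set = ss)
          rep_ <- evaluate_config(if (variant == "full") ds else ds_red, cfg)
          summaries[[length(summaries) + 1]] <- rep_$summary
        }
      }
    }
    metrics <- do.call(rbind, summaries)
    results$metrics <- metrics
    results$comparison <- balanced_accuracy_change(
      metrics[metrics$variant == "full", , drop = FALSE],
      metrics[metrics$variant == "reduced", , drop = FALSE])
    emit(NULL, "metrics.tsv", function(o, p)
      utils::write.table(metrics, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit(NULL, "comparison.tsv", function(o, p)
      utils::write.table(results$comparison$detail, p, sep = "\t",
                         quote = FALSE, row.names = FALSE))
  }

  manifest <- structure(list(
    spec = spec, alpha = alpha, tau = tau, bundling = bundling,
    iknn = iknn, classifiers = classifiers, signal_sets = signal_sets,
    n_folds = n_folds, test_fraction = test_fraction, seed = seed,
    stages = stages,
    package_version = as.character(utils::packageVersion("physioscreen")),
    outputs = data.frame(path = outputs,
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE),
    timing_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    results = results
  ), class = "run_manifest")
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("physioscreen run:", nrow(x$outputs), "artifacts in",
      dirname(x$outputs$path[1]), sprintf("(%.1f s)\n", x$timing_sec))
  if (!is.null(x$results$group_difference)) {
    cat("  selected bundle:", x$results$group_difference$selected_bundle, "\n")
  }
  if (!is.null(x$results$comparison)) print(x$results$comparison)
  invisible(x)
}
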