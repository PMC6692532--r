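# Confusion-matrix evaluation against a gold standard, derived metrics,
# coverage, and error-percentage bookkeeping.

#' Serialize relationship rows to comparison keys at a chosen granularity
#'
#' Granularities: `"quaternary"` (disease, drug, gene, variant), `"triplet"`
#' (disease, drug, gene) and `"pair"` (drug, gene — the granularity of a
#' PharmGKB-style drug-gene gold standard). Rows collapsing to the same key
#' are deduplicated.
#'
#' @param table Relationship tibble (needs the columns the granularity uses).
#' @param granularity One of `"quaternary"`, `"triplet"`, `"pair"`.
#' @return Character vector of unique keys.
#' @export
relation_keys <- function(table, granularity = c("triplet", "quaternary", "pair")) {
  granularity <- match.arg(granularity)
  cols <- switch(granularity,
                 quaternary = c("disease_id", "drug_id", "gene_symbol", "variant_id"),
                 triplet = c("disease_id", "drug_id", "gene_symbol"),
                 pair = c("drug_id", "gene_symbol"))
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols) > 0) {
    abort_invalid(sprintf(
      "Granularity '%s' needs column(s) %s absent from the table.",
      granularity, paste(missing_cols, collapse = ", ")))
  }
  parts <- lapply(cols, function(cl) dplyr::coalesce(as.character(table[[cl]]), ""))
  unique(do.call(paste, c(parts, sep = "\t")))
}

#' Confusion counts of a test set against a gold standard
#'
#' Both sets must be subsets of the explicit candidate universe (an
#' open-world extraction task has no countable true negatives without one):
#' TP = test n gold, FP = test \\ gold, FN = gold \\ test,
#' TN = universe \\ (test u gold). The four counts always partition the
#' universe.
#'
#' @param test,gold,universe Character vectors of relationship keys.
#' @return A list of class `pgx_confusion` with `TP`, `TN`, `FP`, `FN` and
#'   `universe_size`.
#' @export
confusion <- function(test, gold, universe) {
  test <- unique(test); gold <- unique(gold); universe <- unique(universe)
  if (!all(test %in% universe)) {
    abort_invalid("`test` must be a subset of `universe`.")
  }
  if (!all(gold %in% universe)) {
    abort_invalid("`gold` must be a subset of `universe`.")
  }
  tp <- length(intersect(test, gold))
  fp <- length(setdiff(test, gold))
  fn <- length(setdiff(gold, test))
  tn <- length(universe) - tp - fp - fn
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 universe_size = length(universe)),
            class = "pgx_confusion")
}

#' @export
print.pgx_confusion <- function(x, ...) {
  cat(sprintf("<pgx_confusion: TP=%d TN=%d FP=%d FN=%d (universe %d)>\n",
              x$TP, x$TN, x$FP, x$FN, x$universe_size))
  invisible(x)
}

#' Default candidate universe for confusion counting
#'
#' The union of the test keys, the gold keys and any reference-dataset keys
#' already projected to the comparison granularity. Making the universe
#' explicit (and recording it in the report) is what renders TN well-defined.
#'
#' @param test,gold Character key vectors.
#' @param reference_keys Optional additional keys.
#' @return Character vector of universe keys.
#' @export
build_universe <- function(test, gold, reference_keys = character()) {
  unique(c(test, gold, reference_keys))
}

#' Performance metrics from confusion counts
#'
#' Standard definitions: sensitivity = recall = TP/(TP+FN); specificity =
#' TN/(TN+FP); precision = TP/(TP+FP); accuracy = (TP+TN)/universe;
#' F = 2PR/(P+R). A zero denominator yields `NA` (the undefined marker),
#' never an error.
#'
#' @param counts A `pgx_confusion`.
#' @return A named list of metrics in `[0, 1]` or `NA`.
#' @export
metrics <- function(counts) {
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(counts$TP, counts$TP + counts$FN)
  spec <- safe_div(counts$TN, counts$TN + counts$FP)
  prec <- safe_div(counts$TP, counts$TP + counts$FP)
  acc <- safe_div(counts$TP + counts$TN, counts$universe_size)
  fmeas <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  list(sensitivity = sens, specificity = spec, precision = prec,
       recall = sens, f_measure = fmeas, accuracy = acc)
}

#' Error percentage of an observed count against its true count
#'
#' Absolute error over the exact value, times 100. Stored at full precision;
#' use [format_error_percent()] for the two-decimal truncated display form.
#'
#' @param true_value True (reference) count, strictly positive.
#' @param observed_value Observed count.
#' @return Numeric percentage(s).
#' @examples
#' error_percentage(100, 150)  # 50
#' @export
error_percentage <- function(true_value, observed_value) {
  if (any(is.na(true_value)) || any(true_value <= 0)) {
    abort_invalid("`true_value` must be strictly positive.")
  }
  abs(observed_value - true_value) / true_value * 100
}

#' Two-decimal truncated display of an error percentage
#'
#' Truncates (does not round) to two decimals, the convention under which
#' the bookkeeping examples in this package reproduce their printed values.
#'
#' @param x Numeric percentages.
#' @return Character vector like `"18.14"`.
#' @export
format_error_percent <- function(x) {
  sprintf("%.2f", floor(x * 100) / 100)
}

#' Error-percentage report over (true, observed) count pairs
#'
#' @param counts Tibble with columns `source`, `true_value`,
#'   `observed_value`.
#' @return The same tibble with `error_percent` (full precision) and
#'   `error_percent_display` (two-decimal truncation) columns.
#' @export
error_report <- function(counts) {
  needed <- c("source", "true_value", "observed_value")
  missing_cols <- setdiff(needed, names(counts))
  if (length(missing_cols) > 0) {
    abort_invalid(sprintf("Counts table is missing column(s): %s",
                          paste(missing_cols, collapse = ", ")))
  }
  counts$error_percent <- error_percentage(counts$true_value,
                                           counts$observed_value)
  counts$error_percent_display <- format_error_percent(counts$error_percent)
  counts
}

#' Coverage of a reference set by a test set
#'
#' @param test,reference Character key vectors; `reference` must be
#'   non-empty.
#' @return `|test n reference| / |reference|`.
#' @export
coverage <- function(test, reference) {
  reference <- unique(reference)
  if (length(reference) == 0) {
    abort_invalid("`reference` must be non-empty.")
  }
  length(intersect(unique(test), reference)) / length(reference)
}

#' Full evaluation report of a relationship table against a gold standard
#'
#' Computes confusion counts and metrics at the requested granularity over
#' an explicit universe (by default the union of test, gold and reference
#' keys), coverage of each reference dataset, and (optionally) the
#' error-percentage table. The universe definition and granularity are
#' recorded in the report.
#'
#' @param table Relationship table (the test data).
#' @param gold Gold-standard relationship tibble (same column dialect).
#' @param granularity Comparison granularity (see [relation_keys()]).
#' @param references Optional named list of `pgx_reference` objects for
#'   per-dataset coverage (computed at pair granularity on drug-gene keys).
#' @param universe Optional explicit universe; defaults to
#'   [build_universe()].
#' @param error_counts Optional (true, observed) counts tibble for
#'   [error_report()].
#' @return A list of class `pgx_evaluation`.
#' @export
evaluate_relations <- function(table, gold,
                               granularity = c("triplet", "quaternary", "pair"),
                               references = NULL, universe = NULL,
                               error_counts = NULL) {
  granularity <- match.arg(granularity)
  test_keys <- relation_keys(table, granularity)
  gold_keys <- relation_keys(gold, granularity)
  if (is.null(universe)) {
    universe <- build_universe(test_keys, gold_keys)
  }
  counts <- confusion(test_keys, gold_keys, universe)
  cov <- NULL
  if (!is.null(references)) {
    pair_test <- relation_keys(table, "pair")
    cov <- lapply(references, function(ref) {
      dg <- ref$assertions[ref$assertions$kind == "drug_gene", , drop = FALSE]
      if (nrow(dg) == 0) return(NA_real_)
      coverage(pair_test, paste(dg$id1, dg$id2, sep = "\t"))
    })
  }
  structure(list(
    granularity = granularity,
    universe_size = length(universe),
    universe_definition = "union of test, gold and reference keys",
    counts = counts,
    metrics = metrics(counts),
    coverage = cov,
    error_table = if (!is.null(error_counts)) error_report(error_counts)
  ), class = "pgx_evaluation")
}

#' Serialize an evaluation report to JSON
#'
#' @param report A `pgx_evaluation`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
evaluation_report_json <- function(report, path = NULL) {
  payload <- list(
    granularity = report$granularity,
    universe = list(size = report$universe_size,
                    definition = report$universe_definition),
    counts = unclass(report$counts),
    metrics = report$metrics,
    coverage = report$coverage,
    error_table = report$error_table
  )
  json <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                           pretty = TRUE, na = "null", digits = NA)
  if (!is.null(path)) {
    readr::write_lines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}
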