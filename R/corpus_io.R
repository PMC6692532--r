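# Reading MEDLINE-export CSV corpora and PubTator offset TSVs, and the
# publication-level filter cascade with auditable per-stage counts.

MEDLINE_COLUMNS <- c("pmid", "title", "abstract", "pub_types", "is_human", "year")

#' Build a boolean-OR PubMed query over MeSH terms
#'
#' Each term is double-quoted and the terms are joined with `OR`, the form
#' used to assemble a pharmacogenomics literature query from MeSH headings.
#'
#' @param mesh_terms Character vector of query terms. The default is the
#'   four-term pharmacogenomics heading set used to seed the corpus.
#' @return A single query string.
#' @examples
#' build_query(c("pharmacogenomics", "drug response"))
#' @export
build_query <- function(mesh_terms = default_query_terms()) {
  if (length(mesh_terms) == 0 || !is.character(mesh_terms)) {
    abort_invalid("`mesh_terms` must be a non-empty character vector.")
  }
  if (any(is.na(mesh_terms) | mesh_terms == "")) {
    abort_invalid("`mesh_terms` must not contain empty or missing terms.")
  }
  paste(sprintf('"%s"', mesh_terms), collapse = " OR ")
}

#' @rdname build_query
#' @export
default_query_terms <- function() {
  c("inter-individual variability", "pharmacogenomics", "pharmacogenetics",
    "drug response")
}

#' Read a MEDLINE-export CSV into an abstract-record table
#'
#' The expected dialect is UTF-8 comma-separated with quoted fields and
#' columns `pmid,title,abstract,pub_types,is_human,year`; `pub_types` holds
#' pipe-separated publication types. e-utilities exports vary, so `col_map`
#' renames columns of the file to this dialect before validation.
#'
#' Malformed rows (missing or non-positive pmid, duplicated pmid, unparseable
#' year) are skipped with a warning and counted in the `skipped` attribute,
#' never silently dropped.
#'
#' @param path Path to the CSV file.
#' @param col_map Optional named character vector mapping dialect column
#'   names to the names used in the file, e.g. `c(pmid = "PMID")`.
#' @return A tibble with columns `pmid` (integer), `title`, `abstract`
#'   (empty string when none), `pub_types` (pipe-separated), `is_human`
#'   (logical), `year` (integer) and a `has_abstract` logical column.
#' @export
read_medline_csv <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    abort_io(sprintf("Corpus file does not exist: %s", path))
  }
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) abort_io(sprintf("Cannot read corpus CSV %s: %s",
                                         path, conditionMessage(e)))
  )
  if (!is.null(col_map)) {
    for (dialect_name in names(col_map)) {
      file_name <- col_map[[dialect_name]]
      if (file_name %in% names(raw)) {
        names(raw)[names(raw) == file_name] <- dialect_name
      }
    }
  }
  missing_cols <- setdiff(MEDLINE_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort_format(sprintf("Corpus CSV is missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }

  pmid <- suppressWarnings(as.integer(raw$pmid))
  year <- suppressWarnings(as.integer(raw$year))
  is_human <- toupper(trimws(raw$is_human %||% "")) %in% c("TRUE", "T", "1", "YES")
  bad <- is.na(pmid) | pmid <= 0 | is.na(year) | duplicated(pmid)
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    warn(sprintf("Skipped %d malformed corpus row(s) in %s.", sum(bad), path))
  }

  records <- tibble(
    pmid = pmid[!bad],
    title = dplyr::coalesce(raw$title[!bad], ""),
    abstract = dplyr::coalesce(raw$abstract[!bad], ""),
    pub_types = dplyr::coalesce(raw$pub_types[!bad], ""),
    is_human = is_human[!bad],
    year = year[!bad]
  )
  records$has_abstract <- records$abstract != ""
  attr(records, "skipped") <- sum(bad)
  records
}

#' Write an abstract-record table in the MEDLINE-export CSV dialect
#'
#' Inverse of [read_medline_csv()]: writing then reading is the identity on
#' the record fields.
#'
#' @param records Abstract-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_medline_csv <- function(records, path) {
  out <- records[, MEDLINE_COLUMNS]
  out$is_human <- ifelse(out$is_human, "TRUE", "FALSE")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# PubTator class labels accepted for each pipeline entity class.
PUBTATOR_CLASS_MAP <- c(
  disease = "disease",
  chemical = "drug", drug = "drug",
  gene = "gene",
  mutation = "variant", variant = "variant", snp = "variant",
  dnamutation = "variant", proteinmutation = "variant"
)

#' Read a PubTator-style offset TSV of pre-computed entity mentions
#'
#' Lines follow `pmid<TAB>start<TAB>end<TAB>mention<TAB>class<TAB>id` with
#' 0-based half-open character offsets into the annotated text
#' (title + " " + abstract). Mention classes outside
#' disease/chemical/gene/mutation are ignored and counted in the
#' `ignored_classes` attribute.
#'
#' @param path Path to the TSV file.
#' @return A mention tibble (columns `pmid`, `entity_class`, `surface`,
#'   `start`, `end`, `candidate_ids`, `source = "imported"`).
#' @export
read_pubtator_tsv <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("PubTator file does not exist: %s", path))
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[lines != ""]
  if (length(lines) == 0) {
    out <- empty_mentions()
    attr(out, "ignored_classes") <- 0L
    return(out)
  }
  fields <- str_split(lines, "\t")
  n_fields <- lengths(fields)
  bad_shape <- which(n_fields < 6)
  if (length(bad_shape) > 0) {
    abort_format(sprintf("PubTator line %d has %d field(s); expected 6.",
                         bad_shape[1], n_fields[bad_shape[1]]))
  }
  pmid <- suppressWarnings(as.integer(map_chr(fields, 1)))
  start <- suppressWarnings(as.integer(map_chr(fields, 2)))
  end <- suppressWarnings(as.integer(map_chr(fields, 3)))
  surface <- map_chr(fields, 4)
  type <- tolower(map_chr(fields, 5))
  id <- map_chr(fields, 6)

  bad_offset <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad_offset) > 0) {
    abort_format(sprintf("PubTator line %d has invalid offsets (end <= start).",
                         bad_offset[1]))
  }

  known <- type %in% names(PUBTATOR_CLASS_MAP)
  ignored <- sum(!known)
  out <- tibble(
    pmid = pmid[known],
    entity_class = unname(PUBTATOR_CLASS_MAP[type[known]]),
    surface = surface[known],
    start = start[known],
    end = end[known],
    candidate_ids = map(id[known], function(x) {
      if (is.na(x) || x == "" || x == "-") character() else x
    }),
    source = "imported"
  )
  attr(out, "ignored_classes") <- ignored
  out
}

#' Write mentions in the PubTator offset TSV dialect
#'
#' @param mentions Mention tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pubtator_tsv <- function(mentions, path) {
  class_out <- c(disease = "Disease", drug = "Chemical", gene = "Gene",
                 variant = "Mutation", population = "Species")
  lines <- sprintf(
    "%d\t%d\t%d\t%s\t%s\t%s",
    mentions$pmid, mentions$start, mentions$end, mentions$surface,
    class_out[mentions$entity_class],
    map_chr(mentions$candidate_ids, function(x) {
      if (length(x) == 0) "-" else paste(x, collapse = ",")
    })
  )
  readr::write_lines(lines, path)
  invisible(path)
}

# ---- Filter cascade ---------------------------------------------------------

new_filter_report <- function() {
  tibble(
    stage = character(),
    input_count = integer(),
    excluded_count = integer(),
    retained_count = integer()
  )
}

#' Append a stage to a filter report
#'
#' Enforces the conservation invariant `retained = input - excluded` and the
#' chaining invariant that a stage's input equals the previous stage's
#' retained count.
#'
#' @param report A filter-report tibble (or `NULL` to start one).
#' @param stage Stage name.
#' @param input_count,excluded_count Non-negative integers.
#' @return The extended report.
#' @export
add_filter_stage <- function(report, stage, input_count, excluded_count) {
  if (is.null(report)) report <- new_filter_report()
  input_count <- as.integer(input_count)
  excluded_count <- as.integer(excluded_count)
  if (is.na(input_count) || is.na(excluded_count) ||
      input_count < 0 || excluded_count < 0 || excluded_count > input_count) {
    abort_invalid("Filter-stage counts must satisfy 0 <= excluded <= input.")
  }
  if (nrow(report) > 0 && report$retained_count[nrow(report)] != input_count) {
    abort_invalid(sprintf(
      "Stage '%s' input (%d) must equal the previous stage's retained count (%d).",
      stage, input_count, report$retained_count[nrow(report)]))
  }
  bind_rows(report, tibble(
    stage = stage,
    input_count = input_count,
    excluded_count = excluded_count,
    retained_count = input_count - excluded_count
  ))
}

#' Validate filter-report invariants
#'
#' @param report Filter-report tibble.
#' @return `TRUE` invisibly; aborts when an invariant is violated.
#' @export
validate_filter_report <- function(report) {
  if (nrow(report) == 0) return(invisible(TRUE))
  if (any(report$retained_count != report$input_count - report$excluded_count)) {
    abort_invalid("Filter report violates retained = input - excluded.")
  }
  if (nrow(report) > 1 &&
      any(report$input_count[-1] != report$retained_count[-nrow(report)])) {
    abort_invalid("Filter report stages are not chained consistently.")
  }
  invisible(TRUE)
}

#' Publication-level filter cascade
#'
#' Applies, in order: the original-article filter (records whose publication
#' types intersect the configured exclusion list are dropped), the human
#' filter, and the has-abstract filter. The later entity-presence filter is
#' applied downstream by the pipeline and appended to the same report.
#'
#' @param records Abstract-record tibble.
#' @param exclude_pub_types Publication types that disqualify a record from
#'   the "original articles" set.
#' @return A list with `records` (retained tibble) and `report` (a
#'   filter-report tibble with stages `original_articles`, `human_studies`,
#'   `has_abstract`).
#' @export
filter_cascade <- function(records,
                           exclude_pub_types = c("Review", "Editorial",
                                                 "Comment", "Letter",
                                                 "Case Reports")) {
  report <- new_filter_report()

  types <- str_split(records$pub_types, stringr::fixed("|"))
  is_original <- !map_lgl(types, function(x) any(trimws(x) %in% exclude_pub_types))
  report <- add_filter_stage(report, "original_articles",
                             nrow(records), sum(!is_original))
  records <- records[is_original, ]

  report <- add_filter_stage(report, "human_studies",
                             nrow(records), sum(!records$is_human))
  records <- records[records$is_human, ]

  has_abs <- records$abstract != ""
  report <- add_filter_stage(report, "has_abstract", nrow(records), sum(!has_abs))
  records <- records[has_abs, ]

  validate_filter_report(report)
  list(records = records, report = report)
}

#' Serialize a filter report to JSON
#'
#' @param report Filter-report tibble.
#' @param path Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
filter_report_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(list(stages = report), dataframe = "rows",
                           auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    readr::write_lines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}
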