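# End-to-end orchestration: corpus -> NER -> normalization -> relation
# extraction -> aggregation, plus ranking and evaluation drivers. These are
# the programmatic equivalents of the mine/rank/evaluate/simulate
# subcommands exposed by the command-line wrapper.

#' Load the lexicon set a pipeline run needs
#'
#' @param paths Named list/vector with elements `gene`, `disease`, `drug`,
#'   `variant`, `population` pointing at lexicon files.
#' @return Named list of `pgx_lexicon` objects.
#' @export
load_lexica <- function(paths) {
  needed <- c("gene", "disease", "drug", "variant", "population")
  missing_lx <- setdiff(needed, names(paths))
  if (length(missing_lx) > 0) {
    abort_invalid(sprintf("Missing lexicon path(s): %s",
                          paste(missing_lx, collapse = ", ")))
  }
  for (p in paths[needed]) {
    if (!file.exists(p)) abort_io(sprintf("Lexicon file does not exist: %s", p))
  }
  list(
    gene = load_lexicon(paths[["gene"]], "gene"),
    disease = load_lexicon(paths[["disease"]], "disease"),
    drug = load_lexicon(paths[["drug"]], "drug"),
    variant = load_variant_index(paths[["variant"]]),
    population = load_population_list(paths[["population"]])
  )
}

#' Mine a corpus for pharmacogenomic relationships
#'
#' Runs the full extraction pipeline: the publication-level filter cascade,
#' entity recognition (dictionary NER over the disease/drug/gene/population
#' lexica plus pattern-based variant recognition, or imported PubTator-style
#' annotations), the entity-presence filter (appended to the same filter
#' report), normalization, and co-occurrence relation extraction with
#' corpus-wide aggregation.
#'
#' @param records Abstract-record tibble (from [read_medline_csv()] or the
#'   fixtures generator).
#' @param lexica Named lexicon list (see [load_lexica()]).
#' @param config Optional list: `exclude_pub_types`, `symptom_terms`,
#'   `family_terms`, `chapter_priority`, `star_alleles`,
#'   `imported_annotations` (a mention tibble from [read_pubtator_tsv()];
#'   when present it replaces dictionary/pattern recognition but still goes
#'   through the presence filter and normalization).
#' @return A list with `table` (aggregated relationship table), `report`
#'   (filter report including the `entity_presence` stage), `mentions`,
#'   `entities` (all normalization outcomes), `summary`
#'   ([normalization_summary()]) and `curation_queue` (ambiguous/failed
#'   rows).
#' @export
pgx_mine <- function(records, lexica, config = list()) {
  exclude_pub_types <- config$exclude_pub_types %||%
    c("Review", "Editorial", "Comment", "Letter", "Case Reports")
  star_alleles <- isTRUE(config$star_alleles)

  cascade <- filter_cascade(records, exclude_pub_types)
  retained <- cascade$records
  report <- cascade$report

  rec_lexica <- lexica[intersect(c("disease", "drug", "gene", "population"),
                                 names(lexica))]
  mention_sets <- vector("list", nrow(retained))
  if (nrow(retained) > 0) {
    imported <- config$imported_annotations
    for (k in seq_len(nrow(retained))) {
      rec <- retained[k, ]
      if (!is.null(imported)) {
        mention_sets[[k]] <- imported[imported$pmid == rec$pmid, , drop = FALSE]
      } else {
        mention_sets[[k]] <- recognize_record(rec, rec_lexica,
                                              star_alleles = star_alleles)
      }
    }
  }
  has_pgx <- map_lgl(mention_sets, entity_presence_filter)
  report <- add_filter_stage(report, "entity_presence",
                             nrow(retained), sum(!has_pgx))
  validate_filter_report(report)

  mentions <- if (any(has_pgx)) bind_rows(mention_sets[has_pgx]) else
    empty_mentions()
  entities <- normalize_mentions(mentions, lexica, config)

  keys <- list()
  for (pm in unique(entities$pmid)) {
    keys[[length(keys) + 1]] <- extract_relations(
      entities[entities$pmid == pm, , drop = FALSE], lexica$variant)
  }
  table <- aggregate_relations(
    if (length(keys)) bind_rows(keys) else empty_relation_keys())

  list(
    table = table,
    report = report,
    mentions = mentions,
    entities = entities,
    summary = normalization_summary(entities),
    curation_queue = entities[entities$status %in% c("ambiguous", "failed"), ]
  )
}

#' Rank a mined relationship table against the reference datasets
#'
#' Applies [rank_relationships()] and [flag_novel()] (novelty against the
#' PharmGKB-style dataset when present).
#'
#' @param table Aggregated relationship table.
#' @param references Named list of `pgx_reference` objects.
#' @param f_threshold Strict frequency threshold for unsupported rows.
#' @return The ranked, novel-flagged table (attributes `dropped`,
#'   `novel_count`).
#' @export
pgx_rank <- function(table, references, f_threshold = 10) {
  if (length(references) == 0) {
    abort_invalid("At least one reference dataset is required for ranking.")
  }
  ranked <- rank_relationships(table, references, f_threshold)
  if ("PharmGKB" %in% names(references)) {
    dropped <- attr(ranked, "dropped")
    ranked <- flag_novel(ranked, references$PharmGKB)
    attr(ranked, "dropped") <- dropped
  }
  ranked
}

#' Evaluate a mined relationship table against a gold standard
#'
#' Thin driver over [evaluate_relations()] that checks the gold standard can
#' be compared at the requested granularity before any work is done.
#'
#' @param table Aggregated relationship table.
#' @param gold Gold-standard tibble (from [read_gold_tsv()]).
#' @param granularity Comparison granularity.
#' @param references Optional named `pgx_reference` list for coverage.
#' @param error_counts Optional (true, observed) counts for the
#'   error-percentage table.
#' @return A `pgx_evaluation`.
#' @export
pgx_evaluate <- function(table, gold,
                         granularity = c("triplet", "quaternary", "pair"),
                         references = NULL, error_counts = NULL) {
  granularity <- match.arg(granularity)
  needed <- switch(granularity,
                   quaternary = c("disease_id", "drug_id", "gene_symbol",
                                  "variant_id"),
                   triplet = c("disease_id", "drug_id", "gene_symbol"),
                   pair = c("drug_id", "gene_symbol"))
  missing_gold <- setdiff(needed, names(gold))
  if (length(missing_gold) > 0) {
    abort_invalid(sprintf(
      "Gold standard lacks column(s) %s required by granularity '%s'.",
      paste(missing_gold, collapse = ", "), granularity))
  }
  evaluate_relations(table, gold, granularity, references = references,
                     error_counts = error_counts)
}

#' Generate a fixtures bundle (simulate subcommand)
#'
#' @param spec A `pgx_fixture_spec` (or arguments for [fixture_spec()]
#'   given as a list).
#' @param dir Output directory.
#' @return See [generate_bundle()].
#' @export
pgx_simulate <- function(spec, dir) {
  if (!inherits(spec, "pgx_fixture_spec")) {
    spec <- do.call(fixture_spec, as.list(spec))
  }
  generate_bundle(spec, dir)
}

#' Run mine -> rank -> evaluate over a fixtures bundle directory
#'
#' Convenience driver used by the worked examples: reads every input back
#' from its file form (nothing is passed in memory), so it exercises the
#' exact on-disk dialects.
#'
#' @param dir A bundle directory written by [pgx_simulate()].
#' @param config Optional [pgx_mine()] config.
#' @param f_threshold Ranking threshold.
#' @param granularity Evaluation granularity.
#' @return A list with `mined`, `ranked` and `evaluation`.
#' @export
pgx_run_bundle <- function(dir, config = list(), f_threshold = 10,
                           granularity = "triplet") {
  lexica <- load_lexica(list(
    gene = file.path(dir, "hgnc_mini.tsv"),
    disease = file.path(dir, "icd10_mini.tsv"),
    drug = file.path(dir, "drugbank_mini.tsv"),
    variant = file.path(dir, "dbsnp_mini.tsv"),
    population = file.path(dir, "populations.txt")
  ))
  records <- read_medline_csv(file.path(dir, "corpus.csv"))
  references <- list(
    PharmGKB = read_reference_tsv(file.path(dir, "pharmgkb.tsv"), "PharmGKB"),
    OMIM = read_reference_tsv(file.path(dir, "omim.tsv"), "OMIM"),
    CTD = read_reference_tsv(file.path(dir, "ctd.tsv"), "CTD")
  )
  gold <- read_gold_tsv(file.path(dir, "gold.tsv"))
  mined <- pgx_mine(records, lexica, config)
  ranked <- pgx_rank(mined$table, references, f_threshold)
  evaluation <- pgx_evaluate(mined$table, gold, granularity,
                             references = references)
  list(mined = mined, ranked = ranked, evaluation = evaluation)
}
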