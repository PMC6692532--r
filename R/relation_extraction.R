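# Abstract-level co-occurrence extraction of disease-drug-gene(-variant)
# relationships, corpus-wide aggregation, and binary projections.

empty_relation_keys <- function() {
  tibble(
    pmid = integer(),
    disease_id = character(),
    drug_id = character(),
    gene_symbol = character(),
    variant_id = character(),
    populations = list()
  )
}

#' Extract co-occurrence relationship keys from one abstract
#'
#' Emits the full cross-product of the distinct normalized diseases, drugs
#' and genes of the abstract (co-occurrence is scoped to the whole abstract,
#' not the sentence). Each (disease, drug, gene) tuple is duplicated once per
#' co-mentioned variant owned by that gene in the variant index; when the
#' gene owns no co-mentioned variant the variant-less tuple is emitted.
#' Variants whose owner gene is not mentioned produce no tuple. Abstracts
#' with no normalized disease use the reserved disease id `"UNSPECIFIED"`.
#' Ambiguous and failed normalizations never enter a tuple. All population
#' terms of the record are attached to every tuple.
#'
#' @param entities Normalized-entity tibble for a single pmid.
#' @param variant_index Variant `pgx_lexicon` (ownership via `parent_id`).
#' @return A tibble of per-record relationship keys.
#' @export
extract_relations <- function(entities, variant_index = NULL) {
  if (nrow(entities) == 0) return(empty_relation_keys())
  stopifnot(length(unique(entities$pmid)) == 1)
  ok <- entities$status %in% c("exact", "variant_match", "partial_match")
  ent <- entities[ok, ]
  ids_of <- function(cl) unique(ent$canonical_id[ent$entity_class == cl])

  drugs <- ids_of("drug")
  genes <- ids_of("gene")
  if (length(drugs) == 0 || length(genes) == 0) return(empty_relation_keys())
  diseases <- ids_of("disease")
  if (length(diseases) == 0) diseases <- UNSPECIFIED_DISEASE
  variants <- ids_of("variant")
  pops <- list(unique(ent$canonical_id[ent$entity_class == "population"]))

  owner_of <- function(v) {
    if (is.null(variant_index)) return(NA_character_)
    lexicon_entry(variant_index, v)$parent_id
  }
  rows <- list()
  for (g in genes) {
    owned <- variants[map_chr(variants, owner_of) %in% g]
    v_slots <- if (length(owned) > 0) owned else NA_character_
    for (d in diseases) for (dr in drugs) for (v in v_slots) {
      rows[[length(rows) + 1]] <- tibble(
        pmid = entities$pmid[1], disease_id = d, drug_id = dr,
        gene_symbol = g, variant_id = v, populations = pops
      )
    }
  }
  bind_rows(rows)
}

#' Aggregate per-record relationship keys over a corpus
#'
#' Groups identical (disease, drug, gene, variant) keys; the frequency `f` is
#' the number of distinct supporting PMIDs (a record contributes at most once
#' to a key). Output is deterministically sorted: `f` descending, then
#' lexicographic key.
#'
#' @param keys Row-bound per-record keys from [extract_relations()].
#' @return The relationship table: one row per key with `f`,
#'   `supporting_pmids` (list of sorted integer vectors) and `populations`
#'   (list; multiset union over supporting records).
#' @export
aggregate_relations <- function(keys) {
  if (nrow(keys) == 0) {
    return(tibble(disease_id = character(), drug_id = character(),
                  gene_symbol = character(), variant_id = character(),
                  f = integer(), supporting_pmids = list(),
                  populations = list()))
  }
  out <- keys |>
    group_by(disease_id, drug_id, gene_symbol, variant_id) |>
    summarise(
      f = dplyr::n_distinct(pmid),
      supporting_pmids = list(sort(unique(pmid))),
      populations = list(sort(unlist(populations))),
      .groups = "drop"
    )
  out[order(-out$f, out$disease_id, out$drug_id, out$gene_symbol,
            dplyr::coalesce(out$variant_id, ""), method = "radix"), ]
}

PAIR_KINDS <- c("disease_drug", "disease_gene", "drug_gene", "drug_variant",
                "gene_variant")

#' Project the quaternary table onto the five binary relations
#'
#' Returns disease-drug, disease-gene, drug-gene, drug-variant and
#' gene-variant tables. Pair support is the union of the supporting PMID
#' sets of all quaternary rows containing the pair (never the sum of their
#' frequencies); `f` is the size of that union. Variant-less rows contribute
#' only to the three variant-free pairs; rows with the reserved
#' `"UNSPECIFIED"` disease contribute only to the disease-free pairs.
#'
#' @param table Aggregated relationship table.
#' @return Named list of five tibbles (`id1`, `id2`, `f`,
#'   `supporting_pmids`), sorted like the quaternary table.
#' @export
binary_projections <- function(table) {
  project <- function(col1, col2) {
    rows <- table[!is.na(table[[col1]]) & !is.na(table[[col2]]) &
                    table[[col1]] != UNSPECIFIED_DISEASE, , drop = FALSE]
    if (nrow(rows) == 0) {
      return(tibble(id1 = character(), id2 = character(), f = integer(),
                    supporting_pmids = list()))
    }
    out <- rows |>
      mutate(id1 = .data[[col1]], id2 = .data[[col2]]) |>
      group_by(id1, id2) |>
      summarise(
        supporting_pmids = list(sort(unique(unlist(supporting_pmids)))),
        .groups = "drop"
      ) |>
      mutate(f = lengths(supporting_pmids)) |>
      select(id1, id2, f, supporting_pmids)
    out[order(-out$f, out$id1, out$id2, method = "radix"), ]
  }
  list(
    disease_drug = project("disease_id", "drug_id"),
    disease_gene = project("disease_id", "gene_symbol"),
    drug_gene = project("drug_id", "gene_symbol"),
    drug_variant = project("drug_id", "variant_id"),
    gene_variant = project("gene_symbol", "variant_id")
  )
}

#' Write / read the relationship table TSV
#'
#' Dialect: `disease_id  drug_id  gene  variant  f  pmids  populations`
#' with comma-joined pmid and population lists.
#'
#' @param table Aggregated relationship table.
#' @param path File path.
#' @return `path` invisibly (writer); the table (reader).
#' @export
write_relation_tsv <- function(table, path) {
  out <- tibble(
    disease_id = table$disease_id,
    drug_id = table$drug_id,
    gene = table$gene_symbol,
    variant = dplyr::coalesce(table$variant_id, ""),
    f = table$f,
    pmids = map_chr(table$supporting_pmids, paste, collapse = ","),
    populations = map_chr(table$populations, paste, collapse = ",")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_relation_tsv
#' @export
read_relation_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    disease_id = readr::col_character(), drug_id = readr::col_character(),
    gene = readr::col_character(), variant = readr::col_character(),
    f = readr::col_integer(), pmids = readr::col_character(),
    populations = readr::col_character()), progress = FALSE)
  tibble(
    disease_id = raw$disease_id,
    drug_id = raw$drug_id,
    gene_symbol = raw$gene,
    variant_id = ifelse(is.na(raw$variant) | raw$variant == "",
                        NA_character_, raw$variant),
    f = raw$f,
    supporting_pmids = map(raw$pmids, function(x) {
      if (is.na(x) || x == "") integer() else as.integer(strsplit(x, ",")[[1]])
    }),
    populations = map(raw$populations, function(x) {
      if (is.na(x) || x == "") character() else strsplit(x, ",")[[1]]
    })
  )
}
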