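# Resolution of recognized mentions to canonical identifiers with
# exact -> orthographic-variant -> partial fallbacks and explicit failure
# codes. Failures are data (curation-queue rows), never exceptions.

NORM_STATUSES <- c("exact", "variant_match", "partial_match", "ambiguous", "failed")
FAILURE_REASONS <- c("abbreviated", "unconventional", "unspecified", "nonhuman",
                     "family_level", "metabolite", "other")

# Default generic symptom/consequence terms excluded from disease
# normalization; user-configurable.
DEFAULT_SYMPTOM_TERMS <- c("pain", "nausea", "vomiting", "fever", "toxicity",
                           "headache", "fatigue", "rash", "inflammation")

# Default family-level gene terms that never normalize to a single symbol.
DEFAULT_GENE_FAMILY_TERMS <- c("major histocompatibility complex",
                               "human leukocyte antigen",
                               "cytochrome p450")

norm_row <- function(mention, status, canonical_id = NA_character_,
                     canonical_name = NA_character_,
                     failure_reason = NA_character_,
                     candidate_ids = character()) {
  tibble(
    pmid = mention$pmid,
    entity_class = mention$entity_class,
    surface = mention$surface,
    start = mention$start,
    end = mention$end,
    canonical_id = canonical_id,
    canonical_name = canonical_name,
    status = status,
    failure_reason = failure_reason,
    candidate_ids = list(candidate_ids)
  )
}

tokens_of <- function(x) {
  toks <- strsplit(normalize_surface(x), "[^a-z0-9]+")[[1]]
  toks[toks != ""]
}

# Shared exact -> synonym -> variant-expansion ladder used by gene and drug
# normalization. A hit on the canonical name is "exact"; a hit on a synonym
# or via orthographic-variant expansion is "variant_match".
match_ladder <- function(mention, lexicon) {
  surface_norm <- normalize_surface(mention$surface)
  ids <- lexicon_lookup(lexicon, surface_norm)
  status <- "variant_match"
  if (length(ids) == 0) {
    forms <- expand_variants(mention$surface, lexicon$entity_class)
    ids <- lexicon_lookup(lexicon, forms)
  }
  if (length(ids) == 1) {
    entry <- lexicon_entry(lexicon, ids)
    if (normalize_surface(entry$name) == surface_norm) status <- "exact"
  }
  list(ids = ids, status = status)
}

#' Normalize a gene mention to its canonical symbol
#'
#' Resolution ladder: exact hit on the symbol -> `exact`; hit on a synonym or
#' after orthographic-variant expansion -> `variant_match`; family-level
#' terms (configurable list) -> `failed(family_level)`; several candidate
#' symbols -> `ambiguous`; otherwise `failed` with a heuristic reason
#' (`unspecified` for molecule-class phrases like "src inhibitors",
#' `abbreviated` for short all-caps tokens, `unconventional` otherwise).
#'
#' @param mention Single-row mention tibble of class `gene`.
#' @param gene_lexicon The gene `pgx_lexicon`.
#' @param family_terms Family-level terms that must not resolve to one gene.
#' @return A single-row normalized-entity tibble.
#' @export
normalize_gene <- function(mention, gene_lexicon,
                           family_terms = DEFAULT_GENE_FAMILY_TERMS) {
  stopifnot(nrow(mention) == 1, mention$entity_class == "gene")
  surface_norm <- normalize_surface(mention$surface)
  if (surface_norm %in% normalize_surface(family_terms)) {
    return(norm_row(mention, "failed", failure_reason = "family_level"))
  }
  hit <- match_ladder(mention, gene_lexicon)
  if (length(hit$ids) == 1) {
    entry <- lexicon_entry(gene_lexicon, hit$ids)
    return(norm_row(mention, hit$status, hit$ids, entry$name))
  }
  if (length(hit$ids) > 1) {
    return(norm_row(mention, "ambiguous", candidate_ids = hit$ids))
  }
  reason <- classify_gene_failure(mention$surface)
  norm_row(mention, "failed", failure_reason = reason)
}

classify_gene_failure <- function(surface) {
  s <- normalize_surface(surface)
  molecule_words <- c("inhibitor", "inhibitors", "agonist", "agonists",
                      "antagonist", "antagonists", "blocker", "blockers",
                      "pathway", "family", "genes")
  if (any(tokens_of(s) %in% molecule_words)) return("unspecified")
  raw <- str_trim(surface)
  if (str_length(raw) <= 5 && raw == toupper(raw) && !str_detect(raw, " ")) {
    return("abbreviated")
  }
  "unconventional"
}

#' Normalize a disease mention to an ICD-style parent chapter
#'
#' Terms on the symptom exclusion list (token-subset test, so "severe nausea"
#' is caught by "nausea") fail with reason `unspecified`. An exact term hit
#' on an entry's name is reported at the entry's parent chapter with status
#' `exact` (synonym or orthographic hits are `variant_match`); when no term
#' hits, a partial match is attempted: a parent chapter matches when every
#' token of its head term appears among the mention's tokens. A mention
#' resolving to several chapters is `ambiguous` unless `chapter_priority`
#' gives a preference order.
#'
#' @param mention Single-row mention tibble of class `disease`.
#' @param disease_lexicon Disease `pgx_lexicon` (entries with a `parent_id`
#'   pointing at their chapter; chapter entries have no parent).
#' @param symptom_terms Exclusion list of symptom/consequence terms.
#' @param chapter_priority Optional character vector of chapter ids, highest
#'   priority first, used to break multi-chapter ties.
#' @return A single-row normalized-entity tibble whose `canonical_id` is a
#'   chapter id.
#' @export
normalize_disease <- function(mention, disease_lexicon,
                              symptom_terms = DEFAULT_SYMPTOM_TERMS,
                              chapter_priority = NULL) {
  stopifnot(nrow(mention) == 1, mention$entity_class == "disease")
  m_tokens <- tokens_of(mention$surface)
  for (s in symptom_terms) {
    if (all(tokens_of(s) %in% m_tokens)) {
      return(norm_row(mention, "failed", failure_reason = "unspecified"))
    }
  }
  hit <- match_ladder(mention, disease_lexicon)
  to_chapter <- function(id) {
    entry <- lexicon_entry(disease_lexicon, id)
    if (is.na(entry$parent_id) || entry$parent_id == "") id else entry$parent_id
  }
  if (length(hit$ids) >= 1) {
    chapters <- unique(map_chr(hit$ids, to_chapter))
    status <- hit$status
    return(resolve_chapters(mention, disease_lexicon, chapters, status,
                            chapter_priority))
  }
  # partial match against parent chapter head terms
  chapters <- disease_lexicon$entries$id[
    is.na(disease_lexicon$entries$parent_id) |
      disease_lexicon$entries$parent_id == ""]
  hits <- chapters[map_lgl(chapters, function(ch) {
    head_tokens <- tokens_of(lexicon_entry(disease_lexicon, ch)$name)
    length(head_tokens) > 0 && all(head_tokens %in% m_tokens)
  })]
  if (length(hits) >= 1) {
    return(resolve_chapters(mention, disease_lexicon, hits, "partial_match",
                            chapter_priority))
  }
  norm_row(mention, "failed", failure_reason = "unconventional")
}

resolve_chapters <- function(mention, lexicon, chapters, status,
                             chapter_priority) {
  if (length(chapters) > 1 && !is.null(chapter_priority)) {
    ordered <- chapters[order(match(chapters, chapter_priority))]
    chapters <- ordered[1]
  }
  if (length(chapters) > 1) {
    return(norm_row(mention, "ambiguous", candidate_ids = chapters))
  }
  norm_row(mention, status, chapters,
           lexicon_entry(lexicon, chapters)$name)
}

#' Normalize a drug mention to a DrugBank-style identifier
#'
#' Hits on the canonical name are `exact`; brand/synonym or
#' orthographic-variant hits are `variant_match`. Entries flagged
#' `metabolite` in the lexicon fail with reason `metabolite` (their
#' `parent_id` names the parent drug but, mirroring the curation rule, the
#' mention is excluded rather than remapped).
#'
#' @param mention Single-row mention tibble of class `drug`.
#' @param drug_lexicon Drug `pgx_lexicon`.
#' @return A single-row normalized-entity tibble.
#' @export
normalize_drug <- function(mention, drug_lexicon) {
  stopifnot(nrow(mention) == 1, mention$entity_class == "drug")
  hit <- match_ladder(mention, drug_lexicon)
  if (length(hit$ids) >= 1) {
    flags <- map_chr(hit$ids, function(id) lexicon_entry(drug_lexicon, id)$flags)
    metab <- str_detect(flags, "metabolite")
    if (all(metab)) {
      return(norm_row(mention, "failed", failure_reason = "metabolite"))
    }
    ids <- hit$ids[!metab]
    if (length(ids) == 1) {
      entry <- lexicon_entry(drug_lexicon, ids)
      status <- if (normalize_surface(entry$name) ==
                    normalize_surface(mention$surface)) "exact" else hit$status
      return(norm_row(mention, status, ids, entry$name))
    }
    return(norm_row(mention, "ambiguous", candidate_ids = ids))
  }
  norm_row(mention, "failed", failure_reason = "other")
}

#' Normalize a variant mention to a dbSNP rsID
#'
#' rs mentions resolve exactly when the rsID is in the variant index and fail
#' with reason `unconventional` otherwise. HGVS mentions are resolved by a
#' gene-scoped lookup: the notation is searched among the index entries owned
#' by `nearby_genes` (the gene symbols normalized in the same abstract);
#' success is a `variant_match`.
#'
#' @param mention Single-row mention tibble of class `variant`.
#' @param variant_index Variant `pgx_lexicon` (ids are rsIDs, `parent_id`
#'   the owner gene symbol, synonyms the HGVS notations).
#' @param nearby_genes Character vector of gene symbols in the same abstract.
#' @return A single-row normalized-entity tibble.
#' @export
normalize_variant <- function(mention, variant_index, nearby_genes = character()) {
  stopifnot(nrow(mention) == 1, mention$entity_class == "variant")
  surface_norm <- normalize_surface(mention$surface)
  if (str_detect(surface_norm, "^rs[0-9]+$")) {
    if (surface_norm %in% variant_index$entries$id) {
      return(norm_row(mention, "exact", surface_norm, surface_norm))
    }
    return(norm_row(mention, "failed", failure_reason = "unconventional"))
  }
  # gene-scoped HGVS lookup
  scoped <- variant_index$entries[
    variant_index$entries$parent_id %in% nearby_genes, , drop = FALSE]
  owns <- map_lgl(scoped$synonyms, function(syn) {
    surface_norm %in% normalize_surface(syn)
  })
  if (any(owns)) {
    id <- scoped$id[which(owns)[1]]
    return(norm_row(mention, "variant_match", id, id))
  }
  norm_row(mention, "failed", failure_reason = "other")
}

#' Normalize every mention of a record set
#'
#' Dispatches each mention to its class-specific normalizer. Population
#' mentions resolve by direct lookup. The result is independent of mention
#' order.
#'
#' @param mentions Mention tibble (any mix of records and classes).
#' @param lexica Named list with elements `gene`, `disease`, `drug`,
#'   `variant` and optionally `population` (`pgx_lexicon` objects).
#' @param config Optional list with `symptom_terms`, `family_terms`,
#'   `chapter_priority`.
#' @return A normalized-entity tibble, one row per mention.
#' @export
normalize_mentions <- function(mentions, lexica, config = list()) {
  if (nrow(mentions) == 0) {
    return(norm_row(empty_mentions(), character())[0, ])
  }
  symptom_terms <- config$symptom_terms %||% DEFAULT_SYMPTOM_TERMS
  family_terms <- config$family_terms %||% DEFAULT_GENE_FAMILY_TERMS
  chapter_priority <- config$chapter_priority

  # gene symbols per pmid, needed for gene-scoped HGVS resolution
  gene_rows <- mentions[mentions$entity_class == "gene", , drop = FALSE]
  genes_by_pmid <- list()
  if (nrow(gene_rows) > 0 && !is.null(lexica$gene)) {
    for (k in seq_len(nrow(gene_rows))) {
      g <- normalize_gene(gene_rows[k, ], lexica$gene, family_terms)
      if (g$status %in% c("exact", "variant_match")) {
        key <- as.character(g$pmid)
        genes_by_pmid[[key]] <- unique(c(genes_by_pmid[[key]], g$canonical_id))
      }
    }
  }

  rows <- vector("list", nrow(mentions))
  for (k in seq_len(nrow(mentions))) {
    m <- mentions[k, ]
    rows[[k]] <- switch(
      m$entity_class,
      gene = normalize_gene(m, lexica$gene, family_terms),
      disease = normalize_disease(m, lexica$disease, symptom_terms,
                                  chapter_priority),
      drug = normalize_drug(m, lexica$drug),
      variant = normalize_variant(m, lexica$variant,
                                  genes_by_pmid[[as.character(m$pmid)]] %||%
                                    character()),
      population = {
        ids <- lexicon_lookup(lexica$population, normalize_surface(m$surface))
        if (length(ids) == 1) norm_row(m, "exact", ids, ids)
        else if (length(ids) > 1) norm_row(m, "ambiguous", candidate_ids = ids)
        else norm_row(m, "failed", failure_reason = "other")
      },
      abort_invalid(sprintf("Unknown entity class '%s'.", m$entity_class))
    )
  }
  out <- bind_rows(rows)
  out[order(out$pmid, out$entity_class, out$start, method = "radix"), ]
}

#' Per-class normalization bookkeeping
#'
#' Counts attempted, resolved (`exact`/`variant_match`/`partial_match`),
#' ambiguous and failed mentions per entity class, failure counts by reason,
#' and the same tallies over unique surface forms (both views are reported
#' because mapping rates over mentions and over unique names differ).
#'
#' @param entities Normalized-entity tibble.
#' @return A list with `by_class` (tibble), `by_reason` (tibble) and
#'   `unique_names` (tibble).
#' @export
normalization_summary <- function(entities) {
  resolved_statuses <- c("exact", "variant_match", "partial_match")
  if (nrow(entities) == 0) {
    return(list(
      by_class = tibble(entity_class = character(), attempted = integer(),
                        resolved = integer(), ambiguous = integer(),
                        failed = integer(), resolved_fraction = double(),
                        failed_fraction = double()),
      by_reason = tibble(entity_class = character(),
                         failure_reason = character(), n = integer()),
      unique_names = tibble(entity_class = character(), attempted = integer(),
                            resolved = integer(), failed = integer())
    ))
  }
  by_class <- entities |>
    dplyr::mutate(norm_surface = normalize_surface(surface)) |>
    group_by(entity_class) |>
    summarise(
      attempted = n(),
      resolved = sum(status %in% resolved_statuses),
      ambiguous = sum(status == "ambiguous"),
      failed = sum(status == "failed"),
      .groups = "drop"
    ) |>
    mutate(resolved_fraction = resolved / attempted,
           failed_fraction = failed / attempted)
  by_reason <- entities |>
    filter(status == "failed") |>
    group_by(entity_class, failure_reason) |>
    summarise(n = n(), .groups = "drop")
  unique_names <- entities |>
    mutate(norm_surface = normalize_surface(surface)) |>
    distinct(entity_class, norm_surface, status) |>
    group_by(entity_class) |>
    summarise(
      attempted = dplyr::n_distinct(norm_surface),
      resolved = dplyr::n_distinct(norm_surface[status %in% resolved_statuses]),
      failed = dplyr::n_distinct(norm_surface[status == "failed"]),
      .groups = "drop"
    )
  list(by_class = by_class, by_reason = by_reason, unique_names = unique_names)
}

#' Export the manual-curation queue
#'
#' Writes the ambiguous and failed normalizations (the rows a curator must
#' review) as a TSV with one row per mention resolution.
#'
#' @param entities Normalized-entity tibble.
#' @param path Output path.
#' @return The queue tibble, invisibly.
#' @export
write_curation_queue <- function(entities, path) {
  queue <- entities |>
    filter(status %in% c("ambiguous", "failed")) |>
    mutate(candidate_ids = map_chr(candidate_ids, paste, collapse = ",")) |>
    select(pmid, entity_class, surface, start, end, status, failure_reason,
           candidate_ids)
  readr::write_tsv(queue, path, progress = FALSE)
  invisible(queue)
}
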