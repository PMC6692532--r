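# Cross-database support scoring, rank assignment with the f > 10 rule for
# pipeline-only relationships, and novel-relationship flagging.

REFERENCE_GRANULARITY <- list(
  PharmGKB = c("drug_gene", "drug_variant"),
  OMIM = "disease_gene",
  CTD = c("drug_gene", "disease_drug", "disease_gene")
)

#' Construct a reference dataset
#'
#' @param name `"PharmGKB"`, `"OMIM"` or `"CTD"` (fixes the granularity:
#'   PharmGKB asserts drug-gene and drug-variant pairs, OMIM disease-gene,
#'   CTD drug-gene, disease-drug and disease-gene).
#' @param assertions Tibble with columns `kind`, `id1`, `id2` where `kind`
#'   is one of the dataset's pair kinds and (`id1`, `id2`) follow the kind's
#'   name order (e.g. `drug_gene`: `id1` = drug, `id2` = gene).
#' @return An object of class `pgx_reference`.
#' @export
new_reference <- function(name, assertions) {
  name <- match.arg(name, names(REFERENCE_GRANULARITY))
  granularity <- REFERENCE_GRANULARITY[[name]]
  bad <- setdiff(unique(assertions$kind), granularity)
  if (length(bad) > 0) {
    abort_format(sprintf("%s cannot assert pair kind '%s'.", name, bad[1]))
  }
  keys <- new.env(parent = emptyenv(), hash = TRUE)
  for (k in seq_len(nrow(assertions))) {
    assign(paste(assertions$kind[k], assertions$id1[k], assertions$id2[k],
                 sep = "\t"), TRUE, envir = keys)
  }
  structure(list(name = name, granularity = granularity,
                 assertions = assertions, keys = keys),
            class = "pgx_reference")
}

#' Read a reference dataset TSV (`kind  id1  id2`)
#'
#' @param path Path to the TSV.
#' @param name Dataset name (see [new_reference()]).
#' @return A `pgx_reference`.
#' @export
read_reference_tsv <- function(path, name) {
  if (!file.exists(path)) {
    abort_io(sprintf("Reference dataset file does not exist: %s", path))
  }
  raw <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  missing_cols <- setdiff(c("kind", "id1", "id2"), names(raw))
  if (length(missing_cols) > 0) {
    abort_format(sprintf("Reference TSV %s is missing column(s): %s", path,
                         paste(missing_cols, collapse = ", ")))
  }
  new_reference(name, raw)
}

reference_asserts <- function(ref, kind, id1, id2) {
  isTRUE(get0(paste(kind, id1, id2, sep = "\t"), envir = ref$keys,
              ifnotfound = FALSE))
}

# Sub-tuples of a relationship row that `ref` is able to assert.
projectable_subtuples <- function(rel, ref) {
  has_disease <- !is.na(rel$disease_id) && rel$disease_id != UNSPECIFIED_DISEASE
  has_variant <- !is.na(rel$variant_id)
  pairs <- list(
    drug_gene = c(rel$drug_id, rel$gene_symbol),
    drug_variant = if (has_variant) c(rel$drug_id, rel$variant_id),
    disease_gene = if (has_disease) c(rel$disease_id, rel$gene_symbol),
    disease_drug = if (has_disease) c(rel$disease_id, rel$drug_id)
  )
  pairs <- pairs[!vapply(pairs, is.null, logical(1))]
  pairs[names(pairs) %in% ref$granularity]
}

#' Support of one relationship across the reference datasets
#'
#' A dataset supports a relationship when it asserts, at its own
#' granularity, every projectable sub-tuple of the relationship (PharmGKB
#' must assert the drug-gene pair, and the drug-variant pair when the
#' relationship carries a variant; OMIM the disease-gene pair; CTD every
#' pair it curates). A dataset able to assert no sub-tuple (e.g. OMIM for a
#' disease-less relationship) contributes no support.
#'
#' @param rel Single-row relationship table.
#' @param datasets List of `pgx_reference` objects.
#' @return Integer support count `s` between 0 and `length(datasets)`.
#' @export
reference_support <- function(rel, datasets) {
  stopifnot(nrow(rel) == 1)
  s <- 0L
  for (ref in datasets) {
    subs <- projectable_subtuples(rel, ref)
    if (length(subs) == 0) next
    ok <- all(vapply(names(subs), function(kind) {
      reference_asserts(ref, kind, subs[[kind]][1], subs[[kind]][2])
    }, logical(1)))
    if (ok) s <- s + 1L
  }
  s
}

#' Rank relationships by cross-database support and frequency
#'
#' Relationships supported by at least one reference dataset are ordered by
#' (`s` descending, `f` descending, lexicographic key). Unsupported
#' relationships (`s = 0`) with `f > f_threshold` are appended after all
#' supported rows, ordered by (`f` descending, key); unsupported
#' relationships at or below the threshold are dropped (frequencies of 10 or
#' fewer co-occurrences are treated as potentially random) and counted in
#' the `dropped` attribute. Ranks are the permutation `1..N` of the retained
#' rows; the total order makes the result stable under input shuffling.
#'
#' @param table Aggregated relationship table.
#' @param datasets List of `pgx_reference` objects.
#' @param f_threshold Strict frequency threshold for unsupported rows
#'   (default 10: `f = 10` is dropped, `f = 11` kept).
#' @return The ranked table with columns `s` and `rank` added and attribute
#'   `dropped` (count of discarded unsupported rows).
#' @export
rank_relationships <- function(table, datasets, f_threshold = 10) {
  if (f_threshold < 0) abort_invalid("`f_threshold` must be >= 0.")
  if (nrow(table) == 0) {
    out <- table
    out$s <- integer()
    out$rank <- integer()
    attr(out, "dropped") <- 0L
    return(out)
  }
  table$s <- vapply(seq_len(nrow(table)), function(k) {
    reference_support(table[k, ], datasets)
  }, integer(1))

  key <- paste(table$disease_id, table$drug_id, table$gene_symbol,
               dplyr::coalesce(table$variant_id, ""), sep = "\t")
  supported <- table[table$s >= 1, , drop = FALSE]
  key_s <- key[table$s >= 1]
  supported <- supported[order(-supported$s, -supported$f, key_s,
                              method = "radix"), ]

  unsupported <- table[table$s == 0, , drop = FALSE]
  key_u <- key[table$s == 0]
  keep_u <- unsupported$f > f_threshold
  dropped <- sum(!keep_u)
  appended <- unsupported[keep_u, , drop = FALSE]
  appended <- appended[order(-appended$f, key_u[keep_u], method = "radix"), ]

  out <- bind_rows(supported, appended)
  out$rank <- seq_len(nrow(out))
  attr(out, "dropped") <- as.integer(dropped)
  out
}

#' Flag relationships absent from PharmGKB as novel
#'
#' A relationship is novel when PharmGKB asserts none of its projectable
#' sub-tuples (neither the drug-gene pair nor, when present, the
#' drug-variant pair): these are the candidate additions to the curated
#' knowledge base.
#'
#' @param ranked Ranked relationship table.
#' @param pharmgkb The PharmGKB-style `pgx_reference`.
#' @return `ranked` with a logical `novel` column; the novel count is in
#'   attribute `novel_count`.
#' @export
flag_novel <- function(ranked, pharmgkb) {
  if (nrow(ranked) == 0) {
    ranked$novel <- logical()
    attr(ranked, "novel_count") <- 0L
    return(ranked)
  }
  ranked$novel <- vapply(seq_len(nrow(ranked)), function(k) {
    subs <- projectable_subtuples(ranked[k, ], pharmgkb)
    if (length(subs) == 0) return(TRUE)
    !any(vapply(names(subs), function(kind) {
      reference_asserts(pharmgkb, kind, subs[[kind]][1], subs[[kind]][2])
    }, logical(1)))
  }, logical(1))
  attr(ranked, "novel_count") <- as.integer(sum(ranked$novel))
  ranked
}

#' Write a ranked relationship table with its JSON sidecar
#'
#' The TSV adds `s`, `rank` and `novel` columns to the relationship dialect;
#' the sidecar (same path + `.json`) records the dropped and novel counts.
#'
#' @param ranked Ranked (and optionally novel-flagged) table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ranked_tsv <- function(ranked, path) {
  out <- tibble(
    rank = ranked$rank,
    s = ranked$s,
    novel = if ("novel" %in% names(ranked)) ranked$novel else NA,
    disease_id = ranked$disease_id,
    drug_id = ranked$drug_id,
    gene = ranked$gene_symbol,
    variant = dplyr::coalesce(ranked$variant_id, ""),
    f = ranked$f,
    pmids = map_chr(ranked$supporting_pmids, paste, collapse = ",")
  )
  readr::write_tsv(out, path, progress = FALSE)
  sidecar <- list(
    dropped = attr(ranked, "dropped") %||% 0L,
    novel_count = attr(ranked, "novel_count") %||% NA,
    n_ranked = nrow(ranked)
  )
  readr::write_lines(
    jsonlite::toJSON(sidecar, auto_unbox = TRUE, pretty = TRUE),
    paste0(path, ".json"))
  invisible(path)
}
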