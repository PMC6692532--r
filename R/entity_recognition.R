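# Dictionary/longest-match recognition of disease, drug, gene and population
# mentions, plus pattern-based recognition of genetic variants, over the
# annotated text (title + " " + abstract) of each record.

# Token spans: alphanumeric runs, with hyphens and dots retained when they sit
# between alphanumerics ("il-2", "c.76a" stay single tokens). Returns 0-based
# half-open offsets.
tokenize_spans <- function(text) {
  m <- gregexpr("[A-Za-z0-9](?:[A-Za-z0-9]|[-.](?=[A-Za-z0-9]))*", text,
                perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble(start = integer(), end = integer()))
  }
  tibble(start = as.integer(m) - 1L,
         end = as.integer(m) - 1L + attr(m, "match.length"))
}

# Resolve same-class overlaps longest-then-leftmost: candidates are sorted by
# decreasing length then increasing start and accepted greedily when they do
# not overlap an already-accepted mention of the same class.
resolve_overlaps <- function(cands) {
  if (nrow(cands) == 0) return(cands)
  cands <- cands[order(-(cands$end - cands$start), cands$start), ]
  keep <- logical(nrow(cands))
  for (cl in unique(cands$entity_class)) {
    idx <- which(cands$entity_class == cl)
    taken_start <- integer()
    taken_end <- integer()
    for (i in idx) {
      s <- cands$start[i]; e <- cands$end[i]
      if (!any(s < taken_end & e > taken_start)) {
        keep[i] <- TRUE
        taken_start <- c(taken_start, s)
        taken_end <- c(taken_end, e)
      }
    }
  }
  out <- cands[keep, ]
  out[order(out$start, out$entity_class, method = "radix"), ]
}

#' Dictionary-based mention recognition
#'
#' Scans the token windows of the record's annotated text and emits a mention
#' wherever some orthographic variant ([expand_variants()]) of the window hits
#' the lexicon's surface index. All candidate ids of the matched surface are
#' kept (ambiguity is resolved downstream). Same-class overlaps are resolved
#' longest-then-leftmost, so the output does not depend on lexicon entry
#' order.
#'
#' @param record A single-row abstract-record tibble.
#' @param lexicon A `pgx_lexicon` for one entity class.
#' @param max_window Maximum window size in tokens; defaults to the longest
#'   surface form in the lexicon.
#' @return A mention tibble with `source = "dictionary"`.
#' @export
recognize_dictionary <- function(record, lexicon, max_window = NULL) {
  stopifnot(nrow(record) == 1)
  if (nrow(lexicon$entries) == 0) return(empty_mentions())
  text <- annotated_text(record$title, record$abstract)
  spans <- tokenize_spans(text)
  n_tok <- nrow(spans)
  if (n_tok == 0) return(empty_mentions())
  max_window <- max_window %||% max(lexicon$max_tokens, 1L)

  # window -> ids memo persists across records of a corpus run
  cache <- lexicon$window_cache %||% new.env(parent = emptyenv(), hash = TRUE)
  skip_special <- isTRUE(lexicon$plain_surfaces)
  lookup_window <- function(surface) {
    hit <- get0(surface, envir = cache, ifnotfound = NULL)
    if (!is.null(hit)) return(hit)
    if (skip_special && grepl(WINDOW_SPECIAL_RE, tolower(surface), perl = TRUE)) {
      ids <- character()
    } else {
      forms <- expand_variants(surface, lexicon$entity_class)
      ids <- lexicon_lookup(lexicon, forms)
    }
    assign(surface, list(ids), envir = cache)
    list(ids)
  }

  starts <- integer(); ends <- integer(); ids_list <- list()
  for (i in seq_len(n_tok)) {
    for (j in seq(min(i + max_window - 1L, n_tok), i)) {
      surface <- substr(text, spans$start[i] + 1L, spans$end[j])
      ids <- lookup_window(surface)[[1]]
      if (length(ids) > 0) {
        starts <- c(starts, spans$start[i])
        ends <- c(ends, spans$end[j])
        ids_list <- c(ids_list, list(ids))
      }
    }
  }
  if (length(starts) == 0) return(empty_mentions())
  cands <- tibble(
    pmid = record$pmid,
    entity_class = lexicon$entity_class,
    surface = substr(rep(text, length(starts)), starts + 1L, ends),
    start = starts,
    end = ends,
    candidate_ids = ids_list,
    source = "dictionary"
  )
  resolve_overlaps(cands)
}

# Variant patterns recognized in free text. rsIDs must be word-bounded on
# both sides ("Mrs2", "rsq1" are not variants); the simple HGVS forms cover
# nucleotide substitutions (c.76A>T, g.1234G>C, m.###) and protein
# substitutions in three-letter code (p.Val600Glu) or one-letter (p.V600E).
RS_PATTERN <- "(?<![A-Za-z0-9])rs[0-9]+(?![A-Za-z0-9])"
HGVS_PATTERNS <- c(
  nucleotide = "(?<![A-Za-z0-9])[cgmn]\\.[-*+0-9_]+[ACGTacgt]>[ACGTacgt](?![A-Za-z0-9])",
  protein3 = "(?<![A-Za-z0-9])p\\.[A-Z][a-z]{2}[0-9]+[A-Z][a-z]{2}(?![A-Za-z0-9])",
  protein1 = "(?<![A-Za-z0-9])p\\.[A-Z][0-9]+[A-Z](?![A-Za-z0-9])"
)
STAR_ALLELE_PATTERN <- "(?<![A-Za-z0-9])[A-Z][A-Z0-9]{1,9}\\*[0-9]+[A-Z]?(?![A-Za-z0-9])"

#' Pattern-based recognition of genetic-variant mentions
#'
#' Recognizes dbSNP rs identifiers (word-bounded `rs` + digits; their rsID is
#' the candidate id) and simple substitution-style HGVS mentions (candidate
#' ids left empty; they are resolved later against the variant index scoped
#' to genes mentioned in the same abstract). Copy-number and other complex
#' notations are deliberately not recognized. Star-allele mentions
#' (`CYP2D6*2`) are recognized only when `star_alleles = TRUE` and are never
#' normalized to rsIDs.
#'
#' @param record A single-row abstract-record tibble.
#' @param star_alleles Recognize star-allele mentions as variants?
#' @return A mention tibble with `source = "pattern"`.
#' @export
recognize_variants <- function(record, star_alleles = FALSE) {
  stopifnot(nrow(record) == 1)
  text <- annotated_text(record$title, record$abstract)
  pats <- c(rs = RS_PATTERN, HGVS_PATTERNS)
  if (star_alleles) pats <- c(pats, star = STAR_ALLELE_PATTERN)

  rows <- list()
  for (pname in names(pats)) {
    m <- gregexpr(pats[[pname]], text, perl = TRUE)[[1]]
    if (m[1] == -1) next
    starts <- as.integer(m) - 1L
    lens <- attr(m, "match.length")
    for (k in seq_along(starts)) {
      surface <- substr(text, starts[k] + 1L, starts[k] + lens[k])
      rows[[length(rows) + 1]] <- tibble(
        pmid = record$pmid,
        entity_class = "variant",
        surface = surface,
        start = starts[k],
        end = starts[k] + lens[k],
        candidate_ids = list(if (pname == "rs") tolower(surface) else character()),
        source = "pattern"
      )
    }
  }
  if (length(rows) == 0) return(empty_mentions())
  resolve_overlaps(bind_rows(rows))
}

#' Recognize all entity classes in one record
#'
#' @param record A single-row abstract-record tibble.
#' @param lexica Named list of `pgx_lexicon` objects (names among
#'   `disease`, `drug`, `gene`, `population`).
#' @param star_alleles Passed to [recognize_variants()].
#' @return A mention tibble sorted by class and offset.
#' @export
recognize_record <- function(record, lexica, star_alleles = FALSE) {
  parts <- lapply(lexica, function(lx) recognize_dictionary(record, lx))
  parts <- c(parts, list(recognize_variants(record, star_alleles = star_alleles)))
  out <- bind_rows(parts)
  out[order(out$entity_class, out$start, method = "radix"), ]
}

#' Pharmacogenomic entity-presence filter
#'
#' A record stays in the PGx subcorpus iff it has at least one drug mention
#' and at least one gene or genetic-variant mention. Monotone: adding
#' mentions can never flip `TRUE` to `FALSE`.
#'
#' @param mentions Mention tibble for one record.
#' @return Logical scalar.
#' @export
entity_presence_filter <- function(mentions) {
  any(mentions$entity_class == "drug") &&
    (any(mentions$entity_class == "gene") ||
       any(mentions$entity_class == "variant"))
}
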