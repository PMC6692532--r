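# Independent oracles and shared fixture helpers. The oracles deliberately
# avoid the package's scanning code paths: they enumerate every candidate
# exhaustively and test membership against the raw lexicon surface list.

make_record <- function(pmid, title, abstract, pub_types = "Journal Article",
                        is_human = TRUE, year = 2018L) {
  tibble::tibble(pmid = as.integer(pmid), title = title, abstract = abstract,
                 pub_types = pub_types, is_human = is_human,
                 year = as.integer(year))
}

make_lexicon <- function(entity_class, ids, names, synonyms = NULL,
                         parent_ids = NULL, flags = NULL) {
  n <- length(ids)
  entries <- tibble::tibble(
    id = ids, name = names,
    synonyms = if (is.null(synonyms)) rep(list(character()), n) else synonyms,
    parent_id = if (is.null(parent_ids)) rep(NA_character_, n) else parent_ids,
    flags = if (is.null(flags)) rep("", n) else flags
  )
  new_lexicon(entries, entity_class)
}

make_mention <- function(pmid, entity_class, surface, start = 0L,
                         end = start + nchar(surface)) {
  tibble::tibble(pmid = as.integer(pmid), entity_class = entity_class,
                 surface = surface, start = as.integer(start),
                 end = as.integer(end), candidate_ids = list(character()),
                 source = "dictionary")
}

# Character-walk tokenizer, written independently of the package's
# regex-based one: maximal alphanumeric runs with -/. retained between
# alphanumerics. Returns 0-based half-open spans.
oracle_token_spans <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  alnum <- grepl("[A-Za-z0-9]", chars)
  starts <- integer(); ends <- integer()
  i <- 1L
  while (i <= n) {
    if (alnum[i]) {
      j <- i
      repeat {
        if (j < n && alnum[j + 1L]) {
          j <- j + 1L
        } else if (j + 2L <= n && chars[j + 1L] %in% c("-", ".") &&
                   alnum[j + 2L]) {
          j <- j + 2L
        } else break
      }
      starts <- c(starts, i - 1L)
      ends <- c(ends, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, end = ends)
}

# Brute-force dictionary recognition: every token window of every length is
# tested against the full list of lexicon surface forms via orthographic
# expansion, then the longest-then-leftmost overlap rule is applied by a
# separate greedy pass.
oracle_recognize <- function(record, lexicon, max_window = 8L) {
  text <- annotated_text(record$title, record$abstract)
  spans <- oracle_token_spans(text)
  all_surfaces <- ls(lexicon$surface_index, all.names = TRUE)
  cands <- list()
  n_tok <- nrow(spans)
  for (i in seq_len(n_tok)) {
    for (j in i:min(n_tok, i + max_window - 1L)) {
      window <- substr(text, spans$start[i] + 1L, spans$end[j])
      forms <- expand_variants(window, lexicon$entity_class)
      hits <- all_surfaces[all_surfaces %in% forms]
      if (length(hits) > 0) {
        ids <- sort(unique(unlist(lapply(hits, function(s) {
          lexicon_lookup(lexicon, s)
        }))))
        cands[[length(cands) + 1]] <- data.frame(
          start = spans$start[i], end = spans$end[j],
          surface = window, ids = paste(ids, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cands) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      surface = character(), ids = character()))
  }
  cands <- do.call(rbind, cands)
  cands <- cands[order(-(cands$end - cands$start), cands$start), ]
  taken_start <- integer(); taken_end <- integer(); keep <- logical(nrow(cands))
  for (k in seq_len(nrow(cands))) {
    s <- cands$start[k]; e <- cands$end[k]
    if (!any(s < taken_end & e > taken_start)) {
      keep[k] <- TRUE
      taken_start <- c(taken_start, s); taken_end <- c(taken_end, e)
    }
  }
  out <- cands[keep, ]
  out[order(out$start), ]
}

# Character-walk rsID finder (no regex): word-bounded "rs" + digits.
oracle_rsids <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  alnum <- grepl("[A-Za-z0-9]", chars)
  found <- character()
  for (i in seq_len(n)) {
    if (i > 1 && alnum[i - 1L]) next
    if (chars[i] != "r" || i + 2L > n || chars[i + 1L] != "s") next
    j <- i + 2L
    if (!grepl("[0-9]", chars[j])) next
    while (j < n && grepl("[0-9]", chars[j + 1L])) j <- j + 1L
    if (j < n && alnum[j + 1L]) next
    found <- c(found, paste(chars[i:j], collapse = ""))
  }
  found
}

# A small planted plan for tests that shrink the corpus below what the
# default ten-relationship plan needs.
small_plan <- function(n = 3L, f = c(3L, 2L, 1L)) {
  tibble::tibble(
    disease_id = sprintf("CH%02d", seq_len(n)),
    drug_id = sprintf("DB%05d", seq_len(n)),
    gene_symbol = sprintf("GX%d", seq_len(n)),
    variant_id = c(sprintf("rs%d", 100000L + 7L),
                   rep(NA_character_, n - 1L)),
    f = f[seq_len(n)],
    support = rep(c(3L, 0L), length.out = n),
    in_gold = rep(c(TRUE, FALSE), length.out = n)
  )
}

# One shared default fixtures bundle per test run (generation is seeded, so
# every use sees identical data).
shared_bundle <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      dir <- file.path(tempdir(), "pgxminer-shared-bundle")
      memo <<- pgx_simulate(fixture_spec(seed = 42), dir)
      memo$dir <<- dir
    }
    memo
  }
})

shared_bundle_run <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      b <- shared_bundle()
      memo <<- pgx_run_bundle(b$dir)
    }
    memo
  }
})
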