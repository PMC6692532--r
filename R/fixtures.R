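# Deterministic generator of toy lexica, reference datasets, gold standards
# and a MEDLINE-style corpus with planted entities, relationships,
# frequencies and filter-trap records, so every pipeline stage is testable
# offline with exact ground truth.

# Run code under a seed, restoring the caller's RNG state afterwards, so the
# generators are pure functions of (spec, seed).
with_fixture_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

GREEK_WORDS <- c("alpha", "beta", "gamma", "delta", "kappa")
DISEASE_STEMS <- c("cardi", "neur", "derm", "hepat", "nephr", "pulmon",
                   "arthr", "gastr")
DRUG_STEMS <- c("velpa", "zorvi", "maci", "telbi", "ruxo", "dapro")
DRUG_SUFFIXES <- c("nib", "mab", "stat", "vir")
BRAND_STEMS <- c("Zentra", "Corvex", "Alderon", "Novexa", "Tryphos", "Quilar")
POPULATION_TERMS <- c("Caucasian", "Japanese", "Han Chinese", "African American",
                      "Korean", "Indian", "Hispanic", "Finnish")
# Reserved decoy tokens, guaranteed absent from every lexicon, so
# false-positive accounting on fixtures is exact.
DECOY_TOKENS <- c("zorblatt", "quintrixole", "flubberon", "wexalide",
                  "smargline", "bretavox")

#' Specification of a synthetic fixtures bundle
#'
#' Defaults define the standard study conditions of the package's test
#' corpus: 200 abstracts, ten planted relationships with frequencies
#' spanning the ranking threshold (one unsupported relationship at f = 11,
#' one at the f = 10 boundary), trap records for each cascade stage, two
#' synonyms per lexicon entry and no decoy noise.
#'
#' @param seed Integer seed; all generators are pure functions of the spec
#'   including this seed.
#' @param n_abstracts Corpus size.
#' @param n_genes,n_diseases,n_drugs,n_variants Lexicon sizes.
#' @param planted_relationships Tibble (`disease_id`, `drug_id`,
#'   `gene_symbol`, `variant_id`, `f`, `support`, `in_gold`) or `NULL` for
#'   the default plan. `support` in 0..3 chooses which reference datasets
#'   assert the relationship (3 = all, 2 = PharmGKB+OMIM, 1 = CTD only).
#' @param trap_reviews,trap_nonhuman,trap_no_abstract,trap_no_drug Counts of
#'   planted filter-trap records.
#' @param n_gold_only Gold-standard rows not planted in the corpus
#'   (exercises false negatives).
#' @param synonym_depth Synonyms per lexicon entry (0, 1 or 2): depth 1 adds
#'   a hyphen variant, depth 2 also a Greek-letter variant.
#' @param noise_mention_rate Expected decoy tokens per abstract (decoys come
#'   from a reserved non-lexicon pool).
#' @return A list of class `pgx_fixture_spec`.
#' @export
fixture_spec <- function(seed = 20191L,
                         n_abstracts = 200L,
                         n_genes = 30L, n_diseases = 15L, n_drugs = 20L,
                         n_variants = 40L,
                         planted_relationships = NULL,
                         trap_reviews = 3L, trap_nonhuman = 2L,
                         trap_no_abstract = 2L, trap_no_drug = 3L,
                         n_gold_only = 2L,
                         synonym_depth = 2L,
                         noise_mention_rate = 0) {
  if (min(n_genes, n_diseases, n_drugs, n_variants) < 1) {
    abort_invalid("Lexicon sizes must be >= 1.")
  }
  spec <- list(
    seed = as.integer(seed), n_abstracts = as.integer(n_abstracts),
    n_genes = as.integer(n_genes), n_diseases = as.integer(n_diseases),
    n_drugs = as.integer(n_drugs), n_variants = as.integer(n_variants),
    planted_relationships = planted_relationships,
    trap_reviews = as.integer(trap_reviews),
    trap_nonhuman = as.integer(trap_nonhuman),
    trap_no_abstract = as.integer(trap_no_abstract),
    trap_no_drug = as.integer(trap_no_drug),
    n_gold_only = as.integer(n_gold_only),
    synonym_depth = as.integer(synonym_depth),
    noise_mention_rate = noise_mention_rate
  )
  if (is.null(spec$planted_relationships)) {
    spec$planted_relationships <- default_planted_plan(spec)
  }
  pr <- spec$planted_relationships
  n_traps <- spec$trap_reviews + spec$trap_nonhuman + spec$trap_no_abstract +
    spec$trap_no_drug
  if (sum(pr$f) + n_traps > spec$n_abstracts) {
    abort_invalid(sprintf(
      "Infeasible spec: %d supporting abstracts + %d traps exceed %d abstracts.",
      sum(pr$f), n_traps, spec$n_abstracts))
  }
  structure(spec, class = "pgx_fixture_spec")
}

# Default planted plan: ten relationships over the first lexicon entries.
# Support cycles 3,2,1,0; the two unsupported relationships sit at f = 11
# (kept by the ranking threshold) and f = 10 (dropped at the boundary).
default_planted_plan <- function(spec) {
  n <- 10L
  n <- min(n, spec$n_diseases, spec$n_drugs, spec$n_genes)
  f <- c(12L, 7L, 1L, 11L, 9L, 6L, 4L, 10L, 3L, 2L)[seq_len(n)]
  support <- rep(c(3L, 2L, 1L, 0L), length.out = n)
  tibble(
    disease_id = sprintf("CH%02d", (seq_len(n) - 1L) %% 5L + 1L),
    drug_id = sprintf("DB%05d", seq_len(n)),
    gene_symbol = sprintf("GX%d", seq_len(n)),
    variant_id = ifelse(seq_len(n) %% 2L == 1L,
                        fixture_rsid(seq_len(n)), NA_character_),
    f = f,
    support = support,
    in_gold = seq_len(n) %% 2L == 1L
  )
}

fixture_rsid <- function(i) sprintf("rs%d", 100000L + i * 7L)

#' Generate the five toy lexicon files
#'
#' Writes `hgnc_mini.tsv`, `icd10_mini.tsv`, `drugbank_mini.tsv`,
#' `dbsnp_mini.tsv` and `populations.txt` into `dir`. Entries are synthetic
#' but format-faithful: at synonym depth 1 every entry gains a hyphen
#' variant, at depth 2 also a Greek-letter variant; every fifth drug gets a
#' metabolite entry flagged `metabolite`; variants are assigned owner genes
#' round-robin with one HGVS synonym each. Byte-identical output under a
#' fixed spec.
#'
#' @param spec A `pgx_fixture_spec`.
#' @param dir Output directory (created if needed).
#' @return A list with `paths` (named file paths) and `lexica` (named list
#'   of loaded `pgx_lexicon` objects).
#' @export
generate_lexica <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  depth <- spec$synonym_depth

  syn_col <- function(syns) {
    vapply(syns, function(x) paste(x, collapse = "|"), character(1))
  }
  pick_syns <- function(all_syns) {
    lapply(all_syns, function(x) x[seq_len(min(depth, length(x)))])
  }

  g_id <- sprintf("GX%d", seq_len(spec$n_genes))
  g_greek <- GREEK_WORDS[(seq_len(spec$n_genes) - 1L) %% length(GREEK_WORDS) + 1L]
  g_syns <- pick_syns(lapply(seq_len(spec$n_genes), function(i) {
    c(sprintf("GX-%d", i),
      sprintf("factor %s %d", names(GREEK_MAP)[match(g_greek[i], GREEK_MAP)], i))
  }))
  genes <- tibble(id = g_id, name = g_id, synonyms = syn_col(g_syns),
                  parent_id = "", flags = "")

  n_ch <- 5L
  ch_names <- sprintf("diseases of the %s system",
                      c("circulatory", "nervous", "respiratory", "digestive",
                        "immune"))
  d_idx <- seq_len(spec$n_diseases)
  d_stem <- DISEASE_STEMS[(d_idx - 1L) %% length(DISEASE_STEMS) + 1L]
  d_name <- sprintf("%sopathy %d", d_stem, d_idx)
  d_syns <- pick_syns(lapply(d_idx, function(i) {
    c(sprintf("%sopathy-%d", d_stem[i], i),
      sprintf("chronic %sitis %d", d_stem[i], i))
  }))
  diseases <- bind_rows(
    tibble(id = sprintf("CH%02d", seq_len(n_ch)), name = ch_names,
           synonyms = "", parent_id = "", flags = ""),
    tibble(id = sprintf("D%03d", d_idx), name = d_name,
           synonyms = syn_col(d_syns),
           parent_id = sprintf("CH%02d", (d_idx - 1L) %% n_ch + 1L),
           flags = "")
  )

  dr_idx <- seq_len(spec$n_drugs)
  dr_name <- sprintf("%s%s%d",
                     DRUG_STEMS[(dr_idx - 1L) %% length(DRUG_STEMS) + 1L],
                     DRUG_SUFFIXES[(dr_idx - 1L) %% length(DRUG_SUFFIXES) + 1L],
                     dr_idx)
  dr_syns <- pick_syns(lapply(dr_idx, function(i) {
    c(sprintf("%s %d", BRAND_STEMS[(i - 1L) %% length(BRAND_STEMS) + 1L], i),
      sprintf("methyl-%s", dr_name[i]))
  }))
  drugs <- tibble(id = sprintf("DB%05d", dr_idx), name = dr_name,
                  synonyms = syn_col(dr_syns), parent_id = "", flags = "")
  metab_for <- dr_idx[dr_idx %% 5L == 0L]
  if (length(metab_for) > 0) {
    drugs <- bind_rows(drugs, tibble(
      id = sprintf("DB%05dM", metab_for),
      name = sprintf("desmethyl%s", dr_name[metab_for]),
      synonyms = "",
      parent_id = sprintf("DB%05d", metab_for),
      flags = "metabolite"
    ))
  }

  v_idx <- seq_len(spec$n_variants)
  variants <- tibble(
    id = fixture_rsid(v_idx),
    name = fixture_rsid(v_idx),
    synonyms = sprintf("c.%dA>T", 100L + v_idx),
    parent_id = sprintf("GX%d", (v_idx - 1L) %% spec$n_genes + 1L),
    flags = ""
  )

  paths <- c(
    gene = file.path(dir, "hgnc_mini.tsv"),
    disease = file.path(dir, "icd10_mini.tsv"),
    drug = file.path(dir, "drugbank_mini.tsv"),
    variant = file.path(dir, "dbsnp_mini.tsv"),
    population = file.path(dir, "populations.txt")
  )
  readr::write_tsv(genes, paths[["gene"]], progress = FALSE)
  readr::write_tsv(diseases, paths[["disease"]], progress = FALSE)
  readr::write_tsv(drugs, paths[["drug"]], progress = FALSE)
  readr::write_tsv(variants, paths[["variant"]], progress = FALSE)
  readr::write_lines(POPULATION_TERMS, paths[["population"]])

  # variant ownership is validated against the gene lexicon separately,
  # because its parent ids live in a different vocabulary
  lexica <- list(
    gene = load_lexicon(paths[["gene"]], "gene"),
    disease = load_lexicon(paths[["disease"]], "disease"),
    drug = load_lexicon(paths[["drug"]], "drug"),
    variant = load_variant_index(paths[["variant"]]),
    population = load_population_list(paths[["population"]])
  )
  list(paths = paths, lexica = lexica)
}

#' Load a variant index TSV without parent validation
#'
#' Variant entries point at owner genes, which live in a different
#' vocabulary, so the dangling-parent check of [load_lexicon()] does not
#' apply.
#'
#' @param path Path to the variant TSV.
#' @return A `pgx_lexicon` of class `variant`.
#' @export
load_variant_index <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  entries <- tibble(
    id = raw$id, name = raw$name,
    synonyms = map(raw$synonyms %||% rep("", nrow(raw)), function(x) {
      if (is.na(x) || x == "") character() else strsplit(x, "|", fixed = TRUE)[[1]]
    }),
    parent_id = NA_character_,
    flags = if ("flags" %in% names(raw)) dplyr::coalesce(raw$flags, "") else ""
  )
  lex <- new_lexicon(entries, "variant")
  lex$entries$parent_id <- raw$parent_id %||% NA_character_
  lex
}

# Surface chosen for a planted mention: rotate through name and synonyms by
# support index so some abstracts use synonyms/orthographic variants.
rotate_surface <- function(lexicon, id, k) {
  entry <- lexicon_entry(lexicon, id)
  forms <- c(entry$name, entry$synonyms[[1]])
  forms[(k - 1L) %% length(forms) + 1L]
}

# Assemble one abstract from (piece, class, id) parts, tracking 0-based
# half-open offsets into title + " " + abstract.
build_abstract <- function(pmid, title, parts) {
  offset <- nchar(title) + 1L
  text <- ""
  mentions <- list()
  for (p in parts) {
    if (!is.null(p$class)) {
      mentions[[length(mentions) + 1]] <- tibble(
        pmid = pmid, entity_class = p$class, entity_id = p$id,
        surface = p$text, start = offset + nchar(text),
        end = offset + nchar(text) + nchar(p$text)
      )
    }
    text <- paste0(text, p$text)
  }
  list(abstract = text, mentions = bind_rows(mentions))
}

lit <- function(text) list(text = text)
ent <- function(text, class, id) list(text = text, class = class, id = id)

#' Generate the MEDLINE-style corpus with planted ground truth
#'
#' Writes `corpus.csv` (the MEDLINE dialect of [read_medline_csv()]) and
#' `truth.json` into `dir`. Each planted relationship is supported by `f`
#' dedicated abstracts built from a sentence template embedding the tuple's
#' surface forms (rotating through synonyms), followed by the planted trap
#' records (review, non-human, abstract-less, gene-without-drug) and
#' decoy-only filler abstracts. The truth file lists every planted mention
#' offset, entity id, tuple (with supporting pmids) and trap flag, plus the
#' expected filter-cascade counts.
#'
#' @param spec A `pgx_fixture_spec`.
#' @param lexica Named lexicon list from [generate_lexica()].
#' @param dir Output directory.
#' @return A list with `records` (the corpus tibble), `truth` (the planted
#'   truth list) and `paths`.
#' @export
generate_corpus <- function(spec, lexica, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pr <- spec$planted_relationships
  with_fixture_seed(spec$seed, {
    records <- list()
    mentions <- list()
    flags <- list()
    pmid_next <- 10001L
    planted_pmids <- vector("list", nrow(pr))

    decoy_tail <- function() {
      if (spec$noise_mention_rate <= 0) return("")
      n <- stats::rpois(1, spec$noise_mention_rate)
      if (n == 0) return("")
      paste0(" Assay batch included ",
             paste(sample(DECOY_TOKENS, n, replace = TRUE), collapse = " "),
             ".")
    }

    for (r in seq_len(nrow(pr))) {
      dis <- lexica$disease$entries[lexica$disease$entries$parent_id %in%
                                      pr$disease_id[r], ]
      dis_id <- dis$id[1]  # a leaf disease whose chapter is the planted id
      for (k in seq_len(pr$f[r])) {
        pmid <- pmid_next; pmid_next <- pmid_next + 1L
        pop <- POPULATION_TERMS[(k - 1L) %% length(POPULATION_TERMS) + 1L]
        title <- sprintf("Pharmacogenetic outcome study %d.", pmid)
        parts <- list(
          lit("In "), ent(pop, "population", pop),
          lit(" patients with "),
          ent(rotate_surface(lexica$disease, dis_id, k), "disease", dis_id),
          lit(", ")
        )
        if (!is.na(pr$variant_id[r])) {
          parts <- c(parts, list(
            ent(pr$variant_id[r], "variant", pr$variant_id[r]),
            lit(" in ")
          ))
        } else {
          parts <- c(parts, list(lit("variation in ")))
        }
        parts <- c(parts, list(
          ent(rotate_surface(lexica$gene, pr$gene_symbol[r], k), "gene",
              pr$gene_symbol[r]),
          lit(" altered response to "),
          ent(rotate_surface(lexica$drug, pr$drug_id[r], k), "drug",
              pr$drug_id[r]),
          lit("."), lit(decoy_tail())
        ))
        built <- build_abstract(pmid, title, parts)
        records[[length(records) + 1]] <- tibble(
          pmid = pmid, title = title, abstract = built$abstract,
          pub_types = "Journal Article", is_human = TRUE,
          year = 2015L + (pmid %% 5L)
        )
        mentions[[length(mentions) + 1]] <- built$mentions
        planted_pmids[[r]] <- c(planted_pmids[[r]], pmid)
      }
    }

    trap <- function(n, type) {
      for (k in seq_len(n)) {
        pmid <- pmid_next; pmid_next <<- pmid_next + 1L
        rec <- tibble(
          pmid = pmid,
          title = sprintf("Background note %d.", pmid),
          abstract = switch(type,
            review = "A survey of zorblatt assays in quintrixole research.",
            nonhuman = "Murine zorblatt exposure altered wexalide uptake.",
            no_abstract = "",
            no_drug = sprintf("Expression of %s correlated with flubberon signal.",
                              sprintf("GX%d", k))
          ),
          pub_types = if (type == "review") "Review|Journal Article"
                      else "Journal Article",
          is_human = type != "nonhuman",
          year = 2016L
        )
        records[[length(records) + 1]] <<- rec
        flags[[length(flags) + 1]] <<- tibble(pmid = pmid, trap = type)
      }
    }
    trap(spec$trap_reviews, "review")
    trap(spec$trap_nonhuman, "nonhuman")
    trap(spec$trap_no_abstract, "no_abstract")
    trap(spec$trap_no_drug, "no_drug")

    n_filler <- spec$n_abstracts - (pmid_next - 10001L)
    for (k in seq_len(n_filler)) {
      pmid <- pmid_next; pmid_next <- pmid_next + 1L
      records[[length(records) + 1]] <- tibble(
        pmid = pmid,
        title = sprintf("Methodological note %d.", pmid),
        abstract = paste0("Calibration of the ",
                          DECOY_TOKENS[(k - 1L) %% length(DECOY_TOKENS) + 1L],
                          " platform.", decoy_tail()),
        pub_types = "Journal Article", is_human = TRUE,
        year = 2014L + (k %% 6L)
      )
    }

    records <- bind_rows(records)
    mentions <- bind_rows(mentions)
    flags <- if (length(flags)) bind_rows(flags) else
      tibble(pmid = integer(), trap = character())

    planted <- pr
    planted$pmids <- planted_pmids
    # leaf disease used for each planted chapter (what the text mentions)
    planted$disease_leaf <- map_chr(planted$disease_id, function(ch) {
      lexica$disease$entries$id[which(lexica$disease$entries$parent_id == ch)[1]]
    })

    expected_filter <- tibble(
      stage = c("original_articles", "human_studies", "has_abstract",
                "entity_presence"),
      excluded_count = c(spec$trap_reviews, spec$trap_nonhuman,
                         spec$trap_no_abstract,
                         spec$trap_no_drug + n_filler)
    )

    truth <- list(
      spec = unclass(spec)[setdiff(names(spec), "planted_relationships")],
      planted_relationships = planted,
      mentions = mentions,
      trap_flags = flags,
      expected_filter = expected_filter
    )

    paths <- c(corpus = file.path(dir, "corpus.csv"),
               truth = file.path(dir, "truth.json"))
    write_medline_csv(records, paths[["corpus"]])
    readr::write_lines(
      jsonlite::toJSON(truth, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE, na = "null", digits = NA),
      paths[["truth"]])
    list(records = records, truth = truth, paths = paths)
  })
}

#' Generate reference datasets and the gold standard
#'
#' Writes `pharmgkb.tsv`, `omim.tsv`, `ctd.tsv` (dialect
#' `kind  id1  id2`, each honoring its dataset's granularity) and
#' `gold.tsv` into `dir`. Each planted relationship's `support` pattern
#' decides which datasets assert its sub-tuples (3 = all three, 2 =
#' PharmGKB + OMIM, 1 = CTD only, 0 = none); `in_gold` rows plus
#' `n_gold_only` extra unplanted tuples form the gold standard.
#'
#' @param spec A `pgx_fixture_spec`.
#' @param truth Planted-truth list from [generate_corpus()].
#' @param dir Output directory.
#' @return A list with `references` (named `pgx_reference` list), `gold`
#'   (tibble) and `paths`.
#' @export
generate_references <- function(spec, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pr <- truth$planted_relationships

  assert_rows <- function(r, kinds) {
    rows <- list()
    if ("drug_gene" %in% kinds) {
      rows <- c(rows, list(tibble(kind = "drug_gene", id1 = pr$drug_id[r],
                                  id2 = pr$gene_symbol[r])))
    }
    if ("drug_variant" %in% kinds && !is.na(pr$variant_id[r])) {
      rows <- c(rows, list(tibble(kind = "drug_variant", id1 = pr$drug_id[r],
                                  id2 = pr$variant_id[r])))
    }
    if ("disease_gene" %in% kinds) {
      rows <- c(rows, list(tibble(kind = "disease_gene", id1 = pr$disease_id[r],
                                  id2 = pr$gene_symbol[r])))
    }
    if ("disease_drug" %in% kinds) {
      rows <- c(rows, list(tibble(kind = "disease_drug", id1 = pr$disease_id[r],
                                  id2 = pr$drug_id[r])))
    }
    bind_rows(rows)
  }

  pgkb <- list(); omim <- list(); ctd <- list()
  for (r in seq_len(nrow(pr))) {
    s <- pr$support[r]
    if (s >= 2) {
      pgkb <- c(pgkb, list(assert_rows(r, REFERENCE_GRANULARITY$PharmGKB)))
      omim <- c(omim, list(assert_rows(r, REFERENCE_GRANULARITY$OMIM)))
    }
    if (s == 3 || s == 1) {
      ctd <- c(ctd, list(assert_rows(r, REFERENCE_GRANULARITY$CTD)))
    }
  }
  empty_assert <- tibble(kind = character(), id1 = character(),
                         id2 = character())
  bind_or_empty <- function(x) {
    if (length(x)) distinct(bind_rows(x)) else empty_assert
  }

  gold <- tibble(
    disease_id = pr$disease_id[pr$in_gold],
    drug_id = pr$drug_id[pr$in_gold],
    gene_symbol = pr$gene_symbol[pr$in_gold],
    variant_id = pr$variant_id[pr$in_gold]
  )
  if (spec$n_gold_only > 0) {
    k <- seq_len(spec$n_gold_only)
    gold <- bind_rows(gold, tibble(
      disease_id = sprintf("CH%02d", (k - 1L) %% 5L + 1L),
      drug_id = sprintf("DB%05d", spec$n_drugs - k + 1L),
      gene_symbol = sprintf("GX%d", spec$n_genes - k + 1L),
      variant_id = NA_character_
    ))
  }

  paths <- c(pharmgkb = file.path(dir, "pharmgkb.tsv"),
             omim = file.path(dir, "omim.tsv"),
             ctd = file.path(dir, "ctd.tsv"),
             gold = file.path(dir, "gold.tsv"))
  readr::write_tsv(bind_or_empty(pgkb), paths[["pharmgkb"]], progress = FALSE)
  readr::write_tsv(bind_or_empty(omim), paths[["omim"]], progress = FALSE)
  readr::write_tsv(bind_or_empty(ctd), paths[["ctd"]], progress = FALSE)
  gold_out <- gold
  gold_out$variant_id <- dplyr::coalesce(gold_out$variant_id, "")
  readr::write_tsv(gold_out, paths[["gold"]], progress = FALSE)

  list(
    references = list(
      PharmGKB = new_reference("PharmGKB", bind_or_empty(pgkb)),
      OMIM = new_reference("OMIM", bind_or_empty(omim)),
      CTD = new_reference("CTD", bind_or_empty(ctd))
    ),
    gold = gold,
    paths = paths
  )
}

#' Read a gold-standard relationship TSV
#'
#' @param path Path to the TSV (`disease_id  drug_id  gene_symbol
#'   variant_id`, empty variant for triplet rows).
#' @return A tibble in the relationship-key dialect.
#' @export
read_gold_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  raw$variant_id <- ifelse(is.na(raw$variant_id) | raw$variant_id == "",
                           NA_character_, raw$variant_id)
  raw
}

#' Generate a complete fixtures bundle
#'
#' Runs [generate_lexica()], [generate_corpus()] and
#' [generate_references()] into one directory.
#'
#' @param spec A `pgx_fixture_spec`.
#' @param dir Bundle directory.
#' @return A list with `lexica`, `records`, `truth`, `references`, `gold`
#'   and all `paths`.
#' @export
generate_bundle <- function(spec, dir) {
  lx <- generate_lexica(spec, dir)
  co <- generate_corpus(spec, lx$lexica, dir)
  rf <- generate_references(spec, co$truth, dir)
  list(lexica = lx$lexica, records = co$records, truth = co$truth,
       references = rf$references, gold = rf$gold,
       paths = c(lx$paths, co$paths, rf$paths))
}
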