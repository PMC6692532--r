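gene_lex <- make_lexicon(
  "gene",
  ids = c("TPMT", "ABCB1", "SLCO1B1"),
  names = c("TPMT", "ATP binding cassette subfamily B member 1", "SLCO1B1"),
  synonyms = list(character(), c("ABCB1", "MDR1", "P-glycoprotein"),
                  character())
)

disease_lex <- make_lexicon(
  "disease",
  ids = c("CHN", "CHC", "D1", "D2", "D3"),
  names = c("diseases of the nervous system",
            "diseases of the circulatory system",
            "cerebral infarction", "cerebrovascular accident", "epilepsy"),
  synonyms = list(character(), character(), "stroke", "stroke", character()),
  parent_ids = c(NA, NA, "CHN", "CHC", "CHN")
)

drug_lex <- make_lexicon(
  "drug",
  ids = c("DB00682", "DB01118", "DB00682M"),
  names = c("warfarin", "amiodarone", "7-hydroxywarfarin"),
  synonyms = list(c("Coumadin"), character(), character()),
  parent_ids = c(NA, NA, "DB00682"),
  flags = c("", "", "metabolite")
)

variant_lex <- make_lexicon(
  "variant",
  ids = c("rs4149056", "rs9923231"),
  names = c("rs4149056", "rs9923231"),
  synonyms = list(c("c.521T>C"), c("c.-1639G>A"))
)
variant_lex$entries$parent_id <- c("SLCO1B1", "VKORC1")

test_that("gene normalization walks exact, synonym and failure ladder", {
  exact <- normalize_gene(make_mention(1, "gene", "TPMT"), gene_lex)
  expect_equal(exact$status, "exact")
  expect_equal(exact$canonical_id, "TPMT")

  syn <- normalize_gene(make_mention(1, "gene", "P-glycoprotein"), gene_lex)
  expect_equal(syn$status, "variant_match")
  expect_equal(syn$canonical_id, "ABCB1")

  unspecified <- normalize_gene(make_mention(1, "gene", "src inhibitors"),
                                gene_lex)
  expect_equal(unspecified$status, "failed")
  expect_equal(unspecified$failure_reason, "unspecified")

  family <- normalize_gene(
    make_mention(1, "gene", "major histocompatibility complex"), gene_lex)
  expect_equal(family$failure_reason, "family_level")

  abbrev <- normalize_gene(make_mention(1, "gene", "XYZ9"), gene_lex)
  expect_equal(abbrev$failure_reason, "abbreviated")
})

test_that("ambiguous gene surfaces are preserved, not resolved", {
  amb_lex <- make_lexicon("gene", ids = c("G1", "G2"),
                          names = c("G1", "G2"),
                          synonyms = list("shared name", "shared name"))
  out <- normalize_gene(make_mention(1, "gene", "shared name"), amb_lex)
  expect_equal(out$status, "ambiguous")
  expect_setequal(out$candidate_ids[[1]], c("G1", "G2"))
  expect_true(is.na(out$canonical_id))
})

test_that("disease normalization reports chapters, ambiguity and symptoms", {
  stroke <- normalize_disease(make_mention(1, "disease", "stroke"),
                              disease_lex)
  expect_equal(stroke$status, "ambiguous")
  expect_setequal(stroke$candidate_ids[[1]], c("CHN", "CHC"))

  prioritized <- normalize_disease(make_mention(1, "disease", "stroke"),
                                   disease_lex,
                                   chapter_priority = c("CHC", "CHN"))
  expect_equal(prioritized$canonical_id, "CHC")

  epilepsy <- normalize_disease(make_mention(1, "disease", "epilepsy"),
                                disease_lex)
  expect_equal(epilepsy$status, "exact")
  expect_equal(epilepsy$canonical_id, "CHN")

  nausea <- normalize_disease(make_mention(1, "disease", "severe nausea"),
                              disease_lex)
  expect_equal(nausea$status, "failed")
  expect_equal(nausea$failure_reason, "unspecified")

  partial <- normalize_disease(
    make_mention(1, "disease", "acute diseases of the circulatory system"),
    disease_lex)
  expect_equal(partial$status, "partial_match")
  expect_equal(partial$canonical_id, "CHC")

  miss <- normalize_disease(make_mention(1, "disease", "zorblatt syndrome"),
                            disease_lex)
  expect_equal(miss$status, "failed")
})

test_that("drug normalization resolves names and brands, rejects metabolites", {
  exact <- normalize_drug(make_mention(1, "drug", "warfarin"), drug_lex)
  expect_equal(exact$status, "exact")
  expect_equal(exact$canonical_id, "DB00682")

  brand <- normalize_drug(make_mention(1, "drug", "Coumadin"), drug_lex)
  expect_equal(brand$status, "variant_match")
  expect_equal(brand$canonical_id, "DB00682")

  metab <- normalize_drug(make_mention(1, "drug", "7-hydroxywarfarin"),
                          drug_lex)
  expect_equal(metab$status, "failed")
  expect_equal(metab$failure_reason, "metabolite")
})

test_that("variant normalization uses the index and gene scoping", {
  hit <- normalize_variant(make_mention(1, "variant", "rs4149056"),
                           variant_lex)
  expect_equal(hit$status, "exact")
  expect_equal(hit$canonical_id, "rs4149056")

  miss <- normalize_variant(make_mention(1, "variant", "rs99999999999"),
                            variant_lex)
  expect_equal(miss$status, "failed")

  hgvs <- normalize_variant(make_mention(1, "variant", "c.521T>C"),
                            variant_lex, nearby_genes = "SLCO1B1")
  expect_equal(hgvs$status, "variant_match")
  expect_equal(hgvs$canonical_id, "rs4149056")

  unscoped <- normalize_variant(make_mention(1, "variant", "c.521T>C"),
                                variant_lex, nearby_genes = character())
  expect_equal(unscoped$status, "failed")
})

lexica <- list(gene = gene_lex, disease = disease_lex, drug = drug_lex,
               variant = variant_lex,
               population = make_lexicon("population", "Japanese", "Japanese"))

test_that("normalization is order-independent and partitions statuses", {
  mentions <- dplyr::bind_rows(
    make_mention(1, "gene", "SLCO1B1", 0),
    make_mention(1, "variant", "c.521T>C", 10),
    make_mention(1, "drug", "warfarin", 25),
    make_mention(1, "disease", "stroke", 40),
    make_mention(2, "gene", "unknownase enzyme", 0),
    make_mention(2, "drug", "Coumadin", 20),
    make_mention(2, "population", "Japanese", 30)
  )
  out <- normalize_mentions(mentions, lexica)
  expect_equal(nrow(out), nrow(mentions))
  expect_true(all(out$status %in%
                    c("exact", "variant_match", "partial_match", "ambiguous",
                      "failed")))
  # failed <=> no canonical id <=> a reason is present
  expect_equal(is.na(out$canonical_id) & out$status == "failed",
               !is.na(out$failure_reason))
  # gene-scoped HGVS resolution worked through the full path
  expect_equal(out$canonical_id[out$surface == "c.521T>C"], "rs4149056")

  withr::local_seed(23)
  shuffled <- normalize_mentions(mentions[sample(nrow(mentions)), ], lexica)
  key <- function(x) x[order(x$pmid, x$start), c("pmid", "start", "status",
                                                 "canonical_id")]
  expect_equal(key(shuffled), key(out))
})

test_that("enlarging a lexicon never converts resolved mentions to failed", {
  small <- make_lexicon("gene", "TPMT", "TPMT")
  big <- make_lexicon("gene", c("TPMT", "NEW1"), c("TPMT", "NEW1"),
                      synonyms = list(character(), "novel kinase"))
  for (surface in c("TPMT", "novel kinase", "unknownase")) {
    before <- normalize_gene(make_mention(1, "gene", surface), small)
    after <- normalize_gene(make_mention(1, "gene", surface), big)
    if (before$status != "failed") {
      expect_false(after$status == "failed")
    }
  }
})

test_that("normalization summary partitions counts by class and reason", {
  empty <- normalization_summary(normalize_mentions(make_mention(1, "gene", "x")[0, ], lexica))
  expect_equal(nrow(empty$by_class), 0)

  mentions <- dplyr::bind_rows(
    lapply(1:8, function(k) make_mention(k, "gene", "TPMT", k)),
    lapply(1:2, function(k) make_mention(k + 10, "gene", "unknownase", k))
  )
  out <- normalization_summary(normalize_mentions(mentions, lexica))
  gene_row <- out$by_class[out$by_class$entity_class == "gene", ]
  expect_equal(gene_row$attempted, 10L)
  expect_equal(gene_row$resolved, 8L)
  expect_equal(gene_row$resolved_fraction, 0.8)
  expect_equal(gene_row$attempted,
               gene_row$resolved + gene_row$ambiguous + gene_row$failed)
  # mention-level and unique-name-level rates are both reported
  un <- out$unique_names[out$unique_names$entity_class == "gene", ]
  expect_equal(un$attempted, 2L)
})

test_that("a planted unresolvable fraction is reported exactly", {
  n <- 50L
  n_bad <- 9L  # 18% of attempted gene names cannot be mapped
  mentions <- dplyr::bind_rows(
    lapply(seq_len(n - n_bad), function(k) make_mention(k, "gene", "TPMT", k)),
    lapply(seq_len(n_bad), function(k) {
      make_mention(100 + k, "gene", sprintf("pseudogene region %d", k), k)
    })
  )
  out <- normalization_summary(normalize_mentions(mentions, lexica))
  gene_row <- out$by_class[out$by_class$entity_class == "gene", ]
  expect_equal(gene_row$failed_fraction, 0.18)
})

test_that("the curation queue exports ambiguous and failed rows", {
  mentions <- dplyr::bind_rows(
    make_mention(1, "disease", "stroke"),
    make_mention(1, "gene", "TPMT"),
    make_mention(1, "gene", "unknownase enzyme")
  )
  out <- normalize_mentions(mentions, lexica)
  path <- withr::local_tempfile(fileext = ".tsv")
  queue <- write_curation_queue(out, path)
  expect_equal(nrow(queue), 2)
  expect_setequal(queue$status, c("ambiguous", "failed"))
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 2)
})
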