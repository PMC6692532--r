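# Normalized-entity rows built directly (extraction consumes normalization
# output, so tests plant canonical ids and statuses).
norm_entity <- function(pmid, class, id, status = "exact") {
  tibble::tibble(
    pmid = as.integer(pmid), entity_class = class, surface = id,
    start = 0L, end = 1L, canonical_id = id, canonical_name = id,
    status = status, failure_reason = NA_character_,
    candidate_ids = list(character())
  )
}

variant_index <- make_lexicon(
  "variant",
  ids = c("rs1", "rs2"), names = c("rs1", "rs2")
)
variant_index$entries$parent_id <- c("G1", "G2")

test_that("extraction emits the full disease x drug x gene cross-product", {
  ents <- dplyr::bind_rows(
    norm_entity(1, "disease", "CH1"),
    norm_entity(1, "drug", "DB1"), norm_entity(1, "drug", "DB2"),
    norm_entity(1, "gene", "G1"), norm_entity(1, "gene", "G2")
  )
  out <- extract_relations(ents, variant_index)
  expect_equal(nrow(out), 4)
  expect_true(all(is.na(out$variant_id)))

  # brute-force cross-product oracle at 3 x 2 x 2
  ents2 <- dplyr::bind_rows(
    lapply(sprintf("CH%d", 1:3), function(d) norm_entity(2, "disease", d)),
    lapply(sprintf("DB%d", 1:2), function(d) norm_entity(2, "drug", d)),
    lapply(sprintf("G%d", 1:2), function(g) norm_entity(2, "gene", g))
  )
  out2 <- extract_relations(ents2, variant_index)
  oracle <- expand.grid(disease_id = sprintf("CH%d", 1:3),
                        drug_id = sprintf("DB%d", 1:2),
                        gene_symbol = sprintf("G%d", 1:2),
                        stringsAsFactors = FALSE)
  expect_equal(nrow(out2), nrow(oracle))
  got <- paste(out2$disease_id, out2$drug_id, out2$gene_symbol)
  want <- paste(oracle$disease_id, oracle$drug_id, oracle$gene_symbol)
  expect_setequal(got, want)
})

test_that("variants join only tuples of their owner gene", {
  ents <- dplyr::bind_rows(
    norm_entity(3, "disease", "CH1"), norm_entity(3, "drug", "DB1"),
    norm_entity(3, "gene", "G1"), norm_entity(3, "variant", "rs1")
  )
  out <- extract_relations(ents, variant_index)
  expect_equal(nrow(out), 1)
  expect_equal(out$variant_id, "rs1")

  # rs2 belongs to G2 which is absent: the tuple stays variant-less
  ents_unowned <- dplyr::bind_rows(
    norm_entity(4, "disease", "CH1"), norm_entity(4, "drug", "DB1"),
    norm_entity(4, "gene", "G1"), norm_entity(4, "variant", "rs2")
  )
  out2 <- extract_relations(ents_unowned, variant_index)
  expect_equal(nrow(out2), 1)
  expect_true(is.na(out2$variant_id))
})

test_that("failed or ambiguous normalizations never enter tuples", {
  ents <- dplyr::bind_rows(
    norm_entity(5, "disease", "CH1", status = "ambiguous"),
    norm_entity(5, "drug", "DB1"),
    norm_entity(5, "gene", "G1")
  )
  out <- extract_relations(ents, variant_index)
  expect_equal(out$disease_id, "UNSPECIFIED")

  no_drug <- dplyr::bind_rows(
    norm_entity(6, "drug", "DB1", status = "failed"),
    norm_entity(6, "gene", "G1")
  )
  expect_equal(nrow(extract_relations(no_drug, variant_index)), 0)
})

test_that("aggregation merges keys, counts distinct pmids and sorts stably", {
  keys <- dplyr::bind_rows(lapply(1:3, function(pm) {
    extract_relations(dplyr::bind_rows(
      norm_entity(pm, "disease", "CH1"), norm_entity(pm, "drug", "DB1"),
      norm_entity(pm, "gene", "G1")
    ), variant_index)
  }))
  tab <- aggregate_relations(keys)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$f, 3L)
  expect_equal(tab$supporting_pmids[[1]], 1:3)

  expect_equal(nrow(aggregate_relations(keys[0, ])), 0)
})

test_that("planted frequencies reappear exactly after aggregation", {
  plan <- list(list(key = c("CH1", "DB1", "G1"), f = 12),
               list(key = c("CH2", "DB2", "G2"), f = 7),
               list(key = c("CH3", "DB1", "G2"), f = 1))
  pm <- 0L
  keys <- dplyr::bind_rows(lapply(plan, function(p) {
    dplyr::bind_rows(lapply(seq_len(p$f), function(i) {
      pm <<- pm + 1L
      extract_relations(dplyr::bind_rows(
        norm_entity(pm, "disease", p$key[1]),
        norm_entity(pm, "drug", p$key[2]),
        norm_entity(pm, "gene", p$key[3])
      ), variant_index)
    }))
  }))
  tab <- aggregate_relations(keys)
  expect_equal(tab$f, c(12L, 7L, 1L))
  expect_equal(tab$gene_symbol, c("G1", "G2", "G2"))
})

test_that("binary projections split rows by schema and union pmid sets", {
  with_variant <- tibble::tibble(
    disease_id = "CH1", drug_id = "DB1", gene_symbol = "G1",
    variant_id = "rs1", f = 2L, supporting_pmids = list(c(1L, 2L)),
    populations = list(character())
  )
  proj <- binary_projections(with_variant)
  expect_equal(vapply(proj, nrow, integer(1)),
               c(disease_drug = 1L, disease_gene = 1L, drug_gene = 1L,
                 drug_variant = 1L, gene_variant = 1L))

  without_variant <- with_variant
  without_variant$variant_id <- NA_character_
  proj2 <- binary_projections(without_variant)
  expect_equal(vapply(proj2, nrow, integer(1)),
               c(disease_drug = 1L, disease_gene = 1L, drug_gene = 1L,
                 drug_variant = 0L, gene_variant = 0L))

  # shared drug-gene pair: support is the union {1,2} u {2,3}, never the sum
  two_rows <- dplyr::bind_rows(
    with_variant,
    tibble::tibble(disease_id = "CH2", drug_id = "DB1", gene_symbol = "G1",
                   variant_id = NA_character_, f = 2L,
                   supporting_pmids = list(c(2L, 3L)),
                   populations = list(character()))
  )
  dg <- binary_projections(two_rows)$drug_gene
  expect_equal(nrow(dg), 1)
  expect_equal(dg$f, 3L)
  expect_equal(dg$supporting_pmids[[1]], 1:3)

  empty <- binary_projections(with_variant[0, ])
  expect_true(all(vapply(empty, nrow, integer(1)) == 0))
})

test_that("every projected pair traces back to a quaternary row", {
  run <- shared_bundle_run()
  tab <- run$mined$table
  proj <- binary_projections(tab)
  quat_pairs <- list(
    disease_drug = paste(tab$disease_id, tab$drug_id),
    drug_gene = paste(tab$drug_id, tab$gene_symbol),
    gene_variant = paste(tab$gene_symbol, tab$variant_id)
  )
  for (kind in names(quat_pairs)) {
    got <- paste(proj[[kind]]$id1, proj[[kind]]$id2)
    expect_true(all(got %in% quat_pairs[[kind]]), info = kind)
  }
  # support sets are unions of quaternary supports, so sizes cannot exceed
  # the summed frequencies of contributing rows
  dg <- proj$drug_gene
  for (k in seq_len(nrow(dg))) {
    contributing <- tab[tab$drug_id == dg$id1[k] & tab$gene_symbol == dg$id2[k], ]
    expect_lte(dg$f[k], sum(contributing$f))
    expect_equal(sort(unique(unlist(contributing$supporting_pmids))),
                 dg$supporting_pmids[[k]])
  }
})

test_that("relationship tables round-trip through their TSV dialect", {
  run <- shared_bundle_run()
  tab <- run$mined$table
  path <- withr::local_tempfile(fileext = ".tsv")
  write_relation_tsv(tab, path)
  back <- read_relation_tsv(path)
  expect_equal(back$disease_id, tab$disease_id)
  expect_equal(back$drug_id, tab$drug_id)
  expect_equal(back$gene_symbol, tab$gene_symbol)
  expect_equal(back$variant_id, tab$variant_id)
  expect_equal(back$f, tab$f)
  expect_equal(back$supporting_pmids, tab$supporting_pmids)
})
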