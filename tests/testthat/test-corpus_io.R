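test_that("build_query quotes and ORs MeSH terms", {
  expect_identical(build_query("pharmacogenomics"), '"pharmacogenomics"')
  expect_identical(build_query(c("a", "b")), '"a" OR "b"')
  default <- build_query()
  for (term in c("inter-individual variability", "pharmacogenomics",
                 "pharmacogenetics", "drug response")) {
    expect_match(default, term, fixed = TRUE)
  }
  expect_error(build_query(character()), class = "pgxminer_invalid_argument")
  expect_error(build_query(c("a", "")), class = "pgxminer_invalid_argument")
})

test_that("MEDLINE CSV writer and reader round-trip records", {
  records <- tibble::tibble(
    pmid = 1:10,
    title = sprintf("Title %d", 1:10),
    abstract = c(sprintf("Abstract %d.", 1:9), ""),
    pub_types = rep(c("Journal Article", "Review|Journal Article"), 5),
    is_human = rep(c(TRUE, FALSE), 5),
    year = 2010:2019
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_medline_csv(records, path)
  back <- read_medline_csv(path)
  expect_equal(nrow(back), 10)
  for (col in c("pmid", "title", "abstract", "pub_types", "is_human", "year")) {
    expect_equal(back[[col]], records[[col]], info = col)
  }
  expect_false(back$has_abstract[10])
  expect_true(all(back$has_abstract[1:9]))
  expect_equal(attr(back, "skipped"), 0L)
})

test_that("empty and malformed corpus rows are handled without aborting", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("pmid,title,abstract,pub_types,is_human,year", path)
  expect_equal(nrow(read_medline_csv(path)), 0)

  writeLines(c(
    "pmid,title,abstract,pub_types,is_human,year",
    "1,ok,text,Journal Article,TRUE,2018",
    "notanid,bad,text,Journal Article,TRUE,2018",
    "1,duplicate,text,Journal Article,TRUE,2018"
  ), path)
  expect_warning(out <- read_medline_csv(path), "2 malformed")
  expect_equal(out$pmid, 1L)
  expect_equal(attr(out, "skipped"), 2L)
})

test_that("missing corpus columns raise a format error naming them", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pmid,title", "1,x"), path)
  expect_error(read_medline_csv(path), "abstract",
               class = "pgxminer_format_error")
  expect_error(read_medline_csv(file.path(tempdir(), "absent-corpus.csv")),
               class = "pgxminer_io_error")
})

test_that("column mapping adapts foreign CSV dialects", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("PMID,title,abstract,pub_types,is_human,year",
               "7,t,a,Journal Article,TRUE,2019"), path)
  out <- read_medline_csv(path, col_map = c(pmid = "PMID"))
  expect_equal(out$pmid, 7L)
})

test_that("PubTator offset TSV reader handles classes, offsets and errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), path)
  empty <- read_pubtator_tsv(path)
  expect_equal(nrow(empty), 0)

  writeLines("123\t0\t4\tTPMT\tGene\tTPMT", path)
  one <- read_pubtator_tsv(path)
  expect_equal(nrow(one), 1)
  expect_equal(one$entity_class, "gene")
  expect_equal(one$start, 0L)
  expect_equal(one$end, 4L)

  # planted class totals: 3 genes, 2 diseases, 2 chemicals, 1 mutation,
  # 2 ignored (species)
  lines <- c(
    sprintf("1\t%d\t%d\tg%d\tGene\tG%d", 0:2 * 10, 0:2 * 10 + 2, 1:3, 1:3),
    sprintf("2\t%d\t%d\td%d\tDisease\tD%d", 0:1 * 10, 0:1 * 10 + 2, 1:2, 1:2),
    sprintf("3\t%d\t%d\tc%d\tChemical\tC%d", 0:1 * 10, 0:1 * 10 + 2, 1:2, 1:2),
    "4\t0\t5\trs999\tMutation\trs999",
    "5\t0\t3\thsa\tSpecies\t9606",
    "5\t4\t7\tmmu\tSpecies\t10090"
  )
  writeLines(lines, path)
  out <- read_pubtator_tsv(path)
  expect_equal(sum(out$entity_class == "gene"), 3)
  expect_equal(sum(out$entity_class == "disease"), 2)
  expect_equal(sum(out$entity_class == "drug"), 2)
  expect_equal(sum(out$entity_class == "variant"), 1)
  expect_equal(attr(out, "ignored_classes"), 2L)

  writeLines("1\t5\t5\tx\tGene\tX", path)
  expect_error(read_pubtator_tsv(path), "line 1",
               class = "pgxminer_format_error")
})

test_that("mention tables round-trip through the PubTator dialect", {
  mentions <- dplyr::bind_rows(
    make_mention(11, "gene", "TPMT", 10),
    make_mention(11, "drug", "warfarin", 20),
    make_mention(12, "variant", "rs4149056", 5)
  )
  mentions$candidate_ids <- list("TPMT", "DB00682", "rs4149056")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pubtator_tsv(mentions, path)
  back <- read_pubtator_tsv(path)
  expect_equal(back$pmid, mentions$pmid)
  expect_equal(back$start, mentions$start)
  expect_equal(back$end, mentions$end)
  expect_equal(back$entity_class, mentions$entity_class)
  expect_equal(back$candidate_ids, mentions$candidate_ids)
  expect_true(all(back$source == "imported"))
})

test_that("filter cascade excludes planted traps stage by stage", {
  records <- dplyr::bind_rows(
    make_record(1:14, "t", "abstract text"),
    make_record(15:17, "t", "abstract text", pub_types = "Review"),
    make_record(18:19, "t", "abstract text", is_human = FALSE),
    make_record(20, "t", "")
  )
  # shuffle so stage order, not record order, drives the counts
  records <- records[sample(nrow(records)), ]
  out <- filter_cascade(records)
  expect_equal(out$report$input_count, c(20L, 17L, 15L))
  expect_equal(out$report$excluded_count, c(3L, 2L, 1L))
  expect_equal(out$report$retained_count, c(17L, 15L, 14L))
  expect_equal(nrow(out$records), 14)
  expect_true(validate_filter_report(out$report))

  # idempotence: re-filtering the retained set excludes nothing
  again <- filter_cascade(out$records)
  expect_equal(again$report$excluded_count, c(0L, 0L, 0L))
  expect_equal(nrow(again$records), 14)
})

test_that("empty input yields an empty cascade with zero counts", {
  out <- filter_cascade(make_record(integer(), character(), character())[0, ])
  expect_equal(nrow(out$records), 0)
  expect_true(all(out$report$input_count == 0))
  expect_true(all(out$report$excluded_count == 0))
})

test_that("filter-report bookkeeping enforces conservation and chaining", {
  rpt <- add_filter_stage(NULL, "screened", 430320, 183625)
  expect_equal(rpt$retained_count, 246695L)
  rpt <- add_filter_stage(rpt, "drug_entity", 246695, 66607)
  expect_equal(rpt$retained_count[2], 180088L)
  expect_true(validate_filter_report(rpt))

  expect_error(add_filter_stage(rpt, "broken", 999, 1),
               class = "pgxminer_invalid_argument")
  expect_error(add_filter_stage(NULL, "bad", 5, 6),
               class = "pgxminer_invalid_argument")
  bad <- rpt
  bad$retained_count[1] <- 1L
  expect_error(validate_filter_report(bad),
               class = "pgxminer_invalid_argument")
})

test_that("filter reports serialize to JSON with all stages", {
  rpt <- add_filter_stage(NULL, "a", 10, 4)
  rpt <- add_filter_stage(rpt, "b", 6, 1)
  parsed <- jsonlite::fromJSON(filter_report_json(rpt))
  expect_equal(parsed$stages$stage, c("a", "b"))
  expect_equal(parsed$stages$retained_count, c(6, 5))
})
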