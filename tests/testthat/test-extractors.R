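# A worked three-paper micro-corpus in the style of published association
# tables: a correct precise phenotype, a dash (missing) precise phenotype,
# and an acronym resolved via a definition table.
worked_corpus_xml <- function() {
  list(
    p1 = paper_xml(
      pmid = "101",
      title = paste0("Genome-wide pharmacogenomic study of metabolic side",
                     " effects to antipsychotic drugs."),
      tables = table_xml(c("SNP", "Trait", "P value"),
                         list(c("rs17661538", "Clozapine—Triglycerides",
                                "1.00E−06")))
    ),
    p2 = paper_xml(
      pmid = "102",
      title = paste0("Genome-wide meta-analysis identifies seven loci",
                     " associated with platelet aggregation in response",
                     " to agonists."),
      abstract = "We studied platelet aggregation in three cohorts.",
      tables = table_xml(c("SNP", "Trait", "P"),
                         list(c("rs12566888", "–", "5.00E−19"),
                              c("rs13130255", "funcPS", "3.00E−06")))
    ),
    p3 = paper_xml(
      pmid = "103",
      title = "A genome-wide association study of body mass index.",
      body = "We measured body mass index (BMI) at enrollment.",
      tables = table_xml(c("SNP", "Phenotype", "P"),
                         list(c("rs555555", "BMI", "2.00E−08")))
    )
  )
}

worked_corpus_records <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  xmls <- worked_corpus_xml()
  for (nm in names(xmls)) {
    writeLines(xmls[[nm]], file.path(dir, paste0(nm, ".xml")))
  }
  extract_corpus(dir, mini_dict())
}

test_that("worked association rows are extracted with exact p-values", {
  recs <- worked_corpus_records()
  r1 <- recs[recs$rsid == "rs17661538", ]
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$precise_phenotype, "Clozapine—Triglycerides")
  expect_identical(r1$p_value, 1.0e-6)
  expect_true(r1$significant)

  # dash phenotype: record still reported, with no precise phenotype
  r2 <- recs[recs$rsid == "rs12566888", ]
  expect_equal(nrow(r2), 1L)
  expect_true(is.na(r2$precise_phenotype))
  expect_identical(r2$p_value, 5.0e-19)
  expect_match(r2$simple_phenotypes, "platelet aggregation")

  # funcPS has no definition anywhere: kept verbatim, unresolved
  r3 <- recs[recs$rsid == "rs13130255", ]
  expect_equal(r3$precise_phenotype, "funcPS")
  expect_true(is.na(r3$resolved_phenotype))
  expect_identical(r3$p_value, 3.0e-6)

  # BMI is defined in the text and resolves to its expansion
  r4 <- recs[recs$rsid == "rs555555", ]
  expect_equal(r4$precise_phenotype, "BMI")
  expect_equal(r4$resolved_phenotype, "body mass index")
})

test_that("simple phenotypes come from the title/abstract dictionary scan", {
  dict <- mini_dict()
  doc <- parse_document(paper_xml(
    title = "Seven loci associated with platelet aggregation.",
    pmid = "7"))
  expect_equal(extract_simple_phenotypes(doc, dict),
               "platelet aggregation")
  # at most three distinct phenotypes are reported
  doc3 <- parse_document(paper_xml(
    title = paste("A GWAS of height, body mass index, obesity and",
                  "waist circumference in adults."),
    abstract = paste("Height, body mass index, obesity and waist",
                     "circumference were measured."),
    pmid = "8"))
  out <- extract_simple_phenotypes(doc3, dict)
  expect_lte(length(out), 3L)
  expect_gte(length(out), 1L)
  # no candidates at all: empty result
  doc0 <- parse_document(paper_xml(title = "An unrelated report.",
                                   pmid = "9"))
  expect_length(extract_simple_phenotypes(doc0, dict), 0L)
})

test_that("numeric trait cells are rejected by the precise-phenotype stage", {
  xml <- paper_xml(tables = table_xml(
    c("SNP", "Trait", "P"),
    list(c("rs111111", "1.23", "1.0E−6"),
         c("rs222222", "Serum lipid levels", "2.0E−6"))
  ), pmid = "11")
  doc <- parse_document(xml)
  out <- extract_precise_phenotypes(doc)
  expect_equal(out$rsid, "rs222222")
  expect_equal(out$phenotype, "Serum lipid levels")
  # rsid-only table yields nothing
  doc2 <- parse_document(paper_xml(tables = table_xml(
    c("SNP", "P"), list(c("rs333333", "1.0E−6"))), pmid = "12"))
  expect_equal(nrow(extract_precise_phenotypes(doc2)), 0L)
})

test_that("conflicting acronym expansions resolve to the stronger pair", {
  # two definitions for BMI; only one has matching initials
  xml <- paper_xml(
    body = c("We measured body mass index (BMI) in adults.",
             "The bone density (BMI) score was ignored."),
    pmid = "13")
  doc <- parse_document(xml)
  amap <- resolve_acronyms(doc, dictionary = mini_dict())
  expect_equal(unname(amap["BMI"]), "body mass index")
})

test_that("acronym replacement is whole-token and case-sensitive", {
  amap <- c(BMI = "body mass index")
  expect_equal(gwasminer:::apply_acronym_map("BMI change", amap),
               "body mass index change")
  # substrings and lowercase forms are not replaced
  expect_true(is.na(gwasminer:::apply_acronym_map("SUBMIT", amap)))
  expect_true(is.na(gwasminer:::apply_acronym_map("bmi", amap)))
})

test_that("p-value relations are reported in full, without classification", {
  xml <- paper_xml(tables = table_xml(
    c("SNP", "Discovery P", "Replication P"),
    list(c("rs12566888", "5.00E−19", "0.03"))), pmid = "14")
  rel <- extract_pvalue_relations(parse_document(xml))
  expect_equal(nrow(rel), 2L)
  expect_setequal(rel$p_value, c(5e-19, 0.03))
})

test_that("assembly keeps the minimum p-value and a strict significance flag", {
  prel <- tibble::tibble(
    rsid = c("rs111111", "rs111111", "rs222222"),
    p_value = c(1.0e-6, 0.03, 1.0e-5),
    table_id = c("t1", "t2", "t1"), row_index = c(1L, 3L, 2L)
  )
  precise <- tibble::tibble(rsid = "rs111111", phenotype = "LDL response",
                            table_id = "t1", row_index = 1L,
                            posterior = 0.9)
  recs <- assemble_associations("55", "cholesterol", precise,
                                character(), prel)
  r1 <- recs[recs$rsid == "rs111111", ]
  expect_equal(r1$p_value, 1.0e-6)
  expect_true(r1$significant)
  # exactly 1e-5 is NOT significant (strict inequality)
  r2 <- recs[recs$rsid == "rs222222", ]
  expect_false(r2$significant)
  # every reported p-value appears in its provenance rows
  for (i in seq_len(nrow(recs))) {
    expect_true(recs$p_value[i] %in% recs$provenance[[i]]$p_value)
  }
})

test_that("assembly is idempotent and order-independent", {
  prel <- tibble::tibble(
    rsid = c("rs222222", "rs111111", "rs111111"),
    p_value = c(2e-6, 0.03, 1e-6),
    table_id = "t1", row_index = c(3L, 2L, 1L)
  )
  precise <- tibble::tibble(rsid = c("rs111111", "rs222222"),
                            phenotype = c("LDL", "HDL"),
                            table_id = "t1", row_index = c(1L, 3L),
                            posterior = 0.9)
  a <- assemble_associations("1", "x", precise, character(), prel)
  b <- assemble_associations("1", "x", precise[2:1, ], character(),
                             prel[c(3, 1, 2), ])
  expect_equal(a, b)
})

test_that("the pipeline recovers planted associations end to end", {
  dict <- mini_dict()
  dir <- withr::local_tempdir()
  corp <- generate_corpus(
    corpus_config(n_papers = 10, distractor_rate = 0.2, seed = 33),
    dict, dir)
  recs <- extract_corpus(dir, dict)
  tk <- truth_keys(corp$truth)
  rk <- record_keys(recs)
  expect_gte(mean(tk %in% rk), 0.95)
  expect_gte(mean(rk %in% tk), 0.9)
  # simple phenotypes attach to every record of a document
  expect_true(all(nzchar(recs$simple_phenotypes)))
  # round-trip through the CSV writer
  path <- withr::local_tempfile(fileext = ".csv")
  write_associations(recs, path)
  back <- read_associations(path)
  expect_equal(nrow(back), nrow(recs))
  expect_equal(back$p_value, recs$p_value)
})
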