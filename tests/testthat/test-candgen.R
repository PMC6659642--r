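test_that("p-value normalization handles all three printed dialects", {
  # worked examples from published association tables
  expect_identical(normalize_pvalue("1.00E−06"), 1.0e-6)
  expect_identical(normalize_pvalue("5.00E−19"), 5.0e-19)
  expect_identical(normalize_pvalue("3.00E−06"), 3.0e-6)
  # typeset dialect: mantissa x 10^-k (hand-computed)
  expect_equal(normalize_pvalue("3.2 × 10−7"), 3.2e-7)
  expect_equal(normalize_pvalue("2.5×10−3"), 0.0025)
  # plain decimals and the (0, 1] boundary
  expect_identical(normalize_pvalue("0.5"), 0.5)
  expect_identical(normalize_pvalue("1"), 1.0)
  # comparator prefixes and ASCII typography tolerated
  expect_equal(normalize_pvalue("p < 5.0E-8"), 5e-8)
  expect_equal(normalize_pvalue("P = 0.03"), 0.03)
  expect_equal(normalize_pvalue("4.1 x 10-5"), 4.1e-5)
  expect_error(normalize_pvalue("not a number"), "cannot normalize")
})

test_that("rendering and normalization are mutually inverse on all dialects", {
  withr::with_seed(4, {
    for (dialect in c("e_notation", "typeset", "plain")) {
      for (rep in 1:20) {
        mant <- round(runif(1, 1, 9.9), 1)
        expo <- sample(2:12, 1)
        txt <- gwasminer:::render_pvalue(mant, expo, dialect,
                                         unicode = runif(1) < 0.5)
        expect_equal(normalize_pvalue(txt), mant * 10^-expo,
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("rsid candidates follow the word-bounded rs pattern", {
  xml <- paper_xml(
    title = "Variants rs12566888 and rs13130255 in versus text.",
    tables = table_xml(c("SNP", "P"), list(c("rs17661538", "1.00E−06"),
                                           c("rs0", "0.2")))
  )
  doc <- parse_document(xml)
  rsids <- find_rsids(doc)
  expect_setequal(rsids$text, c("rs12566888", "rs13130255", "rs17661538"))
  # "rs0" (leading zero, short) and "versus" (no word boundary) excluded
  expect_false(any(grepl("rs0$|versus", rsids$text)))
  # offsets index into their container text
  for (i in seq_len(nrow(rsids))) {
    txt <- gwasminer:::container_text(doc, rsids$container_id[i])
    expect_identical(substr(txt, rsids$start[i], rsids$end[i] - 1L),
                     rsids$text[i])
  }
})

test_that("p-value mentions carry normalized values and skip junk", {
  xml <- paper_xml(tables = table_xml(
    c("SNP", "Beta", "P"),
    list(c("rs123456", "12.3", "5.00E−19"),
         c("rs234567", "x", "3.2 × 10−7"),
         c("rs345678", "1.0E−", "0.5"))
  ))
  pv <- find_pvalues(parse_document(xml))
  expect_setequal(pv$value, c(5e-19, 3.2e-7, 0.5))
  # "12.3" (> 1) and the malformed "1.0E−" yield no mention
})

test_that("dictionary matching is longest-match with no surface stemming", {
  dict <- mini_dict()
  doc <- parse_document(paper_xml(
    title = "A GWAS of systolic blood pressure and platelet aggregation.",
    abstract = "We recruited bipolar patients for comparison."
  ))
  m <- find_phenotype_candidates(doc, dict)
  # nested term: only the longer "systolic blood pressure" is kept
  expect_true("systolic blood pressure" %in% m$dict_entry)
  expect_false("blood pressure" %in% m$dict_entry)
  expect_true("platelet aggregation" %in% m$dict_entry)
  # "bipolar patients" is not a surface match for "bipolar disorder"
  expect_false("bipolar disorder" %in% m$dict_entry)
  expect_error(find_phenotype_candidates(doc, dict[0, ]), "empty")
})

test_that("rsid/p-value relations pair only rows with exactly one rsid", {
  xml <- paper_xml(tables = table_xml(
    c("SNP", "MAF", "P"),
    list(c("rs111111", "0.2", "1.0E−6"),        # 2 p-value mentions
         c("rs111111 rs222222", "", "1.0E−6"),  # ambiguous: 2 rsids
         c("rs333333", "x", "y"))               # no p-value
  ))
  rels <- generate_rsid_pvalue_relations(parse_document(xml))
  expect_equal(nrow(rels), 2L)
  expect_true(all(rels$left_text == "rs111111"))
  expect_setequal(rels$right_value, c(0.2, 1e-6))
})

test_that("phenotype cells come from trait/phenotype/outcome columns only", {
  xml <- paper_xml(tables = list(
    table_xml(c("SNP", "Trait", "P"),
              list(c("rs17661538", "Clozapine—Triglycerides", "1.00E−06")),
              id = "t1"),
    table_xml(c("SNP", "Gene", "P"),
              list(c("rs999999", "ABCA1", "1.0E−7")), id = "t2"),
    table_xml(c("SNP", "Outcome (primary)", "P"),
              list(c("rs888888", "stroke", "2.0E−6")), id = "t3")
  ))
  rels <- generate_phenotype_pvalue_relations(parse_document(xml))
  expect_setequal(rels$left_text, c("Clozapine—Triglycerides", "stroke"))
  # "Gene" column yields nothing; "Outcome (primary)" matches by substring
  expect_false(any(rels$table_id == "t2"))
})

test_that("acronym candidates come from text patterns and labeled tables", {
  xml <- paper_xml(
    body = c("We measured body mass index (BMI) in adults.",
             "Enrollment began in (2019) as planned."),
    tables = table_xml(c("Abbreviation", "Description"),
                       list(c("funcPS", "functional protein S")),
                       id = "t1")
  )
  cands <- generate_acronym_candidates(parse_document(xml))
  txt <- cands[is.na(cands$table_id), ]
  expect_equal(txt$left_text, "BMI")
  expect_equal(txt$right_text, "body mass index")
  # digits-only parenthetical rejected
  expect_false(any(cands$left_text == "2019"))
  tab <- cands[!is.na(cands$table_id), ]
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$left_text, "funcPS")
  expect_equal(tab$right_text, "functional protein S")
})

test_that("transposed abbreviation tables are paired row-wise", {
  xml <- paper_xml(tables = paste0(
    "<table-wrap id=\"t1\"><table><tbody>",
    "<tr><td>Abbreviation</td><td>BMI</td><td>SBP</td></tr>",
    "<tr><td>Description</td><td>body mass index</td>",
    "<td>systolic blood pressure</td></tr>",
    "</tbody></table></table-wrap>"
  ))
  cands <- generate_acronym_candidates(parse_document(xml))
  expect_setequal(cands$left_text, c("BMI", "SBP"))
  expect_setequal(cands$right_text,
                  c("body mass index", "systolic blood pressure"))
})

test_that("every planted entity appears among candidates (recall by construction)", {
  dict <- mini_dict()
  corp <- generate_corpus(
    corpus_config(n_papers = 8, seed = 17, acronym_rate = 0.5),
    dict, withr::local_tempdir())
  docs <- lapply(corp$paths, parse_document)
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  for (pm in names(docs)) {
    doc <- docs[[pm]]
    tr <- corp$truth[corp$truth$pmid == pm, ]
    rsids <- find_rsids(doc)$text
    expect_true(all(tr$rsid %in% rsids))
    pvals <- find_pvalues(doc)$value
    expect_true(all(tr$p_value %in% pvals))
    simple <- find_phenotype_candidates(doc, dict)$dict_entry
    expect_true(unique(tr$simple_phenotype) %in% simple)
    acro <- generate_acronym_candidates(doc)
    amap <- corp$acronym_maps[[pm]]
    for (a in names(amap)) {
      hit <- acro$left_text == a & acro$right_text == amap[[a]]
      expect_true(any(hit), label = sprintf("acronym %s in %s", a, pm))
    }
    # mention offset invariant over all candidate mentions
    men <- dplyr::bind_rows(find_rsids(doc), find_pvalues(doc))
    for (i in seq_len(nrow(men))) {
      txt <- gwasminer:::container_text(doc, men$container_id[i])
      expect_gte(men$start[i], 1L)
      expect_lte(men$end[i], nchar(txt) + 1L)
      expect_identical(substr(txt, men$start[i], men$end[i] - 1L),
                       men$text[i])
    }
  }
})
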