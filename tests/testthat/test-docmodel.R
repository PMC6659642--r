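test_that("a title-only document parses to one title sentence and no tables", {
  doc <- parse_document(paper_xml(title = "A study of height."))
  expect_s3_class(doc, "gwas_document")
  expect_equal(doc$doc_id, "123")
  expect_equal(sum(doc$sentences$container == "title"), 1L)
  expect_length(doc$tables, 0L)
})

test_that("a missing title warns but the document is still accepted", {
  xml <- "<article><body><p>Some text here.</p></body></article>"
  expect_warning(doc <- parse_document(xml, doc_id = "d1"), "no <article-title>")
  expect_equal(sum(doc$sentences$container == "title"), 0L)
  expect_equal(sum(doc$sentences$container == "body"), 1L)
})

test_that("malformed XML raises a parse error", {
  expect_error(parse_document("<article><unclosed"), "parse error")
})

test_that("a spanning header is expanded over its full grid footprint", {
  # 3 rows x 4 cols; the 2-col header governs columns 2 and 3
  xml <- paper_xml(tables = paste0(
    "<table-wrap id=\"t1\"><table><thead><tr>",
    "<th>SNP</th><th colspan=\"2\">Discovery</th><th>Trait</th>",
    "</tr></thead><tbody>",
    "<tr><td>rs123456</td><td>0.1</td><td>0.2</td><td>height</td></tr>",
    "<tr><td>rs234567</td><td>0.3</td><td>0.4</td><td>height</td></tr>",
    "</tbody></table></table-wrap>"
  ))
  doc <- parse_document(xml)
  tab <- doc$tables[["t1"]]
  expect_equal(c(tab$n_rows, tab$n_cols), c(3L, 4L))
  # every one of the 12 grid positions maps to exactly one cell
  expect_false(any(is.na(tab$grid)))
  grid <- table_grid(tab)
  expect_equal(dim(grid), c(3L, 4L))
  # hand-constructed expectation for the header row
  expect_equal(grid[1, ], c("SNP", "Discovery", "Discovery", "Trait"))
  # the spanning header's text governs both columns it covers
  body <- tab$cells[!tab$cells$is_header, ]
  expect_equal(body$column_header_text[body$row == 1 & body$col == 1],
               "Discovery")
  expect_equal(body$column_header_text[body$row == 1 & body$col == 2],
               "Discovery")
  expect_equal(body$column_header_text[body$row == 1 & body$col == 3],
               "Trait")
})

test_that("random spanning tables always produce a complete grid", {
  withr::with_seed(99, {
    for (rep in 1:15) {
      nr <- sample(2:5, 1)
      nc <- sample(2:5, 1)
      # build rows left to right, occasionally spanning right/down
      rows_xml <- character()
      occupied <- matrix(FALSE, nr + 3, nc)
      for (r in seq_len(nr)) {
        cells <- character()
        cc <- 1L
        while (cc <= nc) {
          if (occupied[r, cc]) { cc <- cc + 1L; next }
          cs <- sample(1:min(2, nc - cc + 1L), 1)
          rs <- sample(1:2, 1)
          free <- all(!occupied[r:(r + rs - 1L), cc:(cc + cs - 1L)])
          if (!free) { cs <- 1L; rs <- 1L }
          occupied[r:(r + rs - 1L), cc:(cc + cs - 1L)] <- TRUE
          cells <- c(cells, sprintf(
            "<td rowspan=\"%d\" colspan=\"%d\">c%d-%d</td>", rs, cs, r, cc))
          cc <- cc + cs
        }
        rows_xml <- c(rows_xml, paste0("<tr>", paste(cells, collapse = ""),
                                       "</tr>"))
      }
      xml <- paper_xml(tables = paste0(
        "<table-wrap id=\"t1\"><table><tbody>",
        paste(rows_xml, collapse = ""), "</tbody></table></table-wrap>"))
      tab <- parse_document(xml)$tables[["t1"]]
      expect_false(any(is.na(tab$grid)))
      # each grid position covered by exactly one cell
      cover <- matrix(0L, tab$n_rows, tab$n_cols)
      for (i in seq_len(nrow(tab$cells))) {
        rr <- tab$cells$row[i] + seq_len(tab$cells$rowspan[i])
        cc2 <- tab$cells$col[i] + seq_len(tab$cells$colspan[i])
        cover[rr, cc2] <- cover[rr, cc2] + 1L
      }
      expect_true(all(cover[!is.na(tab$grid)] == 1L))
    }
  })
})

test_that("row_of returns horizontally aligned cells, honoring rowspans", {
  xml <- paper_xml(tables = paste0(
    "<table-wrap id=\"t1\"><table><tbody>",
    "<tr><td rowspan=\"2\">span</td><td>a1</td><td>a2</td></tr>",
    "<tr><td>b1</td><td>b2</td></tr>",
    "<tr><td>c0</td><td>c1</td><td>c2</td></tr>",
    "</tbody></table></table-wrap>"
  ))
  tab <- parse_document(xml)$tables[["t1"]]
  # single-row case: all three cells of row 2
  r2 <- row_of(tab, "t1:r2c0")
  expect_equal(r2$text, c("c0", "c1", "c2"))
  # the rowspan=2 neighbor is aligned with both of its rows
  expect_true("span" %in% row_of(tab, "t1:r0c1")$text)
  expect_true("span" %in% row_of(tab, "t1:r1c1")$text)
  expect_error(row_of(tab, "t1:r9c9"), "not part of table")
})

test_that("header-row cells align only with header cells", {
  xml <- paper_xml(tables = table_xml(c("SNP", "P"),
                                      list(c("rs123456", "0.01"))))
  tab <- parse_document(xml)$tables[["t1"]]
  hdr <- row_of(tab, tab$cells$cell_id[tab$cells$is_header][1])
  expect_true(all(hdr$is_header))
})

test_that("parsing is deterministic on identical bytes", {
  dict <- mini_dict()
  corp <- generate_corpus(corpus_config(n_papers = 2, seed = 5), dict,
                          withr::local_tempdir())
  for (p in corp$paths) {
    a <- docmodel_json(parse_document(p))
    b <- docmodel_json(parse_document(p))
    expect_identical(a, b)
  }
})

test_that("generated table shapes round-trip through the parser", {
  dict <- mini_dict()
  corp <- generate_corpus(
    corpus_config(n_papers = 6, seed = 21, acronym_rate = 0.6,
                  transposed_acronym_rate = 0.5),
    dict, withr::local_tempdir())
  parsed <- lapply(corp$paths, parse_document)
  names(parsed) <- vapply(parsed, `[[`, "", "doc_id")
  for (i in seq_len(nrow(corp$table_shapes))) {
    sh <- corp$table_shapes[i, ]
    tab <- parsed[[sh$pmid]]$tables[[sh$table_id]]
    expect_equal(tab$n_rows, sh$n_rows)
    expect_equal(tab$n_cols, sh$n_cols)
  }
})

test_that("tokens reconstruct their sentence and abbreviations survive splitting", {
  s <- "We studied BMI (e.g. in adults) vs. controls."
  toks <- tokenize_and_tag(s)
  rebuilt <- vapply(seq_len(nrow(toks)), function(i) {
    substr(s, toks$start[i], toks$end[i] - 1L)
  }, "")
  expect_equal(rebuilt, toks$token)
  # protected abbreviations do not split sentences
  parts <- gwasminer:::split_sentences(
    "We used rs123 (e.g. in Europeans). Results follow.")
  expect_length(parts, 2L)
  expect_match(parts[1], "e\\.g\\.")
})

test_that("noun tagging flags content words and skips function words", {
  toks <- tokenize_and_tag("Platelet aggregation")
  expect_equal(nrow(toks), 2L)
  expect_true(all(toks$is_noun))
  toks2 <- tokenize_and_tag("the of and")
  expect_equal(nrow(toks2), 3L)
  expect_false(any(toks2$is_noun))
  expect_equal(nrow(tokenize_and_tag("")), 0L)
})
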