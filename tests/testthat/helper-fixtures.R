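# Fixtures are built in code: small XML builders, the packaged
# mini-dictionary, and key helpers for diffing extraction output against
# synthetic-corpus ground truth.

mini_dict <- function() {
  read_dictionary(system.file("extdata", "phenotype_dictionary.tsv",
                              package = "gwasminer"))
}

# A minimal JATS-like paper around a list of tables (each a string of
# <table-wrap> XML) and optional body paragraphs.
paper_xml <- function(title = "A study.", abstract = character(),
                      body = character(), tables = character(),
                      pmid = "123") {
  paste0(
    "<article><front>",
    "<article-meta><article-id pub-id-type=\"pmid\">", pmid,
    "</article-id></article-meta>",
    if (!is.null(title)) paste0("<article-title>", title,
                                "</article-title>") else "",
    if (length(abstract)) paste0("<abstract><p>",
                                 paste(abstract, collapse = "</p><p>"),
                                 "</p></abstract>") else "",
    "</front><body>",
    if (length(body)) paste0("<p>", paste(body, collapse = "</p><p>"),
                             "</p>") else "",
    paste(tables, collapse = ""),
    "</body></article>"
  )
}

# <table-wrap> from a header character vector and a list of row vectors.
table_xml <- function(headers, rows, id = "t1") {
  paste0(
    "<table-wrap id=\"", id, "\"><table><thead><tr>",
    paste0("<th>", headers, "</th>", collapse = ""),
    "</tr></thead><tbody>",
    paste(vapply(rows, function(r) {
      paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
    }, ""), collapse = ""),
    "</tbody></table></table-wrap>"
  )
}

# Comparable keys for (pmid, rsid, resolved-or-precise phenotype, p-value)
# triples, used to diff extraction output against ground truth.
assoc_key <- function(df, phenotype) {
  paste(df$pmid, df$rsid, ifelse(is.na(phenotype), "<none>", phenotype),
        signif(df$p_value, 6))
}
truth_keys <- function(truth) {
  assoc_key(truth, ifelse(is.na(truth$resolved_phenotype),
                          truth$precise_phenotype,
                          truth$resolved_phenotype))
}
record_keys <- function(recs) {
  assoc_key(recs, ifelse(is.na(recs$resolved_phenotype),
                         recs$precise_phenotype,
                         recs$resolved_phenotype))
}

# Independent oracle for the label-model posterior: explicit enumeration of
# the joint over the latent label, written directly from the generative
# story (abstain with prob 1-beta; vote agrees with y with prob alpha).
brute_posterior <- function(row, alpha, beta, pi) {
  joint <- function(y) {
    p <- if (y == 1L) pi else 1 - pi
    for (j in seq_along(row)) {
      p <- p * if (row[j] == 0L) {
        1 - beta[j]
      } else if (row[j] == y) {
        beta[j] * alpha[j]
      } else {
        beta[j] * (1 - alpha[j])
      }
    }
    p
  }
  joint(1L) / (joint(1L) + joint(-1L))
}
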