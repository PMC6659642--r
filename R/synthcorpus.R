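# Synthetic JATS-like corpus with ground truth.
#
# The generator emulates the structural features of open-access GWAS
# publications that the pipeline keys on: a title and abstract mentioning a
# dictionary phenotype, association tables with an rsid column, a
# trait/phenotype/outcome column and a p-value column rendered in one of
# three typographic dialects, acronym-definition tables (optionally
# transposed), acronym definitions in running text, and distractor rows
# modeled on documented real-world failure modes (several rsids in one row,
# p-values attached to haplotypes, malformed numbers, numeric junk in the
# trait column). Every paper ships with a ground-truth sidecar, so
# end-to-end recall and precision are measurable without any downloads.

ACRONYM_POOL <- list(
  c("body mass index", "BMI"),
  c("high density lipoprotein", "HDL"),
  c("low density lipoprotein", "LDL"),
  c("systolic blood pressure", "SBP"),
  c("diastolic blood pressure", "DBP"),
  c("fasting plasma glucose", "FPG"),
  c("waist hip ratio", "WHR"),
  c("bone mineral density", "BMD"),
  c("forced expiratory volume", "FEV"),
  c("total cholesterol level", "TCL")
)

PVALUE_DIALECTS <- c("e_notation", "typeset", "plain")

#' Configuration for the synthetic corpus generator
#'
#' @param n_papers Number of papers to generate.
#' @param rows_per_table Integer range (min, max) of true association rows
#'   per table.
#' @param dialect_weights Named weights over the three p-value dialects
#'   `e_notation`, `typeset`, `plain`.
#' @param distractor_rate Expected fraction of additional distractor rows
#'   per true row, in `[0, 1]`.
#' @param acronym_rate Probability that a row's precise phenotype is written
#'   as an acronym (with a definition planted elsewhere in the paper).
#' @param transposed_acronym_rate Probability that an acronym-definition
#'   table is transposed (row-label headers instead of column headers).
#' @param unresolvable_rate Probability that a planted acronym has no
#'   definition anywhere in the paper (kept verbatim in the truth).
#' @param missing_phenotype_rate Probability that a row has no precise
#'   phenotype (a dash cell).
#' @param unicode_rate Probability that typographic unicode (multiplication
#'   sign, U+2212 minus) is used when rendering a p-value.
#' @param seed Integer seed fixing all randomness of the generator.
#' @return A `corpus_config` list.
#' @export
corpus_config <- function(n_papers = 50L,
                          rows_per_table = c(4L, 10L),
                          dialect_weights = c(e_notation = 1, typeset = 1,
                                              plain = 1),
                          distractor_rate = 0,
                          acronym_rate = 0.3,
                          transposed_acronym_rate = 0.2,
                          unresolvable_rate = 0.1,
                          missing_phenotype_rate = 0.15,
                          unicode_rate = 0.5,
                          seed = 42L) {
  stopifnot(
    n_papers >= 1L, length(rows_per_table) == 2L,
    rows_per_table[1] >= 1L, rows_per_table[2] >= rows_per_table[1],
    all(dialect_weights >= 0), sum(dialect_weights) > 0,
    distractor_rate >= 0, distractor_rate <= 1,
    acronym_rate >= 0, acronym_rate <= 1,
    transposed_acronym_rate >= 0, transposed_acronym_rate <= 1,
    unresolvable_rate >= 0, unresolvable_rate <= 1,
    missing_phenotype_rate >= 0, missing_phenotype_rate <= 1,
    unicode_rate >= 0, unicode_rate <= 1
  )
  if (is.null(names(dialect_weights))) {
    names(dialect_weights) <- PVALUE_DIALECTS
  }
  structure(
    list(n_papers = as.integer(n_papers),
         rows_per_table = as.integer(rows_per_table),
         dialect_weights = dialect_weights[PVALUE_DIALECTS],
         distractor_rate = distractor_rate,
         acronym_rate = acronym_rate,
         transposed_acronym_rate = transposed_acronym_rate,
         unresolvable_rate = unresolvable_rate,
         missing_phenotype_rate = missing_phenotype_rate,
         unicode_rate = unicode_rate,
         seed = as.integer(seed)),
    class = "corpus_config"
  )
}

# Render a p-value with given mantissa (1 decimal or 2) and exponent in one
# of the three dialects. The ground-truth numeric value is defined as
# normalize_pvalue(render), so rendering and normalization are closed by
# construction.
render_pvalue <- function(mantissa, exponent, dialect, unicode = TRUE) {
  minus <- if (unicode) "−" else "-"
  times <- if (unicode) " × " else " x "
  switch(
    dialect,
    e_notation = sprintf("%.2fE%s%02d", mantissa, minus, exponent),
    typeset = sprintf("%.1f%s10%s%d", mantissa, times, minus, exponent),
    plain = {
      digits <- gsub("\\.", "", sprintf("%.1f", mantissa))
      digits <- sub("0+$", "", digits)
      if (!nzchar(digits)) digits <- "0"
      paste0("0.", strrep("0", exponent - 1L), digits)
    },
    stop("unknown p-value dialect: ", dialect)
  )
}

sample_weighted <- function(choices, weights) {
  choices[sample.int(length(choices), 1L, prob = weights)]
}

# One paper: returns list(xml = string, truth = list(...))
generate_paper <- function(pmid, cfg, dictionary, rsid_pool) {
  simple <- sample(dictionary$term, 1L)
  canonical <- dictionary$canonical[match(simple, dictionary$term)]
  n_rows <- sample(seq(cfg$rows_per_table[1], cfg$rows_per_table[2]), 1L)

  trait_header <- sample(c("Trait", "Phenotype", "Outcome"), 1L)
  snp_header <- sample(c("SNP", "Variant", "SNP ID"), 1L)
  p_header <- sample(c("P-value", "P value", "P"), 1L)

  acro_defs <- list()      # (expansion, acronym, where: table|text)
  acro_unresolvable <- list()
  truth_rows <- list()
  body_rows <- list()      # character vectors of 3 cells

  mantissas <- round(runif(n_rows, 1.0, 9.9), 1)
  exponents <- sample(6:12, n_rows, replace = TRUE)
  # a few non-significant rows exercise the significance flag
  weak <- runif(n_rows) < 0.2
  exponents[weak] <- sample(2:4, sum(weak), replace = TRUE)

  used_rsids <- sample(rsid_pool, n_rows + 4L)
  for (r in seq_len(n_rows)) {
    rsid <- used_rsids[r]
    dialect <- sample_weighted(PVALUE_DIALECTS, cfg$dialect_weights)
    ptext <- render_pvalue(mantissas[r], exponents[r], dialect,
                           unicode = runif(1) < cfg$unicode_rate)
    pval <- normalize_pvalue(ptext)

    precise <- NA_character_
    resolved <- NA_character_
    if (runif(1) >= cfg$missing_phenotype_rate) {
      if (runif(1) < cfg$acronym_rate) {
        pair <- ACRONYM_POOL[[sample.int(length(ACRONYM_POOL), 1L)]]
        precise <- pair[2]
        # resolvability is decided once per acronym per paper so the truth
        # stays consistent when an acronym recurs across rows
        planted <- vapply(acro_defs, function(d) d$acronym, "")
        if (pair[2] %in% names(acro_unresolvable)) {
          resolved <- NA_character_
        } else if (pair[2] %in% planted) {
          resolved <- pair[1]
        } else if (runif(1) < cfg$unresolvable_rate) {
          acro_unresolvable[[pair[2]]] <- TRUE
          resolved <- NA_character_   # no definition planted: kept verbatim
        } else {
          resolved <- pair[1]
          where <- if (runif(1) < 0.5) "table" else "text"
          acro_defs[[length(acro_defs) + 1L]] <-
            list(expansion = pair[1], acronym = pair[2], where = where)
        }
      } else {
        noun <- sample(c("levels", "response", "ratio", "concentration"), 1L)
        precise <- paste("Serum", canonical, noun)
      }
    }
    cell <- if (is.na(precise)) "–" else precise
    body_rows[[length(body_rows) + 1L]] <- c(rsid, cell, ptext)
    truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
      pmid = pmid, rsid = rsid, precise_phenotype = precise,
      resolved_phenotype = resolved, p_value = pval,
      table_id = "tbl1", row = length(body_rows)   # grid row (0-based: +hdr)
    )
  }

  # distractor rows, appended after the true rows
  n_distract <- rbinom(1L, n_rows, cfg$distractor_rate)
  extra_rsids <- used_rsids[n_rows + seq_len(4L)]
  if (n_distract > 0) {
    for (d in seq_len(n_distract)) {
      type <- sample(c("multi_rsid", "haplotype", "junk_pheno", "malformed"),
                     1L)
      dialect <- sample_weighted(PVALUE_DIALECTS, cfg$dialect_weights)
      ptext <- render_pvalue(round(runif(1, 1, 9.9), 1),
                             sample(6:9, 1L), dialect,
                             unicode = runif(1) < cfg$unicode_rate)
      row <- switch(
        type,
        multi_rsid = c(paste(extra_rsids[1], extra_rsids[2]),
                       paste("Serum", canonical, "levels"), ptext),
        haplotype = c(paste0(paste(sample(c("A", "C", "G", "T"), 4L,
                                          replace = TRUE), collapse = ""),
                             " haplotype"),
                      paste("Serum", canonical, "levels"), ptext),
        junk_pheno = {
          rsid <- extra_rsids[3L + (d %% 2L)]
          pval <- normalize_pvalue(ptext)
          # a real association whose trait cell is numeric junk: the truth
          # is (rsid, no phenotype, p); a pipeline that accepts the junk
          # trait emits a wrong record
          truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
            pmid = pmid, rsid = rsid, precise_phenotype = NA_character_,
            resolved_phenotype = NA_character_, p_value = pval,
            table_id = "tbl1", row = length(body_rows) + 1L
          )
          c(rsid, sprintf("%.2f", runif(1, 1, 99)), ptext)
        },
        malformed = c(extra_rsids[4], paste("Serum", canonical, "levels"),
                      "1.0E−")
      )
      body_rows[[length(body_rows) + 1L]] <- row
    }
  }

  # assemble XML
  title <- sprintf(
    "A genome-wide association study of %s in a population cohort.", simple
  )
  abstract <- sprintf(
    paste0("We performed a genome-wide association study of %s. ",
           "We identified %d loci associated with %s."),
    simple, n_rows, simple
  )
  text_defs <- Filter(function(d) d$where == "text", acro_defs)
  table_defs <- Filter(function(d) d$where == "table", acro_defs)
  body_par <- paste0(
    "Genotyping was performed on a standard array platform. ",
    paste(vapply(text_defs, function(d) {
      sprintf("We measured %s (%s) in all participants.",
              d$expansion, d$acronym)
    }, ""), collapse = " ")
  )

  assoc_rows_xml <- vapply(body_rows, function(cells) {
    paste0("<tr>",
           paste0("<td>", xml_escape(cells), "</td>", collapse = ""),
           "</tr>")
  }, "")
  assoc_table <- paste0(
    "<table-wrap id=\"tbl1\"><table><thead><tr>",
    sprintf("<th>%s</th><th>%s</th><th>%s</th>",
            snp_header, trait_header, p_header),
    "</tr></thead><tbody>",
    paste(assoc_rows_xml, collapse = ""),
    "</tbody></table></table-wrap>"
  )

  acro_table <- ""
  acronym_truth <- list()
  for (d in c(table_defs, text_defs)) {
    acronym_truth[[d$acronym]] <- d$expansion
  }
  if (length(table_defs)) {
    defs <- unique(do.call(rbind, lapply(table_defs, function(d) {
      c(d$acronym, d$expansion)
    })))
    if (runif(1) < cfg$transposed_acronym_rate) {
      acro_table <- paste0(
        "<table-wrap id=\"tbl2\"><table><tbody>",
        "<tr><td>Abbreviation</td>",
        paste0("<td>", xml_escape(defs[, 1]), "</td>", collapse = ""),
        "</tr><tr><td>Description</td>",
        paste0("<td>", xml_escape(defs[, 2]), "</td>", collapse = ""),
        "</tr></tbody></table></table-wrap>"
      )
    } else {
      acro_table <- paste0(
        "<table-wrap id=\"tbl2\"><table><thead><tr>",
        "<th>Abbreviation</th><th>Description</th></tr></thead><tbody>",
        paste0("<tr><td>", xml_escape(defs[, 1]), "</td><td>",
               xml_escape(defs[, 2]), "</td></tr>", collapse = ""),
        "</tbody></table></table-wrap>"
      )
    }
  }

  xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<article><front>",
    "<article-meta><article-id pub-id-type=\"pmid\">", pmid,
    "</article-id></article-meta>",
    "<article-title>", xml_escape(title), "</article-title>",
    "<abstract><p>", xml_escape(abstract), "</p></abstract>",
    "</front><body>",
    "<p>", xml_escape(body_par), "</p>",
    assoc_table, acro_table,
    "</body></article>"
  )

  truth <- dplyr::bind_rows(truth_rows)
  truth$simple_phenotype <- canonical
  # grid row of each table line: +1 for the header row
  truth$row <- truth$row
  n_assoc_rows <- length(body_rows)
  shapes <- tibble::tibble(
    table_id = "tbl1", n_rows = n_assoc_rows + 1L, n_cols = 3L
  )
  if (nzchar(acro_table)) {
    defs_n <- nrow(unique(do.call(rbind, lapply(table_defs, function(d) {
      c(d$acronym, d$expansion)
    }))))
    tr <- grepl("<td>Abbreviation</td>", acro_table, fixed = TRUE)
    shapes <- dplyr::bind_rows(shapes, tibble::tibble(
      table_id = "tbl2",
      n_rows = if (tr) 2L else defs_n + 1L,
      n_cols = if (tr) defs_n + 1L else 2L
    ))
  }
  list(xml = xml, truth = truth, acronym_map = acronym_truth,
       simple_phenotype = canonical, table_shapes = shapes)
}

#' Generate a synthetic corpus with ground truth
#'
#' Writes one JATS-like XML file per paper to `dir`, plus a
#' `ground_truth.json` sidecar and a `ground_truth.csv` in the same schema
#' as [extract_corpus()] output, for direct diffing. Generation is fully
#' deterministic given `config$seed` (the caller's RNG state is untouched).
#'
#' @param config A [corpus_config()].
#' @param dictionary A `gwas_dictionary`; planted simple phenotypes are
#'   drawn from it.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (XML files), `truth` (association
#'   tibble: `pmid`, `rsid`, `precise_phenotype`, `resolved_phenotype`,
#'   `p_value`, `table_id`, `row`, `simple_phenotype`), `acronym_maps`,
#'   `table_shapes`, and the `config`.
#' @export
generate_corpus <- function(config, dictionary, dir) {
  stopifnot(inherits(config, "corpus_config"))
  if (!nrow(dictionary)) stop("empty phenotype dictionary")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- with_seed(config$seed, {
    rsid_pool <- sprintf("rs%d", sample(100000:99999999,
                                        config$n_papers * 40L))
    rsid_pool <- unique(rsid_pool)
    papers <- vector("list", config$n_papers)
    for (i in seq_len(config$n_papers)) {
      pmid <- sprintf("%d", 10000000L + i)
      pool_i <- rsid_pool[((i - 1L) * 30L + 1L):(i * 30L)]
      papers[[i]] <- c(list(pmid = pmid),
                       generate_paper(pmid, config, dictionary, pool_i))
    }
    papers
  })
  paths <- character()
  truth <- list()
  acro <- list()
  shapes <- list()
  for (p in out) {
    path <- file.path(dir, paste0("PMC", p$pmid, ".xml"))
    writeLines(p$xml, path, useBytes = FALSE)
    paths <- c(paths, path)
    truth[[p$pmid]] <- p$truth
    acro[[p$pmid]] <- p$acronym_map
    shapes[[p$pmid]] <- dplyr::mutate(p$table_shapes, pmid = p$pmid)
  }
  truth_df <- dplyr::bind_rows(truth)
  shapes_df <- dplyr::bind_rows(shapes)
  jsonlite::write_json(
    list(truth = truth_df, acronym_maps = acro, table_shapes = shapes_df),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  truth_csv <- dplyr::mutate(
    truth_df,
    simple_phenotypes = .data$simple_phenotype,
    significant = .data$p_value < 1e-5
  )
  write.csv(truth_csv[, c("pmid", "rsid", "simple_phenotypes",
                          "precise_phenotype", "resolved_phenotype",
                          "p_value", "significant", "table_id", "row")],
            file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(list(paths = paths, truth = truth_df, acronym_maps = acro,
                 table_shapes = shapes_df, config = config))
}

#' Simulate a label matrix from known model parameters
#'
#' Draws latent labels `y_i` from the class prior, then each LF votes with
#' probability `betas[j]`; a vote agrees with `y_i` with probability
#' `alphas[j]` and is flipped otherwise. Used for parameter-recovery checks
#' of [fit_label_model()].
#'
#' @param n Number of candidates.
#' @param alphas,betas Per-LF accuracies and vote propensities in (0, 1).
#' @param pi Class prior `P(y = +1)` in (0, 1).
#' @param seed Integer seed.
#' @return A list with `L` (n x m label matrix) and `y` (true labels in
#'   \{-1, +1\}).
#' @export
simulate_label_matrix <- function(n, alphas, betas, pi = 0.5, seed = 1L) {
  stopifnot(length(alphas) == length(betas),
            all(alphas > 0 & alphas < 1), all(betas > 0 & betas < 1),
            pi > 0, pi < 1)
  m <- length(alphas)
  with_seed(as.integer(seed), {
    y <- ifelse(runif(n) < pi, 1L, -1L)
    L <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      votes <- runif(n) < betas[j]
      agree <- runif(n) < alphas[j]
      L[votes, j] <- ifelse(agree[votes], y[votes], -y[votes])
    }
    list(L = L, y = y)
  })
}
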