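# The five pipeline components: simple phenotypes, precise phenotypes,
# acronym resolution, rsid/p-value relations, and database assembly.
#
# The first three are classified (labeling functions + generative label
# model); p-value relations are rule-based and reported in full. When a
# corpus is processed, candidates of each kind are pooled across documents
# and a single label model per kind is fit, mirroring how the model is
# meant to be trained: on a large unlabeled candidate set.

#' Pipeline configuration
#'
#' @param threshold Posterior acceptance threshold in (0, 1), strict.
#' @param sig_threshold Significance threshold on the p-value (an
#'   association is flagged significant when some p-value is strictly below
#'   it; default `1e-5`).
#' @param long_header Header-length threshold handed to [builtin_lfs()].
#' @return A named list of settings.
#' @export
pipeline_config <- function(threshold = 0.5, sig_threshold = 1e-5,
                            long_header = 30L) {
  stopifnot(threshold > 0, threshold < 1, sig_threshold > 0,
            sig_threshold <= 1)
  list(threshold = threshold, sig_threshold = sig_threshold,
       long_header = long_header)
}

# Fit a label model for one candidate kind. Below a minimum candidate
# count the accuracies are unidentifiable from the unlabeled matrix (EM
# drifts onto the flat ridge alpha = pi where every posterior collapses to
# ~0.5), so small inputs are scored with the fixed prior parameterization
# (alpha = 0.7, pi = 0.5) instead of a fit; posteriors depend only on
# alpha and pi, the propensities cancel.
fit_kind_model <- function(L, init_alpha = 0.7, min_candidates = 20L) {
  if (nrow(L) < min_candidates) {
    return(label_model_params(rep(init_alpha, ncol(L)),
                              rep(0.5, ncol(L)), 0.5))
  }
  suppressWarnings(fit_label_model(L))
}

#' Extract the simple (paper-level) phenotypes of a document
#'
#' Dictionary candidates from the title and abstract are scored by the
#' label model over the simple-phenotype labeling functions. The result is
#' the up-to-three distinct highest-scoring mentions above the acceptance
#' threshold, or the single highest-scoring mention if none clears it;
#' empty only when there are no candidates at all.
#'
#' @param doc A `gwas_document`.
#' @param dictionary A `gwas_dictionary`.
#' @param config A [pipeline_config()].
#' @param model Optional pre-fit `gwas_label_model` for this kind (one is
#'   fit on the document's own candidates when `NULL`).
#' @return A character vector of 0-3 canonical phenotype names.
#' @export
extract_simple_phenotypes <- function(doc, dictionary,
                                      config = pipeline_config(),
                                      model = NULL) {
  cands <- find_phenotype_candidates(doc, dictionary)
  if (!nrow(cands)) return(character())
  lfs <- builtin_lfs("simple_phenotype")
  L <- apply_lfs(cands, lfs, docs = doc, dictionary = dictionary)
  if (is.null(model)) model <- fit_kind_model(L)
  post <- posterior_labels(model, L)
  # one score per distinct canonical phenotype: its best-scoring mention
  scored <- tibble::tibble(phenotype = cands$dict_entry, posterior = post)
  scored <- dplyr::summarise(
    dplyr::group_by(scored, .data$phenotype),
    posterior = max(.data$posterior), .groups = "drop"
  )
  scored <- dplyr::arrange(scored, dplyr::desc(.data$posterior),
                           .data$phenotype)
  above <- scored[scored$posterior > config$threshold, ]
  if (nrow(above)) head(above$phenotype, 3L) else scored$phenotype[1]
}

#' Extract precise (variant-level) phenotypes from tables
#'
#' Phenotype-cell / p-value candidate relations are scored by the label
#' model over the precise-phenotype labeling functions; accepted phenotype
#' cells are joined to the single rsid of their table row. Rows without an
#' rsid (or with several) yield nothing.
#'
#' @inheritParams extract_simple_phenotypes
#' @return A tibble with `rsid`, `phenotype`, `table_id`, `row_index`,
#'   `posterior`.
#' @export
extract_precise_phenotypes <- function(doc, config = pipeline_config(),
                                       model = NULL, dictionary = NULL) {
  rels <- generate_phenotype_pvalue_relations(doc)
  empty <- tibble::tibble(rsid = character(), phenotype = character(),
                          table_id = character(), row_index = integer(),
                          posterior = numeric())
  if (!nrow(rels)) return(empty)
  lfs <- builtin_lfs("precise_phenotype", long_header = config$long_header)
  L <- apply_lfs(rels, lfs, docs = doc, dictionary = dictionary)
  if (is.null(model)) model <- fit_kind_model(L)
  rels$posterior <- posterior_labels(model, L)
  accepted <- rels[rels$posterior > config$threshold, ]
  if (!nrow(accepted)) return(empty)
  # join each accepted phenotype cell to the unique rsid of its row
  rsids <- find_rsids(doc)
  out <- list()
  for (i in seq_len(nrow(accepted))) {
    tab <- doc$tables[[accepted$table_id[i]]]
    cell_i <- match(accepted$left_container[i], tab$cells$cell_id)
    rows_i <- cell_rows(tab, cell_i)
    rm <- mentions_by_grid_row(tab, rsids)
    if (is.null(rm)) next
    in_row <- which(vapply(rm$rows, function(x) any(x %in% rows_i), TRUE))
    if (length(in_row) != 1L) next
    out[[length(out) + 1L]] <- tibble::tibble(
      rsid = rm$mention$text[in_row],
      phenotype = accepted$left_text[i],
      table_id = accepted$table_id[i],
      row_index = accepted$row_index[i],
      posterior = accepted$posterior[i]
    )
  }
  if (!length(out)) return(empty)
  dplyr::distinct(dplyr::bind_rows(out))
}

#' Resolve phenotype acronyms across a whole document
#'
#' Acronym/expansion candidate pairs (from running text and from
#' definition tables) are scored by the label model over the acronym
#' labeling functions. Accepted pairs form the per-document acronym map;
#' when two expansions compete for one acronym the higher-posterior pair
#' wins (ties break lexicographically for determinism).
#'
#' @inheritParams extract_simple_phenotypes
#' @return A named character vector: `map["BMI"] == "body mass index"`.
#' @export
resolve_acronyms <- function(doc, config = pipeline_config(), model = NULL,
                             dictionary = NULL) {
  cands <- generate_acronym_candidates(doc)
  if (!nrow(cands)) return(stats::setNames(character(), character()))
  lfs <- builtin_lfs("acronym")
  L <- apply_lfs(cands, lfs, docs = doc, dictionary = dictionary)
  if (is.null(model)) model <- fit_kind_model(L)
  cands$posterior <- posterior_labels(model, L)
  accepted <- cands[cands$posterior > config$threshold, ]
  if (!nrow(accepted)) return(stats::setNames(character(), character()))
  accepted <- dplyr::arrange(accepted, .data$left_text,
                             dplyr::desc(.data$posterior), .data$right_text)
  best <- accepted[!duplicated(accepted$left_text), ]
  stats::setNames(best$right_text, best$left_text)
}

# Whole-token acronym replacement; case-sensitive on the acronym side.
apply_acronym_map <- function(phenotype, acronym_map) {
  if (is.na(phenotype) || !length(acronym_map)) return(NA_character_)
  toks <- tokenize_and_tag(phenotype)
  if (!nrow(toks)) return(NA_character_)
  hit <- toks$token %in% names(acronym_map)
  if (!any(hit)) return(NA_character_)
  out <- phenotype
  # replace right-to-left so recorded offsets stay valid
  for (i in rev(which(hit))) {
    repl <- unname(acronym_map[toks$token[i]])
    out <- paste0(substr(out, 1, toks$start[i] - 1L), repl,
                  substring(out, toks$end[i]))
  }
  out
}

#' Extract all rsid / p-value relations of a document
#'
#' The rule-based component: every horizontally aligned (rsid, p-value)
#' pair from rows with exactly one rsid is reported, without
#' classification.
#'
#' @param doc A `gwas_document`.
#' @return A tibble with `rsid`, `p_value`, `table_id`, `row_index`.
#' @export
extract_pvalue_relations <- function(doc) {
  rels <- generate_rsid_pvalue_relations(doc)
  tibble::tibble(
    rsid = rels$left_text, p_value = rels$right_value,
    table_id = rels$table_id, row_index = rels$row_index
  )
}

#' Assemble association records for one document
#'
#' The fifth component: one record per distinct (rsid, resolved-or-precise
#' phenotype), carrying the minimum p-value over all the rsid's table rows,
#' the full provenance list, a significance flag (some p-value strictly
#' below `sig_threshold`), and the document's simple phenotypes. Assembly
#' is idempotent and order-independent: outputs are sorted by rsid and
#' phenotype.
#'
#' @param doc_id Publication identifier.
#' @param simple Character vector of simple phenotypes (joined with `|`).
#' @param precise Tibble from [extract_precise_phenotypes()].
#' @param acronym_map Named vector from [resolve_acronyms()].
#' @param pvalue_relations Tibble from [extract_pvalue_relations()].
#' @param config A [pipeline_config()].
#' @return An association tibble with columns `pmid`, `rsid`,
#'   `simple_phenotypes`, `precise_phenotype`, `resolved_phenotype`,
#'   `p_value`, `significant`, `table_id`, `row_index`, `provenance`
#'   (list-column of per-row `table_id`/`row_index`).
#' @export
assemble_associations <- function(doc_id, simple, precise, acronym_map,
                                  pvalue_relations,
                                  config = pipeline_config()) {
  empty <- tibble::tibble(
    pmid = character(), rsid = character(), simple_phenotypes = character(),
    precise_phenotype = character(), resolved_phenotype = character(),
    p_value = numeric(), significant = logical(), table_id = character(),
    row_index = integer(), provenance = list()
  )
  if (!nrow(pvalue_relations)) return(empty)
  simple_str <- paste(simple, collapse = "|")
  recs <- list()
  for (rs in sort(unique(pvalue_relations$rsid))) {
    prel <- pvalue_relations[pvalue_relations$rsid == rs, ]
    prel <- dplyr::arrange(prel, .data$p_value, .data$table_id,
                           .data$row_index)
    phens <- character()
    if (nrow(precise)) {
      phens <- sort(unique(precise$phenotype[precise$rsid == rs]))
    }
    if (!length(phens)) phens <- NA_character_
    for (ph in phens) {
      resolved <- if (is.na(ph)) NA_character_ else
        apply_acronym_map(ph, acronym_map)
      recs[[length(recs) + 1L]] <- tibble::tibble(
        pmid = doc_id, rsid = rs, simple_phenotypes = simple_str,
        precise_phenotype = ph, resolved_phenotype = resolved,
        p_value = min(prel$p_value),
        significant = any(prel$p_value < config$sig_threshold),
        table_id = prel$table_id[1], row_index = prel$row_index[1],
        provenance = list(prel[, c("table_id", "row_index", "p_value")])
      )
    }
  }
  out <- dplyr::bind_rows(recs)
  dplyr::arrange(out, .data$rsid, .data$precise_phenotype)
}

#' Extract the association records of a single document
#'
#' Runs all five components on one parsed document. For corpus-level
#' processing prefer [extract_corpus()], which pools candidates across
#' documents before fitting the label models.
#'
#' @param doc A `gwas_document`.
#' @param dictionary A `gwas_dictionary`.
#' @param config A [pipeline_config()].
#' @param models Optional named list of pre-fit label models
#'   (`simple_phenotype`, `precise_phenotype`, `acronym`).
#' @return An association tibble (see [assemble_associations()]).
#' @export
extract_associations <- function(doc, dictionary,
                                 config = pipeline_config(),
                                 models = list()) {
  simple <- extract_simple_phenotypes(doc, dictionary, config,
                                      model = models$simple_phenotype)
  precise <- extract_precise_phenotypes(doc, config,
                                        model = models$precise_phenotype,
                                        dictionary = dictionary)
  acromap <- resolve_acronyms(doc, config, model = models$acronym,
                              dictionary = dictionary)
  prel <- extract_pvalue_relations(doc)
  assemble_associations(doc$doc_id, simple, precise, acromap, prel, config)
}

#' Extract associations from a corpus of XML files
#'
#' Parses every XML file, pools candidates of each classified kind across
#' all documents, fits one label model per kind on the pooled (unlabeled)
#' label matrix, and assembles per-document association records.
#'
#' @param paths A directory containing `.xml`/`.nxml` files, or a character
#'   vector of file paths.
#' @param dictionary A `gwas_dictionary`.
#' @param config A [pipeline_config()].
#' @return An association tibble over all documents.
#' @export
extract_corpus <- function(paths, dictionary, config = pipeline_config()) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(xml|nxml)$",
                        full.names = TRUE)
  }
  if (!length(paths)) stop("no XML files to process")
  docs <- lapply(sort(paths), parse_document)
  names(docs) <- vapply(docs, `[[`, "", "doc_id")

  pool <- function(fn) {
    dplyr::bind_rows(lapply(docs, fn))
  }
  simple_cands <- pool(function(d) find_phenotype_candidates(d, dictionary))
  precise_cands <- pool(generate_phenotype_pvalue_relations)
  acro_cands <- pool(generate_acronym_candidates)

  lfs_s <- builtin_lfs("simple_phenotype")
  lfs_p <- builtin_lfs("precise_phenotype",
                       long_header = config$long_header)
  lfs_a <- builtin_lfs("acronym")
  models <- list(
    simple_phenotype = fit_kind_model(
      apply_lfs(simple_cands, lfs_s, docs, dictionary)),
    precise_phenotype = fit_kind_model(
      apply_lfs(precise_cands, lfs_p, docs, dictionary)),
    acronym = fit_kind_model(
      apply_lfs(acro_cands, lfs_a, docs, dictionary))
  )
  out <- lapply(docs, extract_associations, dictionary = dictionary,
                config = config, models = models)
  dplyr::bind_rows(out)
}

#' Write association records to CSV
#'
#' Flattens the provenance list-column to the shape of the published
#' output: one row per record with the `table_id`/`row_index` of its
#' minimum p-value.
#'
#' @param records An association tibble.
#' @param path Output CSV path.
#' @export
write_associations <- function(records, path) {
  flat <- records[, setdiff(names(records), "provenance")]
  write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' Read association records written by [write_associations()]
#'
#' @param path CSV path.
#' @return An association tibble (without the provenance list-column).
#' @export
read_associations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(pmid = "character"))
  tibble::as_tibble(df)
}
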