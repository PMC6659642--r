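# High-recall candidate generation.
#
# Candidates are generated with regular expressions and dictionary scans,
# erring on the side of recall; the labeling-function + label-model stage
# decides which are correct. Mentions are located spans (document id,
# container id, half-open character offsets) with a role tag; relations are
# ordered pairs of mentions with table/row provenance.

# rsid: "rs" + at least three digits, no leading zero, word-bounded.
RE_RSID <- "\\brs[1-9][0-9]{2,}\\b"

# All containers of a document (sentences + table cells) as id/text pairs.
doc_containers <- function(doc) {
  s <- doc$sentences
  cont <- tibble::tibble(container_id = s$sent_id, text = s$text)
  for (tab in doc$tables) {
    cont <- dplyr::bind_rows(cont, tibble::tibble(
      container_id = tab$cells$cell_id, text = tab$cells$text
    ))
  }
  cont
}

#' Find rsid mentions in a document
#'
#' Scans every sentence and table cell for Reference SNP cluster IDs: `rs`
#' followed by three or more digits with no leading zero, word-bounded,
#' case-insensitive. Matches are maximal and never overlap.
#'
#' @param doc A `gwas_document` from [parse_document()].
#' @return A mention tibble (`doc_id`, `container_id`, `start`, `end`,
#'   `text`, `role = "rsid"`).
#' @export
find_rsids <- function(doc) {
  stopifnot(inherits(doc, "gwas_document"))
  cont <- doc_containers(doc)
  out <- list()
  for (i in seq_len(nrow(cont))) {
    m <- gregexpr(RE_RSID, cont$text[i], perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    st <- as.integer(m)
    len <- attr(m, "match.length")
    out[[length(out) + 1L]] <- tibble::tibble(
      doc_id = doc$doc_id, container_id = cont$container_id[i],
      start = st, end = st + len,
      text = substring(cont$text[i], st, st + len - 1L),
      role = "rsid"
    )
  }
  if (!length(out)) return(empty_mentions()[, 1:6])
  dplyr::bind_rows(out)
}

#' Find p-value mentions in a document
#'
#' Scans every sentence and table cell for printed p-values in the three
#' typographic dialects handled by [normalize_pvalue()]; each match carries
#' its normalized decimal value. Values outside `(0, 1]` are discarded.
#'
#' @inheritParams find_rsids
#' @return A mention tibble with `role = "pvalue"` and a numeric `value`.
#' @export
find_pvalues <- function(doc) {
  stopifnot(inherits(doc, "gwas_document"))
  cont <- doc_containers(doc)
  out <- list()
  for (i in seq_len(nrow(cont))) {
    hits <- scan_pvalues(cont$text[i])
    if (!nrow(hits)) next
    out[[length(out) + 1L]] <- tibble::tibble(
      doc_id = doc$doc_id, container_id = cont$container_id[i],
      start = hits$start, end = hits$end, text = hits$text,
      role = "pvalue", value = hits$value
    )
  }
  if (!length(out)) return(empty_mentions()[, 1:7])
  dplyr::bind_rows(out)
}

#' Find phenotype mentions by dictionary scan
#'
#' Case-insensitive longest-match scan of sentences against an ontology
#' dictionary (optionally tolerating a plural `-s` on the term). When two
#' dictionary terms overlap, only the longer match is kept. Each mention
#' carries the matched entry's canonical name and ontology source.
#'
#' @param sentences A sentence tibble (`sent_id`/`container_id`, `text`) or
#'   a `gwas_document`, in which case its title and abstract sentences are
#'   scanned.
#' @param dictionary A `gwas_dictionary` from [read_dictionary()].
#' @param doc_id Document id recorded on the mentions (taken from the
#'   document when one is supplied).
#' @return A mention tibble with `role = "phenotype"`, `dict_entry` and
#'   `dict_source` columns.
#' @export
find_phenotype_candidates <- function(sentences, dictionary,
                                      doc_id = "unknown") {
  if (inherits(sentences, "gwas_document")) {
    doc_id <- sentences$doc_id
    s <- sentences$sentences
    sentences <- s[s$container %in% c("title", "abstract"), ]
  }
  if (!nrow(dictionary)) stop("empty phenotype dictionary")
  id_col <- if ("sent_id" %in% names(sentences)) "sent_id" else "container_id"
  # longest terms first so shorter overlapping matches are suppressed
  ord <- order(-nchar(dictionary$term), tolower(dictionary$term))
  dict <- dictionary[ord, ]
  out <- list()
  for (i in seq_len(nrow(sentences))) {
    text <- sentences$text[i]
    masked <- text
    for (k in seq_len(nrow(dict))) {
      pat <- paste0("\\b", escape_regex(dict$term[k]), "s?\\b")
      m <- gregexpr(pat, masked, perl = TRUE, ignore.case = TRUE)[[1]]
      if (m[1] == -1L) next
      st <- as.integer(m)
      len <- attr(m, "match.length")
      for (j in seq_along(st)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          doc_id = doc_id, container_id = sentences[[id_col]][i],
          start = st[j], end = st[j] + len[j],
          text = substring(text, st[j], st[j] + len[j] - 1L),
          role = "phenotype",
          dict_entry = dict$canonical[k], dict_source = dict$source[k]
        )
        substr(masked, st[j], st[j] + len[j] - 1L) <- strrep("#", len[j])
      }
    }
  }
  if (!length(out)) return(empty_mentions()[, c(1:6, 8:9)])
  dplyr::arrange(dplyr::bind_rows(out), .data$container_id, .data$start)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# ---- relation generation over tables -------------------------------------

# Index mentions that live in cells of a table by the 0-based grid rows
# their cell covers.
mentions_by_grid_row <- function(table, mentions) {
  idx <- match(mentions$container_id, table$cells$cell_id)
  keep <- which(!is.na(idx))
  if (!length(keep)) return(NULL)
  rows_list <- lapply(idx[keep], function(i) cell_rows(table, i))
  list(mention = mentions[keep, ], rows = rows_list)
}

header_grid_rows <- function(table) {
  hdr <- which(table$cells$is_header)
  if (!length(hdr)) return(integer())
  sort(unique(unlist(lapply(hdr, function(i) cell_rows(table, i)))))
}

#' Generate rsid / p-value candidate relations
#'
#' For every non-header table row containing exactly one rsid mention, the
#' rsid is paired with every p-value mention horizontally aligned with it.
#' Rows with two or more rsid mentions are ambiguous and yield no relations
#' (at most one rsid per row).
#'
#' @inheritParams find_rsids
#' @param rsids,pvalues Optional precomputed mention tibbles (recomputed
#'   when `NULL`).
#' @return A relation tibble with `kind = "rsid_pvalue"`, left = rsid
#'   mention, right = p-value mention, and `table_id`/`row_index`
#'   provenance.
#' @export
generate_rsid_pvalue_relations <- function(doc, rsids = NULL, pvalues = NULL) {
  stopifnot(inherits(doc, "gwas_document"))
  if (is.null(rsids)) rsids <- find_rsids(doc)
  if (is.null(pvalues)) pvalues <- find_pvalues(doc)
  out <- list()
  for (tab in doc$tables) {
    ri <- mentions_by_grid_row(tab, rsids)
    pi <- mentions_by_grid_row(tab, pvalues)
    if (is.null(ri) || is.null(pi)) next
    hdr_rows <- header_grid_rows(tab)
    seen <- character()
    for (r in setdiff(0:(tab$n_rows - 1L), hdr_rows)) {
      in_row_r <- which(vapply(ri$rows, function(x) r %in% x, TRUE))
      if (length(in_row_r) != 1L) next
      in_row_p <- which(vapply(pi$rows, function(x) r %in% x, TRUE))
      for (p in in_row_p) {
        key <- paste(in_row_r, p)
        if (key %in% seen) next      # spanning cells: keep first row only
        seen <- c(seen, key)
        L <- ri$mention[in_row_r, ]
        R <- pi$mention[p, ]
        out[[length(out) + 1L]] <- tibble::tibble(
          kind = "rsid_pvalue", doc_id = doc$doc_id,
          table_id = tab$table_id, row_index = r,
          left_container = L$container_id, left_start = L$start,
          left_end = L$end, left_text = L$text,
          right_container = R$container_id, right_start = R$start,
          right_end = R$end, right_text = R$text, right_value = R$value
        )
      }
    }
  }
  if (!length(out)) return(empty_relations())
  dplyr::bind_rows(out)
}

PHENO_HEADER_KEYWORDS <- c("phenotype", "trait", "outcome")

#' Generate precise-phenotype / p-value candidate relations
#'
#' Phenotype-cell candidates are non-header, non-empty cells whose column
#' header contains (case-insensitive substring) one of "phenotype", "trait"
#' or "outcome"; each is paired with every horizontally aligned p-value
#' mention.
#'
#' @inheritParams generate_rsid_pvalue_relations
#' @return A relation tibble with `kind = "phenotype_pvalue"`, left = the
#'   phenotype cell (whole cell text), right = p-value mention.
#' @export
generate_phenotype_pvalue_relations <- function(doc, pvalues = NULL) {
  stopifnot(inherits(doc, "gwas_document"))
  if (is.null(pvalues)) pvalues <- find_pvalues(doc)
  kw <- paste(PHENO_HEADER_KEYWORDS, collapse = "|")
  out <- list()
  for (tab in doc$tables) {
    pheno_cells <- which(
      !tab$cells$is_header & nzchar(tab$cells$text) &
        grepl(kw, tab$cells$column_header_text, ignore.case = TRUE)
    )
    if (!length(pheno_cells)) next
    pi <- mentions_by_grid_row(tab, pvalues)
    if (is.null(pi)) next
    for (i in pheno_cells) {
      rows_i <- cell_rows(tab, i)
      in_row_p <- which(vapply(pi$rows, function(x) any(x %in% rows_i), TRUE))
      for (p in in_row_p) {
        R <- pi$mention[p, ]
        out[[length(out) + 1L]] <- tibble::tibble(
          kind = "phenotype_pvalue", doc_id = doc$doc_id,
          table_id = tab$table_id, row_index = min(rows_i),
          left_container = tab$cells$cell_id[i],
          left_start = 1L, left_end = nchar(tab$cells$text[i]) + 1L,
          left_text = tab$cells$text[i],
          right_container = R$container_id, right_start = R$start,
          right_end = R$end, right_text = R$text, right_value = R$value
        )
      }
    }
  }
  if (!length(out)) return(empty_relations())
  dplyr::bind_rows(out)
}

ACRO_EXPANSION_KEYWORDS <- c("phenotype", "trait", "description")
ACRO_SHORT_KEYWORDS <- c("abbreviation", "acronym", "phenotype")

# an acronym token: 2-10 word characters with at least one uppercase letter
# and at least one letter (rejects "(2019)")
is_acronym_token <- function(x) {
  nchar(x) >= 2 & nchar(x) <= 10 &
    grepl("^[A-Za-z0-9-]+$", x) & grepl("[A-Z]", x)
}

#' Generate acronym / expansion candidate pairs
#'
#' Two candidate sources: (a) running text matching
#' `"<expansion words> (<ACRO>)"`, where the acronym is 2-10 characters with
#' at least one uppercase letter and the candidate expansion is the
#' preceding words (as many as the acronym has characters); (b) table cell
#' pairs aligned under header keyword groups -- "phenotype"/"trait"/
#' "description" on the expansion side and "abbreviation"/"acronym"/
#' "phenotype" on the short side -- supporting both column-oriented headers
#' and transposed (row-label) layouts.
#'
#' @inheritParams find_rsids
#' @return A relation tibble with `kind = "acronym_expansion"`, left =
#'   acronym mention, right = expansion mention.
#' @export
generate_acronym_candidates <- function(doc) {
  stopifnot(inherits(doc, "gwas_document"))
  out <- list()
  add <- function(table_id, row_index, left_cont, left_text, left_start,
                  left_end, right_cont, right_text, right_start, right_end) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      kind = "acronym_expansion", doc_id = doc$doc_id,
      table_id = table_id, row_index = row_index,
      left_container = left_cont, left_start = left_start,
      left_end = left_end, left_text = left_text,
      right_container = right_cont, right_start = right_start,
      right_end = right_end, right_text = right_text,
      right_value = NA_real_
    )
  }

  # (a) text pattern "<words> (<ACRO>)"
  for (i in seq_len(nrow(doc$sentences))) {
    text <- doc$sentences$text[i]
    m <- gregexpr("\\(([A-Za-z0-9-]{2,10})\\)", text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    toks <- tokenize_and_tag(text)
    words <- toks[grepl("^[A-Za-z0-9]", toks$token), ]
    for (k in seq_along(m)) {
      st <- as.integer(m[k])
      len <- attr(m, "match.length")[k]
      acro <- substr(text, st + 1L, st + len - 2L)
      if (!is_acronym_token(acro)) next
      n_letters <- nchar(gsub("[^A-Za-z0-9]", "", acro))
      before <- words[words$end <= st, ]
      if (!nrow(before)) next
      take <- tail(seq_len(nrow(before)), n_letters)
      exp_start <- before$start[take[1]]
      exp_end <- before$end[nrow(before)]
      expansion <- substr(text, exp_start, exp_end - 1L)
      add(NA_character_, NA_integer_,
          doc$sentences$sent_id[i], acro, st + 1L, st + len - 1L,
          doc$sentences$sent_id[i], expansion, exp_start, exp_end)
    }
  }

  # (b) table-derived pairs
  exp_kw <- paste(ACRO_EXPANSION_KEYWORDS, collapse = "|")
  short_kw <- paste(ACRO_SHORT_KEYWORDS, collapse = "|")
  for (tab in doc$tables) {
    grid <- table_grid(tab)
    cells <- tab$cells
    # column-oriented: header row keywords govern columns
    col_hdr <- vapply(seq_len(tab$n_cols), function(cc) {
      idx <- unique(tab$grid[, cc])
      paste(cells$column_header_text[idx[1]], collapse = " ")
    }, "")
    exp_cols <- which(grepl(exp_kw, col_hdr, ignore.case = TRUE))
    short_cols <- which(grepl(short_kw, col_hdr, ignore.case = TRUE))
    hdr_rows <- header_grid_rows(tab) + 1L
    body_rows <- setdiff(seq_len(tab$n_rows), hdr_rows)
    for (ec in exp_cols) {
      for (sc in setdiff(short_cols, ec)) {
        for (r in body_rows) {
          ei <- tab$grid[r, ec]; si <- tab$grid[r, sc]
          if (!nzchar(cells$text[ei]) || !nzchar(cells$text[si])) next
          add(tab$table_id, r - 1L,
              cells$cell_id[si], cells$text[si], 1L,
              nchar(cells$text[si]) + 1L,
              cells$cell_id[ei], cells$text[ei], 1L,
              nchar(cells$text[ei]) + 1L)
        }
      }
    }
    # row-oriented (transposed): first-column labels govern rows
    row_lab <- grid[, 1]
    exp_rows <- which(grepl(exp_kw, row_lab, ignore.case = TRUE))
    short_rows <- which(grepl(short_kw, row_lab, ignore.case = TRUE))
    for (er in exp_rows) {
      for (sr in setdiff(short_rows, er)) {
        for (cc in seq_len(tab$n_cols)[-1]) {
          ei <- tab$grid[er, cc]; si <- tab$grid[sr, cc]
          if (!nzchar(cells$text[ei]) || !nzchar(cells$text[si])) next
          add(tab$table_id, er - 1L,
              cells$cell_id[si], cells$text[si], 1L,
              nchar(cells$text[si]) + 1L,
              cells$cell_id[ei], cells$text[ei], 1L,
              nchar(cells$text[ei]) + 1L)
        }
      }
    }
  }
  if (!length(out)) return(empty_relations())
  dplyr::distinct(dplyr::bind_rows(out))
}
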