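# Hierarchical document model for JATS/PMC-style XML.
#
# A parsed document holds the title, abstract and body as sentence tables and
# every table as a dense cell grid: rowspan/colspan attributes are expanded so
# each (row, col) position of the grid maps to exactly one cell. All
# downstream candidate generation works on this model, never on raw XML.

#' Parse a JATS/PMC-style XML publication into a document model
#'
#' Traverses the XML tree and builds a hierarchical model: title, abstract
#' and body paragraphs as sentences, and each `table-wrap`/`table` as a
#' dense cell grid with `rowspan`/`colspan` expanded. Unknown elements are
#' skipped; a missing title produces a warning, not an error. Parsing is
#' deterministic: identical bytes give an identical model, with table and
#' sentence identifiers stable across runs.
#'
#' @param xml Path to an XML file, a length-one XML string, or a raw vector.
#' @param doc_id Publication identifier (PMID string). Defaults to the
#'   `article-id` of type `pmid` when present, else the file name, else
#'   `"unknown"`.
#' @return A `gwas_document`: a list with `doc_id`, `sentences` (tibble with
#'   `sent_id`, `container` in title/abstract/body, `text`) and `tables`
#'   (named list of `gwas_table`, see [table_grid()]).
#' @examples
#' doc <- parse_document("<article><front><article-title>A GWAS of
#'   height</article-title></front></article>")
#' doc$sentences
#' @export
parse_document <- function(xml, doc_id = NULL) {
  x <- tryCatch(
    xml2::read_xml(xml),
    error = function(e) {
      stop("XML parse error: ", conditionMessage(e), call. = FALSE)
    }
  )
  if (is.null(doc_id)) {
    pmid <- xml2::xml_find_first(x, ".//article-id[@pub-id-type='pmid']")
    if (!inherits(pmid, "xml_missing")) {
      doc_id <- squish(xml2::xml_text(pmid))
    } else if (is.character(xml) && length(xml) == 1L && file.exists(xml)) {
      doc_id <- sub("\\.[^.]*$", "", basename(xml))
    } else {
      doc_id <- "unknown"
    }
  }
  stopifnot(nzchar(doc_id))

  title_node <- xml2::xml_find_first(x, ".//article-title")
  title_text <- if (inherits(title_node, "xml_missing")) {
    warning("document ", doc_id, " has no <article-title>; using empty title")
    character()
  } else {
    squish(xml2::xml_text(title_node))
  }

  abstract_ps <- xml2::xml_find_all(x, ".//abstract//p")
  abstract_text <- squish(xml2::xml_text(abstract_ps))

  # body paragraphs, excluding any text living inside tables
  body_ps <- xml2::xml_find_all(x, ".//body//p[not(ancestor::table-wrap) and not(ancestor::table)]")
  body_text <- squish(xml2::xml_text(body_ps))

  sent <- list()
  add_sentences <- function(texts, container) {
    for (t in texts) {
      for (s in split_sentences(t)) {
        sent[[length(sent) + 1L]] <<- list(container = container, text = s)
      }
    }
  }
  add_sentences(title_text, "title")
  add_sentences(abstract_text, "abstract")
  add_sentences(body_text, "body")
  sentences <- if (length(sent)) {
    tibble::tibble(
      sent_id = sprintf("s%d", seq_along(sent)),
      container = vapply(sent, `[[`, "", "container"),
      text = vapply(sent, `[[`, "", "text")
    )
  } else {
    tibble::tibble(sent_id = character(), container = character(),
                   text = character())
  }

  wraps <- xml2::xml_find_all(x, ".//table-wrap")
  table_nodes <- if (length(wraps)) {
    lapply(wraps, function(w) xml2::xml_find_first(w, ".//table"))
  } else {
    as.list(xml2::xml_find_all(x, ".//table"))
  }
  tables <- list()
  for (i in seq_along(table_nodes)) {
    tnode <- table_nodes[[i]]
    if (inherits(tnode, "xml_missing")) next
    tid <- NULL
    if (length(wraps) >= i) tid <- xml2::xml_attr(wraps[[i]], "id")
    if (is.null(tid) || is.na(tid) || !nzchar(tid)) {
      tid <- sprintf("tbl%d", i)
    }
    tab <- parse_table(tnode, tid)
    if (!is.null(tab)) tables[[tid]] <- tab
  }

  structure(
    list(doc_id = doc_id, sentences = sentences, tables = tables),
    class = "gwas_document"
  )
}

#' @export
print.gwas_document <- function(x, ...) {
  cat(sprintf(
    "<gwas_document %s: %d sentences (%d title), %d tables>\n",
    x$doc_id, nrow(x$sentences), sum(x$sentences$container == "title"),
    length(x$tables)
  ))
  invisible(x)
}

# Parse one <table> node into a gwas_table: a cell tibble plus a dense
# integer grid mapping every (row, col) position to the index of the cell
# covering it (HTML table algorithm: each cell is placed at the first free
# column of its row, then its rowspan x colspan footprint is marked).
parse_table <- function(tnode, table_id) {
  head_rows <- xml2::xml_find_all(tnode, "./thead/tr")
  body_rows <- xml2::xml_find_all(tnode, "./tbody/tr | ./tr")
  rows <- c(as.list(head_rows), as.list(body_rows))
  is_header_row <- c(rep(TRUE, length(head_rows)), rep(FALSE, length(body_rows)))
  if (!length(rows)) return(NULL)

  cells <- list()
  occupied <- matrix(FALSE, nrow = 0, ncol = 0)
  ensure_dim <- function(m, nr, nc) {
    if (nrow(m) < nr) m <- rbind(m, matrix(FALSE, nr - nrow(m), ncol(m)))
    if (ncol(m) < nc) m <- cbind(m, matrix(FALSE, nrow(m), nc - ncol(m)))
    m
  }
  for (r in seq_along(rows)) {
    tds <- xml2::xml_find_all(rows[[r]], "./td | ./th")
    col <- 1L
    occupied <- ensure_dim(occupied, r, max(1L, ncol(occupied)))
    for (td in tds) {
      while (col <= ncol(occupied) && occupied[r, col]) col <- col + 1L
      rs <- suppressWarnings(as.integer(xml2::xml_attr(td, "rowspan")))
      cs <- suppressWarnings(as.integer(xml2::xml_attr(td, "colspan")))
      if (is.na(rs) || rs < 1L) rs <- 1L
      if (is.na(cs) || cs < 1L) cs <- 1L
      occupied <- ensure_dim(occupied, r + rs - 1L, col + cs - 1L)
      occupied[r:(r + rs - 1L), col:(col + cs - 1L)] <- TRUE
      cells[[length(cells) + 1L]] <- list(
        row = r - 1L, col = col - 1L, rowspan = rs, colspan = cs,
        is_header = is_header_row[r] || xml2::xml_name(td) == "th",
        text = squish(xml2::xml_text(td))
      )
      col <- col + cs
    }
  }
  if (!length(cells)) return(NULL)
  cdf <- tibble::tibble(
    cell_id = vapply(cells, function(c)
      sprintf("%s:r%dc%d", table_id, c$row, c$col), ""),
    row = vapply(cells, function(c) c$row, 0L),
    col = vapply(cells, function(c) c$col, 0L),
    rowspan = vapply(cells, function(c) c$rowspan, 0L),
    colspan = vapply(cells, function(c) c$colspan, 0L),
    is_header = vapply(cells, function(c) c$is_header, TRUE),
    text = vapply(cells, function(c) c$text, "")
  )
  n_rows <- nrow(occupied)
  n_cols <- ncol(occupied)
  grid <- matrix(NA_integer_, n_rows, n_cols)
  for (i in seq_len(nrow(cdf))) {
    rr <- cdf$row[i] + seq_len(cdf$rowspan[i])
    cc <- cdf$col[i] + seq_len(cdf$colspan[i])
    grid[rr, cc] <- i
  }
  # if a malformed table leaves holes, fill them with empty synthetic cells
  holes <- which(is.na(grid), arr.ind = TRUE)
  if (nrow(holes)) {
    for (h in seq_len(nrow(holes))) {
      cdf <- dplyr::bind_rows(cdf, tibble::tibble(
        cell_id = sprintf("%s:r%dc%d", table_id,
                          holes[h, 1] - 1L, holes[h, 2] - 1L),
        row = holes[h, 1] - 1L, col = holes[h, 2] - 1L,
        rowspan = 1L, colspan = 1L, is_header = FALSE, text = ""
      ))
      grid[holes[h, 1], holes[h, 2]] <- nrow(cdf)
    }
  }

  # column_header_text: header cells vertically above, joined top-to-bottom;
  # a cell spanning several columns contributes once per distinct header cell
  col_header <- vapply(seq_len(n_cols), function(cc) {
    idx <- grid[, cc]
    hdr <- unique(idx[cdf$is_header[idx]])
    paste(cdf$text[hdr][nzchar(cdf$text[hdr])], collapse = " ")
  }, "")
  cdf$column_header_text <- vapply(seq_len(nrow(cdf)), function(i) {
    cols <- cdf$col[i] + seq_len(cdf$colspan[i])
    paste(unique(col_header[cols][nzchar(col_header[cols])]), collapse = " ")
  }, "")

  structure(
    list(table_id = table_id, cells = cdf, grid = grid,
         n_rows = n_rows, n_cols = n_cols),
    class = "gwas_table"
  )
}

#' Dense grid of a parsed table
#'
#' @param table A `gwas_table` as found in `doc$tables`.
#' @return An `n_rows` x `n_cols` character matrix of cell texts, with
#'   spanning cells repeated over their footprint.
#' @export
table_grid <- function(table) {
  stopifnot(inherits(table, "gwas_table"))
  matrix(table$cells$text[table$grid], table$n_rows, table$n_cols)
}

#' Cells horizontally aligned with a given cell
#'
#' Returns every cell whose expanded row range intersects that of `cell_id`
#' (the cell itself included), ordered by column. Cells spanning several
#' rows are aligned with all of them.
#'
#' @param table A `gwas_table`.
#' @param cell_id A cell identifier from `table$cells$cell_id`.
#' @return The aligned rows of `table$cells`, ordered by `col`.
#' @export
row_of <- function(table, cell_id) {
  stopifnot(inherits(table, "gwas_table"))
  i <- match(cell_id, table$cells$cell_id)
  if (is.na(i)) {
    stop("cell ", cell_id, " is not part of table ", table$table_id)
  }
  rows <- table$cells$row[i] + seq_len(table$cells$rowspan[i]) - 1L
  idx <- sort(unique(as.vector(table$grid[rows + 1L, , drop = FALSE])))
  out <- table$cells[idx, ]
  dplyr::arrange(out, col, row)
}

# Rows (0-based) of the grid covered by each cell index: helper for
# relation generation.
cell_rows <- function(table, i) {
  table$cells$row[i] + seq_len(table$cells$rowspan[i]) - 1L
}

# Look up the text of a container (sentence id or cell id) in a document.
container_text <- function(doc, container_id) {
  j <- match(container_id, doc$sentences$sent_id)
  if (!is.na(j)) return(doc$sentences$text[j])
  for (tab in doc$tables) {
    k <- match(container_id, tab$cells$cell_id)
    if (!is.na(k)) return(tab$cells$text[k])
  }
  NA_character_
}

# Serialize a document model to JSON (debugging / --dump-docmodel).
#' @rdname parse_document
#' @param doc A `gwas_document`.
#' @export
docmodel_json <- function(doc) {
  stopifnot(inherits(doc, "gwas_document"))
  jsonlite::toJSON(list(
    doc_id = doc$doc_id,
    sentences = doc$sentences,
    tables = lapply(doc$tables, function(t) list(
      table_id = t$table_id, n_rows = t$n_rows, n_cols = t$n_cols,
      cells = t$cells
    ))
  ), auto_unbox = TRUE, digits = NA)
}
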