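# Labeling functions (LFs) and the label matrix.
#
# An LF is a deterministic heuristic that votes +1 (correct), -1 (incorrect)
# or 0 (abstain) on a candidate, given its document context. LFs may be
# noisy, may overlap, and may conflict; the generative label model learns
# each one's accuracy from the unlabeled vote matrix. Polarities are part of
# each LF's definition and are configurable when building the registry.

new_lf <- function(name, kind, fn) {
  structure(list(name = name, kind = kind, fn = fn), class = "gwas_lf")
}

#' @export
print.gwas_lf <- function(x, ...) {
  cat(sprintf("<labeling function %s (%s)>\n", x$name, x$kind))
  invisible(x)
}

lf_vote <- function(cond, yes, no = 0L) if (isTRUE(cond)) yes else no

#' Built-in labeling functions for a candidate kind
#'
#' Returns the registered LF set for one of the three classified candidate
#' kinds:
#' \describe{
#'   \item{`simple_phenotype`}{mention in the title (+1); mention shorter
#'     than five characters (-1); mention contains a noun (+1 / -1);
#'     mention in the first half of its sentence (+1).}
#'   \item{`precise_phenotype`}{candidate is mostly a number (-1, else +1);
#'     column header very long, more than `long_header` characters (-1);
#'     candidate contains rsid-like words (-1).}
#'   \item{`acronym`}{short form all in capitals (+1); either side matches
#'     the ontology dictionary (+1); short form spells the initials of the
#'     expansion words (+1 / -1); one side a prefix of the other (+1).}
#' }
#' Every set is within the 4-12 band the generative model is designed for,
#' and the registry is extensible: pass extra `gwas_lf` objects through
#' `extra`.
#'
#' @param kind One of `"simple_phenotype"`, `"precise_phenotype"`,
#'   `"acronym"`.
#' @param long_header Character threshold above which a phenotype-column
#'   header is considered suspiciously long (default 30).
#' @param extra Optional list of additional `gwas_lf` objects to append.
#' @return A list of `gwas_lf` objects.
#' @export
builtin_lfs <- function(kind, long_header = 30L, extra = list()) {
  lfs <- switch(
    kind,
    simple_phenotype = list(
      new_lf("in_title", kind, function(cand, ctx) {
        lf_vote(cand$container %in% "title", +1L)
      }),
      new_lf("short_mention", kind, function(cand, ctx) {
        lf_vote(nchar(cand$text) < 5L, -1L)
      }),
      new_lf("contains_nouns", kind, function(cand, ctx) {
        toks <- tokenize_and_tag(cand$text)
        lf_vote(any(toks$is_noun), +1L, -1L)
      }),
      new_lf("first_half_of_sentence", kind, function(cand, ctx) {
        n <- nchar(cand$sentence_text %||% "")
        lf_vote(n > 0L && cand$start <= n / 2, +1L)
      })
    ),
    precise_phenotype = list(
      # the one positive-evidence LF of the trio: a trait name is words,
      # not a number (and not bare punctuation like "-")
      new_lf("mostly_number", kind, function(cand, ctx) {
        chars <- gsub("[^A-Za-z0-9]", "", cand$text)
        if (!nzchar(chars)) return(-1L)
        frac <- nchar(gsub("[^0-9.]", "", cand$text)) / nchar(chars)
        if (frac > 0.5) -1L else +1L
      }),
      new_lf("very_long_header", kind, function(cand, ctx) {
        lf_vote(nchar(cand$column_header_text %||% "") > long_header, -1L)
      }),
      new_lf("rsid_words", kind, function(cand, ctx) {
        pat <- paste0(RE_RSID, "|\\b(?:snp|rsid|variant|marker|allele|",
                      "chromosome|haplotype)s?\\b")
        lf_vote(grepl(pat, cand$text, perl = TRUE, ignore.case = TRUE), -1L)
      })
    ),
    acronym = list(
      new_lf("all_caps", kind, function(cand, ctx) {
        letters_only <- gsub("[^A-Za-z]", "", cand$text)
        lf_vote(nchar(letters_only) >= 2L &&
                  identical(letters_only, toupper(letters_only)), +1L)
      }),
      new_lf("dictionary_match", kind, function(cand, ctx) {
        dict <- ctx$dictionary
        if (is.null(dict)) return(0L)
        terms <- tolower(dict$term)
        lf_vote(tolower(squish(cand$text)) %in% terms ||
                  tolower(squish(cand$expansion_text %||% "")) %in% terms,
                +1L)
      }),
      new_lf("initials_match", kind, function(cand, ctx) {
        expn <- cand$expansion_text %||% ""
        words <- strsplit(squish(expn), "[ -]+")[[1]]
        words <- words[nzchar(words)]
        if (!length(words)) return(-1L)
        initials <- paste(toupper(substr(words, 1, 1)), collapse = "")
        acro <- toupper(gsub("[^A-Za-z0-9]", "", cand$text))
        lf_vote(identical(initials, acro), +1L, -1L)
      }),
      new_lf("prefix", kind, function(cand, ctx) {
        a <- tolower(gsub("[^a-z0-9]", "", tolower(cand$text)))
        b <- tolower(gsub("[^a-z0-9]", "",
                          tolower(cand$expansion_text %||% "")))
        lf_vote(nchar(a) >= 3L && nchar(b) >= 3L &&
                  (startsWith(a, b) || startsWith(b, a)), +1L)
      })
    ),
    stop("unknown labeling-function kind: ", kind)
  )
  c(lfs, extra)
}

# Build the per-candidate context rows LFs consume, from a candidate table
# plus the parsed documents. Mentions need their sentence container; cell
# candidates need their column header.
candidate_context <- function(candidates, docs) {
  docs <- as_doc_list(docs)
  lapply(seq_len(nrow(candidates)), function(i) {
    cand <- as.list(candidates[i, ])
    doc <- docs[[cand$doc_id]]
    cid <- cand$container_id %||% cand$left_container
    if (!is.null(cand$left_text)) {
      cand$text <- cand$left_text
      cand$start <- cand$left_start
      cand$expansion_text <- cand$right_text
    }
    if (!is.null(doc)) {
      j <- match(cid, doc$sentences$sent_id)
      if (!is.na(j)) {
        cand$container <- doc$sentences$container[j]
        cand$sentence_text <- doc$sentences$text[j]
      } else {
        for (tab in doc$tables) {
          k <- match(cid, tab$cells$cell_id)
          if (!is.na(k)) {
            cand$container <- "table-cell"
            cand$column_header_text <- tab$cells$column_header_text[k]
            break
          }
        }
      }
    }
    cand
  })
}

as_doc_list <- function(docs) {
  if (inherits(docs, "gwas_document")) docs <- list(docs)
  if (is.null(names(docs)) || any(!nzchar(names(docs)))) {
    names(docs) <- vapply(docs, `[[`, "", "doc_id")
  }
  docs
}

#' Apply labeling functions to candidates
#'
#' Evaluates every LF on every candidate, producing the n x m label matrix
#' over \{-1, 0, +1\} consumed by [fit_label_model()]. Application is
#' deterministic; an LF returning anything outside \{-1, 0, +1\} is an
#' error naming the function.
#'
#' @param candidates A mention or relation tibble (one row per candidate).
#' @param lfs A list of `gwas_lf` objects, all of the same kind (see
#'   [builtin_lfs()]).
#' @param docs The `gwas_document`(s) the candidates came from (single
#'   document or named list), used to give LFs their context.
#' @param dictionary Optional `gwas_dictionary` exposed to LFs.
#' @return An integer matrix with one row per candidate and one column per
#'   LF (column names are LF names).
#' @export
apply_lfs <- function(candidates, lfs, docs = NULL, dictionary = NULL) {
  stopifnot(is.list(lfs), all(vapply(lfs, inherits, TRUE, "gwas_lf")))
  kinds <- unique(vapply(lfs, `[[`, "", "kind"))
  if (length(kinds) > 1L) {
    stop("labeling functions of mixed kinds: ", paste(kinds, collapse = ", "))
  }
  m <- length(lfs)
  n <- nrow(candidates)
  L <- matrix(0L, n, m,
              dimnames = list(NULL, vapply(lfs, `[[`, "", "name")))
  if (n == 0L) return(L)
  ctx <- list(dictionary = dictionary)
  cands <- candidate_context(candidates, docs %||% list())
  for (j in seq_len(m)) {
    fn <- lfs[[j]]$fn
    votes <- vapply(cands, function(cand) {
      v <- tryCatch(fn(cand, ctx), error = function(e) 0L)
      as.integer(v)
    }, 0L)
    if (!all(votes %in% c(-1L, 0L, 1L))) {
      stop("labeling function '", lfs[[j]]$name,
           "' returned a vote outside {-1, 0, +1}")
    }
    L[, j] <- votes
  }
  L
}

#' Summarise a label matrix
#'
#' Per-LF coverage (fraction of non-abstains), overlap (fraction of
#' candidates where the LF votes together with at least one other LF) and
#' conflict (votes against at least one other LF). An LF that abstains on
#' every candidate is flagged.
#'
#' @param L A label matrix from [apply_lfs()].
#' @return A tibble with one row per LF.
#' @export
lf_summary <- function(L) {
  n <- nrow(L)
  votes <- L != 0L
  out <- tibble::tibble(
    lf = colnames(L) %||% paste0("lf", seq_len(ncol(L))),
    coverage = colMeans(votes),
    overlap = vapply(seq_len(ncol(L)), function(j) {
      if (n == 0) return(0)
      mean(votes[, j] & rowSums(votes[, -j, drop = FALSE]) > 0)
    }, 0),
    conflict = vapply(seq_len(ncol(L)), function(j) {
      if (n == 0) return(0)
      mean(vapply(seq_len(n), function(i) {
        L[i, j] != 0L && any(L[i, -j] != 0L & L[i, -j] != L[i, j])
      }, TRUE))
    }, 0)
  )
  out$always_abstains <- out$coverage == 0
  if (any(out$always_abstains) && n > 0) {
    warning("labeling function(s) abstain on every candidate: ",
            paste(out$lf[out$always_abstains], collapse = ", "))
  }
  out
}
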