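# Phenotype ontology dictionaries: flat term lists in the style of EFO,
# SNOMED CT and MeSH. Matching downstream is exact-surface (case-folded,
# optional plural -s), so the dictionary is just a term table.

#' Load a phenotype ontology dictionary
#'
#' Reads a 2-3 column TSV (`term`, optional `canonical`, optional `source`)
#' into a dictionary tibble. Lookup is case-insensitive; `canonical`
#' defaults to the term itself and `source` to `"EFO"`.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A `gwas_dictionary` tibble with columns `term`, `canonical`,
#'   `source`.
#' @examples
#' dict <- read_dictionary(system.file("extdata",
#'   "phenotype_dictionary.tsv", package = "gwasminer"))
#' head(dict)
#' @export
read_dictionary <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- tolower(names(df))
  stopifnot("term" %in% names(df))
  if (!"canonical" %in% names(df)) df$canonical <- df$term
  if (!"source" %in% names(df)) df$source <- "EFO"
  as_dictionary(df[, c("term", "canonical", "source")])
}

#' @rdname read_dictionary
#' @param df A data frame with at least a `term` column.
#' @export
as_dictionary <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot("term" %in% names(df))
  if (!"canonical" %in% names(df)) df$canonical <- df$term
  if (!"source" %in% names(df)) df$source <- "EFO"
  df$term <- squish(df$term)
  if (any(!nzchar(df$term))) stop("dictionary contains empty terms")
  df <- dplyr::distinct(df, tolower(.data$term), .keep_all = TRUE)
  df <- df[, c("term", "canonical", "source")]
  class(df) <- c("gwas_dictionary", class(df))
  df
}

#' @importFrom dplyr .data
NULL

# The packaged mini-dictionary (used by examples, tests and the synthetic
# corpus generator).
default_dictionary <- function() {
  read_dictionary(system.file("extdata", "phenotype_dictionary.tsv",
                              package = "gwasminer"))
}
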