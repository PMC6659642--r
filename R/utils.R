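# Internal helpers shared across modules.

# Collapse runs of whitespace (incl. non-breaking / thin spaces) and trim.
squish <- function(x) {
  x <- gsub("[\\s   ]+", " ", x, perl = TRUE)
  trimws(x)
}

norm_phenotype <- function(x) tolower(squish(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic RNG scope: every stochastic operation in the package takes a
# seed and runs inside withr::with_seed so the caller's RNG is untouched.
with_seed <- withr::with_seed

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

empty_mentions <- function() {
  tibble::tibble(
    doc_id = character(), container_id = character(),
    start = integer(), end = integer(), text = character(),
    role = character(), value = numeric(), dict_entry = character(),
    dict_source = character()
  )
}

empty_relations <- function() {
  tibble::tibble(
    kind = character(), doc_id = character(), table_id = character(),
    row_index = integer(),
    left_container = character(), left_start = integer(),
    left_end = integer(), left_text = character(),
    right_container = character(), right_start = integer(),
    right_end = integer(), right_text = character(),
    right_value = numeric()
  )
}
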