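# Tokenization, noun tagging, and sentence splitting.
#
# Downstream stages only consume a per-token boolean noun flag (one labeling
# function asks whether a mention contains a noun), so instead of a full
# part-of-speech tagger we use a closed-class lexicon: a token is tagged as a
# noun when it contains a letter and its lowercased form is not a known
# function word (article, preposition, pronoun, auxiliary, conjunction,
# common adverb/adjective/verb). Content words in titles and trait names are
# overwhelmingly nouns, so this errs in the right direction for this corpus.

FUNCTION_WORDS <- c(
  # determiners / articles
  "a", "an", "the", "this", "that", "these", "those", "each", "every",
  "either", "neither", "some", "any", "no", "all", "both", "such",
  # prepositions
  "of", "in", "on", "at", "by", "for", "with", "about", "against", "between",
  "into", "through", "during", "before", "after", "above", "below", "to",
  "from", "up", "down", "over", "under", "across", "near", "among", "within",
  "without", "via", "per", "versus", "vs",
  # conjunctions
  "and", "or", "but", "nor", "so", "yet", "if", "while", "although",
  "because", "since", "than", "whether", "as", "when", "where", "how", "why",
  # pronouns
  "i", "you", "he", "she", "it", "we", "they", "them", "his", "her", "its",
  "their", "our", "your", "my", "who", "whom", "which", "what",
  # auxiliaries / copulas / modal verbs
  "is", "are", "was", "were", "be", "been", "being", "am", "do", "does",
  "did", "have", "has", "had", "can", "could", "may", "might", "must",
  "shall", "should", "will", "would",
  # frequent adverbs / particles
  "not", "also", "very", "more", "most", "less", "least", "only", "just",
  "then", "there", "here", "too", "well", "however", "thus", "hence",
  # frequent non-noun content words in methods prose
  "associated", "identified", "found", "using", "based", "performed",
  "reported", "observed", "significant", "significantly", "novel", "new",
  "respectively", "approximately", "several", "multiple", "other", "same"
)

# Abbreviations that must not terminate a sentence.
SENT_ABBREV <- c(
  "e.g.", "i.e.", "vs.", "et al.", "al.", "cf.", "ca.", "approx.", "fig.",
  "figs.", "dr.", "no.", "vol.", "st.", "resp."
)

#' Tokenize a sentence and tag nouns
#'
#' Splits a single sentence into word and punctuation tokens with character
#' offsets, and flags probable nouns using a function-word lexicon: a token
#' is flagged when it contains at least one letter and is not a closed-class
#' English word. Offsets are half-open `[start, end)`, 1-based `start`.
#'
#' @param text A length-one character string (one sentence). `""` yields an
#'   empty token table.
#' @return A tibble with columns `token`, `start`, `end`, `is_noun`.
#'   Substrings at the recorded offsets reconstruct `text` exactly.
#' @examples
#' tokenize_and_tag("Platelet aggregation")
#' @export
tokenize_and_tag <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- tibble::tibble(
    token = character(), start = integer(), end = integer(),
    is_noun = logical()
  )
  if (is.na(text) || !nzchar(text)) return(empty)
  pat <- "[A-Za-z0-9]+(?:['’-][A-Za-z0-9]+)*|[^A-Za-z0-9\\s]"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  start <- as.integer(m)
  len <- attr(m, "match.length")
  tok <- substring(text, start, start + len - 1L)
  tibble::tibble(
    token = tok,
    start = start,
    end = start + len,
    is_noun = grepl("[A-Za-z]", tok) & !(tolower(tok) %in% FUNCTION_WORDS)
  )
}

# Split a paragraph into sentences. Terminal punctuation followed by
# whitespace and a capital/digit starts a new sentence; a protected
# abbreviation list keeps "e.g.", "vs.", "et al." intact.
split_sentences <- function(text) {
  text <- squish(text)
  if (!nzchar(text)) return(character())
  protected <- text
  # shield abbreviation periods with a placeholder character
  ph <- "\u0001"
  for (ab in SENT_ABBREV) {
    for (form in unique(c(
      ab, paste0(toupper(substr(ab, 1, 1)), substr(ab, 2, nchar(ab)))
    ))) {
      shielded <- gsub(".", ph, form, fixed = TRUE)
      protected <- gsub(form, shielded, protected, fixed = TRUE)
    }
  }
  parts <- strsplit(protected, "(?<=[.!?])\\s+(?=[A-Z0-9])", perl = TRUE)[[1]]
  parts <- gsub(ph, ".", parts, fixed = TRUE)
  parts[nzchar(trimws(parts))]
}
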