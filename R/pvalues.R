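# P-value recognition and normalization.
#
# Published association tables print p-values in three typographic dialects:
#   (1) E-notation:      1.00E-06, 5.00E−19 (unicode minus U+2212 common)
#   (2) typeset power:   3.2 × 10−7  (multiplication sign, superscript minus)
#   (3) plain decimal:   0.003 (a probability in (0, 1])
# Recognition scans each dialect in that order and masks matched spans so the
# mantissa of "3.2 × 10−7" is never re-matched as the plain decimal "3.2".

# Unicode typography seen in typeset scientific notation.
MINUS_CHARS <- "−‐–—-"   # minus, hyphen, en/em dash
TIMES_CHARS <- "×⋅·xX*"  # multiplication sign, dots, x

# regex fragments; minus may be ASCII or typographic
RE_MINUS <- sprintf("[%s]", MINUS_CHARS)
RE_E_NOTATION <- sprintf(
  "[0-9]+(?:\\.[0-9]+)?[eE]\\s*(?:[+%s])?\\s*[0-9]+", MINUS_CHARS
)
RE_TYPESET <- sprintf(
  "[0-9]+(?:\\.[0-9]+)?\\s*[%s]\\s*10\\s*(?:[+%s])?\\s*[0-9]+",
  TIMES_CHARS, MINUS_CHARS
)
RE_PLAIN <- "(?<![0-9A-Za-z.%−-])(?:0?\\.[0-9]+|1\\.0+)(?![0-9A-Za-z.])"

#' Normalize a printed p-value to a decimal number
#'
#' Accepts the three typographic dialects used by association tables:
#' E-notation (`"1.00E−06"`), typeset powers of ten (`"3.2 × 10−7"`) and
#' plain decimals (`"0.5"`, `"1"`). Unicode minus signs (U+2212, dashes),
#' multiplication signs (`×`, `·`, `x`) and a leading comparator (`"p ="`,
#' `"P <"`) are all tolerated.
#'
#' @param text A character vector of printed p-values.
#' @return A numeric vector of the same length.
#' @examples
#' normalize_pvalue(c("1.00E−06", "3.2 × 10−7", "0.5"))
#' @export
normalize_pvalue <- function(text) {
  vapply(text, normalize_pvalue1, 0, USE.NAMES = FALSE)
}

normalize_pvalue1 <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- squish(text)
  # strip a leading "p"/"P" with an optional comparator
  s <- sub("^[pP]\\s*[=<>≤≥]?\\s*", "", s, perl = TRUE)
  s <- squish(s)
  # E-notation
  m <- regmatches(s, regexpr(paste0("^", RE_E_NOTATION, "$"), s, perl = TRUE))
  if (length(m)) {
    parts <- strsplit(sub("E", "e", m, ignore.case = TRUE), "e")[[1]]
    exp_str <- gsub(RE_MINUS, "-", squish(parts[2]), perl = TRUE)
    return(as.numeric(parts[1]) * 10^as.numeric(gsub("\\s", "", exp_str)))
  }
  # typeset mantissa x 10^exponent
  pat <- sprintf(
    "^([0-9]+(?:\\.[0-9]+)?)\\s*[%s]\\s*10\\s*([+%s])?\\s*([0-9]+)$",
    TIMES_CHARS, MINUS_CHARS
  )
  mm <- regmatches(s, regexec(pat, s, perl = TRUE))[[1]]
  if (length(mm)) {
    sign <- if (nzchar(mm[3]) && mm[3] != "+") -1 else 1
    return(as.numeric(mm[2]) * 10^(sign * as.numeric(mm[4])))
  }
  # plain decimal in (0, 1]
  if (grepl("^(?:0?\\.[0-9]+|1(?:\\.0+)?|1\\.)$", s)) {
    return(as.numeric(s))
  }
  stop("cannot normalize p-value text: '", text, "'", call. = FALSE)
}

# Scan one string for p-value mentions in all three dialects, masking each
# match so later (weaker) dialects cannot rematch inside it. Returns a data
# frame of start, end (half-open, 1-based), text, value.
scan_pvalues <- function(text) {
  out <- list()
  masked <- text
  scan_one <- function(pattern) {
    m <- gregexpr(pattern, masked, perl = TRUE)[[1]]
    if (m[1] == -1L) return(invisible())
    for (k in seq_along(m)) {
      st <- as.integer(m[k])
      len <- attr(m, "match.length")[k]
      frag <- substr(text, st, st + len - 1L)
      val <- tryCatch(normalize_pvalue1(frag), error = function(e) NA_real_)
      if (!is.na(val) && val > 0 && val <= 1) {
        out[[length(out) + 1L]] <<- list(
          start = st, end = st + len, text = frag, value = val
        )
      }
      # mask regardless of acceptance so weaker dialects skip the span
      substr(masked, st, st + len - 1L) <<- strrep("#", len)
    }
  }
  scan_one(RE_E_NOTATION)
  scan_one(RE_TYPESET)
  scan_one(RE_PLAIN)
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      text = character(), value = numeric()))
  }
  df <- do.call(rbind, lapply(out, as.data.frame))
  df[order(df$start), , drop = FALSE]
}
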