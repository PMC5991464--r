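## Text normalization and tokenization shared by the dictionary compiler and
## the tagger. Offsets are 0-based, half-open, in characters (not bytes).

#' Normalize whitespace and Unicode form of a string
#'
#' Applies NFC Unicode normalization, collapses runs of whitespace to a
#' single space and trims. Used on every dictionary surface and on section
#' text before key construction so matching is reproducible.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @keywords internal
normalizeString <- function(x) {
  x <- stringi::stri_trans_nfc(enc2utf8(x))
  x <- gsub("[[:space:]]+", " ", x, perl = TRUE)
  trimws(x)
}

## Token pattern: alphanumeric runs, allowing internal hyphens/apostrophes
## ("drug-induced", "Stevens-Johnson"). Punctuation never enters a token, so
## boundary punctuation is stripped implicitly.
.TOKEN_RE <- "[A-Za-z0-9]+(?:['’-][A-Za-z0-9]+)*"

#' Tokenize text with character offsets
#'
#' @param text a single string.
#' @return data.frame with columns `token`, `start` (0-based) and `length`,
#'   one row per token, in text order.
#' @keywords internal
tokenizeText <- function(text) {
  stopifnot(length(text) == 1L)
  text <- enc2utf8(text)
  m <- gregexpr(.TOKEN_RE, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(token = character(), start = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(token = substring(text, starts, starts + lens - 1L),
             start = starts - 1L, length = lens, stringsAsFactors = FALSE)
}

#' Canonical surface key of a phrase
#'
#' NFC-normalizes, tokenizes (dropping boundary punctuation) and rejoins
#' tokens with single spaces. Case is preserved; callers lower-case for
#' case-insensitive indexing.
#'
#' @param x character vector of phrases.
#' @return character vector of keys ("" where no token survives).
#' @keywords internal
surfaceKey <- function(x) {
  vapply(x, function(s) {
    toks <- tokenizeText(normalizeString(s))$token
    paste(toks, collapse = " ")
  }, character(1L), USE.NAMES = FALSE)
}

## Character slice of `text` at 0-based half-open [start, start + length).
sliceText <- function(text, start, length) {
  substring(text, start + 1L, start + length)
}
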