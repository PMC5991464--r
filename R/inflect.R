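## Rule-based English noun inflection used for dictionary expansion: where a
## vocabulary carries only one grammatical number of a term, the other is
## generated ("peripheral neuropathy" <-> "peripheral neuropathies").
## Deliberately conservative: a wrong plural in the index creates false
## positives, so uninflectable-looking words are passed through.

.IRREGULAR_PLURALS <- c(
  man = "men", woman = "women", foot = "feet", tooth = "teeth",
  child = "children", oedema = "oedemas", edema = "edemas"
)

## Words we refuse to inflect either way: Latin mass nouns and similar forms
## common in clinical vocabularies (pruritus, emesis, ascites, ...).
.noInflect <- function(w) {
  nchar(w) < 3L ||
    grepl("(us|is|os|ics|itis|osis|oma)$", w, perl = TRUE) ||
    grepl("^[A-Z0-9]+$", w, perl = TRUE)   # acronyms stay as-is
}

#' Pluralize a single English word
#'
#' @param word a single word (no spaces).
#' @return the plural form, or `NA_character_` when no plural is generated
#'   (mass nouns, Latin endings, acronyms, already-plural forms).
#' @keywords internal
pluralizeWord <- function(word) {
  lw <- tolower(word)
  if (lw %in% names(.IRREGULAR_PLURALS)) {
    return(.matchCase(.IRREGULAR_PLURALS[[lw]], word))
  }
  if (.noInflect(word) || grepl("s$", lw)) return(NA_character_)
  if (grepl("[^aeiou]y$", lw)) {
    return(paste0(substr(word, 1L, nchar(word) - 1L), "ies"))
  }
  if (grepl("(x|z|ch|sh)$", lw)) return(paste0(word, "es"))
  paste0(word, "s")
}

#' Singularize a single English word
#'
#' Inverse of [pluralizeWord()]; returns `NA_character_` when the word does
#' not look plural.
#'
#' @param word a single word.
#' @keywords internal
singularizeWord <- function(word) {
  lw <- tolower(word)
  irr <- names(.IRREGULAR_PLURALS)[match(lw, .IRREGULAR_PLURALS)]
  if (!is.na(irr)) return(.matchCase(irr, word))
  if (grepl("^[A-Z0-9]+$", word, perl = TRUE)) return(NA_character_)
  if (grepl("ies$", lw) && nchar(word) > 4L) {
    return(paste0(substr(word, 1L, nchar(word) - 3L), "y"))
  }
  if (grepl("(xes|zes|ches|shes)$", lw)) {
    return(substr(word, 1L, nchar(word) - 2L))
  }
  if (grepl("s$", lw) && !grepl("(ss|us|is|os)$", lw)) {
    return(substr(word, 1L, nchar(word) - 1L))
  }
  NA_character_
}

## Copy leading-capital / all-caps pattern of `model` onto `w`.
.matchCase <- function(w, model) {
  if (grepl("^[A-Z]", model)) {
    paste0(toupper(substr(w, 1L, 1L)), substr(w, 2L, nchar(w)))
  } else w
}

#' Expand a term to its singular/plural surface variants
#'
#' Inflects the head noun (final token) of a phrase, returning the term
#' itself plus any generated singular and plural variants. The operation is
#' closed: expanding any returned form yields only forms already in the set.
#'
#' @param term a non-empty phrase.
#' @return character vector of surface forms, always containing `term`.
#' @examples
#' expandNumber("peripheral neuropathy")  # adds "peripheral neuropathies"
#' expandNumber("rash")                   # adds "rashes"
#' expandNumber("pruritus")               # identity only
#' @export
expandNumber <- function(term) {
  stopifnot(is.character(term), length(term) == 1L, nzchar(trimws(term)))
  term <- normalizeString(term)
  toks <- tokenizeText(term)
  if (nrow(toks) == 0L) return(term)
  head_tok <- toks$token[nrow(toks)]
  replaceHead <- function(h) {
    if (is.na(h)) return(character())
    start <- toks$start[nrow(toks)]
    paste0(substr(term, 1L, start), h)
  }
  out <- term
  sg <- singularizeWord(head_tok)
  pl <- pluralizeWord(head_tok)
  out <- c(out, replaceHead(pl), replaceHead(sg))
  if (!is.na(sg)) out <- c(out, replaceHead(pluralizeWord(sg)))
  if (!is.na(pl)) out <- c(out, replaceHead(singularizeWord(pl)))
  unique(out[nzchar(out)])
}
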