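## Dictionary loading, rule-based expansion and compilation into a
## matchable surface index.

#' Expansion configuration for dictionary compilation
#'
#' @param minAcronymLen surfaces shorter than this many characters are
#'   treated as acronym short forms: indexed only when declared in an
#'   entry's abbreviation lexicon, matched case-sensitively. Default 5.
#' @param stoplist lower-cased surfaces never indexed as short forms;
#'   guards against ambiguous acronyms such as "all" (acute lymphocytic
#'   leukaemia) and "aids".
#' @param directionGroups named list of direction-word synonym groups used
#'   by [generateLabVariants()]. A preferred name ending in any listed word
#'   is treated as a laboratory-test finding "<analyte> <direction>".
#' @return a list with class-checked components, suitable for
#'   [compileDictionary()].
#' @export
dictConfig <- function(minAcronymLen = 5L,
                       stoplist = c("all", "aids"),
                       directionGroups = list(
                         increase = c("increased", "elevated", "high", "raised"),
                         decrease = c("decreased", "reduced", "low", "lowered"))) {
  stopifnot(minAcronymLen >= 1L, is.list(directionGroups))
  list(minAcronymLen = as.integer(minAcronymLen),
       stoplist = tolower(stoplist),
       directionGroups = lapply(directionGroups, tolower))
}

#' Load a term dictionary from a tab-separated table
#'
#' Expected columns: `term_id`, `preferred_name`, `synonyms`
#' (pipe-separated, may be empty) and `abbreviations` (pipe-separated
#' `long form=SHORT` pairs, may be empty). The returned dictionary is not
#' yet compiled; pass it to [compileDictionary()].
#'
#' @param path path to the TSV file (header row required).
#' @return an uncompiled [TermDictionary-class].
#' @export
loadTermTable <- function(path) {
  stopifnot(file.exists(path))
  raw <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", check.names = FALSE,
                    encoding = "UTF-8")
  need <- c("term_id", "preferred_name", "synonyms", "abbreviations")
  if (!all(need %in% names(raw)))
    stop(sprintf("dictionary table must have columns %s",
                 paste(need, collapse = ", ")))
  n <- nrow(raw)
  syn <- vector("list", n); abb <- vector("list", n)
  for (i in seq_len(n)) {
    line <- i + 1L   # 1-based file line incl. header
    id <- trimws(raw$term_id[i]); pn <- normalizeString(raw$preferred_name[i])
    if (!nzchar(id) || !nzchar(pn))
      stop(sprintf("parse error at line %d: empty term_id or preferred_name",
                   line))
    s <- strsplit(raw$synonyms[i], "|", fixed = TRUE)[[1L]]
    s <- normalizeString(s); s <- s[nzchar(s)]
    syn[[i]] <- setdiff(unique(s), pn)
    a <- strsplit(raw$abbreviations[i], "|", fixed = TRUE)[[1L]]
    a <- trimws(a); a <- a[nzchar(a)]
    if (length(a)) {
      bad <- !grepl("=", a, fixed = TRUE)
      if (any(bad))
        stop(sprintf("parse error at line %d: abbreviation '%s' is not a long=short pair",
                     line, a[bad][1L]))
      long <- normalizeString(sub("=.*$", "", a))
      short <- normalizeString(sub("^[^=]*=", "", a))
      if (any(!nzchar(long)) || any(!nzchar(short)))
        stop(sprintf("parse error at line %d: empty abbreviation side", line))
      abb[[i]] <- setNames(short, long)
    } else abb[[i]] <- setNames(character(), character())
    raw$term_id[i] <- id; raw$preferred_name[i] <- pn
  }
  if (anyDuplicated(raw$term_id))
    stop(sprintf("duplicate term_id: %s",
                 paste(unique(raw$term_id[duplicated(raw$term_id)]),
                       collapse = ", ")))
  entries <- data.frame(term_id = raw$term_id,
                        preferred_name = raw$preferred_name,
                        stringsAsFactors = FALSE)
  entries$synonyms <- syn
  entries$abbreviations <- abb
  new("TermDictionary", entries = entries, indexCI = list(),
      indexCS = list(), config = dictConfig(), compiled = FALSE)
}

#' Generate laboratory-finding surface variants of a preferred name
#'
#' Preferred names of the shape `"<analyte phrase> <direction word>"`
#' (e.g. "Aspartate aminotransferase increased") are expanded to all
#' combinations of analyte phrase or abbreviation short form, each synonym
#' of the direction word's group, in both prefix ("increased AST") and
#' postfix ("AST elevated") order. Names not matching the pattern are
#' returned unchanged.
#'
#' @param preferredName the entry's preferred name.
#' @param abbreviations named character vector (long form -> short form).
#' @param config a [dictConfig()] list (supplies the direction groups).
#' @return character vector of surface forms, always containing
#'   `preferredName`.
#' @examples
#' generateLabVariants("Aspartate aminotransferase increased",
#'                     c("aspartate aminotransferase" = "AST"))
#' @export
generateLabVariants <- function(preferredName,
                                abbreviations = setNames(character(), character()),
                                config = dictConfig()) {
  pn <- normalizeString(preferredName)
  toks <- tokenizeText(pn)
  if (nrow(toks) < 2L) return(pn)
  last <- tolower(toks$token[nrow(toks)])
  grp <- NULL
  for (g in config$directionGroups) if (last %in% g) { grp <- g; break }
  if (is.null(grp)) return(pn)
  analyte <- trimws(substr(pn, 1L, toks$start[nrow(toks)]))
  analytes <- analyte
  if (length(abbreviations)) {
    hit <- tolower(surfaceKey(names(abbreviations))) == tolower(surfaceKey(analyte))
    analytes <- c(analytes, unname(abbreviations[hit]))
  }
  forms <- pn
  for (a in analytes) for (d in grp)
    forms <- c(forms, paste(d, a), paste(a, d))
  unique(forms)
}

#' Compile a term dictionary into a matchable surface index
#'
#' For every entry the compiler indexes the preferred name, every synonym,
#' every abbreviation short form and all laboratory-finding variants, each
#' closed under singular/plural expansion ([expandNumber()]). Surfaces of
#' at least `config$minAcronymLen` characters are indexed lower-cased for
#' case-insensitive matching; shorter surfaces are indexed exact-case and
#' only when they are declared abbreviation short forms of the entry and
#' not stoplisted (the acronym guard).
#'
#' @param x an uncompiled [TermDictionary-class], or the `entries`
#'   data.frame of one.
#' @param config expansion configuration from [dictConfig()].
#' @return a compiled [TermDictionary-class].
#' @export
compileDictionary <- function(x, config = dictConfig()) {
  entries <- if (is(x, "TermDictionary")) x@entries else x
  indexCI <- new.env(parent = emptyenv())
  indexCS <- new.env(parent = emptyenv())
  add <- function(env, key, id) {
    env[[key]] <- c(env[[key]], id)
  }
  for (i in seq_len(nrow(entries))) {
    id <- entries$term_id[i]
    abbr <- entries$abbreviations[[i]]
    base <- c(entries$preferred_name[i], entries$synonyms[[i]])
    base <- unique(unlist(lapply(base, generateLabVariants,
                                 abbreviations = abbr, config = config)))
    base <- c(base, unname(abbr))
    ## inflect both the raw surface and its case-folded form so the index
    ## is closed under number expansion of its own (lower-cased) keys
    surfaces <- unique(unlist(lapply(base, function(b)
      union(expandNumber(b), expandNumber(tolower(b))))))
    shortForms <- surfaceKey(unname(abbr))
    for (s in surfaces) {
      key <- surfaceKey(s)
      if (!nzchar(key)) next
      if (nchar(key) >= config$minAcronymLen) {
        add(indexCI, tolower(key), id)
      } else {
        if (!key %in% shortForms) next          # acronym guard
        if (tolower(key) %in% config$stoplist) next
        add(indexCS, key, id)
      }
    }
  }
  tidy <- function(env) {
    out <- as.list(env)
    if (!length(out)) return(list())
    out <- lapply(out, function(v) sort(unique(v)))
    out[order(names(out))]
  }
  new("TermDictionary", entries = entries,
      indexCI = tidy(indexCI), indexCS = tidy(indexCS),
      config = config, compiled = TRUE)
}
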