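## Dictionary tagging: leftmost-longest matching over token boundaries,
## header filtering, and normalization of mentions to per-drug profiles.

.emptyMentions <- function() {
  m <- data.frame(section_id = character(), start = integer(),
                  length = integer(), surface = character(),
                  stringsAsFactors = FALSE)
  m$term_ids <- list()
  m
}

#' Tag ADR mentions in a label document
#'
#' Scans each section with leftmost-longest matching at token boundaries:
#' at every token the longest indexed surface starting there wins; shorter
#' matches inside it are suppressed and scanning resumes after it.
#' Case-insensitive for surfaces of at least `minAcronymLen` characters,
#' exact-case for declared acronym short forms (the acronym guard), so the
#' ordinary word "all" never maps to an "ALL" abbreviation. Ambiguous
#' surfaces yield a mention carrying every matched term id.
#'
#' @param doc a [LabelDocument-class].
#' @param dict a compiled [TermDictionary-class].
#' @return data.frame of mentions with columns `section_id`, `start`,
#'   `length` (0-based half-open character offsets), `surface` and
#'   list-column `term_ids`; ordered by section then start. No two
#'   mentions in a section overlap.
#' @export
tagDocument <- function(doc, dict) {
  stopifnot(is(doc, "LabelDocument"), is(dict, "TermDictionary"))
  if (!dict@compiled) stop("dictionary must be compiled first")
  maxTok <- .maxKeyTokens(dict)
  out <- list()
  s <- doc@sections
  for (si in seq_len(nrow(s))) {
    text <- s$text[si]
    toks <- tokenizeText(text)
    n <- nrow(toks)
    i <- 1L
    while (i <= n) {
      hit_len <- 0L; hit_ids <- NULL
      for (len in seq(min(maxTok, n - i + 1L), 1L)) {
        j <- i + len - 1L
        key <- paste(toks$token[i:j], collapse = " ")
        ids <- dict@indexCI[[tolower(key)]]
        if (is.null(ids)) ids <- dict@indexCS[[key]]
        if (!is.null(ids)) { hit_len <- len; hit_ids <- ids; break }
      }
      if (hit_len > 0L) {
        j <- i + hit_len - 1L
        start <- toks$start[i]
        end <- toks$start[j] + toks$length[j]
        out[[length(out) + 1L]] <- list(
          section_id = s$section_id[si], start = start,
          length = end - start,
          surface = sliceText(text, start, end - start),
          term_ids = sort(hit_ids))
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (!length(out)) return(.emptyMentions())
  m <- data.frame(section_id = vapply(out, `[[`, "", "section_id"),
                  start = vapply(out, `[[`, 0L, "start"),
                  length = vapply(out, `[[`, 0L, "length"),
                  surface = vapply(out, `[[`, "", "surface"),
                  stringsAsFactors = FALSE)
  m$term_ids <- lapply(out, `[[`, "term_ids")
  ord <- order(match(m$section_id, s$section_id), m$start)
  m <- m[ord, , drop = FALSE]
  rownames(m) <- NULL
  m
}

.maxKeyTokens <- function(dict) {
  keys <- c(names(dict@indexCI), names(dict@indexCS))
  if (!length(keys)) return(1L)
  max(lengths(strsplit(keys, " ", fixed = TRUE)))
}

#' Remove mentions overlapping section or table headers
#'
#' A mention is dropped when its span intersects any header span (any
#' overlap, including straddling a boundary); all other mentions pass
#' through unchanged.
#'
#' @param mentions mention data.frame from [tagDocument()].
#' @param headers header spans from [detectHeaders()] (columns
#'   `section_id`, `start`, `length`).
#' @return the filtered mention data.frame.
#' @export
filterHeaders <- function(mentions, headers) {
  if (!nrow(mentions) || !nrow(headers)) return(mentions)
  keep <- vapply(seq_len(nrow(mentions)), function(i) {
    h <- headers[headers$section_id == mentions$section_id[i], , drop = FALSE]
    if (!nrow(h)) return(TRUE)
    a0 <- mentions$start[i]; a1 <- a0 + mentions$length[i]
    !any(a0 < h$start + h$length & h$start < a1)
  }, logical(1L))
  out <- mentions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse mentions from all of a drug's labels into an ADR profile
#'
#' A drug can have multiple brands with different labels; the profile is
#' the union over labels at the level of normalized preferred terms.
#' Ambiguous mentions (more than one matched id) contribute one count to
#' every matched id.
#'
#' @param drugName drug name.
#' @param mentionsList a list of mention data.frames (one per label), or a
#'   single mention data.frame.
#' @return a [DrugAdrProfile-class].
#' @export
normalizeToProfile <- function(drugName, mentionsList) {
  if (is.data.frame(mentionsList)) mentionsList <- list(mentionsList)
  ids <- unlist(lapply(mentionsList, function(m) unlist(m$term_ids)),
                use.names = FALSE)
  counts <- if (length(ids)) table(ids) else table(character())
  mc <- setNames(as.integer(counts), names(counts))
  if (length(mc)) mc <- mc[order(names(mc))]
  new("DrugAdrProfile", drugName = drugName, mentionCount = mc)
}

#' Build a DrugAdrTable from per-drug profiles
#'
#' @param profiles a list of [DrugAdrProfile-class] objects.
#' @return a [DrugAdrTable-class] mapping each drug to its ADR term set.
#' @export
profilesToTable <- function(profiles) {
  stopifnot(all(vapply(profiles, is, logical(1L), "DrugAdrProfile")))
  sets <- lapply(profiles, adrTerms)
  names(sets) <- vapply(profiles, drugName, character(1L))
  drugAdrTable(sets)
}
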