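## Central S4 containers. Validity methods enforce the structural invariants;
## everything downstream may assume them.

#' TermDictionary: a matchable ADR vocabulary
#'
#' Holds preferred-term entries (with synonyms and abbreviation lexicon) and,
#' once compiled, a surface-form index. Surfaces at least
#' `minAcronymLen` characters long are matched case-insensitively
#' (`indexCI`, lower-cased keys); shorter surfaces are acronym short forms,
#' matched case-sensitively (`indexCS`) and suppressed when stoplisted.
#'
#' @slot entries data.frame with columns `term_id`, `preferred_name`,
#'   list-column `synonyms` (character vectors) and list-column
#'   `abbreviations` (named character vectors, names = long forms,
#'   values = short forms).
#' @slot indexCI named list: lower-cased surface key -> character vector of
#'   term ids (ambiguity preserved).
#' @slot indexCS named list: exact-case short surface -> term ids.
#' @slot config expansion configuration (see [dictConfig()]).
#' @slot compiled logical scalar.
#' @exportClass TermDictionary
setClass("TermDictionary",
  representation(entries = "data.frame", indexCI = "list", indexCS = "list",
                 config = "list", compiled = "logical"))

setValidity("TermDictionary", function(object) {
  e <- object@entries
  need <- c("term_id", "preferred_name", "synonyms", "abbreviations")
  if (!all(need %in% names(e)))
    return(sprintf("entries must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(e$term_id))
    return(sprintf("duplicate term_id: %s",
                   paste(unique(e$term_id[duplicated(e$term_id)]), collapse = ", ")))
  if (any(!nzchar(trimws(e$term_id))) || any(!nzchar(trimws(e$preferred_name))))
    return("term_id and preferred_name must be non-empty")
  for (i in seq_len(nrow(e))) {
    if (e$preferred_name[i] %in% e$synonyms[[i]])
      return(sprintf("entry %s: preferred_name repeated among synonyms", e$term_id[i]))
  }
  TRUE
})

#' Ontology: an is-a DAG of named terms
#'
#' @slot terms data.frame with columns `id`, `name`.
#' @slot parents named list: term id -> character vector of parent ids
#'   (empty for roots). The relation must be acyclic.
#' @exportClass Ontology
setClass("Ontology", representation(terms = "data.frame", parents = "list"))

setValidity("Ontology", function(object) {
  ids <- object@terms$id
  if (anyDuplicated(ids)) return("duplicate term ids")
  if (!setequal(names(object@parents), ids))
    return("parents list must have exactly one element per term id")
  all_parents <- unique(unlist(object@parents, use.names = FALSE))
  unknown <- setdiff(all_parents, ids)
  if (length(unknown))
    return(sprintf("is_a parent(s) not defined as terms: %s",
                   paste(unknown, collapse = ", ")))
  cyc <- .findCycle(object@parents)
  if (!is.null(cyc))
    return(sprintf("is_a relation contains a cycle: %s",
                   paste(cyc, collapse = " -> ")))
  TRUE
})

#' LabelDocument: one structured drug label
#'
#' @slot drugName generic drug name the label belongs to.
#' @slot labelId unique label identifier.
#' @slot sections data.frame with columns `section_id`, `title`, `text`
#'   (plus any extra attributes preserved from the source XML).
#' @slot goldMentions `NULL` when the label is unannotated, else a
#'   data.frame with columns `section_id`, `start`, `length`,
#'   `mention_type`, `surface` (0-based half-open character offsets).
#' @slot goldReactions `NULL` or character vector of normalized term ids.
#' @slot headerRows data.frame of table-header rows flagged in the source
#'   markup: columns `section_id`, `start`, `length`.
#' @slot extraAttrs named character vector of unrecognized attributes on the
#'   root element, preserved on round trip.
#' @exportClass LabelDocument
setClass("LabelDocument",
  representation(drugName = "character", labelId = "character",
                 sections = "data.frame", goldMentions = "ANY",
                 goldReactions = "ANY", headerRows = "data.frame",
                 extraAttrs = "character"))

setValidity("LabelDocument", function(object) {
  s <- object@sections
  if (!all(c("section_id", "title", "text") %in% names(s)))
    return("sections needs columns section_id, title, text")
  if (anyDuplicated(s$section_id)) return("section_ids must be unique")
  gm <- object@goldMentions
  if (!is.null(gm)) {
    for (i in seq_len(nrow(gm))) {
      sec <- match(gm$section_id[i], s$section_id)
      if (is.na(sec))
        return(sprintf("gold mention %d references unknown section '%s'",
                       i, gm$section_id[i]))
      got <- sliceText(s$text[sec], gm$start[i], gm$length[i])
      if (!identical(got, gm$surface[i]))
        return(sprintf(
          "gold mention %d: text slice '%s' does not equal str attribute '%s'",
          i, got, gm$surface[i]))
    }
  }
  TRUE
})

#' DrugAdrProfile: normalized per-drug ADR profile
#'
#' @slot drugName drug name.
#' @slot mentionCount named integer vector: term id -> number of tagged
#'   mentions across all of the drug's labels (ambiguous mentions count for
#'   every matched id). The ADR term set is `names(mentionCount)`.
#' @exportClass DrugAdrProfile
setClass("DrugAdrProfile",
  representation(drugName = "character", mentionCount = "integer"))

setValidity("DrugAdrProfile", function(object) {
  mc <- object@mentionCount
  if (length(mc) && (is.null(names(mc)) || any(!nzchar(names(mc)))))
    return("mentionCount must be named by term id")
  if (any(mc <= 0L)) return("mentionCount entries must be positive")
  TRUE
})

#' DrugAdrTable: drug -> ADR-term-set table feeding network construction
#'
#' @slot drugs character vector of unique drug names.
#' @slot profiles named list (per drug) of character vectors of term ids.
#' @exportClass DrugAdrTable
setClass("DrugAdrTable",
  representation(drugs = "character", profiles = "list"))

setValidity("DrugAdrTable", function(object) {
  if (anyDuplicated(object@drugs)) return("drug names must be unique")
  if (!identical(names(object@profiles), object@drugs))
    return("profiles must be named by drugs, in order")
  TRUE
})

#' AdrNetwork: thresholded ADR-ADR co-occurrence network
#'
#' Undirected; an edge joins two ADR terms when they co-occur in at least
#' `minCount` drugs of the source table; edge weight is that drug count.
#' Terms with no qualifying edge are excluded from `nodes`.
#'
#' @slot nodes character vector of term ids with degree >= 1.
#' @slot edges data.frame with columns `a`, `b` (a < b), `weight`.
#' @slot thresholdFraction fraction of drugs required, in (0, 1].
#' @slot minCount the resulting integer drug-count threshold.
#' @slot support named integer: term id -> number of drugs listing the ADR
#'   (over all terms in the source table, not only surviving nodes).
#' @exportClass AdrNetwork
setClass("AdrNetwork",
  representation(nodes = "character", edges = "data.frame",
                 thresholdFraction = "numeric", minCount = "integer",
                 support = "integer"))

setValidity("AdrNetwork", function(object) {
  e <- object@edges
  if (!all(c("a", "b", "weight") %in% names(e)))
    return("edges needs columns a, b, weight")
  if (any(e$a == e$b)) return("self-loops are not allowed")
  if (nrow(e) && any(e$weight < object@minCount))
    return("all edge weights must be >= minCount")
  sup <- object@support
  if (nrow(e)) {
    cap <- pmin(sup[e$a], sup[e$b])
    if (any(e$weight > cap))
      return("edge weight exceeds min(support) of its endpoints")
  }
  if (!setequal(object@nodes, unique(c(e$a, e$b))))
    return("nodes must be exactly the edge endpoints")
  TRUE
})

#' SubOntology: an extracted hierarchical view over selected terms
#'
#' @slot terms data.frame (`id`, `name`) of included terms.
#' @slot edges data.frame (`child`, `parent`): the source ontology's is_a
#'   reachability restricted to included terms, transitively reduced.
#' @slot selected character vector of the originally selected ids.
#' @slot inclusionMode `"computed_intermediate"` or `"ancestors_all"`.
#' @exportClass SubOntology
setClass("SubOntology",
  representation(terms = "data.frame", edges = "data.frame",
                 selected = "character", inclusionMode = "character"))

## ---- show methods -------------------------------------------------------

setMethod("show", "TermDictionary", function(object) {
  cat(sprintf("TermDictionary: %d entries, %s\n", nrow(object@entries),
              if (object@compiled)
                sprintf("compiled (%d case-insensitive + %d case-sensitive surfaces)",
                        length(object@indexCI), length(object@indexCS))
              else "not compiled"))
})

setMethod("show", "Ontology", function(object) {
  cat(sprintf("Ontology: %d terms, %d is_a edges, %d root(s)\n",
              nrow(object@terms),
              sum(lengths(object@parents)), length(oboRoots(object))))
})

setMethod("show", "LabelDocument", function(object) {
  cat(sprintf("LabelDocument '%s' (drug %s): %d section(s), %s, %s\n",
              object@labelId, object@drugName, nrow(object@sections),
              if (is.null(object@goldMentions)) "no gold mentions"
              else sprintf("%d gold mention(s)", nrow(object@goldMentions)),
              if (is.null(object@goldReactions)) "no gold reactions"
              else sprintf("%d gold reaction(s)", length(object@goldReactions))))
})

setMethod("show", "DrugAdrProfile", function(object) {
  cat(sprintf("DrugAdrProfile '%s': %d ADR term(s), %d mention(s)\n",
              object@drugName, length(object@mentionCount),
              sum(object@mentionCount)))
})

setMethod("show", "DrugAdrTable", function(object) {
  cat(sprintf("DrugAdrTable: %d drug(s), %d distinct ADR term(s)\n",
              length(object@drugs),
              length(unique(unlist(object@profiles, use.names = FALSE)))))
})

setMethod("show", "AdrNetwork", function(object) {
  cat(sprintf(
    "AdrNetwork: %d nodes, %d edges (co-occurrence in >= %d drugs, fraction %.2f)\n",
    length(object@nodes), nrow(object@edges), object@minCount,
    object@thresholdFraction))
})

setMethod("show", "SubOntology", function(object) {
  cat(sprintf("SubOntology [%s]: %d terms (%d selected), %d edges\n",
              object@inclusionMode, nrow(object@terms),
              length(object@selected), nrow(object@edges)))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for adrminer containers
#'
#' Small read-only accessors for the S4 containers; user code should prefer
#' these over direct slot access.
#'
#' @param x the object.
#' @name accessors
#' @aliases termEntries dictConfigOf oboTerms termParents oboRoots sections
#'   goldMentions goldReactions drugName labelId adrTerms mentionCounts
#'   networkNodes networkEdges networkSupport tableDrugs tableProfiles
NULL

#' @rdname accessors
#' @export
termEntries <- function(x) { stopifnot(is(x, "TermDictionary")); x@entries }

#' @rdname accessors
#' @export
dictConfigOf <- function(x) { stopifnot(is(x, "TermDictionary")); x@config }

#' Look up the term ids indexed under a surface form
#'
#' @param dict a compiled [TermDictionary-class].
#' @param surface a surface string as it would appear in text.
#' @return character vector of term ids (empty when unmatched).
#' @export
lookupSurface <- function(dict, surface) {
  stopifnot(is(dict, "TermDictionary"), dict@compiled)
  key <- surfaceKey(surface)
  hit <- dict@indexCI[[tolower(key)]]
  if (!is.null(hit)) return(hit)
  hit <- dict@indexCS[[key]]
  if (!is.null(hit)) hit else character()
}

#' @rdname accessors
#' @export
oboTerms <- function(x) { stopifnot(is(x, "Ontology")); x@terms }

#' @rdname accessors
#' @export
termParents <- function(x) { stopifnot(is(x, "Ontology")); x@parents }

#' @rdname accessors
#' @export
oboRoots <- function(x) {
  stopifnot(is(x, "Ontology"))
  names(x@parents)[lengths(x@parents) == 0L]
}

#' @rdname accessors
#' @export
sections <- function(x) { stopifnot(is(x, "LabelDocument")); x@sections }

#' @rdname accessors
#' @export
goldMentions <- function(x) { stopifnot(is(x, "LabelDocument")); x@goldMentions }

#' @rdname accessors
#' @export
goldReactions <- function(x) { stopifnot(is(x, "LabelDocument")); x@goldReactions }

#' @rdname accessors
#' @export
drugName <- function(x) {
  stopifnot(is(x, "LabelDocument") || is(x, "DrugAdrProfile"))
  x@drugName
}

#' @rdname accessors
#' @export
labelId <- function(x) { stopifnot(is(x, "LabelDocument")); x@labelId }

#' @rdname accessors
#' @export
adrTerms <- function(x) {
  stopifnot(is(x, "DrugAdrProfile"))
  names(x@mentionCount)
}

#' @rdname accessors
#' @export
mentionCounts <- function(x) { stopifnot(is(x, "DrugAdrProfile")); x@mentionCount }

#' @rdname accessors
#' @export
networkNodes <- function(x) { stopifnot(is(x, "AdrNetwork")); x@nodes }

#' @rdname accessors
#' @export
networkEdges <- function(x) { stopifnot(is(x, "AdrNetwork")); x@edges }

#' @rdname accessors
#' @export
networkSupport <- function(x) { stopifnot(is(x, "AdrNetwork")); x@support }

#' @rdname accessors
#' @export
tableDrugs <- function(x) { stopifnot(is(x, "DrugAdrTable")); x@drugs }

#' @rdname accessors
#' @export
tableProfiles <- function(x) { stopifnot(is(x, "DrugAdrTable")); x@profiles }

#' Construct a DrugAdrTable from per-drug ADR term sets
#'
#' @param profiles named list: drug name -> character vector of term ids.
#' @return a [DrugAdrTable-class].
#' @export
drugAdrTable <- function(profiles) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  profiles <- lapply(profiles, function(p) sort(unique(as.character(p))))
  new("DrugAdrTable", drugs = names(profiles), profiles = profiles)
}
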