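## Ontology-based drug class-effect analysis: map drugs into chemical
## ontology classes (ancestor closure), compute the proportional
## class-level ratio (PCR) of each (class, ADR) pair, flag class effects
## (PCR = 1), and extract the hierarchical sub-ontology of shared ADRs.

#' Assign every drug to all ontology ancestors of its chemical term
#'
#' @param drugTerms named character vector: drug name -> ontology term id
#'   of the drug's chemical.
#' @param ontology an [Ontology-class] (e.g. a chemical classification).
#' @return named list: drug name -> character vector of class ids (all
#'   is-a ancestors of the drug's term; ancestor-closed by construction).
#' @export
assignClasses <- function(drugTerms, ontology) {
  stopifnot(is(ontology, "Ontology"), !is.null(names(drugTerms)))
  known <- names(ontology@parents)
  missing <- !drugTerms %in% known
  if (any(missing))
    stop(sprintf("drug(s) with chemical term absent from ontology: %s",
                 paste(names(drugTerms)[missing], collapse = ", ")))
  lapply(setNames(as.character(drugTerms), names(drugTerms)),
         function(t) ancestorsOf(ontology, t))
}

#' Drugs belonging to a class
#'
#' @param classId ontology class id.
#' @param assignment output of [assignClasses()].
#' @param table optional [DrugAdrTable-class]; when given, membership is
#'   restricted to drugs present in the table.
#' @return character vector of drug names.
#' @export
classMembers <- function(classId, assignment, table = NULL) {
  members <- names(assignment)[vapply(assignment, function(cl)
    classId %in% cl, logical(1L))]
  if (!is.null(table)) members <- intersect(members, tableDrugs(table))
  members
}

#' Proportional class-level ratio (PCR) of one (class, ADR) pair
#'
#' PCR is the fraction of the class's drugs whose ADR profile contains the
#' ADR. A drug class effect exists exactly when PCR = 1, i.e. every drug
#' in the class is associated with the adverse event.
#'
#' @param classId ontology class id with at least one member drug in
#'   `table`.
#' @param adrTermId ADR term id.
#' @param assignment output of [assignClasses()].
#' @param table a [DrugAdrTable-class].
#' @return one-row data.frame with columns `class_id`, `adr_term_id`,
#'   `n_class_drugs`, `n_with_adr`, `pcr`, `class_effect`.
#' @export
computePcr <- function(classId, adrTermId, assignment, table) {
  stopifnot(is(table, "DrugAdrTable"))
  members <- classMembers(classId, assignment, table)
  if (!length(members))
    stop(sprintf("class '%s' has no member drugs in the table", classId))
  nWith <- sum(vapply(table@profiles[members],
                      function(p) adrTermId %in% p, logical(1L)))
  pcr <- nWith / length(members)
  data.frame(class_id = classId, adr_term_id = adrTermId,
             n_class_drugs = length(members), n_with_adr = as.integer(nWith),
             pcr = pcr, class_effect = pcr == 1,
             stringsAsFactors = FALSE)
}

#' PCR table over all classes and ADRs
#'
#' @param assignment output of [assignClasses()].
#' @param table a [DrugAdrTable-class].
#' @param minClassSize smallest class (member drugs in the table) to
#'   report; default 2, so single-drug "classes" are not called class
#'   effects.
#' @param adrIds optional restriction of the ADR id set (default: every
#'   ADR appearing in the table).
#' @return data.frame with one row per (class, ADR) pair, columns as in
#'   [computePcr()], ordered by class then ADR.
#' @export
pcrTable <- function(assignment, table, minClassSize = 2L, adrIds = NULL) {
  stopifnot(is(table, "DrugAdrTable"))
  classes <- sort(unique(unlist(assignment, use.names = FALSE)))
  if (is.null(adrIds))
    adrIds <- sort(unique(unlist(table@profiles, use.names = FALSE)))
  rows <- list()
  for (cl in classes) {
    members <- classMembers(cl, assignment, table)
    if (length(members) < minClassSize) next
    inProfile <- vapply(table@profiles[members],
                        function(p) adrIds %in% p, logical(length(adrIds)))
    nWith <- if (length(adrIds) == 1L) sum(inProfile)
             else as.integer(rowSums(matrix(inProfile, nrow = length(adrIds))))
    rows[[length(rows) + 1L]] <- data.frame(
      class_id = cl, adr_term_id = adrIds,
      n_class_drugs = length(members), n_with_adr = nWith,
      pcr = nWith / length(members),
      class_effect = nWith == length(members),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(class_id = character(), adr_term_id = character(),
                      n_class_drugs = integer(), n_with_adr = integer(),
                      pcr = numeric(), class_effect = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$class_id, out$adr_term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ADRs shared by every drug of a class
#'
#' The intersection of the member drugs' ADR profiles; identical to the
#' set of ADRs with PCR = 1 for the class.
#'
#' @inheritParams computePcr
#' @return character vector of term ids.
#' @export
sharedAdrs <- function(classId, assignment, table) {
  members <- classMembers(classId, assignment, table)
  if (!length(members))
    stop(sprintf("class '%s' has no member drugs in the table", classId))
  sort(Reduce(intersect, table@profiles[members]))
}

#' Extract a hierarchical sub-ontology around selected terms
#'
#' In `"computed_intermediate"` mode (mirroring subtree extraction with
#' computed intermediates) the included set is: the selected terms; every
#' term lying on an upward is-a chain between two selected terms; and, for
#' each selected term, a deterministic path to a root, preferring parents
#' already included and breaking remaining ties by smallest parent id. In
#' `"ancestors_all"` mode all ancestors of all selected terms are
#' included. Output edges are the ontology's is-a reachability restricted
#' to included terms, transitively reduced.
#'
#' @param ontology an [Ontology-class].
#' @param selected character vector of term ids to extract.
#' @param mode `"computed_intermediate"` (default) or `"ancestors_all"`.
#' @return a [SubOntology-class].
#' @export
extractSubtree <- function(ontology, selected,
                           mode = c("computed_intermediate", "ancestors_all")) {
  mode <- match.arg(mode)
  stopifnot(is(ontology, "Ontology"))
  selected <- unique(as.character(selected))
  unknown <- setdiff(selected, names(ontology@parents))
  if (length(unknown))
    stop(sprintf("unknown selected term(s): %s", paste(unknown, collapse = ", ")))

  anc <- lapply(setNames(selected, selected),
                function(s) ancestorsOf(ontology, s))
  if (mode == "ancestors_all") {
    included <- unique(c(selected, unlist(anc, use.names = FALSE)))
  } else {
    ## terms on an upward chain between two selected terms:
    ## u such that u is an ancestor of some selected a and some selected b
    ## is an ancestor of (or equal to) u with a != b
    base <- selected
    ancAll <- unique(unlist(anc, use.names = FALSE))
    for (u in ancAll) {
      below <- selected[vapply(selected, function(a) u %in% anc[[a]], logical(1L))]
      ancU <- ancestorsOf(ontology, u)
      above <- selected[selected %in% c(u, ancU)]
      if (length(below) && length(setdiff(above, below))) base <- c(base, u)
    }
    base <- unique(base)
    ## deterministic path upward for each selected term, preferring parents
    ## already included; iterated to a fixpoint on the induced reduced
    ## graph so that re-extracting an extracted view changes nothing
    included <- .rootPathClosure(ontology@parents, selected, base)
    repeat {
      red <- .reducedParents(ontology, included)
      nxt <- .rootPathClosure(red, selected, base)
      if (setequal(nxt, included)) break
      included <- nxt
    }
  }
  included <- sort(unique(included))

  edges <- .parentsToEdges(.reducedParents(ontology, included))
  terms <- ontology@terms[ontology@terms$id %in% included, , drop = FALSE]
  terms <- terms[order(terms$id), , drop = FALSE]
  rownames(terms) <- NULL
  new("SubOntology", terms = terms, edges = edges, selected = sort(selected),
      inclusionMode = mode)
}

## Walk from each selected term toward a top node of the graph given by
## `parents`, preferring parents already in the accumulating included set,
## then the smallest parent id; returns the accumulated set.
.rootPathClosure <- function(parents, selected, base) {
  included <- base
  for (s in sort(selected)) {
    cur <- s
    repeat {
      ps <- parents[[cur]]
      if (is.null(ps) || !length(ps)) break
      inIncluded <- ps[ps %in% included]
      nxt <- if (length(inIncluded)) sort(inIncluded)[1L] else sort(ps)[1L]
      included <- unique(c(included, nxt))
      cur <- nxt
    }
  }
  included
}

## is-a reachability of the ontology restricted to `included`, transitively
## reduced: each term's minimal included ancestors.
.reducedParents <- function(ontology, included) {
  ancInc <- lapply(setNames(included, included),
                   function(t) intersect(ancestorsOf(ontology, t), included))
  lapply(ancInc, function(ups) {
    keep <- vapply(ups, function(v)
      !any(vapply(setdiff(ups, v), function(w) v %in% ancInc[[w]],
                  logical(1L))), logical(1L))
    sort(ups[keep])
  })
}

.parentsToEdges <- function(parents) {
  edges <- data.frame(
    child = rep(names(parents), lengths(parents)),
    parent = as.character(unlist(parents, use.names = FALSE)),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$child, edges$parent), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Treat an extracted sub-ontology as an ontology
#'
#' @param sub a [SubOntology-class].
#' @return an [Ontology-class] over the included terms with the reduced
#'   edges as its is-a relation.
#' @export
subOntologyAsOntology <- function(sub) {
  stopifnot(is(sub, "SubOntology"))
  parents <- lapply(setNames(sub@terms$id, sub@terms$id), function(id)
    sort(sub@edges$parent[sub@edges$child == id]))
  new("Ontology", terms = sub@terms, parents = parents)
}
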