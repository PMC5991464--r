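## Minimal OBO 1.2 reader/writer for is-a hierarchies (the ChEBI / OAE
## subset this package needs: [Term] stanzas with id, name, is_a,
## is_obsolete). Written in-package because no installed R package parses
## OBO.

#' Load an is-a ontology from an OBO file
#'
#' Parses `[Term]` stanzas, keeping `id`, `name` and `is_a` tags; obsolete
#' terms are skipped. The is_a relation must form a DAG.
#'
#' @param path path to an OBO 1.2-style file.
#' @return an [Ontology-class].
#' @examples
#' f <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: A", "name: leaf", "is_a: B ! mid",
#'              "", "[Term]", "id: B", "name: mid"), f)
#' ont <- loadObo(f)
#' oboRoots(ont)
#' @export
loadObo <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  ids <- character(); nms <- character(); parents <- list()

  in_term <- FALSE
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return()
    if (isTRUE(cur$obsolete)) return()
    if (is.null(cur$id) || !nzchar(cur$id))
      stop(sprintf("OBO parse error near line %d: [Term] stanza without id",
                   cur$line))
    ids <<- c(ids, cur$id)
    nms <<- c(nms, if (is.null(cur$name)) cur$id else cur$name)
    parents[[cur$id]] <<- cur$is_a
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "[Term]") {
      flush(cur)
      cur <- list(line = i, is_a = character(), obsolete = FALSE)
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {           # other stanza type
      flush(cur); cur <- NULL; in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      ln <- sub("\\s*!.*$", "", ln)           # strip trailing comment
      if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
      else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
      else if (grepl("^is_a:", ln)) {
        p <- trimws(sub("^is_a:", "", ln))
        if (nzchar(p)) cur$is_a <- c(cur$is_a, p)
      } else if (grepl("^is_obsolete:\\s*true", ln)) cur$obsolete <- TRUE
    }
  }
  flush(cur)

  if (anyDuplicated(ids))
    stop(sprintf("duplicate term id(s) in OBO file: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  parents <- parents[ids]
  parents[vapply(parents, is.null, logical(1L))] <- list(character())
  ont <- new("Ontology",
             terms = data.frame(id = ids, name = nms, stringsAsFactors = FALSE),
             parents = parents)
  ont
}

## Detect a cycle in a parent-list; returns NULL or one cycle as an id path.
.findCycle <- function(parents) {
  color <- setNames(rep(0L, length(parents)), names(parents)) # 0 new 1 open 2 done
  path <- character()
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    color[v] <<- 1L
    path <<- c(path, v)
    for (p in parents[[v]]) {
      if (!p %in% names(color)) next
      if (color[p] == 1L) {
        i <- match(p, path)
        found <<- c(path[i:length(path)], p)
        return()
      }
      if (color[p] == 0L) visit(p)
      if (!is.null(found)) return()
    }
    color[v] <<- 2L
    path <<- path[-length(path)]
  }
  for (v in names(parents)) if (color[v] == 0L) visit(v)
  found
}

#' All is-a ancestors of a term
#'
#' Breadth-first closure over the parent relation; the term itself is not
#' included.
#'
#' @param ontology an [Ontology-class].
#' @param id a term id present in the ontology.
#' @return character vector of ancestor ids (empty for a root).
#' @export
ancestorsOf <- function(ontology, id) {
  stopifnot(is(ontology, "Ontology"))
  if (!id %in% names(ontology@parents))
    stop(sprintf("unknown term '%s'", id))
  seen <- character()
  frontier <- ontology@parents[[id]]
  while (length(frontier)) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(ontology@parents[frontier], use.names = FALSE))
  }
  sort(seen)
}

#' Write an ontology or extracted sub-ontology to an OBO file
#'
#' @param x an [Ontology-class] or [SubOntology-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeObo <- function(x, path) {
  if (is(x, "SubOntology")) {
    terms <- x@terms
    kids <- split(x@edges$parent, x@edges$child)
    parents <- lapply(terms$id, function(id) {
      p <- kids[[id]]; if (is.null(p)) character() else sort(p)
    })
    names(parents) <- terms$id
  } else {
    stopifnot(is(x, "Ontology"))
    terms <- x@terms
    parents <- x@parents
  }
  nm <- setNames(terms$name, terms$id)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (id in terms$id) {
    writeLines(c("", "[Term]", paste0("id: ", id),
                 paste0("name: ", nm[[id]])), con)
    for (p in parents[[id]])
      writeLines(sprintf("is_a: %s ! %s", p, nm[[p]]), con)
  }
  invisible(path)
}
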