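## Fixture builders and independent oracles. Oracles deliberately use
## different primitives than the implementation (explicit loops, dense
## eigendecomposition, path enumeration) so the two routes cross-check.

## one-row dictionary entries data.frame
makeEntry <- function(id, preferred, synonyms = character(),
                      abbreviations = setNames(character(), character())) {
  e <- data.frame(term_id = id, preferred_name = preferred,
                  stringsAsFactors = FALSE)
  e$synonyms <- list(synonyms)
  e$abbreviations <- list(abbreviations)
  e
}

makeEntries <- function(...) do.call(rbind, list(...))

astEntry <- function() {
  makeEntry("10003481", "Aspartate aminotransferase increased",
            abbreviations = c("aspartate aminotransferase" = "AST"))
}

## minimal single-section label
makeLabel <- function(text, drug = "drugX", id = "drugX_L1", title = "adverse reactions",
                      goldMentions = NULL, goldReactions = NULL,
                      headerRows = data.frame(section_id = character(),
                                              start = integer(),
                                              length = integer(),
                                              stringsAsFactors = FALSE)) {
  labelDocument(drug, id,
                sections = data.frame(section_id = "S1", title = title,
                                      text = text, stringsAsFactors = FALSE),
                goldMentions = goldMentions, goldReactions = goldReactions,
                headerRows = headerRows)
}

## ontology from an edge list "child->parent" plus optional extra ids
makeOntology <- function(edges, extraIds = character()) {
  ids <- unique(c(unlist(edges), extraIds))
  parents <- setNames(rep(list(character()), length(ids)), ids)
  for (e in edges) parents[[e[1L]]] <- c(parents[[e[1L]]], e[2L])
  new("Ontology",
      terms = data.frame(id = ids, name = paste("term", ids),
                         stringsAsFactors = FALSE),
      parents = parents)
}

## random DAG: term i may take 1-2 parents among terms with smaller index
randomDag <- function(n, p2 = 0.3) {
  ids <- sprintf("T%02d", seq_len(n))
  parents <- setNames(rep(list(character()), n), ids)
  for (i in seq_len(n)) {
    if (i == 1L) next
    if (i > 2L && stats::runif(1) < 0.15) next         # extra root
    np <- if (i > 2L && stats::runif(1) < p2) 2L else 1L
    parents[[ids[i]]] <- sample(ids[seq_len(i - 1L)], min(np, i - 1L))
  }
  new("Ontology",
      terms = data.frame(id = ids, name = ids, stringsAsFactors = FALSE),
      parents = parents)
}

## exhaustive pair-count network oracle
oracleEdges <- function(profiles, fraction) {
  n <- length(profiles)
  thr <- ceiling(fraction * n - 1e-9)
  terms <- sort(unique(unlist(profiles, use.names = FALSE)))
  out <- list()
  for (i in seq_along(terms)) for (j in seq_along(terms)) {
    if (j <= i) next
    a <- terms[i]; b <- terms[j]
    w <- 0L
    for (p in profiles) if (a %in% p && b %in% p) w <- w + 1L
    if (w >= thr)
      out[[length(out) + 1L]] <- data.frame(a = a, b = b, weight = w,
                                            stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(a = character(), b = character(), weight = integer(),
                         stringsAsFactors = FALSE)
  res <- res[order(res$a, res$b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## dense eigendecomposition oracle for eigenvector centrality
oracleEigenvector <- function(net) {
  nodes <- networkNodes(net)
  e <- networkEdges(net)
  g <- igraph::graph_from_data_frame(e[, c("a", "b")], directed = FALSE,
                                     vertices = nodes)
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  keep <- nodes[comp$membership == main]
  A <- matrix(0, length(keep), length(keep), dimnames = list(keep, keep))
  for (r in seq_len(nrow(e))) {
    if (e$a[r] %in% keep && e$b[r] %in% keep) {
      A[e$a[r], e$b[r]] <- 1
      A[e$b[r], e$a[r]] <- 1
    }
  }
  v <- abs(eigen(A, symmetric = TRUE)$vectors[, 1L])
  out <- setNames(rep(0, length(nodes)), nodes)
  out[keep] <- v / sqrt(sum(v^2))
  out
}

## brute-force ancestor set by explicit DFS path walking
oracleAncestors <- function(ontology, id) {
  parents <- termParents(ontology)
  acc <- character()
  walk <- function(v) {
    for (p in parents[[v]]) {
      acc <<- union(acc, p)
      walk(p)
    }
  }
  walk(id)
  sort(acc)
}

## path-enumeration oracle: every node on an upward is_a path between two
## selected terms (enumerates all paths explicitly; endpoints included).
oracleBetweenTerms <- function(ontology, selected) {
  parents <- termParents(ontology)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    paths[[length(paths) + 1L]] <<- path
    for (p in parents[[v]]) walk(c(path, p))
  }
  for (s in selected) walk(s)
  included <- selected
  for (p in paths) {
    hits <- which(p %in% selected)
    if (length(hits) >= 2L)
      included <- union(included, p[seq_len(max(hits))])
  }
  sort(included)
}

## reachability over a child->parent edge list by explicit closure
oracleReachable <- function(edges, from, to) {
  frontier <- from
  seen <- character()
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(edges$parent[edges$child %in% frontier], seen)
  }
  to %in% seen
}

## random drug-ADR table
randomTable <- function(nDrugs, nAdrs) {
  adrs <- sprintf("A%02d", seq_len(nAdrs))
  profiles <- lapply(seq_len(nDrugs), function(i)
    sort(sample(adrs, sample.int(nAdrs, 1L))))
  names(profiles) <- sprintf("d%02d", seq_len(nDrugs))
  drugAdrTable(profiles)
}

writeTempDict <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("term_id\tpreferred_name\tsynonyms\tabbreviations", lines), f)
  f
}

writeTempObo <- function(lines) {
  f <- tempfile(fileext = ".obo")
  writeLines(lines, f)
  f
}
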