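## ADR-ADR co-occurrence networks: two ADR terms are joined when they are
## listed together by at least a threshold fraction of the drugs; degree
## and eigenvector centrality identify the most salient ADRs.

#' Minimum drug count for a co-occurrence edge
#'
#' The smallest integer number of drugs that is at least
#' `fraction * n_drugs` (ceiling), e.g. 27 of 53 drugs at fraction 0.5.
#'
#' @param nDrugs positive integer number of drugs.
#' @param fraction required fraction in (0, 1].
#' @return integer threshold.
#' @export
minEdgeCount <- function(nDrugs, fraction) {
  stopifnot(length(nDrugs) == 1L, nDrugs >= 1L)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  m <- fraction * nDrugs
  mi <- round(m)
  as.integer(if (abs(m - mi) < 1e-9) mi else ceiling(m))
}

#' Build a thresholded ADR-ADR co-occurrence network
#'
#' An edge joins ADR terms a and b when the number of drugs whose profile
#' contains both is at least [minEdgeCount()]; the edge weight is that drug
#' count. ADRs with no qualifying edge are excluded from the node set.
#'
#' @param table a [DrugAdrTable-class].
#' @param fraction co-occurrence threshold as a fraction of drugs
#'   (default 0.5).
#' @return an [AdrNetwork-class].
#' @export
buildCooccurrenceNetwork <- function(table, fraction = 0.5) {
  stopifnot(is(table, "DrugAdrTable"))
  if (!length(table@drugs)) stop("empty drug-ADR table")
  minCount <- minEdgeCount(length(table@drugs), fraction)
  terms <- sort(unique(unlist(table@profiles, use.names = FALSE)))
  support <- setNames(integer(length(terms)), terms)
  edges <- data.frame(a = character(), b = character(), weight = integer(),
                      stringsAsFactors = FALSE)
  if (length(terms)) {
    inc <- vapply(table@profiles,
                  function(p) terms %in% p, logical(length(terms)))
    inc <- matrix(inc, nrow = length(terms),
                  dimnames = list(terms, table@drugs))
    support <- setNames(as.integer(rowSums(inc)), terms)
    co <- tcrossprod(inc * 1L)            # terms x terms co-occurrence counts
    ut <- which(upper.tri(co) & co >= minCount, arr.ind = TRUE)
    if (nrow(ut)) {
      edges <- data.frame(a = terms[ut[, 1L]], b = terms[ut[, 2L]],
                          weight = as.integer(co[ut]),
                          stringsAsFactors = FALSE)
      edges <- edges[order(edges$a, edges$b), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  new("AdrNetwork", nodes = sort(unique(c(edges$a, edges$b))), edges = edges,
      thresholdFraction = fraction, minCount = minCount, support = support)
}

#' Degree centrality of every network node
#'
#' The number of neighbors each node has; each neighbor contributes
#' equally.
#'
#' @param net an [AdrNetwork-class].
#' @return data.frame with columns `term_id`, `degree`, ordered by
#'   `term_id`.
#' @export
degreeCentrality <- function(net) {
  stopifnot(is(net, "AdrNetwork"))
  if (!length(net@nodes)) stop("network has no nodes")
  deg <- table(factor(c(net@edges$a, net@edges$b), levels = net@nodes))
  data.frame(term_id = net@nodes, degree = as.integer(deg),
             stringsAsFactors = FALSE)
}

.adjacencyMatrix <- function(net) {
  n <- length(net@nodes)
  A <- matrix(0, n, n, dimnames = list(net@nodes, net@nodes))
  if (nrow(net@edges)) {
    ia <- match(net@edges$a, net@nodes); ib <- match(net@edges$b, net@nodes)
    A[cbind(ia, ib)] <- 1; A[cbind(ib, ia)] <- 1
  }
  A
}

## Connected components by BFS; returns an integer membership vector.
.components <- function(net) {
  nodes <- net@nodes
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  nb <- lapply(setNames(nodes, nodes), function(v)
    c(net@edges$b[net@edges$a == v], net@edges$a[net@edges$b == v]))
  k <- 0L
  for (v in nodes) {
    if (!is.na(comp[v])) next
    k <- k + 1L
    frontier <- v
    while (length(frontier)) {
      comp[frontier] <- k
      frontier <- unique(unlist(nb[frontier], use.names = FALSE))
      frontier <- frontier[is.na(comp[frontier])]
    }
  }
  comp
}

#' Eigenvector centrality of network nodes
#'
#' The principal eigenvector of the unweighted adjacency matrix (edge
#' weights do not enter), computed by power iteration to a relative
#' tolerance of 1e-10 on the largest connected component, nonnegative and
#' normalized to unit Euclidean norm over that component. Nodes in other
#' components get value 0 with a warning, since the principal eigenvector
#' is only supported on one component.
#'
#' @param net an [AdrNetwork-class].
#' @return data.frame with columns `term_id`, `eigenvector`, ordered by
#'   `term_id`.
#' @export
eigenvectorCentrality <- function(net) {
  stopifnot(is(net, "AdrNetwork"))
  if (!length(net@nodes)) stop("network has no nodes")
  comp <- .components(net)
  sizes <- table(comp)
  main <- as.integer(names(sizes)[which.max(sizes)])
  if (length(sizes) > 1L)
    warning(sprintf(
      "network has %d components; eigenvector centrality computed on the largest (%d nodes), others set to 0",
      length(sizes), max(sizes)))
  keep <- names(comp)[comp == main]
  A <- .adjacencyMatrix(net)[keep, keep, drop = FALSE]
  x <- rep(1 / sqrt(length(keep)), length(keep))
  if (length(keep) > 1L) {
    ## shifted iteration (A + I): same eigenvectors, but avoids the
    ## non-convergent +/-lambda oscillation on bipartite graphs
    for (it in seq_len(100000L)) {
      y <- drop(A %*% x) + x
      ny <- sqrt(sum(y^2))
      if (ny == 0) break
      y <- y / ny
      if (max(abs(y - x)) < 1e-10 * max(abs(y))) { x <- y; break }
      x <- y
    }
  }
  ev <- setNames(rep(0, length(net@nodes)), net@nodes)
  ev[keep] <- abs(x)
  data.frame(term_id = net@nodes, eigenvector = unname(ev),
             stringsAsFactors = FALSE)
}

#' Combined centrality table
#'
#' @param net an [AdrNetwork-class].
#' @return data.frame `term_id`, `degree`, `eigenvector` sorted by rank
#'   (eigenvector desc, then degree desc, then term_id).
#' @export
centralityTable <- function(net) {
  d <- degreeCentrality(net)
  e <- eigenvectorCentrality(net)
  out <- merge(d, e, by = "term_id")
  out <- out[order(-out$eigenvector, -out$degree, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank two networks and report ADRs specific to the first
#'
#' @param netA,netB [AdrNetwork-class] objects over the same term id
#'   space (e.g. drug-subset-specific vs background networks).
#' @return list with `rankingA`, `rankingB` (centrality tables sorted by
#'   eigenvector desc, degree desc, term_id), `onlyInA` (nodes of A absent
#'   from B) and `sameRankingA`: whether degree and eigenvector order the
#'   nodes of A identically (a diagnostic, not an invariant).
#' @export
rankAndCompare <- function(netA, netB) {
  ra <- centralityTable(netA)
  rb <- centralityTable(netB)
  byDeg <- ra$term_id[order(-ra$degree, ra$term_id)]
  byEig <- ra$term_id[order(-ra$eigenvector, -ra$degree, ra$term_id)]
  list(rankingA = ra, rankingB = rb,
       onlyInA = sort(setdiff(networkNodes(netA), networkNodes(netB))),
       sameRankingA = identical(byDeg, byEig))
}

#' Export a network as weighted edge-list TSV and GraphML
#'
#' @param net an [AdrNetwork-class].
#' @param prefix output path prefix; writes `<prefix>_edges.tsv`,
#'   `<prefix>_centrality.tsv` and `<prefix>.graphml`.
#' @param termNames optional named character vector (term id -> display
#'   name) for the centrality table.
#' @return character vector of written paths, invisibly.
#' @export
exportNetwork <- function(net, prefix, termNames = NULL) {
  stopifnot(is(net, "AdrNetwork"))
  edgePath <- paste0(prefix, "_edges.tsv")
  write.table(networkEdges(net), edgePath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cent <- centralityTable(net)
  cent$name <- if (is.null(termNames)) cent$term_id
               else unname(termNames[cent$term_id])
  cent <- cent[, c("term_id", "name", "degree", "eigenvector")]
  centPath <- paste0(prefix, "_centrality.tsv")
  write.table(cent, centPath, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- igraph::graph_from_data_frame(networkEdges(net), directed = FALSE,
                                     vertices = networkNodes(net))
  gmlPath <- paste0(prefix, ".graphml")
  igraph::write_graph(g, gmlPath, format = "graphml")
  invisible(c(edgePath, centPath, gmlPath))
}
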