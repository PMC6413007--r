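# Graph primitives every descriptor consumes: adjacency, topological
# distances, detour (longest-simple-path) distances and Kier-Hall subgraph
# enumeration. Every bond counts as a single edge here regardless of order.

assertNoMarkers <- function(g) {
  if (hasMarkers(g)) {
    stop("graph still contains anchor markers; resolve the fragment first",
         call. = FALSE)
  }
}

edgeMatrix <- function(g) {
  if (bondCount(g) == 0) return(matrix(integer(0), ncol = 2))
  cbind(g@bonds$i, g@bonds$j)
}

#' Adjacency matrix of the hydrogen-suppressed graph
#'
#' Unit entries for every bond (any order); used by the charge indices and
#' the adjacency eigenvector descriptor.
#'
#' @param g a [MolGraph-class].
#' @return n x n symmetric 0/1 matrix.
#' @export
adjacencyMatrix <- function(g) {
  n <- atomCount(g)
  A <- matrix(0, n, n)
  if (bondCount(g)) {
    A[cbind(g@bonds$i, g@bonds$j)] <- 1
    A[cbind(g@bonds$j, g@bonds$i)] <- 1
  }
  A
}

#' Topological distance matrix
#'
#' All-pairs shortest paths counting every bond as length 1.
#'
#' @param g a connected [MolGraph-class].
#' @return n x n symmetric integer matrix with zero diagonal.
#' @export
distanceMatrix <- function(g) {
  n <- atomCount(g)
  D <- cpp_bfs_distances(n, edgeMatrix(g))
  if (any(D < 0)) stop("graph is disconnected", call. = FALSE)
  D
}

#' Detour (longest-simple-path) distance matrix
#'
#' \eqn{\Delta_{ij}} is the length of the longest simple path between atoms
#' i and j. Computed by biconnected-component decomposition: detour distance
#' is additive across cut vertices, so exhaustive search is needed only
#' inside each block; across blocks the detour metric is recovered as a
#' weighted shortest path over per-block detours.
#'
#' @param g a connected [MolGraph-class].
#' @param maxBlock atoms allowed per biconnected component before the search
#'   is declared intractable (default 30, far above typical ring systems).
#' @return n x n symmetric integer matrix; equals [distanceMatrix()] exactly
#'   when the graph is acyclic.
#' @export
detourMatrix <- function(g, maxBlock = 30) {
  n <- atomCount(g)
  if (n == 1) return(matrix(0L, 1, 1))
  ig <- igraph::graph_from_edgelist(edgeMatrix(g), directed = FALSE)
  if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  bc <- igraph::biconnected_components(ig)
  wi <- integer(0); wj <- integer(0); wt <- integer(0)
  for (comp in bc$components) {
    vs <- sort(as.integer(comp))
    if (length(vs) == 2) {
      wi <- c(wi, vs[1]); wj <- c(wj, vs[2]); wt <- c(wt, 1L)
      next
    }
    if (length(vs) > maxBlock) {
      stop(sprintf(paste0("detour intractable: biconnected component with %d",
                          " atoms exceeds the limit of %d"),
                   length(vs), maxBlock), call. = FALSE)
    }
    sub <- g@bonds[g@bonds$i %in% vs & g@bonds$j %in% vs, , drop = FALSE]
    le <- cbind(match(sub$i, vs), match(sub$j, vs))
    L <- cpp_block_longest_paths(length(vs), le)
    idx <- which(upper.tri(L), arr.ind = TRUE)
    wi <- c(wi, vs[idx[, 1]]); wj <- c(wj, vs[idx[, 2]])
    wt <- c(wt, L[idx])
  }
  H <- igraph::graph_from_edgelist(cbind(wi, wj), directed = FALSE)
  if (igraph::vcount(H) < n) H <- igraph::add_vertices(H, n - igraph::vcount(H))
  Delta <- igraph::distances(H, weights = wt)
  if (any(!is.finite(Delta))) stop("graph is disconnected", call. = FALSE)
  storage.mode(Delta) <- "integer"
  dimnames(Delta) <- NULL
  Delta
}

#' Enumerate Kier-Hall connected subgraphs
#'
#' Returns every connected edge-subgraph with `order` edges of the requested
#' type, each exactly once. Types follow the Kier-Hall classification of the
#' within-subgraph degree sequence: `path` (all degrees <= 2, tree),
#' `cluster` (star, order >= 3), `path_cluster` (mixed, order >= 4).
#' Cycle-containing subgraphs (the ring/"chain" subtype) are excluded.
#' Requesting `cluster` below order 3 or `path_cluster` below order 4 yields
#' an empty list.
#'
#' @param g a [MolGraph-class].
#' @param order number of edges, 0..4 (order 0 returns single vertices).
#' @param kind one of `"path"`, `"cluster"`, `"path_cluster"`.
#' @return list of subgraphs, each a list with `vertices` (atom indices) and
#'   `edges` (two-column matrix of bonds).
#' @export
enumerateSubgraphs <- function(g, order, kind = c("path", "cluster", "path_cluster")) {
  kind <- match.arg(kind)
  stopifnot(order >= 0, order <= 4)
  if (order == 0) {
    if (kind != "path") return(list())
    return(lapply(seq_len(atomCount(g)), function(v) {
      list(vertices = v, edges = matrix(integer(0), ncol = 2))
    }))
  }
  if ((kind == "cluster" && order < 3) || (kind == "path_cluster" && order < 4)) {
    return(list())
  }
  em <- edgeMatrix(g)
  sets <- cpp_enumerate_edge_subgraphs(atomCount(g), em, as.integer(order))
  out <- list()
  for (es in sets) {
    sub <- em[es, , drop = FALSE]
    verts <- sort(unique(as.integer(sub)))
    if (subgraphKind(sub, verts) == kind) {
      out[[length(out) + 1]] <- list(vertices = verts, edges = sub)
    }
  }
  out
}

# Kier-Hall type of an edge subgraph from its degree sequence.
subgraphKind <- function(edges, verts = sort(unique(as.integer(edges)))) {
  ne <- nrow(edges)
  deg <- table(factor(as.integer(edges), levels = verts))
  if (length(verts) <= ne) return("chain")
  maxdeg <- max(deg)
  if (maxdeg <= 2) "path"
  else if (maxdeg == ne) "cluster"
  else "path_cluster"
}
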