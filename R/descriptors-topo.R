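# Kier-Hall connectivity indices, their valence/simple combinations, the
# Galvez topological charge indices, the Wiener index and constitutional
# counts.

.CHI_KINDS <- c("path", "cluster", "path_cluster")
.KIND_COL <- c(path = 1L, cluster = 2L, path_cluster = 3L)

chiCensus <- function(g, maxOrder = 4) {
  assertNoMarkers(g)
  cpp_subgraph_census(atomCount(g), edgeMatrix(g),
                      as.numeric(g@atoms$delta), as.numeric(g@atoms$deltaV),
                      as.integer(maxOrder))
}

#' Molecular connectivity index
#'
#' The order-m, type-t connectivity index
#' \deqn{{}^m\chi_t = \sum_{s} \prod_{v \in s} (\delta^*_v)^{-1/2}}
#' summed over the connected subgraphs of the requested order (edge count)
#' and Kier-Hall type, with \eqn{\delta^* = \delta} (simple) or
#' \eqn{\delta^v} (valence). Order 0 sums over single vertices.
#'
#' @param g a connected [MolGraph-class] without markers.
#' @param order subgraph order (edge count), 0..4.
#' @param kind `"path"`, `"cluster"` or `"path_cluster"`.
#' @param valence logical; use the valence degrees \eqn{\delta^v}.
#' @return numeric connectivity index (0 when no subgraph of the requested
#'   order/type exists).
#' @examples
#' chiIndex(parseSmiles("CC"), 1, "path")            # 1
#' chiIndex(parseSmiles("CCO"), 1, "path", valence = TRUE)
#' @export
chiIndex <- function(g, order, kind = c("path", "cluster", "path_cluster"),
                     valence = FALSE) {
  kind <- match.arg(kind)
  stopifnot(order >= 0, order <= 4)
  cen <- chiCensus(g, maxOrder = order)
  mat <- if (valence) cen$chiV else cen$chiS
  unname(mat[order + 1L, .KIND_COL[[kind]]])
}

#' Quotient and difference connectivity combinations
#'
#' Combines the simple and valence connectivity index of one order/type into
#' the difference D and quotient C descriptors. The orientation of either
#' combination is configurable (see [topoConventions()]): by default
#' \eqn{D = \chi - \chi^v} and \eqn{C = \chi / \chi^v}. A zero denominator
#' yields `NaN` for C, never a silent 0.
#'
#' @inheritParams chiIndex
#' @param conventions a [topoConventions()] object.
#' @return named numeric vector `c(C = ..., D = ...)`.
#' @export
chiCombined <- function(g, order, kind = c("path", "cluster", "path_cluster"),
                        conventions = topoConventions()) {
  kind <- match.arg(kind)
  cen <- chiCensus(g, maxOrder = order)
  s <- unname(cen$chiS[order + 1L, .KIND_COL[[kind]]])
  v <- unname(cen$chiV[order + 1L, .KIND_COL[[kind]]])
  combineChi(s, v, conventions)
}

combineChi <- function(s, v, conventions) {
  C <- if (conventions$chiQuotient == "valence_over_simple") {
    ifelse(s == 0, NaN, v / s)
  } else {
    ifelse(v == 0, NaN, s / v)
  }
  D <- if (conventions$chiDifference == "simple_minus_valence") s - v else v - s
  c(C = C, D = D)
}

#' Galvez topological charge indices
#'
#' With A the unit adjacency matrix and Q the reciprocal-square-distance
#' matrix (\eqn{q_{ij} = d_{ij}^{-2}}, zero diagonal), form \eqn{M = AQ} and
#' the charge terms \eqn{c_{ij} = m_{ij} - m_{ji}}. Then
#' \deqn{G_k = \sum_{i<j} |c_{ij}| \,[d_{ij} = k], \qquad J_k = G_k/(n-1).}
#' `GGI10` of the regression model is \eqn{G_{10}}.
#'
#' @param g a connected [MolGraph-class] with at least 2 atoms.
#' @param maxOrder highest topological distance k to report (default 10).
#' @return named numeric vector `G1..Gk, J1..Jk`.
#' @export
chargeIndices <- function(g, maxOrder = 10) {
  assertNoMarkers(g)
  n <- atomCount(g)
  stopifnot(n >= 2)
  A <- adjacencyMatrix(g)
  D <- distanceMatrix(g)
  Q <- ifelse(D == 0, 0, 1 / D^2)
  M <- A %*% Q
  C <- abs(M - t(M))
  ks <- seq_len(maxOrder)
  G <- vapply(ks, function(k) sum(C[upper.tri(C)][D[upper.tri(D)] == k]),
              numeric(1))
  J <- G / (n - 1)
  stats::setNames(c(G, J), c(paste0("G", ks), paste0("J", ks)))
}

#' Wiener index
#'
#' Sum of all pairwise shortest topological distances,
#' \eqn{W = \sum_{i<j} d_{ij}}.
#'
#' @param g a connected [MolGraph-class].
#' @return numeric (integer-valued) Wiener index.
#' @export
wienerIndex <- function(g) {
  assertNoMarkers(g)
  D <- distanceMatrix(g)
  sum(D[upper.tri(D)])
}

#' Constitutional indices
#'
#' Atom and bond counts, vertex-degree counts `V1..V4` (`Vk` = number of
#' heavy atoms with degree k; `V4` enters the discriminant model), the
#' cyclomatic ring count and per-element heavy-atom counts.
#'
#' @param g a connected [MolGraph-class].
#' @return named numeric vector.
#' @export
constitutionalIndices <- function(g) {
  assertNoMarkers(g)
  d <- g@atoms$delta
  v <- vapply(1:4, function(k) sum(d == k), numeric(1))
  elems <- setdiff(elementTable()$symbol, "H")
  counts <- vapply(elems, function(e) sum(g@atoms$symbol == e), numeric(1))
  c(nAtoms = atomCount(g), nBonds = bondCount(g),
    stats::setNames(v, paste0("V", 1:4)),
    nRings = bondCount(g) - atomCount(g) + 1,
    stats::setNames(counts, paste0("n", elems)))
}
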