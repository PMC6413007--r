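# Descriptors of the affinity regression model that fall outside the
# connectivity/charge families: hyper-detour index, MAXDN, Burden-matrix
# eigenvalues and the adjacency principal-eigenvector sum.

#' Hyper-detour index
#'
#' \deqn{ww = \tfrac12 \sum_{i<j} (\Delta_{ij} + \Delta_{ij}^2)}
#' over the detour (longest-simple-path) distances. On acyclic graphs the
#' detour matrix equals the distance matrix, so ww reduces to the
#' hyper-Wiener index.
#'
#' @param g a connected [MolGraph-class].
#' @param maxBlock passed to [detourMatrix()].
#' @return numeric hyper-detour index.
#' @examples
#' hyperDetour(parseSmiles("CC"))            # 1
#' hyperDetour(parseSmiles("c1ccccc1"))      # 168
#' @export
hyperDetour <- function(g, maxBlock = 30) {
  assertNoMarkers(g)
  Dl <- detourMatrix(g, maxBlock = maxBlock)
  u <- Dl[upper.tri(Dl)]
  sum(u + u^2) / 2
}

#' Maximal electrotopological negative variation (MAXDN)
#'
#' From the Kier-Hall intrinsic states
#' \eqn{I_i = ((2/L_i)^2 \delta^v_i + 1)/\delta_i} and the field
#' perturbations \eqn{\Delta I_i = \sum_{j \ne i} (I_i - I_j)/(d_{ij}+1)^2},
#' MAXDN is the largest negative perturbation, negated:
#' \eqn{\max_i(-\Delta I_i)} when any \eqn{\Delta I_i < 0}, else 0. The
#' perturbations are pairwise antisymmetric, so they sum to zero over the
#' molecule.
#'
#' @param g a connected [MolGraph-class].
#' @return numeric MAXDN (>= 0).
#' @export
maxdn <- function(g) {
  assertNoMarkers(g)
  n <- atomCount(g)
  if (n < 2) return(0)
  L <- elementInfo(g@atoms$symbol)$L
  I <- ((2 / L)^2 * g@atoms$deltaV + 1) / g@atoms$delta
  D <- distanceMatrix(g)
  Wm <- 1 / (D + 1)^2
  diag(Wm) <- 0
  dI <- I * rowSums(Wm) - as.vector(Wm %*% I)
  if (any(dI < 0)) max(-dI) else 0
}

#' Mass-weighted Burden matrix
#'
#' Symmetric n x n matrix with diagonal \eqn{m_i / m_C} (relative atomic
#' mass over the mass of carbon), bonded off-diagonal entries 0.1 x
#' conventional bond order (1, 2, 3; 1.5 for aromatic bonds) plus 0.01 when
#' either atom is terminal, and 0.001 for non-bonded pairs. Whether aromatic
#' rings written in Kekulé form are perceived and weighted 1.5 is a
#' convention toggle (see [topoConventions()]); perception is the default,
#' matching conventional bond orders.
#'
#' @param g a connected [MolGraph-class].
#' @param conventions a [topoConventions()] object.
#' @return n x n numeric matrix.
#' @export
burdenMatrix <- function(g, conventions = topoConventions()) {
  assertNoMarkers(g)
  n <- atomCount(g)
  mC <- elementInfo("C")$mass
  B <- matrix(0.001, n, n)
  diag(B) <- elementInfo(g@atoms$symbol)$mass / mC
  if (bondCount(g)) {
    arom <- if (conventions$burdenAromatic == "perceive") {
      perceiveAromaticBonds(g)
    } else {
      g@bonds$aromatic
    }
    ord <- ifelse(arom, 1.5, g@bonds$order)
    term <- g@atoms$delta[g@bonds$i] == 1 | g@atoms$delta[g@bonds$j] == 1
    val <- 0.1 * ord + ifelse(term, 0.01, 0)
    B[cbind(g@bonds$i, g@bonds$j)] <- val
    B[cbind(g@bonds$j, g@bonds$i)] <- val
  }
  B
}

# Mark bonds as aromatic for conventional bond orders: bonds already flagged
# aromatic in the input, plus bonds of six-membered rings whose atoms are all
# C/N and each carry at least one double or aromatic bond (benzenoid Kekulé
# rings). Deliberately minimal; documented in the methods vignette.
perceiveAromaticBonds <- function(g) {
  arom <- g@bonds$aromatic
  if (atomCount(g) < 6 || bondCount(g) < 6) return(arom)
  hasPi <- logical(atomCount(g))
  pi_b <- g@bonds$order == 2 | g@bonds$aromatic
  hasPi[unique(c(g@bonds$i[pi_b], g@bonds$j[pi_b]))] <- TRUE
  eligible <- g@atoms$symbol %in% c("C", "N") & hasPi
  cand <- which(eligible[g@bonds$i] & eligible[g@bonds$j])
  if (length(cand) < 6) return(arom)
  sub <- igraph::graph_from_edgelist(cbind(g@bonds$i[cand], g@bonds$j[cand]),
                                     directed = FALSE)
  if (igraph::vcount(sub) < atomCount(g)) {
    sub <- igraph::add_vertices(sub, atomCount(g) - igraph::vcount(sub))
  }
  ig <- sub
  key <- paste(g@bonds$i, g@bonds$j)
  for (circuit in sixMemberedCycles(ig)) {
    pairs <- cbind(circuit, c(circuit[-1], circuit[1]))
    ek <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    arom[match(ek, key)] <- TRUE
  }
  arom
}

# all simple 6-cycles of an igraph, as vertex sequences
sixMemberedCycles <- function(ig) {
  res <- list()
  n <- igraph::vcount(ig)
  adj <- igraph::as_adj_list(ig)
  adj <- lapply(adj, as.integer)
  for (start in seq_len(n)) {
    path <- integer(6)
    path[1] <- start
    # anchor each cycle at its smallest vertex; orientation fixed by
    # path[2] < path[6] so every cycle is emitted exactly once
    sub <- function(v, depth) {
      path[depth] <<- v
      if (depth == 6) {
        if (start %in% adj[[v]] && path[2] < path[6]) {
          res[[length(res) + 1]] <<- path
        }
        return(invisible())
      }
      for (u in adj[[v]]) {
        if (u <= start || u %in% path[seq_len(depth)]) next
        sub(u, depth + 1)
      }
    }
    for (w in adj[[start]]) {
      if (w > start) sub(w, 2)
    }
  }
  res
}

#' Burden-matrix eigenvalue descriptor (BELm family)
#'
#' Builds the mass-weighted [burdenMatrix()] and returns its `rank`-th
#' smallest eigenvalue; `BELm5` of the affinity model is rank 5.
#'
#' @param g a connected [MolGraph-class] with at least `rank` atoms.
#' @param rank which smallest eigenvalue to return (default 5).
#' @param conventions a [topoConventions()] object.
#' @return numeric eigenvalue, or `NA` (undefined-descriptor marker) when the
#'   molecule has fewer than `rank` atoms.
#' @export
belm <- function(g, rank = 5, conventions = topoConventions()) {
  assertNoMarkers(g)
  if (atomCount(g) < rank) return(NA_real_)
  ev <- eigen(burdenMatrix(g, conventions), symmetric = TRUE,
              only.values = TRUE)$values
  sort(ev)[rank]
}

#' Adjacency principal-eigenvector coefficient sum (VEA1)
#'
#' Takes the eigenvector of the adjacency matrix for the largest eigenvalue,
#' scaled to unit Euclidean norm with all components non-negative
#' (Perron-Frobenius guarantees a non-negative principal eigenvector for a
#' connected graph), and returns the sum of its components. Bounded between
#' 1 and \eqn{\sqrt{n}}.
#'
#' @param g a connected [MolGraph-class].
#' @return numeric VEA1.
#' @export
vea1 <- function(g) {
  assertNoMarkers(g)
  if (atomCount(g) == 1) return(1)
  e <- eigen(adjacencyMatrix(g), symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- v / sqrt(sum(v^2))
  if (sum(v) < 0) v <- -v
  sum(abs(v))
}
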