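# Independent brute-force oracles, deliberately kept free of the package's
# computational paths: plain-R BFS, exhaustive simple-path search, edge-subset
# enumeration and direct double-sum formulas.

adjListOf <- function(g) {
  n <- atomCount(g)
  adj <- vector("list", n)
  b <- bonds(g)
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  adj
}

# all-pairs shortest paths, repeated BFS in plain R
oracleDistances <- function(g) {
  adj <- adjListOf(g)
  n <- atomCount(g)
  D <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); dist[s] <- 0L
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (dist[w] < 0) { dist[w] <- dist[v] + 1L; q <- c(q, w) }
    }
    D[s, ] <- dist
  }
  D
}

# all-pairs longest simple paths by exhaustive DFS (tiny graphs only)
oracleDetour <- function(g) {
  adj <- adjListOf(g)
  n <- atomCount(g)
  best <- matrix(0L, n, n)
  dfs <- function(v, visited, len, s) {
    if (len > best[s, v]) best[s, v] <<- len
    for (w in adj[[v]]) {
      if (!visited[w]) {
        visited[w] <- TRUE
        dfs(w, visited, len + 1L, s)
        visited[w] <- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    visited <- rep(FALSE, n); visited[s] <- TRUE
    dfs(s, visited, 0L, s)
  }
  pmax(best, t(best))
}

# every connected m-edge subgraph by filtering all edge subsets (combn)
oracleEdgeSubsets <- function(g, m) {
  b <- bonds(g)
  ne <- nrow(b)
  if (m < 1 || ne < m) return(list())
  sets <- utils::combn(ne, m, simplify = FALSE)
  keep <- Filter(function(es) {
    verts <- unique(c(b$i[es], b$j[es]))
    # connectivity of the edge-induced subgraph
    reach <- verts[1]
    repeat {
      nxt <- unique(c(b$j[es][b$i[es] %in% reach], b$i[es][b$j[es] %in% reach]))
      nxt <- union(reach, nxt)
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    length(reach) == length(verts)
  }, sets)
  keep
}

oracleKindOf <- function(g, es) {
  b <- bonds(g)
  verts <- unique(c(b$i[es], b$j[es]))
  deg <- vapply(verts, function(v) sum(b$i[es] == v) + sum(b$j[es] == v),
                numeric(1))
  ne <- length(es)
  if (length(verts) <= ne) return("chain")
  if (max(deg) <= 2) "path" else if (max(deg) == ne) "cluster" else "path_cluster"
}

# chi by direct enumeration over the oracle subsets
oracleChi <- function(g, m, kind, valence = FALSE) {
  w <- if (valence) atoms(g)$deltaV else atoms(g)$delta
  if (m == 0) return(sum(1 / sqrt(w)))
  b <- bonds(g)
  total <- 0
  for (es in oracleEdgeSubsets(g, m)) {
    if (oracleKindOf(g, es) != kind) next
    verts <- unique(c(b$i[es], b$j[es]))
    total <- total + prod(1 / sqrt(w[verts]))
  }
  total
}

# charge indices by explicit double loops (no matrix product shortcut)
oracleGk <- function(g, k) {
  n <- atomCount(g)
  A <- matrix(0, n, n)
  b <- bonds(g)
  A[cbind(b$i, b$j)] <- 1; A[cbind(b$j, b$i)] <- 1
  D <- oracleDistances(g)
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) Q[i, j] <- 1 / D[i, j]^2
  }
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    M[i, j] <- sum(A[i, ] * Q[, j])
  }
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] == k) total <- total + abs(M[i, j] - M[j, i])
  }
  total
}

# MAXDN by the explicit double sum
oracleMaxdn <- function(g) {
  a <- atoms(g)
  L <- elementTable()$L[match(a$symbol, elementTable()$symbol)]
  I <- ((2 / L)^2 * a$deltaV + 1) / a$delta
  D <- oracleDistances(g)
  n <- atomCount(g)
  dI <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) dI[i] <- dI[i] + (I[i] - I[j]) / (D[i, j] + 1)^2
    }
  }
  if (any(dI < 0)) max(-dI) else 0
}

# small seeded random connected graphs as MolGraph carbon skeletons
randomTestGraphs <- function(seed = 42, n = 12, maxAtoms = 10) {
  fx <- makeFixtures(seed = seed, nRandom = n, maxRandomAtoms = maxAtoms)
  fx[grep("^random", names(fx))]
}

# permutation of atom indices of a MolGraph (for invariance tests)
permuteAtoms <- function(g, perm) {
  a <- atoms(g)[order(perm), , drop = FALSE]
  rownames(a) <- NULL
  b <- bonds(g)
  bi <- perm[b$i]; bj <- perm[b$j]
  b2 <- data.frame(i = pmin(bi, bj), j = pmax(bi, bj), order = b$order,
                   aromatic = b$aromatic)
  new("MolGraph", atoms = a, bonds = b2, id = g@id, smiles = NA_character_)
}

# graph isomorphism with element/hydrogen colours via igraph VF2
molIsomorphic <- function(g1, g2) {
  if (atomCount(g1) != atomCount(g2) || bondCount(g1) != bondCount(g2)) {
    return(FALSE)
  }
  mk <- function(g) {
    ig <- igraph::graph_from_edgelist(cbind(bonds(g)$i, bonds(g)$j),
                                      directed = FALSE)
    if (igraph::vcount(ig) < atomCount(g)) {
      ig <- igraph::add_vertices(ig, atomCount(g) - igraph::vcount(ig))
    }
    col <- as.integer(factor(paste(atoms(g)$symbol, atoms(g)$hcount),
                             levels = sort(unique(c(
                               paste(atoms(g1)$symbol, atoms(g1)$hcount),
                               paste(atoms(g2)$symbol, atoms(g2)$hcount))))))
    list(ig = ig, col = col)
  }
  a <- mk(g1); b <- mk(g2)
  igraph::isomorphic(a$ig, b$ig, method = "vf2", vertex.color1 = a$col,
                     vertex.color2 = b$col)
}
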