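# SMILES parsing, degrees, distance/detour matrices and subgraph enumeration.

test_that("parser populates hydrogen counts and Kier-Hall degrees", {
  g <- parseSmiles("CC")
  expect_equal(atoms(g)$hcount, c(3L, 3L))
  expect_equal(atoms(g)$delta, c(1L, 1L))
  expect_equal(atoms(g)$deltaV, c(1, 1))

  g <- parseSmiles("CCO")
  o <- atoms(g)[3, ]
  expect_equal(o$symbol, "O")
  expect_equal(o$delta, 1L)
  expect_equal(o$deltaV, 5)      # Zv - h = 6 - 1

  # beyond the second period: (Zv - h) / (Z - Zv - 1)
  s <- atoms(parseSmiles("CSC"))[2, ]
  expect_equal(s$deltaV, 6 / 9)
  cl <- atoms(parseSmiles("CCl"))[2, ]
  expect_equal(cl$deltaV, 7 / 9)

  # explicit hydrogens fold into hcount
  g <- parseSmiles("[H]C([H])([H])C")
  expect_equal(atomCount(g), 2)
  expect_equal(atoms(g)$hcount, c(3L, 3L))
})

test_that("parse errors name the offending token and position", {
  expect_error(parseSmiles("C1CC"), "unclosed ring")
  expect_error(parseSmiles("CC)C"), "unmatched")
  expect_error(parseSmiles("C(C"), "unclosed branch")
  expect_error(parseSmiles("CXQ"), "unknown atom symbol")
  expect_error(parseSmiles("C.C"), "disconnected")
  expect_error(parseSmiles(""), "empty")
  expect_error(parseSmiles("[Zz]C"), "malformed|unsupported")
})

test_that("charged atoms are accepted with a warning, neutral Zv used", {
  expect_warning(g <- parseSmiles("CC[N+](C)(C)C"), "neutral")
  n <- atoms(g)[3, ]
  expect_equal(n$charge, 1L)
  expect_equal(n$deltaV, 5)      # neutral N: Zv - h = 5 - 0
})

test_that("aromatic and Kekulé input agree on hydrogen counts and degrees", {
  for (pair in list(c("c1ccccc1", "C1=CC=CC=C1"),
                    c("c1ccncc1", "C1=CC=NC=C1"),
                    c("Cc1ccccc1", "CC1=CC=CC=C1"))) {
    a <- parseSmiles(pair[1]); k <- parseSmiles(pair[2])
    expect_equal(sort(atoms(a)$hcount), sort(atoms(k)$hcount), info = pair[1])
    expect_equal(sort(atoms(a)$deltaV), sort(atoms(k)$deltaV), info = pair[1])
    for (o in 0:2) {
      expect_equal(chiIndex(a, o, "path", valence = TRUE),
                   chiIndex(k, o, "path", valence = TRUE), info = pair[1])
    }
  }
})

test_that("delta equals adjacency row sums and sums to twice the bonds", {
  for (g in makeFixtures(seed = 7, nRandom = 5)) {
    if (hasMarkers(g)) next
    A <- adjacencyMatrix(g)
    expect_equal(atoms(g)$delta, as.integer(rowSums(A)))
    expect_equal(sum(atoms(g)$delta), 2 * bondCount(g))
  }
})

test_that("distance matrix matches examples and the BFS oracle", {
  expect_equal(distanceMatrix(parseSmiles("CCCC"))[1, 4], 3L)
  expect_equal(max(distanceMatrix(parseSmiles("c1ccccc1"))), 3L)
  for (g in randomTestGraphs(seed = 11, n = 8)) {
    expect_equal(distanceMatrix(g), oracleDistances(g), info = molId(g))
  }
})

test_that("detour matrix equals the exhaustive longest-path oracle", {
  # trees: detour == distance
  for (nm in c("pentane", "isobutane", "neopentane", "3-methylpentane")) {
    g <- makeFixtures(seed = 1, nRandom = 0)[[nm]]
    expect_equal(detourMatrix(g), distanceMatrix(g), info = nm)
  }
  # benzene: adjacent pair detour 5
  b <- parseSmiles("c1ccccc1")
  expect_equal(detourMatrix(b)[1, 2], 5L)
  # naphthalene and random cyclic graphs vs brute force
  naph <- parseSmiles("C1=CC2=CC=CC=C2C=C1")
  expect_equal(detourMatrix(naph), oracleDetour(naph))
  for (g in randomTestGraphs(seed = 23, n = 8)) {
    Dl <- detourMatrix(g)
    expect_equal(Dl, oracleDetour(g), info = molId(g))
    D <- distanceMatrix(g)
    expect_true(all(Dl >= D))
    acyclic <- bondCount(g) == atomCount(g) - 1
    expect_equal(all(Dl == D), acyclic, info = molId(g))
  }
})

test_that("detour search refuses oversized biconnected components", {
  b <- parseSmiles("c1ccccc1")
  expect_error(detourMatrix(b, maxBlock = 5), "intractable")
})

test_that("subgraph enumeration matches examples and the subset oracle", {
  iso <- parseSmiles("CC(C)C")
  expect_length(enumerateSubgraphs(iso, 3, "cluster"), 1)
  pent <- parseSmiles("CCCCC")
  expect_length(enumerateSubgraphs(pent, 4, "path"), 1)
  # below-minimum orders yield empty lists, not errors
  expect_length(enumerateSubgraphs(pent, 2, "cluster"), 0)
  expect_length(enumerateSubgraphs(pent, 3, "path_cluster"), 0)

  probes <- c(list(parseSmiles("CCC(C)CC", "3-methylpentane"),
                   parseSmiles("C1CCC1C", "methylcyclobutane")),
              randomTestGraphs(seed = 5, n = 5, maxAtoms = 8))
  for (g in probes) {
    for (m in 1:4) {
      subsets <- oracleEdgeSubsets(g, m)
      kinds <- vapply(subsets, function(es) oracleKindOf(g, es), character(1))
      counted <- 0
      for (kd in c("path", "cluster", "path_cluster")) {
        got <- enumerateSubgraphs(g, m, kd)
        expect_length(got, sum(kinds == kd))
        counted <- counted + length(got)
      }
      # the three kinds plus cycle-containing subgraphs account for every
      # connected m-edge subgraph
      expect_equal(counted + sum(kinds == "chain"), length(subsets),
                   info = paste(molId(g), m))
    }
  }
})

test_that("SMILES writer round-trips to an isomorphic graph", {
  fx <- makeFixtures(seed = 3, nRandom = 0)
  for (nm in c("isobutane", "cyclohexane", "benzene", "naphthalene",
               "pyridine", "thiophene", "toluene", "ethanol")) {
    g <- fx[[nm]]
    back <- parseSmiles(asSmiles(g))
    expect_true(molIsomorphic(g, back), info = nm)
  }
})
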