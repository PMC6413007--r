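# Connectivity, charge, Wiener and constitutional descriptors against hand
# values and brute-force oracles.

test_that("chi indices match hand-derived values", {
  expect_equal(chiIndex(parseSmiles("CC"), 1, "path"), 1.0)
  expect_equal(chiIndex(parseSmiles("CC(C)C"), 1, "path"), 3 / sqrt(3))
  expect_equal(chiIndex(parseSmiles("CCO"), 1, "path", valence = TRUE),
               1 / sqrt(2) + 1 / sqrt(10))
})

test_that("every chi value equals the brute-force subgraph oracle", {
  fx <- makeFixtures(seed = 19, nRandom = 6)
  fx <- Filter(function(g) !hasMarkers(g) && atomCount(g) <= 12, fx)
  expect_gt(length(fx), 20)
  for (g in fx) {
    for (m in 0:4) {
      for (kd in c("path", "cluster", "path_cluster")) {
        if ((kd == "cluster" && m < 3) || (kd == "path_cluster" && m < 4)) next
        for (val in c(FALSE, TRUE)) {
          expect_equal(chiIndex(g, m, kd, valence = val),
                       oracleChi(g, m, kd, valence = val),
                       tolerance = 1e-9,
                       info = paste(molId(g), m, kd, val))
        }
      }
    }
  }
})

test_that("C/D combinations follow the configured orientation", {
  # saturated hydrocarbons: delta == delta^v, so D = 0 and C = 1 everywhere
  for (nm in c("butane", "isobutane", "neopentane", "cyclohexane")) {
    g <- makeFixtures(seed = 1, nRandom = 0)[[nm]]
    for (m in 0:2) {
      cd <- chiCombined(g, m, "path")
      expect_equal(unname(cd["C"]), 1, info = nm)
      expect_equal(unname(cd["D"]), 0, info = nm)
    }
  }
  # ethanol order 1: chi = 1.4142, chi^v = 1.0233
  eth <- parseSmiles("CCO")
  s <- sqrt(2); v <- 1 / sqrt(2) + 1 / sqrt(10)
  cd <- chiCombined(eth, 1, "path")
  expect_equal(unname(cd["D"]), s - v, tolerance = 1e-9)
  expect_equal(unname(cd["C"]), s / v, tolerance = 1e-9)
  # both toggles flip their combination
  conv <- topoConventions(chiQuotient = "valence_over_simple",
                          chiDifference = "valence_minus_simple")
  cd2 <- chiCombined(eth, 1, "path", conventions = conv)
  expect_equal(unname(cd2["C"]), v / s, tolerance = 1e-9)
  expect_equal(unname(cd2["D"]), v - s, tolerance = 1e-9)
  # benzene order 1: chi = 6/2 = 3, chi^v = 6/3 = 2 (delta^v = 3 > delta)
  cdb <- chiCombined(parseSmiles("c1ccccc1"), 1, "path")
  expect_equal(unname(cdb["D"]), 1, tolerance = 1e-9)
  expect_equal(unname(cdb["C"]), 3 / 2, tolerance = 1e-9)
})

test_that("charge indices match hand values and the double-loop oracle", {
  eth <- parseSmiles("CC")
  expect_equal(unname(chargeIndices(eth, 1)["G1"]), 0)
  pro <- parseSmiles("CCC")
  ci <- chargeIndices(pro, 2)
  expect_equal(unname(ci["G1"]), 0.5)
  expect_equal(unname(ci["J1"]), 0.25)
  # diameter shorter than k implies G_k = 0
  expect_equal(unname(chargeIndices(pro, 5)["G5"]), 0)

  for (g in randomTestGraphs(seed = 31, n = 6)) {
    ci <- chargeIndices(g, 4)
    for (k in 1:4) {
      expect_equal(unname(ci[paste0("G", k)]), oracleGk(g, k),
                   tolerance = 1e-9, info = paste(molId(g), k))
    }
  }
})

test_that("charge indices and Wiener are invariant under atom permutation", {
  withr::with_seed(77, {
    for (g in randomTestGraphs(seed = 13, n = 5)) {
      perm <- sample(atomCount(g))
      gp <- permuteAtoms(g, perm)
      expect_equal(chargeIndices(g, 5), chargeIndices(gp, 5), tolerance = 1e-12)
      expect_equal(wienerIndex(g), wienerIndex(gp))
    }
  })
})

test_that("distance histogram underlying G_k bucketing is conserved", {
  for (g in randomTestGraphs(seed = 3, n = 5)) {
    D <- distanceMatrix(g)
    n <- atomCount(g)
    expect_equal(length(D[upper.tri(D)]), n * (n - 1) / 2)
    counts <- table(D[upper.tri(D)])
    expect_equal(sum(counts), n * (n - 1) / 2)
  }
})

test_that("Wiener index matches hand values", {
  expect_equal(wienerIndex(parseSmiles("CCCC")), 10)
  expect_equal(wienerIndex(parseSmiles("CC(C)C")), 9)
  expect_equal(wienerIndex(parseSmiles("CC")), 1)
})

test_that("constitutional indices count degrees, rings and elements", {
  neo <- constitutionalIndices(parseSmiles("CC(C)(C)C"))
  expect_equal(unname(neo["V4"]), 1)
  expect_equal(unname(neo["V1"]), 4)
  ben <- constitutionalIndices(parseSmiles("c1ccccc1"))
  expect_equal(unname(ben["V2"]), 6)
  expect_equal(unname(ben["nRings"]), 1)
  expect_equal(unname(ben["nC"]), 6)
  for (nm in c("butane", "3-methylpentane", "neopentane")) {
    g <- makeFixtures(seed = 1, nRandom = 0)[[nm]]
    expect_equal(unname(constitutionalIndices(g)["nRings"]), 0, info = nm)
  }
})

test_that("valence and simple chi coincide for saturated hydrocarbons", {
  fx <- makeFixtures(seed = 1, nRandom = 0)
  for (nm in c("hexane", "isopentane", "cyclopentane", "2,3-dimethylbutane")) {
    g <- fx[[nm]]
    for (m in 0:4) {
      for (kd in c("path", "cluster", "path_cluster")) {
        if ((kd == "cluster" && m < 3) || (kd == "path_cluster" && m < 4)) next
        expect_equal(chiIndex(g, m, kd), chiIndex(g, m, kd, valence = TRUE),
                     info = paste(nm, m, kd))
      }
    }
  }
})

test_that("computeDescriptors returns stable columns and collects rejects", {
  mols <- list(parseSmiles("CCO", "ok1"), parseSmiles("CCCCC", "ok2"),
               parseSmiles("C[R]", "marked"))
  d <- computeDescriptors(mols)
  expect_equal(d$id, c("ok1", "ok2"))
  rej <- attr(d, "rejects")
  expect_equal(rej$id, "marked")
  expect_match(rej$reason, "marker")
  # fixed column order across runs
  d2 <- computeDescriptors(mols)
  expect_identical(names(d), names(d2))
  # BELm5 undefined below 5 atoms surfaces as NA, not an error
  expect_true(is.na(d[d$id == "ok1", "BELm5"]))
  expect_false(is.na(d[d$id == "ok2", "BELm5"]))
})
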