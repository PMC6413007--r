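# Deterministic molecule fixture sets used throughout the test-suite and
# available from the CLI: named series of small molecules plus seeded random
# connected graphs.

#' Build the fixture molecule set
#'
#' Deterministic from `seed`. Contains linear alkanes C2-C10, branched
#' alkane isomers, cycloalkanes C3-C8, heteroatom probes (ethanol, benzene
#' in Kekulé and aromatic form, pyridine, thiophene), the packaged library
#' fragments (markers resolved by a methyl cap so descriptors are
#' computable) and `nRandom` random connected graphs rendered as abstract
#' carbon skeletons.
#'
#' @param seed integer seed for the random-graph batch.
#' @param nRandom number of random connected graphs (default 10).
#' @param maxRandomAtoms vertex cap for random graphs (default 10).
#' @return named list of [MolGraph-class] objects.
#' @export
makeFixtures <- function(seed = 1, nRandom = 10, maxRandomAtoms = 10) {
  smiles <- c(
    ethane = "CC", propane = "CCC", butane = "CCCC", pentane = "CCCCC",
    hexane = "CCCCCC", heptane = "CCCCCCC", octane = "CCCCCCCC",
    nonane = "CCCCCCCCC", decane = "CCCCCCCCCC",
    isobutane = "CC(C)C", neopentane = "CC(C)(C)C", isopentane = "CCC(C)C",
    `3-methylpentane` = "CCC(C)CC", `2,3-dimethylbutane` = "CC(C)C(C)C",
    cyclopropane = "C1CC1", cyclobutane = "C1CCC1", cyclopentane = "C1CCCC1",
    cyclohexane = "C1CCCCC1", cycloheptane = "C1CCCCCC1",
    cyclooctane = "C1CCCCCCC1",
    ethanol = "CCO", benzene = "c1ccccc1", benzeneKekule = "C1=CC=CC=C1",
    pyridine = "c1ccncc1", thiophene = "c1ccsc1",
    naphthalene = "C1=CC2=CC=CC=C2C=C1", toluene = "Cc1ccccc1"
  )
  out <- lapply(names(smiles), function(nm) parseSmiles(smiles[[nm]], id = nm))
  names(out) <- names(smiles)
  # library fragments, methyl-capped at the attachment marker
  spec <- fprLibrarySpecQuiet()
  for (anchor in spec@anchors) {
    df <- spec@substituents[[anchor]]
    for (r in seq_len(nrow(df))) {
      nm <- sprintf("frag_%s_%s", anchor, df$code[r])
      frag <- parseSmiles(df$smiles[r])
      capSpec <- new("MolGraph",
                     atoms = frag@atoms, bonds = frag@bonds,
                     id = nm, smiles = df$smiles[r])
      mk <- frag@atoms$anchor[!is.na(frag@atoms$anchor)][1]
      capScaffold <- parseSmiles(sub("R", mk, "C[R]", fixed = TRUE))
      g <- spliceFragments(capScaffold, stats::setNames(list(frag), mk))
      g@id <- nm
      g@smiles <- asSmiles(g)
      out[[nm]] <- g
    }
  }
  # seeded random connected graphs (tree plus a few extra edges)
  withr::with_seed(seed, {
    for (k in seq_len(nRandom)) {
      n <- sample(4:maxRandomAtoms, 1)
      edges <- cbind(2:n, vapply(2:n, function(v) sample(v - 1, 1), numeric(1)))
      extra <- min(sample(0:2, 1), n * (n - 1) / 2 - (n - 1))
      tries <- 0
      while (extra > 0 && tries < 50) {
        cand <- sort(sample(n, 2))
        dup <- any(edges[, 1] == cand[2] & edges[, 2] == cand[1]) ||
               any(edges[, 1] == cand[1] & edges[, 2] == cand[2])
        if (!dup) {
          edges <- rbind(edges, c(cand[2], cand[1]))
          extra <- extra - 1
        }
        tries <- tries + 1
      }
      out[[sprintf("random%02d", k)]] <- graphFromEdges(n, edges,
                                                        sprintf("random%02d", k))
    }
  })
  out
}

# abstract connected graph rendered as a carbon skeleton MolGraph (hcount
# forced non-negative; degrees above 4 are allowed for test graphs)
graphFromEdges <- function(n, edges, id = NA_character_) {
  atoms <- data.frame(symbol = rep("C", n), aromatic = FALSE,
                      hcount = 0L, charge = 0L, isotope = NA_integer_,
                      anchor = NA_character_, stringsAsFactors = FALSE)
  bonds <- data.frame(i = pmin(edges[, 1], edges[, 2]),
                      j = pmax(edges[, 1], edges[, 2]),
                      order = 1L, aromatic = FALSE)
  deg <- tabulate(c(bonds$i, bonds$j), nbins = n)
  atoms$hcount <- pmax(0L, 4L - as.integer(deg))
  atoms$delta <- as.integer(deg)
  atoms$deltaV <- kierHallDeltaV(atoms$symbol, atoms$hcount)
  new("MolGraph", atoms = atoms, bonds = bonds, id = id,
      smiles = NA_character_)
}

fprLibrarySpecQuiet <- function() suppressMessages(fprLibrarySpec())
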