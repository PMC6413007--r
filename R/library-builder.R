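# Combinatorial library construction: scaffold + per-anchor substituent
# lists -> all assembled molecules, with SMILES re-emitted with freshly
# renumbered ring closures.

#' Construct a LibrarySpec
#'
#' @param scaffoldSmiles scaffold SMILES with k >= 1 distinct indexed anchor
#'   markers `[R1]`...`[Rk]`.
#' @param substituents named list (by anchor id) of data.frames with columns
#'   `code` (single letter), `name`, `smiles` (fragment with one `[R]`
#'   marker). Every anchor needs a non-empty list; an explicit hydrogen-like
#'   fragment expresses the zero-substituent case.
#' @param anchors optional explicit anchor order (governs id-code letter
#'   order); defaults to `R1 < R2 < ...` numeric order when all anchors are
#'   of the `R<k>` form, otherwise scaffold string order.
#' @return a [LibrarySpec-class].
#' @export
librarySpec <- function(scaffoldSmiles, substituents, anchors = NULL) {
  g <- parseSmiles(scaffoldSmiles, id = "scaffold")
  found <- as.character(stats::na.omit(g@atoms$anchor))
  if (!length(found)) stop("scaffold has no anchor markers", call. = FALSE)
  if (is.null(anchors)) {
    anchors <- if (all(grepl("^R[0-9]+$", found))) {
      found[order(as.integer(sub("^R", "", found)))]
    } else {
      found
    }
  } else if (!setequal(anchors, found)) {
    stop("declared anchors do not match the scaffold markers", call. = FALSE)
  }
  for (a in names(substituents)) {
    df <- substituents[[a]]
    for (r in seq_len(nrow(df))) {
      rep <- validateFragment(df$smiles[r], expectMarker = TRUE)
      if (!rep$ok) {
        stop(sprintf("anchor %s, substituent %s ('%s'): %s", a, df$code[r],
                     df$smiles[r], paste(rep$faults, collapse = "; ")),
             call. = FALSE)
      }
    }
  }
  new("LibrarySpec", scaffoldSmiles = scaffoldSmiles, scaffold = g,
      anchors = as.character(anchors), substituents = substituents)
}

#' Attach substituents to a scaffold
#'
#' Replaces each anchor placeholder by a single bond from its scaffold
#' neighbour to the fragment atom adjacent to the fragment's `[R]` marker;
#' the marker atoms contribute no atoms to the product. The returned
#' molecule's SMILES is regenerated, which renumbers ring closures so that no
#' digit is reused while open.
#'
#' @param spec a [LibrarySpec-class] (or a scaffold `MolGraph` with markers).
#' @param assignment named character vector or list, anchor id -> fragment
#'   SMILES; alternatively anchor id -> row index into the spec's lists.
#' @param id identifier for the product molecule.
#' @return a marker-free [MolGraph-class]; its `@smiles` holds the assembled
#'   SMILES.
#' @export
attachSubstituents <- function(spec, assignment, id = NA_character_) {
  scaffold <- if (is(spec, "LibrarySpec")) spec@scaffold else spec
  frags <- lapply(assignment, function(s) {
    if (is(s, "MolGraph")) s else parseSmiles(as.character(s))
  })
  g <- spliceFragments(scaffold, frags)
  g@id <- id
  g@smiles <- asSmiles(g)
  # round-trip guard: the emitted SMILES must re-parse to the same size
  chk <- parseSmiles(g@smiles)
  stopifnot(atomCount(chk) == atomCount(g), bondCount(chk) == bondCount(g))
  g
}

# Graph-level assembly. Each fragment must contain exactly one [R] marker;
# the scaffold must contain each anchor in names(frags) exactly once.
spliceFragments <- function(scaffold, frags) {
  atoms <- scaffold@atoms; bonds <- scaffold@bonds
  for (anchor in names(frags)) {
    fg <- frags[[anchor]]
    aIdx <- which(atoms$anchor == anchor)
    if (length(aIdx) != 1) {
      stop(sprintf("anchor %s not present exactly once in scaffold", anchor),
           call. = FALSE)
    }
    mIdx <- which(!is.na(fg@atoms$anchor))
    if (length(mIdx) != 1) {
      stop(sprintf("fragment for %s must contain exactly one [R] marker", anchor),
           call. = FALSE)
    }
    # neighbours of the two markers
    sNb <- c(bonds$j[bonds$i == aIdx], bonds$i[bonds$j == aIdx])
    fNb <- c(fg@bonds$j[fg@bonds$i == mIdx], fg@bonds$i[fg@bonds$j == mIdx])
    if (length(sNb) != 1 || length(fNb) != 1) {
      stop(sprintf("anchor %s: markers must be terminal", anchor), call. = FALSE)
    }
    off <- nrow(atoms)
    fa <- fg@atoms; fb <- fg@bonds
    fb$i <- fb$i + off; fb$j <- fb$j + off
    atoms <- rbind(atoms, fa)
    # attachment bond is always single order
    bonds <- rbind(bonds, fb,
                   data.frame(i = sNb, j = fNb + off, order = 1L,
                              aromatic = FALSE))
    # drop the two marker vertices
    drop <- c(aIdx, mIdx + off)
    keep <- setdiff(seq_len(nrow(atoms)), drop)
    remap <- match(seq_len(nrow(atoms)), keep)
    bonds <- bonds[!(bonds$i %in% drop | bonds$j %in% drop), , drop = FALSE]
    bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    sw <- bonds$i > bonds$j
    tmp <- bonds$i[sw]; bonds$i[sw] <- bonds$j[sw]; bonds$j[sw] <- tmp
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL; rownames(bonds) <- NULL
  }
  # junction valence check, then recompute degrees
  checkValences(atoms, bonds)
  na <- nrow(atoms)
  atoms$delta <- as.integer(tabulate(c(bonds$i, bonds$j), nbins = na))
  real <- is.na(atoms$anchor)
  atoms$deltaV[real] <- kierHallDeltaV(atoms$symbol[real], atoms$hcount[real])
  new("MolGraph", atoms = atoms, bonds = bonds, id = NA_character_,
      smiles = NA_character_)
}

checkValences <- function(atoms, bonds) {
  na <- nrow(atoms)
  bsum <- numeric(na)
  if (nrow(bonds)) {
    ordv <- ifelse(bonds$aromatic, 1L, bonds$order)
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$i[k]] <- bsum[bonds$i[k]] + ordv[k]
      bsum[bonds$j[k]] <- bsum[bonds$j[k]] + ordv[k]
    }
  }
  bsum <- bsum + as.integer(atoms$aromatic) + atoms$hcount
  for (v in seq_len(na)) {
    if (!is.na(atoms$anchor[v])) next
    vals <- .DEFAULT_VALENCES[[atoms$symbol[v]]]
    if (is.null(vals)) next
    if (bsum[v] > max(vals) + abs(atoms$charge[v])) {
      stop(sprintf("valence violation at atom %d (%s): %g connections",
                   v, atoms$symbol[v], bsum[v]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Enumerate a combinatorial library
#'
#' Builds the full Cartesian product over the anchor substituent lists in a
#' documented order: the first anchor is the most significant position and
#' the last anchor varies fastest (anchor order major, list order minor).
#' Each molecule's `id` is the concatenation of the substituent letter codes
#' in anchor order (e.g. `CAAA`).
#'
#' @param spec a [LibrarySpec-class].
#' @return list of marker-free [MolGraph-class] objects with unique ids;
#'   assembly failures abort with the offending id code.
#' @export
enumerateLibrary <- function(spec) {
  anchors <- spec@anchors
  lists <- spec@substituents[anchors]
  frags <- lapply(lists, function(df) {
    fl <- lapply(df$smiles, parseSmiles)
    names(fl) <- df$code
    fl
  })
  sizes <- vapply(lists, nrow, integer(1))
  idx <- rev(expand.grid(rev(lapply(sizes, seq_len)), KEEP.OUT.ATTRS = FALSE))
  names(idx) <- anchors
  out <- vector("list", nrow(idx))
  for (r in seq_len(nrow(idx))) {
    pick <- as.integer(idx[r, ])
    code <- paste(mapply(function(df, i) df$code[i], lists, pick), collapse = "")
    asg <- lapply(seq_along(anchors), function(a) frags[[a]][[pick[a]]])
    names(asg) <- anchors
    out[[r]] <- tryCatch(attachSubstituents(spec, asg, id = code),
                         error = function(e) {
                           stop(sprintf("assembly failed for %s: %s", code,
                                        conditionMessage(e)), call. = FALSE)
                         })
  }
  ids <- vapply(out, molId, character(1))
  if (anyDuplicated(ids)) stop("duplicated id codes in enumeration", call. = FALSE)
  out
}

#' Write molecules as a .smi file
#'
#' One line per molecule: SMILES, a space, then the identifier. UTF-8,
#' stable ordering, `#` starts a comment line on read.
#'
#' @param mols list of [MolGraph-class] objects.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeSmi <- function(mols, path) {
  if (length(mols) == 0) {
    warning("writing an empty .smi file", call. = FALSE)
    writeLines(character(0), path, useBytes = TRUE)
    return(invisible(path))
  }
  lines <- vapply(mols, function(g) {
    smi <- if (!is.na(g@smiles)) g@smiles else asSmiles(g)
    paste(smi, ifelse(is.na(g@id), "", g@id))
  }, character(1))
  writeLines(trimws(lines), path, useBytes = TRUE)
  invisible(path)
}
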