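# SMILES reader for the organic subset plus bracket atoms and the library
# builder's anchor markers [R], [R1]..[R9]. Produces the hydrogen-suppressed
# MolGraph with implicit-hydrogen counts and Kier-Hall degrees populated.
#
# Supported: atoms B C N O P S F Cl Br I Si, aromatic b c n o p s, bracket
# atoms with isotope / chirality (ignored) / explicit H / charge / atom class,
# bonds - = # : / \ (slashes read as single; stereochemistry is out of scope),
# branches, ring bonds 1-9 and %nn. Dots (multi-fragment input) are rejected:
# every descriptor here requires a connected graph.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I", "Si")
.AROMATIC_OK <- c("b", "c", "n", "o", "p", "s")

parseError <- function(smiles, pos, token, why) {
  stop(sprintf("SMILES parse error in '%s' at position %d ('%s'): %s",
               smiles, pos, token, why), call. = FALSE)
}

#' Parse SMILES into a hydrogen-suppressed molecular graph
#'
#' Explicit `[H]` atoms are folded into the heavy-atom hydrogen counts; the
#' simple degree \eqn{\delta}, the valence degree \eqn{\delta^v} (computed as
#' \eqn{Z_v - h} for second-period atoms and \eqn{(Z_v - h)/(Z - Z_v - 1)}
#' beyond) and implicit hydrogens are populated on return. Charged or
#' isotopically labelled atoms are accepted with a warning: \eqn{\delta^v}
#' uses the neutral-element electron count. Anchor markers `[R]`/`[Rk]` are
#' kept as placeholder vertices (see [hasMarkers()]).
#'
#' @param smiles a single SMILES string.
#' @param id optional molecule identifier.
#' @return a [MolGraph-class] object.
#' @examples
#' g <- parseSmiles("CCO", "ethanol")
#' atoms(g)$deltaV  # oxygen: 6 - 1 = 5
#' @export
parseSmiles <- function(smiles, id = NA_character_) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (is.na(smiles) || !nzchar(smiles)) {
    stop("empty SMILES", call. = FALSE)
  }
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)

  at_symbol <- character(); at_arom <- logical(); at_h <- integer()
  at_charge <- integer(); at_iso <- integer(); at_anchor <- character()
  at_hexplicit <- logical()
  bd_i <- integer(); bd_j <- integer(); bd_order <- integer(); bd_arom <- logical()

  prev <- NA_integer_
  stack <- integer()
  pend_order <- NA_integer_; pend_arom <- NA; pend_pos <- NA_integer_
  rings <- list()   # key: ring number as character -> list(atom, order, arom, pos)

  addAtom <- function(symbol, aromatic, h, charge, iso, anchor, hexp) {
    at_symbol[length(at_symbol) + 1L] <<- symbol
    at_arom[length(at_arom) + 1L] <<- aromatic
    at_h[length(at_h) + 1L] <<- h
    at_charge[length(at_charge) + 1L] <<- charge
    at_iso[length(at_iso) + 1L] <<- iso
    at_anchor[length(at_anchor) + 1L] <<- anchor
    at_hexplicit[length(at_hexplicit) + 1L] <<- hexp
    idx <- length(at_symbol)
    if (!is.na(prev)) {
      ord <- pend_order; arm <- pend_arom
      if (is.na(ord)) {   # default bond
        arm <- at_arom[prev] && aromatic
        ord <- 1L
      }
      addBond(prev, idx, ord, isTRUE(arm))
    }
    pend_order <<- NA_integer_; pend_arom <<- NA
    prev <<- idx
    idx
  }
  addBond <- function(i, j, order, aromatic) {
    bd_i[length(bd_i) + 1L] <<- min(i, j)
    bd_j[length(bd_j) + 1L] <<- max(i, j)
    bd_order[length(bd_order) + 1L] <<- order
    bd_arom[length(bd_arom) + 1L] <<- aromatic
  }

  k <- 1L
  while (k <= n) {
    ch <- chars[k]
    if (ch == "(") {
      if (is.na(prev)) parseError(smiles, k, ch, "branch before any atom")
      stack <- c(stack, prev); k <- k + 1L
    } else if (ch == ")") {
      if (!length(stack)) parseError(smiles, k, ch, "unmatched closing parenthesis")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; k <- k + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pend_order <- switch(ch, "=" = 2L, "#" = 3L, 1L)
      pend_arom <- (ch == ":")
      pend_pos <- k
      k <- k + 1L
    } else if (ch == ".") {
      parseError(smiles, k, ch,
                 "multi-fragment (disconnected) molecules are unsupported")
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (is.na(prev)) parseError(smiles, k, ch, "ring bond before any atom")
      if (ch == "%") {
        if (k + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[k + 1L], chars[k + 2L]))) {
          parseError(smiles, k, ch, "'%' must be followed by two digits")
        }
        num <- paste0(chars[k + 1L], chars[k + 2L]); k <- k + 3L
      } else {
        num <- ch; k <- k + 1L
      }
      if (!is.null(rings[[num]])) {
        op <- rings[[num]]
        if (op$atom == prev) parseError(smiles, k - 1L, num, "ring bond to itself")
        ord <- pend_order; arm <- pend_arom
        if (!is.na(op$order) && !is.na(ord) && (op$order != ord)) {
          parseError(smiles, k - 1L, num, "conflicting ring-bond orders")
        }
        if (is.na(ord)) { ord <- op$order; arm <- op$arom }
        if (is.na(ord)) {
          arm <- at_arom[op$atom] && at_arom[prev]
          ord <- 1L
        }
        addBond(op$atom, prev, ord, isTRUE(arm))
        rings[[num]] <- NULL
      } else {
        rings[[num]] <- list(atom = prev, order = pend_order, arom = pend_arom,
                             pos = k - 1L)
      }
      pend_order <- NA_integer_; pend_arom <- NA
    } else if (ch == "[") {
      close <- which(chars == "]" & seq_len(n) > k)
      if (!length(close)) parseError(smiles, k, ch, "unterminated bracket atom")
      close <- close[1]
      body <- paste(chars[(k + 1L):(close - 1L)], collapse = "")
      parseBracket(smiles, k, body, addAtom)
      k <- close + 1L
    } else if (grepl("[A-Za-z*]", ch)) {
      two <- if (k < n) paste0(ch, chars[k + 1L]) else ""
      if (two %in% c("Cl", "Br", "Si")) {
        addAtom(two, FALSE, NA_integer_, 0L, NA_integer_, NA_character_, FALSE)
        k <- k + 2L
      } else if (ch %in% .ORGANIC_SUBSET) {
        addAtom(ch, FALSE, NA_integer_, 0L, NA_integer_, NA_character_, FALSE)
        k <- k + 1L
      } else if (ch %in% .AROMATIC_OK) {
        addAtom(toupper(ch), TRUE, NA_integer_, 0L, NA_integer_, NA_character_, FALSE)
        k <- k + 1L
      } else {
        parseError(smiles, k, ch, "unknown atom symbol outside brackets")
      }
    } else {
      parseError(smiles, k, ch, "unexpected character")
    }
  }
  if (length(stack)) parseError(smiles, n, chars[n], "unclosed branch")
  if (length(rings)) {
    op <- rings[[1]]
    parseError(smiles, op$pos, names(rings)[1],
               sprintf("unclosed ring bond %s", names(rings)[1]))
  }
  if (!length(at_symbol)) parseError(smiles, 1L, chars[1], "no atoms")

  buildMolGraph(smiles, id,
                data.frame(symbol = at_symbol, aromatic = at_arom,
                           hcount = at_h, charge = at_charge, isotope = at_iso,
                           anchor = at_anchor, hexplicit = at_hexplicit,
                           stringsAsFactors = FALSE),
                data.frame(i = bd_i, j = bd_j, order = bd_order,
                           aromatic = bd_arom))
}

parseBracket <- function(smiles, pos, body, addAtom) {
  m <- regmatches(body, regexec(
    "^([0-9]+)?(R[0-9]?|[A-Z][a-z]?|[bcnops]|\\*)(@{1,2})?(H[0-9]*)?(\\+[0-9]*|-[0-9]*|\\++|-+)?(:[0-9]+)?$",
    body))[[1]]
  if (!length(m)) {
    parseError(smiles, pos, paste0("[", body, "]"), "malformed bracket atom")
  }
  iso <- if (nzchar(m[2])) as.integer(m[2]) else NA_integer_
  sym <- m[3]
  hstr <- m[5]; cstr <- m[6]
  h <- if (!nzchar(hstr)) 0L else if (hstr == "H") 1L else as.integer(sub("H", "", hstr))
  charge <- 0L
  if (nzchar(cstr)) {
    sign <- if (startsWith(cstr, "+")) 1L else -1L
    digits <- gsub("[+-]", "", cstr)
    charge <- sign * if (nzchar(digits)) as.integer(digits) else
      nchar(gsub("[0-9]", "", cstr))
  }
  if (grepl("^R[0-9]?$", sym)) {
    addAtom("R", FALSE, 0L, 0L, NA_integer_, sym, TRUE)
    return(invisible())
  }
  aromatic <- sym %in% .AROMATIC_OK
  symbol <- if (aromatic) toupper(sym) else sym
  if (symbol != "H" && !symbol %in% c(.ORGANIC_SUBSET, "H")) {
    if (!symbol %in% elementTable()$symbol) {
      parseError(smiles, pos, paste0("[", body, "]"),
                 sprintf("unsupported element '%s'", symbol))
    }
  }
  addAtom(symbol, aromatic, h, charge, iso, NA_character_, TRUE)
  invisible()
}

# Assemble atoms/bonds into a validated MolGraph: fold explicit hydrogens,
# assign implicit hydrogens from default valences, compute delta / delta^v,
# and require connectivity.
buildMolGraph <- function(smiles, id, atoms, bonds) {
  # fold explicit [H] vertices into neighbour hcounts
  hIdx <- which(atoms$symbol == "H" & is.na(atoms$anchor))
  if (length(hIdx)) {
    if (length(hIdx) == nrow(atoms)) {
      stop("molecule has no heavy atoms", call. = FALSE)
    }
    for (h in hIdx) {
      inc <- which(bonds$i == h | bonds$j == h)
      if (length(inc) != 1 || bonds$order[inc[1]] != 1) {
        stop("explicit hydrogen must carry exactly one single bond", call. = FALSE)
      }
      nb <- setdiff(c(bonds$i[inc], bonds$j[inc]), h)
      atoms$hcount[nb] <- ifelse(is.na(atoms$hcount[nb]), 1L,
                                 atoms$hcount[nb] + 1L)
      atoms$hexplicit[nb] <- TRUE
    }
    keep <- setdiff(seq_len(nrow(atoms)), hIdx)
    remap <- match(seq_len(nrow(atoms)), keep)
    bonds <- bonds[!(bonds$i %in% hIdx | bonds$j %in% hIdx), , drop = FALSE]
    bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL; rownames(bonds) <- NULL
  }
  na <- nrow(atoms)
  # connectivity (BFS over bonds)
  if (na > 1) {
    seen <- logical(na); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- c(bonds$j[bonds$i == v], bonds$i[bonds$j == v])
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
    if (!all(seen)) stop("disconnected molecular graph", call. = FALSE)
  }
  # bond-order sums (aromatic bonds count 1, aromatic atoms get +1)
  bsum <- numeric(na)
  if (nrow(bonds)) {
    ordv <- ifelse(bonds$aromatic, 1L, bonds$order)
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$i[k]] <- bsum[bonds$i[k]] + ordv[k]
      bsum[bonds$j[k]] <- bsum[bonds$j[k]] + ordv[k]
    }
  }
  bsum <- bsum + as.integer(atoms$aromatic)
  # implicit hydrogens for organic-subset atoms written without brackets
  for (v in seq_len(na)) {
    if (!is.na(atoms$hcount[v])) next
    vals <- .DEFAULT_VALENCES[[atoms$symbol[v]]]
    fit <- vals[vals >= bsum[v]]
    atoms$hcount[v] <- if (length(fit)) as.integer(fit[1] - bsum[v]) else 0L
  }
  # degrees
  atoms$delta <- 0L
  if (nrow(bonds)) {
    tab <- tabulate(c(bonds$i, bonds$j), nbins = na)
    atoms$delta <- as.integer(tab)
  }
  atoms$deltaV <- NA_real_
  real <- is.na(atoms$anchor)
  if (any(real)) {
    atoms$deltaV[real] <- kierHallDeltaV(atoms$symbol[real], atoms$hcount[real])
  }
  if (any(atoms$charge[real] != 0) || any(!is.na(atoms$isotope[real]))) {
    warning("charged/isotopic atoms: valence degree uses the neutral element",
            call. = FALSE)
  }
  atoms$hexplicit <- NULL
  new("MolGraph", atoms = atoms, bonds = bonds, id = id, smiles = smiles)
}

#' Validate a SMILES fragment for library building
#'
#' Runs the parser and reports faults as data rather than raising errors:
#' unparseable input, a missing, duplicated or non-terminal attachment
#' marker, or an anchor marker carrying a ring closure. A fragment with zero
#' faults is accepted by the library builder.
#'
#' @param smiles fragment SMILES.
#' @param expectMarker logical; require exactly one `[R]`-type marker.
#' @return list with elements `smiles`, `ok` (logical) and `faults`
#'   (character vector of fault descriptions, empty when accepted).
#' @export
validateFragment <- function(smiles, expectMarker = TRUE) {
  faults <- character()
  g <- tryCatch(suppressWarnings(parseSmiles(smiles)), error = function(e) {
    faults <<- c(faults, conditionMessage(e))
    NULL
  })
  if (!is.null(g)) {
    nmark <- sum(!is.na(g@atoms$anchor))
    if (expectMarker) {
      if (nmark == 0) faults <- c(faults, "no attachment marker [R] in fragment")
      if (nmark > 1) faults <- c(faults, "more than one attachment marker")
      if (nmark == 1) {
        mk <- which(!is.na(g@atoms$anchor))
        if (g@atoms$delta[mk] != 1) {
          faults <- c(faults, paste0("attachment marker must be terminal ",
                                     "(it carries a ring closure or several bonds)"))
        }
        if (atomCount(g) < 2) faults <- c(faults, "fragment has no atoms besides the marker")
      }
    } else if (nmark > 0) {
      faults <- c(faults, "unexpected attachment marker")
    }
  }
  list(smiles = smiles, ok = length(faults) == 0, faults = faults)
}
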