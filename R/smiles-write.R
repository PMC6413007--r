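# SMILES writer. Produces valid (not canonical) SMILES from a MolGraph by
# depth-first traversal; ring-closure digits are assigned from the lowest
# free digit at the moment a ring bond is opened and released when closed,
# escaping to the %nn form above 9 — so no digit is ever reused while open.

#' Write a MolGraph as SMILES
#'
#' The output re-parses to a graph isomorphic to the input (asserted in the
#' test suite); aromatic atoms are emitted in lowercase, bracket atoms are
#' used whenever charge, isotope or a hydrogen count that the reader could
#' not infer requires them. Anchor markers are written back as `[R]`/`[Rk]`.
#'
#' @param g a [MolGraph-class].
#' @return a single SMILES string.
#' @export
asSmiles <- function(g) {
  a <- g@atoms; b <- g@bonds
  n <- nrow(a)
  if (n == 0) stop("empty graph", call. = FALSE)
  a$bondsum <- as.integer(a$aromatic)
  if (nrow(b)) {
    ordv <- ifelse(b$aromatic, 1L, b$order)
    for (k in seq_len(nrow(b))) {
      a$bondsum[b$i[k]] <- a$bondsum[b$i[k]] + ordv[k]
      a$bondsum[b$j[k]] <- a$bondsum[b$j[k]] + ordv[k]
    }
  }
  if (n == 1) return(atomToken(a, 1L, 0))

  nb <- vector("list", n)          # neighbour -> bond row index
  for (k in seq_len(nrow(b))) {
    nb[[b$i[k]]] <- c(nb[[b$i[k]]], k)
    nb[[b$j[k]]] <- c(nb[[b$j[k]]], k)
  }
  other <- function(k, v) if (b$i[k] == v) b$j[k] else b$i[k]

  # iterative DFS building a spanning tree; non-tree edges are ring closures
  visited <- logical(n)
  treechild <- vector("list", n)   # v -> list of (bond row, child)
  ringAt <- vector("list", n)      # v -> bond rows of ring closures at v
  usedEdge <- logical(nrow(b))
  stack <- 1L; visited[1] <- TRUE
  order <- integer(0)
  parentEdge <- integer(n)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, v)
    for (k in nb[[v]]) {
      if (usedEdge[k]) next
      w <- other(k, v)
      if (!visited[w]) {
        visited[w] <- TRUE
        usedEdge[k] <- TRUE
        treechild[[v]] <- c(treechild[[v]], list(c(k, w)))
        parentEdge[w] <- k
        stack <- c(stack, w)
      } else {
        usedEdge[k] <- TRUE
        ringAt[[v]] <- c(ringAt[[v]], k)
        ringAt[[w]] <- c(ringAt[[w]], k)
      }
    }
  }

  digitOf <- new.env(parent = emptyenv())  # bond row -> assigned digit label
  usedDigits <- integer(0)
  nextDigit <- function() {
    d <- setdiff(1:99, usedDigits)[1]
    usedDigits <<- c(usedDigits, d)
    d
  }
  digitLabel <- function(d) if (d > 9) sprintf("%%%02d", d) else as.character(d)

  emit <- function(v, inBond) {
    out <- if (is.na(inBond)) "" else bondToken(b, inBond, a)
    out <- paste0(out, atomToken(a, v, length(nb[[v]])))
    for (k in ringAt[[v]]) {
      key <- as.character(k)
      if (is.null(digitOf[[key]])) {
        d <- nextDigit()
        digitOf[[key]] <- d
        out <- paste0(out, bondToken(b, k, a), digitLabel(d))
      } else {
        d <- digitOf[[key]]
        usedDigits <<- setdiff(usedDigits, d)
        out <- paste0(out, digitLabel(d))
      }
    }
    kids <- treechild[[v]]
    if (length(kids)) {
      for (q in seq_along(kids)) {
        kk <- kids[[q]]
        sub <- emit(kk[2], kk[1])
        out <- if (q < length(kids)) paste0(out, "(", sub, ")")
               else paste0(out, sub)
      }
    }
    out
  }
  emit(1L, NA_integer_)
}

bondToken <- function(b, k, a) {
  if (b$aromatic[k]) return("")
  switch(as.character(b$order[k]), "2" = "=", "3" = "#",
         # explicit single bond between two aromatic atoms (e.g. biphenyl)
         if (a$aromatic[b$i[k]] && a$aromatic[b$j[k]]) "-" else "")
}

atomToken <- function(a, v, nNeighbours) {
  if (!is.na(a$anchor[v])) return(paste0("[", a$anchor[v], "]"))
  sym <- a$symbol[v]
  outSym <- if (a$aromatic[v]) tolower(sym) else sym
  plain <- sym %in% .ORGANIC_SUBSET && a$charge[v] == 0 && is.na(a$isotope[v])
  if (plain) {
    # would the reader infer the stored hcount?
    inferred <- impliedHcount(a, v)
    if (identical(inferred, a$hcount[v])) return(outSym)
  }
  h <- a$hcount[v]
  hTok <- if (h == 0) "" else if (h == 1) "H" else paste0("H", h)
  ch <- a$charge[v]
  cTok <- if (ch == 0) "" else if (ch > 0) {
    if (ch == 1) "+" else paste0("+", ch)
  } else {
    if (ch == -1) "-" else paste0("-", abs(ch))
  }
  iTok <- if (is.na(a$isotope[v])) "" else as.character(a$isotope[v])
  paste0("[", iTok, outSym, hTok, cTok, "]")
}

# what hcount a reader would infer for atom v written without brackets;
# requires the bond table via the attribute-free recomputation below
impliedHcount <- function(a, v) {
  bs <- a$bondsum[v]
  vals <- .DEFAULT_VALENCES[[a$symbol[v]]]
  fit <- vals[vals >= bs]
  if (length(fit)) as.integer(fit[1] - bs) else 0L
}
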