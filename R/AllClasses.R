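#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib MolTopo, .registration = TRUE
NULL

#' MolGraph: hydrogen-suppressed molecular graph
#'
#' The central container of the package: heavy atoms as vertices, bonds as
#' edges. Implicit and explicit hydrogens are folded into the per-atom
#' `hcount`; the Kier-Hall vertex weights (simple degree \eqn{\delta} and
#' valence degree \eqn{\delta^v}) are precomputed at parse time. Anchor-point
#' placeholders (`[R]`, `[R1]`...) from library fragments are carried as
#' marker vertices; descriptor functions refuse graphs that still contain
#' markers.
#'
#' @slot atoms data.frame with one row per heavy atom: `symbol`, `aromatic`,
#'   `hcount`, `charge`, `isotope`, `anchor` (marker id or NA), `delta`,
#'   `deltaV`.
#' @slot bonds data.frame with one row per bond: `i`, `j` (1-based atom
#'   indices, i < j), `order` (1, 2, 3), `aromatic` (logical).
#' @slot id molecule identifier string.
#' @slot smiles the input SMILES the graph was parsed from (informative only).
#' @export
setClass("MolGraph",
  representation(atoms = "data.frame", bonds = "data.frame",
                 id = "character", smiles = "character"),
  prototype(id = NA_character_, smiles = NA_character_))

setValidity("MolGraph", function(object) {
  a <- object@atoms; b <- object@bonds
  msgs <- character()
  need <- c("symbol", "aromatic", "hcount", "charge", "isotope", "anchor",
            "delta", "deltaV")
  if (!all(need %in% names(a))) {
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(b) > 0) {
    if (any(b$i == b$j)) msgs <- c(msgs, "self-loop bond")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate bond")
    if (any(b$i < 1 | b$j < 1 | b$i > nrow(a) | b$j > nrow(a))) {
      msgs <- c(msgs, "bond index out of range")
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn MolGraph number of heavy atoms
#' @param x,object a `MolGraph`
#' @export
atomCount <- function(x) nrow(x@atoms)

#' @describeIn MolGraph number of bonds
#' @export
bondCount <- function(x) nrow(x@bonds)

#' @describeIn MolGraph atom table accessor
#' @export
atoms <- function(x) x@atoms

#' @describeIn MolGraph bond table accessor
#' @export
bonds <- function(x) x@bonds

#' @describeIn MolGraph molecule identifier accessor
#' @export
molId <- function(x) x@id

#' @describeIn MolGraph TRUE if the graph still carries anchor markers
#' @export
hasMarkers <- function(x) any(!is.na(x@atoms$anchor))

setMethod("show", "MolGraph", function(object) {
  cat(sprintf("MolGraph '%s': %d heavy atoms, %d bonds",
              ifelse(is.na(object@id), "<unnamed>", object@id),
              atomCount(object), bondCount(object)))
  if (hasMarkers(object)) {
    cat(sprintf(" [markers: %s]",
                paste(stats::na.omit(object@atoms$anchor), collapse = ", ")))
  }
  cat("\n")
  if (!is.na(object@smiles)) cat("  smiles:", object@smiles, "\n")
})

#' LibrarySpec: a combinatorial library definition
#'
#' One base scaffold carrying k indexed anchor points `[R1]`...`[Rk]` plus an
#' ordered substituent list per anchor. Substituent fragments use the plain
#' `[R]` marker; the marker-adjacent atom becomes the attachment atom and the
#' marker itself contributes no atom.
#'
#' @slot scaffoldSmiles scaffold SMILES containing the indexed anchors.
#' @slot scaffold parsed scaffold `MolGraph` (with marker vertices).
#' @slot anchors ordered anchor ids, e.g. `c("R1","R2","R3","R4")`.
#' @slot substituents named list (by anchor id) of data.frames with columns
#'   `code`, `name`, `smiles`.
#' @export
setClass("LibrarySpec",
  representation(scaffoldSmiles = "character", scaffold = "MolGraph",
                 anchors = "character", substituents = "list"))

setValidity("LibrarySpec", function(object) {
  msgs <- character()
  found <- stats::na.omit(object@scaffold@atoms$anchor)
  if (!setequal(found, object@anchors)) {
    msgs <- c(msgs, "scaffold markers do not match declared anchors")
  }
  if (anyDuplicated(found)) msgs <- c(msgs, "duplicated anchor in scaffold")
  if (!setequal(names(object@substituents), object@anchors)) {
    msgs <- c(msgs, "substituent lists must be named by anchor id")
  }
  for (a in names(object@substituents)) {
    df <- object@substituents[[a]]
    if (!is.data.frame(df) || nrow(df) == 0 ||
        !all(c("code", "name", "smiles") %in% names(df))) {
      msgs <- c(msgs, sprintf("anchor %s: need a non-empty code/name/smiles table", a))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "LibrarySpec", function(object) {
  sizes <- vapply(object@substituents[object@anchors], nrow, integer(1))
  cat(sprintf("LibrarySpec: %d anchors (%s), list sizes %s -> %d molecules\n",
              length(object@anchors), paste(object@anchors, collapse = ", "),
              paste(sizes, collapse = " x "), prod(sizes)))
  cat("  scaffold:", object@scaffoldSmiles, "\n")
})

#' LinearQsarModel: intercept + named linear coefficients
#'
#' Holds a linear QSAR model `response = intercept + sum(coef * descriptor)`
#' plus an optional applicability window on the model output.
#'
#' @slot response name of the modelled response (e.g. `"DF"`, `"LogKi"`).
#' @slot intercept numeric intercept.
#' @slot coefficients named numeric vector; names are descriptor column names.
#' @slot window optional numeric length-2 `(low, high)` applicability window
#'   on the model output; `c(NA, NA)` if absent.
#' @slot stats named numeric vector of fit statistics (may be empty).
#' @export
setClass("LinearQsarModel",
  representation(response = "character", intercept = "numeric",
                 coefficients = "numeric", window = "numeric",
                 stats = "numeric"),
  prototype(window = c(NA_real_, NA_real_), stats = numeric()))

setValidity("LinearQsarModel", function(object) {
  if (length(object@intercept) != 1) return("intercept must be length 1")
  if (is.null(names(object@coefficients)) ||
      any(!nzchar(names(object@coefficients)))) {
    return("coefficients must be named")
  }
  if (length(object@window) != 2) return("window must be length 2")
  if (!any(is.na(object@window)) && object@window[1] >= object@window[2]) {
    return("window low must be < high")
  }
  TRUE
})

#' @describeIn LinearQsarModel construct a model from its pieces
#' @param response,intercept,coefficients,window,stats see slots
#' @export
linearQsarModel <- function(response, intercept, coefficients,
                            window = c(NA_real_, NA_real_),
                            stats = numeric()) {
  new("LinearQsarModel", response = response, intercept = as.numeric(intercept),
      coefficients = coefficients, window = as.numeric(window), stats = stats)
}

setMethod("show", "LinearQsarModel", function(object) {
  terms <- paste(sprintf("%+g*%s", object@coefficients,
                         names(object@coefficients)), collapse = " ")
  cat(sprintf("LinearQsarModel: %s = %g %s\n", object@response,
              object@intercept, terms))
  if (!any(is.na(object@window))) {
    cat(sprintf("  applicability window: (%g, %g)\n",
                object@window[1], object@window[2]))
  }
  if (length(object@stats)) {
    cat("  stats:", paste(sprintf("%s=%g", names(object@stats), object@stats),
                          collapse = ", "), "\n")
  }
})
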