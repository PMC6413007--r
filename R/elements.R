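# Element data entering the Kier-Hall valence-degree model and the
# mass-weighted Burden matrix. Zv is the valence-electron count, L the
# principal quantum number of the valence shell, mass the relative atomic
# mass (u). Default valences drive implicit-hydrogen assignment for
# organic-subset SMILES atoms.

.ELEMENTS <- data.frame(
  symbol = c("H", "B",  "C",  "N",  "O",  "F",  "Si", "P",  "S",  "Cl", "Br", "I"),
  Z      = c(1,   5,    6,    7,    8,    9,    14,   15,   16,   17,   35,   53),
  Zv     = c(1,   3,    4,    5,    6,    7,    4,    5,    6,    7,    7,    7),
  L      = c(1,   2,    2,    2,    2,    2,    3,    3,    3,    3,    4,    5),
  mass   = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998, 28.085, 30.974,
             32.06, 35.45, 79.904, 126.904),
  stringsAsFactors = FALSE
)

.DEFAULT_VALENCES <- list(B = 3, C = 4, N = c(3, 5), O = 2, F = 1, Si = 4,
                          P = c(3, 5), S = c(2, 4, 6), Cl = 1, Br = 1, I = 1)

#' Element lookup table
#'
#' Returns the table of supported elements with atomic number `Z`,
#' valence-electron count `Zv`, principal quantum number `L` and relative
#' atomic mass, i.e. the quantities entering the valence degree
#' \eqn{\delta^v} and mass-weighted descriptors.
#'
#' @return data.frame with columns `symbol`, `Z`, `Zv`, `L`, `mass`.
#' @export
elementTable <- function() .ELEMENTS

elementInfo <- function(symbol) {
  i <- match(symbol, .ELEMENTS$symbol)
  if (anyNA(i)) {
    stop("unsupported element(s): ",
         paste(unique(symbol[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  .ELEMENTS[i, , drop = FALSE]
}

# Kier-Hall valence degree: Zv - h for second-period atoms,
# (Zv - h) / (Z - Zv - 1) beyond the second period. Charged or isotopic
# atoms use the neutral-element Zv (callers warn at parse time).
kierHallDeltaV <- function(symbol, hcount) {
  info <- elementInfo(symbol)
  ifelse(info$L <= 2, info$Zv - hcount,
         (info$Zv - hcount) / (info$Z - info$Zv - 1))
}
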