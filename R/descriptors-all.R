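# Convention toggles and the per-molecule descriptor driver.

#' Descriptor convention toggles
#'
#' Two descriptor families admit more than one published convention; both
#' are first-class switches so any screening count can be reproduced under
#' either orientation, and every run records the conventions in effect.
#'
#' * `chiQuotient`: orientation of the quotient combination C of simple and
#'   valence connectivity indices. Default `"simple_over_valence"`
#'   (\eqn{C = \chi/\chi^v}); the alternative is `"valence_over_simple"`.
#'   Neither orientation is fixed by the published models, which is why this
#'   is a first-class toggle (see the methods vignette).
#' * `chiDifference`: orientation of the difference combination D. Default
#'   `"simple_minus_valence"` (\eqn{D = \chi - \chi^v}).
#' * `burdenAromatic`: `"perceive"` (default) weights bonds of benzenoid
#'   rings 1.5 in the Burden matrix even when the input was written in
#'   Kekulé form; `"as_input"` uses the bond orders as written.
#'
#' @param chiQuotient,chiDifference,burdenAromatic see above.
#' @return a list of class `"topoConventions"`.
#' @export
topoConventions <- function(chiQuotient = c("simple_over_valence",
                                            "valence_over_simple"),
                            chiDifference = c("simple_minus_valence",
                                              "valence_minus_simple"),
                            burdenAromatic = c("perceive", "as_input")) {
  out <- list(chiQuotient = match.arg(chiQuotient),
              chiDifference = match.arg(chiDifference),
              burdenAromatic = match.arg(burdenAromatic))
  class(out) <- "topoConventions"
  out
}

#' @export
format.topoConventions <- function(x, ...) {
  paste(sprintf("%s=%s", names(x), unlist(x)), collapse = ", ")
}

#' @export
print.topoConventions <- function(x, ...) {
  cat("descriptor conventions:", format(x), "\n")
  invisible(x)
}

.CHI_NAMES <- c("chi0", "chi1", "chi2", "chi3p", "chi3c", "chi4p", "chi4c",
                "chi4pc")
.CHI_SPEC <- data.frame(
  name = .CHI_NAMES,
  order = c(0, 1, 2, 3, 3, 4, 4, 4),
  kind = c("path", "path", "path", "path", "cluster", "path", "cluster",
           "path_cluster"),
  stringsAsFactors = FALSE
)

#' Compute descriptor families for molecules
#'
#' Evaluates the requested descriptor families on each molecule and returns
#' one row per successfully processed molecule; failures are collected (not
#' fatal) and reported in the `rejects` attribute, mirroring the
#' "unprocessed molecules" sheet of the descriptor table output.
#'
#' Families:
#' * `"chi"`: connectivity indices of orders 0-4 (path, cluster,
#'   path-cluster subtypes), their valence variants (`*v` suffix) and the
#'   quotient/difference combinations (`C*`/`D*` prefixes).
#' * `"charge"`: Galvez charge indices `G1..G10`, `J1..J10` (`GGI10` = `G10`).
#' * `"wiener"`: `W`.
#' * `"constitutional"`: atom/bond/degree/ring/element counts (incl. `V4`).
#' * `"ext"`: `ww`, `MAXDN`, `BELm5`, `VEA1`.
#'
#' @param mols a list of [MolGraph-class] objects (or a single one).
#' @param families character subset of
#'   `c("chi", "charge", "wiener", "constitutional", "ext")`.
#' @param conventions a [topoConventions()] object.
#' @param maxBlock detour tractability guard, see [detourMatrix()].
#' @return data.frame with column `id` then descriptor columns in a fixed
#'   documented order; attributes `rejects` (data.frame id/reason) and
#'   `conventions`.
#' @export
computeDescriptors <- function(mols,
                               families = c("chi", "charge", "wiener",
                                            "constitutional", "ext"),
                               conventions = topoConventions(),
                               maxBlock = 30) {
  if (is(mols, "MolGraph")) mols <- list(mols)
  families <- match.arg(families, several.ok = TRUE)
  rows <- vector("list", length(mols))
  ids <- character(length(mols))
  rejIds <- character(); rejWhy <- character()
  for (k in seq_along(mols)) {
    g <- mols[[k]]
    ids[k] <- if (is.na(g@id)) as.character(k) else g@id
    row <- tryCatch(descriptorRow(g, families, conventions, maxBlock),
                    error = function(e) structure(conditionMessage(e),
                                                  class = "descriptorFault"))
    if (inherits(row, "descriptorFault")) {
      rejIds <- c(rejIds, ids[k]); rejWhy <- c(rejWhy, unclass(row))
    } else {
      rows[[k]] <- row
    }
  }
  keep <- !vapply(rows, is.null, logical(1))
  out <- if (any(keep)) {
    mat <- do.call(rbind, rows[keep])
    cbind(data.frame(id = ids[keep], stringsAsFactors = FALSE),
          as.data.frame(mat))
  } else {
    data.frame(id = character())
  }
  rownames(out) <- NULL
  attr(out, "rejects") <- data.frame(id = rejIds, reason = rejWhy,
                                     stringsAsFactors = FALSE)
  attr(out, "conventions") <- conventions
  out
}

descriptorRow <- function(g, families, conventions, maxBlock) {
  assertNoMarkers(g)
  out <- numeric(0)
  if ("chi" %in% families) {
    cen <- chiCensus(g, maxOrder = 4)
    idx <- cbind(.CHI_SPEC$order + 1L, .KIND_COL[.CHI_SPEC$kind])
    s <- cen$chiS[idx]; v <- cen$chiV[idx]
    cd <- combineChi(s, v, conventions)
    out <- c(out,
             stats::setNames(s, .CHI_NAMES),
             stats::setNames(v, paste0(.CHI_NAMES, "v")),
             stats::setNames(cd[seq_along(s)], paste0("C", .CHI_NAMES)),
             stats::setNames(cd[length(s) + seq_along(s)],
                             paste0("D", .CHI_NAMES)))
  }
  if ("charge" %in% families) out <- c(out, chargeIndices(g, 10))
  if ("wiener" %in% families) out <- c(out, W = wienerIndex(g))
  if ("constitutional" %in% families) out <- c(out, constitutionalIndices(g))
  if ("ext" %in% families) {
    out <- c(out, ww = hyperDetour(g, maxBlock = maxBlock), MAXDN = maxdn(g),
             BELm5 = belm(g, 5, conventions), VEA1 = vea1(g))
  }
  out
}
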