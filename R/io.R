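# Molecule file readers and the two-part descriptor table writer.

#' Read molecules from .smi, .mol or .sdf files
#'
#' `.smi` is whitespace-separated "SMILES name" with `#` comments and blank
#' lines ignored; `.mol`/`.sdf` parsing is delegated to ChemmineR and the
#' atom/bond blocks converted to [MolGraph-class] (explicit hydrogens are
#' folded into the heavy-atom counts). Per-record failures are collected,
#' not fatal.
#'
#' @param path input file.
#' @param format `"smi"`, `"mol"` or `"sdf"`; default guessed from the file
#'   extension.
#' @return list of [MolGraph-class] objects, with attribute `rejects`
#'   (data.frame: record, id, reason).
#' @export
readMolecules <- function(path, format = c("auto", "smi", "mol", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = "smi", mol = "mol", sdf = "sdf",
                     stop("cannot guess format from extension '", ext, "'",
                          call. = FALSE))
  }
  if (format == "smi") readSmi(path) else readSdfLike(path, format)
}

readSmi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mols <- list()
  rec <- integer(); rid <- character(); why <- character()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "[ \t]+")[[1]]
    id <- if (length(parts) > 1) parts[2] else NA_character_
    g <- tryCatch(parseSmiles(parts[1], id = id), error = function(e) {
      rec <<- c(rec, k); rid <<- c(rid, ifelse(is.na(id), "", id))
      why <<- c(why, conditionMessage(e))
      NULL
    })
    if (!is.null(g)) mols[[length(mols) + 1]] <- g
  }
  attr(mols, "rejects") <- data.frame(record = rec, id = rid, reason = why,
                                      stringsAsFactors = FALSE)
  mols
}

readSdfLike <- function(path, format) {
  sdf <- ChemmineR::read.SDFset(path)
  mols <- list()
  rec <- integer(); rid <- character(); why <- character()
  ids <- ChemmineR::sdfid(sdf)
  for (k in seq_along(sdf)) {
    g <- tryCatch(sdfToMolGraph(sdf[[k]], id = ids[k]), error = function(e) {
      rec <<- c(rec, k); rid <<- c(rid, ids[k])
      why <<- c(why, conditionMessage(e))
      NULL
    })
    if (!is.null(g)) mols[[length(mols) + 1]] <- g
  }
  attr(mols, "rejects") <- data.frame(record = rec, id = rid, reason = why,
                                      stringsAsFactors = FALSE)
  mols
}

# Convert one ChemmineR SDF record into a hydrogen-suppressed MolGraph.
sdfToMolGraph <- function(sdf, id = NA_character_) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  symbols <- gsub("_.*$", "", rownames(ab))
  n <- length(symbols)
  bi <- as.integer(bb[, 1]); bj <- as.integer(bb[, 2])
  bo <- as.integer(bb[, 3])
  # Molfile aromatic bond type 4 -> aromatic flag, order 1
  arom <- bo == 4
  bo[arom] <- 1L
  atoms <- data.frame(symbol = symbols, aromatic = FALSE,
                      hcount = NA_integer_, charge = 0L,
                      isotope = NA_integer_, anchor = NA_character_,
                      hexplicit = FALSE, stringsAsFactors = FALSE)
  # restore aromatic atom flags from aromatic bonds
  atoms$aromatic[unique(c(bi[arom], bj[arom]))] <- TRUE
  bonds <- data.frame(i = pmin(bi, bj), j = pmax(bi, bj), order = bo,
                      aromatic = arom)
  buildMolGraph(NA_character_, id, atoms, bonds)
}

#' Write the two-part descriptor table
#'
#' Mirrors a two-sheet spreadsheet as a pair of delimited files: the values
#' part holds one row per processed molecule (id, then descriptor columns in
#' a fixed order); the metadata part holds the run information (input,
#' convention toggles, timestamp) followed by the unprocessed molecules with
#' their fault reasons. Column order is identical across runs with
#' identical configuration.
#'
#' @param descriptors data.frame from [computeDescriptors()] (its `rejects`
#'   and `conventions` attributes are used when present).
#' @param path base output path: `<path>_values.csv` and `<path>_meta.csv`
#'   are written (tab-separated with `format = "tsv"`).
#' @param format `"csv"` (default) or `"tsv"`.
#' @param input label of the input file for the metadata part.
#' @param rejects optional explicit rejects data.frame (id, reason).
#' @return invisibly, the two paths written.
#' @export
writeDescriptorTable <- function(descriptors, path, format = c("csv", "tsv"),
                                 input = NA_character_, rejects = NULL) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  ext <- format
  pValues <- paste0(path, "_values.", ext)
  pMeta <- paste0(path, "_meta.", ext)
  utils::write.table(descriptors, pValues, sep = sep, row.names = FALSE,
                     quote = FALSE)
  if (is.null(rejects)) rejects <- attr(descriptors, "rejects")
  if (is.null(rejects)) rejects <- data.frame(id = character(),
                                              reason = character())
  conv <- attr(descriptors, "conventions")
  meta <- data.frame(
    key = c("input", "n_processed", "n_unprocessed", "conventions",
            "timestamp"),
    value = c(ifelse(is.na(input), "", input), nrow(descriptors),
              nrow(rejects), if (!is.null(conv)) format(conv) else "default",
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    stringsAsFactors = FALSE)
  con <- file(pMeta, "w")
  on.exit(close(con))
  utils::write.table(meta, con, sep = sep, row.names = FALSE, quote = FALSE)
  writeLines("", con)
  writeLines(paste("unprocessed", "reason", sep = sep), con)
  if (nrow(rejects)) {
    utils::write.table(rejects, con, sep = sep, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(c(values = pValues, meta = pMeta))
}
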