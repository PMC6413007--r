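# Evaluation of linear QSAR models, the applicability-domain classifier and
# the full screening cascade.

#' Evaluate a linear QSAR model on descriptor rows
#'
#' Computes `intercept + sum(coef * descriptor)` per row. Every model term
#' must resolve to a present, defined descriptor column.
#'
#' @param model a [LinearQsarModel-class].
#' @param descriptors a data.frame of descriptors (one row per molecule) or
#'   a named numeric vector for a single molecule.
#' @return numeric vector of model values.
#' @export
evalModel <- function(model, descriptors) {
  if (is.numeric(descriptors)) {
    descriptors <- as.data.frame(as.list(descriptors))
  }
  terms <- names(model@coefficients)
  missing <- setdiff(terms, names(descriptors))
  if (length(missing)) {
    stop("descriptor(s) missing for model term(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(descriptors[, terms, drop = FALSE])
  if (anyNA(X)) {
    bad <- terms[apply(is.na(X), 2, any)]
    stop("undefined descriptor value(s) for model term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  as.numeric(model@intercept + X %*% model@coefficients[terms])
}

#' Classify a discriminant score against the applicability window
#'
#' Partitions the real line: `active` for 0 < DF < 8, `inactive` for
#' -8 <= DF <= 0, `unclassified` for DF >= 8 or DF < -8 (outside the domain
#' of applicability). The window bounds come from the model's domain window
#' when supplied.
#'
#' @param df numeric vector of discriminant scores.
#' @param window numeric `(low, high)` applicability window (default `c(0, 8)`).
#' @return character vector in `{"active", "inactive", "unclassified"}`.
#' @export
classifyDF <- function(df, window = c(0, 8)) {
  low <- window[1]; high <- window[2]
  ifelse(df > low & df < high, "active",
         ifelse(df >= -high & df <= low, "inactive", "unclassified"))
}

#' Model-posterior activity probability (convention)
#'
#' The activity probability attached to a discriminant score is nowhere
#' defined by the printed models; this package computes the logistic
#' transform of the score, `1/(1 + exp(-DF))`, i.e. the standard two-class
#' discriminant posterior with the prior log-odds absorbed into the score.
#' It is labelled "model-posterior (convention)" in all outputs.
#'
#' @param df numeric vector of discriminant scores.
#' @return numeric vector of probabilities.
#' @export
probActive <- function(df) stats::plogis(df)

#' Screen a molecule library through the two-model cascade
#'
#' Applies the discriminant model to every molecule, classifies each score
#' against the applicability window, predicts the affinity response for the
#' predicted actives only, and tiers actives by the activity thresholds
#' (strict inequalities): `high` below `thresholds[2]` (default 1.0, i.e.
#' below 10 nM), `moderate` below `thresholds[1]` (default 2.60, 400 nM),
#' else `none`.
#'
#' @param x a list of [MolGraph-class] objects, or a precomputed descriptor
#'   data.frame containing every term of both models.
#' @param modelDf discriminant [LinearQsarModel-class] (window used for
#'   classification when present).
#' @param modelLogki affinity [LinearQsarModel-class], evaluated on actives.
#' @param thresholds numeric `(moderate, high)` cuts on the predicted
#'   response, default `c(2.60, 1.0)`.
#' @param conventions a [topoConventions()] object (used when descriptors
#'   are computed here).
#' @param maxBlock detour guard, see [detourMatrix()].
#' @return list with `records` (data.frame: id, smiles, DF, probA, class,
#'   logKi, tier), `summary` (named counts: nTotal, nActive, nModerate =
#'   response < first threshold, nHigh = response < second threshold) and
#'   `rejects` (molecules whose descriptors failed, with reasons).
#' @export
screenLibrary <- function(x, modelDf, modelLogki,
                          thresholds = c(2.60, 1.0),
                          conventions = topoConventions(), maxBlock = 30) {
  rejects <- data.frame(id = character(), reason = character())
  smiles <- NULL
  if (is.data.frame(x)) {
    desc <- x
    if (is.null(desc$id)) desc$id <- as.character(seq_len(nrow(desc)))
    smiles <- if (!is.null(desc$smiles)) desc$smiles else rep(NA_character_, nrow(desc))
  } else {
    if (is(x, "MolGraph")) x <- list(x)
    famDf <- c("chi", "wiener", "constitutional")
    famKi <- c("charge", "ext")
    desc <- computeDescriptors(x, families = c(famDf, famKi),
                               conventions = conventions, maxBlock = maxBlock)
    rejects <- attr(desc, "rejects")
    smiles <- vapply(x, function(g) g@smiles, character(1))[
      match(desc$id, vapply(x, molId, character(1)))]
  }
  window <- if (!any(is.na(modelDf@window))) modelDf@window else c(0, 8)
  df <- evalModel(modelDf, desc)
  cls <- classifyDF(df, window)
  logki <- rep(NA_real_, nrow(desc))
  act <- cls == "active"
  if (any(act)) logki[act] <- evalModel(modelLogki, desc[act, , drop = FALSE])
  tier <- rep(NA_character_, nrow(desc))
  tier[act] <- ifelse(logki[act] < thresholds[2], "high",
                      ifelse(logki[act] < thresholds[1], "moderate", "none"))
  records <- data.frame(id = desc$id, smiles = smiles, DF = df,
                        probA = probActive(df), class = cls, logKi = logki,
                        tier = tier, stringsAsFactors = FALSE)
  summary <- c(nTotal = nrow(desc) + nrow(rejects), nActive = sum(act),
               nModerate = sum(act & logki < thresholds[1], na.rm = TRUE),
               nHigh = sum(act & logki < thresholds[2], na.rm = TRUE))
  list(records = records, summary = summary, rejects = rejects)
}

#' Classification metrics from true and predicted labels
#'
#' Sensitivity = percentage of actives correctly classified, specificity =
#' percentage of inactives correctly classified, accuracy = percentage of
#' all cases correctly classified. An empty class yields `NA` for its
#' metric (undefined marker).
#'
#' @param truth,predicted vectors of binary labels (same length); the
#'   "active" level is `active`.
#' @param activeLabel the label counted as active (default `"active"`).
#' @return named numeric vector `c(sensitivity, specificity, accuracy)` in
#'   percent.
#' @export
classMetrics <- function(truth, predicted, activeLabel = "active") {
  stopifnot(length(truth) == length(predicted))
  isA <- truth == activeLabel
  sens <- if (any(isA)) 100 * mean(predicted[isA] == truth[isA]) else NA_real_
  spec <- if (any(!isA)) 100 * mean(predicted[!isA] == truth[!isA]) else NA_real_
  acc <- if (length(truth)) 100 * mean(predicted == truth) else NA_real_
  c(sensitivity = sens, specificity = spec, accuracy = acc)
}

#' Pharmacological distribution diagram
#'
#' Bins discriminant scores and reports, per bin, the expectancy of activity
#' \eqn{E_a = a/(i+1)} and of inactivity \eqn{E_i = i/(a+1)}, where a and i
#' are the fractions of all actives (resp. inactives) falling in the bin.
#' The within-bin fractions sum to 1 over the diagram for each class.
#'
#' @param df numeric discriminant scores.
#' @param truth labels parallel to `df`.
#' @param binWidth bin width in score units (default 1).
#' @param activeLabel label counted as active.
#' @return data.frame with `low`, `high`, `nActive`, `nInactive`, `Ea`, `Ei`;
#'   empty when either class total is zero.
#' @export
pdd <- function(df, truth, binWidth = 1, activeLabel = "active") {
  isA <- truth == activeLabel
  nA <- sum(isA); nI <- sum(!isA)
  if (nA == 0 || nI == 0) {
    return(data.frame(low = numeric(), high = numeric(), nActive = integer(),
                      nInactive = integer(), Ea = numeric(), Ei = numeric()))
  }
  lo <- floor(min(df) / binWidth) * binWidth
  hi <- ceiling(max(df) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  breaks <- seq(lo, hi, by = binWidth)
  bin <- cut(df, breaks, include.lowest = TRUE, right = FALSE)
  tab <- table(bin, factor(ifelse(isA, "A", "I"), levels = c("A", "I")))
  a <- tab[, "A"] / nA
  i <- tab[, "I"] / nI
  data.frame(low = breaks[-length(breaks)], high = breaks[-1],
             nActive = as.integer(tab[, "A"]), nInactive = as.integer(tab[, "I"]),
             Ea = as.numeric(a / (i + 1)), Ei = as.numeric(i / (a + 1)),
             row.names = NULL)
}

#' Read / write linear QSAR model files
#'
#' Structured-text (YAML) model files: `response`, `intercept`, named
#' `coefficients`, optional `window` and `stats`.
#'
#' @param path file path.
#' @return a [LinearQsarModel-class].
#' @export
readQsarModel <- function(path) {
  y <- yaml::read_yaml(path)
  linearQsarModel(response = y$response %||% "y",
                  intercept = y$intercept,
                  coefficients = unlist(y$coefficients),
                  window = if (!is.null(y$window)) as.numeric(y$window)
                           else c(NA_real_, NA_real_),
                  stats = if (!is.null(y$stats)) unlist(y$stats) else numeric())
}

#' @rdname readQsarModel
#' @param model a [LinearQsarModel-class] to serialise.
#' @export
writeQsarModel <- function(model, path) {
  y <- list(response = model@response, intercept = model@intercept,
            coefficients = as.list(model@coefficients))
  if (!any(is.na(model@window))) y$window <- model@window
  if (length(model@stats)) y$stats <- as.list(model@stats)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged FPR screening models and library definition
#'
#' `fprDiscriminantModel()` and `fprAffinityModel()` load the two packaged
#' linear models (the discriminant with its (0, 8) applicability window and
#' the affinity regression). `fprLibrarySpec()` loads the packaged
#' dioxopiperazine library definition: the synthetic scaffold transcription
#' plus the four printed substituent lists (5, 8, 9 and 17 fragments), with
#' the documented structural repairs applied.
#'
#' @return a [LinearQsarModel-class] or [LibrarySpec-class].
#' @export
fprDiscriminantModel <- function() {
  readQsarModel(system.file("extdata", "model_fpr_discriminant.yaml",
                            package = "MolTopo", mustWork = TRUE))
}

#' @rdname fprDiscriminantModel
#' @export
fprAffinityModel <- function() {
  readQsarModel(system.file("extdata", "model_fpr_logki.yaml",
                            package = "MolTopo", mustWork = TRUE))
}

#' @rdname fprDiscriminantModel
#' @param repairs apply the documented fragment repairs (default TRUE; with
#'   FALSE the spec is returned unrepaired and will fail validation for the
#'   fragments that are unusable as printed).
#' @export
fprLibrarySpec <- function(repairs = TRUE) {
  subsFile <- system.file("extdata", "fpr_substituents.yaml",
                          package = "MolTopo", mustWork = TRUE)
  scafFile <- system.file("extdata", "fpr_scaffold_synthetic.yaml",
                          package = "MolTopo", mustWork = TRUE)
  readLibrarySpec(subsFile, scafFile, repairs = repairs)
}

#' Read a library definition from config files
#'
#' The substituent file holds `anchors`, per-anchor `substituents`
#' (code/name/smiles rows) and an optional `repairs` block; the scaffold
#' file (or the same file) holds `scaffold: {smiles, anchors}`.
#'
#' @param substituentsPath YAML file with the substituent lists.
#' @param scaffoldPath YAML file with the scaffold (defaults to the
#'   substituent file).
#' @param repairs apply the `repairs` block (default TRUE).
#' @return a [LibrarySpec-class]; applied repairs are reported via message().
#' @export
readLibrarySpec <- function(substituentsPath, scaffoldPath = substituentsPath,
                            repairs = TRUE) {
  ys <- yaml::read_yaml(substituentsPath)
  yc <- yaml::read_yaml(scaffoldPath)
  if (is.null(yc$scaffold$smiles)) stop("no scaffold SMILES in config", call. = FALSE)
  lists <- lapply(ys$substituents, function(rows) {
    data.frame(code = vapply(rows, `[[`, "", "code"),
               name = vapply(rows, `[[`, "", "name"),
               smiles = vapply(rows, `[[`, "", "smiles"),
               stringsAsFactors = FALSE)
  })
  if (repairs && !is.null(ys$repairs)) {
    for (rp in ys$repairs) {
      k <- which(lists[[rp$anchor]]$code == rp$code)
      lists[[rp$anchor]]$smiles[k] <- rp$smiles
      message(sprintf("fragment repair applied: %s/%s '%s' -> '%s'",
                      rp$anchor, rp$code, rp$printed, rp$smiles))
    }
  }
  anchors <- ys$anchors %||% yc$scaffold$anchors
  librarySpec(yc$scaffold$smiles, lists, anchors = anchors)
}
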