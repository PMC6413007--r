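# Generic LDA / MLR machinery with leave-one-out cross-validation and
# response scrambling. The fitted objects are returned as LinearQsarModel so
# they plug directly into evalModel()/screenLibrary().

#' Two-class linear discriminant fit with priors
#'
#' Fits the pooled-covariance linear discriminant for two classes with the
#' supplied priors and returns the discriminant function as a linear model:
#' `DF(x) = w'x + b` with `w = S_pooled^{-1} (m1 - m0)` and
#' `b = -w'(m1 + m0)/2 + ln(p1/p0)`, so `DF > 0` predicts the positive
#' class. Also reports Wilks' lambda, its single-function F transform with
#' `(p, n - p - 1)` degrees of freedom, and the p-value.
#'
#' @param X numeric matrix or data.frame of descriptors (full column rank).
#' @param y binary labels; `positive` names the class scored positively.
#' @param priors numeric length-2 `(p_positive, p_negative)`, summing to 1.
#' @param positive the positive-class label (default the first level or
#'   `"active"` when present).
#' @return list with `model` (a [LinearQsarModel-class] with stats `lambda`,
#'   `F`, `df1`, `df2`, `p`), and `scores` (training DF values).
#' @export
ldaFit <- function(X, y, priors = c(0.5, 0.5), positive = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.character(y)
  lev <- unique(y)
  if (length(lev) != 2) stop("y must have exactly two classes", call. = FALSE)
  if (is.null(positive)) positive <- if ("active" %in% lev) "active" else lev[1]
  neg <- setdiff(lev, positive)
  if (abs(sum(priors) - 1) > 1e-8) stop("priors must sum to 1", call. = FALSE)
  i1 <- y == positive; i0 <- y == neg
  n1 <- sum(i1); n0 <- sum(i0); n <- n1 + n0; p <- ncol(X)
  if (n1 < 2 || n0 < 2) stop("both classes need at least 2 cases", call. = FALSE)
  m1 <- colMeans(X[i1, , drop = FALSE]); m0 <- colMeans(X[i0, , drop = FALSE])
  S1 <- stats::cov(X[i1, , drop = FALSE]); S0 <- stats::cov(X[i0, , drop = FALSE])
  Sw <- ((n1 - 1) * S1 + (n0 - 1) * S0) / (n - 2)
  w <- tryCatch(solve(Sw, m1 - m0), error = function(e) {
    stop("singular within-class scatter; prune collinear descriptors",
         call. = FALSE)
  })
  b <- -sum(w * (m1 + m0)) / 2 + log(priors[1] / priors[2])
  # Wilks' lambda = det(W) / det(T) over the SSCP matrices
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Tm <- crossprod(Xc)
  Wm <- (n1 - 1) * S1 + (n0 - 1) * S0
  lambda <- det(Wm) / det(Tm)
  df1 <- p; df2 <- n - p - 1
  Fstat <- (1 - lambda) / lambda * df2 / df1
  pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  model <- linearQsarModel("DF", b, w,
                           stats = c(lambda = lambda, F = Fstat, df1 = df1,
                                     df2 = df2, p = pval))
  list(model = model, scores = as.numeric(X %*% w + b),
       positive = positive, negative = neg)
}

#' Ordinary least squares fit as a QSAR model
#'
#' @param X numeric matrix or data.frame of descriptors.
#' @param y numeric response.
#' @param response name for the response (default `"y"`).
#' @return list with `model` (a [LinearQsarModel-class] with stats `R2`,
#'   `SEE` (residual standard error), `F`, `p`) and the underlying `fit`
#'   (an `lm` object).
#' @export
mlrFit <- function(X, y, response = "y") {
  X <- as.data.frame(X)
  if (nrow(X) <= ncol(X) + 1) stop("need n > p + 1 observations", call. = FALSE)
  dat <- cbind(X, .y = y)
  fit <- stats::lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(fit))) stop("rank-deficient descriptor matrix", call. = FALSE)
  sm <- summary(fit)
  cf <- stats::coef(fit)
  model <- linearQsarModel(response, cf[1], cf[-1],
                           stats = c(R2 = sm$r.squared, SEE = sm$sigma,
                                     F = unname(sm$fstatistic[1]),
                                     p = unname(stats::pf(sm$fstatistic[1],
                                                          sm$fstatistic[2],
                                                          sm$fstatistic[3],
                                                          lower.tail = FALSE))))
  list(model = model, fit = fit)
}

#' Leave-one-out cross-validated Q2
#'
#' `Q2 = 1 - PRESS / SS_tot`, each prediction coming from a model fit that
#' excludes the predicted case. Computed through the exact OLS hat-matrix
#' identity `e_(i) = e_i / (1 - h_ii)` (verified against the explicit
#' refit-per-case loop in the test suite).
#'
#' @inheritParams mlrFit
#' @return numeric Q2.
#' @export
looQ2 <- function(X, y) {
  X <- as.data.frame(X)
  fit <- stats::lm(y ~ ., data = cbind(X, y = y))
  h <- stats::lm.influence(fit, do.coef = FALSE)$hat
  press <- sum((stats::residuals(fit) / (1 - h))^2)
  1 - press / sum((y - mean(y))^2)
}

#' Response scrambling (Y-randomisation)
#'
#' Randomly permutes the response `nPerm` times, refits the linear model on
#' each permutation and returns the scrambled R-squared distribution; a
#' sound model's true R2 should sit far above it.
#'
#' @inheritParams mlrFit
#' @param nPerm number of permutations.
#' @param seed RNG seed for reproducibility.
#' @return numeric vector of length `nPerm` of scrambled R2 values.
#' @export
yScramble <- function(X, y, nPerm = 100, seed = 1) {
  X <- as.data.frame(X)
  withr::with_seed(seed, {
    vapply(seq_len(nPerm), function(k) {
      ys <- sample(y)
      summary(stats::lm(ys ~ ., data = cbind(X, ys = ys)))$r.squared
    }, numeric(1))
  })
}
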