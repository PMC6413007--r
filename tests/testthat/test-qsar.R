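# Model evaluation, the applicability-domain classifier, screening cascade,
# classification metrics, distribution diagrams, and the LDA/MLR machinery.

test_that("evalModel reproduces the printed intercept arithmetic", {
  mdf <- fprDiscriminantModel()
  mki <- fprAffinityModel()
  zero <- stats::setNames(rep(0, 6), c("Cchi1", "Dchi4pc", "W", "V4", "ww",
                                       "MAXDN"))
  zero <- c(zero, BELm5 = 0, G10 = 0, VEA1 = 0)
  expect_equal(evalModel(mdf, zero), 245.5)
  expect_equal(evalModel(mki, zero), 76.50)
  one <- zero; one["Cchi1"] <- 1
  expect_equal(evalModel(mdf, one), 245.5 - 296.2)
  expect_error(evalModel(mdf, c(Cchi1 = 1)), "missing")
  bad <- as.data.frame(as.list(zero)); bad$W <- NA_real_
  expect_error(evalModel(mdf, bad), "undefined.*W")
})

test_that("classifyDF partitions the real line into the three labels", {
  expect_equal(classifyDF(4.0), "active")
  expect_equal(classifyDF(-3.0), "inactive")
  expect_equal(classifyDF(9.5), "unclassified")
  expect_equal(classifyDF(0), "inactive")        # window open at 0
  expect_equal(classifyDF(8), "unclassified")
  expect_equal(classifyDF(-8), "inactive")
  expect_equal(classifyDF(-8.0001), "unclassified")
  withr::with_seed(2, {
    df <- c(runif(500, -30, 30), -8, 0, 8)
    cls <- classifyDF(df)
    expect_true(all(cls %in% c("active", "inactive", "unclassified")))
    expect_equal(sum(cls == "active") + sum(cls == "inactive") +
                   sum(cls == "unclassified"), length(df))
  })
})

test_that("screenLibrary cascades DF then the affinity model", {
  mdf <- fprDiscriminantModel(); mki <- fprAffinityModel()
  # hand-set descriptors: one molecule with DF = 1 and LogKi = 0.5
  desc <- data.frame(id = "X", Cchi1 = (245.5 - 1) / 296.2, Dchi4pc = 0,
                     W = 0, V4 = 0,
                     ww = 0, MAXDN = 0, BELm5 = (76.5 - 0.5) / 15.68,
                     G10 = 0, VEA1 = 0)
  out <- screenLibrary(desc, mdf, mki)
  expect_equal(unname(out$summary),
               c(1L, 1L, 1L, 1L))
  expect_equal(out$records$class, "active")
  expect_equal(out$records$logKi, 0.5, tolerance = 1e-12)
  expect_equal(out$records$tier, "high")

  # boundary: LogKi exactly 2.60 is excluded by the strict cut
  mki260 <- linearQsarModel("LogKi", 2.60, c(ww = 0))
  out <- screenLibrary(desc, mdf, mki260)
  expect_equal(unname(out$summary["nModerate"]), 0L)
  expect_equal(out$records$tier, "none")

  # inactive molecules never get an affinity prediction
  dneg <- desc; dneg$Cchi1 <- 1
  out <- screenLibrary(dneg, mdf, mki)
  expect_true(is.na(out$records$logKi))
  expect_true(is.na(out$records$tier))
})

test_that("screening summary counts are monotone", {
  mdf <- fprDiscriminantModel(); mki <- fprAffinityModel()
  withr::with_seed(5, {
    desc <- data.frame(id = as.character(1:200),
                       Cchi1 = runif(200, 0.75, 0.9), Dchi4pc = runif(200, -1, 1),
                       W = runif(200, 0, 5000), V4 = sample(0:2, 200, TRUE),
                       ww = runif(200, 0, 3e5), MAXDN = runif(200, 0, 4),
                       BELm5 = runif(200, 3, 6), G10 = runif(200, 0, 2),
                       VEA1 = runif(200, 1, 7))
    out <- screenLibrary(desc, mdf, mki)
    s <- out$summary
    expect_lte(s["nHigh"], s["nModerate"])
    expect_lte(s["nModerate"], s["nActive"])
    expect_lte(s["nActive"], s["nTotal"])
  })
})

test_that("classMetrics matches hand tallies and a confusion oracle", {
  expect_equal(unname(classMetrics(c("active", "inactive"),
                                   c("active", "inactive"))),
               c(100, 100, 100))
  truth <- c("active", rep("inactive", 3))
  pred <- rep("inactive", 4)
  expect_equal(unname(classMetrics(truth, pred)), c(0, 100, 75))
  # undefined marker when a class is empty
  expect_true(is.na(classMetrics(rep("inactive", 3),
                                 rep("inactive", 3))["sensitivity"]))
  withr::with_seed(12, {
    truth <- sample(c("active", "inactive"), 50, TRUE)
    pred <- sample(c("active", "inactive"), 50, TRUE)
    tab <- table(truth, pred)
    m <- classMetrics(truth, pred)
    expect_equal(unname(m["sensitivity"]),
                 100 * tab["active", "active"] / sum(tab["active", ]))
    expect_equal(unname(m["specificity"]),
                 100 * tab["inactive", "inactive"] / sum(tab["inactive", ]))
    expect_equal(unname(m["accuracy"]), 100 * sum(diag(tab)) / 50)
  })
})

test_that("pdd computes expectancies from within-bin class fractions", {
  # one bin holding 40% of actives and 10% of inactives: Ea = .4/1.1
  df <- c(rep(0.5, 4), rep(5.5, 6), rep(0.5, 1), rep(9.5, 9))
  truth <- c(rep("active", 10), rep("inactive", 10))
  tab <- pdd(df, truth, binWidth = 1)
  b0 <- tab[tab$low == 0, ]
  expect_equal(b0$Ea, 0.4 / 1.1, tolerance = 1e-12)
  expect_equal(b0$Ei, 0.1 / 1.4, tolerance = 1e-12)
  # a bin with every active and no inactive: Ea = 1
  tab1 <- pdd(c(rep(0.5, 5), rep(8.5, 5)),
              c(rep("active", 5), rep("inactive", 5)))
  expect_equal(tab1[tab1$low == 0, "Ea"], 1)
  # fractions integrate to 1 per class
  withr::with_seed(3, {
    df <- rnorm(300, 0, 4)
    truth <- sample(c("active", "inactive"), 300, TRUE, prob = c(0.3, 0.7))
    tab <- pdd(df, truth)
    expect_equal(sum(tab$nActive) , sum(truth == "active"))
    expect_equal(sum(tab$nActive / sum(tab$nActive)), 1)
    expect_equal(sum(tab$nInactive / sum(tab$nInactive)), 1)
    # Ea increases with the active fraction at fixed inactive fraction
    zeroI <- tab[tab$nInactive == 0, ]
    expect_equal(order(zeroI$Ea), order(zeroI$nActive))
  })
  expect_equal(nrow(pdd(numeric(0), character(0))), 0)
})

test_that("ldaFit separates constructed clouds and matches MASS::lda", {
  withr::with_seed(42, {
    n <- 100
    X1 <- cbind(rnorm(n, 3), rnorm(n, 3))
    X0 <- cbind(rnorm(n, -3), rnorm(n, -3))
    X <- rbind(X1, X0)
    colnames(X) <- c("d1", "d2")
    y <- c(rep("active", n), rep("inactive", n))
    fit <- ldaFit(X, y, priors = c(0.5, 0.5))
    pred <- ifelse(fit$scores > 0, "active", "inactive")
    expect_equal(mean(pred == y), 1)                   # 100% resubstitution
    expect_lt(fit$model@stats["lambda"], 0.05)
    # agreement with an independent discriminant implementation
    ml <- MASS::lda(X, grouping = factor(y, levels = c("inactive", "active")),
                    prior = c(0.5, 0.5))
    mlPred <- as.character(predict(ml)$class)
    expect_equal(pred, mlPred)
    # scaling direction proportional to ours
    ratio <- unname(fit$model@coefficients / as.numeric(ml$scaling))
    expect_equal(ratio[1], ratio[2], tolerance = 1e-8)
  })
})

test_that("priors shift the decision boundary by the log-odds", {
  withr::with_seed(9, {
    n <- 200
    X <- rbind(cbind(rnorm(n, 2), rnorm(n, 0)),
               cbind(rnorm(n, -2), rnorm(n, 0)))
    colnames(X) <- c("d1", "d2")
    y <- c(rep("active", n), rep("inactive", n))
    f50 <- ldaFit(X, y, priors = c(0.5, 0.5))
    fw <- ldaFit(X, y, priors = c(0.306, 0.694))
    expect_equal(fw$model@coefficients, f50$model@coefficients)
    expect_equal(fw$model@intercept - f50$model@intercept,
                 log(0.306 / 0.694), tolerance = 1e-10)
    # equal priors on symmetric data: boundary at the midpoint of the means
    m1 <- colMeans(X[y == "active", ]); m0 <- colMeans(X[y == "inactive", ])
    mid <- (m1 + m0) / 2
    expect_equal(sum(f50$model@coefficients * mid) + f50$model@intercept, 0,
                 tolerance = 1e-10)
  })
})

test_that("lda/mlr recover generating coefficients on clean data", {
  # mlr: exact linear data, noise-free
  withr::with_seed(31, {
    X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
    beta <- c(2, -1.5, 0.25)
    y <- 3 + X %*% beta
    fit <- suppressWarnings(mlrFit(X, as.numeric(y)))  # perfect-fit warning
    expect_equal(unname(fit$model@intercept), 3, tolerance = 1e-6)
    expect_equal(unname(fit$model@coefficients), beta, tolerance = 1e-6)
    expect_equal(unname(fit$model@stats["R2"]), 1, tolerance = 1e-9)
    expect_equal(looQ2(X, as.numeric(y)), 1, tolerance = 1e-9)
  })
  # lda: data with exactly known class moments recovers Sw^-1 (m1 - m0)
  withr::with_seed(17, {
    E <- scale(matrix(rnorm(50 * 2), 50, 2))  # exact mean 0
    E <- E %*% solve(chol(cov(E)))            # exact identity covariance
    mu1 <- c(1, 2); mu0 <- c(-1, 0)
    X <- rbind(sweep(E, 2, mu1, "+"), sweep(E, 2, mu0, "+"))
    colnames(X) <- c("a", "b")
    y <- c(rep("active", 50), rep("inactive", 50))
    fit <- ldaFit(X, y, priors = c(0.5, 0.5))
    expect_equal(unname(fit$model@coefficients), mu1 - mu0, tolerance = 1e-6)
  })
})

test_that("looQ2 equals the explicit refit loop and stays below R2", {
  withr::with_seed(23, {
    X <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("a", "b")))
    y <- 1 + X %*% c(1, -2) + rnorm(30, sd = 0.5)
    y <- as.numeric(y)
    q2 <- looQ2(X, y)
    press <- 0
    for (i in seq_len(30)) {
      fit <- stats::lm(y ~ ., data = data.frame(X, y = y)[-i, ])
      pred <- predict(fit, newdata = data.frame(X)[i, , drop = FALSE])
      press <- press + (y[i] - pred)^2
    }
    expect_equal(q2, unname(1 - press / sum((y - mean(y))^2)),
                 tolerance = 1e-10)
  })
  # Q2 <= R2 across seeded noisy linear datasets
  for (s in 1:20) {
    withr::with_seed(1000 + s, {
      X <- matrix(rnorm(25 * 3), 25, 3, dimnames = list(NULL, c("a", "b", "c")))
      y <- as.numeric(X %*% c(1, 0.5, -1) + rnorm(25))
      r2 <- summary(stats::lm(y ~ ., data = data.frame(X, y = y)))$r.squared
      expect_lte(looQ2(X, y), r2 + 1e-12)
    })
  }
})

test_that("y-scrambling on pure noise matches the null expectation", {
  withr::with_seed(55, {
    n <- 50; p <- 5
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    r2s <- yScramble(X, y, nPerm = 100, seed = 7)
    expect_length(r2s, 100)
    # null R2 has mean p/(n-1); allow a generous simulation band
    expect_lt(abs(mean(r2s) - p / (n - 1)), 0.05)
    # the true fit on noise sits inside the scrambled distribution
    trueR2 <- summary(stats::lm(y ~ ., data = data.frame(X, y = y)))$r.squared
    expect_gt(mean(r2s >= trueR2 - 1e-12), 0.01)
    # reproducible from seed
    expect_identical(r2s, yScramble(X, y, nPerm = 100, seed = 7))
  })
})

test_that("model round-trips through the structured text format", {
  m <- linearQsarModel("DF", 1.5, c(a = 2, b = -0.25), window = c(0, 8),
                       stats = c(R2 = 0.9))
  tmp <- tempfile(fileext = ".yaml")
  writeQsarModel(m, tmp)
  back <- readQsarModel(tmp)
  expect_equal(back@intercept, m@intercept)
  expect_equal(back@coefficients, m@coefficients)
  expect_equal(back@window, m@window)
  expect_equal(back@response, "DF")
})
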