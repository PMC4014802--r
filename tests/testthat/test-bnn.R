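test_that("log posterior decomposes as hand-computed prior plus likelihood", {
  cfg <- netConfig("as_vs_const", nHidden = 2L, sparsityPrior = 0.9,
                   nSamples = 1L, burnIn = 0L, seed = 1L)
  X <- matrix(c(1, -1, 0.5, 0, 2, -0.5), 3, 2)
  y <- c(1, 0, 1)
  # zero weights: every prediction is 0.5
  s0 <- list(M = matrix(0L, 2, 2), W1 = matrix(0, 2, 2), b1 = c(0, 0),
             W2 = matrix(0, 2, 1), b2 = 0)
  lp <- logPosterior(s0, X, y, cfg)
  expect_equal(lp$logLik, 3 * log(0.5))
  # explicit 3-row arithmetic with one active connection
  s1 <- list(M = matrix(c(1L, 0L, 0L, 0L), 2, 2),
             W1 = matrix(c(0.7, 0, 0, 0), 2, 2), b1 = c(0.1, -0.2),
             W2 = matrix(c(1.5, -0.3), 2, 1), b2 = 0.2)
  h <- tanh(cbind(X %*% (s1$W1 * s1$M)[, 1] + 0.1,
                  X %*% (s1$W1 * s1$M)[, 2] - 0.2))
  p <- 1 / (1 + exp(-(h %*% s1$W2 + 0.2)))
  expLik <- sum(y * log(p) + (1 - y) * log(1 - p))
  expPrior <- log(1 - 0.9) + 3 * log(0.9) + dnorm(0.7, log = TRUE) +
    sum(dnorm(c(0.1, -0.2), log = TRUE)) +
    sum(dnorm(c(1.5, -0.3), log = TRUE)) + dnorm(0.2, log = TRUE)
  lp1 <- logPosterior(s1, X, y, cfg)
  expect_equal(lp1$logLik, expLik)
  expect_equal(lp1$logPrior, expPrior)
  expect_equal(lp1$logPost, expLik + expPrior)
  # duplicating the dataset doubles the likelihood term only
  lp2 <- logPosterior(s1, rbind(X, X), c(y, y), cfg)
  expect_equal(lp2$logLik, 2 * expLik)
  expect_equal(lp2$logPrior, expPrior)
  s1$W1[1, 1] <- Inf
  expect_error(logPosterior(s1, X, y, cfg), "non-finite")
})

test_that("sampling is bit-reproducible under a fixed seed", {
  set.seed(2)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- as.integer(X[, 2] + rnorm(60, 0, 0.5) > 0)
  cfg <- netConfig("as_vs_const", nHidden = 3L, nSamples = 10L,
                   burnIn = 100L, thin = 2L, seed = 77L)
  m1 <- sampleEnsemble(X, y, cfg)
  m2 <- sampleEnsemble(X, y, cfg)
  expect_identical(m1@samples, m2@samples)
  expect_identical(m1@inclusion, m2@inclusion)
})

test_that("the sparsity prior dominates under pure-noise labels", {
  set.seed(3)
  X <- matrix(rnorm(80 * 10), 80, 10)
  y <- rep(c(0L, 1L), 40)
  cfg <- netConfig("as_vs_const", nHidden = 5L, sparsityPrior = 0.9,
                   nSamples = 50L, burnIn = 500L, thin = 2L, seed = 5L)
  m <- sampleEnsemble(X, y, cfg)
  # per-connection inclusion stays near the spike prior (0.1) when the
  # likelihood is flat
  connInclusion <- mean(vapply(m@samples, function(s) mean(s$M), numeric(1)))
  expect_lte(connInclusion, 0.25)
})

test_that("a separating feature attains the top inclusion frequency", {
  set.seed(6)
  n <- 300L
  X <- matrix(rnorm(n * 21), n, 21)
  y <- rep(c(0L, 1L), n / 2)
  X[, 7] <- y * 2 + rnorm(n, 0, 0.3)   # feature 7 separates the classes
  colnames(X) <- paste0("f", 1:21)
  cfg <- netConfig("as_vs_const", nHidden = 5L, nSamples = 60L,
                   burnIn = 600L, thin = 2L, seed = 9L)
  m <- sampleEnsemble(X, y, cfg)
  expect_equal(names(which.max(m@inclusion)), "f7")
  expect_gt(m@inclusion["f7"],
            quantile(m@inclusion[-7], 0.95, names = FALSE) - 1e-12)
})

test_that("degenerate stage-1 labels are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(sampleEnsemble(X, rep(1L, 10),
                              netConfig("as_vs_const", nSamples = 2L,
                                        burnIn = 10L)),
               "both classes")
})

test_that("an all-zero-weight ensemble predicts 0.5 and 1/3", {
  m0 <- zeroEnsemble("as_vs_const")
  expect_equal(predictProba(m0, c(f1 = 1, f2 = -2, f3 = 0.5)), 0.5)
  m0t <- zeroEnsemble("tissue")
  q <- predictProba(m0t, c(f1 = 1, f2 = -2, f3 = 0.5))
  expect_equal(unname(as.vector(q)), rep(1 / 3, 12))
})

test_that("predictions are the arithmetic mean of per-sample outputs", {
  m <- smallStage1()
  prep <- smallPrep()
  fv <- prep$X[1, ]
  full <- predictProba(m, fv)
  per <- vapply(seq_along(m@samples), function(i) {
    mi <- m
    mi@samples <- m@samples[i]
    predictProba(mi, fv)
  }, numeric(1))
  expect_equal(full, mean(per), tolerance = 1e-12)
  # single-sample ensemble equals that network's output
  mOne <- m
  mOne@samples <- m@samples[1]
  expect_equal(predictProba(mOne, fv), per[1])
})

test_that("stage-2 predictions lie on the simplex per tissue group", {
  m2 <- smallStage2()
  prep <- smallPrep()
  q <- predictProba(m2, prep$X[1:20, ])
  for (g in c("CNS", "muscle", "digestive", "embryo")) {
    s <- rowSums(q[, paste0(g, "_", c("inc", "exc", "nc"))])
    expect_true(all(abs(s - 1) < 1e-9))
  }
})

test_that("schema mismatches are reported with the offending features", {
  m <- smallStage1()
  fv <- c(bogus = 1)
  expect_error(predictProba(m, fv), "missing")
})

test_that("robust feature selection respects the threshold", {
  m <- zeroEnsemble(p = 2L, featureNames = c("a", "b"))
  m@inclusion <- c(a = 0.9, b = 0.4)
  expect_equal(robustFeatures(m, 0.5), "a")
  expect_setequal(robustFeatures(m, 0), c("a", "b"))
  expect_equal(length(robustFeatures(m, 1 + 1e-9)), 0L)
})

test_that("serialized ensembles reproduce their predictions exactly", {
  m <- smallStage2()
  prep <- smallPrep()
  path <- withr::local_tempfile(fileext = ".json")
  writeEnsemble(m, path)
  m2 <- readEnsemble(path)
  expect_equal(predictProba(m2, prep$X[1:5, ]),
               predictProba(m, prep$X[1:5, ]))
  expect_equal(m2@inclusion, m@inclusion)
  expect_identical(m2@schema$name, m@schema$name)
})
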