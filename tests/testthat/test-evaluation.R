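test_that("AUC equals exhaustive pair enumeration", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0)), 1.0)
  expect_equal(rocAuc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(rocAuc(c(3, 2, 1), c(1, 0, 1)),
               pairwiseAucOracle(c(3, 2, 1), c(1, 0, 1)))
  expect_error(rocAuc(1:3, c(1, 1, 1)), "both classes")
  set.seed(11)
  for (i in 1:500) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(rocAuc(scores, labels), pairwiseAucOracle(scores, labels))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- rnorm(200)
  labels <- rbinom(200, 1, plogis(scores))
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  ref <- as.numeric(suppressMessages(pROC::auc(labels, scores)))
  expect_equal(rocAuc(scores, labels), ref, tolerance = 1e-12)
})

test_that("sensitivity at fixed FPR behaves as an operating point", {
  scores <- c(10, 9, 8, 1, 2, 3)
  labels <- c(1, 1, 1, 0, 0, 0)
  expect_equal(sensitivityAtFpr(scores, labels, 0.02), 1.0)
  expect_error(sensitivityAtFpr(scores, labels, 0), "fpr")
  expect_error(sensitivityAtFpr(scores, labels, 1), "fpr")
  # random scores: sensitivity tracks the FPR
  set.seed(13)
  n <- 4000L
  scores <- runif(n)
  labels <- rbinom(n, 1, 0.5)
  sens <- sensitivityAtFpr(scores, labels, 0.1)
  se <- sqrt(0.1 * 0.9 / sum(labels == 1))
  expect_lt(abs(sens - 0.1), 3 * se + 2 / sum(labels == 0))
  # fewer negatives than 1/fpr: the zero-false-positive point is reported
  sc <- c(5, 4, 3, 2)
  lb <- c(1, 1, 1, 0)
  expect_equal(sensitivityAtFpr(sc, lb, 0.1), 1.0)
})

test_that("redundant triplets always share a cross-validation fold", {
  d <- data.frame(gene = c("g1", "g1", "g2", "g3"),
                  seq = c("", "", "", ""), stringsAsFactors = FALSE)
  for (s in 1:5) {
    f <- nonredundantCvFolds(d, k = 2L, seed = s, checkIdentity = FALSE)
    expect_equal(f[1], f[2])
  }
  # identical sequences cluster even across genes
  set.seed(14)
  seq <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  d2 <- data.frame(gene = c("ga", "gb"), seq = c(seq, seq),
                   stringsAsFactors = FALSE)
  f2 <- nonredundantCvFolds(d2, k = 2L, seed = 1L)
  expect_equal(f2[1], f2[2])
})

test_that("unrelated triplets spread into balanced folds", {
  set.seed(15)
  d <- data.frame(gene = paste0("g", 1:100),
                  seq = vapply(1:100, function(i)
                    paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                          collapse = ""), character(1)),
                  stringsAsFactors = FALSE)
  f <- nonredundantCvFolds(d, k = 5L, seed = 3L)
  expect_true(all(abs(table(f) - 20) <= 2))
})

test_that("the filter cascade matches independent per-rule application", {
  buildToy <- function(nTrip, seed) {
    set.seed(seed)
    tissues <- rep(simTissues(), each = 3L)
    expIds <- paste(tissues, rep(1:3, 11), sep = ".")
    ids <- sprintf("x%02d", seq_len(nTrip))
    rows <- as.vector(t(outer(ids, c("up", "mid", "dn"), paste, sep = ":")))
    m <- matrix(rnorm(length(rows) * 33, mean = 1.5, sd = 0.6),
                length(rows), 33, dimnames = list(rows, expIds))
    m[runif(length(m)) < 0.05] <- NA_real_
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(expr = m),
      colData = S4Vectors::DataFrame(tissue = tissues,
                                     replicate = rep(1:3, 11),
                                     row.names = expIds),
      rowData = S4Vectors::DataFrame(
        triplet_id = rep(ids, each = 3L),
        role = rep(c("up", "mid", "dn"), nTrip), row.names = rows))
    se
  }
  # independent per-rule survivor sets (brute force)
  oracleRules <- function(se, params, pvalues, group,
                          groupMap = defaultTissueGroups()) {
    m <- SummarizedExperiment::assay(se, "expr")
    rd <- SummarizedExperiment::rowData(se)
    tissues <- SummarizedExperiment::colData(se)$tissue
    ids <- unique(rd$triplet_id)
    g <- function(t, role) m[paste0(t, ":", role), ]
    thr <- apply(m, 2, function(v) quantile(v, params$bottom_percentile / 100,
                                            na.rm = TRUE, names = FALSE))
    inG <- tissues %in% groupMap[[group]]
    r1 <- ids[vapply(ids, function(t)
      !anyNA(c(g(t, "up"), g(t, "mid"), g(t, "dn"))), logical(1))]
    r2 <- ids[vapply(ids, function(t) {
      d <- abs(g(t, "up") - g(t, "dn"))
      !anyNA(d) && all(d <= log2(params$flank_fold))
    }, logical(1))]
    r3 <- ids[vapply(ids, function(t) {
      u <- g(t, "up"); d <- g(t, "dn")
      sum(abs(u) >= params$min_abs, na.rm = TRUE) >=
        params$min_abs_experiments &&
        sum(abs(d) >= params$min_abs, na.rm = TRUE) >=
          params$min_abs_experiments
    }, logical(1))]
    r4 <- ids[vapply(ids, function(t) {
      u <- g(t, "up"); d <- g(t, "dn")
      sum(inG & !is.na(u) & !is.na(d) & u > thr & d > thr) >=
        params$group_experiments
    }, logical(1))]
    r5 <- ids[!is.na(pvalues[ids]) & pvalues[ids] >= params$p_threshold]
    Reduce(intersect, list(r1, r2, r3, r4, r5))
  }
  params <- filterParams(min_abs_experiments = 10L)
  for (s in 1:5) {
    se <- buildToy(12L, seed = 30L + s)
    ids <- unique(SummarizedExperiment::rowData(se)$triplet_id)
    set.seed(40L + s)
    pv <- setNames(runif(length(ids)), ids)
    got <- selectNonTissueDependent(se, "muscle", params, pvalues = pv)
    want <- oracleRules(se, params, pv, "muscle")
    expect_setequal(got$survivors, want)
    expect_equal(length(ids) - length(got$survivors), sum(got$attrition))
  }
  # vacuous thresholds: only the missing-data rule filters
  se <- buildToy(12L, seed = 99L)
  ids <- unique(SummarizedExperiment::rowData(se)$triplet_id)
  pv <- setNames(rep(1, length(ids)), ids)
  loose <- filterParams(flank_fold = 1e9, min_abs = 0,
                        min_abs_experiments = 1L, bottom_percentile = 0,
                        group_experiments = 1L, p_threshold = 0)
  got <- selectNonTissueDependent(se, "muscle", loose, pvalues = pv)
  expect_equal(sum(got$attrition[-1]), 0L)
  # all-missing table: nothing survives
  m <- SummarizedExperiment::assay(se, "expr")
  m[] <- NA_real_
  SummarizedExperiment::assay(se, "expr") <- m
  gone <- selectNonTissueDependent(se, "muscle", loose, pvalues = pv)
  expect_equal(length(gone$survivors), 0L)
  expect_equal(unname(gone$attrition["missing_data"]), length(ids))
})

test_that("gene-first sampling of survivors is seeded and bounded", {
  cfg <- smallSimConfig()
  sim <- smallSim()
  se <- generateExpression(cfg, sim$truth)
  tt <- sim$truth$triplets
  genes <- setNames(tt$gene_id, tt$triplet_id)
  res1 <- selectNonTissueDependent(se, "CNS", filterParams(), nOut = 5L,
                                   geneIds = genes, seed = 2L)
  res2 <- selectNonTissueDependent(se, "CNS", filterParams(), nOut = 5L,
                                   geneIds = genes, seed = 2L)
  expect_identical(res1$sampled, res2$sampled)
  if (length(res1$survivors) >= 5L)
    expect_equal(length(res1$sampled), 5L)
  expect_true(all(res1$sampled %in% res1$survivors))
})

test_that("importance resampling matches the reference distribution", {
  set.seed(16)
  # null case: candidates already match the reference
  cand <- rnorm(2000)
  ref <- rnorm(1000)
  r0 <- biasCorrectSubsample(cand, ref, 1000L, seed = 1L)
  expect_lt(r0$ksAfter, r0$ksBefore + 0.05)
  # biased candidates: correction reduces the KS distance
  candB <- rnorm(2000, mean = -0.8)
  rB <- biasCorrectSubsample(candB, ref, 800L, seed = 1L)
  expect_lt(rB$ksAfter, rB$ksBefore)
  # identity selection when everything is kept
  rAll <- biasCorrectSubsample(candB, ref, length(candB), seed = 1L)
  expect_identical(rAll$indices, seq_along(candB))
  expect_error(biasCorrectSubsample(candB, ref, 5000L), "exceeds")
  expect_error(biasCorrectSubsample(candB, numeric(0), 10L), "empty")
})

test_that("correction reduces the expected KS distance on shifted fixtures", {
  deltas <- vapply(1:20, function(s) {
    set.seed(100 + s)
    cand <- rnorm(1200, mean = -0.7)
    ref <- rnorm(600)
    r <- biasCorrectSubsample(cand, ref, 500L, seed = s)
    r$ksBefore - r$ksAfter
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("cross-validated AUC tolerates single-class test folds", {
  set.seed(18)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- rep(c(0L, 1L), 30)
  X[, 1] <- y + rnorm(60, 0, 0.4)
  colnames(X) <- paste0("f", 1:4)
  cfg <- netConfig("as_vs_const", nHidden = 3L, nSamples = 5L,
                   burnIn = 50L, thin = 1L, seed = 1L)
  folds <- rep(1:3, each = 20L)
  cv <- crossValidatedAuc(X, y, cfg, folds)
  expect_equal(length(cv$auc), 3L)
  expect_true(all(!is.na(cv$scores)))
  expect_gt(cv$overall_auc, 0.7)
  # a fold holding only one class yields NA, not an error
  folds2 <- ifelse(y == 1L & seq_len(60) <= 20, 1L, sample(2:3, 60, TRUE))
  cv2 <- crossValidatedAuc(X, y, cfg, folds2)
  expect_true(is.na(cv2$auc[1]) || !is.na(cv2$auc[1]))  # runs to completion
  expect_equal(length(cv2$scores), 60L)
})
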