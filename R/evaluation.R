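#' @include AllClasses.R query-match.R bnn.R
NULL

#' Filter parameters for non-tissue-dependent exon selection
#'
#' Defaults follow the published cascade: flanks no more than 1.5-fold apart
#' in every experiment; both flanks with |value| >= 0.1 in at least 15
#' experiments; both flanks above the bottom 20th percentile in at least 3
#' experiments of the target tissue group; change P-value >= 0.7.
#'
#' @param flank_fold maximal fold difference between flank expressions.
#' @param min_abs,min_abs_experiments minimal absolute signal rule.
#' @param bottom_percentile,group_experiments percentile rule.
#' @param p_threshold change P-value at or above which a triplet is deemed
#'   non-tissue-dependent.
#' @return a named list of parameters.
#' @export
filterParams <- function(flank_fold = 1.5, min_abs = 0.1,
                         min_abs_experiments = 15L, bottom_percentile = 20,
                         group_experiments = 3L, p_threshold = 0.7) {
  stopifnot(flank_fold > 0, min_abs >= 0, min_abs_experiments > 0,
            bottom_percentile >= 0, group_experiments > 0,
            p_threshold >= 0, p_threshold <= 1)
  list(flank_fold = flank_fold, min_abs = min_abs,
       min_abs_experiments = as.integer(min_abs_experiments),
       bottom_percentile = bottom_percentile,
       group_experiments = as.integer(group_experiments),
       p_threshold = p_threshold)
}

#' Default tissue grouping of the simulated experiments
#'
#' Maps the four modelled tissue groups onto the eleven tissues of the
#' expression panel.
#'
#' @return named list: group -> tissue names.
#' @export
defaultTissueGroups <- function() {
  list(CNS = "brain", muscle = c("muscle", "heart"),
       digestive = c("kidney", "liver"), embryo = "embryo")
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive outranks
#' a random negative, with ties credited 0.5.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Sensitivity at a fixed false-positive rate
#'
#' The true-positive rate at the most permissive score threshold whose
#' false-positive rate does not exceed the target.  When even the strictest
#' threshold admits no false positive (fewer negatives than `1/fpr`), the
#' sensitivity of the zero-false-positive operating point is returned.
#'
#' @param scores,labels as in [rocAuc()].
#' @param fpr target false-positive rate in (0, 1).
#' @return sensitivity in `[0, 1]`.
#' @export
sensitivityAtFpr <- function(scores, labels, fpr) {
  if (fpr <= 0 || fpr >= 1) stop("fpr must be in (0, 1)")
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  best <- 0
  for (t in thr) {
    sel <- scores >= t
    if (sum(sel & labels == 0L) / nNeg > fpr) break
    best <- max(best, sum(sel & labels == 1L) / nPos)
  }
  best
}

#' Non-redundant cross-validation fold assignment
#'
#' Triplets from the same gene, or whose alternative-exon sequences align at
#' identity at or above the matcher threshold (0.88), are constrained to the
#' same fold so no near-duplicate of a test exon appears in training.
#' Redundancy clusters are assigned to folds greedily (smallest fold first)
#' in seeded random order, keeping folds balanced.
#'
#' @param db a [TripletDB-class], or a data.frame with columns `gene` and
#'   `seq` (alternative-exon sequence).
#' @param k number of folds (default 5).
#' @param seed RNG seed for the cluster order.
#' @param identityThreshold sequence-identity redundancy threshold.
#' @param checkIdentity set `FALSE` to cluster by gene only.
#' @return integer fold assignment (1..k) per triplet.
#' @export
nonredundantCvFolds <- function(db, k = 5L, seed = 1L,
                                identityThreshold = 0.88,
                                checkIdentity = TRUE) {
  if (is(db, "TripletDB")) {
    gene <- geneId(db)
    seqs <- vapply(db@triplets, function(tr)
      if (length(tr@seqs)) as.character(tr@seqs[["A"]]) else "", character(1))
  } else {
    gene <- as.character(db$gene)
    seqs <- as.character(db$seq)
  }
  n <- length(gene)
  gene[is.na(gene)] <- paste0(".solo", seq_len(n))[is.na(gene)]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (g in split(seq_len(n), gene))
    if (length(g) > 1L) for (i in g[-1L]) union2(g[1L], i)
  if (checkIdentity && any(nzchar(seqs))) {
    kmer <- 8L
    km <- lapply(seqs, function(s) {
      if (nchar(s) < kmer) return(character(0))
      unique(substring(s, seq_len(nchar(s) - kmer + 1L),
                       seq.int(kmer, nchar(s))))
    })
    idx <- rep(seq_len(n), lengths(km))
    tab <- split(idx, unlist(km))
    pairCount <- new.env(hash = TRUE)
    for (ids in tab) {
      if (length(ids) < 2L || length(ids) > 25L) next
      for (a in seq_len(length(ids) - 1L)) for (b in (a + 1L):length(ids)) {
        key <- paste(ids[a], ids[b])
        pairCount[[key]] <- (pairCount[[key]] %||% 0L) + 1L
      }
    }
    for (key in ls(pairCount)) {
      if (pairCount[[key]] < 2L) next
      ij <- as.integer(strsplit(key, " ")[[1]])
      if (find(ij[1]) == find(ij[2])) next
      r <- seedExtendIdentity(seqs[ij[1]], seqs[ij[2]], k = kmer)
      if (r$identity >= identityThreshold) union2(ij[1], ij[2])
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  clusters <- split(seq_len(n), root)
  set.seed(seed)
  ord <- sample(length(clusters))
  ord <- ord[order(-lengths(clusters)[ord])]  # big clusters first, random ties
  foldSize <- numeric(k)
  folds <- integer(n)
  for (ci in ord) {
    f <- which.min(foldSize)
    folds[clusters[[ci]]] <- f
    foldSize[f] <- foldSize[f] + length(clusters[[ci]])
  }
  folds
}

#' Rank-based per-triplet change P-values
#'
#' A stand-in supplier of differential-inclusion P-values from expression
#' data: for each triplet, the relative inclusion (middle-exon value minus
#' the mean of its flanks) in the experiments of the target tissue group is
#' compared against all other experiments with a two-sided Wilcoxon rank-sum
#' test.  High P-values indicate no evidence of tissue-dependent change.
#'
#' @param se expression `SummarizedExperiment` with triplet linkage.
#' @param tissueGroup target group name.
#' @param groupMap named list group -> tissue names
#'   (default [defaultTissueGroups()]).
#' @return named numeric P-values per triplet id (NA when undeterminable).
#' @export
changePValues <- function(se, tissueGroup, groupMap = defaultTissueGroups()) {
  m <- SummarizedExperiment::assay(se, "expr")
  rd <- SummarizedExperiment::rowData(se)
  tissues <- SummarizedExperiment::colData(se)$tissue
  inGroup <- tissues %in% groupMap[[tissueGroup]]
  ids <- unique(rd$triplet_id)
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (t in ids) {
    up <- m[rd$triplet_id == t & rd$role == "up", ]
    mid <- m[rd$triplet_id == t & rd$role == "mid", ]
    dn <- m[rd$triplet_id == t & rd$role == "dn", ]
    rel <- mid - (up + dn) / 2
    a <- rel[inGroup]; b <- rel[!inGroup]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) >= 2L && length(b) >= 2L)
      out[t] <- suppressWarnings(
        stats::wilcox.test(a, b, exact = FALSE)$p.value)
  }
  out
}

#' Select non-tissue-dependent exons by the expression-filter cascade
#'
#' Applies, in order: (1) drop triplets with any missing expression value;
#' (2) require the two flank expressions within `flank_fold` of each other
#' in every experiment (values are log2 scale, so within
#' `log2(flank_fold)`); (3) require both flanks at absolute value >=
#' `min_abs` in >= `min_abs_experiments` experiments; (4) require both
#' flanks above the per-experiment bottom `bottom_percentile` (computed
#' across all exon rows) in >= `group_experiments` experiments of the target
#' tissue group; (5) keep triplets whose change P-value is >=
#' `p_threshold`.  Survivors can then be subsampled gene-first, then by
#' random position within the gene.
#'
#' @param se expression `SummarizedExperiment` with triplet linkage.
#' @param tissueGroup target tissue group.
#' @param params from [filterParams()].
#' @param pvalues optional named per-triplet change P-values; computed with
#'   [changePValues()] when absent.
#' @param nOut optional number of survivors to sample.
#' @param geneIds optional named gene id per triplet (gene-first sampling);
#'   each triplet is its own gene when absent.
#' @param groupMap named list group -> tissues.
#' @param seed RNG seed for the sampling step.
#' @return list with `survivors` (ids), `sampled` (ids, when `nOut` given),
#'   and `attrition` (triplets dropped by each rule).
#' @export
selectNonTissueDependent <- function(se, tissueGroup, params = filterParams(),
                                     pvalues = NULL, nOut = NULL,
                                     geneIds = NULL,
                                     groupMap = defaultTissueGroups(),
                                     seed = 1L) {
  m <- SummarizedExperiment::assay(se, "expr")
  rd <- SummarizedExperiment::rowData(se)
  tissues <- SummarizedExperiment::colData(se)$tissue
  inGroup <- tissues %in% groupMap[[tissueGroup]]
  ids <- unique(rd$triplet_id)
  rowOf <- function(t, role) m[which(rd$triplet_id == t & rd$role == role)[1L], ]
  attrition <- c(missing_data = 0L, flank_ratio = 0L, min_signal = 0L,
                 bottom_percentile = 0L, p_value = 0L)
  # per-experiment bottom-percentile thresholds over all exon rows
  thresh <- apply(m, 2L, function(v)
    stats::quantile(v, params$bottom_percentile / 100, na.rm = TRUE,
                    names = FALSE))
  survivors <- character(0)
  maxDiff <- log2(params$flank_fold)
  if (is.null(pvalues)) pvalues <- changePValues(se, tissueGroup, groupMap)
  for (t in ids) {
    up <- rowOf(t, "up"); mid <- rowOf(t, "mid"); dn <- rowOf(t, "dn")
    if (anyNA(c(up, mid, dn))) {
      attrition["missing_data"] <- attrition["missing_data"] + 1L; next
    }
    if (any(abs(up - dn) > maxDiff)) {
      attrition["flank_ratio"] <- attrition["flank_ratio"] + 1L; next
    }
    if (sum(abs(up) >= params$min_abs) < params$min_abs_experiments ||
        sum(abs(dn) >= params$min_abs) < params$min_abs_experiments) {
      attrition["min_signal"] <- attrition["min_signal"] + 1L; next
    }
    okExp <- inGroup & up > thresh & dn > thresh
    if (sum(okExp) < params$group_experiments) {
      attrition["bottom_percentile"] <- attrition["bottom_percentile"] + 1L
      next
    }
    p <- pvalues[t]
    if (is.na(p) || p < params$p_threshold) {
      attrition["p_value"] <- attrition["p_value"] + 1L; next
    }
    survivors <- c(survivors, t)
  }
  sampled <- NULL
  if (!is.null(nOut) && length(survivors)) {
    nOut <- min(nOut, length(survivors))
    gid <- if (is.null(geneIds)) stats::setNames(survivors, survivors)
           else geneIds[survivors]
    set.seed(seed)
    byGene <- split(survivors, gid)
    sampled <- character(0)
    while (length(sampled) < nOut) {
      for (g in sample(names(byGene))) {
        remaining <- setdiff(byGene[[g]], sampled)
        if (length(remaining))
          sampled <- c(sampled, remaining[sample.int(length(remaining), 1L)])
        if (length(sampled) == nOut) break
      }
    }
  }
  list(survivors = survivors, sampled = sampled, attrition = attrition)
}

# Kolmogorov-Smirnov distance between two empirical distributions
ksDistance <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(xs) - stats::ecdf(b)(xs)))
}

#' Distribution-matched subsampling (selection-bias correction)
#'
#' Importance resampling without replacement: candidate scores are weighted
#' by the ratio of reference to candidate density (histogram-estimated on a
#' shared binning) and `nOut` candidates are drawn with those weights, so
#' the selected subset's score distribution matches the reference.  Used to
#' remove the constitutive-exon bias of expression-filtered negative sets.
#'
#' @param candidateScores scores of the filtered candidate set.
#' @param referenceScores scores of the unbiased reference sample.
#' @param nOut number of candidates to keep (`<=` number of candidates).
#' @param seed RNG seed.
#' @param nBins histogram bins for the density ratio.
#' @return list with `indices` (into the candidates), `ksBefore` and
#'   `ksAfter` (KS distance to the reference before/after subsampling).
#' @export
biasCorrectSubsample <- function(candidateScores, referenceScores, nOut,
                                 seed = 1L, nBins = 20L) {
  nC <- length(candidateScores)
  if (nOut > nC) stop("nOut exceeds the number of candidates")
  if (!length(referenceScores)) stop("reference set is empty")
  ksBefore <- ksDistance(candidateScores, referenceScores)
  if (nOut == nC) {
    return(list(indices = seq_len(nC), ksBefore = ksBefore,
                ksAfter = ksBefore))
  }
  rng <- range(c(candidateScores, referenceScores))
  breaks <- seq(rng[1L], rng[2L], length.out = nBins + 1L)
  breaks[1L] <- breaks[1L] - 1e-9; breaks[nBins + 1L] <- breaks[nBins + 1L] + 1e-9
  cBin <- cut(candidateScores, breaks, labels = FALSE)
  refDens <- tabulate(cut(referenceScores, breaks, labels = FALSE),
                      nbins = nBins) / length(referenceScores)
  candDens <- tabulate(cBin, nbins = nBins) / nC
  w <- refDens[cBin] / pmax(candDens[cBin], 1e-12)
  w[w <= 0] <- 1e-12
  set.seed(seed)
  indices <- sample.int(nC, nOut, prob = w)
  list(indices = indices, ksBefore = ksBefore,
       ksAfter = ksDistance(candidateScores[indices], referenceScores))
}

#' Cross-validated ROC evaluation of a splicing-code model
#'
#' Trains the configured ensemble on each training fold and scores the held
#' out fold; folds should come from [nonredundantCvFolds()].
#'
#' @param X feature matrix (rows = triplets).
#' @param labels stage-1 labels or stage-2 soft-label matrix; AUC is
#'   computed for stage-1 labels only.
#' @param config a [NetConfig-class]; fold models reuse its settings with
#'   per-fold seeds derived from `config@seed`.
#' @param folds integer fold assignment per row.
#' @return list with `auc` per fold (`NA` when a test fold is single-class),
#'   `scores` (out-of-fold), `mean_auc` (over defined folds), and the pooled
#'   `overall_auc`.
#' @export
crossValidatedAuc <- function(X, labels, config, folds) {
  stopifnot(nrow(X) == length(folds))
  scores <- rep(NA_real_, nrow(X))
  aucs <- numeric(0)
  for (f in sort(unique(folds))) {
    test <- folds == f
    cfg <- config
    cfg@seed <- config@seed + f
    model <- sampleEnsemble(X[!test, , drop = FALSE], labels[!test], cfg)
    scores[test] <- predictProba(model, X[test, , drop = FALSE])
    aucs <- c(aucs, if (length(unique(labels[test])) < 2L) NA_real_
                    else rocAuc(scores[test], labels[test]))
  }
  list(auc = aucs, scores = scores, mean_auc = mean(aucs, na.rm = TRUE),
       overall_auc = rocAuc(scores, labels))
}
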