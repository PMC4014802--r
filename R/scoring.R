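#' @include AllClasses.R bnn.R
NULL

#' Combine the two prediction stages by the chain rule
#'
#' The probability of observing a tissue-dependent change is the product of
#' the stage-1 probability that the exon is alternative and the stage-2
#' conditional change probability:
#' `pChange_t = pAS * (q_inc_t + q_exc_t) = pAS * (1 - q_nc_t)`.
#'
#' @param pAS probability the exon is alternative.
#' @param q soft-label matrix (rows = tissue groups, columns inc/exc/nc) or a
#'   single row from [predictProba()] for a tissue model.
#' @return named per-group change probability.
#' @examples
#' combinedTissueChange(0.8, matrix(c(0.3, 0.2, 0.5), 1,
#'   dimnames = list("CNS", c("inc", "exc", "nc"))))  # 0.40
#' @export
combinedTissueChange <- function(pAS, q) {
  stopifnot(pAS >= 0, pAS <= 1)
  q <- softLabelToMatrix(q)
  stats::setNames(pAS * (1 - q[, "nc"]), rownames(q))
}

# accept a G x 3 matrix (inc/exc/nc columns) or a flat named vector/1-row
# matrix with <group>_inc style names, and return the G x 3 form
softLabelToMatrix <- function(q) {
  if (is.matrix(q) && identical(colnames(q), c("inc", "exc", "nc"))) return(q)
  v <- if (is.matrix(q)) stats::setNames(as.numeric(q[1L, ]), colnames(q))
       else q
  nm <- names(v)
  if (is.null(nm) || !all(grepl("_(inc|exc|nc)$", nm)))
    stop("soft label must have inc/exc/nc structure")
  groups <- unique(sub("_(inc|exc|nc)$", "", nm))
  out <- matrix(NA_real_, length(groups), 3L,
                dimnames = list(groups, c("inc", "exc", "nc")))
  for (g in groups)
    out[g, ] <- v[paste0(g, "_", c("inc", "exc", "nc"))]
  if (anyNA(out)) stop("incomplete soft label: every group needs inc, exc, nc")
  out
}

#' Single-stage tissue-classifier baseline score
#'
#' Scores an exon as alternative using only a tissue-change model: the
#' maximum over tissue groups of the chance of differential splicing
#' `1 - q_nc`.  Serves as the comparison baseline for the two-stage scores.
#'
#' @param q soft label (see [combinedTissueChange()]); all configured groups
#'   must be present.
#' @param groups the required tissue groups.
#' @return a single score in `[0, 1]`.
#' @export
singleStageBaseline <- function(q, groups = c("CNS", "muscle", "digestive",
                                              "embryo")) {
  q <- softLabelToMatrix(q)
  missing <- setdiff(groups, rownames(q))
  if (length(missing))
    stop("missing tissue group(s): ", paste(missing, collapse = ", "))
  max(1 - q[groups, "nc"])
}

#' Two-stage splicing prediction for one exon
#'
#' Runs the stage-1 (alternative vs constitutive) and stage-2 (tissue) models
#' on one feature vector and combines them by the chain rule.
#'
#' @param model1 stage-1 [EnsembleModel-class] (task `as_vs_const`).
#' @param model2 stage-2 [EnsembleModel-class] (task `tissue`).
#' @param fv named feature vector.
#' @return a [SplicingPrediction-class].
#' @export
predictSplicing <- function(model1, model2, fv) {
  pAS <- predictProba(model1, fv)
  q <- softLabelToMatrix(predictProba(model2, fv))
  new("SplicingPrediction", pAS = pAS, q = q,
      pChange = combinedTissueChange(pAS, q))
}

# expression-derived features of one triplet: per-tissue mean middle-exon
# expression plus the per-experiment middle-vs-mean(flanks) log-ratio
# (values are log2 scale so the ratio is a difference); missing cells are
# masked to 0 after centering
expressionFeatures <- function(se) {
  m <- SummarizedExperiment::assay(se, "expr")
  rd <- SummarizedExperiment::rowData(se)
  if (!all(c("triplet_id", "role") %in% names(rd)))
    stop("expression table must carry triplet_id/role rowData ",
         "(exon ids formatted 'triplet:up|mid|dn')")
  tissues <- SummarizedExperiment::colData(se)$tissue
  ids <- unique(rd$triplet_id)
  nexp <- ncol(m)
  utissues <- unique(tissues)
  featNames <- c(paste0("mid_", utissues),
                 paste0("relinc_", colnames(m)))
  X <- matrix(NA_real_, length(ids), length(featNames),
              dimnames = list(ids, featNames))
  for (t in ids) {
    up <- m[rd$triplet_id == t & rd$role == "up", , drop = TRUE]
    mid <- m[rd$triplet_id == t & rd$role == "mid", , drop = TRUE]
    dn <- m[rd$triplet_id == t & rd$role == "dn", , drop = TRUE]
    flank <- (up + dn) / 2
    for (ti in utissues)
      X[t, paste0("mid_", ti)] <- mean(mid[tissues == ti], na.rm = TRUE)
    X[t, paste0("relinc_", colnames(m))] <- mid - flank
  }
  X[is.nan(X)] <- NA_real_
  X
}

#' Transfer soft labels from expression data to unlabeled exons
#'
#' Trains a tissue-task ensemble on expression-derived features (per-tissue
#' middle-exon expression and per-experiment middle-vs-flanks inclusion
#' ratios) against the anchor exons' soft labels, then predicts soft labels
#' for all exons.  Anchor exons receive the unweighted mean of their anchor
#' label and the model prediction; exons with no usable expression data are
#' excluded and reported.
#'
#' @param se expression `SummarizedExperiment` (see [loadExpressionTable()]).
#' @param anchorLabels matrix of soft labels (rows = triplet ids, columns as
#'   in [softLabelColumns()]); at least 50 anchors are required.
#' @param config a tissue-task [NetConfig-class].
#' @return list with `labels` (matrix for all usable exons), `excluded`
#'   (ids with no data) and `model`.
#' @export
estimateLabelsFromExpression <- function(se, anchorLabels, config) {
  if (config@task != "tissue") stop("config must be a tissue task")
  if (nrow(anchorLabels) < 50L)
    stop("at least 50 anchor exons are required for calibration (got ",
         nrow(anchorLabels), ")")
  X <- expressionFeatures(se)
  usable <- rowSums(!is.na(X)) > 0L
  excluded <- rownames(X)[!usable]
  X <- X[usable, , drop = FALSE]
  X[is.na(X)] <- 0
  anchors <- intersect(rownames(anchorLabels), rownames(X))
  if (length(anchors) < 50L)
    stop("fewer than 50 anchors overlap the expression table")
  model <- sampleEnsemble(X[anchors, , drop = FALSE],
                          anchorLabels[anchors, , drop = FALSE], config)
  pred <- predictProba(model, X)
  labels <- pred
  labels[anchors, ] <- (pred[anchors, , drop = FALSE] +
    anchorLabels[anchors, colnames(pred), drop = FALSE]) / 2
  list(labels = labels, excluded = excluded, model = model)
}

#' Expression-only alternative-exon classifier
#'
#' The comparison baseline that classifies exons as alternative directly from
#' normalized expression features.  Triplets with any missing expression cell
#' are removed before training (the count is recorded in the model metadata).
#'
#' @param se expression `SummarizedExperiment`.
#' @param labels named 0/1 vector (1 = cassette) indexed by triplet id.
#' @param config an `as_vs_const` [NetConfig-class].
#' @return an [EnsembleModel-class]; `metadata$n_dropped_missing` reports the
#'   removed triplets.
#' @export
expressionOnlyClassifier <- function(se, labels, config) {
  if (config@task != "as_vs_const") stop("config must be an as_vs_const task")
  X <- expressionFeatures(se)
  complete <- rowSums(is.na(X)) == 0L
  nDropped <- sum(!complete)
  X <- X[complete, , drop = FALSE]
  keep <- intersect(rownames(X), names(labels))
  model <- sampleEnsemble(X[keep, , drop = FALSE], labels[keep], config)
  model@metadata$n_dropped_missing <- nDropped
  model
}
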