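#' @include features.R bnn.R scoring.R analysis.R evaluation.R synthetic.R
NULL

#' Prepare model inputs from a triplet database
#'
#' Estimates splice-site PWMs from the database's constitutive junctions,
#' builds the feature schema, and extracts the feature matrix.
#'
#' @param db a [TripletDB-class] with coordinates.
#' @param genome `DNAStringSet`.
#' @param motifLib a [MotifLibrary-class].
#' @param families feature families for [buildFeatureSchema()].  The default
#'   model schema uses motif counts, splice-site strengths, lengths and the
#'   first-upstream-AG distance; composition and track families can be added.
#' @param intronWindow intronic window width.
#' @param nucTrack,accTrack optional tracks.
#' @return list with `X` (feature matrix), `schema`, `pwms`.
#' @export
prepareFeatures <- function(db, genome, motifLib,
                            families = c("motif_count", "splice_site",
                                         "length", "ag_dist"),
                            intronWindow = 300L,
                            nucTrack = NULL, accTrack = NULL) {
  pwms <- estimatePWMs(db, genome)
  schema <- buildFeatureSchema(motifLib, families = families)
  X <- extractFeatureMatrix(db, schema = schema, genome = genome,
                            motifLib = motifLib, pwms = pwms,
                            nucTrack = nucTrack, accTrack = accTrack,
                            intronWindow = intronWindow)
  list(X = X, schema = schema, pwms = pwms)
}

#' Batch feature-removal effects
#'
#' Computes `FE_f` for every feature in `J` and every row of `X`, each row
#' analysed in its own tissue group.
#'
#' @param model2 stage-2 [EnsembleModel-class].
#' @param X raw feature matrix.
#' @param tissues tissue group per row.
#' @param J robust feature set.
#' @return matrix rows x features of feature effects.
#' @export
featureEffectMatrix <- function(model2, X, tissues,
                                J = robustFeatures(model2)) {
  stopifnot(nrow(X) == length(tissues))
  q0 <- predictProba(model2, X)
  FE <- matrix(0, nrow(X), length(J), dimnames = list(rownames(X), J))
  for (f in J) {
    Xd <- X
    Xd[, f] <- 0
    q1 <- predictProba(model2, Xd)
    for (g in unique(tissues)) {
      rows <- tissues == g
      inc <- paste0(g, "_inc"); exc <- paste0(g, "_exc")
      FE[rows, f] <- abs(q0[rows, inc] - q1[rows, inc]) +
        abs(q0[rows, exc] - q1[rows, exc])
    }
  }
  FE
}

#' Run the end-to-end synthetic benchmark
#'
#' Generates the synthetic study, extracts features, trains the two stages
#' on a gene-aware training split, and evaluates: held-out stage-1 AUC,
#' the inclusion-frequency rank of the planted features, and the fraction of
#' true tissue-dependent exons whose top-NFE feature is their planted tissue
#' motif.
#'
#' @param config a [SimConfig-class].
#' @param motifLib motif library (default [defaultMotifLibrary()]).
#' @param nSamples,burnIn,thin MCMC schedule for both stages.
#' @param seed seed for fold assignment and samplers.
#' @return list with `stage1_auc`, `top_feature`, `top_is_planted`,
#'   `nfe_top_fraction`, `inclusion`, `models`, `prep`, `sim`, `folds`.
#' @export
runSyntheticBenchmark <- function(config, motifLib = defaultMotifLibrary(),
                                  nSamples = 200L, burnIn = 1000L, thin = 5L,
                                  seed = 1L) {
  sim <- generateTripletDB(config, motifLib)
  prep <- prepareFeatures(sim$db, sim$genome, motifLib)
  X <- prep$X
  tt <- sim$truth$triplets
  y <- stats::setNames(as.integer(tt$label == "cassette"), tt$triplet_id)
  folds <- nonredundantCvFolds(sim$db, k = 5L, seed = seed,
                               checkIdentity = FALSE)
  test <- folds == 1L
  groups <- names(config@nTissueDep)

  cfg1 <- netConfig("as_vs_const", nSamples = nSamples, burnIn = burnIn,
                    thin = thin, seed = seed)
  ids <- rownames(X)
  m1 <- sampleEnsemble(X[!test, , drop = FALSE], y[ids][!test], cfg1,
                       schema = prep$schema)
  pAS <- predictProba(m1, X[test, , drop = FALSE])
  stage1Auc <- rocAuc(pAS, y[ids][test])

  SL <- truthSoftLabels(sim$truth, tissueGroups = groups)
  casTrain <- ids[!test & y[ids] == 1L]
  cfg2 <- netConfig("tissue", nSamples = nSamples, burnIn = burnIn,
                    thin = thin, seed = seed + 1L, tissueGroups = groups)
  m2 <- sampleEnsemble(X[casTrain, , drop = FALSE],
                       SL[casTrain, , drop = FALSE], cfg2,
                       schema = prep$schema)

  # which planted feature name corresponds to each motif row
  pm <- config@plantedMotifs
  plantedFeatures <- paste0("motif_", pm$motif_id, "_", pm$region)
  topFeature <- names(which.max(m1@inclusion))
  planted <- intersect(plantedFeatures, names(m1@inclusion))
  topIsPlanted <- length(planted) > 0 &&
    max(m1@inclusion[planted]) >= max(m1@inclusion)

  # NFE top-rank fraction over the true tissue-dependent exons
  td <- tt[!is.na(tt$tissue_group), ]
  J <- robustFeatures(m2)
  nfeTopFraction <- NA_real_
  if (length(J)) {
    FE <- featureEffectMatrix(m2, X[td$triplet_id, , drop = FALSE],
                              td$tissue_group, J)
    expected <- stats::setNames(plantedFeatures, pm$class)
    hits <- vapply(seq_len(nrow(td)), function(i) {
      top <- colnames(FE)[which.max(FE[i, ])]
      identical(top, unname(expected[td$tissue_group[i]]))
    }, logical(1))
    nfeTopFraction <- mean(hits)
  }
  list(stage1_auc = stage1Auc, top_feature = topFeature,
       top_is_planted = topIsPlanted,
       nfe_top_fraction = nfeTopFraction,
       inclusion = m1@inclusion, planted_features = plantedFeatures,
       models = list(stage1 = m1, stage2 = m2),
       prep = prep, sim = sim, folds = folds, scores = pAS)
}

#' Two-stage versus single-stage detection of alternative exons
#'
#' Trains, on one synthetic dataset, (a) the two-stage model (stage-1
#' alternative-vs-constitutive classifier plus a conditional tissue model on
#' cassette exons) and (b) a single-stage direct tissue classifier on all
#' exons, and compares their held-out AUC for detecting alternative exons.
#' The two-stage score is `max_t pChange_t`; the single-stage baseline is
#' `max_t (1 - q_nc_t)`.
#'
#' @param config a [SimConfig-class] (its `seed` drives the data).
#' @param motifLib motif library.
#' @param nSamples,burnIn,thin MCMC schedule.
#' @return named numeric: `two_stage` and `single_stage` held-out AUCs.
#' @export
stageComparisonAuc <- function(config, motifLib = defaultMotifLibrary(),
                               nSamples = 50L, burnIn = 500L, thin = 2L) {
  sim <- generateTripletDB(config, motifLib)
  prep <- prepareFeatures(sim$db, sim$genome, motifLib)
  X <- prep$X
  tt <- sim$truth$triplets
  ids <- rownames(X)
  y <- stats::setNames(as.integer(tt$label == "cassette"), tt$triplet_id)[ids]
  folds <- nonredundantCvFolds(sim$db, k = 5L, seed = config@seed,
                               checkIdentity = FALSE)
  test <- folds == 1L
  groups <- names(config@nTissueDep)
  seed <- config@seed

  cfg1 <- netConfig("as_vs_const", nSamples = nSamples, burnIn = burnIn,
                    thin = thin, seed = seed)
  m1 <- sampleEnsemble(X[!test, , drop = FALSE], y[!test], cfg1)
  pAS <- predictProba(m1, X[test, , drop = FALSE])

  SLall <- truthSoftLabels(sim$truth, groups, includeConstitutive = TRUE)
  SLcas <- truthSoftLabels(sim$truth, groups)
  cfg2 <- netConfig("tissue", nSamples = nSamples, burnIn = burnIn,
                    thin = thin, seed = seed + 1L, tissueGroups = groups)
  casTrain <- ids[!test & y == 1L]
  m2 <- sampleEnsemble(X[casTrain, , drop = FALSE],
                       SLcas[casTrain, , drop = FALSE], cfg2)
  cfgS <- netConfig("tissue", nSamples = nSamples, burnIn = burnIn,
                    thin = thin, seed = seed + 2L, tissueGroups = groups)
  mS <- sampleEnsemble(X[!test, , drop = FALSE],
                       SLall[ids[!test], , drop = FALSE], cfgS)

  qC <- predictProba(m2, X[test, , drop = FALSE])
  qS <- predictProba(mS, X[test, , drop = FALSE])
  ncCols <- paste0(groups, "_nc")
  twoStage <- pAS * apply(1 - qC[, ncCols, drop = FALSE], 1L, max)
  singleStage <- apply(1 - qS[, ncCols, drop = FALSE], 1L, max)
  c(two_stage = rocAuc(twoStage, y[test]),
    single_stage = rocAuc(singleStage, y[test]))
}
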