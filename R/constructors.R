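#' @include AllClasses.R
NULL

#' Construct an ExonTriplet
#'
#' @param tripletId identifier string.
#' @param exons `GRanges` of the three exons (any genomic order; they are
#'   reordered into transcription order), or `NULL` for a sequence-only
#'   triplet.
#' @param seqs `DNAStringSet` or character vector of the three exon sequences
#'   in transcription order (C1, A, C2), or `NULL`.
#' @param geneId gene identifier (optional).
#' @param label `"cassette"`, `"constitutive"` or `NA`.
#' @return an [ExonTriplet-class].
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
#'   start = c(1, 101, 201), end = c(50, 150, 250)), strand = "+")
#' ExonTriplet("t1", exons = gr, label = "cassette")
#' @export
ExonTriplet <- function(tripletId, exons = NULL, seqs = NULL,
                        geneId = NA_character_, label = NA_character_) {
  if (is.null(exons)) {
    exons <- GenomicRanges::GRanges()
  } else if (length(exons) == 3L) {
    minus <- as.character(BiocGenerics::strand(exons))[1] == "-"
    exons <- exons[order(BiocGenerics::start(exons), decreasing = minus)]
    names(exons) <- c("C1", "A", "C2")
  }
  if (is.null(seqs)) {
    seqs <- Biostrings::DNAStringSet()
  } else {
    seqs <- Biostrings::DNAStringSet(seqs)
    names(seqs) <- c("C1", "A", "C2")
  }
  new("ExonTriplet", tripletId = as.character(tripletId),
      geneId = as.character(geneId), label = as.character(label),
      exons = exons, seqs = seqs)
}

#' Construct a TripletDB from a list of triplets
#'
#' @param triplets list of [ExonTriplet-class] objects.
#' @return a [TripletDB-class].
#' @export
TripletDB <- function(triplets = list()) {
  new("TripletDB", triplets = unname(triplets))
}

#' Sampler configuration for the Bayesian network ensemble
#'
#' Defaults follow the splicing-code settings: 10 hidden units with a
#' connection sparsity prior of 0.9 for the alternative-vs-constitutive task,
#' and 20 units with a 0.95 prior for the tissue task.  The full-size
#' published ensembles used 5,000 MCMC samples; the default here is a
#' desk-scale 500 (reachable by setting `nSamples = 5000`).
#'
#' @param task `"as_vs_const"` or `"tissue"`.
#' @param nHidden hidden units; default 10 (stage 1) / 20 (tissue).
#' @param sparsityPrior spike probability per feature-to-hidden connection;
#'   default 0.9 (stage 1) / 0.95 (tissue).
#' @param nSamples,burnIn,thin MCMC schedule.
#' @param seed RNG seed.
#' @param tissueGroups ordered tissue-group names.
#' @return a [NetConfig-class].
#' @export
netConfig <- function(task = c("as_vs_const", "tissue"),
                      nHidden = NULL, sparsityPrior = NULL,
                      nSamples = 500L, burnIn = 2000L, thin = 5L,
                      seed = 1L,
                      tissueGroups = c("CNS", "muscle", "digestive", "embryo")) {
  task <- match.arg(task)
  if (is.null(nHidden)) nHidden <- if (task == "tissue") 20L else 10L
  if (is.null(sparsityPrior)) sparsityPrior <- if (task == "tissue") 0.95 else 0.9
  new("NetConfig", nHidden = as.integer(nHidden), sparsityPrior = sparsityPrior,
      nSamples = as.integer(nSamples), burnIn = as.integer(burnIn),
      thin = as.integer(thin), seed = as.integer(seed), task = task,
      tissueGroups = as.character(tissueGroups))
}

#' Default planted-motif table for the synthetic benchmark
#'
#' Cassette exons receive exonic enhancer/silencer-like hexamers (`class =
#' "as"`); each tissue group additionally plants one group-specific motif
#' (e.g. the Fox-1/2 hexamer TGCATG standing in for the CNS class) in its
#' tissue-dependent exons only.
#'
#' @return data.frame with columns `motif_id`, `region`, `effect`, `class`.
#' @export
defaultPlantedMotifs <- function() {
  data.frame(
    motif_id = c("ese_srsf1", "ess_hnrnpa1", "gr_hnrnpfh",
                 "fox", "qk", "ptb", "cugbp"),
    region   = c("A", "A", "I1a", "I2a", "I1b", "I1b", "I2a"),
    effect   = c(1.5, 1.5, 1.5, 2, 2, 2, 2),
    class    = c("as", "as", "as", "CNS", "muscle", "digestive", "embryo"),
    stringsAsFactors = FALSE
  )
}

#' Configure the synthetic benchmark
#'
#' The defaults define the study conditions used throughout the package's
#' tests: 500 cassette and 500 constitutive triplets, 60 tissue-dependent
#' exons per group, log-normal exon (~130 nt) and intron (~800 nt) lengths,
#' a 1 log2-unit tissue shift with 0.25 replicate noise, and 2% missing
#' expression cells.
#'
#' @param nCassette,nConst triplet counts.
#' @param nTissueDep named integer vector of tissue-dependent exon counts per
#'   group.
#' @param plantedMotifs data.frame as from [defaultPlantedMotifs()].
#' @param maxCopies maximum planted copies per region (each inserted with
#'   probability `2 * (plogis(effect) - 0.5)`).
#' @param exonMeanLog,exonSdLog,intronMeanLog,intronSdLog length model.
#' @param gcContent genome GC fraction.
#' @param delta,sigma,missingness expression model.
#' @param tripletsPerGeneMean mean triplets per gene.
#' @param seed RNG seed.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nCassette = 500L, nConst = 500L,
                      nTissueDep = c(CNS = 60L, muscle = 60L,
                                     digestive = 60L, embryo = 60L),
                      plantedMotifs = defaultPlantedMotifs(),
                      maxCopies = 3L,
                      exonMeanLog = log(130), exonSdLog = 0.35,
                      intronMeanLog = log(800), intronSdLog = 0.35,
                      gcContent = 0.45, delta = 1.0, sigma = 0.25,
                      missingness = 0.02, tripletsPerGeneMean = 2,
                      seed = 1L) {
  new("SimConfig", nCassette = as.integer(nCassette), nConst = as.integer(nConst),
      nTissueDep = vapply(nTissueDep, as.integer, integer(1)),
      plantedMotifs = plantedMotifs, maxCopies = as.integer(maxCopies),
      exonMeanLog = exonMeanLog, exonSdLog = exonSdLog,
      intronMeanLog = intronMeanLog, intronSdLog = intronSdLog,
      gcContent = gcContent, delta = delta, sigma = sigma,
      missingness = missingness, tripletsPerGeneMean = tripletsPerGeneMean,
      seed = as.integer(seed))
}
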