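#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @import IRanges
#' @import GenomicRanges
#' @import Biostrings
NULL

REGION_CODES <- c("C1", "I1a", "I1b", "A", "I2a", "I2b", "C2")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' ExonTriplet: a cassette-exon candidate with its flanking exons
#'
#' Holds three exons (upstream flank C1, alternative exon A, downstream flank
#' C2) in transcription order, optionally with genomic coordinates and/or
#' sequences.  Sequences are always stored in transcription orientation (the
#' sense strand of the gene).  This is the unit of every query: feature
#' extraction, prediction and in-silico analysis all start from a triplet.
#'
#' @slot tripletId single identifier string.
#' @slot geneId gene the triplet belongs to (used for non-redundant
#'   cross-validation folds); may be `NA`.
#' @slot label `"cassette"`, `"constitutive"` or `NA` when unknown.
#' @slot exons `GRanges` of length 3 (C1, A, C2 in transcription order) or
#'   length 0 for sequence-only triplets.
#' @slot seqs `DNAStringSet` of length 3 named C1/A/C2, or length 0 when only
#'   coordinates are given.
#' @exportClass ExonTriplet
setClass("ExonTriplet",
  representation(
    tripletId = "character",
    geneId = "character",
    label = "character",
    exons = "GRanges",
    seqs = "DNAStringSet"
  )
)

setValidity("ExonTriplet", function(object) {
  msg <- character()
  if (length(object@tripletId) != 1L) msg <- c(msg, "tripletId must be a single string")
  ne <- length(object@exons)
  ns <- length(object@seqs)
  if (!ne %in% c(0L, 1L, 3L))
    msg <- c(msg, "exons must have length 0, 1 (single-exon query) or 3")
  if (!ns %in% c(0L, 1L, 3L))
    msg <- c(msg, "seqs must have length 0, 1 (single-exon query) or 3")
  if (ne == 0L && ns == 0L) msg <- c(msg, "triplet needs coordinates or sequences")
  if (ne == 3L) {
    ex <- object@exons
    if (length(unique(as.character(GenomicRanges::seqnames(ex)))) != 1L)
      msg <- c(msg, "all exons must be on one chromosome")
    st <- unique(as.character(BiocGenerics::strand(ex)))
    if (length(st) != 1L || !st %in% c("+", "-"))
      msg <- c(msg, "all exons must share one strand (+ or -)")
    if (any(BiocGenerics::width(ex) < 10L))
      msg <- c(msg, "exons must be at least 10 nt long")
    s <- BiocGenerics::start(ex); e <- BiocGenerics::end(ex)
    ordered <- if (identical(st, "-")) all(s[1] > e[2]) && all(s[2] > e[3])
               else all(e[1] < s[2]) && all(e[2] < s[3])
    if (length(st) == 1L && st %in% c("+", "-") && !ordered)
      msg <- c(msg, "exons must be non-overlapping and ordered in transcription direction")
  }
  if (ns == 1L && !identical(names(object@seqs), "A"))
    msg <- c(msg, "a single-exon query sequence must be named A")
  if (ns == 3L) {
    if (!identical(names(object@seqs), c("C1", "A", "C2")))
      msg <- c(msg, "seqs must be named C1, A, C2")
    if (any(BiocGenerics::width(object@seqs) < 10L))
      msg <- c(msg, "exon sequences must be at least 10 nt long")
    if (ne == 3L && !identical(unname(BiocGenerics::width(object@seqs)),
                               unname(BiocGenerics::width(object@exons))))
      msg <- c(msg, "sequence widths must match exon widths")
  }
  if (length(msg)) msg else TRUE
})

#' TripletDB: a database of exon triplets
#'
#' An ordered collection of [ExonTriplet] records with unique ids, each
#' labelled cassette (known alternative) or constitutive.  Queries are matched
#' against such a database before any genome search.
#'
#' @slot triplets list of `ExonTriplet`.
#' @exportClass TripletDB
setClass("TripletDB", representation(triplets = "list"))

setValidity("TripletDB", function(object) {
  msg <- character()
  if (!all(vapply(object@triplets, is, logical(1), class2 = "ExonTriplet")))
    msg <- c(msg, "all elements must be ExonTriplet objects")
  else {
    ids <- vapply(object@triplets, function(x) x@tripletId, character(1))
    if (anyDuplicated(ids)) msg <- c(msg, "triplet ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' MotifLibrary: IUPAC motif definitions with RBP annotations
#'
#' Each motif has an IUPAC pattern (DNA alphabet; U accepted on input and
#' normalised to T), the RNA-binding protein it is associated with, the
#' subset of the seven regions it is counted in, and a group tag separating
#' code-model motifs from general splicing-related ones.
#'
#' @slot defs data.frame with columns `motif_id`, `pattern`, `rbp_name`,
#'   `group` and list-column `allowed_regions`.
#' @exportClass MotifLibrary
setClass("MotifLibrary", representation(defs = "data.frame"))

setValidity("MotifLibrary", function(object) {
  d <- object@defs
  need <- c("motif_id", "pattern", "rbp_name", "allowed_regions", "group")
  if (!all(need %in% names(d)))
    return(paste("defs must have columns", paste(need, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(d$motif_id)) msg <- c(msg, "motif ids must be unique")
  for (i in seq_len(nrow(d))) {
    p <- strsplit(d$pattern[i], "")[[1]]
    if (length(p) == 0L || !all(p %in% names(IUPAC_SETS)))
      msg <- c(msg, sprintf("row %d: invalid IUPAC pattern '%s'", i, d$pattern[i]))
    if (!all(d$allowed_regions[[i]] %in% REGION_CODES))
      msg <- c(msg, sprintf("row %d: unknown region code", i))
    if (!d$group[i] %in% c("code_model", "general_splicing"))
      msg <- c(msg, sprintf("row %d: group must be code_model or general_splicing", i))
  }
  if (length(msg)) msg else TRUE
})

#' RegionSet: the seven regions around a cassette exon
#'
#' Regions C1, I1a, I1b, A, I2a, I2b, C2: the flanking exons, the alternative
#' exon, and exon-proximal windows of the two introns (I1a donor-proximal and
#' I1b acceptor-proximal in the upstream intron; I2a/I2b likewise downstream).
#' Sequences are in transcription orientation.
#'
#' @slot ranges named `GRanges` (subset of the seven codes); empty for
#'   sequence-only triplets.
#' @slot seqs named `DNAStringSet`, same names as `ranges` when both present.
#' @slot flags list of notes (e.g. regions truncated by short introns).
#' @exportClass RegionSet
setClass("RegionSet",
  representation(ranges = "GRanges", seqs = "DNAStringSet", flags = "list")
)

setValidity("RegionSet", function(object) {
  msg <- character()
  if (length(object@seqs) && !all(names(object@seqs) %in% REGION_CODES))
    msg <- c(msg, "region names must be among the seven region codes")
  if (length(object@ranges)) {
    if (!all(names(object@ranges) %in% REGION_CODES))
      msg <- c(msg, "range names must be among the seven region codes")
    common <- intersect(names(object@ranges), names(object@seqs))
    if (length(common) &&
        !identical(unname(BiocGenerics::width(object@ranges[common])),
                   unname(BiocGenerics::width(object@seqs[common]))))
      msg <- c(msg, "sequence widths must match range widths")
  }
  if (length(msg)) msg else TRUE
})

#' NetConfig: sampler and architecture settings for the Bayesian network
#'
#' @slot nHidden number of hidden units (10 for the alternative-vs-constitutive
#'   stage, 20 for the tissue stage, following the splicing-code defaults).
#' @slot sparsityPrior spike (exclusion) probability of each feature-to-hidden
#'   connection under the spike-and-slab prior (0.9 / 0.95 defaults).
#' @slot nSamples retained posterior samples (ensemble size).
#' @slot burnIn discarded initial iterations.
#' @slot thin keep every `thin`-th post-burn-in state.
#' @slot seed RNG seed; the sampler is bit-reproducible given the seed.
#' @slot task `"as_vs_const"` (binary stage 1) or `"tissue"` (per-group
#'   three-class stage 2).
#' @slot tissueGroups ordered group names for the tissue task.
#' @exportClass NetConfig
setClass("NetConfig",
  representation(
    nHidden = "integer", sparsityPrior = "numeric",
    nSamples = "integer", burnIn = "integer", thin = "integer",
    seed = "integer", task = "character", tissueGroups = "character"
  )
)

setValidity("NetConfig", function(object) {
  msg <- character()
  if (object@nHidden < 1L) msg <- c(msg, "nHidden must be >= 1")
  if (object@sparsityPrior <= 0 || object@sparsityPrior >= 1)
    msg <- c(msg, "sparsityPrior must be in (0, 1)")
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
  if (object@burnIn < 0L) msg <- c(msg, "burnIn must be >= 0")
  if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
  if (!object@task %in% c("as_vs_const", "tissue"))
    msg <- c(msg, "task must be 'as_vs_const' or 'tissue'")
  if (object@task == "tissue" && length(object@tissueGroups) < 1L)
    msg <- c(msg, "tissue task needs at least one tissue group")
  if (length(msg)) msg else TRUE
})

#' EnsembleModel: an MCMC ensemble of sparse networks
#'
#' A set of posterior weight configurations sampled by Metropolis-within-Gibbs
#' from a sparse feed-forward classifier; predictions are posterior means over
#' the ensemble.  Per-feature inclusion frequencies (fraction of samples in
#' which the feature has at least one active connection) define the robust
#' feature set.
#'
#' @slot config the [NetConfig-class] used for sampling.
#' @slot schema data.frame describing the feature vector (columns `name`,
#'   `family`, `region`).
#' @slot samples list of weight configurations (`M`, `W1`, `b1`, `W2`, `b2`).
#' @slot inclusion named per-feature inclusion frequency in `[0, 1]`.
#' @slot standardization list with `mean` and `sd` used to standardize inputs.
#' @slot metadata list: acceptance rates, warnings, seed.
#' @exportClass EnsembleModel
setClass("EnsembleModel",
  representation(
    config = "NetConfig", schema = "data.frame", samples = "list",
    inclusion = "numeric", standardization = "list", metadata = "list"
  )
)

setValidity("EnsembleModel", function(object) {
  msg <- character()
  p <- nrow(object@schema)
  if (length(object@inclusion) != p)
    msg <- c(msg, "inclusion frequencies must match schema length")
  if (length(object@inclusion) &&
      (min(object@inclusion) < 0 || max(object@inclusion) > 1))
    msg <- c(msg, "inclusion frequencies must be in [0, 1]")
  for (s in object@samples) {
    if (!identical(dim(s$W1), c(p, object@config@nHidden))) {
      msg <- c(msg, "sample dimensions inconsistent with schema"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' SplicingPrediction: two-stage splicing scores for one exon
#'
#' Combines the stage-1 probability that the exon is alternative (`pAS`) with
#' the stage-2 conditional change probabilities per tissue group
#' (`q_inc`, `q_exc`, `q_nc`) into the combined change probability
#' `pChange_t = pAS * (q_inc + q_exc)` by the chain rule.
#'
#' @slot pAS probability the exon is an alternative cassette exon.
#' @slot q matrix, one row per tissue group, columns `inc`, `exc`, `nc`
#'   summing to 1 (conditional on the exon being alternative).
#' @slot pChange named per-group combined change probability.
#' @exportClass SplicingPrediction
setClass("SplicingPrediction",
  representation(pAS = "numeric", q = "matrix", pChange = "numeric")
)

setValidity("SplicingPrediction", function(object) {
  msg <- character()
  if (object@pAS < 0 || object@pAS > 1) msg <- c(msg, "pAS must be in [0, 1]")
  if (!identical(colnames(object@q), c("inc", "exc", "nc")))
    msg <- c(msg, "q columns must be inc, exc, nc")
  else {
    if (any(object@q < -1e-9) || any(object@q > 1 + 1e-9))
      msg <- c(msg, "q values must be probabilities")
    if (any(abs(rowSums(object@q) - 1) > 1e-9))
      msg <- c(msg, "each q row must sum to 1")
    if (any(object@pChange > object@pAS + 1e-9))
      msg <- c(msg, "pChange cannot exceed pAS")
  }
  if (length(msg)) msg else TRUE
})

#' SimConfig: settings for the synthetic benchmark generator
#'
#' Defines the simulated study: numbers of cassette and constitutive triplets,
#' how many cassette exons are tissue-dependent per group, which motifs are
#' planted where and how strongly, exon/intron length distributions, base
#' composition, and the expression model (tissue shift delta, noise sigma,
#' missingness).
#'
#' @slot nCassette,nConst triplet counts per class.
#' @slot nTissueDep named integer: tissue-dependent cassette exons per group.
#' @slot plantedMotifs data.frame with columns `motif_id`, `region`, `effect`
#'   (logit scale; a copy is planted with probability
#'   `2 * (plogis(effect) - 0.5)` in each of `maxCopies` slots, so a zero
#'   effect plants nothing) and `class` (`"as"` planted in all cassette
#'   exons, or a tissue-group name).
#' @slot maxCopies maximum planted copies per exon region.
#' @slot exonMeanLog,exonSdLog,intronMeanLog,intronSdLog log-normal length
#'   parameters (nt).
#' @slot gcContent genome GC fraction.
#' @slot delta expression shift (log2 units) of the middle exon in the target
#'   tissue group for tissue-dependent exons.
#' @slot sigma replicate noise sd (log2 units).
#' @slot missingness fraction of expression cells set missing.
#' @slot tripletsPerGeneMean mean triplets per simulated gene.
#' @slot seed RNG seed.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nCassette = "integer", nConst = "integer", nTissueDep = "integer",
    plantedMotifs = "data.frame", maxCopies = "integer",
    exonMeanLog = "numeric", exonSdLog = "numeric",
    intronMeanLog = "numeric", intronSdLog = "numeric",
    gcContent = "numeric", delta = "numeric", sigma = "numeric",
    missingness = "numeric", tripletsPerGeneMean = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nCassette < 0L || object@nConst < 0L) msg <- c(msg, "counts must be >= 0")
  if (sum(object@nTissueDep) > object@nCassette)
    msg <- c(msg, "tissue-dependent exons cannot exceed cassette count")
  if (object@sigma <= 0 || object@delta <= 0) msg <- c(msg, "sigma and delta must be > 0")
  if (object@missingness < 0 || object@missingness > 1)
    msg <- c(msg, "missingness must be in [0, 1]")
  if (length(msg)) msg else TRUE
})
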