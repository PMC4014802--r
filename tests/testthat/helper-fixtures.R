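# Shared fixtures, built in code.  The small simulated study and the small
# trained models are computed once per test run.

smallSimConfig <- function(seed = 42L) {
  simConfig(nCassette = 40L, nConst = 40L,
            nTissueDep = c(CNS = 6L, muscle = 6L, digestive = 6L, embryo = 6L),
            seed = seed)
}

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixtureCache)) assign(key, force(expr), .fixtureCache)
  get(key, .fixtureCache)
}

smallSim <- function() cached("smallSim", generateTripletDB(smallSimConfig()))

smallPrep <- function() cached("smallPrep", {
  sim <- smallSim()
  prepareFeatures(sim$db, sim$genome, defaultMotifLibrary())
})

# a quickly trained stage-2 (tissue) model on the small study
smallStage2 <- function() cached("smallStage2", {
  sim <- smallSim()
  prep <- smallPrep()
  tt <- sim$truth$triplets
  cas <- tt$triplet_id[tt$label == "cassette"]
  SL <- truthSoftLabels(sim$truth)
  sampleEnsemble(prep$X[cas, , drop = FALSE], SL[cas, , drop = FALSE],
                 netConfig("tissue", nSamples = 40L, burnIn = 300L,
                           thin = 2L, seed = 5L),
                 schema = prep$schema)
})

# a quickly trained stage-1 model on the small study
smallStage1 <- function() cached("smallStage1", {
  sim <- smallSim()
  prep <- smallPrep()
  tt <- sim$truth$triplets
  y <- setNames(as.integer(tt$label == "cassette"), tt$triplet_id)
  sampleEnsemble(prep$X, y[rownames(prep$X)],
                 netConfig("as_vs_const", nSamples = 40L, burnIn = 300L,
                           thin = 2L, seed = 6L),
                 schema = prep$schema)
})

# a hand-built ensemble whose single sample has all-zero weights
zeroEnsemble <- function(task = "as_vs_const", p = 3L,
                         featureNames = paste0("f", seq_len(p)),
                         nHidden = 2L) {
  cfg <- netConfig(task, nHidden = nHidden, nSamples = 1L, burnIn = 0L,
                   thin = 1L, seed = 1L)
  K <- if (task == "as_vs_const") 1L else 12L
  s <- list(M = matrix(0L, p, nHidden), W1 = matrix(0, p, nHidden),
            b1 = numeric(nHidden), W2 = matrix(0, nHidden, K),
            b2 = numeric(K))
  new("EnsembleModel", config = cfg,
      schema = data.frame(name = featureNames, family = "unknown",
                          region = NA_character_, stringsAsFactors = FALSE),
      samples = list(s), inclusion = setNames(rep(0, p), featureNames),
      standardization = list(mean = setNames(rep(0, p), featureNames),
                             sd = setNames(rep(1, p), featureNames)),
      metadata = list(acceptance_rate = NA_real_))
}

# independent brute-force IUPAC scan used as the motif-count oracle
bruteForceMotifCount <- function(seq, pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  n <- 0L
  if (length(s) < length(p)) return(0L)
  for (start in 1:(length(s) - length(p) + 1L)) {
    ok <- TRUE
    for (j in seq_along(p)) {
      if (!s[start + j - 1L] %in% sets[[p[j]]]) { ok <- FALSE; break }
    }
    if (ok) n <- n + 1L
  }
  n
}

# exhaustive pairwise AUC oracle
pairwiseAucOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# build a plus/minus strand pair of identical triplets in mirrored genomes
mirroredTriplets <- function(seed = 3L) {
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), 3000L, replace = TRUE)
  txSeq <- paste(bases, collapse = "")
  w <- c(60L, 80L, 70L)
  L <- c(700L, 900L)
  starts <- cumsum(c(101L, w[1] + L[1], w[2] + L[2]))
  ends <- starts + w - 1L
  gPlus <- Biostrings::DNAStringSet(txSeq)
  names(gPlus) <- "chr1"
  trPlus <- ExonTriplet("tp",
    exons = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = starts, end = ends), strand = "+"))
  gMinus <- Biostrings::DNAStringSet(
    Biostrings::reverseComplement(Biostrings::DNAString(txSeq)))
  names(gMinus) <- "chr1"
  n <- nchar(txSeq)
  trMinus <- ExonTriplet("tm",
    exons = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = n - ends + 1L, end = n - starts + 1L),
      strand = "-"))
  list(plus = list(genome = gPlus, triplet = trPlus),
       minus = list(genome = gMinus, triplet = trMinus))
}
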