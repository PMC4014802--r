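#' @include AllClasses.R constructors.R formats-io.R features.R
NULL

# random DNA as a character vector
.randBases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# instantiate an IUPAC pattern as a concrete sequence
.instantiate <- function(pattern) {
  vapply(strsplit(pattern, "")[[1]], function(ch) {
    set <- IUPAC_SETS[[ch]]
    set[sample.int(length(set), 1L)]
  }, character(1))
}

# an intron with canonical-ish splice-site ends: GT..donor, polypyrimidine
# tract ending in AG
.buildIntron <- function(L, gc) {
  donor <- c("G", "T",
             sample(c("A", "G"), 1L, prob = c(0.75, 0.25)), "A", "G",
             sample(c("T", "C"), 1L, prob = c(0.8, 0.2)))
  ppt <- sample(c("C", "T"), 8L, replace = TRUE, prob = c(0.4, 0.6))
  acc <- c(ppt, sample(c("C", "T"), 1L), "A", "G")
  c(donor, .randBases(L - length(donor) - length(acc), gc), acc)
}

# plant motif copies into segment character vectors without overlap;
# returns list(segments, placed)
.plantMotifs <- function(segs, rows, maxCopies, intronWindow = 300L) {
  occupied <- list(C1 = integer(0), I1 = integer(0), A = integer(0),
                   I2 = integer(0), C2 = integer(0))
  placed <- integer(nrow(rows))
  if (!nrow(rows)) return(list(segments = segs, placed = placed))
  rangeFor <- function(region, Lm) {
    L1 <- length(segs$I1); L2 <- length(segs$I2)
    switch(region,
      C1 = list(seg = "C1", lo = 1L, hi = length(segs$C1) - Lm + 1L),
      A = list(seg = "A", lo = 1L, hi = length(segs$A) - Lm + 1L),
      I1a = list(seg = "I1",
                 lo = 7L, hi = min(intronWindow, floor(L1 / 2)) - Lm + 1L),
      I1b = list(seg = "I1", lo = L1 - min(intronWindow, ceiling(L1 / 2)) + 1L,
                 hi = L1 - 11L - Lm + 1L),
      I2a = list(seg = "I2",
                 lo = 7L, hi = min(intronWindow, floor(L2 / 2)) - Lm + 1L),
      I2b = list(seg = "I2", lo = L2 - min(intronWindow, ceiling(L2 / 2)) + 1L,
                 hi = L2 - 11L - Lm + 1L),
      C2 = list(seg = "C2", lo = 1L, hi = length(segs$C2) - Lm + 1L)
    )
  }
  for (r in seq_len(nrow(rows))) {
    Lm <- nchar(rows$pattern[r])
    # logit-scaled planting probability: 0 at effect 0 (true null), -> 1 as
    # the effect grows
    pPlant <- max(0, 2 * (stats::plogis(rows$effect[r]) - 0.5))
    want <- stats::rbinom(1L, maxCopies, pPlant)
    if (!want) next
    rg <- rangeFor(rows$region[r], Lm)
    if (rg$hi < rg$lo) next
    for (cp in seq_len(want)) {
      for (try in 1:20) {
        pos <- sample.int(rg$hi - rg$lo + 1L, 1L) + rg$lo - 1L
        span <- pos:(pos + Lm - 1L)
        if (!any(span %in% occupied[[rg$seg]])) {
          segs[[rg$seg]][span] <- .instantiate(rows$pattern[r])
          occupied[[rg$seg]] <- c(occupied[[rg$seg]], span)
          placed[r] <- placed[r] + 1L
          break
        }
      }
    }
  }
  list(segments = segs, placed = placed)
}

#' Generate a synthetic triplet database with planted regulatory motifs
#'
#' Builds a toy genome of exon triplets: constitutive triplets carry only
#' background sequence (with canonical splice-site ends), cassette triplets
#' additionally receive planted copies of the alternative-splicing motifs,
#' and tissue-dependent cassette exons receive their group's motif.  Every
#' planted occurrence is recorded in a truth table.  Triplets are laid on
#' both strands of one chromosome, grouped into genes.
#'
#' @param config a [SimConfig-class]; its `plantedMotifs` patterns are looked
#'   up in `motifLib`.
#' @param motifLib a [MotifLibrary-class] supplying the motif patterns
#'   (default [defaultMotifLibrary()]).
#' @return list with `db` ([TripletDB-class]), `genome` (`DNAStringSet`,
#'   one chromosome `chrS`), and `truth` (list of `triplets` and
#'   `occurrences` data.frames).
#' @export
generateTripletDB <- function(config, motifLib = defaultMotifLibrary()) {
  set.seed(config@seed)
  nCas <- config@nCassette; nCon <- config@nConst
  n <- nCas + nCon
  lab <- c(rep("cassette", nCas), rep("constitutive", nCon))
  # tissue-dependence assignment among cassette triplets
  groups <- names(config@nTissueDep)
  tissueOf <- rep(NA_character_, n)
  dirOf <- rep(NA_character_, n)
  pool <- sample(seq_len(nCas))
  off <- 0L
  for (g in groups) {
    ng <- config@nTissueDep[[g]]
    idx <- pool[seq_len(ng) + off]
    tissueOf[idx] <- g
    dirOf[idx] <- rep_len(c("inc", "exc"), ng)
    off <- off + ng
  }
  # genes: consecutive triplets share a gene
  geneSizes <- integer(0)
  while (sum(geneSizes) < n)
    geneSizes <- c(geneSizes, 1L + stats::rpois(1L, config@tripletsPerGeneMean - 1))
  geneOf <- rep(paste0("g", seq_along(geneSizes)), geneSizes)[seq_len(n)]

  pm <- config@plantedMotifs
  pm$pattern <- vapply(pm$motif_id, function(id) {
    i <- match(id, motifLib@defs$motif_id)
    if (is.na(i)) stop("planted motif not in library: ", id)
    motifLib@defs$pattern[i]
  }, character(1))

  chromParts <- character(0)
  cur <- 0L
  triplets <- vector("list", n)
  occ <- list()
  spacer <- 200L
  order12 <- sample(n)   # randomize genomic order of classes
  ids <- sprintf("t%04d", seq_len(n))
  for (pos in seq_len(n)) {
    i <- order12[pos]
    wEx <- pmax(20L, as.integer(round(stats::rlnorm(3L, config@exonMeanLog,
                                                    config@exonSdLog))))
    wIn <- pmax(60L, as.integer(round(stats::rlnorm(2L, config@intronMeanLog,
                                                    config@intronSdLog))))
    segs <- list(C1 = .randBases(wEx[1], config@gcContent),
                 I1 = .buildIntron(wIn[1], config@gcContent),
                 A = .randBases(wEx[2], config@gcContent),
                 I2 = .buildIntron(wIn[2], config@gcContent),
                 C2 = .randBases(wEx[3], config@gcContent))
    plantRows <- pm[(lab[i] == "cassette" & pm$class == "as") |
                    (!is.na(tissueOf[i]) & pm$class == tissueOf[i]), ,
                    drop = FALSE]
    pl <- .plantMotifs(segs, plantRows, config@maxCopies)
    segs <- pl$segments
    if (nrow(plantRows))
      occ[[length(occ) + 1L]] <- data.frame(
        triplet_id = ids[i], motif_id = plantRows$motif_id,
        region = plantRows$region, copies = pl$placed,
        stringsAsFactors = FALSE)
    txSeq <- paste(unlist(segs), collapse = "")
    len <- nchar(txSeq)
    strand <- sample(c("+", "-"), 1L)
    gSeq <- if (strand == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(txSeq)))
    else txSeq
    chromParts <- c(chromParts,
                    paste(.randBases(spacer, config@gcContent), collapse = ""),
                    gSeq)
    base <- cur + spacer
    # transcription-order exon tx intervals
    b <- cumsum(c(0L, lengths(segs)))
    txIv <- rbind(C1 = c(b[1] + 1L, b[2]), A = c(b[3] + 1L, b[4]),
                  C2 = c(b[5] + 1L, b[6]))
    gIv <- if (strand == "-")
      cbind(base + len - txIv[, 2] + 1L, base + len - txIv[, 1] + 1L)
    else cbind(base + txIv[, 1], base + txIv[, 2])
    exons <- GenomicRanges::GRanges("chrS",
      IRanges::IRanges(start = gIv[, 1], end = gIv[, 2]), strand = strand)
    triplets[[i]] <- ExonTriplet(ids[i], exons = exons,
      seqs = c(substr(txSeq, txIv["C1", 1], txIv["C1", 2]),
               substr(txSeq, txIv["A", 1], txIv["A", 2]),
               substr(txSeq, txIv["C2", 1], txIv["C2", 2])),
      geneId = geneOf[i], label = lab[i])
    cur <- cur + spacer + len
  }
  genome <- Biostrings::DNAStringSet(paste(chromParts, collapse = ""))
  names(genome) <- "chrS"
  truthTriplets <- data.frame(
    triplet_id = ids, label = lab, gene_id = geneOf,
    tissue_group = tissueOf, direction = dirOf, stringsAsFactors = FALSE)
  occurrences <- if (length(occ)) do.call(rbind, occ) else
    data.frame(triplet_id = character(0), motif_id = character(0),
               region = character(0), copies = integer(0))
  list(db = TripletDB(triplets), genome = genome,
       truth = list(triplets = truthTriplets, occurrences = occurrences))
}

#' Simulated tissue panel
#'
#' @return the eleven tissues of the simulated expression panel.
#' @export
simTissues <- function() {
  c("brain", "embryo", "heart", "kidney", "liver", "lung",
    "muscle", "ovary", "spleen", "testis", "thymus")
}

#' Generate a synthetic expression table with planted tissue effects
#'
#' Eleven tissues with three replicates each (33 experiments).  Flank exons
#' vary around a per-triplet baseline; the middle exon of a tissue-dependent
#' cassette exon is shifted by `+delta` (increased inclusion) or `-delta`
#' (increased exclusion) in the experiments of its tissue group.  Values are
#' log2-scale normalized expression with Gaussian replicate noise and
#' missing cells at the configured rate.
#'
#' @param config a [SimConfig-class].
#' @param truth the `truth` element of [generateTripletDB()].
#' @param groupMap named list group -> tissues (default
#'   [defaultTissueGroups()]).
#' @return a `SummarizedExperiment` as from [loadExpressionTable()].
#' @export
generateExpression <- function(config, truth,
                               groupMap = defaultTissueGroups()) {
  set.seed(config@seed + 1L)
  tt <- truth$triplets
  tissues <- rep(simTissues(), each = 3L)
  expIds <- paste(tissues, rep(1:3, length(simTissues())), sep = ".")
  nexp <- length(expIds)
  ids <- tt$triplet_id
  rows <- as.vector(t(outer(ids, c("up", "mid", "dn"), paste, sep = ":")))
  m <- matrix(NA_real_, length(rows), nexp, dimnames = list(rows, expIds))
  for (r in seq_along(ids)) {
    base <- stats::rnorm(1L, 1.5, 0.7)
    up <- base + stats::rnorm(nexp, 0, config@sigma)
    dn <- base + stats::rnorm(nexp, 0, config@sigma)
    midBase <- if (tt$label[r] == "cassette") base - 0.5 else base
    mid <- midBase + stats::rnorm(nexp, 0, config@sigma)
    if (!is.na(tt$tissue_group[r])) {
      inG <- tissues %in% groupMap[[tt$tissue_group[r]]]
      shift <- if (tt$direction[r] == "inc") config@delta else -config@delta
      mid[inG] <- mid[inG] + shift
    }
    m[3L * r - 2L, ] <- up
    m[3L * r - 1L, ] <- mid
    m[3L * r, ] <- dn
  }
  if (config@missingness > 0) {
    drop <- stats::runif(length(m)) < config@missingness
    m[drop] <- NA_real_
  }
  cd <- S4Vectors::DataFrame(tissue = tissues,
                             replicate = rep(1:3, length(simTissues())),
                             row.names = expIds)
  rd <- S4Vectors::DataFrame(triplet_id = rep(ids, each = 3L),
                             role = rep(c("up", "mid", "dn"), length(ids)),
                             row.names = rows)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = m), colData = cd, rowData = rd)
}

#' Generate a smooth synthetic occupancy track
#'
#' A clipped autoregressive profile in `[0, 1]` over the genome, emitted in
#' fixed-width bins (bedGraph-style); stands in for a precomputed
#' nucleosome-occupancy or accessibility track.
#'
#' @param genome `DNAStringSet`.
#' @param seed RNG seed.
#' @param binSize bin width in nt.
#' @return `GRanges` with a `score` column.
#' @export
generateTrack <- function(genome, seed = 1L, binSize = 20L) {
  set.seed(seed)
  grl <- lapply(names(genome), function(chrom) {
    L <- length(genome[[chrom]])
    nb <- ceiling(L / binSize)
    x <- numeric(nb)
    for (i in 2:nb) x[i] <- 0.9 * x[i - 1] + stats::rnorm(1L, 0, 0.3)
    starts <- seq.int(1L, by = binSize, length.out = nb)
    GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = starts, end = pmin(starts + binSize - 1L, L)),
      score = round(stats::plogis(x), 4))
  })
  suppressWarnings(do.call(c, grl))
}

#' Soft labels implied by the synthetic ground truth
#'
#' Tissue-dependent exons receive a confident label in their group
#' (`q_inc = 0.8` or `q_exc = 0.8`, `q_nc = 0.15`); all other group entries
#' (and non-tissue-dependent cassette exons everywhere) are
#' `(0.05, 0.05, 0.9)`.  Constitutive triplets, when included, get
#' `(0.02, 0.02, 0.96)`.
#'
#' @param truth the `truth` element of [generateTripletDB()].
#' @param tissueGroups ordered group names.
#' @param includeConstitutive include constitutive triplets (for training a
#'   single-stage direct tissue classifier on all exons).
#' @return soft-label matrix (rows = triplet ids, columns
#'   [softLabelColumns()]).
#' @export
truthSoftLabels <- function(truth,
                            tissueGroups = c("CNS", "muscle", "digestive",
                                             "embryo"),
                            includeConstitutive = FALSE) {
  tt <- truth$triplets
  if (!includeConstitutive) tt <- tt[tt$label == "cassette", , drop = FALSE]
  cols <- softLabelColumns(tissueGroups)
  L <- matrix(rep(c(0.05, 0.05, 0.9), length(tissueGroups)),
              nrow(tt), length(cols), byrow = TRUE,
              dimnames = list(tt$triplet_id, cols))
  const <- tt$label == "constitutive"
  if (any(const))
    L[const, ] <- matrix(rep(c(0.02, 0.02, 0.96), length(tissueGroups)),
                         sum(const), length(cols), byrow = TRUE)
  for (r in which(!is.na(tt$tissue_group))) {
    g <- tt$tissue_group[r]
    L[r, paste0(g, "_", c("inc", "exc", "nc"))] <-
      if (tt$direction[r] == "inc") c(0.8, 0.05, 0.15) else c(0.05, 0.8, 0.15)
  }
  L
}
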