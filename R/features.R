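#' @include AllClasses.R constructors.R formats-io.R
NULL

# Internal: lay the triplet out in transcription coordinates.
# Returns the spanning sense-strand sequence plus 1-based transcription
# offsets of the five segments (C1, I1, A, I2, C2) and a mapper back to
# genomic coordinates.
tripletFrame <- function(triplet, genome) {
  if (!hasCoordinates(triplet))
    stop("triplet '", triplet@tripletId, "' has no genomic coordinates")
  ex <- triplet@exons
  chrom <- as.character(GenomicRanges::seqnames(ex))[1]
  strand <- as.character(BiocGenerics::strand(ex))[1]
  spanStart <- min(BiocGenerics::start(ex))
  spanEnd <- max(BiocGenerics::end(ex))
  seq <- fetchSeq(genome, chrom, spanStart - 1L, spanEnd, strand)
  w <- BiocGenerics::width(ex)
  minus <- strand == "-"
  gaps <- if (minus) {
    c(BiocGenerics::start(ex)[1] - BiocGenerics::end(ex)[2] - 1L,
      BiocGenerics::start(ex)[2] - BiocGenerics::end(ex)[3] - 1L)
  } else {
    c(BiocGenerics::start(ex)[2] - BiocGenerics::end(ex)[1] - 1L,
      BiocGenerics::start(ex)[3] - BiocGenerics::end(ex)[2] - 1L)
  }
  starts <- cumsum(c(1L, w[1], gaps[1], w[2], gaps[2]))
  ends <- starts + c(w[1], gaps[1], w[2], gaps[2], w[3]) - 1L
  seg <- rbind(starts, ends)
  colnames(seg) <- c("C1", "I1", "A", "I2", "C2")
  list(seq = seq, seg = seg, chrom = chrom, strand = strand,
       spanStart = spanStart, spanEnd = spanEnd)
}

# tx interval [t1, t2] (1-based closed) -> genomic GRanges
txToGenomic <- function(frame, t1, t2) {
  if (frame$strand == "-") {
    GenomicRanges::GRanges(frame$chrom,
      IRanges::IRanges(start = frame$spanEnd - t2 + 1L,
                       end = frame$spanEnd - t1 + 1L),
      strand = "-")
  } else {
    GenomicRanges::GRanges(frame$chrom,
      IRanges::IRanges(start = frame$spanStart + t1 - 1L,
                       end = frame$spanStart + t2 - 1L),
      strand = "+")
  }
}

# transcription-coordinate windows of the seven regions (list of c(t1, t2))
regionTxWindows <- function(frame, intronWindow = 300L) {
  seg <- frame$seg
  L1 <- seg["ends", "I1"] - seg["starts", "I1"] + 1L
  L2 <- seg["ends", "I2"] - seg["starts", "I2"] + 1L
  if (L1 < 2L || L2 < 2L) stop("intron shorter than 2 nt")
  win <- function(intron, L) {
    la <- min(intronWindow, floor(L / 2))
    lb <- min(intronWindow, ceiling(L / 2))
    s <- seg["starts", intron]; e <- seg["ends", intron]
    list(a = c(s, s + la - 1L), b = c(e - lb + 1L, e))
  }
  w1 <- win("I1", L1); w2 <- win("I2", L2)
  list(C1 = unname(seg[, "C1"]), I1a = w1$a, I1b = w1$b,
       A = unname(seg[, "A"]), I2a = w2$a, I2b = w2$b,
       C2 = unname(seg[, "C2"]))
}

# the seven region sequences as a plain named character vector
regionTxSeqs <- function(frame, tx) {
  vapply(tx, function(t) substr(frame$seq, t[1], t[2]), character(1))
}

#' Define the seven regions around a cassette exon
#'
#' C1/A/C2 are the three exons; I1a/I1b are the donor-proximal and
#' acceptor-proximal windows of the upstream intron and I2a/I2b the same for
#' the downstream intron.  Each intronic window extends at most
#' `intronWindow` nt; short introns are split at the midpoint (the
#' donor-proximal window gets the floor) so the two windows never overlap.
#'
#' @param triplet an [ExonTriplet-class].  With genomic coordinates, `genome`
#'   must be supplied so intronic sequence can be fetched; a sequence-only
#'   triplet yields just the three exonic regions.
#' @param genome `DNAStringSet` from [readGenome()].
#' @param intronWindow maximal intronic window width in nt (default 300, the
#'   convention of the splicing-code feature sets; exposed as a knob).
#' @return a [RegionSet-class]; sequences are in transcription orientation.
#' @export
defineRegions <- function(triplet, genome = NULL, intronWindow = 300L) {
  if (!hasCoordinates(triplet)) {
    sq <- triplet@seqs
    names(sq) <- c("C1", "A", "C2")
    return(new("RegionSet", ranges = GenomicRanges::GRanges(), seqs = sq,
               flags = list(sequence_only = TRUE)))
  }
  if (is.null(genome))
    stop("genome is required to define intronic regions from coordinates")
  fr <- tripletFrame(triplet, genome)
  tx <- tryCatch(regionTxWindows(fr, intronWindow), error = function(e)
    stop("intron shorter than 2 nt in triplet '", triplet@tripletId, "'"))
  ranges <- do.call(c, unname(lapply(tx, function(t)
    txToGenomic(fr, t[1], t[2]))))
  names(ranges) <- names(tx)
  seqs <- Biostrings::DNAStringSet(regionTxSeqs(fr, tx))
  wOf <- function(t) t[2] - t[1] + 1L
  flags <- list(
    i1_truncated = wOf(tx$I1a) < intronWindow || wOf(tx$I1b) < intronWindow,
    i2_truncated = wOf(tx$I2a) < intronWindow || wOf(tx$I2b) < intronWindow
  )
  new("RegionSet", ranges = ranges, seqs = seqs, flags = flags)
}

# normalise a motif argument to an IUPAC pattern string (DNA alphabet)
motifPattern <- function(motif) {
  p <- if (is.character(motif)) motif
       else if (is.list(motif)) motif$pattern
       else stop("motif must be a pattern string or a motif definition")
  gsub("U", "T", toupper(p), fixed = TRUE)
}

#' Find IUPAC motif occurrences in a sequence
#'
#' All (possibly overlapping) start positions are reported.  `N` in the
#' sequence matches nothing; IUPAC ambiguity codes in the pattern match their
#' base sets.
#'
#' @param seq DNA sequence (character or `DNAString`); `N` allowed.
#' @param motif an IUPAC pattern string (U accepted) or a motif definition
#'   with a `pattern` element.
#' @return `motifPositions`: integer vector of 1-based start positions.
#' @export
motifPositions <- function(seq, motif) {
  pattern <- motifPattern(motif)
  pchars <- strsplit(pattern, "")[[1]]
  schars <- strsplit(toupper(as.character(seq)), "")[[1]]
  L <- length(pchars)
  n <- length(schars)
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    allowed <- IUPAC_SETS[[pchars[j]]]
    if (is.null(allowed)) stop("invalid IUPAC code in pattern: ", pchars[j])
    ok <- ok & (schars[seq.int(j, n - L + j)] %in% allowed)
  }
  which(ok)
}

#' @rdname motifPositions
#' @return `countMotif`: the number of occurrences.
#' @examples
#' countMotif("TGCATGCATG", "TGCATG")  # 2, overlap counted
#' @export
countMotif <- function(seq, motif) {
  length(motifPositions(seq, motif))
}

#' Score a splice site against a position weight matrix
#'
#' The log-odds score in bits: the sum over positions of
#' `log2(p_base / 0.25)` with epsilon-smoothed column probabilities
#' (`p' = (p + eps) / (1 + 4 eps)`).  `N` positions contribute 0.
#'
#' @param siteSeq sequence whose length equals the PWM width.
#' @param pwm 4-row matrix (rows A, C, G, T), columns summing to 1.
#' @param eps smoothing constant (default 1e-3).
#' @return log-odds score in bits.
#' @export
scoreSpliceSite <- function(siteSeq, pwm, eps = 1e-3) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 4L)
  if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
  ch <- strsplit(toupper(as.character(siteSeq)), "")[[1]]
  if (length(ch) != ncol(pwm))
    stop(sprintf("site length %d does not match PWM width %d",
                 length(ch), ncol(pwm)))
  sm <- (pwm + eps) / (1 + 4 * eps)
  score <- 0
  for (j in seq_along(ch)) {
    if (ch[j] %in% rownames(sm))
      score <- score + log2(sm[ch[j], j] / 0.25)
  }
  unname(score)
}

#' Distance to the first upstream AG from the 3' splice site
#'
#' The input is the acceptor-proximal intronic window whose last two bases
#' are the 3' splice-site AG.  The returned distance is from the start of
#' that AG to the start of the nearest upstream AG dinucleotide.  When no
#' upstream AG exists within the window (or the window is shorter than 4 nt)
#' the censored value `length(seq) - 1` (the maximal distance + 1) is
#' returned.
#'
#' @param i1bSeq acceptor-proximal window of the upstream intron, ending at
#'   the intron's last base.
#' @return integer distance in nt (censored as described).
#' @examples
#' firstUpstreamAgDistance("TTAGAG")  # 2
#' firstUpstreamAgDistance("TTTTAG")  # censored: 5
#' @export
firstUpstreamAgDistance <- function(i1bSeq) {
  s <- toupper(as.character(i1bSeq))
  n <- nchar(s)
  if (n < 4L) return(max(n - 1L, 0L))
  ch <- strsplit(s, "")[[1]]
  for (p in seq.int(n - 3L, 1L)) {
    if (ch[p] == "A" && ch[p + 1L] == "G") return((n - 1L) - p)
  }
  n - 1L
}

#' Mono-, di- and tri-nucleotide composition
#'
#' Frequencies of all 4 + 16 + 64 k-mers (k = 1, 2, 3); windows containing
#' `N` are skipped and each k-mer family sums to 1 over the remaining
#' windows.  An all-`N` (or too short) sequence yields a zero vector with
#' attribute `degenerate = TRUE`.
#'
#' @param seq DNA sequence of length >= 3.
#' @return named numeric of length 84 (`mono_A` ... `tri_TTT`).
#' @export
ntComposition <- function(seq) {
  s <- toupper(as.character(seq))
  out <- numeric(0)
  degenerate <- FALSE
  for (k in 1:3) {
    kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
    fam <- c("mono", "di", "tri")[k]
    n <- nchar(s)
    counts <- stats::setNames(numeric(length(kmers)), kmers)
    if (n >= k) {
      windows <- substring(s, seq_len(n - k + 1L), seq.int(k, n))
      windows <- windows[windows %in% kmers]  # drops windows containing N
      if (length(windows)) {
        tab <- table(factor(windows, levels = kmers))
        counts <- as.numeric(tab) / sum(tab)
        names(counts) <- kmers
      } else degenerate <- TRUE
    } else degenerate <- TRUE
    names(counts) <- paste0(fam, "_", kmers)
    out <- c(out, counts)
  }
  attr(out, "degenerate") <- degenerate
  out
}

# per-base values of a bedGraph-style track over one genomic range;
# positions not covered by the track are 0
trackValues <- function(track, gr) {
  n <- BiocGenerics::width(gr)
  vals <- numeric(n)
  hit <- GenomicRanges::findOverlaps(track, gr, ignore.strand = TRUE)
  for (k in seq_along(hit)) {
    t <- S4Vectors::queryHits(hit)[k]
    lo <- max(BiocGenerics::start(track)[t], BiocGenerics::start(gr))
    hi <- min(BiocGenerics::end(track)[t], BiocGenerics::end(gr))
    vals[(lo - BiocGenerics::start(gr) + 1L):(hi - BiocGenerics::start(gr) + 1L)] <-
      track$score[t]
  }
  vals
}

#' Windowed nucleosome-occupancy features
#'
#' Average and maximal track values in the exon-proximal first 100 nt of each
#' intron, the first and last 50 nt of the alternative exon, and over each
#' full pair of intronic windows: 12 values.  Regions shorter than the
#' requested window are used in full and flagged.
#'
#' @param track `GRanges` with a `score` column (e.g. from [loadTrack()]);
#'   positions it does not cover count as 0.
#' @param regions a [RegionSet-class] with genomic coordinates.
#' @param prefix feature-name prefix (default `"nuc"`; accessibility tracks
#'   use `"acc"`).
#' @return named numeric of length 12 with attribute `truncated` naming any
#'   shortened windows.
#' @export
nucleosomeFeatures <- function(track, regions, prefix = "nuc") {
  rng <- regions@ranges
  if (!length(rng))
    stop("track features require a RegionSet with genomic coordinates")
  truncated <- character(0)
  subwin <- function(gr, n, fix) {
    if (BiocGenerics::width(gr) < n) {
      truncated <<- c(truncated, paste0(names(gr), ".", fix))
      gr
    } else GenomicRanges::resize(gr, n, fix = fix)
  }
  wins <- list(
    I1prox = subwin(rng["I1b"], 100L, "end"),     # abuts the A acceptor
    I2prox = subwin(rng["I2a"], 100L, "start"),   # abuts the A donor
    Afirst50 = subwin(rng["A"], 50L, "start"),
    Alast50 = subwin(rng["A"], 50L, "end"),
    I1 = NULL, I2 = NULL
  )
  vals <- list()
  for (nm in c("I1prox", "I2prox", "Afirst50", "Alast50"))
    vals[[nm]] <- trackValues(track, wins[[nm]])
  vals$I1 <- c(trackValues(track, rng["I1a"]), trackValues(track, rng["I1b"]))
  vals$I2 <- c(trackValues(track, rng["I2a"]), trackValues(track, rng["I2b"]))
  out <- unlist(lapply(vals, function(v) c(mean = mean(v), max = max(v))))
  names(out) <- paste0(prefix, "_", sub("\\.", "_", names(out)))
  attr(out, "truncated") <- truncated
  out
}

#' Build a feature schema
#'
#' A schema is an ordered table of feature names, one of the families
#' `motif_count`, `splice_site`, `length`, `ag_dist`, `composition`,
#' `nucleosome`, `track_summary`, and the region each feature is computed in.
#' Motif-count features are emitted only for each motif's allowed regions.
#'
#' @param motifLib a [MotifLibrary-class] (needed for `motif_count`).
#' @param families which feature families to include, in order.
#' @param compositionRegions regions whose composition is included.
#' @param compositionK which k-mer sizes (subset of 1:3) to include.
#' @return data.frame with columns `name`, `family`, `region`.
#' @export
buildFeatureSchema <- function(motifLib = NULL,
                               families = c("motif_count", "splice_site",
                                            "length", "ag_dist"),
                               compositionRegions = c("A", "I1a", "I1b",
                                                      "I2a", "I2b"),
                               compositionK = 1:3) {
  rows <- list()
  add <- function(name, family, region)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, family = family,
                                             region = region,
                                             stringsAsFactors = FALSE)
  for (fam in families) {
    switch(fam,
      motif_count = {
        if (is.null(motifLib))
          stop("motif_count features require a motif library")
        d <- motifLib@defs
        for (i in seq_len(nrow(d)))
          for (rg in d$allowed_regions[[i]])
            add(paste0("motif_", d$motif_id[i], "_", rg), "motif_count", rg)
      },
      splice_site = {
        add("ss_donor_C1", "splice_site", "C1")
        add("ss_acceptor_A", "splice_site", "A")
        add("ss_donor_A", "splice_site", "A")
        add("ss_acceptor_C2", "splice_site", "C2")
      },
      length = {
        for (rg in c("C1", "A", "C2", "I1", "I2"))
          add(paste0("len_", rg), "length", rg)
      },
      ag_dist = add("first_ag_dist", "ag_dist", "I1b"),
      composition = {
        fams <- c("mono", "di", "tri")[compositionK]
        km <- lapply(compositionK, function(k)
          Biostrings::mkAllStrings(c("A", "C", "G", "T"), k))
        for (rg in compositionRegions)
          for (j in seq_along(km))
            for (w in km[[j]])
              add(paste0("comp_", rg, "_", fams[j], "_", w), "composition", rg)
      },
      nucleosome = {
        for (w in c("I1prox", "I2prox", "Afirst50", "Alast50", "I1", "I2"))
          for (s in c("mean", "max"))
            add(paste0("nuc_", w, "_", s), "nucleosome", w)
      },
      track_summary = {
        for (w in c("I1prox", "I2prox", "Afirst50", "Alast50", "I1", "I2"))
          for (s in c("mean", "max"))
            add(paste0("acc_", w, "_", s), "track_summary", w)
      },
      stop("unknown feature family: ", fam)
    )
  }
  do.call(rbind, rows)
}

# splice-site window sequences (transcription orientation) for one triplet
spliceSiteSeqs <- function(frame, donorWidth = 9L, acceptorWidth = 23L) {
  seg <- frame$seg
  donorEx <- 3L; donorIn <- donorWidth - 3L
  accIn <- acceptorWidth - 3L; accEx <- 3L
  sub <- function(t1, t2) substr(frame$seq, t1, t2)
  c(ss_donor_C1 = sub(seg["ends", "C1"] - donorEx + 1L,
                      seg["ends", "C1"] + donorIn),
    ss_acceptor_A = sub(seg["starts", "A"] - accIn,
                        seg["starts", "A"] + accEx - 1L),
    ss_donor_A = sub(seg["ends", "A"] - donorEx + 1L,
                     seg["ends", "A"] + donorIn),
    ss_acceptor_C2 = sub(seg["starts", "C2"] - accIn,
                         seg["starts", "C2"] + accEx - 1L))
}

#' Estimate donor and acceptor PWMs from a triplet database
#'
#' Column probability matrices are estimated (with a +1 pseudocount) from the
#' donor (-3..+6, width 9) and acceptor (-20..+3, width 23) windows of the
#' constitutive junctions in the database, keeping the tool self-contained
#' when no external PWMs are supplied.
#'
#' @param db a [TripletDB-class] with coordinates.
#' @param genome `DNAStringSet`.
#' @param donorWidth,acceptorWidth window widths in nt.
#' @return list with matrices `donor` and `acceptor`.
#' @export
estimatePWMs <- function(db, genome, donorWidth = 9L, acceptorWidth = 23L) {
  use <- which(tripletLabel(db) == "constitutive")
  if (!length(use)) use <- seq_len(length(db))
  donors <- character(0); acceptors <- character(0)
  for (i in use) {
    fr <- tripletFrame(db[[i]], genome)
    ss <- spliceSiteSeqs(fr, donorWidth, acceptorWidth)
    donors <- c(donors, ss[c("ss_donor_C1", "ss_donor_A")])
    acceptors <- c(acceptors, ss[c("ss_acceptor_A", "ss_acceptor_C2")])
  }
  count <- function(seqs, width) {
    m <- matrix(1, nrow = 4, ncol = width,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    for (s in seqs) {
      ch <- strsplit(s, "")[[1]]
      for (j in seq_len(width))
        if (ch[j] %in% rownames(m)) m[ch[j], j] <- m[ch[j], j] + 1
    }
    sweep(m, 2, colSums(m), "/")
  }
  list(donor = count(donors, donorWidth),
       acceptor = count(acceptors, acceptorWidth))
}

#' Extract the regulatory feature vector of a triplet
#'
#' Deterministically assembles the features named by `schema`: per-region
#' motif occurrence counts, splice-site PWM log-odds scores (C1 donor, A
#' acceptor, A donor, C2 acceptor), log10 lengths of the three exons and two
#' introns, the first-upstream-AG distance, per-region nucleotide
#' composition, and windowed summaries of nucleosome-occupancy or
#' accessibility tracks.
#'
#' @param triplet an [ExonTriplet-class] with genomic coordinates.
#' @param schema from [buildFeatureSchema()].
#' @param genome `DNAStringSet`.
#' @param motifLib [MotifLibrary-class] (required for motif features).
#' @param pwms list with `donor`/`acceptor` matrices (required for
#'   splice-site features), e.g. from [estimatePWMs()].
#' @param nucTrack,accTrack optional per-base `GRanges` tracks.
#' @param intronWindow passed to [defineRegions()].
#' @return named numeric vector in schema order.
#' @export
extractFeatures <- function(triplet, schema, genome = NULL, motifLib = NULL,
                            pwms = NULL, nucTrack = NULL, accTrack = NULL,
                            intronWindow = 300L) {
  fams <- unique(schema$family)
  missing <- character(0)
  if ("motif_count" %in% fams && is.null(motifLib))
    missing <- c(missing, "motifLib (motif_count features)")
  if ("splice_site" %in% fams && is.null(pwms))
    missing <- c(missing, "pwms (splice_site features)")
  if ("nucleosome" %in% fams && is.null(nucTrack))
    missing <- c(missing, "nucTrack (nucleosome features)")
  if ("track_summary" %in% fams && is.null(accTrack))
    missing <- c(missing, "accTrack (track_summary features)")
  needsGenome <- hasCoordinates(triplet)
  if (needsGenome && is.null(genome))
    missing <- c(missing, "genome (coordinate triplet)")
  if (length(missing))
    stop("missing required inputs: ", paste(missing, collapse = "; "))
  needCoords <- intersect(fams, c("splice_site", "length", "ag_dist",
                                  "nucleosome", "track_summary"))
  if (!hasCoordinates(triplet) && length(needCoords))
    stop("families requiring genomic coordinates for triplet '",
         triplet@tripletId, "': ", paste(needCoords, collapse = ", "))

  if (hasCoordinates(triplet)) {
    fr <- tripletFrame(triplet, genome)
    tx <- regionTxWindows(fr, intronWindow)
    seqs <- regionTxSeqs(fr, tx)
    seg <- fr$seg
  } else {
    if (length(triplet@seqs) != 3L)
      stop("sequence-only extraction needs all three exon sequences")
    seqs <- stats::setNames(as.character(triplet@seqs), c("C1", "A", "C2"))
  }
  regions <- NULL  # GRanges built only for track families
  vals <- stats::setNames(numeric(nrow(schema)), schema$name)
  for (fam in fams) {
    idx <- which(schema$family == fam)
    switch(fam,
      motif_count = {
        d <- motifLib@defs
        pat <- stats::setNames(d$pattern, d$motif_id)
        for (i in idx) {
          nm <- schema$name[i]
          rg <- schema$region[i]
          mid <- sub(paste0("_", rg, "$"), "", sub("^motif_", "", nm))
          if (!rg %in% names(seqs))
            stop("region ", rg, " unavailable for triplet '",
                 triplet@tripletId, "'")
          vals[i] <- countMotif(seqs[[rg]], pat[[mid]])
        }
      },
      splice_site = {
        ss <- spliceSiteSeqs(fr, ncol(pwms$donor), ncol(pwms$acceptor))
        for (i in idx) {
          nm <- schema$name[i]
          pwm <- if (grepl("donor", nm)) pwms$donor else pwms$acceptor
          vals[i] <- scoreSpliceSite(ss[[nm]], pwm)
        }
      },
      length = {
        lens <- c(C1 = seg["ends", "C1"] - seg["starts", "C1"] + 1L,
                  A = seg["ends", "A"] - seg["starts", "A"] + 1L,
                  C2 = seg["ends", "C2"] - seg["starts", "C2"] + 1L,
                  I1 = seg["ends", "I1"] - seg["starts", "I1"] + 1L,
                  I2 = seg["ends", "I2"] - seg["starts", "I2"] + 1L)
        for (i in idx)
          vals[i] <- log10(lens[[schema$region[i]]])
      },
      ag_dist = {
        vals[idx] <- firstUpstreamAgDistance(seqs[["I1b"]])
      },
      composition = {
        for (rg in unique(schema$region[idx])) {
          comp <- ntComposition(seqs[[rg]])
          ri <- idx[schema$region[idx] == rg]
          key <- sub(paste0("^comp_", rg, "_"), "", schema$name[ri])
          vals[ri] <- comp[key]
        }
      },
      nucleosome = {
        if (is.null(regions))
          regions <- defineRegions(triplet, genome, intronWindow)
        nf <- nucleosomeFeatures(nucTrack, regions, prefix = "nuc")
        vals[idx] <- nf[schema$name[idx]]
      },
      track_summary = {
        if (is.null(regions))
          regions <- defineRegions(triplet, genome, intronWindow)
        af <- nucleosomeFeatures(accTrack, regions, prefix = "acc")
        vals[idx] <- af[schema$name[idx]]
      }
    )
  }
  vals
}

#' Extract the feature matrix of a triplet database
#'
#' @param db a [TripletDB-class].
#' @param ... passed to [extractFeatures()] (schema, genome, motifLib, ...).
#' @return numeric matrix, one row per triplet (rownames = triplet ids).
#' @export
extractFeatureMatrix <- function(db, ...) {
  rows <- lapply(db@triplets, extractFeatures, ...)
  m <- do.call(rbind, rows)
  rownames(m) <- tripletId(db)
  m
}
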