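#' @include AllClasses.R constructors.R formats-io.R
NULL

# shared k-mer seed count between two sequences
sharedSeeds <- function(a, b, k = 8L) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) < k || nchar(b) < k) return(0L)
  ka <- unique(substring(a, seq_len(nchar(a) - k + 1L), seq.int(k, nchar(a))))
  kb <- unique(substring(b, seq_len(nchar(b) - k + 1L), seq.int(k, nchar(b))))
  length(intersect(ka, kb))
}

#' Seed-and-extend sequence identity
#'
#' Shared k-mer seeds anchor the comparison; the extension is a global
#' (gapped) alignment whose identity — matches over aligned columns — is
#' returned.  Symmetric in its arguments.  Together with the thresholds in
#' [matchQuery()] (k = 8, at least 2 seeds, identity >= 0.88) this
#' re-expresses the external aligner settings the matching procedure was
#' designed around (tileSize 8, minMatch 2, minIdentity 88).
#'
#' @param querySeq,targetSeq non-empty DNA sequences.
#' @param k seed length (default 8).
#' @return list with `identity` in `[0, 1]` and `nSeeds`.
#' @export
seedExtendIdentity <- function(querySeq, targetSeq, k = 8L) {
  a <- toupper(as.character(querySeq)); b <- toupper(as.character(targetSeq))
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global")
  ncols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  list(identity = Biostrings::nmatch(aln) / ncols,
       nSeeds = sharedSeeds(a, b, k))
}

# exact / reciprocal-overlap coordinate lookup of one exon against a set
.coordMatches <- function(query, targets, minReciprocal = 0.9) {
  if (!length(targets)) return(integer(0))
  hits <- GenomicRanges::findOverlaps(query, targets)
  keep <- vapply(seq_along(hits), function(h) {
    t <- targets[S4Vectors::subjectHits(hits)[h]]
    ov <- BiocGenerics::width(GenomicRanges::pintersect(query, t))
    ov / BiocGenerics::width(query) >= minReciprocal &&
      ov / BiocGenerics::width(t) >= minReciprocal
  }, logical(1))
  S4Vectors::subjectHits(hits)[keep]
}

#' Match a query exon or triplet against a triplet database and genome
#'
#' Coordinate queries are matched by interval lookup first (an exon counts as
#' a database exon at >= 90% reciprocal overlap).  Sequence queries are
#' matched by seed-and-extend: every exon needs at least `minSeeds` shared
#' `tileSize`-mers and alignment identity >= `minIdentity` against the
#' database record.  A genome search runs only when no database match is
#' found and coordinates for all three exons were given.  Ties are broken by
#' highest identity, then lexicographically smallest triplet id.
#'
#' @param query an [ExonTriplet-class] (coordinates and/or sequences).  A
#'   single-exon query is given as a triplet whose flanks are to be resolved
#'   from the database: pass `singleExon = TRUE` and a query with only the A
#'   sequence/coordinates via [queryExon()].
#' @param db a [TripletDB-class].
#' @param genome optional `DNAStringSet` for the genome fallback.
#' @param tileSize seed length (default 8).
#' @param minSeeds minimum shared seeds per exon (default 2).
#' @param minIdentity minimum alignment identity (default 0.88).
#' @param minReciprocal reciprocal-overlap fraction for coordinate matches.
#' @return a list (MatchResult) with `status` (`known_cassette`,
#'   `known_constitutive`, `genome_matched`, `unmatched`), `triplet`,
#'   `identity`, `db_triplet_id`, `ambiguous` and `reason`.
#' @export
matchQuery <- function(query, db, genome = NULL, tileSize = 8L,
                       minSeeds = 2L, minIdentity = 0.88,
                       minReciprocal = 0.9) {
  if (length(query@seqs) &&
      any(BiocGenerics::width(query@seqs) < 10L) ||
      (hasCoordinates(query) && any(BiocGenerics::width(query@exons) < 10L)))
    stop("query exons must be at least 10 nt long")
  statusOf <- function(tr)
    switch(tr@label, cassette = "known_cassette",
           constitutive = "known_constitutive", "known_constitutive")
  unmatched <- function(reason)
    list(status = "unmatched", triplet = NULL, identity = NA_real_,
         db_triplet_id = NA_character_, ambiguous = FALSE, reason = reason)

  # 1. coordinate lookup
  if (hasCoordinates(query)) {
    qx <- query@exons
    for (i in seq_len(length(db))) {
      tr <- db[[i]]
      if (!hasCoordinates(tr)) next
      tx <- tr@exons
      if (as.character(GenomicRanges::seqnames(tx))[1] !=
          as.character(GenomicRanges::seqnames(qx))[1] ||
          as.character(BiocGenerics::strand(tx))[1] !=
          as.character(BiocGenerics::strand(qx))[1]) next
      ok <- all(vapply(1:3, function(e)
        length(.coordMatches(qx[e], tx[e], minReciprocal)) > 0L, logical(1)))
      if (ok)
        return(list(status = statusOf(tr), triplet = tr, identity = 1.0,
                    db_triplet_id = tr@tripletId, ambiguous = FALSE,
                    reason = "coordinate_match"))
    }
  }

  # 2. sequence seed-and-extend against the database
  qseqs <- if (length(query@seqs)) query@seqs
           else if (!is.null(genome)) fetchGRanges(genome, query@exons)
           else NULL
  if (!is.null(qseqs)) {
    singleExon <- length(qseqs) == 1L
    cand <- list()
    for (i in seq_len(length(db))) {
      tr <- db[[i]]
      if (!length(tr@seqs)) next
      exonsToCheck <- if (singleExon) "A" else c("C1", "A", "C2")
      idents <- vapply(exonsToCheck, function(e) {
        q <- if (singleExon) qseqs[[1L]] else qseqs[[e]]
        r <- seedExtendIdentity(q, tr@seqs[[e]], k = tileSize)
        if (r$nSeeds < min(minSeeds,
                           nchar(as.character(q)) - tileSize + 1L)) -1
        else r$identity
      }, numeric(1))
      if (all(idents >= minIdentity))
        cand[[length(cand) + 1L]] <- list(id = tr@tripletId,
                                          identity = mean(idents), tr = tr)
    }
    if (length(cand)) {
      ids <- vapply(cand, `[[`, character(1), "id")
      idn <- vapply(cand, `[[`, numeric(1), "identity")
      ord <- order(-idn, ids)
      best <- cand[[ord[1L]]]
      return(list(status = statusOf(best$tr), triplet = best$tr,
                  identity = best$identity, db_triplet_id = best$id,
                  ambiguous = length(cand) > 1L, reason = "sequence_match"))
    }
    if (singleExon)
      return(unmatched("single_exon_no_db_hit"))
  }

  # 3. genome fallback: only when coordinates for all three exons are given
  if (hasCoordinates(query) && !is.null(genome)) {
    seqs <- tryCatch(fetchGRanges(genome, query@exons), error = function(e) NULL)
    if (!is.null(seqs)) {
      tr <- query
      tr@seqs <- seqs
      names(tr@seqs) <- c("C1", "A", "C2")
      return(list(status = "genome_matched", triplet = tr, identity = 1.0,
                  db_triplet_id = NA_character_, ambiguous = FALSE,
                  reason = "genome_match"))
    }
    return(unmatched("coordinates_outside_genome"))
  }
  unmatched(if (hasCoordinates(query)) "no_genome_for_fallback"
            else "no_db_match")
}

#' Build a single-exon query
#'
#' Wraps one exon (sequence and/or coordinates) so it can be matched against
#' a database that resolves the flanking exons.  When several database
#' triplets disagree about the flanks, the highest-identity one is returned
#' and flagged ambiguous.
#'
#' @param id query id.
#' @param seq exon sequence (optional).
#' @param range `GRanges` of length 1 (optional).
#' @return an object accepted by [matchQuery()].
#' @export
queryExon <- function(id, seq = NULL, range = NULL) {
  q <- new("ExonTriplet", tripletId = as.character(id),
           geneId = NA_character_, label = NA_character_,
           exons = if (is.null(range)) GenomicRanges::GRanges() else range,
           seqs = if (is.null(seq)) Biostrings::DNAStringSet()
                  else {
                    s <- Biostrings::DNAStringSet(seq)
                    names(s) <- "A"
                    s
                  })
  q
}
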