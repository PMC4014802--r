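#' @include AllClasses.R constructors.R
NULL

#' Read a genome FASTA into an indexed sequence store
#'
#' @param path FASTA file with unique record names (names are truncated at
#'   the first whitespace).
#' @return a `DNAStringSet` usable with [fetchSeq()].
#' @export
readGenome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    stop("duplicate record names in genome FASTA: ", path)
  genome
}

#' Fetch a genomic subsequence
#'
#' Coordinates are BED-style 0-based half-open.  Minus-strand fetches return
#' the reverse complement (the sense-strand sequence of a minus-strand
#' feature).
#'
#' @param genome `DNAStringSet` from [readGenome()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return a character string of length `end - start`.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AACGG"))
#' fetchSeq(g, "chr1", 1, 3, "-")  # revcomp("AC") = "GT"
#' @export
fetchSeq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome))
    stop("chromosome not found in genome: ", chrom)
  if (start < 0 || end <= start)
    stop("invalid interval: start must satisfy 0 <= start < end")
  if (end > length(genome[[chrom]]))
    stop(sprintf("interval %d-%d out of range for %s (length %d)",
                 start, end, chrom, length(genome[[chrom]])))
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

# fetch sense-strand sequences for a GRanges (1-based, strand-aware)
fetchGRanges <- function(genome, gr) {
  out <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
    fetchSeq(genome, as.character(GenomicRanges::seqnames(gr))[i],
             BiocGenerics::start(gr)[i] - 1L, BiocGenerics::end(gr)[i],
             as.character(BiocGenerics::strand(gr))[i])
  }, character(1)))
  names(out) <- names(gr)
  out
}

#' Read and write motif libraries
#'
#' The library is a TSV with columns `motif_id`, `pattern` (IUPAC; U is
#' accepted and normalised to T), `rbp_name`, `allowed_regions`
#' (pipe-separated subset of C1,I1a,I1b,A,I2a,I2b,C2) and `group`
#' (`code_model` or `general_splicing`).
#'
#' @param path TSV file.
#' @return `loadMotifLibrary`: a [MotifLibrary-class].
#' @export
loadMotifLibrary <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("motif_id", "pattern", "rbp_name", "allowed_regions", "group")
  if (!all(need %in% names(d)))
    stop("motif library must have columns: ", paste(need, collapse = ", "))
  pat <- toupper(d$pattern)
  pat <- gsub("U", "T", pat, fixed = TRUE)
  for (i in seq_along(pat)) {
    ch <- strsplit(pat[i], "")[[1]]
    bad <- setdiff(ch, names(IUPAC_SETS))
    if (length(ch) == 0L || length(bad))
      stop(sprintf("row %d (motif '%s'): invalid IUPAC character(s) %s",
                   i, d$motif_id[i], paste(bad, collapse = "")))
  }
  defs <- data.frame(motif_id = d$motif_id, pattern = pat,
                     rbp_name = d$rbp_name, group = d$group,
                     stringsAsFactors = FALSE)
  defs$allowed_regions <- strsplit(d$allowed_regions, "|", fixed = TRUE)
  new("MotifLibrary", defs = defs)
}

#' @rdname loadMotifLibrary
#' @param lib a [MotifLibrary-class].
#' @return `writeMotifLibrary`: the path, invisibly.
#' @export
writeMotifLibrary <- function(lib, path) {
  d <- lib@defs
  out <- data.frame(motif_id = d$motif_id, pattern = d$pattern,
                    rbp_name = d$rbp_name,
                    allowed_regions = vapply(d$allowed_regions, paste,
                                             character(1), collapse = "|"),
                    group = d$group, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The default code-model motif library
#'
#' A compact library of IUPAC motifs for RNA-binding proteins of the
#' splicing-code literature (Fox-1/2, Quaking, Ptb1/2, Nova, Mbnl1/2,
#' Cugbp1/2, hnRNP and SR families), shipped with the package.
#'
#' @return a [MotifLibrary-class].
#' @export
defaultMotifLibrary <- function() {
  loadMotifLibrary(system.file("extdata", "motif_library.tsv",
                               package = "splicecode", mustWork = TRUE))
}

#' Read and write exon-by-experiment expression tables
#'
#' The on-disk format is a TSV whose first column is `exon_id` and whose
#' remaining headers are experiment ids formatted `tissue.replicate`
#' (e.g. `brain.1`).  Empty cells are missing data.  Exon ids of the form
#' `tripletID:up|mid|dn` carry the triplet linkage into `rowData`.
#'
#' @param path TSV file.
#' @return `loadExpressionTable`: a `SummarizedExperiment` with assay
#'   `"expr"`, `colData` columns `tissue` and `replicate`, and (when ids are
#'   linked) `rowData` columns `triplet_id` and `role`.
#' @export
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
loadExpressionTable <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", blank.lines.skip = TRUE,
                            quote = "")
  if (length(unique(nf)) != 1L)
    stop("ragged rows in expression table: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = c("character", rep("numeric", nf[1] - 1L)))
  ids <- d[[1]]
  if (anyDuplicated(ids)) stop("duplicate exon_id in expression table")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- ids
  exps <- colnames(m)
  cd <- S4Vectors::DataFrame(
    tissue = sub("\\.[^.]*$", "", exps),
    replicate = sub("^.*\\.", "", exps),
    row.names = exps
  )
  linked <- grepl("^.+:(up|mid|dn)$", ids)
  rd <- if (all(linked) && length(ids)) {
    S4Vectors::DataFrame(
      triplet_id = sub(":[^:]*$", "", ids),
      role = sub("^.*:", "", ids),
      row.names = ids
    )
  } else S4Vectors::DataFrame(row.names = ids)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = m), colData = cd, rowData = rd
  )
}

#' @rdname loadExpressionTable
#' @param se a `SummarizedExperiment` as returned by `loadExpressionTable`.
#' @return `writeExpressionTable`: the path, invisibly.
#' @export
writeExpressionTable <- function(se, path) {
  m <- SummarizedExperiment::assay(se, "expr")
  txt <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  txt[is.na(m)] <- ""
  out <- cbind(exon_id = rownames(m), as.data.frame(txt, stringsAsFactors = FALSE))
  names(out) <- c("exon_id", colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write BED6 records
#'
#' Coordinates are written 0-based half-open (BED convention); internal
#' `GRanges` (1-based closed) are converted.  Scores are clamped to the BED
#' 0-1000 integer range.
#'
#' @param x a `GRanges` with metadata columns `name` and `score`, or a
#'   data.frame with columns `chrom`, `start`, `end` (already 0-based
#'   half-open), `name`, `score`, `strand`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeBed <- function(x, path) {
  if (is(x, "GRanges")) {
    x <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(x)),
      start = BiocGenerics::start(x) - 1L,
      end = BiocGenerics::end(x),
      name = if (!is.null(x$name)) x$name else ".",
      score = if (!is.null(x$score)) x$score else 0L,
      strand = as.character(BiocGenerics::strand(x)),
      stringsAsFactors = FALSE
    )
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(x)) {
    score <- pmin(1000L, pmax(0L, as.integer(round(x$score))))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", x$chrom, as.integer(x$start),
                       as.integer(x$end), x$name, score, x$strand), con)
  }
  invisible(path)
}

#' Read and write triplet databases
#'
#' The on-disk format is a TSV with one row per triplet: id, label, gene,
#' chromosome, strand, the three exon intervals in transcription order
#' (0-based half-open, empty when the triplet is sequence-only) and the three
#' exon sequences (sense strand).
#'
#' @param path TSV file.
#' @return `readTripletDB`: a [TripletDB-class].
#' @export
readTripletDB <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  triplets <- lapply(seq_len(nrow(d)), function(i) {
    r <- d[i, ]
    exons <- NULL
    if (nzchar(r$chrom)) {
      starts <- as.integer(c(r$c1_start, r$a_start, r$c2_start)) + 1L
      ends <- as.integer(c(r$c1_end, r$a_end, r$c2_end))
      exons <- GenomicRanges::GRanges(r$chrom,
        IRanges::IRanges(start = starts, end = ends), strand = r$strand)
    }
    seqs <- if (nzchar(r$c1_seq)) c(r$c1_seq, r$a_seq, r$c2_seq) else NULL
    ExonTriplet(r$triplet_id, exons = exons, seqs = seqs,
                geneId = if (nzchar(r$gene_id)) r$gene_id else NA_character_,
                label = if (nzchar(r$label)) r$label else NA_character_)
  })
  TripletDB(triplets)
}

#' @rdname readTripletDB
#' @param db a [TripletDB-class].
#' @return `writeTripletDB`: the path, invisibly.
#' @export
writeTripletDB <- function(db, path) {
  rows <- lapply(db@triplets, function(tr) {
    hasco <- hasCoordinates(tr)
    ex <- tr@exons
    sq <- tr@seqs
    data.frame(
      triplet_id = tr@tripletId,
      label = if (is.na(tr@label)) "" else tr@label,
      gene_id = if (is.na(tr@geneId)) "" else tr@geneId,
      chrom = if (hasco) as.character(GenomicRanges::seqnames(ex))[1] else "",
      strand = if (hasco) as.character(BiocGenerics::strand(ex))[1] else "",
      c1_start = if (hasco) BiocGenerics::start(ex)[1] - 1L else "",
      c1_end = if (hasco) BiocGenerics::end(ex)[1] else "",
      a_start = if (hasco) BiocGenerics::start(ex)[2] - 1L else "",
      a_end = if (hasco) BiocGenerics::end(ex)[2] else "",
      c2_start = if (hasco) BiocGenerics::start(ex)[3] - 1L else "",
      c2_end = if (hasco) BiocGenerics::end(ex)[3] else "",
      c1_seq = if (length(sq)) as.character(sq[["C1"]]) else "",
      a_seq = if (length(sq)) as.character(sq[["A"]]) else "",
      c2_seq = if (length(sq)) as.character(sq[["C2"]]) else "",
      stringsAsFactors = FALSE
    )
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Import exon triplets from a GFF3 file
#'
#' Exon features (1-based closed, converted to the internal `GRanges`
#' representation) are grouped into triplets by their `Parent` attribute
#' (or `triplet_id` when present).  Each group must contain exactly three
#' exons on one strand.
#'
#' @param path GFF3 file.
#' @param genome optional `DNAStringSet`; when given, exon sequences are
#'   attached.
#' @return a [TripletDB-class].
#' @export
importTripletsGFF <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  key <- if (!is.null(gr$triplet_id)) as.character(gr$triplet_id)
         else vapply(gr$Parent, function(p) as.character(p)[1], character(1))
  triplets <- lapply(split(seq_along(gr), key), function(idx) {
    ex <- gr[idx]
    if (length(ex) != 3L)
      stop("triplet '", key[idx[1]], "' must have exactly 3 exons, has ",
           length(ex))
    tr <- ExonTriplet(key[idx[1]], exons = GenomicRanges::granges(ex),
                      geneId = if (!is.null(ex$gene_id))
                        as.character(ex$gene_id)[1] else NA_character_)
    if (!is.null(genome)) tr@seqs <- fetchGRanges(genome, tr@exons)
    tr
  })
  TripletDB(triplets[order(names(triplets))])
}

#' Export a TripletDB's exon coordinates as GFF3
#'
#' @param db a [TripletDB-class] with coordinates.
#' @param path output GFF3 file.
#' @return the path, invisibly.
#' @export
exportTripletsGFF <- function(db, path) {
  grl <- lapply(db@triplets, function(tr) {
    ex <- tr@exons
    ex$type <- "exon"
    ex$triplet_id <- tr@tripletId
    ex$gene_id <- tr@geneId
    ex$ID <- paste0(tr@tripletId, ":", names(ex))
    names(ex) <- NULL
    ex
  })
  gr <- suppressWarnings(do.call(c, grl))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Load a per-base track from a bedGraph file
#'
#' @param path bedGraph file (0-based half-open intervals with a value
#'   column).
#' @return a `GRanges` with a `score` metadata column.
#' @export
loadTrack <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Write a per-base track to a bedGraph file
#'
#' @param track `GRanges` with `score`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTrack <- function(track, path) {
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(track)),
                  start = BiocGenerics::start(track) - 1L,
                  end = BiocGenerics::end(track),
                  score = sprintf("%.17g", track$score))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
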