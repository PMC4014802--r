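test_that("fetchSeq honours BED-style coordinates and strand", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTT", chr2 = "AACGG"))
  expect_equal(fetchSeq(g, "chr1", 0, 4, "+"), "ACGT")
  # palindromic prefix: both strands agree
  expect_equal(fetchSeq(g, "chr1", 0, 4, "-"), "ACGT")
  expect_equal(fetchSeq(g, "chr2", 1, 3, "-"), "GT")
  expect_error(fetchSeq(g, "chrX", 0, 4), "not found")
  expect_error(fetchSeq(g, "chr1", 0, 99), "out of range")
  expect_error(fetchSeq(g, "chr1", 3, 3), "invalid interval")
})

test_that("plus-strand fetch equals reverse complement of minus-strand fetch", {
  set.seed(1)
  g <- Biostrings::DNAStringSet(c(chr = paste(
    sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")))
  for (i in 1:25) {
    s <- sample(0:400, 1)
    e <- s + sample(1:80, 1)
    fwd <- fetchSeq(g, "chr", s, e, "+")
    rev <- fetchSeq(g, "chr", s, e, "-")
    expect_equal(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(rev))), fwd)
  }
})

test_that("motif library loading validates IUPAC and normalises U to T", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("motif_id\tpattern\trbp_name\tallowed_regions\tgroup",
               "fox1\tUGCAUG\tFox-1/2\tI2a|I2b\tcode_model",
               "qk\tACTAAY\tQk\tI1b\tcode_model",
               "gr\tGGGG\thnRNP-F/H\tI1a\tgeneral_splicing"), path)
  lib <- loadMotifLibrary(path)
  expect_equal(length(lib), 3L)
  expect_equal(lib@defs$pattern[1], "TGCATG")
  expect_equal(length(lib@defs$allowed_regions[[1]]), 2L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("motif_id\tpattern\trbp_name\tallowed_regions\tgroup",
               "ok\tACGT\tx\tA\tcode_model",
               "weird\tXQ\ty\tA\tcode_model"), bad)
  expect_error(loadMotifLibrary(bad), "row 2")
})

test_that("motif library round-trips exactly", {
  lib <- defaultMotifLibrary()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeMotifLibrary(lib, path)
  lib2 <- loadMotifLibrary(path)
  expect_identical(lib@defs, lib2@defs)
})

test_that("expression tables parse headers, missing cells and linkage", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("exon_id\tbrain.1\tbrain.2\tliver.1",
               "e1\t0.5\t\t-1.25",
               "e2\t1\t2\t3"), path)
  se <- loadExpressionTable(path)
  m <- SummarizedExperiment::assay(se, "expr")
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(sum(is.na(m)), 1L)
  expect_true(is.na(m["e1", "brain.2"]))
  expect_equal(as.character(SummarizedExperiment::colData(se)$tissue),
               c("brain", "brain", "liver"))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("exon_id\tbrain.1", "e1\t1", "e1\t2"), dup)
  expect_error(loadExpressionTable(dup), "duplicate")

  ragged <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("exon_id\tbrain.1\tbrain.2", "e1\t1"), ragged)
  expect_error(loadExpressionTable(ragged), "ragged")
})

test_that("expression tables round-trip exactly, preserving NA", {
  cfg <- smallSimConfig()
  sim <- smallSim()
  se <- generateExpression(cfg, sim$truth)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionTable(se, path)
  se2 <- loadExpressionTable(path)
  expect_identical(SummarizedExperiment::assay(se, "expr"),
                   SummarizedExperiment::assay(se2, "expr"))
  expect_equal(as.character(SummarizedExperiment::rowData(se2)$role),
               as.character(SummarizedExperiment::rowData(se)$role))
})

test_that("writeBed emits BED6 with 0-based half-open coordinates", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start = 6, end = 11),
                               strand = "+", name = "fox1", score = 1000)
  path <- withr::local_tempfile(fileext = ".bed")
  writeBed(gr, path)
  expect_equal(readLines(path), "chr1\t5\t11\tfox1\t1000\t+")

  writeBed(gr[0], path)
  expect_equal(length(readLines(path)), 0L)

  gr2 <- suppressWarnings(c(gr, GenomicRanges::GRanges("chr2",
    IRanges::IRanges(start = 1, end = 4), strand = "-",
    name = "b", score = 250)))
  writeBed(gr2, path)
  expect_equal(readLines(path),
               c("chr1\t5\t11\tfox1\t1000\t+", "chr2\t0\t4\tb\t250\t-"))
})

test_that("triplet databases round-trip exactly", {
  sim <- smallSim()
  db <- sim$db[1:10]
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTripletDB(db, path)
  db2 <- readTripletDB(path)
  expect_equal(tripletId(db2), tripletId(db))
  expect_equal(tripletLabel(db2), tripletLabel(db))
  for (i in 1:10) {
    expect_identical(as.character(exonSeqs(db2[[i]])),
                     as.character(exonSeqs(db[[i]])))
    expect_equal(BiocGenerics::start(exonRanges(db2[[i]])),
                 BiocGenerics::start(exonRanges(db[[i]])))
    expect_equal(as.character(BiocGenerics::strand(exonRanges(db2[[i]]))),
                 as.character(BiocGenerics::strand(exonRanges(db[[i]]))))
  }
})

test_that("GFF3 export/import preserves triplet coordinates", {
  sim <- smallSim()
  db <- sim$db[1:5]
  path <- withr::local_tempfile(fileext = ".gff3")
  exportTripletsGFF(db, path)
  db2 <- importTripletsGFF(path, genome = sim$genome)
  expect_setequal(tripletId(db2), tripletId(db))
  for (id in tripletId(db)) {
    expect_equal(BiocGenerics::start(exonRanges(db2[[id]])),
                 BiocGenerics::start(exonRanges(db[[id]])))
    # sequences fetched from the genome match the stored sense-strand ones
    expect_identical(as.character(exonSeqs(db2[[id]])),
                     as.character(exonSeqs(db[[id]])))
  }
})

test_that("bedGraph tracks round-trip", {
  track <- GenomicRanges::GRanges("chrS",
    IRanges::IRanges(start = c(1, 21), end = c(20, 40)),
    score = c(0.25, 0.75))
  path <- withr::local_tempfile(fileext = ".bedgraph")
  writeTrack(track, path)
  track2 <- loadTrack(path)
  expect_equal(BiocGenerics::start(track2), BiocGenerics::start(track))
  expect_equal(track2$score, track$score)
})
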