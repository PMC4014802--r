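makeTriplet <- function(exonW = c(60L, 80L, 70L), intronL = c(1000L, 1000L),
                        seed = 9L, strand = "+") {
  set.seed(seed)
  n <- sum(exonW) + sum(intronL) + 200L
  seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- "chr1"
  starts <- cumsum(c(101L, exonW[1] + intronL[1], exonW[2] + intronL[2]))
  ends <- starts + exonW - 1L
  list(genome = g,
       triplet = ExonTriplet("t", exons = GenomicRanges::GRanges("chr1",
         IRanges::IRanges(start = starts, end = ends), strand = strand)))
}

test_that("intronic windows follow the 300-nt / midpoint rule", {
  fx <- makeTriplet(intronL = c(1000L, 400L))
  rs <- defineRegions(fx$triplet, fx$genome, intronWindow = 300L)
  rng <- rs@ranges
  ex <- exonRanges(fx$triplet)
  # upstream intron of 1000: I1a = first 300 nt after the C1 donor
  expect_equal(BiocGenerics::start(rng["I1a"]), BiocGenerics::end(ex)[1] + 1L)
  expect_equal(BiocGenerics::width(rng["I1a"]), 300L)
  # I1b = last 300 nt before the A acceptor
  expect_equal(BiocGenerics::end(rng["I1b"]), BiocGenerics::start(ex)[2] - 1L)
  expect_equal(BiocGenerics::width(rng["I1b"]), 300L)
  # downstream intron of 400 splits at the midpoint: adjacent and disjoint
  expect_equal(BiocGenerics::width(rng["I2a"]), 200L)
  expect_equal(BiocGenerics::width(rng["I2b"]), 200L)
  expect_equal(BiocGenerics::start(rng["I2b"]),
               BiocGenerics::end(rng["I2a"]) + 1L)
})

test_that("region tiling holds over random triplet geometries", {
  set.seed(21)
  for (i in 1:100) {
    iL <- sample(60:900, 2)
    fx <- makeTriplet(intronL = iL, seed = i)
    rs <- defineRegions(fx$triplet, fx$genome, intronWindow = 300L)
    rng <- rs@ranges
    ex <- exonRanges(fx$triplet)
    i1 <- IRanges::IRanges(BiocGenerics::end(ex)[1] + 1L,
                           BiocGenerics::start(ex)[2] - 1L)
    for (code in c("I1a", "I1b")) {
      r <- IRanges::ranges(rng[code])
      expect_true(BiocGenerics::start(r) >= BiocGenerics::start(i1) &&
                  BiocGenerics::end(r) <= BiocGenerics::end(i1))
    }
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(rng["I1a"]), IRanges::ranges(rng["I1b"]),
      resolve.empty = "max.start"))
    expect_equal(ov, 0L)
  }
})

test_that("minus-strand regions mirror the plus-strand construction", {
  fx <- mirroredTriplets()
  rsP <- defineRegions(fx$plus$triplet, fx$plus$genome)
  rsM <- defineRegions(fx$minus$triplet, fx$minus$genome)
  expect_identical(as.character(rsP@seqs), as.character(rsM@seqs))
})

test_that("triplets with degenerate introns are rejected", {
  fx <- makeTriplet()
  ex <- exonRanges(fx$triplet)
  squeezed <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(101L, BiocGenerics::end(ex)[1] + 2L, 2000L),
    end = c(BiocGenerics::end(ex)[1], BiocGenerics::end(ex)[1] + 61L, 2100L)),
    strand = "+")
  tr <- ExonTriplet("bad", exons = squeezed)
  expect_error(defineRegions(tr, fx$genome), "intron")
})

test_that("countMotif counts overlapping IUPAC occurrences, N matches nothing", {
  expect_equal(countMotif("TGCATGCATG", "TGCATG"), 2L)
  expect_equal(countMotif("ACGT", "TTTT"), 0L)
  expect_equal(countMotif("AC", "RY"), 1L)
  expect_equal(countMotif("ANGT", "ACGT"), 0L)
  expect_equal(countMotif("acgt", "ACGT"), 1L)   # case-insensitive
  expect_equal(countMotif("ACG", "ACGT"), 0L)    # shorter than pattern
})

test_that("countMotif agrees with a brute-force scan on random cases", {
  set.seed(17)
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  for (i in 1:200) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), sample(20:120, 1),
                        replace = TRUE, prob = c(rep(0.24, 4), 0.04)),
                 collapse = "")
    pat <- paste(sample(codes, sample(2:6, 1), replace = TRUE,
                        prob = c(rep(0.15, 4), rep(0.4 / 11, 11))),
                 collapse = "")
    expect_equal(countMotif(seq, pat), bruteForceMotifCount(seq, pat),
                 info = paste(seq, pat))
  }
})

test_that("splice-site scoring is log-odds in bits with smoothing", {
  consensus <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  consensus["G", ] <- 1
  expect_equal(scoreSpliceSite("GGGG", consensus), 8, tolerance = 0.01)
  uniform <- matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(scoreSpliceSite("ACGT", uniform), 0)
  pwm <- matrix(c(0.5, 0.5, 0, 0, 0, 0, 1, 0), 4, 2,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(scoreSpliceSite("AG", pwm), 3, tolerance = 0.01)
  expect_error(scoreSpliceSite("AGG", pwm), "width")
})

test_that("first upstream AG distance scans from the 3' splice site", {
  expect_equal(firstUpstreamAgDistance("TTAGAG"), 2L)
  expect_equal(firstUpstreamAgDistance("TTTTAG"), 5L)  # censored
  expect_equal(firstUpstreamAgDistance("AGAGAG"), 2L)
  expect_equal(firstUpstreamAgDistance("AGTTTTTAG"), 7L)
  expect_equal(firstUpstreamAgDistance("TAG"), 2L)     # too short: censored
})

test_that("nucleotide composition frequencies sum to 1 per family", {
  c1 <- ntComposition("AAAA")
  expect_equal(unname(c1["mono_A"]), 1)
  expect_equal(unname(c1["di_AA"]), 1)
  expect_equal(unname(c1["tri_AAA"]), 1)
  c2 <- ntComposition("ACGT")
  expect_equal(unname(c2[c("mono_A", "mono_C", "mono_G", "mono_T")]),
               rep(0.25, 4))
  c3 <- ntComposition("ACAC")
  expect_equal(unname(c3["di_AC"]), 2 / 3)
  expect_equal(unname(c3["di_CA"]), 1 / 3)
  cn <- ntComposition("NNNN")
  expect_true(attr(cn, "degenerate"))
  expect_equal(sum(cn), 0)
  # N-containing windows are dropped, remaining ones renormalized
  c4 <- ntComposition("AANTT")
  expect_equal(unname(c4["di_AA"]), 0.5)
  expect_equal(unname(c4["di_TT"]), 0.5)
})

test_that("nucleosome features summarise the configured windows", {
  fx <- makeTriplet(exonW = c(60L, 60L, 60L), intronL = c(400L, 400L))
  rs <- defineRegions(fx$triplet, fx$genome)
  span <- range(exonRanges(fx$triplet), ignore.strand = TRUE)
  const <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(1, BiocGenerics::end(span) + 100L), score = 0.7)
  nf <- nucleosomeFeatures(const, rs)
  expect_equal(length(nf), 12L)
  expect_true(all(abs(nf - 0.7) < 1e-12))

  # single covered base inside the first 50 nt of the 60-nt A exon:
  # both the first-50 and last-50 windows overlap it (overlap is computed
  # independently); here the spike sits in the first 10 nt so only first-50
  # sees it
  aStart <- BiocGenerics::start(exonRanges(fx$triplet))[2]
  spike <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(aStart + 4L, aStart + 4L), score = 1)
  nf2 <- nucleosomeFeatures(spike, rs)
  expect_equal(unname(nf2["nuc_Afirst50_max"]), 1)
  expect_equal(unname(nf2["nuc_Afirst50_mean"]), 1 / 50)
  expect_equal(unname(nf2["nuc_Alast50_max"]), 0)
})

test_that("extractFeatures is deterministic and schema-driven", {
  sim <- smallSim()
  prep <- smallPrep()
  lib <- defaultMotifLibrary()
  tr <- sim$db[[3]]
  v1 <- extractFeatures(tr, prep$schema, genome = sim$genome, motifLib = lib,
                        pwms = prep$pwms)
  v2 <- extractFeatures(tr, prep$schema, genome = sim$genome, motifLib = lib,
                        pwms = prep$pwms)
  expect_identical(v1, v2)
  expect_equal(names(v1), prep$schema$name)

  lenSchema <- buildFeatureSchema(families = "length")
  vl <- extractFeatures(tr, lenSchema, genome = sim$genome)
  expect_equal(length(vl), 5L)
  expect_true(all(is.finite(vl)))

  expect_error(
    extractFeatures(tr, prep$schema, genome = sim$genome, motifLib = lib),
    "pwms")
})

test_that("feature vectors are strand-invariant", {
  fx <- mirroredTriplets()
  lib <- defaultMotifLibrary()
  schema <- buildFeatureSchema(lib, families = c("motif_count", "length",
                                                 "ag_dist", "composition"))
  vP <- extractFeatures(fx$plus$triplet, schema, genome = fx$plus$genome,
                        motifLib = lib)
  vM <- extractFeatures(fx$minus$triplet, schema, genome = fx$minus$genome,
                        motifLib = lib)
  expect_equal(unname(vP), unname(vM))
})

test_that("triplets with no motif hits get all-zero motif features", {
  lib <- loadMotifLibrary(system.file("extdata", "motif_library.tsv",
                                      package = "splicecode"))
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("AC", 2000)))
  tr <- ExonTriplet("t", exons = GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(101, 501, 901), end = c(160, 560, 960)),
    strand = "+"))
  schema <- buildFeatureSchema(lib, families = "motif_count")
  # ACAC... contains no library motif except none
  v <- extractFeatures(tr, schema, genome = g, motifLib = lib)
  expect_true(all(v == 0))
})
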