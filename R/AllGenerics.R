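#' @include AllClasses.R
NULL

#' Accessors for triplet objects
#'
#' @param x an [ExonTriplet-class] or [TripletDB-class].
#' @return `tripletId`: character id(s); `geneId`: gene id(s);
#'   `exonRanges`: `GRanges` of the three exons; `exonSeqs`: `DNAStringSet`
#'   of the three exon sequences; `tripletLabel`: cassette/constitutive label.
#' @name triplet-accessors
#' @aliases tripletId geneId exonRanges exonSeqs tripletLabel
#' @export tripletId
setGeneric("tripletId", function(x) standardGeneric("tripletId"))

#' @rdname triplet-accessors
#' @export geneId
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname triplet-accessors
#' @export exonRanges
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname triplet-accessors
#' @export exonSeqs
setGeneric("exonSeqs", function(x) standardGeneric("exonSeqs"))

#' @rdname triplet-accessors
#' @export tripletLabel
setGeneric("tripletLabel", function(x) standardGeneric("tripletLabel"))

#' @rdname triplet-accessors
#' @param object object to display.
#' @export hasCoordinates
setGeneric("hasCoordinates", function(x) standardGeneric("hasCoordinates"))

setMethod("tripletId", "ExonTriplet", function(x) x@tripletId)
setMethod("geneId", "ExonTriplet", function(x) x@geneId)
setMethod("exonRanges", "ExonTriplet", function(x) x@exons)
setMethod("exonSeqs", "ExonTriplet", function(x) x@seqs)
setMethod("tripletLabel", "ExonTriplet", function(x) x@label)
setMethod("hasCoordinates", "ExonTriplet", function(x) length(x@exons) == 3L)

setMethod("tripletId", "TripletDB",
  function(x) vapply(x@triplets, tripletId, character(1)))
setMethod("geneId", "TripletDB",
  function(x) vapply(x@triplets, geneId, character(1)))
setMethod("tripletLabel", "TripletDB",
  function(x) vapply(x@triplets, tripletLabel, character(1)))

setMethod("length", "TripletDB", function(x) length(x@triplets))
setMethod("names", "TripletDB", function(x) tripletId(x))

setMethod("[[", "TripletDB", function(x, i, ...) {
  if (is.character(i)) i <- match(i, tripletId(x))
  x@triplets[[i]]
})

setMethod("[", "TripletDB", function(x, i, ...) {
  if (is.character(i)) i <- match(i, tripletId(x))
  new("TripletDB", triplets = x@triplets[i])
})

setMethod("show", "ExonTriplet", function(object) {
  cat("ExonTriplet", object@tripletId,
      if (!is.na(object@label)) sprintf("(%s)", object@label) else "(unlabelled)", "\n")
  if (hasCoordinates(object)) {
    ex <- object@exons
    cat(sprintf("  %s:%d-%d(%s), exon widths %s\n",
                as.character(GenomicRanges::seqnames(ex))[1],
                min(BiocGenerics::start(ex)), max(BiocGenerics::end(ex)),
                as.character(BiocGenerics::strand(ex))[1],
                paste(BiocGenerics::width(ex), collapse = "/")))
  }
  if (length(object@seqs))
    cat(sprintf("  sequences: %s nt\n",
                paste(BiocGenerics::width(object@seqs), collapse = "/")))
})

setMethod("show", "TripletDB", function(object) {
  lab <- table(factor(tripletLabel(object), c("cassette", "constitutive")))
  cat(sprintf("TripletDB with %d triplets (%d cassette, %d constitutive)\n",
              length(object), lab[["cassette"]], lab[["constitutive"]]))
})

#' @describeIn loadMotifLibrary number of motifs in a library.
#' @param x a `MotifLibrary`.
#' @export
setMethod("length", "MotifLibrary", function(x) nrow(x@defs))

setMethod("show", "MotifLibrary", function(object) {
  cat(sprintf("MotifLibrary with %d motifs (%d code_model, %d general_splicing)\n",
              nrow(object@defs), sum(object@defs$group == "code_model"),
              sum(object@defs$group == "general_splicing")))
})

setMethod("show", "RegionSet", function(object) {
  nm <- if (length(object@seqs)) names(object@seqs) else names(object@ranges)
  cat("RegionSet:", paste(nm, collapse = " "), "\n")
  if (length(object@seqs))
    cat("  widths:", paste(BiocGenerics::width(object@seqs), collapse = " "), "\n")
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: task %s, %d samples, %d features, %d hidden units\n",
              object@config@task, length(object@samples), nrow(object@schema),
              object@config@nHidden))
  cat(sprintf("  mean inclusion frequency %.3f; acceptance %.2f\n",
              mean(object@inclusion),
              object@metadata$acceptance_rate %||% NA_real_))
})

setMethod("show", "SplicingPrediction", function(object) {
  cat(sprintf("SplicingPrediction: p(AS) = %.3f\n", object@pAS))
  q <- cbind(object@q, pChange = object@pChange)
  print(round(q, 3))
})

setMethod("show", "NetConfig", function(object) {
  cat(sprintf("NetConfig: task %s, %d hidden, sparsity %.2f, %d samples (burn-in %d, thin %d)\n",
              object@task, object@nHidden, object@sparsityPrior,
              object@nSamples, object@burnIn, object@thin))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
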