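#' @include AllClasses.R bnn.R scoring.R features.R
NULL

#' In-silico feature-removal effect
#'
#' The feature is set to zero on the raw scale (a zero motif count is the
#' biologically "removed" state; after standardization this maps to the
#' training-set zero, not the training mean), stage-2 predictions are
#' recomputed, and the effect is the total change in the conditional
#' differential-splicing probabilities:
#' `FE_f = |q_inc - q_inc^(del f)| + |q_exc - q_exc^(del f)|` for the tissue
#' group analysed.
#'
#' @param model2 stage-2 (tissue) [EnsembleModel-class].
#' @param fv named raw feature vector.
#' @param feature feature name to remove.
#' @param tissue tissue-group name.
#' @return non-negative feature effect.
#' @export
featureEffect <- function(model2, fv, feature, tissue) {
  if (!feature %in% model2@schema$name)
    stop("feature not in model schema: ", feature)
  if (!tissue %in% model2@config@tissueGroups)
    stop("unknown tissue group: ", tissue)
  q0 <- predictProba(model2, fv)
  fvDel <- fv
  fvDel[feature] <- 0
  q1 <- predictProba(model2, fvDel)
  inc <- paste0(tissue, "_inc"); exc <- paste0(tissue, "_exc")
  unname(abs(q0[1L, inc] - q1[1L, inc]) + abs(q0[1L, exc] - q1[1L, exc]))
}

#' Normalized feature effects over the robust feature set
#'
#' Computes `FE_f` for every feature in the robust set `J` and normalizes:
#' `NFE_f = FE_f / sum_{j in J} FE_j`.  The NFE ranks the regulatory features
#' by their effect on the model's prediction confidence; it carries no
#' statistical significance measure.
#'
#' @param model2 stage-2 [EnsembleModel-class].
#' @param fv named raw feature vector.
#' @param tissue tissue-group name.
#' @param J robust feature set (default [robustFeatures()] of the model).
#' @param motifLib optional [MotifLibrary-class] used to annotate motif
#'   features with their RBP.
#' @return data.frame (an NFEReport) with columns `feature`, `region`,
#'   `rbp`, `tissue`, `FE`, `NFE`, ranked by descending NFE; attribute
#'   `degenerate` is `TRUE` when every FE is 0 (all NFE set to 0).
#' @export
normalizedFeatureEffects <- function(model2, fv, tissue,
                                     J = robustFeatures(model2),
                                     motifLib = NULL) {
  if (!length(J)) stop("robust feature set J is empty")
  fe <- vapply(J, function(f) featureEffect(model2, fv, f, tissue), numeric(1))
  total <- sum(fe)
  degenerate <- total <= 0
  nfe <- if (degenerate) rep(0, length(fe)) else fe / total
  sc <- model2@schema
  region <- sc$region[match(J, sc$name)]
  rbp <- rep(NA_character_, length(J))
  if (!is.null(motifLib)) {
    d <- motifLib@defs
    for (k in seq_along(J)) {
      hit <- vapply(d$motif_id, function(id)
        grepl(paste0("^motif_", id, "_"), J[k]), logical(1))
      if (any(hit)) rbp[k] <- d$rbp_name[which(hit)[1L]]
    }
  }
  out <- data.frame(feature = J, region = region, rbp = rbp, tissue = tissue,
                    FE = unname(fe), NFE = unname(nfe),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$NFE, out$feature), ]
  rownames(out) <- NULL
  attr(out, "degenerate") <- degenerate
  out
}

#' Feature enrichment percentiles against reference exon sets
#'
#' For each feature, the percentile of the query's value within each
#' reference set, with mid-rank tie credit:
#' `100 * (#below + 0.5 * #ties) / n`.  A heat-map bin is assigned by
#' two-sided cutoffs: `low` below the lower cutoff (depleted, "blue"),
#' `high` above the upper (enriched, "red"), `neutral` otherwise.
#'
#' @param fv named query feature vector.
#' @param references named list of reference matrices (rows = exons, columns
#'   = features), e.g. `list(AS = ..., Const = ...)`.
#' @param cutoffs lower/upper percentile cutoffs (default `c(5, 95)`).
#' @return data.frame (an EnrichmentReport): `feature`, `value`, one
#'   percentile and one bin column per reference set; features absent from a
#'   reference are flagged `NA` and listed in attribute `skipped`.
#' @export
enrichmentPercentile <- function(fv, references, cutoffs = c(5, 95)) {
  stopifnot(length(references) >= 1L, !is.null(names(references)))
  out <- data.frame(feature = names(fv), value = unname(fv),
                    stringsAsFactors = FALSE)
  skipped <- character(0)
  for (rn in names(references)) {
    ref <- references[[rn]]
    if (!nrow(ref)) stop("reference set '", rn, "' is empty")
    pct <- vapply(seq_along(fv), function(i) {
      f <- names(fv)[i]
      if (!f %in% colnames(ref)) {
        skipped <<- union(skipped, f)
        return(NA_real_)
      }
      v <- ref[, f]
      100 * (sum(v < fv[i]) + 0.5 * sum(v == fv[i])) / length(v)
    }, numeric(1))
    bin <- ifelse(is.na(pct), NA_character_,
                  ifelse(pct < cutoffs[1L], "low",
                         ifelse(pct > cutoffs[2L], "high", "neutral")))
    out[[paste0("pct_", rn)]] <- pct
    out[[paste0("bin_", rn)]] <- bin
  }
  attr(out, "skipped") <- skipped
  out
}

#' Export motif occurrences around a triplet as BED6 records
#'
#' Scans the seven regions with each motif (restricted to its allowed
#' regions), converts the region-local hit positions back to genomic
#' coordinates, and scores each record with 1000 times the NFE of the parent
#' motif-region feature (0 when the feature is not in the robust set or no
#' NFE report is given).  Record names are `motif_id|rbp_name`.
#'
#' @param triplet an [ExonTriplet-class] with genomic coordinates.
#' @param motifLib a [MotifLibrary-class].
#' @param genome `DNAStringSet`.
#' @param nfe optional NFE report from [normalizedFeatureEffects()].
#' @param intronWindow passed to [defineRegions()].
#' @return a `GRanges` with `name` and `score` columns, writable with
#'   [writeBed()].
#' @export
motifHitsToBed <- function(triplet, motifLib, genome, nfe = NULL,
                           intronWindow = 300L) {
  if (!hasCoordinates(triplet))
    stop("motif track export requires genomic coordinates; ",
         "submit the query with coordinates")
  regions <- defineRegions(triplet, genome, intronWindow)
  rng <- regions@ranges
  seqs <- regions@seqs
  strand <- as.character(BiocGenerics::strand(triplet@exons))[1]
  d <- motifLib@defs
  recs <- list()
  for (i in seq_len(nrow(d))) {
    L <- nchar(d$pattern[i])
    for (rg in d$allowed_regions[[i]]) {
      if (!rg %in% names(seqs)) next
      pos <- motifPositions(seqs[[rg]], d$pattern[i])
      if (!length(pos)) next
      gs <- BiocGenerics::start(rng[rg]); ge <- BiocGenerics::end(rng[rg])
      if (strand == "-") {
        starts <- ge - (pos - 1L) - L + 1L
        ends <- ge - (pos - 1L)
      } else {
        starts <- gs + (pos - 1L)
        ends <- gs + (pos - 1L) + L - 1L
      }
      score <- 0
      if (!is.null(nfe)) {
        fname <- paste0("motif_", d$motif_id[i], "_", rg)
        hit <- match(fname, nfe$feature)
        if (!is.na(hit)) score <- 1000 * nfe$NFE[hit]
      }
      recs[[length(recs) + 1L]] <- GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(rng[rg])),
        IRanges::IRanges(start = starts, end = ends), strand = strand,
        name = paste0(d$motif_id[i], "|", d$rbp_name[i]), score = score)
    }
  }
  if (!length(recs)) {
    empty <- GenomicRanges::GRanges()
    empty$name <- character(0)
    empty$score <- numeric(0)
    return(empty)
  }
  out <- suppressWarnings(do.call(c, recs))
  out[order(BiocGenerics::start(out))]
}
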