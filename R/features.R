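# Segment profile -> canonical feature vector: gene-level mapping, per-segment
# gene averaging, TF/ploidy adjustment, altered-segment counting, TF gating.

# Altered-segment thresholds: gains above / losses below, strict inequality.
.GAIN_RAW <- 0.07
.LOSS_RAW <- -0.07
.GAIN_ADJ <- 0.32
.LOSS_ADJ <- -0.42

#' TF/ploidy adjustment of a segmentation profile
#'
#' Replaces every segment's value by
#' \code{log2(corrected_copy_number / ploidy)}, i.e. the log2 ratio of the
#' TF-corrected absolute tumor copy number to the sample's average tumor
#' ploidy. An unaltered tumor genome (copy number equal to ploidy) maps to
#' exactly 0, which removes the tumor-fraction dependence that raw plasma
#' log2 ratios carry. Corrected copy numbers of 0 (homozygous loss) are
#' floored at 2^-10 before the log.
#'
#' @param profile \linkS4class{SegmentationProfile} with a
#'   \code{corrected_copy_number} column and tumor fraction > 0.
#' @return the adjusted profile (\code{isAdjusted() == TRUE}).
#' @export
adjustForTFPloidy <- function(profile) {
  stopifnot(is(profile, "SegmentationProfile"))
  if (profile@adjusted) return(profile)
  if (profile@tumorFraction <= 0) {
    stop("tumor fraction is 0: no tumor signal to adjust; ",
         "gate samples with tfGate() before adjustment", call. = FALSE)
  }
  ccn <- mcols(profile@segments)$corrected_copy_number
  if (is.null(ccn) || anyNA(ccn)) {
    stop("corrected_copy_number is required on every segment for adjustment",
         call. = FALSE)
  }
  mcols(profile@segments)$log2_ratio <- log2(pmax(ccn, 2^-10) / profile@ploidy)
  profile@adjusted <- TRUE
  validObject(profile)
  profile
}

#' Map a segmentation profile to gene-level copy values
#'
#' Each gene takes the value of its overlapping segment; a gene spanning
#' several segments gets the overlap-length-weighted mean. Genes overlapped
#' by no segment are flagged missing (never silently 0).
#'
#' @param profile \linkS4class{SegmentationProfile}.
#' @param gene_map \code{GRanges} with a \code{gene} metadata column, on the
#'   same assembly as the profile (a mismatch is undetectable here and is the
#'   caller's responsibility).
#' @return data.frame with columns \code{gene}, \code{value}, \code{missing}.
#' @export
geneLevelValues <- function(profile, gene_map) {
  stopifnot(is(profile, "SegmentationProfile"))
  if (length(gene_map) == 0L) stop("empty gene map", call. = FALSE)
  seg <- profile@segments
  vals <- mcols(seg)$log2_ratio
  hits <- findOverlaps(gene_map, seg)
  out <- data.frame(gene = mcols(gene_map)$gene,
                    value = NA_real_, missing = TRUE,
                    stringsAsFactors = FALSE)
  if (length(hits)) {
    ov <- width(pintersect(gene_map[queryHits(hits)], seg[subjectHits(hits)]))
    num <- tapply(ov * vals[subjectHits(hits)], queryHits(hits), sum)
    den <- tapply(ov, queryHits(hits), sum)
    idx <- as.integer(names(num))
    out$value[idx] <- as.numeric(num / den)
    out$missing[idx] <- FALSE
  }
  out
}

#' Collapse gene-level values onto the canonical segment scheme
#'
#' Each canonical segment's value is the arithmetic mean over its member
#' genes with observed values. Segments whose member genes are all missing
#' are imputed neutral (0) and flagged, so downstream weighted sums never
#' propagate NA.
#'
#' @param genes data.frame from \code{\link{geneLevelValues}}.
#' @param sigs \linkS4class{SignatureSet} (provides the scheme with member
#'   gene lists).
#' @param profile the source \linkS4class{SegmentationProfile} (sample id,
#'   TF, ploidy and the adjusted flag are copied onto the vector).
#' @return \linkS4class{SegmentFeatureVector}.
#' @export
segmentFeatureVector <- function(genes, sigs, profile) {
  stopifnot(is(sigs, "SignatureSet"))
  ids <- mcols(sigs@scheme)$segment_id
  members <- strsplit(mcols(sigs@scheme)$genes, ",", fixed = TRUE)
  lookup <- stats::setNames(genes$value, genes$gene)
  lookup[genes$missing] <- NA_real_
  vals <- numeric(length(ids))
  imp <- logical(length(ids))
  for (i in seq_along(ids)) {
    v <- lookup[members[[i]]]
    v <- v[is.finite(v)]
    if (length(v)) {
      vals[i] <- mean(v)
    } else {
      vals[i] <- 0
      imp[i] <- TRUE
    }
  }
  names(vals) <- ids
  names(imp) <- ids
  new("SegmentFeatureVector", sampleId = profile@sampleId, values = vals,
      imputed = imp, adjusted = profile@adjusted,
      tumorFraction = profile@tumorFraction, ploidy = profile@ploidy)
}

#' Profile to feature vector in one step
#'
#' Convenience wrapper: optional TF/ploidy adjustment, gene-level mapping,
#' then collapse onto the scheme.
#'
#' @param profile \linkS4class{SegmentationProfile}.
#' @param gene_map \code{GRanges} gene map.
#' @param sigs \linkS4class{SignatureSet}.
#' @param adjust apply \code{\link{adjustForTFPloidy}} first.
#' @return \linkS4class{SegmentFeatureVector}.
#' @export
profileToFeatures <- function(profile, gene_map, sigs, adjust = FALSE) {
  if (adjust) profile <- adjustForTFPloidy(profile)
  segmentFeatureVector(geneLevelValues(profile, gene_map), sigs, profile)
}

#' Count altered segments
#'
#' A segment is called altered when its value is strictly above the gain
#' threshold or strictly below the loss threshold. Published cutoffs:
#' +0.07/-0.07 for unadjusted values, +0.32/-0.42 for TF/ploidy-adjusted
#' values; the vector's \code{adjusted} flag picks the pair.
#'
#' @param v \linkS4class{SegmentFeatureVector}, or a numeric vector together
#'   with \code{adjusted}.
#' @param adjusted used only when \code{v} is a bare numeric vector.
#' @return non-negative integer count.
#' @export
countAltered <- function(v, adjusted = NULL) {
  if (is(v, "SegmentFeatureVector")) {
    adjusted <- v@adjusted
    v <- v@values
  }
  if (is.null(adjusted)) stop("supply 'adjusted' for bare numeric input")
  gain <- if (adjusted) .GAIN_ADJ else .GAIN_RAW
  loss <- if (adjusted) .LOSS_ADJ else .LOSS_RAW
  sum(v > gain | v < loss)
}

#' Tumor-fraction gate
#'
#' Signature scoring is applied only to samples whose estimated tumor
#' fraction reaches the detection cutoff (3\% by default, the ichorCNA
#' detection threshold the study used). Inclusive: \code{tf == cutoff}
#' passes.
#'
#' @param tf tumor fraction(s) in \code{[0, 1]}.
#' @param cutoff gate cutoff, default 0.03.
#' @return logical, \code{TRUE} where \code{tf >= cutoff}.
#' @export
tfGate <- function(tf, cutoff = 0.03) {
  if (any(!is.finite(tf)) || any(tf < 0 | tf > 1)) {
    stop("tumor fraction must be in [0, 1]", call. = FALSE)
  }
  tf >= cutoff
}

#' Per-sample missingness report
#'
#' @param vectors list of \linkS4class{SegmentFeatureVector}.
#' @return data.frame with sample id, number and fraction of imputed
#'   segments.
#' @export
missingnessReport <- function(vectors) {
  data.frame(
    sample_id = vapply(vectors, sampleId, character(1)),
    n_imputed = vapply(vectors, function(v) sum(v@imputed), integer(1)),
    frac_imputed = vapply(vectors, function(v) mean(v@imputed), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Altered-segment thresholds in use
#' @param adjusted logical; which threshold pair.
#' @return named numeric \code{c(gain=, loss=)}.
#' @export
alteredThresholds <- function(adjusted) {
  if (adjusted) c(gain = .GAIN_ADJ, loss = .LOSS_ADJ)
  else c(gain = .GAIN_RAW, loss = .LOSS_RAW)
}
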