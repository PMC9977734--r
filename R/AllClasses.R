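#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps pintersect
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<- metadata metadata<-
NULL

setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' SegmentationProfile: one sample's copy-number segmentation
#'
#' Holds the segments of a single plasma (or tissue) sample as a
#' \link[GenomicRanges]{GRanges} (internal convention: 0-based half-open,
#' chromosome names without a \code{"chr"} prefix) with metadata columns
#' \code{log2_ratio} and, when available, \code{corrected_copy_number} (the
#' tumor-fraction-corrected absolute copy number reported by ichorCNA),
#' \code{n_bins} and \code{call}. Tumor fraction and average tumor ploidy
#' travel with the object because the downstream adjustment
#' \code{log2(corrected_copy_number / ploidy)} needs them.
#'
#' @slot sampleId single sample identifier.
#' @slot segments \code{GRanges} of non-overlapping segments with metadata
#'   column \code{log2_ratio} (numeric) and optional columns
#'   \code{corrected_copy_number}, \code{n_bins}, \code{call}.
#' @slot tumorFraction estimated tumor fraction in \code{[0, 1]}.
#' @slot ploidy average tumor ploidy (copies), > 0.
#' @slot dialect source dialect, one of \code{"ichorcna"},
#'   \code{"generic_seg"}, \code{"cnvkit_cns"}, \code{"synthetic"}.
#' @slot adjusted \code{TRUE} once \code{log2_ratio} has been replaced by the
#'   TF/ploidy-adjusted value.
#' @slot bins optional bin-level table (synthetic profiles keep their 500-kb
#'   bin values here; \code{NULL} for profiles read from disk).
#'
#' @export
setClass("SegmentationProfile",
  slots = c(
    sampleId = "character",
    segments = "GRanges",
    tumorFraction = "numeric",
    ploidy = "numeric",
    dialect = "character",
    adjusted = "logical",
    bins = "dfOrNULL"
  ),
  prototype = prototype(adjusted = FALSE, dialect = "generic_seg", bins = NULL)
)

setValidity("SegmentationProfile", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId) ||
      !nzchar(object@sampleId)) {
    msg <- c(msg, "sampleId must be a single non-empty string")
  }
  if (!"log2_ratio" %in% names(mcols(object@segments))) {
    msg <- c(msg, "segments must carry a 'log2_ratio' metadata column")
  }
  if (length(object@tumorFraction) != 1L || is.na(object@tumorFraction) ||
      object@tumorFraction < 0 || object@tumorFraction > 1) {
    msg <- c(msg, "tumorFraction must be a single value in [0, 1]")
  }
  if (length(object@ploidy) != 1L || is.na(object@ploidy) ||
      object@ploidy <= 0) {
    msg <- c(msg, "ploidy must be a single positive value")
  }
  ccn <- mcols(object@segments)$corrected_copy_number
  if (!is.null(ccn) && any(ccn < 0, na.rm = TRUE)) {
    msg <- c(msg, "corrected_copy_number must be >= 0")
  }
  nb <- mcols(object@segments)$n_bins
  if (!is.null(nb) && any(nb < 1, na.rm = TRUE)) {
    msg <- c(msg, "n_bins must be >= 1")
  }
  # non-overlap within chromosome
  if (length(object@segments) > 1L) {
    gr <- object@segments
    self <- findOverlaps(gr, gr, minoverlap = 1L)
    if (any(queryHits(self) != subjectHits(self))) {
      msg <- c(msg, "segments must not overlap within a chromosome")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SignatureSet: canonical segment scheme plus signature weight vectors
#'
#' The fixed partition of the genome into canonical copy-number segments
#' (the published resource uses 514 of them) together with the member genes
#' of each segment and the named signature weight vectors defined over
#' segment ids.
#'
#' @slot scheme \code{GRanges} of canonical segments with metadata columns
#'   \code{segment_id} (unique) and \code{genes} (comma-separated symbols).
#' @slot weights named list; each element is a named numeric vector of
#'   segment weights for one signature.
#'
#' @export
setClass("SignatureSet",
  slots = c(scheme = "GRanges", weights = "list")
)

setValidity("SignatureSet", function(object) {
  msg <- character()
  mc <- mcols(object@scheme)
  if (!all(c("segment_id", "genes") %in% names(mc))) {
    msg <- c(msg, "scheme needs 'segment_id' and 'genes' metadata columns")
  } else {
    ids <- mc$segment_id
    if (anyDuplicated(ids)) msg <- c(msg, "scheme segment_id values must be unique")
    if (length(object@weights)) {
      if (is.null(names(object@weights)) || anyDuplicated(names(object@weights)) ||
          any(!nzchar(names(object@weights)))) {
        msg <- c(msg, "signature names must be unique and non-empty")
      }
      bad <- vapply(object@weights, function(w) {
        !is.numeric(w) || is.null(names(w)) || !all(names(w) %in% ids)
      }, logical(1))
      if (any(bad)) {
        msg <- c(msg, sprintf(
          "signature(s) %s reference segment ids absent from the scheme or are not named numeric",
          paste(names(object@weights)[bad], collapse = ", ")))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' SegmentFeatureVector: per-sample values over the canonical segment scheme
#'
#' An ordered numeric vector aligned to a \linkS4class{SignatureSet} scheme
#' (one value per canonical segment; default published scheme: 514), with an
#' imputation flag per segment. Segments covered by no gene value are imputed
#' neutral (0) and flagged rather than propagated as NA.
#'
#' @slot sampleId sample identifier.
#' @slot values named numeric, names = scheme segment ids, scheme order.
#' @slot imputed logical, parallel to \code{values}.
#' @slot adjusted whether the values derive from TF/ploidy-adjusted segments.
#' @slot tumorFraction,ploidy copied from the source profile.
#'
#' @export
setClass("SegmentFeatureVector",
  slots = c(
    sampleId = "character",
    values = "numeric",
    imputed = "logical",
    adjusted = "logical",
    tumorFraction = "numeric",
    ploidy = "numeric"
  )
)

setValidity("SegmentFeatureVector", function(object) {
  msg <- character()
  if (length(object@values) != length(object@imputed)) {
    msg <- c(msg, "values and imputed must have equal length")
  }
  if (is.null(names(object@values))) {
    msg <- c(msg, "values must be named by segment id")
  }
  if (any(!is.finite(object@values))) {
    msg <- c(msg, "values must be finite (missing segments are imputed, not NA)")
  }
  if (length(msg)) msg else TRUE
})

#' SignatureScoreMatrix: signatures x samples score matrix
#'
#' @slot scores numeric matrix, rows = signature names, columns = sample ids.
#' @slot tumorFraction named numeric, TF per sample (column order).
#' @slot adjusted whether scores come from adjusted feature vectors.
#' @slot lowConfidence logical matrix parallel to \code{scores}; \code{TRUE}
#'   where more than the configured fraction of a signature's weighted
#'   segments were imputed in that sample.
#'
#' @export
setClass("SignatureScoreMatrix",
  slots = c(
    scores = "matrix",
    tumorFraction = "numeric",
    adjusted = "logical",
    lowConfidence = "matrix"
  )
)

setValidity("SignatureScoreMatrix", function(object) {
  msg <- character()
  s <- object@scores
  if (is.null(rownames(s)) || is.null(colnames(s))) {
    msg <- c(msg, "scores must have signature rownames and sample colnames")
  } else {
    if (anyDuplicated(rownames(s))) msg <- c(msg, "duplicate signature names")
    if (anyDuplicated(colnames(s))) msg <- c(msg, "duplicate sample ids")
  }
  if (any(!is.finite(s))) msg <- c(msg, "scores must be finite")
  if (!identical(dim(object@lowConfidence), dim(s))) {
    msg <- c(msg, "lowConfidence must match scores dimensions")
  }
  if (length(object@tumorFraction) != ncol(s)) {
    msg <- c(msg, "tumorFraction must have one entry per sample")
  }
  if (length(msg)) msg else TRUE
})

#' ConsensusResult: consensus clustering output
#'
#' @slot consensus list (one per k) of samples x samples consensus matrices
#'   with entries in \code{[0, 1]}, symmetric, unit diagonal.
#' @slot kRange integer vector of evaluated k.
#' @slot area area under the consensus CDF per k.
#' @slot deltaArea relative area gain per k (first k: the area itself).
#' @slot chosenK selected number of clusters.
#' @slot labels integer cluster labels (1..chosenK) named by sample id.
#'
#' @export
setClass("ConsensusResult",
  slots = c(
    consensus = "list",
    kRange = "integer",
    area = "numeric",
    deltaArea = "numeric",
    chosenK = "integer",
    labels = "integer"
  )
)

#' SubtypeModel: SAM-selected signatures plus per-cluster centroids
#'
#' @slot signatures character vector of selected signature names.
#' @slot centroids numeric matrix, rows = selected signatures, columns =
#'   cluster labels; centroid_k is the per-signature mean over training
#'   samples in cluster k.
#' @slot metadata list (fdr, n_perm, seed, training sizes).
#'
#' @export
setClass("SubtypeModel",
  slots = c(signatures = "character", centroids = "matrix", metadata = "list")
)

setValidity("SubtypeModel", function(object) {
  msg <- character()
  if (ncol(object@centroids) < 2L) msg <- c(msg, "need >= 2 cluster centroids")
  if (!identical(rownames(object@centroids), object@signatures)) {
    msg <- c(msg, "centroid rows must align with selected signatures")
  }
  if (length(msg)) msg else TRUE
})

#' ClinicalTable: per-patient outcomes keyed to samples
#'
#' Validated clinical annotation: PFS/OS time + event, RECIST-style response
#' category, ER/HER2 status, treatment line, plus free covariate columns.
#'
#' @slot data data.frame with columns \code{patient_id}, \code{sample_id},
#'   \code{pfs_months}, \code{pfs_event}, \code{os_months}, \code{os_event},
#'   \code{response} (CR/PR/SD/PD/NA), \code{er_status}, \code{her2_status}
#'   (pos/neg/NA), \code{treatment_line} and any extra covariates.
#'
#' @export
setClass("ClinicalTable", slots = c(data = "data.frame"))

.response_levels <- c("CR", "PR", "SD", "PD")
.status_levels <- c("pos", "neg")

setValidity("ClinicalTable", function(object) {
  d <- object@data
  msg <- character()
  need <- c("patient_id", "sample_id", "pfs_months", "pfs_event",
            "os_months", "os_event", "response", "er_status", "her2_status",
            "treatment_line")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    return(sprintf("missing clinical column(s): %s", paste(miss, collapse = ", ")))
  }
  for (tm in c("pfs_months", "os_months")) {
    if (any(d[[tm]] < 0, na.rm = TRUE)) {
      msg <- c(msg, sprintf("%s contains negative times", tm))
    }
  }
  for (ev in c("pfs_event", "os_event")) {
    if (!all(d[[ev]] %in% c(0, 1, NA))) {
      msg <- c(msg, sprintf("%s must be 0/1", ev))
    }
  }
  if (!all(is.na(d$response) | d$response %in% .response_levels)) {
    msg <- c(msg, "response must be one of CR, PR, SD, PD or NA")
  }
  for (st in c("er_status", "her2_status")) {
    if (!all(is.na(d[[st]]) | d[[st]] %in% .status_levels)) {
      msg <- c(msg, sprintf("%s must be 'pos', 'neg' or NA", st))
    }
  }
  if (length(msg)) msg else TRUE
})

#' GenomeScheme: synthetic genome layout for the cohort generator
#'
#' A reduced genome (default 22 synthetic chromosomes tiled by 500-kb bins)
#' partitioned into canonical copy-number segments, each carrying member
#' genes; every gene maps to exactly one canonical segment.
#'
#' @slot bins \code{GRanges} of 500-kb bins with \code{segment_id}.
#' @slot segments \code{GRanges} of canonical segments with
#'   \code{segment_id} and \code{genes}.
#' @slot genes \code{GRanges} of synthetic genes with \code{gene} and
#'   \code{segment_id}.
#' @slot binSize bin width in bp.
#'
#' @export
setClass("GenomeScheme",
  slots = c(bins = "GRanges", segments = "GRanges", genes = "GRanges",
            binSize = "numeric")
)

#' Archetype: a cluster's true copy-number landscape
#'
#' @slot name archetype label (\code{cluster1..cluster4}, \code{cluster2A},
#'   \code{cluster2B}, \code{healthy}).
#' @slot copyNumber named numeric vector of true absolute tumor copy number
#'   per canonical segment (healthy = uniform 2).
#' @slot ploidy intended average tumor ploidy (bin-weighted mean copies).
#'
#' @export
setClass("Archetype",
  slots = c(name = "character", copyNumber = "numeric", ploidy = "numeric")
)

setValidity("Archetype", function(object) {
  if (any(object@copyNumber < 0)) "copy numbers must be >= 0" else TRUE
})

# ---- show methods ----------------------------------------------------------

setMethod("show", "SegmentationProfile", function(object) {
  cat(sprintf(
    "SegmentationProfile '%s': %d segments, TF=%.3f, ploidy=%.2f, dialect=%s%s\n",
    object@sampleId, length(object@segments), object@tumorFraction,
    object@ploidy, object@dialect,
    if (object@adjusted) " [TF/ploidy-adjusted]" else ""))
})

setMethod("show", "SignatureSet", function(object) {
  cat(sprintf("SignatureSet: %d canonical segments, %d signatures\n",
              length(object@scheme), length(object@weights)))
})

setMethod("show", "SegmentFeatureVector", function(object) {
  cat(sprintf(
    "SegmentFeatureVector '%s': %d segments (%d imputed)%s\n",
    object@sampleId, length(object@values), sum(object@imputed),
    if (object@adjusted) " [adjusted]" else ""))
})

setMethod("show", "SignatureScoreMatrix", function(object) {
  cat(sprintf("SignatureScoreMatrix: %d signatures x %d samples%s\n",
              nrow(object@scores), ncol(object@scores),
              if (object@adjusted) " [adjusted]" else ""))
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: k in {%s}, chosen k = %d\n",
              paste(object@kRange, collapse = ","), object@chosenK))
})

setMethod("show", "SubtypeModel", function(object) {
  cat(sprintf("SubtypeModel: %d signatures, %d centroids (%s)\n",
              length(object@signatures), ncol(object@centroids),
              paste(colnames(object@centroids), collapse = ", ")))
})

setMethod("show", "ClinicalTable", function(object) {
  cat(sprintf("ClinicalTable: %d patients\n", nrow(object@data)))
})

setMethod("show", "GenomeScheme", function(object) {
  cat(sprintf(
    "GenomeScheme: %d chromosomes, %d bins (%.0f kb), %d segments, %d genes\n",
    length(unique(as.character(seqnames(object@bins)))), length(object@bins),
    object@binSize / 1000, length(object@segments), length(object@genes)))
})

setMethod("show", "Archetype", function(object) {
  cat(sprintf("Archetype '%s': %d segments, ploidy %.2f\n",
              object@name, length(object@copyNumber), object@ploidy))
})
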