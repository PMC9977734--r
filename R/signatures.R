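# Signature scoring: weighted sums of canonical segment values, TF-correlation
# screening, and the segment-ablation robustness experiment.

#' Score one sample against one signature
#'
#' The score is the weighted sum over the signature's weighted segments,
#' \eqn{\sum_i w_i x_i} (the linear predictor of the published Elastic-Net
#' models; no intercept was published and none is added). Optionally the sum
#' is normalized by \eqn{\sum_i |w_i|}; with mixed-sign weights a plain sum
#' divided by \eqn{\sum w_i} would be unstable, and any positive rescaling
#' leaves the sample ordering (all that downstream analyses use) unchanged.
#'
#' @param v \linkS4class{SegmentFeatureVector}.
#' @param weights named numeric weight vector over segment ids (e.g. from
#'   \code{\link{signatureWeights}}).
#' @param normalize divide by \code{sum(abs(weights))}.
#' @param max_imputed_frac above this fraction of imputed weighted segments
#'   the score carries a low-confidence flag (attribute
#'   \code{"lowConfidence"}).
#' @return numeric score with attribute \code{lowConfidence}.
#' @export
scoreSignature <- function(v, weights, normalize = FALSE,
                           max_imputed_frac = 0.5) {
  stopifnot(is(v, "SegmentFeatureVector"))
  miss <- setdiff(names(weights), names(v@values))
  if (length(miss)) {
    stop("feature vector lacks weighted segment(s): ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  x <- v@values[names(weights)]
  s <- sum(weights * x)
  if (normalize) s <- s / sum(abs(weights))
  structure(s, lowConfidence =
              mean(v@imputed[names(weights)]) > max_imputed_frac)
}

#' Score a cohort against a signature set
#'
#' @param vectors list of \linkS4class{SegmentFeatureVector} sharing one
#'   scheme.
#' @param sigs \linkS4class{SignatureSet}.
#' @param normalize,max_imputed_frac passed to \code{\link{scoreSignature}}.
#' @return \linkS4class{SignatureScoreMatrix} of shape
#'   (signatures x samples).
#' @export
scoreCohort <- function(vectors, sigs, normalize = FALSE,
                        max_imputed_frac = 0.5) {
  if (!length(vectors)) stop("empty cohort", call. = FALSE)
  ids <- vapply(vectors, sampleId, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  scheme_ids <- mcols(sigs@scheme)$segment_id
  X <- vapply(vectors, function(v) v@values[scheme_ids],
              numeric(length(scheme_ids)))          # segments x samples
  IMP <- vapply(vectors, function(v) v@imputed[scheme_ids],
                logical(length(scheme_ids)))
  dim(X) <- c(length(scheme_ids), length(vectors))
  dim(IMP) <- dim(X)
  sig_names <- names(sigs@weights)
  S <- matrix(0, length(sig_names), length(vectors),
              dimnames = list(sig_names, ids))
  LC <- matrix(FALSE, length(sig_names), length(vectors),
               dimnames = list(sig_names, ids))
  for (j in seq_along(sig_names)) {
    w <- sigs@weights[[j]]
    idx <- match(names(w), scheme_ids)
    s <- as.numeric(crossprod(w, X[idx, , drop = FALSE]))
    if (normalize) s <- s / sum(abs(w))
    S[j, ] <- s
    LC[j, ] <- colMeans(IMP[idx, , drop = FALSE]) > max_imputed_frac
  }
  adj <- vapply(vectors, isAdjusted, logical(1))
  new("SignatureScoreMatrix", scores = S,
      tumorFraction = stats::setNames(
        vapply(vectors, tumorFraction, numeric(1)), ids),
      adjusted = all(adj), lowConfidence = LC)
}

#' Screen signatures for tumor-fraction correlation
#'
#' Pearson correlation of each signature's scores with tumor fraction, with
#' the banding used in the study: strong |rho| >= 0.70, moderate
#' 0.50 <= |rho| < 0.70, weak otherwise. Raw (unadjusted) scores scale with
#' TF; after TF/ploidy adjustment no signature is expected to reach the
#' moderate band.
#'
#' @param m \linkS4class{SignatureScoreMatrix}.
#' @param tf tumor fractions per sample; defaults to the matrix's own.
#' @return data.frame (signature, rho, p, band), one row per signature;
#'   zero-variance signatures get \code{NA} rho and band \code{"undefined"}.
#' @export
tfCorrelationScreen <- function(m, tf = tumorFraction(m)) {
  s <- scores(m)
  if (ncol(s) < 3L) stop("need >= 3 samples for a correlation screen")
  res <- lapply(rownames(s), function(sig) {
    x <- s[sig, ]
    if (stats::sd(x) == 0 || stats::sd(tf) == 0) {
      return(data.frame(signature = sig, rho = NA_real_, p = NA_real_,
                        band = "undefined"))
    }
    ct <- stats::cor.test(x, tf, method = "pearson")
    rho <- unname(ct$estimate)
    band <- if (abs(rho) >= 0.70) "strong"
            else if (abs(rho) >= 0.50) "moderate" else "weak"
    data.frame(signature = sig, rho = rho, p = ct$p.value, band = band)
  })
  do.call(rbind, res)
}

#' Segment-ablation robustness of a signature's prognostic value
#'
#' Randomly removes \code{n_remove} of a signature's weighted segments,
#' rescores the cohort, refits a univariate Cox model of PFS on the
#' (per-SD standardized) ablated score, and repeats \code{reps} times; the
#' mean hazard ratio and mean p-value over successful repetitions are
#' reported per removal size. As more segments are removed the mean HR is
#' expected to decay toward 1 and p to grow.
#'
#' @param sigs \linkS4class{SignatureSet}.
#' @param signature signature name to ablate.
#' @param vectors list of \linkS4class{SegmentFeatureVector} (the cohort).
#' @param clinical \linkS4class{ClinicalTable} with \code{pfs_months} and
#'   \code{pfs_event}, keyed by \code{sample_id}.
#' @param n_remove integer vector of removal sizes (default the study's
#'   20, 40, 80, 160, truncated to the signature size).
#' @param reps repetitions per removal size (default 500).
#' @param seed RNG seed; per-rep draws derive deterministically from it.
#' @return data.frame (n_remove, mean_hr, mean_p, n_failed).
#' @export
signatureAblation <- function(sigs, signature, vectors, clinical,
                              n_remove = c(20L, 40L, 80L, 160L),
                              reps = 500L, seed = 1L) {
  w_full <- signatureWeights(sigs, signature)
  if (any(n_remove >= length(w_full))) {
    stop("n_remove must be smaller than the signature's segment count (",
         length(w_full), ")", call. = FALSE)
  }
  if (reps < 1L) stop("reps must be >= 1")
  ids <- vapply(vectors, sampleId, character(1))
  X <- vapply(vectors, function(v) v@values[names(w_full)],
              numeric(length(w_full)))   # weighted segments x samples
  dim(X) <- c(length(w_full), length(vectors))
  clin <- clinicalData(clinical)
  hit <- match(ids, clin$sample_id)
  if (anyNA(hit)) stop("clinical table lacks sample(s): ",
                       paste(ids[is.na(hit)][1:min(3, sum(is.na(hit)))],
                             collapse = ", "))
  time <- clin$pfs_months[hit]
  event <- clin$pfs_event[hit]

  fit_one <- function(score) {
    if (stats::sd(score) == 0) return(NULL)
    z <- (score - mean(score)) / stats::sd(score)
    f <- tryCatch(
      survival::coxph(survival::Surv(time, event) ~ z, ties = "efron"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(f)) return(NULL)
    beta <- unname(stats::coef(f))
    if (!is.finite(beta) || abs(beta) > 20) return(NULL)
    c(hr = exp(beta),
      p = summary(f)$coefficients[1, "Pr(>|z|)"])
  }

  out <- lapply(n_remove, function(nr) {
    set.seed(seed + nr)    # deterministic substream per removal size
    hr <- p <- numeric(0)
    failed <- 0L
    for (r in seq_len(reps)) {
      keep <- if (nr > 0L) {
        sort(sample.int(length(w_full), length(w_full) - nr))
      } else seq_along(w_full)
      score <- as.numeric(crossprod(w_full[keep], X[keep, , drop = FALSE]))
      res <- fit_one(score)
      if (is.null(res)) failed <- failed + 1L
      else { hr <- c(hr, res["hr"]); p <- c(p, res["p"]) }
    }
    data.frame(n_remove = nr, mean_hr = mean(hr), mean_p = mean(p),
               n_failed = failed)
  })
  do.call(rbind, out)
}
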