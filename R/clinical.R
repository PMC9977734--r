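# Clinical association and survival statistics: Pearson correlations, rank
# AUC, Kaplan-Meier/log-rank, Cox models (Efron ties, Wald CIs), tertile
# grouping with frozen cutpoints, contingency tests and Bonferroni
# correction. Two-sided tests throughout, alpha = 0.05.

#' Pearson correlation with p-value
#'
#' @param x,y numeric vectors of equal length >= 3, finite.
#' @return list \code{(rho, p)}; both NA (with a warning) when either vector
#'   has zero variance.
#' @export
pearsonWithP <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need >= 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Correlation between two paired feature vectors
#'
#' Pearson correlation of the canonical segment values of a plasma/tissue
#' pair (the intra-patient concordance measure).
#'
#' @param a,b \linkS4class{SegmentFeatureVector} on the same scheme.
#' @return list \code{(rho, p)}.
#' @export
pairedProfileCorrelation <- function(a, b) {
  stopifnot(is(a, "SegmentFeatureVector"), is(b, "SegmentFeatureVector"))
  if (!identical(names(a@values), names(b@values))) {
    stop("feature vectors are not on the same segment scheme")
  }
  pearsonWithP(a@values, b@values)
}

#' Rank-based ROC AUC
#'
#' Probability that a random positive scores above a random negative, with
#' ties counted half (the Wilcoxon rank-sum normalization).
#'
#' @param score numeric scores.
#' @param label binary labels (logical, or coercible; \code{TRUE}/1 =
#'   positive).
#' @return AUC in \code{[0, 1]}.
#' @export
rocAUC <- function(score, label) {
  label <- as.logical(label)
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(score)                 # average ranks handle ties
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Kaplan-Meier curves with log-rank test
#'
#' @param times event/censoring times (>= 0).
#' @param events event indicator (1 = event, 0 = censored).
#' @param groups group label per subject (>= 2 non-empty groups).
#' @return list with \code{curves} (data.frame: group, time, surv, n_risk),
#'   \code{median} (named numeric, NA when the curve never reaches 0.5),
#'   \code{logrank_chisq}, \code{logrank_df} and \code{logrank_p}.
#' @export
kmLogrank <- function(times, events, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) == 0L)) stop("empty group", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  sm <- summary(fit)
  grp <- if (is.null(sm$strata)) rep(levels(groups)[1L], length(sm$time)) else
    sub("^groups=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, surv = sm$surv,
                       n_risk = sm$n.risk, stringsAsFactors = FALSE)
  med <- vapply(levels(groups), function(g) {
    cg <- curves[curves$group == g, , drop = FALSE]
    hit <- which(cg$surv <= 0.5)
    if (length(hit)) cg$time[min(hit)] else NA_real_
  }, numeric(1))
  if (sum(events) == 0) {
    # no events anywhere: log-rank is degenerate, no evidence of difference
    return(list(curves = curves, median = med, logrank_chisq = 0,
                logrank_df = nlevels(groups) - 1L, logrank_p = 1))
  }
  lr <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1L
  list(curves = curves, median = med, logrank_chisq = unname(lr$chisq),
       logrank_df = df,
       logrank_p = stats::pchisq(lr$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit (univariate or multivariable)
#'
#' Partial-likelihood estimates with the Efron tie approximation and Wald
#' confidence intervals / p-values. Non-convergence, separation or a
#' degenerate design are reported as an explicit failure status instead of
#' an error.
#'
#' @param times,events outcome (>= 1 event required).
#' @param covariates data.frame of covariates.
#' @param terms column names to include (default: all).
#' @return list with \code{status} ("ok" or "failed"), \code{n},
#'   \code{events} and a \code{terms} data.frame (term, hr, ci_low, ci_high,
#'   p) when the fit succeeded.
#' @export
coxFit <- function(times, events, covariates, terms = names(covariates)) {
  if (sum(events) < 1L) stop("need at least one event", call. = FALSE)
  X <- covariates[, terms, drop = FALSE]
  fail <- function(reason) list(status = "failed", reason = reason,
                                n = length(times), events = sum(events))
  const <- vapply(X, function(col) length(unique(col)) < 2L, logical(1))
  if (any(const)) {
    return(fail(paste("constant covariate:",
                      paste(terms[const], collapse = ", "))))
  }
  dat <- data.frame(.time = times, .event = events, X, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", terms), collapse = " + ")))
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(fml, data = dat, ties = "efron"),
      warning = function(w) {
        if (grepl("converge|infinite|singular", conditionMessage(w))) {
          stop(conditionMessage(w))
        }
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("non-convergence or degenerate design"))
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || any(is.na(beta))) {
    return(fail("non-finite coefficient (separation or aliasing)"))
  }
  sm <- summary(fit)
  ci <- sm$conf.int
  list(status = "ok", n = length(times), events = sum(events),
       terms = data.frame(
         term = names(beta),
         hr = unname(exp(beta)),
         ci_low = unname(ci[, "lower .95"]),
         ci_high = unname(ci[, "upper .95"]),
         p = unname(sm$coefficients[, "Pr(>|z|)"]),
         stringsAsFactors = FALSE))
}

#' Tertile grouping with frozen cutpoints
#'
#' \code{tertileGroups} derives cutpoints at the 1/3 and 2/3 empirical
#' quantiles and labels each score low/mid/high. \code{applyCutpoints}
#' reapplies cutpoints frozen in a training cohort to a new cohort (the
#' cross-cohort validation mechanism: cutoffs derived in one cohort, reused
#' unchanged in the next).
#'
#' @param scores numeric scores (>= 3 distinct values for derivation).
#' @return \code{tertileGroups}: list with \code{labels} (factor
#'   low/mid/high) and \code{cutpoints} (length-2 numeric);
#'   \code{applyCutpoints}: the labels factor.
#' @export
tertileGroups <- function(scores) {
  if (length(unique(scores)) < 3L) {
    stop("need >= 3 distinct values to derive tertiles", call. = FALSE)
  }
  cut_pts <- unname(stats::quantile(scores, c(1, 2) / 3))
  list(labels = applyCutpoints(scores, cut_pts), cutpoints = cut_pts)
}

#' @rdname tertileGroups
#' @param cutpoints length-2 numeric vector of frozen cutpoints.
#' @export
applyCutpoints <- function(scores, cutpoints) {
  stopifnot(length(cutpoints) == 2L, !is.unsorted(cutpoints))
  cut(scores, breaks = c(-Inf, cutpoints, Inf),
      labels = c("low", "mid", "high"), right = TRUE)
}

#' Contingency-table test (chi-square or Fisher by expected counts)
#'
#' Declared rule: Fisher's exact test when any expected cell count is below
#' 5, otherwise the chi-square test (without continuity correction).
#'
#' @param tab two-way table/matrix of non-negative counts.
#' @return list \code{(p, method)}.
#' @export
contingencyTest <- function(tab) {
  tab <- as.matrix(tab)
  if (sum(tab) == 0) stop("empty table", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    list(p = stats::fisher.test(tab)$p.value, method = "fisher")
  } else {
    list(p = stats::chisq.test(tab, correct = FALSE)$p.value,
         method = "chisq")
  }
}

#' Per-group outcome proportions (e.g. overall response rate per cluster)
#'
#' @param labels group label per subject.
#' @param outcomes logical/0-1 outcome per subject (NA dropped per group).
#' @return data.frame (group, n, n_outcome, rate).
#' @export
groupRates <- function(labels, outcomes) {
  labels <- as.factor(labels)
  out <- lapply(levels(labels), function(g) {
    o <- outcomes[labels == g]
    o <- o[!is.na(o)]
    data.frame(group = g, n = length(o), n_outcome = sum(o),
               rate = mean(o), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bonferroni correction
#'
#' @param p p-values in \code{[0, 1]}.
#' @return \code{min(1, m * p)} per value.
#' @export
bonferroni <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "bonferroni")
}
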