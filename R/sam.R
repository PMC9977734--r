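# Significance analysis of microarrays (SAM): moderated statistics with a
# fudge factor s0 and permutation-based FDR. Used multiclass (to select the
# signatures that separate the consensus clusters) and two-class
# paired/unpaired (differential signature calls between groups/timepoints).
#
# Conventions (the source publications leave them unprinted): s0 is the 5th
# percentile of the per-feature standard errors; permutations shuffle class
# labels globally (or flip pair signs for the paired test); pi0 is fixed at 1,
# which makes the FDR estimate conservative.

.sam_s0 <- function(s) as.numeric(stats::quantile(s, 0.05, names = FALSE))

# Permutation FDR at cutoff |d_j| for each feature, monotonized so q is
# non-increasing in |d|.
.sam_qvalues <- function(d_obs, d_perm) {
  a <- abs(d_obs)
  ord <- order(a, decreasing = TRUE)
  n_obs <- seq_along(ord)                          # observed calls at cutoff
  perm_abs <- sort(abs(as.numeric(d_perm)))
  n_perm_cols <- ncol(d_perm)
  # expected null calls at each cutoff = mean over perms of #{|d*| >= cutoff}
  exp_null <- (length(perm_abs) -
                 findInterval(a[ord] - 1e-12, perm_abs)) / n_perm_cols
  q <- pmin(1, exp_null / n_obs)
  q <- rev(cummin(rev(q)))                         # enforce monotonicity
  out <- numeric(length(a))
  out[ord] <- q
  out
}

# Multiclass moderated statistic: sqrt(between-class mean square) over
# (pooled within-class SD + s0); without moderation this is sqrt(F) of the
# one-way ANOVA.
.sam_stat_multiclass <- function(X, y, s0 = NULL) {
  y <- as.factor(y)
  K <- nlevels(y)
  n_k <- as.numeric(table(y))
  n <- sum(n_k)
  G <- stats::model.matrix(~ y - 1)                # samples x K indicator
  M <- X %*% G %*% diag(1 / n_k, K)                # class means
  grand <- as.numeric(X %*% rep(1 / n, n))
  msb <- as.numeric((M - grand)^2 %*% n_k) / (K - 1)
  # pooled within-class variance
  EX2 <- X^2 %*% G
  ssw <- rowSums(EX2 - t(t(M^2) * n_k))
  s <- sqrt(pmax(ssw / (n - K), 0))
  if (is.null(s0)) s0 <- .sam_s0(s)
  d <- sqrt(pmax(msb, 0)) / (s + s0)
  d[!is.finite(d)] <- 0
  list(d = d, s = s, s0 = s0)
}

.sam_stat_twoclass <- function(X, g, s0 = NULL) {
  g <- as.logical(g)
  n1 <- sum(!g); n2 <- sum(g)
  m1 <- rowMeans(X[, !g, drop = FALSE])
  m2 <- rowMeans(X[, g, drop = FALSE])
  v1 <- if (n1 > 1) apply(X[, !g, drop = FALSE], 1, stats::var) else 0
  v2 <- if (n2 > 1) apply(X[, g, drop = FALSE], 1, stats::var) else 0
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  se <- sp * sqrt(1 / n1 + 1 / n2)
  if (is.null(s0)) s0 <- .sam_s0(se)
  d <- (m2 - m1) / (se + s0)
  d[!is.finite(d)] <- 0
  list(d = d, s = se, s0 = s0)
}

.sam_stat_paired <- function(D, s0 = NULL) {      # D = feature x pair diffs
  n <- ncol(D)
  dbar <- rowMeans(D)
  se <- apply(D, 1, stats::sd) / sqrt(n)
  if (is.null(s0)) s0 <- .sam_s0(se)
  d <- dbar / (se + s0)
  d[!is.finite(d)] <- 0
  list(d = d, s = se, s0 = s0)
}

.as_score_matrix <- function(m) {
  if (is(m, "SignatureScoreMatrix")) scores(m) else as.matrix(m)
}

#' Multiclass SAM feature selection
#'
#' Per feature (signature), the moderated statistic
#' \eqn{d_j = \sqrt{MS_{between,j}} / (s_j + s_0)} with pooled within-class
#' \eqn{s_j} and fudge factor \eqn{s_0} (5th percentile of the \eqn{s_j});
#' the false discovery rate of the selection \eqn{|d_j| \ge} cutoff is
#' estimated by global label permutation. Features with q-value below
#' \code{fdr} are selected.
#'
#' @param m \linkS4class{SignatureScoreMatrix} or numeric matrix
#'   (features x samples).
#' @param labels class label per sample (>= 2 classes, each with >= 2
#'   samples).
#' @param fdr target FDR (default 0.05, the study's <5\%).
#' @param n_perm number of label permutations (>= 100; default 1000).
#' @param seed RNG seed for the permutations.
#' @return list with \code{table} (data.frame: feature, d, s, q, selected)
#'   and \code{selected} (character vector), plus \code{s0}.
#' @export
multiclassSAM <- function(m, labels, fdr = 0.05, n_perm = 1000L, seed = 1L) {
  X <- .as_score_matrix(m)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (any(table(labels) < 2L)) {
    stop("every class needs >= 2 samples", call. = FALSE)
  }
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  obs <- .sam_stat_multiclass(X, labels)
  set.seed(seed)
  d_perm <- vapply(seq_len(n_perm), function(b) {
    .sam_stat_multiclass(X, sample(labels), s0 = obs$s0)$d
  }, numeric(nrow(X)))
  q <- .sam_qvalues(obs$d, d_perm)
  tab <- data.frame(feature = rownames(X), d = obs$d, s = obs$s, q = q,
                    selected = q < fdr, stringsAsFactors = FALSE)
  list(table = tab, selected = tab$feature[tab$selected], s0 = obs$s0)
}

#' Two-class SAM (paired or unpaired)
#'
#' Unpaired: moderated two-sample t-type statistic with pooled SD and fudge
#' factor, FDR by group-label permutation. Paired: moderated one-sample
#' statistic on within-pair differences (group2 - group1), FDR by random
#' sign flips of the pairs.
#'
#' @param m \linkS4class{SignatureScoreMatrix} or matrix
#'   (features x samples).
#' @param groups two-level factor/vector per sample. For the paired test the
#'   two groups must have equal size and matched order (i-th sample of group
#'   1 pairs with i-th of group 2).
#' @param paired paired test?
#' @param fdr target FDR.
#' @param n_perm permutations (>= 100).
#' @param seed RNG seed.
#' @return list with \code{table} (feature, d, q, selected) and
#'   \code{selected}; positive d means higher in the second group level.
#' @export
twoClassSAM <- function(m, groups, paired = FALSE, fdr = 0.05,
                        n_perm = 1000L, seed = 1L) {
  X <- .as_score_matrix(m)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("need exactly 2 groups", call. = FALSE)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  g2 <- groups == levels(groups)[2L]
  set.seed(seed)
  if (paired) {
    if (sum(g2) != sum(!g2)) {
      stop("paired test requires equal group sizes", call. = FALSE)
    }
    D <- X[, g2, drop = FALSE] - X[, !g2, drop = FALSE]
    obs <- .sam_stat_paired(D)
    d_perm <- vapply(seq_len(n_perm), function(b) {
      signs <- sample(c(-1, 1), ncol(D), replace = TRUE)
      .sam_stat_paired(sweep(D, 2L, signs, `*`), s0 = obs$s0)$d
    }, numeric(nrow(X)))
  } else {
    obs <- .sam_stat_twoclass(X, g2)
    d_perm <- vapply(seq_len(n_perm), function(b) {
      .sam_stat_twoclass(X, sample(g2), s0 = obs$s0)$d
    }, numeric(nrow(X)))
  }
  q <- .sam_qvalues(obs$d, d_perm)
  tab <- data.frame(feature = rownames(X), d = obs$d, q = q,
                    selected = q < fdr, stringsAsFactors = FALSE)
  list(table = tab, selected = tab$feature[tab$selected], s0 = obs$s0)
}
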