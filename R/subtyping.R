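# Cluster discovery and the 4-class nearest-centroid subtype predictor:
# consensus clustering over signature scores, SAM-based signature selection,
# per-cluster centroids, Euclidean nearest-centroid assignment, and the
# within-cluster subdivision rule.

.pearson_dist <- function(X) {
  # X: features x samples; distance between sample score profiles
  stats::as.dist(1 - stats::cor(X))
}

#' Consensus clustering of samples over signature scores
#'
#' Repeatedly subsamples the cohort (without replacement), clusters each
#' subsample by average-linkage hierarchical clustering on the
#' 1 - Pearson-correlation distance between sample score profiles, and
#' records how often each sample pair lands in the same cluster among the
#' resamples where both were drawn. The number of clusters is chosen by the
#' relative delta-area criterion on the consensus CDF, refined by an
#' ambiguity check: the chosen k is the largest one whose relative gain in
#' CDF area is at least \code{delta_threshold} and whose proportion of
#' ambiguous consensus entries (PAC, entries strictly between 0.1 and 0.9)
#' is at most \code{pac_threshold}; if no k qualifies, the k with the
#' largest relative gain is used. Final labels come from clustering the
#' consensus matrix at the selected k; clusters smaller than
#' \code{min_cluster_frac} of the cohort (isolated outlier samples routinely
#' claim a cluster slot of their own) are then merged into the cluster with
#' which they share the highest mean consensus, and the reported
#' \code{chosenK} is the number of clusters that remain.
#'
#' @param m \linkS4class{SignatureScoreMatrix} or matrix
#'   (features x samples).
#' @param k_range candidate cluster numbers (default 2:6; capped at
#'   n_samples / 3).
#' @param n_resamples subsampling iterations (default 1000).
#' @param subsample_frac fraction of samples per resample (default 0.8).
#' @param delta_threshold relative area-gain threshold for accepting a
#'   larger k (default 0.1).
#' @param pac_threshold maximum proportion of ambiguous consensus entries
#'   for an acceptable k (default 0.05).
#' @param min_cluster_frac final clusters smaller than this fraction of the
#'   cohort are folded into their nearest cluster (default 0.05).
#' @param seed RNG seed.
#' @return \linkS4class{ConsensusResult}.
#' @export
consensusCluster <- function(m, k_range = 2:6, n_resamples = 1000L,
                             subsample_frac = 0.8, delta_threshold = 0.1,
                             pac_threshold = 0.05, min_cluster_frac = 0.05,
                             seed = 1L) {
  X <- .as_score_matrix(m)
  n <- ncol(X)
  k_range <- as.integer(k_range[k_range >= 2 & k_range <= max(2, n %/% 3)])
  if (!length(k_range)) stop("k_range empty after capping at n/3")
  if (subsample_frac <= 0 || subsample_frac > 1) {
    stop("subsample_frac must be in (0, 1]")
  }
  ids <- colnames(X)
  n_sub <- max(2L, floor(subsample_frac * n))
  co_sample <- matrix(0, n, n)
  co_cluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_cluster) <- as.character(k_range)

  set.seed(seed)
  for (b in seq_len(n_resamples)) {
    idx <- sort(sample.int(n, n_sub))
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
    hc <- stats::hclust(.pearson_dist(X[, idx, drop = FALSE]),
                        method = "average")
    for (ki in seq_along(k_range)) {
      lab <- stats::cutree(hc, k = k_range[ki])
      same <- outer(lab, lab, `==`)
      co_cluster[[ki]][idx, idx] <- co_cluster[[ki]][idx, idx] + same
    }
  }

  consensus <- lapply(co_cluster, function(cc) {
    M <- cc / co_sample
    M[co_sample == 0] <- NA
    diag(M) <- 1
    dimnames(M) <- list(ids, ids)
    M
  })

  cdf_area <- vapply(consensus, function(M) {
    v <- sort(M[upper.tri(M)])
    v <- v[!is.na(v)]
    # area under the empirical CDF on [0, 1]
    cdf <- seq_along(v) / length(v)
    sum(diff(c(v, 1)) * cdf)
  }, numeric(1))

  delta <- numeric(length(k_range))
  delta[1L] <- cdf_area[1L]
  if (length(k_range) > 1L) {
    delta[-1L] <- diff(cdf_area) / utils::head(cdf_area, -1L)
  }
  pac <- vapply(consensus, function(M) {
    v <- M[upper.tri(M)]
    v <- v[!is.na(v)]
    mean(v > 0.1 & v < 0.9)
  }, numeric(1))
  ok <- which(delta >= delta_threshold & pac <= pac_threshold)
  chosen <- if (length(ok)) k_range[max(ok)] else k_range[which.max(delta)]

  Mk <- consensus[[as.character(chosen)]]
  D <- 1 - Mk
  D[is.na(D)] <- 1
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  labels <- stats::cutree(hc, k = chosen)
  names(labels) <- ids

  # fold trivially small clusters into the cluster with the highest mean
  # consensus, then renumber 1..K by cluster size
  min_size <- max(1, ceiling(min_cluster_frac * n))
  repeat {
    sizes <- table(labels)
    small <- names(sizes)[sizes < min_size]
    if (!length(small) || length(sizes) <= 2L) break
    big <- setdiff(names(sizes), small)
    victim <- small[1L]
    for (id in names(labels)[labels == as.integer(victim)]) {
      affinity <- vapply(big, function(g) {
        mean(Mk[id, names(labels)[labels == as.integer(g)]], na.rm = TRUE)
      }, numeric(1))
      labels[id] <- as.integer(big[which.max(affinity)])
    }
  }
  remap <- stats::setNames(seq_along(sort(unique(labels))),
                           sort(unique(labels)))
  labels <- stats::setNames(as.integer(remap[as.character(labels)]), ids)

  new("ConsensusResult", consensus = consensus, kRange = k_range,
      area = unname(cdf_area), deltaArea = delta,
      chosenK = length(unique(labels)), labels = labels)
}

#' Renumber cluster labels by a reference signature
#'
#' Convention used throughout: clusters are renumbered 1..k by descending
#' mean of a designated signature (a luminal-A-like signature in the
#' intended use), so that cluster 1 carries the best-prognosis semantics.
#' This is a labeling convention, not a biological claim.
#'
#' @param labels integer cluster labels named by sample.
#' @param m \linkS4class{SignatureScoreMatrix} covering those samples.
#' @param signature signature name used for ordering.
#' @return relabeled integer vector (same names).
#' @export
relabelClusters <- function(labels, m, signature) {
  s <- scores(m)[signature, names(labels)]
  means <- tapply(s, labels, mean)
  remap <- stats::setNames(seq_along(means), names(sort(means,
                                                        decreasing = TRUE)))
  out <- unname(remap[as.character(labels)])
  names(out) <- names(labels)
  out
}

#' Train the nearest-centroid subtype model
#'
#' Selects the signatures that differ across the clusters by multiclass SAM
#' at the given FDR, then computes one centroid per cluster: the per-signature
#' mean score over that cluster's training samples, restricted to the
#' selected signatures.
#'
#' @param m \linkS4class{SignatureScoreMatrix}.
#' @param labels cluster labels named by sample id.
#' @param fdr SAM selection FDR (default 0.05).
#' @param n_perm SAM permutations.
#' @param seed RNG seed.
#' @return \linkS4class{SubtypeModel}.
#' @export
buildCentroidModel <- function(m, labels, fdr = 0.05, n_perm = 1000L,
                               seed = 1L) {
  X <- scores(m)[, names(labels), drop = FALSE]
  sam <- multiclassSAM(X, labels, fdr = fdr, n_perm = n_perm, seed = seed)
  sel <- sam$selected
  if (!length(sel)) {
    stop("no signature passed SAM selection at FDR ", fdr,
         "; consider a looser fdr", call. = FALSE)
  }
  cl <- sort(unique(labels))
  cent <- matrix(vapply(cl, function(k) {
    rowMeans(X[sel, labels == k, drop = FALSE])
  }, numeric(length(sel))), nrow = length(sel))
  dimnames(cent) <- list(sel, as.character(cl))
  new("SubtypeModel", signatures = sel, centroids = cent,
      metadata = list(fdr = fdr, n_perm = n_perm, seed = seed,
                      n_per_cluster = as.list(table(labels))))
}

#' Assign a sample to the nearest centroid
#'
#' Euclidean distance to each cluster centroid over the model's selected
#' signatures; the sample gets the label of the nearest centroid, ties going
#' to the lowest-numbered cluster.
#'
#' @param model \linkS4class{SubtypeModel}.
#' @param v named numeric score vector covering all selected signatures, or
#'   a \linkS4class{SignatureScoreMatrix} (every sample is assigned).
#' @return for a vector: list with \code{label} and \code{distances}; for a
#'   matrix: data.frame with one row per sample plus per-cluster distance
#'   columns.
#' @export
assignSubtype <- function(model, v) {
  if (is(v, "SignatureScoreMatrix")) {
    s <- scores(v)
    res <- lapply(colnames(s), function(id) {
      a <- assignSubtype(model, s[, id])
      c(list(sample_id = id, label = a$label), as.list(a$distances))
    })
    return(do.call(rbind, lapply(res, as.data.frame)))
  }
  miss <- setdiff(model@signatures, names(v))
  if (length(miss)) {
    stop("score vector lacks selected signature(s): ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  x <- v[model@signatures]
  d <- sqrt(colSums((model@centroids - x)^2))
  names(d) <- colnames(model@centroids)
  list(label = names(d)[which.min(d)], distances = d)
}

#' Subdivide one cluster into two correlated subgroups
#'
#' Within the target cluster, the sample dendrogram (average linkage,
#' 1 - Pearson distance) is cut into its two top-level branches; the split is
#' accepted only when both branches have at least \code{min_size} samples and
#' each branch's mean pairwise Pearson correlation exceeds
#' \code{corr_threshold} (the study's rule: minimum 20 samples and a
#' correlation coefficient > 0.75). Otherwise the cluster is returned
#' undivided, which is a valid outcome.
#'
#' @param m \linkS4class{SignatureScoreMatrix}.
#' @param labels cluster labels named by sample id.
#' @param target_cluster label of the cluster to subdivide.
#' @param min_size minimum samples per branch (default 20).
#' @param corr_threshold minimum within-branch mean pairwise correlation
#'   (default 0.75).
#' @return character label vector for all samples; target-cluster members
#'   become e.g. \code{"2A"}/\code{"2B"} when the split is accepted.
#' @export
subdivideCluster <- function(m, labels, target_cluster, min_size = 20L,
                             corr_threshold = 0.75) {
  out <- as.character(labels)
  names(out) <- names(labels)
  members <- names(labels)[labels == target_cluster]
  if (length(members) < 2L * min_size) return(out)
  X <- scores(m)[, members, drop = FALSE]
  hc <- stats::hclust(.pearson_dist(X), method = "average")
  branch <- stats::cutree(hc, k = 2L)
  sizes <- table(branch)
  if (any(sizes < min_size)) return(out)
  mean_cor <- vapply(1:2, function(b) {
    C <- stats::cor(X[, branch == b, drop = FALSE])
    mean(C[upper.tri(C)])
  }, numeric(1))
  if (any(mean_cor <= corr_threshold)) return(out)
  out[members] <- paste0(target_cluster, c("A", "B")[branch])
  out
}
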