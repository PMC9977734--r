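# Consensus clustering, centroid model, nearest-centroid assignment,
# cluster subdivision.

# k_true blobs with distinct random mean patterns (so the 1 - Pearson
# distance between sample score profiles separates them) and within-blob
# noise of the given SD; separation between patterns is ~sqrt(2) in feature
# units, i.e. >= 5 noise SDs at sd <= 0.25.
make_blob_matrix <- function(k_true, n_each, n_feat = 20, sd = 0.15,
                             seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(n_feat * k_true), n_feat, k_true)
  X <- do.call(cbind, lapply(seq_len(k_true), function(k) {
    centers[, k] + matrix(rnorm(n_feat * n_each, sd = sd), n_feat, n_each)
  }))
  dimnames(X) <- list(sprintf("f%02d", seq_len(n_feat)),
                      sprintf("S%03d", seq_len(ncol(X))))
  X
}

test_that("consensus matrices are well-formed and duplicates always co-cluster", {
  X <- make_blob_matrix(2, n_each = 10, seed = 2)
  X[, 2] <- X[, 1]   # exact duplicate pair
  res <- consensusCluster(X, k_range = 2:3, n_resamples = 100, seed = 3)
  for (M in res@consensus) {
    expect_true(isSymmetric(unname(M)))
    expect_true(all(diag(M) == 1))
    expect_true(all(M >= 0 & M <= 1, na.rm = TRUE))
  }
  M2 <- res@consensus[["2"]]
  expect_equal(M2["S001", "S002"], 1)
})

test_that("consensus k selection recovers the generative k for k in 2..4", {
  for (k_true in 2:4) {
    X <- make_blob_matrix(k_true, n_each = 15, sd = 0.15,
                          seed = 10 + k_true)
    res <- consensusCluster(X, k_range = 2:6, n_resamples = 150,
                            seed = k_true)
    expect_equal(chosenK(res), k_true)
    # labels partition samples consistently with the blobs
    truth <- rep(seq_len(k_true), each = 15)
    tab <- table(clusterLabels(res), truth)
    expect_equal(sum(apply(tab, 2, max)), 15 * k_true)
  }
})

test_that("centroid model training selects the separating signature", {
  set.seed(5)
  n_per <- 8
  s <- rbind(informative = rep(c(0, 1), each = n_per) +
               rnorm(2 * n_per, sd = 0.01),
             matrix(rnorm(2 * n_per * 49, sd = 0.01), 49, 2 * n_per,
                    dimnames = list(sprintf("null%02d", 1:49), NULL)))
  colnames(s) <- sprintf("S%d", seq_len(2 * n_per))
  m <- make_ssm(s)
  labels <- setNames(rep(1:2, each = n_per), colnames(s))
  model <- buildCentroidModel(m, labels, fdr = 0.05, n_perm = 200, seed = 6)
  expect_true("informative" %in% signatureNames(model))
  cent <- centroids(model)["informative", ]
  expect_equal(unname(cent), c(0, 1), tolerance = 0.05)
  model2 <- buildCentroidModel(m, labels, fdr = 0.05, n_perm = 200, seed = 6)
  expect_identical(centroids(model), centroids(model2))
})

test_that("nearest-centroid assignment: exactness, ties, missing input", {
  cent <- cbind(`1` = c(0, 0), `2` = c(1, 1), `3` = c(2, 0))
  rownames(cent) <- c("sigA", "sigB")
  model <- new("SubtypeModel", signatures = c("sigA", "sigB"),
               centroids = cent, metadata = list())
  a <- assignSubtype(model, c(sigA = 2, sigB = 0))
  expect_equal(a$label, "3")
  expect_equal(unname(a$distances["3"]), 0)
  # exact tie between centroids 1 and 2 -> lowest-numbered cluster
  tie <- assignSubtype(model, c(sigA = 0.5, sigB = 0.5))
  expect_equal(tie$label, "1")
  expect_error(assignSubtype(model, c(sigA = 1)), "sigB")
})

test_that("a near-noiseless archetype cohort is recovered perfectly", {
  w <- tiny_world()
  arch4 <- c("cluster1", "cluster2", "cluster3", "cluster4")
  profs <- unlist(lapply(arch4, function(a) {
    lapply(1:5, function(i) {
      simulateSample(w$scheme, w$arch[[a]], tf = 0.5, noise_sd = 0.02,
                     seed = i, sample_id = sprintf("%s_%d", a, i))
    })
  }), recursive = FALSE)
  vecs <- lapply(profs, profileToFeatures, gene_map = w$gene_map,
                 sigs = w$sigs, adjust = TRUE)
  m <- scoreCohort(vecs, w$sigs)
  truth <- setNames(rep(arch4, each = 5), colnames(scores(m)))
  labels <- setNames(as.integer(factor(truth)), names(truth))
  model <- buildCentroidModel(m, labels, fdr = 0.05, n_perm = 150, seed = 2)
  asg <- assignSubtype(model, m)
  expect_equal(as.character(asg$label),
               as.character(labels[asg$sample_id]))
})

test_that("cluster subdivision obeys the size and correlation gates", {
  # two tight, separated pattern blobs of 25 each -> accepted split
  X <- make_blob_matrix(2, n_each = 25, sd = 0.05, seed = 7)
  labels <- setNames(rep(2L, 50), colnames(X))
  m <- make_ssm(X)
  sub <- subdivideCluster(m, labels, target_cluster = 2L)
  expect_setequal(unique(sub), c("2A", "2B"))
  expect_equal(sort(as.vector(table(sub))), c(25, 25))

  # homogeneous (patternless) cluster: branch correlations stay low -> undivided
  set.seed(8)
  Xh <- matrix(rnorm(20 * 50, sd = 0.5), 20, 50,
               dimnames = list(sprintf("f%02d", 1:20),
                               sprintf("S%03d", 1:50)))
  labs_h <- setNames(rep(2L, 50), colnames(Xh))
  expect_equal(unique(subdivideCluster(make_ssm(Xh), labs_h, 2L)), "2")

  # 30 samples cannot yield two branches of >= 20 -> undivided
  X30 <- make_blob_matrix(2, n_each = 15, sd = 0.05, seed = 9)
  labs_30 <- setNames(rep(2L, 30), colnames(X30))
  expect_equal(unique(subdivideCluster(make_ssm(X30), labs_30, 2L)), "2")
})

test_that("relabeling orders clusters by the designated signature", {
  s <- rbind(LuminalA_like = c(5, 5, 1, 1, 3, 3))
  colnames(s) <- sprintf("S%d", 1:6)
  m <- make_ssm(s)
  labels <- setNames(c(1L, 1L, 2L, 2L, 3L, 3L), colnames(s))
  out <- relabelClusters(labels, m, "LuminalA_like")
  expect_equal(unname(out), c(1L, 1L, 3L, 3L, 2L, 2L))
})
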