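# Weighted-sum scoring, cohort matrices, TF-correlation screen, ablation.

test_that("signature scores are weighted sums with documented edge cases", {
  v <- make_fv(c(seg_001 = 0.5, seg_002 = 0.5))
  expect_equal(as.numeric(scoreSignature(v, c(seg_001 = 1, seg_002 = -1))), 0)
  expect_equal(as.numeric(scoreSignature(make_fv(c(seg_001 = 0.3)),
                                         c(seg_001 = 2))), 0.6)
  # normalization toggle divides by sum(|w|)
  expect_equal(as.numeric(scoreSignature(v, c(seg_001 = 3, seg_002 = 1),
                                         normalize = TRUE)), 2 / 4 * 1)
  expect_error(scoreSignature(v, c(seg_099 = 1)), "seg_099")
})

test_that("scoring equals a term-by-term oracle and is linear", {
  set.seed(3)
  for (rep in 1:20) {
    x <- rnorm(10)
    w <- rnorm(10)
    names(x) <- names(w) <- sprintf("seg_%03d", 1:10)
    v <- make_fv(x)
    oracle <- 0
    for (i in seq_along(w)) oracle <- oracle + w[[i]] * x[[i]]
    expect_equal(as.numeric(scoreSignature(v, w)), oracle)
    # linearity: score(v1 + v2) = score(v1) + score(v2)
    y <- rnorm(10); names(y) <- names(x)
    expect_equal(as.numeric(scoreSignature(make_fv(x + y), w)),
                 as.numeric(scoreSignature(make_fv(x), w)) +
                   as.numeric(scoreSignature(make_fv(y), w)))
  }
})

test_that("a neutral (all-zero) vector scores 0 for every signature", {
  w <- tiny_world()
  fv <- make_fv(setNames(rep(0, schemeSize(w$sigs)),
                         mcols(segmentScheme(w$sigs))$segment_id))
  for (sig in signatureNames(w$sigs)) {
    expect_equal(as.numeric(scoreSignature(fv, signatureWeights(w$sigs, sig))),
                 0)
  }
})

test_that("imputation above the threshold flags a low-confidence score", {
  v <- make_fv(c(seg_001 = 0.1, seg_002 = 0, seg_003 = 0),
               imputed = c(FALSE, TRUE, TRUE))
  s <- scoreSignature(v, c(seg_001 = 1, seg_002 = 1, seg_003 = 1))
  expect_true(attr(s, "lowConfidence"))
  s2 <- scoreSignature(v, c(seg_001 = 1, seg_002 = 1, seg_003 = 1),
                       max_imputed_frac = 0.8)
  expect_false(attr(s2, "lowConfidence"))
})

test_that("cohort scoring matches per-sample scoring and validates input", {
  ids <- sprintf("seg_%03d", 1:5)
  ss <- make_sigset(rep(list("g"), 5),
                    weights = list(A = setNames(c(1, -1), ids[1:2]),
                                   B = setNames(2, ids[5])))
  set.seed(9)
  vecs <- lapply(1:3, function(i) {
    make_fv(setNames(rnorm(5), ids), sample_id = sprintf("P%d", i))
  })
  m <- scoreCohort(vecs, ss)
  expect_equal(dim(scores(m)), c(2L, 3L))
  for (i in 1:3) {
    for (sig in c("A", "B")) {
      expect_equal(scores(m)[sig, i],
                   as.numeric(scoreSignature(vecs[[i]],
                                             signatureWeights(ss, sig))))
    }
  }
  expect_error(scoreCohort(list(), ss), "empty cohort")
  expect_error(scoreCohort(c(vecs, vecs[1]), ss), "duplicate")
})

test_that("TF-correlation screen bands rho and handles degenerate rows", {
  tf <- c(0.05, 0.1, 0.2, 0.4, 0.6)
  s <- rbind(same = tf, neg = -tf, flat = rep(1, 5),
             mid = 0.6 * scale(tf)[, 1] + c(0.4, -0.5, 0.3, -0.2, 0.0))
  colnames(s) <- sprintf("S%d", 1:5)
  m <- make_ssm(s, tf = setNames(tf, colnames(s)))
  scr <- tfCorrelationScreen(m)
  expect_equal(scr$rho[scr$signature == "same"], 1)
  expect_equal(scr$band[scr$signature == "same"], "strong")
  expect_equal(scr$rho[scr$signature == "neg"], -1)
  expect_equal(scr$band[scr$signature == "neg"], "strong")
  expect_true(is.na(scr$rho[scr$signature == "flat"]))
  expect_equal(scr$band[scr$signature == "flat"], "undefined")
})

test_that("raw scores track TF while adjusted scores do not", {
  w <- tiny_world()
  set.seed(21)
  b <- makeCohort(cohortConfig(
    n_per_archetype = c(cluster1 = 10, cluster2 = 10, cluster3 = 10,
                        cluster4 = 10),
    n_segments = 44L, bins_per_segment = 3L, genes_per_segment = 2L,
    n_signatures = 30L, seed = 13))
  raw_max <- max(abs(tfCorrelationScreen(b$scores_raw)$rho), na.rm = TRUE)
  adj_max <- max(abs(tfCorrelationScreen(b$scores)$rho), na.rm = TRUE)
  expect_gt(raw_max, 0.7)     # raw signal scales with tumor fraction
  expect_lt(adj_max, 0.5)     # adjustment removes the TF dependence
})

test_that("ablation is deterministic, honors identity, and reports failures", {
  w <- tiny_world()
  cc <- cohortConfig(n_per_archetype = c(cluster1 = 20, cluster3 = 20),
                     n_segments = 44L, bins_per_segment = 3L,
                     genes_per_segment = 2L, n_signatures = 30L, seed = 4)
  b <- makeCohort(cc, include_raw = FALSE)
  abl0 <- signatureAblation(b$signatures, "RB_LOH_like", b$vectors,
                            b$clinical, n_remove = 0L, reps = 3L, seed = 2)
  # n_remove = 0 reproduces the un-ablated fit in every rep
  z <- scale(scores(b$scores)["RB_LOH_like", ])[, 1]
  clin <- clinicalData(b$clinical)
  ref <- survival::coxph(survival::Surv(pfs_months, pfs_event) ~ z,
                         data = clin, ties = "efron")
  expect_equal(abl0$mean_hr, unname(exp(coef(ref))), tolerance = 1e-10)

  a1 <- signatureAblation(b$signatures, "RB_LOH_like", b$vectors, b$clinical,
                          n_remove = c(5L, 10L), reps = 10L, seed = 7)
  a2 <- signatureAblation(b$signatures, "RB_LOH_like", b$vectors, b$clinical,
                          n_remove = c(5L, 10L), reps = 10L, seed = 7)
  expect_identical(a1, a2)
  expect_error(
    signatureAblation(b$signatures, "RB_LOH_like", b$vectors, b$clinical,
                      n_remove = 10000L, reps = 2L),
    "smaller than")
})
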