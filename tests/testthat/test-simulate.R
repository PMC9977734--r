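# Synthetic cohort generator: mixture arithmetic, determinism, dilution,
# downsampling, paired tissue, outcome model, cohort bundles.

test_that("scheme geometry partitions bins and genes into segments", {
  sch <- makeGenomeScheme(n_segments = 120L, bins_per_segment = 5L,
                          genes_per_segment = 3L)
  expect_equal(length(schemeSegments(sch)), 120L)
  expect_equal(length(schemeBins(sch)), 600L)
  expect_equal(length(schemeGenes(sch)), 360L)
  # every gene maps to exactly one canonical segment, by containment
  hits <- findOverlaps(schemeGenes(sch), schemeSegments(sch))
  expect_equal(length(hits), length(schemeGenes(sch)))
  expect_equal(
    mcols(schemeSegments(sch))$segment_id[subjectHits(hits)],
    mcols(schemeGenes(sch))$segment_id)
  # full-size scheme on demand
  full <- makeGenomeScheme(n_segments = 514L)
  expect_equal(length(schemeSegments(full)), 514L)
})

test_that("archetypes include the documented landscapes and a diploid healthy", {
  w <- tiny_world()
  expect_setequal(names(w$arch),
                  c("cluster1", "cluster2", "cluster2A", "cluster2B",
                    "cluster3", "cluster4", "healthy"))
  expect_true(all(archetypeCopyNumber(w$arch$healthy) == 2))
  expect_equal(ploidy(w$arch$healthy), 2)
  # cluster 3 carries gains and deletions (the RB-LOH-like landscape)
  cn3 <- archetypeCopyNumber(w$arch$cluster3)
  expect_true(any(cn3 > 2) && any(cn3 < 2))
})

test_that("tumor-free samples average zero and pure tumor hits the closed form", {
  w <- tiny_world()
  p0 <- simulateSample(w$scheme, w$arch$healthy, tf = 0, noise_sd = 0.1,
                       seed = 2, sample_id = "H1")
  expect_lt(abs(mean(binTable(p0)$log2)), 3 * 0.1 / sqrt(nrow(binTable(p0))))

  p1 <- simulateSample(w$scheme, w$arch$cluster3, tf = 1, noise_sd = 0,
                       seed = 3, sample_id = "T1")
  cn <- archetypeCopyNumber(w$arch$cluster3)
  seg <- segments(p1)
  gained <- mcols(seg)$corrected_copy_number == 4
  expect_true(any(gained))
  expect_equal(mcols(seg)$log2_ratio[gained],
               rep(1, sum(gained)))           # log2(4/2) = 1 at tf = 1
})

test_that("simulation is deterministic in the seed", {
  w <- tiny_world()
  a <- simulateSample(w$scheme, w$arch$cluster2, tf = 0.3, noise_sd = 0.1,
                      seed = 9)
  b <- simulateSample(w$scheme, w$arch$cluster2, tf = 0.3, noise_sd = 0.1,
                      seed = 9)
  expect_identical(binTable(a)$log2, binTable(b)$log2)
  c2 <- simulateSample(w$scheme, w$arch$cluster2, tf = 0.3, noise_sd = 0.1,
                       seed = 10)
  expect_false(identical(binTable(a)$log2, binTable(c2)$log2))
})

test_that("noiseless mixture matches log2(tf*c/2 + 1 - tf) exactly", {
  w <- tiny_world()
  for (tf in c(0.05, 0.2, 0.5, 0.9)) {
    p <- simulateSample(w$scheme, w$arch$cluster4, tf = tf, noise_sd = 0,
                        seed = 1)
    seg <- segments(p)
    cexp <- log2(tf * mcols(seg)$corrected_copy_number / 2 + (1 - tf))
    expect_equal(mcols(seg)$log2_ratio, cexp)
  }
})

test_that("dilution series shrinks segment values monotonically toward 0", {
  w <- tiny_world()
  dil <- dilutionSeries(w$scheme, w$arch$cluster3, noise_sd = 0, seed = 1)
  expect_equal(names(dil), sprintf("tf_%g", c(0.5, 0.2, 0.1, 0.05, 0.01)))
  # the study's worked value: a c=4 segment at fraction 0.5 -> log2(1.5)
  seg <- segments(dil[["tf_0.5"]])
  expect_equal(unique(mcols(seg)$log2_ratio[
    mcols(seg)$corrected_copy_number == 4]), log2(1.5))
  # per-segment |value| decreases with the fraction, toward 0
  vals <- vapply(dil, function(p) mcols(segments(p))$log2_ratio,
                 numeric(length(segments(dil[[1]]))))
  for (i in seq_len(nrow(vals))) {
    expect_true(all(diff(abs(vals[i, ])) <= 1e-12))
  }
})

test_that("downsampling inflates bin noise by the shot-noise rule", {
  w <- tiny_world()
  full <- simulateSample(w$scheme, w$arch$cluster3, tf = 0.2, noise_sd = 0.1,
                         seed = 4)
  same <- downsampleProfile(full, 1)
  expect_identical(binTable(same)$log2, binTable(full)$log2)

  quarter <- downsampleProfile(full, 0.25, seed = 5)
  expect_equal(attr(binTable(quarter), "noise_sd"), 0.2)  # SD doubled
  added <- binTable(quarter)$log2 - binTable(full)$log2
  expect_equal(sd(added), 0.1 * sqrt(1 / 0.25 - 1), tolerance = 0.15)

  # correlation with the full profile degrades as coverage drops
  half <- downsampleProfile(full, 0.5, seed = 6)
  twentieth <- downsampleProfile(full, 0.05, seed = 7)
  expect_gt(cor(binTable(full)$log2, binTable(half)$log2),
            cor(binTable(full)$log2, binTable(twentieth)$log2))
})

test_that("paired tissue concordance is recovered from the generator", {
  w <- tiny_world()
  plasma <- simulateSample(w$scheme, w$arch$cluster3, tf = 0.4,
                           noise_sd = 0, seed = 8)
  tis1 <- simulatePairedTissue(plasma, w$scheme, w$arch, concordance = 1,
                               noise_sd = 0, seed = 9)
  expect_equal(
    tapply(binTable(tis1)$truth_cn, binTable(tis1)$segment_id, `[`, 1),
    tapply(binTable(plasma)$truth_cn, binTable(plasma)$segment_id, `[`, 1))

  # concordance 0.8: paired feature correlation lands well above the
  # independent-archetype baseline
  gm <- w$gene_map
  rho_at <- function(conc, seeds) {
    vapply(seeds, function(s) {
      pl <- simulateSample(w$scheme, w$arch$cluster3, tf = 0.5,
                           noise_sd = 0.05, seed = s)
      ts <- simulatePairedTissue(pl, w$scheme, w$arch, concordance = conc,
                                 noise_sd = 0.05, seed = s + 1000)
      va <- profileToFeatures(pl, gm, w$sigs, adjust = TRUE)
      vb <- profileToFeatures(ts, gm, w$sigs, adjust = TRUE)
      pairedProfileCorrelation(va, vb)$rho
    }, numeric(1))
  }
  high <- median(rho_at(0.9, 1:8))
  low <- median(rho_at(0.1, 1:8))
  expect_gt(high, 0.8)
  expect_gt(high, low + 0.2)
})

test_that("outcome model: null beta gives HR near 1, clusters drive response", {
  set.seed(40)
  s <- matrix(rnorm(150 * 600), 150, 600,
              dimnames = list(c("RB_LOH_like", sprintf("x%03d", 1:149)),
                              sprintf("S%03d", 1:600)))
  m <- make_ssm(s, tf = setNames(runif(600, 0.05, 0.6), colnames(s)))
  clin0 <- clinicalData(simulateOutcomes(m, beta = c(RB_LOH_like = 0),
                                         seed = 41))
  f0 <- coxFit(clin0$pfs_months, clin0$pfs_event,
               data.frame(z = scale(s["RB_LOH_like", ])[, 1]))
  expect_lt(abs(log(f0$terms$hr[1])), 0.2)

  truth <- setNames(rep(sprintf("cluster%d", 1:4), each = 150), colnames(s))
  clin <- clinicalData(simulateOutcomes(m, beta = c(RB_LOH_like = 0.5),
                                        cluster_labels = truth, seed = 42))
  expect_true(all(clin$pfs_months >= 0))
  expect_true(all(clin$response %in% c("CR", "PR", "SD", "PD")))
  # configured ORR gradient (52.7/34.0/7.1/16.7%) is detectable at n=600
  responder <- clin$response %in% c("CR", "PR")
  tab <- table(clin$cluster, responder)
  expect_lt(contingencyTest(tab)$p, 0.001)
  rates <- groupRates(clin$cluster, responder)
  expect_gt(rates$rate[rates$group == "cluster1"],
            rates$rate[rates$group == "cluster3"])
})

test_that("cohort bundles are reproducible and respect the TF structure", {
  cc <- cohortConfig(n_per_archetype = c(cluster1 = 12, cluster2 = 12,
                                         cluster3 = 12, cluster4 = 12),
                     n_segments = 44L, bins_per_segment = 3L,
                     genes_per_segment = 2L, n_signatures = 25L, seed = 17)
  b1 <- makeCohort(cc, include_raw = FALSE)
  b2 <- makeCohort(cc, include_raw = FALSE)
  expect_identical(scores(b1$scores), scores(b2$scores))
  expect_identical(clinicalData(b1$clinical), clinicalData(b2$clinical))
  # cluster 1 is generated at lower tumor fractions (default config)
  tf <- tumorFraction(b1$scores)
  expect_lt(mean(tf[b1$truth == "cluster1"]),
            mean(tf[b1$truth != "cluster1"]))
  expect_equal(nrow(clinicalData(b1$clinical)), 48L)
})
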