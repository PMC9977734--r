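# Gene-level mapping, scheme averaging, TF/ploidy adjustment, altered counts,
# TF gate.

test_that("gene values take their segment's value, overlap-weighted", {
  prof <- make_profile("1", c(1, 751), c(750, 1000), c(0.0, 1.0))
  gm <- GRanges(c("1", "1", "2"),
                IRanges(start = c(100, 1, 1), end = c(200, 1000, 500)))
  mcols(gm)$gene <- c("inside", "split", "nosegs")
  prof2 <- make_profile("1", 1, 1000, 0.3)
  g1 <- geneLevelValues(prof2, gm[1])
  expect_equal(g1$value, 0.3)

  g <- geneLevelValues(prof, gm)
  # 75% of the gene in the 0.0 segment, 25% in the 1.0 segment
  expect_equal(g$value[g$gene == "split"], 0.25)
  expect_true(g$missing[g$gene == "nosegs"])
  expect_false(g$missing[g$gene == "split"])

  expect_error(geneLevelValues(prof, gm[0]), "empty gene map")
})

test_that("segment features average member genes; empty segments impute 0", {
  ss <- make_sigset(list(c("a", "b", "c"), c("d", "e"), "f"))
  genes <- data.frame(gene = letters[1:5],
                      value = c(1, 2, 3, 0.5, NA),
                      missing = c(rep(FALSE, 4), TRUE))
  prof <- make_profile("1", 1, 1000, 0)
  fv <- segmentFeatureVector(genes, ss, prof)
  expect_equal(unname(featureValues(fv)), c(2, 0.5, 0))
  expect_equal(unname(imputedFlags(fv)), c(FALSE, FALSE, TRUE))
  expect_equal(length(featureValues(fv)), schemeSize(ss))
})

test_that("segment averaging matches a brute-force oracle on random input", {
  set.seed(42)
  n_seg <- 6
  members <- split(sprintf("g%02d", 1:20),
                   rep(seq_len(n_seg), length.out = 20))
  ss <- make_sigset(members)
  genes <- data.frame(gene = sprintf("g%02d", 1:20),
                      value = rnorm(20), missing = runif(20) < 0.2)
  genes$value[genes$missing] <- NA
  prof <- make_profile("1", 1, 1000, 0)
  fv <- segmentFeatureVector(genes, ss, prof)
  oracle <- vapply(members, function(gs) {
    v <- genes$value[match(gs, genes$gene)]
    v <- v[!is.na(v)]
    if (length(v) == 0) 0 else sum(v) / length(v)
  }, numeric(1))
  expect_equal(unname(featureValues(fv)), unname(oracle))
})

test_that("TF/ploidy adjustment is log2(copy number / ploidy)", {
  prof <- make_profile("1", c(1, 1001, 2001), c(1000, 2000, 3000),
                       c(0.5, 0.9, -0.2), ccn = c(2, 4, 1.6),
                       tf = 0.3, ploidy = 2)
  adj <- adjustForTFPloidy(prof)
  expect_true(isAdjusted(adj))
  expect_equal(mcols(segments(adj))$log2_ratio[1:2], c(0, 1))

  prof32 <- make_profile("1", 1, 1000, 0, ccn = 1.6, tf = 0.3, ploidy = 3.2)
  expect_equal(mcols(segments(adjustForTFPloidy(prof32)))$log2_ratio, -1)
})

test_that("adjustment identity: copy number equal to ploidy maps to 0", {
  set.seed(7)
  for (pl in c(1.8, 2, 2.7, 3.9)) {
    prof <- make_profile("1", (0:9) * 1000 + 1, (1:10) * 1000,
                         rnorm(10), ccn = rep(pl, 10), tf = 0.4, ploidy = pl)
    expect_equal(mcols(segments(adjustForTFPloidy(prof)))$log2_ratio,
                 rep(0, 10))
  }
})

test_that("adjustment gates on TF > 0 and requires corrected copy number", {
  p0 <- make_profile("1", 1, 1000, 0.5, ccn = 2, tf = 0)
  expect_error(adjustForTFPloidy(p0), "tfGate")
  p1 <- make_profile("1", 1, 1000, 0.5, tf = 0.2)
  expect_error(adjustForTFPloidy(p1), "corrected_copy_number")
})

test_that("altered-segment counting applies the printed cutoffs strictly", {
  expect_equal(countAltered(make_fv(c(0.40, -0.50, 0.10), adjusted = TRUE)), 2)
  # boundary values are not altered (strict inequality)
  expect_equal(countAltered(make_fv(c(0.07, -0.07, 0.0), adjusted = FALSE)), 0)
  expect_equal(countAltered(make_fv(c(0.32, -0.42), adjusted = TRUE)), 0)
  expect_equal(countAltered(make_fv(numeric(0), imputed = logical(0))), 0)
  expect_equal(alteredThresholds(FALSE), c(gain = 0.07, loss = -0.07))
  expect_equal(alteredThresholds(TRUE), c(gain = 0.32, loss = -0.42))
})

test_that("altered count is non-increasing as threshold magnitudes grow", {
  set.seed(11)
  x <- rnorm(200, sd = 0.5)
  counts <- vapply(seq(0, 1, by = 0.05), function(th) {
    sum(x > th | x < -th)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # and the adjusted pair (larger magnitudes) never flags more than raw
  expect_lte(countAltered(x, adjusted = TRUE),
             countAltered(x, adjusted = FALSE))
})

test_that("TF gate is inclusive at the 3% cutoff and validates range", {
  expect_true(tfGate(0.094))
  expect_false(tfGate(0.029))
  expect_true(tfGate(0.03))
  expect_equal(tfGate(c(0, 0.03, 1)), c(FALSE, TRUE, TRUE))
  expect_error(tfGate(1.2), "\\[0, 1\\]")
  expect_error(tfGate(-0.1), "\\[0, 1\\]")
})
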