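# Shared fixture builders: tiny hand-sized objects constructed in code.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

# A profile from a bare segment table (1-based closed coordinates).
make_profile <- function(chrom, start, end, log2_ratio, ccn = NULL,
                         sample_id = "S1", tf = 0.2, ploidy = 2,
                         adjusted = FALSE) {
  gr <- GRanges(chrom, IRanges(start = start, end = end))
  mcols(gr)$log2_ratio <- log2_ratio
  if (!is.null(ccn)) mcols(gr)$corrected_copy_number <- ccn
  new("SegmentationProfile", sampleId = sample_id, segments = gr,
      tumorFraction = tf, ploidy = ploidy, dialect = "generic_seg",
      adjusted = adjusted, bins = NULL)
}

# A SignatureSet over n dummy segments on one chromosome; each segment has
# the given member genes (list of character vectors).
make_sigset <- function(member_genes, weights = list()) {
  n <- length(member_genes)
  gr <- GRanges("1", IRanges(start = (seq_len(n) - 1) * 1000 + 1,
                             width = 1000))
  mcols(gr)$segment_id <- sprintf("seg_%03d", seq_len(n))
  mcols(gr)$genes <- vapply(member_genes, paste, character(1), collapse = ",")
  new("SignatureSet", scheme = gr, weights = weights)
}

# A feature vector straight from values.
make_fv <- function(values, imputed = rep(FALSE, length(values)),
                    sample_id = "S1", adjusted = TRUE, tf = 0.2, ploidy = 2) {
  if (is.null(names(values))) {
    names(values) <- sprintf("seg_%03d", seq_along(values))
  }
  names(imputed) <- names(values)
  new("SegmentFeatureVector", sampleId = sample_id, values = values,
      imputed = imputed, adjusted = adjusted, tumorFraction = tf,
      ploidy = ploidy)
}

# A score matrix from a bare matrix.
make_ssm <- function(s, tf = NULL, adjusted = TRUE) {
  if (is.null(rownames(s))) rownames(s) <- sprintf("sig%d", seq_len(nrow(s)))
  if (is.null(colnames(s))) colnames(s) <- sprintf("S%03d", seq_len(ncol(s)))
  if (is.null(tf)) tf <- stats::setNames(rep(0.2, ncol(s)), colnames(s))
  new("SignatureScoreMatrix", scores = s, tumorFraction = tf,
      adjusted = adjusted,
      lowConfidence = matrix(FALSE, nrow(s), ncol(s), dimnames = dimnames(s)))
}

# Small shared synthetic world for subtyping/simulation tests.
tiny_world <- function(seed = 5) {
  scheme <- makeGenomeScheme(n_segments = 44L, bins_per_segment = 3L,
                             genes_per_segment = 2L)
  arch <- makeArchetypes(scheme)
  sigs <- makeSignatureSet(scheme, n_signatures = 30L, seed = seed)
  list(scheme = scheme, arch = arch, sigs = sigs,
       gene_map = schemeGenes(scheme))
}

write_generic_seg <- function(path, df) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
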