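# Pipeline orchestration: the score / subtype / survival / simulate /
# validate stages as plain R functions over a validated run configuration.
# Each stage writes its outputs plus a manifest (inputs, seed, package
# version, output checksums) so a run is reproducible from its manifest.
# A thin command-line dispatcher over these functions ships in
# inst/scripts/ctdnasig.

#' Run configuration
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed used by every stochastic stage.
#' @param tf_cutoff tumor-fraction gate (default 0.03).
#' @param adjust apply TF/ploidy adjustment before scoring (default TRUE).
#' @param seg_path,params_path,gene_map_path,weights_path,scheme_path input
#'   artifact paths (as written by \code{\link{cmdSimulate}} or from a real
#'   ichorCNA run).
#' @param scores_path,clinical_path inputs for the subtype/survival stages.
#' @param model \code{"train"} or a saved model prefix for
#'   \code{\link{loadSubtypeModel}}.
#' @param signature signature analyzed by the survival stage.
#' @param cutpoints optional frozen tertile cutpoints (length 2) to reuse.
#' @param k_range,n_resamples consensus clustering controls.
#' @param cohort optional \code{\link{cohortConfig}} for the simulate stage.
#' @return validated \code{runConfig} list.
#' @export
runConfig <- function(out_dir, seed = 1L, tf_cutoff = 0.03, adjust = TRUE,
                      seg_path = NULL, params_path = NULL,
                      gene_map_path = NULL, weights_path = NULL,
                      scheme_path = NULL, scores_path = NULL,
                      clinical_path = NULL, model = "train",
                      signature = "RB_LOH_like", cutpoints = NULL,
                      k_range = 2:6, n_resamples = 250L, cohort = NULL) {
  stopifnot(tf_cutoff >= 0, tf_cutoff <= 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 tf_cutoff = tf_cutoff, adjust = adjust, seg_path = seg_path,
                 params_path = params_path, gene_map_path = gene_map_path,
                 weights_path = weights_path, scheme_path = scheme_path,
                 scores_path = scores_path, clinical_path = clinical_path,
                 model = model, signature = signature, cutpoints = cutpoints,
                 k_range = k_range, n_resamples = n_resamples,
                 cohort = cohort),
            class = "runConfig")
}

#' Read a run configuration from YAML
#' @param path YAML file; keys as in \code{\link{runConfig}}.
#' @param overrides named list overriding file values.
#' @return \code{runConfig}.
#' @export
readRunConfig <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(runConfig, vals)
}

.write_manifest <- function(config, stage, inputs, outputs) {
  man <- list(stage = stage,
              package_version = as.character(utils::packageVersion("ctDNAsig")),
              seed = config$seed,
              timestamp = format(Sys.time(), tz = "UTC"),
              inputs = inputs,
              outputs = lapply(outputs, function(f) {
                list(path = f, md5 = unname(tools::md5sum(f)))
              }))
  path <- file.path(config$out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  path
}

.ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Simulate stage: write a synthetic cohort bundle to disk
#'
#' Writes SEG (ichorCNA-style columns), a parameter record, the gene BED, the
#' signature weight/scheme TSVs, the clinical CSV and the truth labels, in
#' the same formats real ichorCNA-derived inputs would use.
#'
#' @param config \code{\link{runConfig}} (its \code{cohort} field, or a
#'   default \code{\link{cohortConfig}} seeded from \code{config$seed}).
#' @return invisible list of written paths plus the in-memory bundle.
#' @export
cmdSimulate <- function(config) {
  .ensure_dir(config$out_dir)
  cc <- if (is.null(config$cohort)) cohortConfig(seed = config$seed) else
    config$cohort
  bundle <- makeCohort(cc)
  p <- function(f) file.path(config$out_dir, f)
  writeSeg(bundle$profiles, p("cohort.seg"))
  params <- data.frame(
    sample_id = names(bundle$profiles),
    tumor_fraction = vapply(bundle$profiles, tumorFraction, numeric(1)),
    ploidy = vapply(bundle$profiles, ploidy, numeric(1)))
  utils::write.table(params, p("cohort_params.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeGeneMap(schemeGenes(bundle$scheme), p("genes.bed"))
  writeSignatureSet(bundle$signatures, p("signature_weights.tsv"),
                    p("signature_scheme.tsv"))
  writeClinical(bundle$clinical, p("clinical.csv"))
  utils::write.table(
    data.frame(sample_id = names(bundle$truth), truth = bundle$truth),
    p("truth_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  outs <- c(p("cohort.seg"), p("cohort_params.tsv"), p("genes.bed"),
            p("signature_weights.tsv"), p("signature_scheme.tsv"),
            p("clinical.csv"), p("truth_labels.tsv"))
  .write_manifest(config, "simulate",
                  inputs = list(cohort_seed = cc$seed), outputs = outs)
  invisible(list(paths = outs, bundle = bundle))
}

#' Score stage: SEG in, gated signature score matrix out
#'
#' Applies the TF gate (excluded samples are reported with reasons), the
#' optional TF/ploidy adjustment, gene-level mapping, scheme averaging and
#' signature scoring. Also writes the altered-segment counts per sample.
#'
#' @param config \code{\link{runConfig}} with \code{seg_path},
#'   \code{params_path}, \code{gene_map_path}, \code{weights_path},
#'   \code{scheme_path} set.
#' @return invisible \linkS4class{SignatureScoreMatrix}.
#' @export
cmdScore <- function(config) {
  .ensure_dir(config$out_dir)
  params <- readIchorParams(config$params_path)
  profiles <- readSeg(config$seg_path, dialect = "ichorcna", params = params)
  gene_map <- readGeneMap(config$gene_map_path)
  sigs <- readSignatureSet(config$weights_path, config$scheme_path)

  tf <- vapply(profiles, tumorFraction, numeric(1))
  pass <- tfGate(tf, config$tf_cutoff)
  gate <- data.frame(sample_id = names(profiles), tumor_fraction = tf,
                     passed = pass,
                     reason = ifelse(pass, "",
                                     sprintf("TF %.3f below cutoff %.3f", tf,
                                             config$tf_cutoff)))
  p <- function(f) file.path(config$out_dir, f)
  utils::write.table(gate, p("tf_gate_report.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!any(pass)) {
    stop(errorCondition("no sample passes the TF gate",
                        class = c("ctdnasig_empty_after_gate", "error")))
  }
  kept <- profiles[pass]
  vectors <- lapply(kept, profileToFeatures, gene_map = gene_map,
                    sigs = sigs, adjust = config$adjust)
  m <- scoreCohort(vectors, sigs)
  writeScoreMatrix(m, p("score_matrix.tsv"))
  altered <- data.frame(
    sample_id = vapply(vectors, sampleId, character(1)),
    n_altered = vapply(vectors, countAltered, integer(1)),
    missingnessReport(vectors)[, -1, drop = FALSE])
  utils::write.table(altered, p("altered_segments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .write_manifest(config, "score",
                  inputs = list(seg = config$seg_path,
                                params = config$params_path,
                                adjust = config$adjust,
                                tf_cutoff = config$tf_cutoff),
                  outputs = c(p("tf_gate_report.tsv"), p("score_matrix.tsv"),
                              p("altered_segments.tsv")))
  invisible(m)
}

#' Subtype stage: consensus clusters and/or nearest-centroid assignment
#'
#' With \code{model = "train"}: consensus clustering, relabeling by the
#' luminal-A-like signature when present, centroid model training and
#' serialization. With a model prefix: assignment of every sample to the
#' nearest stored centroid.
#'
#' @param config \code{\link{runConfig}} with \code{scores_path} set.
#' @return invisible list (labels, model, consensus when trained).
#' @export
cmdSubtype <- function(config) {
  .ensure_dir(config$out_dir)
  m <- readScoreMatrix(config$scores_path)
  p <- function(f) file.path(config$out_dir, f)
  if (identical(config$model, "train")) {
    cons <- consensusCluster(m, k_range = config$k_range,
                             n_resamples = config$n_resamples,
                             seed = config$seed)
    labels <- clusterLabels(cons)
    if ("LuminalA_like" %in% signatureNames(m)) {
      labels <- relabelClusters(labels, m, "LuminalA_like")
    }
    model <- buildCentroidModel(m, labels, seed = config$seed)
    saveSubtypeModel(model, p("subtype_model"))
    res <- list(labels = labels, model = model, consensus = cons)
  } else {
    model <- loadSubtypeModel(config$model)
    asg <- assignSubtype(model, m)
    labels <- stats::setNames(asg$label, asg$sample_id)
    res <- list(labels = labels, model = model)
  }
  utils::write.table(
    data.frame(sample_id = names(res$labels), cluster = res$labels),
    p("subtype_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  .write_manifest(config, "subtype",
                  inputs = list(scores = config$scores_path,
                                model = config$model),
                  outputs = p("subtype_labels.tsv"))
  invisible(res)
}

#' Survival stage: tertile KM/log-rank and Cox for one signature
#'
#' Derives tertile groups for the configured signature (or applies frozen
#' cutpoints from a previous cohort), runs KM with the log-rank test on PFS,
#' and fits the univariate and TF-adjusted Cox models on the per-SD
#' standardized score. Results go to a JSON report.
#'
#' @param config \code{\link{runConfig}} with \code{scores_path} and
#'   \code{clinical_path} set.
#' @return invisible report list.
#' @export
cmdSurvival <- function(config) {
  .ensure_dir(config$out_dir)
  m <- readScoreMatrix(config$scores_path)
  clin <- clinicalData(readClinical(config$clinical_path))
  s <- scores(m)[config$signature, ]
  hit <- match(colnames(scores(m)), clin$sample_id)
  if (anyNA(hit)) stop("clinical table lacks scored sample(s)")
  clin <- clin[hit, ]
  if (is.null(config$cutpoints)) {
    tert <- tertileGroups(s)
  } else {
    tert <- list(labels = applyCutpoints(s, config$cutpoints),
                 cutpoints = config$cutpoints)
  }
  km <- kmLogrank(clin$pfs_months, clin$pfs_event, tert$labels)
  z <- (s - mean(s)) / stats::sd(s)
  uni <- coxFit(clin$pfs_months, clin$pfs_event, data.frame(score = z))
  adj <- coxFit(clin$pfs_months, clin$pfs_event,
                data.frame(score = z, tf = clin$tf))
  report <- list(signature = config$signature,
                 cutpoints = tert$cutpoints,
                 median_pfs_by_tertile = as.list(km$median),
                 logrank_p = km$logrank_p,
                 cox_univariate = uni, cox_tf_adjusted = adj)
  path <- file.path(config$out_dir, "survival_report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  .write_manifest(config, "survival",
                  inputs = list(scores = config$scores_path,
                                clinical = config$clinical_path,
                                signature = config$signature),
                  outputs = path)
  invisible(report)
}

#' Validate stage: dilution, downsampling and ablation reports
#'
#' Runs the three analytical-validation experiments on a synthetic tumor:
#' the TF dilution series (signature score vs fraction), coverage
#' downsampling (bin-level correlation with the full-coverage profile) and
#' the segment-ablation experiment for the RB-LOH-like signature.
#'
#' @param config \code{\link{runConfig}}.
#' @param reps ablation repetitions (default 100 for the command surface;
#'   the study design used 500).
#' @return invisible list of the three report tables.
#' @export
cmdValidate <- function(config, reps = 100L) {
  .ensure_dir(config$out_dir)
  cc <- if (is.null(config$cohort)) cohortConfig(seed = config$seed) else
    config$cohort
  scheme <- makeGenomeScheme(n_segments = cc$n_segments,
                             bins_per_segment = cc$bins_per_segment,
                             genes_per_segment = cc$genes_per_segment)
  arch <- makeArchetypes(scheme)
  sigs <- makeSignatureSet(scheme, n_signatures = cc$n_signatures,
                           seed = cc$seed %% 1000L + 11L)
  gene_map <- schemeGenes(scheme)
  w <- signatureWeights(sigs, "RB_LOH_like")

  # dilution: noiseless closed form, score per fraction
  dil <- dilutionSeries(scheme, arch$cluster3, noise_sd = 0,
                        seed = config$seed)
  dil_tab <- data.frame(
    fraction = as.numeric(sub("tf_", "", names(dil))),
    rb_loh_score = vapply(dil, function(pr) {
      as.numeric(scoreSignature(
        profileToFeatures(pr, gene_map, sigs), w))
    }, numeric(1)))

  # downsampling: bin-level correlation to full coverage at tf = 0.2
  full <- simulateSample(scheme, arch$cluster3, tf = 0.2, noise_sd = 0.1,
                         seed = config$seed, sample_id = "ds_full")
  ds_tab <- do.call(rbind, lapply(c(1, 0.5, 0.25, 0.1, 0.05), function(f) {
    dsp <- downsampleProfile(full, f, seed = config$seed + round(100 * f))
    data.frame(coverage_factor = f,
               bin_correlation = stats::cor(binTable(full)$log2,
                                            binTable(dsp)$log2))
  }))

  # ablation on a prognostic-continuum cohort (the setting where removing
  # segments genuinely loses information); removal sizes follow the study
  # design (20/40/80/160) truncated to the signature's size, falling back to
  # proportional sizes on small schemes
  bundle <- makePrognosticCohort(n = sum(cc$n_per_archetype),
                                 n_segments = cc$n_segments,
                                 bins_per_segment = cc$bins_per_segment,
                                 genes_per_segment = cc$genes_per_segment,
                                 n_signatures = cc$n_signatures,
                                 noise_sd = cc$noise_sd, seed = cc$seed)
  sig_size <- length(signatureWeights(bundle$signatures, "RB_LOH_like"))
  nr <- c(20L, 40L, 80L, 160L)
  nr <- nr[nr < sig_size]
  if (!length(nr)) {
    nr <- unique(pmax(1L, as.integer(sig_size * c(0.1, 0.2, 0.4, 0.8))))
    nr <- nr[nr < sig_size]
  }
  abl <- signatureAblation(bundle$signatures, "RB_LOH_like", bundle$vectors,
                           bundle$clinical, n_remove = nr, reps = reps,
                           seed = config$seed)
  p <- function(f) file.path(config$out_dir, f)
  utils::write.table(dil_tab, p("dilution_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds_tab, p("downsampling_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(abl, p("ablation_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .write_manifest(config, "validate", inputs = list(seed = config$seed),
                  outputs = c(p("dilution_report.tsv"),
                              p("downsampling_report.tsv"),
                              p("ablation_report.tsv")))
  invisible(list(dilution = dil_tab, downsampling = ds_tab, ablation = abl))
}
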