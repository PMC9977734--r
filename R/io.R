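# Readers and writers for the on-disk artifacts: SEG dialects (generic/IGV,
# ichorCNA, CNVkit .cns), ichorCNA parameter records, BED4 gene maps, signature
# weight tables, clinical CSVs and score matrices.
#
# Coordinate conventions: intervals live in GRanges, i.e. 1-based closed.
# SEG and .cns files are read/written 1-based inclusive unchanged; BED input
# (0-based half-open) is shifted on read. Chromosome names are normalized by
# stripping a leading "chr"; mitochondrial records are dropped.

.normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x))
  x
}

.is_mito <- function(x) toupper(x) %in% c("M", "MT")

.match_col <- function(cols, candidates) {
  for (cand in candidates) {
    hit <- which(tolower(cols) == tolower(cand))
    if (length(hit)) return(hit[1L])
  }
  NA_integer_
}

.numeric_or_stop <- function(x, what, lines) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("non-numeric %s at line %d: '%s'",
                 what, lines[bad[1L]], x[bad[1L]]), call. = FALSE)
  }
  out
}

#' Read a segmentation file (SEG dialects)
#'
#' Parses an IGV-style SEG file, an ichorCNA \code{.seg}/\code{.cna.seg}
#' export (which additionally carries a TF-corrected absolute copy-number
#' column named like \code{logR_Copy_Number} and a call column), or a CNVkit
#' \code{.cns} file (accepted as generic). File coordinates are 1-based
#' inclusive. One \linkS4class{SegmentationProfile} is returned per distinct
#' sample id in the file.
#'
#' @param path SEG file path.
#' @param dialect one of \code{"generic_seg"}, \code{"ichorcna"},
#'   \code{"cnvkit_cns"}.
#' @param params optional per-sample parameter table (data.frame with columns
#'   \code{sample_id}, \code{tumor_fraction}, \code{ploidy}, as read by
#'   \code{\link{readIchorParams}}). Samples absent from it default to
#'   TF 0 / ploidy 2.
#' @param sample_id sample id to use for dialects without a sample column
#'   (CNVkit); defaults to the file base name.
#' @return named list of \linkS4class{SegmentationProfile}.
#' @export
readSeg <- function(path, dialect = c("generic_seg", "ichorcna", "cnvkit_cns"),
                    params = NULL, sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  cols <- names(tab)
  lines <- seq_len(nrow(tab)) + 1L   # header is line 1

  if (dialect == "cnvkit_cns") {
    need <- list(chrom = c("chromosome", "chrom"), start = "start",
                 end = "end", mean = c("log2", "seg.mean"))
    opt_mark <- .match_col(cols, c("probes", "num.mark"))
    id_col <- NA_integer_
  } else {
    need <- list(chrom = c("chrom", "chromosome"),
                 start = c("start", "loc.start"),
                 end = c("end", "loc.end"),
                 mean = c("seg.mean", "seg_mean", "median"))
    opt_mark <- .match_col(cols, c("num.mark", "num_mark", "num.snps", "bins"))
    id_col <- .match_col(cols, c("ID", "sample", "sampleID", "sample_id"))
    if (is.na(id_col)) {
      stop("missing required column 'ID' (sample identifier) in ", path)
    }
  }
  idx <- vapply(need, function(cand) .match_col(cols, cand), integer(1))
  if (anyNA(idx)) {
    miss <- names(need)[is.na(idx)]
    canonical <- c(chrom = "chrom", start = "start", end = "end",
                   mean = if (dialect == "cnvkit_cns") "log2" else "seg.mean")
    stop(sprintf("missing required column(s) in %s: %s", path,
                 paste(canonical[miss], collapse = ", ")), call. = FALSE)
  }

  ccn_col <- NA_integer_
  call_col <- NA_integer_
  if (dialect == "ichorcna") {
    ccn_col <- grep("logR_Copy_Number$", cols, ignore.case = TRUE)[1]
    if (is.na(ccn_col)) {
      stop("ichorcna dialect requires a column named like 'logR_Copy_Number' in ",
           path, call. = FALSE)
    }
    call_col <- grep("(Corrected_Call|\\bcall\\b|\\.call)$", cols,
                     ignore.case = TRUE)[1]
  }

  chrom <- .normalize_chrom(tab[[idx["chrom"]]])
  start <- .numeric_or_stop(tab[[idx["start"]]], "start coordinate", lines)
  end <- .numeric_or_stop(tab[[idx["end"]]], "end coordinate", lines)
  segmean <- .numeric_or_stop(tab[[idx["mean"]]], "segment mean", lines)
  ids <- if (is.na(id_col)) {
    rep(if (is.null(sample_id)) sub("\\.[^.]*$", "", basename(path)) else
        sample_id, nrow(tab))
  } else as.character(tab[[id_col]])

  keep <- !.is_mito(chrom)
  df <- data.frame(id = ids, chrom = chrom, start = start, end = end,
                   seg_mean = segmean, stringsAsFactors = FALSE)[keep, ,
                                                                 drop = FALSE]
  if (!is.na(opt_mark)) df$n_bins <- as.integer(tab[[opt_mark]])[keep]
  if (!is.na(ccn_col)) {
    df$ccn <- .numeric_or_stop(tab[[ccn_col]], "corrected copy number",
                               lines)[keep]
  }
  if (!is.na(call_col)) df$call <- as.character(tab[[call_col]])[keep]

  pars <- function(id) {
    if (!is.null(params)) {
      hit <- match(id, params$sample_id)
      if (!is.na(hit)) {
        return(list(tf = params$tumor_fraction[hit], ploidy = params$ploidy[hit]))
      }
    }
    list(tf = 0, ploidy = 2)
  }

  out <- lapply(split(df, df$id), function(d) {
    gr <- GRanges(d$chrom, IRanges(start = d$start, end = d$end))
    mcols(gr)$log2_ratio <- d$seg_mean
    if (!is.null(d$ccn)) mcols(gr)$corrected_copy_number <- d$ccn
    if (!is.null(d$n_bins)) mcols(gr)$n_bins <- d$n_bins
    if (!is.null(d$call)) mcols(gr)$call <- d$call
    p <- pars(d$id[1L])
    new("SegmentationProfile", sampleId = d$id[1L], segments = gr,
        tumorFraction = p$tf, ploidy = p$ploidy, dialect = dialect,
        adjusted = FALSE, bins = NULL)
  })
  out[unique(df$id)]
}

#' Write segmentation profiles as a generic SEG file
#'
#' Inverse of \code{\link{readSeg}}: 1-based inclusive coordinates, tab
#' separated, columns \code{ID, chrom, start, end, num.mark, seg.mean} plus
#' \code{logR_Copy_Number} and \code{call} when present.
#'
#' @param profiles a \linkS4class{SegmentationProfile} or list of them.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSeg <- function(profiles, path) {
  if (is(profiles, "SegmentationProfile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    gr <- p@segments
    d <- data.frame(ID = p@sampleId,
                    chrom = as.character(seqnames(gr)),
                    start = start(gr), end = end(gr),
                    num.mark = if (!is.null(mcols(gr)$n_bins))
                      mcols(gr)$n_bins else NA_integer_,
                    seg.mean = mcols(gr)$log2_ratio,
                    stringsAsFactors = FALSE)
    if (!is.null(mcols(gr)$corrected_copy_number)) {
      d$logR_Copy_Number <- mcols(gr)$corrected_copy_number
    }
    if (!is.null(mcols(gr)$call)) d$call <- mcols(gr)$call
    d
  })
  common <- Reduce(intersect, lapply(rows, names))
  tab <- do.call(rbind, lapply(rows, function(d) d[common]))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ichorCNA-style parameter record
#'
#' Tab-separated table with columns \code{sample_id} (or \code{sample}/
#' \code{ID}), \code{tumor_fraction} and \code{ploidy}.
#'
#' @param path file path.
#' @return data.frame with columns \code{sample_id, tumor_fraction, ploidy}.
#' @export
readIchorParams <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  id <- .match_col(names(tab), c("sample_id", "sample", "ID"))
  tf <- .match_col(names(tab), c("tumor_fraction", "tumor.fraction", "tf"))
  pl <- .match_col(names(tab), c("ploidy", "tumor_ploidy"))
  if (is.na(id) || is.na(tf) || is.na(pl)) {
    stop("parameter file needs columns sample_id, tumor_fraction, ploidy")
  }
  out <- data.frame(sample_id = as.character(tab[[id]]),
                    tumor_fraction = as.numeric(tab[[tf]]),
                    ploidy = as.numeric(tab[[pl]]),
                    stringsAsFactors = FALSE)
  if (any(out$tumor_fraction < 0 | out$tumor_fraction > 1, na.rm = TRUE)) {
    stop("tumor_fraction outside [0, 1] in ", path)
  }
  if (any(out$ploidy <= 0, na.rm = TRUE)) stop("non-positive ploidy in ", path)
  out
}

#' Read a BED4 gene map
#'
#' BED coordinates (0-based half-open) are converted to the internal 1-based
#' closed convention. Mitochondrial genes are dropped and chromosome names
#' normalized.
#'
#' @param path BED4 file (chrom, start, end, name), no header.
#' @return \code{GRanges} with metadata column \code{gene}.
#' @export
readGeneMap <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("gene map must be BED4 (chrom, start, end, name)")
  chrom <- .normalize_chrom(tab[[1L]])
  keep <- !.is_mito(chrom)
  gr <- GRanges(chrom[keep],
                IRanges(start = as.numeric(tab[[2L]][keep]) + 1L,
                        end = as.numeric(tab[[3L]][keep])))
  mcols(gr)$gene <- as.character(tab[[4L]][keep])
  gr
}

#' Write a gene map as BED4
#' @param genes \code{GRanges} with a \code{gene} metadata column.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneMap <- function(genes, path) {
  tab <- data.frame(chrom = as.character(seqnames(genes)),
                    start = start(genes) - 1L, end = end(genes),
                    name = mcols(genes)$gene)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a signature set from weight and scheme tables
#'
#' The weight table is a TSV with columns \code{signature, segment_id,
#' weight}; the scheme table a TSV with columns \code{segment_id, chrom,
#' start, end, genes} (comma-separated gene symbols). The published resource
#' ships as a supplementary spreadsheet; exporting its weight sheet to these
#' two TSVs is a one-time conversion.
#'
#' @param weights_path,scheme_path file paths.
#' @return \linkS4class{SignatureSet}.
#' @export
readSignatureSet <- function(weights_path, scheme_path) {
  sch <- utils::read.delim(scheme_path, stringsAsFactors = FALSE)
  need <- c("segment_id", "chrom", "start", "end", "genes")
  miss <- setdiff(need, names(sch))
  if (length(miss)) {
    stop("scheme table missing column(s): ", paste(miss, collapse = ", "))
  }
  wt <- utils::read.delim(weights_path, stringsAsFactors = FALSE)
  miss <- setdiff(c("signature", "segment_id", "weight"), names(wt))
  if (length(miss)) {
    stop("weight table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(sch$segment_id)) stop("duplicate segment_id in scheme")
  unknown <- setdiff(unique(wt$segment_id), sch$segment_id)
  if (length(unknown)) {
    stop("weight rows reference segment id(s) absent from the scheme: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  if (anyDuplicated(wt[c("signature", "segment_id")])) {
    stop("duplicate (signature, segment_id) weight rows")
  }
  gr <- GRanges(.normalize_chrom(sch$chrom),
                IRanges(start = as.numeric(sch$start),
                        end = as.numeric(sch$end)))
  mcols(gr)$segment_id <- as.character(sch$segment_id)
  mcols(gr)$genes <- as.character(sch$genes)
  weights <- lapply(split(wt, wt$signature), function(d) {
    stats::setNames(as.numeric(d$weight), as.character(d$segment_id))
  })
  new("SignatureSet", scheme = gr, weights = weights)
}

#' Write a signature set back to weight/scheme TSVs
#' @param sigs \linkS4class{SignatureSet}.
#' @param weights_path,scheme_path output paths.
#' @return invisibly, the two paths.
#' @export
writeSignatureSet <- function(sigs, weights_path, scheme_path) {
  sch <- data.frame(segment_id = mcols(sigs@scheme)$segment_id,
                    chrom = as.character(seqnames(sigs@scheme)),
                    start = start(sigs@scheme), end = end(sigs@scheme),
                    genes = mcols(sigs@scheme)$genes)
  utils::write.table(sch, scheme_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  wt <- do.call(rbind, lapply(names(sigs@weights), function(nm) {
    data.frame(signature = nm, segment_id = names(sigs@weights[[nm]]),
               weight = unname(sigs@weights[[nm]]))
  }))
  utils::write.table(wt, weights_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(weights_path, scheme_path))
}

#' Read a clinical table (CSV)
#'
#' Validates outcome times (non-negative), event indicators (0/1), response
#' categories (CR/PR/SD/PD) and ER/HER2 status (pos/neg). Extra columns are
#' kept as covariates.
#'
#' @param path CSV path.
#' @return \linkS4class{ClinicalTable}.
#' @export
readClinical <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("response", "er_status", "her2_status")) {
    if (col %in% names(d)) d[[col]][d[[col]] %in% c("", "NA")] <- NA
  }
  new("ClinicalTable", data = d)
}

#' Write a clinical table (CSV)
#' @param clin \linkS4class{ClinicalTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeClinical <- function(clin, path) {
  utils::write.csv(clin@data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a signature score matrix (TSV)
#'
#' Signatures in rows, samples in columns. Per-sample tumor fraction and the
#' adjusted flag are stored in \code{#}-prefixed header lines so the
#' round-trip restores a full \linkS4class{SignatureScoreMatrix}.
#'
#' @param m \linkS4class{SignatureScoreMatrix}.
#' @param path TSV path.
#' @return \code{path} (write) or the restored object (read).
#' @export
writeScoreMatrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# adjusted: %s", m@adjusted), con)
  writeLines(sprintf("# tumor_fraction: %s",
                     paste(sprintf("%s=%.17g", colnames(m@scores),
                                   m@tumorFraction), collapse = ",")), con)
  tab <- data.frame(signature = rownames(m@scores),
                    m@scores, check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScoreMatrix
#' @export
readScoreMatrix <- function(path) {
  hdr <- readLines(path, n = 2L)
  adjusted <- grepl("TRUE", hdr[1L])
  tf_items <- strsplit(sub("^# tumor_fraction: ", "", hdr[2L]), ",")[[1L]]
  tf <- vapply(strsplit(tf_items, "="), function(x) as.numeric(x[2L]),
               numeric(1))
  names(tf) <- vapply(strsplit(tf_items, "="), `[`, character(1), 1L)
  tab <- utils::read.delim(path, skip = 2L, check.names = FALSE)
  s <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(s) <- tab[[1L]]
  new("SignatureScoreMatrix", scores = s, tumorFraction = tf[colnames(s)],
      adjusted = adjusted,
      lowConfidence = matrix(FALSE, nrow(s), ncol(s),
                             dimnames = dimnames(s)))
}

#' Save / load a subtype model as a TSV + JSON bundle
#'
#' \code{<prefix>_centroids.tsv} holds the selected-signature centroid matrix;
#' \code{<prefix>_meta.json} holds the selected signature list and training
#' metadata (FDR, permutations, seed, format version).
#'
#' @param model \linkS4class{SubtypeModel}.
#' @param prefix path prefix for the two files.
#' @return the prefix (save) or the restored model (load).
#' @export
saveSubtypeModel <- function(model, prefix) {
  tab <- data.frame(signature = rownames(model@centroids), model@centroids,
                    check.names = FALSE)
  utils::write.table(tab, paste0(prefix, "_centroids.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- c(list(format_version = 1L, signatures = model@signatures),
            model@metadata)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname saveSubtypeModel
#' @export
loadSubtypeModel <- function(prefix) {
  tab <- utils::read.delim(paste0(prefix, "_centroids.tsv"),
                           check.names = FALSE)
  cent <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(cent) <- tab[[1L]]
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  sigs <- as.character(meta$signatures)
  meta$signatures <- NULL
  meta$format_version <- NULL
  new("SubtypeModel", signatures = sigs,
      centroids = cent[sigs, , drop = FALSE], metadata = as.list(meta))
}
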