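## Alignment-evidence features per SV call, for the random-forest filter.
## All twelve features are read-depth and read-length independent by
## construction: per-side means, CI distances, a depth ratio and the variant
## allele fraction.

feature_names <- c("mapq1", "mapq2", "pid1", "pid2", "cipos1", "cipos2",
                   "plength1", "plength2", "ciend1", "ciend2",
                   "total_cov_norm", "vaf")

#' Estimate mean sample coverage from a segment table
#'
#' Total aligned reference bases divided by genome length.
#'
#' @param segments Segment `data.frame`.
#' @param genome_length Total reference length in bp.
#' @return Mean depth of coverage (dimensionless).
#' @export
estimate_mean_coverage <- function(segments, genome_length) {
  stopifnot(genome_length > 0)
  sum(as.numeric(segments$ref_end - segments$ref_start)) / genome_length
}

#' Extract the twelve filter features for each call
#'
#' Per call (side 1 / side 2 = lower / higher genomic coordinate, as fixed by
#' canonicalization):
#' \describe{
#'   \item{mapq1, mapq2}{mean mapping quality of the segments supporting each
#'     side;}
#'   \item{pid1, pid2}{mean percent identity of those segments (segments with
#'     unknown PID excluded from the mean);}
#'   \item{cipos1, cipos2}{distances from the median start breakpoint to the
#'     low/high bound of its confidence interval;}
#'   \item{plength1, plength2}{mean aligned fraction of the read taken up by
#'     the supporting segment;}
#'   \item{ciend1, ciend2}{CI distances for the end breakpoint;}
#'   \item{total_cov_norm}{segment depth summed over both breakpoints,
#'     divided by `mean_coverage`;}
#'   \item{vaf}{fraction of breakpoint-spanning reads supporting the variant
#'     allele, `n_alt / (n_alt + n_ref)`.}
#' }
#'
#' @param calls Call `data.frame` with `n_ref` filled in.
#' @param junctions Clustered member junctions (from [call_svs()]).
#' @param segments Segment table used for depth at the breakpoints.
#' @param mean_coverage Average sample depth (> 0), e.g. from
#'   [estimate_mean_coverage()].
#' @return `data.frame` with one row per call (rownames = call ids) and the
#'   12 feature columns.
#' @export
extract_features <- function(calls, junctions, segments, mean_coverage) {
  if (mean_coverage <= 0) stop("mean_coverage must be > 0")
  if (nrow(calls) == 0) {
    out <- as.data.frame(setNames(rep(list(double(0)), length(feature_names)),
                                  feature_names))
    return(out)
  }
  seg_gr <- GenomicRanges::GRanges(
    segments$chrom,
    IRanges::IRanges(start = segments$ref_start + 1L, end = segments$ref_end))
  depth_at <- function(chrom, pos0) {
    pts <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = pos0 + 1L, width = 1L))
    GenomicRanges::countOverlaps(pts, seg_gr)
  }
  cov1 <- depth_at(calls$chrom1, calls$pos1)
  cov2 <- depth_at(calls$chrom2, calls$pos2)
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    m <- junctions[junctions$cluster == calls$cluster[i], , drop = FALSE]
    c(mapq1 = mean(m$mapq1), mapq2 = mean(m$mapq2),
      pid1 = mean(m$pid1, na.rm = TRUE), pid2 = mean(m$pid2, na.rm = TRUE),
      cipos1 = calls$pos1[i] - calls$ci1_low[i],
      cipos2 = calls$ci1_high[i] - calls$pos1[i],
      plength1 = mean(m$plen1), plength2 = mean(m$plen2),
      ciend1 = calls$pos2[i] - calls$ci2_low[i],
      ciend2 = calls$ci2_high[i] - calls$pos2[i],
      total_cov_norm = (cov1[i] + cov2[i]) / mean_coverage,
      vaf = calls$n_alt[i] / (calls$n_alt[i] + calls$n_ref[i]))
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- calls$id
  out[feature_names]
}

#' Write / read a feature matrix as TSV
#'
#' One row per call: call id, the 12 named feature columns, and optionally a
#' `label` column (`TP`/`FP`).
#'
#' @param features Feature `data.frame` (rownames = call ids).
#' @param path TSV path.
#' @param labels Optional character vector of labels.
#' @return `path` invisibly; for the reader, a list with `features` and
#'   `labels` (or `NULL`).
#' @export
write_features <- function(features, path, labels = NULL) {
  df <- cbind(data.frame(id = rownames(features)), features)
  if (!is.null(labels)) df$label <- labels
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  labels <- if ("label" %in% names(df)) df$label else NULL
  features <- df[feature_names]
  rownames(features) <- df$id
  list(features = features, labels = labels)
}
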