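## Repeat-region tracks and call-level post-filters.
##
## Tracks are GRanges (1-based, closed, per GRanges convention); breakpoint
## coordinates (internal, 0-based) are shifted by +1 for containment tests.

#' Compute the homopolymer track of a genome
#'
#' Finds maximal single-base runs of length at least `min_run` (case
#' insensitive; N runs excluded), expands each by `border` bp on both sides,
#' and merges overlapping or bookended expanded runs — so motifs of the form
#' `XXXXXYZZZZZ` collapse into one homopolymer region.
#'
#' @param reference `DNAStringSet`, single `DNAString`, named character
#'   vector of sequences, or a FASTA path.
#' @param min_run Minimum run length in bp (default 5; must be >= 2).
#' @param border Expansion in bp on each side of a run (default 1).
#' @return `GRanges` of merged homopolymer regions with a `label` metadata
#'   column set to `"homopolymer"`.
#' @export
homopolymer_track <- function(reference, min_run = 5, border = 1) {
  stopifnot(min_run >= 2)
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (is(reference, "DNAString"))
    reference <- Biostrings::DNAStringSet(setNames(list(reference), "seq"))
  if (is.character(reference))
    reference <- Biostrings::DNAStringSet(reference)
  names(reference) <- sub("\\s.*", "", names(reference))
  per_chrom <- lapply(seq_along(reference), function(i) {
    s <- toupper(as.character(reference[[i]]))
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$lengths >= min_run & r$values %in% c("A", "C", "G", "T")
    if (!any(keep)) return(NULL)
    GenomicRanges::GRanges(
      names(reference)[i],
      IRanges::IRanges(start = pmax(1L, starts[keep] - border),
                       end = pmin(nchar(s), ends[keep] + border)))
  })
  gr <- GenomicRanges::reduce(do.call(c, c(
    per_chrom[!vapply(per_chrom, is.null, TRUE)],
    list(GenomicRanges::GRanges()))))
  S4Vectors::mcols(gr)$label <- if (length(gr)) "homopolymer" else character(0)
  gr
}

#' Read a BED track
#'
#' Thin wrapper over [rtracklayer::import()] attaching a `label` column.
#'
#' @param path BED file path (0-based half-open, as per BED).
#' @param label Track label, e.g. `"tandem_repeat"`.
#' @return `GRanges`.
#' @export
read_track <- function(path, label = "tandem_repeat") {
  gr <- rtracklayer::import(path, format = "BED")
  gr <- GenomicRanges::reduce(gr)
  S4Vectors::mcols(gr)$label <- if (length(gr)) label else character(0)
  gr
}

#' Write a track to BED
#'
#' @param track `GRanges`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  rtracklayer::export(track, path, format = "BED")
  invisible(path)
}

## which breakpoint points (0-based) fall inside the merged track union
points_in_track <- function(chrom, pos0, track) {
  if (length(track) == 0) return(rep(FALSE, length(pos0)))
  pts <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(start = pos0 + 1L, width = 1L))
  GenomicRanges::countOverlaps(pts, track) > 0
}

#' Discard calls with both breakpoints in repeat regions
#'
#' A call is removed iff *both* of its breakpoint coordinates fall inside the
#' union of the homopolymer and tandem-repeat tracks (point containment of
#' the breakpoint itself). Calls with at most one repeat-contained end are
#' kept.
#'
#' @param calls Call `data.frame`.
#' @param hp Homopolymer track (`GRanges`), e.g. from [homopolymer_track()].
#' @param tr Tandem-repeat track (`GRanges`), e.g. from [read_track()];
#'   may be `NULL`.
#' @return Filtered calls.
#' @export
filter_repeat_calls <- function(calls, hp, tr = NULL) {
  if (nrow(calls) == 0) return(calls)
  un <- GenomicRanges::reduce(c(
    GenomicRanges::granges(if (is.null(hp)) GenomicRanges::GRanges() else hp),
    GenomicRanges::granges(if (is.null(tr)) GenomicRanges::GRanges() else tr)))
  in1 <- points_in_track(calls$chrom1, calls$pos1, un)
  in2 <- points_in_track(calls$chrom2, calls$pos2, un)
  out <- calls[!(in1 & in2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discard small insertions and deletions
#'
#' Removes deletions with reference span and insertions with inserted-gap
#' size below `min_size`; all other SV types are untouched. Such events do
#' not typically produce a split alignment and are dominated by indel-type
#' sequencing error.
#'
#' @param calls Call `data.frame`.
#' @param min_size Minimum indel size in bp to keep (default 40; a 40 bp
#'   indel is kept).
#' @return Filtered calls.
#' @export
filter_small_indels <- function(calls, min_size = 40) {
  if (nrow(calls) == 0) return(calls)
  small <- calls$svtype %in% c("DEL", "INS") & calls$svlen < min_size
  out <- calls[!small, , drop = FALSE]
  rownames(out) <- NULL
  out
}
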