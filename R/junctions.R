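## Candidate breakpoint junctions.
##
## A junction is the joined pair of genomic loci evidenced by two consecutive
## aligned segments of one read. Each side carries a breakend orientation:
##   "+"  the joined segment lies at lower coordinates and ends at `pos`
##        (junction at the 3' side of the locus),
##   "-"  the joined segment starts at `pos` and extends to higher
##        coordinates (junction at the 5' side).
## In this convention the side coordinate is always the segment end - 1 for
## orientation "+" and the segment start for orientation "-", for both sides,
## and reverse-complementing the evidencing read leaves (pos, ori) pairs
## unchanged up to a side swap, which is what canonicalization normalizes.

junction_columns <- c("read_id", "chrom1", "pos1", "ori1",
                      "chrom2", "pos2", "ori2", "gap",
                      "mapq1", "mapq2", "pid1", "pid2", "plen1", "plen2")

empty_junctions <- function() {
  data.frame(read_id = character(),
             chrom1 = character(), pos1 = integer(), ori1 = character(),
             chrom2 = character(), pos2 = integer(), ori2 = character(),
             gap = integer(),
             mapq1 = integer(), mapq2 = integer(),
             pid1 = double(), pid2 = double(),
             plen1 = double(), plen2 = double(),
             stringsAsFactors = FALSE)
}

#' Extract candidate breakpoint junctions from segmented reads
#'
#' Every pair of consecutive aligned segments of a read defines one candidate
#' junction carrying the size of the intervening unaligned gap. A read with N
#' segments yields exactly N - 1 candidates; single-segment reads yield none.
#'
#' Side 1 derives from the earlier segment in read order (junction at its
#' read-3' end), side 2 from the later segment (read-5' end). In genomic
#' terms: a segment mapped on "+" contributes breakend
#' (`ref_end - 1`, `"+"`) from its read-3' end and (`ref_start`, `"-"`) from
#' its read-5' end; for a "-" segment the two are swapped.
#'
#' @param segments Output of [segment_reads()] (or any ordered segment table).
#' @return Junction `data.frame` with per-side evidence columns
#'   (`mapq`, `pid`, `plen` = aligned fraction of the read) used later for
#'   feature extraction. Not yet canonicalized.
#' @export
extract_junctions <- function(segments) {
  if (nrow(segments) < 2) return(empty_junctions())
  ord <- order(segments$read_id, segments$read_start)
  s <- segments[ord, , drop = FALSE]
  n <- nrow(s)
  a <- seq_len(n - 1)
  b <- a + 1L
  same <- s$read_id[a] == s$read_id[b]
  a <- a[same]; b <- b[same]
  if (length(a) == 0) return(empty_junctions())
  ## first segment: junction at read-3' end; second: at read-5' end
  ori1 <- ifelse(s$strand[a] == "+", "+", "-")
  pos1 <- ifelse(s$strand[a] == "+", s$ref_end[a] - 1L, s$ref_start[a])
  ori2 <- ifelse(s$strand[b] == "+", "-", "+")
  pos2 <- ifelse(s$strand[b] == "+", s$ref_start[b], s$ref_end[b] - 1L)
  data.frame(read_id = s$read_id[a],
             chrom1 = s$chrom[a], pos1 = as.integer(pos1), ori1 = ori1,
             chrom2 = s$chrom[b], pos2 = as.integer(pos2), ori2 = ori2,
             gap = as.integer(s$read_start[b] - s$read_end[a]),
             mapq1 = s$mapq[a], mapq2 = s$mapq[b],
             pid1 = s$pid[a], pid2 = s$pid[b],
             plen1 = (s$read_end[a] - s$read_start[a]) / s$read_length[a],
             plen2 = (s$read_end[b] - s$read_start[b]) / s$read_length[b],
             stringsAsFactors = FALSE)
}

#' Canonicalize junction orientation
#'
#' Junctions discovered from reads mapping to opposite reference strands
#' describe the same event with their sides swapped. Canonical form orders
#' the two sides by genome position: sides are swapped iff they are on the
#' same chromosome with `pos1 > pos2`, or side 1's chromosome sorts after
#' side 2's under `chrom_order`. Breakend orientations travel with their
#' coordinates (swapping sides of a breakend pair is the coordinate-level
#' image of reverse-complementing the evidencing segments). Idempotent.
#'
#' @param junctions Junction `data.frame` from [extract_junctions()].
#' @param chrom_order Total order over chromosome names (character vector);
#'   defaults to [default_chrom_order()] of the chromosomes present. An
#'   unknown chromosome is an error.
#' @return The junctions with sides in canonical order and a logical
#'   `canonical` column (all `TRUE`).
#' @export
canonicalize_junctions <- function(junctions, chrom_order = NULL) {
  j <- junctions
  if (nrow(j) == 0) {
    j$canonical <- logical(0)
    return(j)
  }
  if (is.null(chrom_order))
    chrom_order <- default_chrom_order(c(j$chrom1, j$chrom2))
  r1 <- chrom_rank(j$chrom1, chrom_order)
  r2 <- chrom_rank(j$chrom2, chrom_order)
  flip <- r1 > r2 | (r1 == r2 & j$pos1 > j$pos2)
  if (any(flip)) {
    sw <- function(x1, x2) {
      tmp <- x1[flip]
      x1[flip] <- x2[flip]
      x2[flip] <- tmp
      list(x1, x2)
    }
    for (p in list(c("chrom1", "chrom2"), c("pos1", "pos2"),
                   c("ori1", "ori2"), c("mapq1", "mapq2"),
                   c("pid1", "pid2"), c("plen1", "plen2"))) {
      if (all(p %in% names(j))) {
        res <- sw(j[[p[1]]], j[[p[2]]])
        j[[p[1]]] <- res[[1]]
        j[[p[2]]] <- res[[2]]
      }
    }
  }
  j$canonical <- TRUE
  j
}
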