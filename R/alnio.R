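## Alignment ingest: SAM/BAM records -> per-read ordered segment tables.
##
## The canonical in-memory representation of split alignments is a plain
## data.frame with one row per aligned segment and columns
##   read_id, chrom, ref_start, ref_end, strand, mapq,
##   read_start, read_end, read_length, pid
## where ref_* are 0-based half-open reference coordinates and read_* are
## 0-based half-open offsets in the *originally sequenced* read orientation.

#' Read split alignments from a SAM/BAM file
#'
#' Parses primary and supplementary alignment records into the package's
#' aligned-segment table. Read offsets are recovered from CIGAR clip lengths
#' with strand correction, so that all segments of one read live on a common
#' read coordinate system. Optionally, `SA` tag entries are expanded into
#' additional segments; duplicated segments (overlapping read intervals) are
#' collapsed later by [segment_reads()].
#'
#' @param path Path to a coordinate-sorted BAM file, or a SAM text file
#'   (converted on the fly).
#' @param region Optional `GRanges` restricting the records fetched.
#' @param expand_sa Also materialize segments recorded only in `SA` tags
#'   (default `TRUE`).
#' @return Aligned-segment `data.frame` (see package overview). Records
#'   without a CIGAR are skipped with a warning; secondary alignments are
#'   ignored.
#' @export
read_alignments <- function(path, region = NULL, expand_sa = TRUE) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar")
  param <- Rsamtools::ScanBamParam(
    what = what, tag = c("NM", "SA"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE),
    which = if (is.null(region)) IRanges::IRangesList() else region)
  res <- Rsamtools::scanBam(path, param = param)
  ## merge chunks (one element per region, or a single element)
  pull <- function(field) do.call(c, lapply(res, function(x) x[[field]]))
  qname <- pull("qname"); flag <- pull("flag")
  rname <- as.character(pull("rname")); pos <- pull("pos")
  mapq <- pull("mapq"); cigar <- pull("cigar")
  nm <- do.call(c, lapply(res, function(x) x$tag$NM))
  sa <- do.call(c, lapply(res, function(x) x$tag$SA))
  if (length(qname) == 0) return(empty_segments())

  no_cigar <- is.na(cigar) | cigar == "*"
  if (any(no_cigar)) {
    warning(sum(no_cigar), " record(s) lacking a CIGAR were skipped")
  }
  keep <- !no_cigar
  seg <- cigar_to_segment(qname[keep], rname[keep], pos[keep], mapq[keep],
                          cigar[keep], flag[keep], nm[keep])
  if (expand_sa && !is.null(sa)) {
    sa <- sa[keep]
    has_sa <- which(!is.na(sa) & nzchar(sa))
    if (length(has_sa) > 0) {
      extra <- do.call(rbind, lapply(has_sa, function(i) {
        entries <- strsplit(strsplit(sa[i], ";")[[1]], ",")
        ok <- vapply(entries, length, 1L) == 6L
        entries <- entries[ok]
        if (length(entries) == 0) return(NULL)
        m <- do.call(rbind, entries)
        cigar_to_segment(rep(qname[keep][i], nrow(m)), m[, 1],
                         as.integer(m[, 2]), as.integer(m[, 5]), m[, 4],
                         ifelse(m[, 3] == "-", 16L, 0L),
                         as.integer(m[, 6]))
      }))
      seg <- rbind(seg, extra)
    }
  }
  ## reject reads with inconsistent read_length across their segments
  rl <- tapply(seg$read_length, seg$read_id, function(x) length(unique(x)))
  bad <- names(rl)[rl > 1]
  if (length(bad) > 0) {
    warning(length(bad),
            " read(s) with inconsistent read length were rejected")
    seg <- seg[!(seg$read_id %in% bad), , drop = FALSE]
  }
  rownames(seg) <- NULL
  seg
}

## Build segment rows from SAM fields. pos is 1-based leftmost (SAM).
cigar_to_segment <- function(qname, rname, pos, mapq, cigar, flag, nm) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  n <- length(cigar)
  ref_span <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  qspan <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar,
                                                        after.soft.clipping = TRUE)
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  lead <- integer(n); trail <- integer(n)
  mlen <- integer(n); ins <- integer(n); del <- integer(n)
  for (i in seq_len(n)) {
    o <- ops[[i]]; l <- lens[[i]]
    clip <- o %in% c("S", "H")
    k <- length(o)
    lead[i] <- if (clip[1]) l[1] else 0L
    ## a second leading clip (H then S) is possible
    if (k >= 2 && clip[1] && clip[2]) lead[i] <- l[1] + l[2]
    trail[i] <- if (clip[k]) l[k] else 0L
    if (k >= 2 && clip[k] && clip[k - 1]) trail[i] <- l[k] + l[k - 1]
    mlen[i] <- sum(l[o %in% c("M", "=", "X")])
    ins[i] <- sum(l[o == "I"])
    del[i] <- sum(l[o %in% c("D", "N")])
  }
  read_length <- lead + qspan + trail
  ## offsets in original read orientation: reverse-strand records report the
  ## reverse-complemented read, so clips swap ends
  read_start <- ifelse(strand == "+", lead, trail)
  read_end <- read_start + qspan
  pid <- percent_identity(mlen, ins, del, nm)
  data.frame(read_id = qname, chrom = rname,
             ref_start = pos - 1L, ref_end = pos - 1L + ref_span,
             strand = strand, mapq = as.integer(mapq),
             read_start = as.integer(read_start),
             read_end = as.integer(read_end),
             read_length = as.integer(read_length),
             pid = pid, stringsAsFactors = FALSE)
}

#' Percent identity of an aligned segment
#'
#' PID = matches / (matches + mismatches + inserted + deleted bases), i.e.
#' identical bases over aligned columns. With a SAM `NM` tag,
#' mismatches = NM - inserted - deleted.
#'
#' @param aligned Number of M/=/X bases (query bases aligned to reference).
#' @param inserted,deleted Inserted / deleted base counts from the CIGAR.
#' @param nm Edit distance (`NM` tag); `NA` when unavailable.
#' @return Fraction in \[0, 1\]; `NA` when `nm` is missing (such segments are
#'   excluded from feature averages downstream).
#' @export
percent_identity <- function(aligned, inserted, deleted, nm) {
  mismatches <- pmax(0, nm - inserted - deleted)
  matches <- aligned - mismatches
  out <- matches / (matches + mismatches + inserted + deleted)
  out[is.na(nm)] <- NA_real_
  pmin(pmax(out, 0), 1)
}

#' Collapse read versions and fold low-quality segments into gaps
#'
#' Turns a raw aligned-segment table into per-read ordered split alignments:
#' \enumerate{
#'   \item when a read was sequenced in several versions (e.g. 2D, 1D
#'     template, 1D complement, recognized by `version_regex` on the read
#'     name) only the most preferred version is kept;
#'   \item exact duplicate segments (same read interval) are collapsed,
#'     keeping the higher mapping quality;
#'   \item overlapping read-offset intervals are resolved by trimming the
#'     lower-mapq segment (ties broken by lower PID);
#'   \item segments with `mapq < q1` are removed — their read span becomes
#'     part of the enclosing alignment gap.
#' }
#' After this step each read is an alternation gap, segment, ..., segment,
#' gap (gaps possibly of size 0), ordered by read offset.
#'
#' @param segments Aligned-segment `data.frame`.
#' @param q1 Mapping-quality threshold below which a segment is treated as an
#'   alignment gap (default 20).
#' @param version_regex Optional regex whose first capture group extracts a
#'   version token from the read name; remaining name is the read identity.
#'   Default `NULL`: every read name is a single version.
#' @param version_order Preference order of version tokens, most preferred
#'   first. Default `c("2d", "template", "complement")` (case-insensitive).
#' @return Segment `data.frame` sorted by `read_id`, `read_start`, with
#'   attribute `"q1"`.
#' @export
segment_reads <- function(segments, q1 = 20,
                          version_regex = NULL,
                          version_order = c("2d", "template", "complement")) {
  check_segments(segments)
  seg <- segments
  if (!is.null(version_regex)) {
    m <- regmatches(seg$read_id, regexec(version_regex, seg$read_id))
    token <- vapply(m, function(x)
      if (length(x) >= 2) tolower(x[2]) else "", "")
    base_id <- ifelse(token == "", seg$read_id,
                      sub(version_regex, "", seg$read_id))
    pref <- match(token, tolower(version_order))
    pref[is.na(pref)] <- length(version_order) + 1L
    best <- tapply(pref, base_id, min)
    keep <- pref == best[base_id]
    seg <- seg[keep, , drop = FALSE]
    seg$read_id <- base_id[keep]
  }
  seg <- seg[order(seg$read_id, seg$read_start, seg$read_end,
                   -seg$mapq), , drop = FALSE]
  ## collapse exact duplicates of the same read interval, keep higher mapq
  dup <- duplicated(seg[, c("read_id", "read_start", "read_end")])
  seg <- seg[!dup, , drop = FALSE]
  seg <- resolve_read_overlaps(seg)
  seg <- seg[seg$mapq >= q1, , drop = FALSE]
  seg <- seg[order(seg$read_id, seg$read_start), , drop = FALSE]
  rownames(seg) <- NULL
  attr(seg, "q1") <- q1
  seg
}

## Trim overlapping read intervals within a read: the lower-mapq segment
## (tie: lower pid) loses the overlapped span; segments trimmed to nothing
## are dropped. Reference interval is shrunk proportionally so invariants
## hold approximately; downstream only the read offsets of the trimmed side
## matter for gap computation.
resolve_read_overlaps <- function(seg) {
  if (nrow(seg) < 2) return(seg)
  o <- order(seg$read_id, seg$read_start)
  seg <- seg[o, , drop = FALSE]
  drop <- rep(FALSE, nrow(seg))
  for (i in seq_len(nrow(seg) - 1)) {
    if (drop[i]) next
    j <- i + 1L
    while (j <= nrow(seg) && seg$read_id[j] == seg$read_id[i]) {
      if (drop[j]) { j <- j + 1L; next }
      ov <- seg$read_end[i] - seg$read_start[j]
      if (ov <= 0) break
      ## decide loser: lower mapq; tie -> lower pid; tie -> the later one
      pid_i <- ifelse(is.na(seg$pid[i]), 0, seg$pid[i])
      pid_j <- ifelse(is.na(seg$pid[j]), 0, seg$pid[j])
      i_loses <- seg$mapq[i] < seg$mapq[j] ||
        (seg$mapq[i] == seg$mapq[j] && pid_i < pid_j)
      if (i_loses) {
        seg$read_end[i] <- seg$read_end[i] - ov
        if (seg$strand[i] == "+") {
          seg$ref_end[i] <- seg$ref_end[i] - ov
        } else {
          seg$ref_start[i] <- seg$ref_start[i] + ov
        }
        if (seg$read_end[i] <= seg$read_start[i] ||
            seg$ref_end[i] <= seg$ref_start[i]) drop[i] <- TRUE
      } else {
        seg$read_start[j] <- seg$read_start[j] + ov
        if (seg$strand[j] == "+") {
          seg$ref_start[j] <- seg$ref_start[j] + ov
        } else {
          seg$ref_end[j] <- seg$ref_end[j] - ov
        }
        if (seg$read_end[j] <= seg$read_start[j] ||
            seg$ref_end[j] <= seg$ref_start[j]) drop[j] <- TRUE
      }
      if (drop[i]) break
      j <- j + 1L
    }
  }
  seg[!drop, , drop = FALSE]
}

#' Alignment gaps of segmented reads
#'
#' For each read, the sizes of the unaligned stretches `u_1 .. u_{N+1}`
#' flanking and separating its N retained segments (first and last gap may be
#' zero). Gap sizes always satisfy
#' `sum(gaps) + sum(segment read spans) == read_length`.
#'
#' @param segments Output of [segment_reads()].
#' @return Named list (by read id) of integer gap vectors, each of length
#'   N + 1.
#' @export
read_gaps <- function(segments) {
  split_idx <- split(seq_len(nrow(segments)), segments$read_id)
  lapply(split_idx, function(idx) {
    rs <- segments$read_start[idx]
    re <- segments$read_end[idx]
    rl <- segments$read_length[idx][1]
    c(rs[1], if (length(idx) > 1) rs[-1] - re[-length(idx)] else NULL,
      rl - re[length(idx)])
  })
}

#' Load segmented reads from an alignment file
#'
#' Convenience wrapper: [read_alignments()] followed by [segment_reads()].
#'
#' @inheritParams read_alignments
#' @inheritParams segment_reads
#' @return Segment `data.frame`, one ordered block of rows per retained read.
#' @export
load_reads <- function(path, q1 = 20, region = NULL,
                       version_regex = NULL,
                       version_order = c("2d", "template", "complement"),
                       expand_sa = TRUE) {
  segment_reads(read_alignments(path, region = region, expand_sa = expand_sa),
                q1 = q1, version_regex = version_regex,
                version_order = version_order)
}
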