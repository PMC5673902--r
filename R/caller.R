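## Junction clustering and SV call derivation.

#' Cluster canonicalized junctions
#'
#' Two junctions are mergeable iff they agree on both chromosomes and both
#' breakend orientations and their side coordinates are within `d` bp on each
#' side. Clusters are the connected components of this pairwise relation
#' (the order-independent fixpoint of recursive merging).
#'
#' @param junctions Canonicalized junction `data.frame`
#'   (see [canonicalize_junctions()]).
#' @param d Maximum per-side coordinate distance for two junctions to support
#'   the same breakpoint (default 10 bp).
#' @return The junctions with an integer `cluster` column; cluster ids are
#'   assigned in deterministic order (sorted by chrom1, median pos1, chrom2,
#'   median pos2, orientations).
#' @export
cluster_junctions <- function(junctions, d = 10) {
  j <- junctions
  if (nrow(j) == 0) {
    j$cluster <- integer(0)
    return(j)
  }
  stopifnot(!is.null(j$canonical), all(j$canonical))
  key <- paste(j$chrom1, j$chrom2, j$ori1, j$ori2, sep = "\r")
  parent <- seq_len(nrow(j))
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) {
      nxt <- parent[i]
      parent[i] <<- root
      i <- nxt
    }
    root
  }
  for (idx in split(seq_len(nrow(j)), key)) {
    if (length(idx) < 2) next
    idx <- idx[order(j$pos1[idx], j$pos2[idx])]
    p1 <- j$pos1[idx]
    p2 <- j$pos2[idx]
    for (a in seq_len(length(idx) - 1)) {
      for (b in (a + 1):length(idx)) {
        if (p1[b] - p1[a] > d) break
        if (abs(p2[b] - p2[a]) <= d) {
          ra <- find(idx[a]); rb <- find(idx[b])
          if (ra != rb) parent[rb] <- ra
        }
      }
    }
  }
  root <- vapply(seq_len(nrow(j)), find, 1L)
  ## deterministic cluster numbering
  med1 <- tapply(j$pos1, root, median_low)
  med2 <- tapply(j$pos2, root, median_low)
  info <- data.frame(root = as.integer(names(med1)),
                     chrom1 = j$chrom1[as.integer(names(med1))],
                     chrom2 = j$chrom2[as.integer(names(med1))],
                     ori1 = j$ori1[as.integer(names(med1))],
                     ori2 = j$ori2[as.integer(names(med1))],
                     med1 = as.integer(med1), med2 = as.integer(med2))
  co <- default_chrom_order(c(info$chrom1, info$chrom2))
  ord <- order(chrom_rank(info$chrom1, co), info$med1,
               chrom_rank(info$chrom2, co), info$med2,
               info$ori1, info$ori2)
  renum <- setNames(seq_along(ord), info$root[ord])
  j$cluster <- unname(renum[as.character(root)])
  j
}

#' Derive typed SV calls from junction clusters
#'
#' Each cluster becomes one candidate SV `b = (c1, c2, p1, p2, k1, k2, g)`
#' with `p1`, `p2`, `g` the (lower-middle) medians over members and
#' confidence intervals spanning member minima/maxima. Candidates supported
#' by fewer distinct reads than `min_support` are suppressed.
#'
#' Typing: different chromosomes give `BND`; on one chromosome the breakend
#' orientation pair decides: 3'-3' (`+/+`) or 5'-5' (`-/-`) are inversions,
#' 5'-3' (`-/+`) tandem duplications, and 3'-5' (`+/-`) is an insertion when
#' the median gap `g` exceeds the reference span `l = |p1 - p2|`, otherwise a
#' deletion.
#'
#' @param clustered Output of [cluster_junctions()].
#' @param min_support Minimum distinct supporting reads (default 2).
#' @param strict If `TRUE`, require strictly more than `min_support` reads;
#'   default `FALSE` (at least `min_support`).
#' @return Call `data.frame`: one row per emitted SV with positions,
#'   orientations, type, `svlen`, gap, confidence intervals, support count,
#'   a list-column `alt_reads`, and the originating `cluster` id. Reciprocal
#'   inversion junction pairs bridging the same region are linked via
#'   `link_id` (as are the two records of a BND pair in VCF output).
#' @export
derive_calls <- function(clustered, min_support = 2, strict = FALSE) {
  j <- clustered
  if (nrow(j) == 0 || is.null(j$cluster)) return(empty_calls())
  parts <- split(seq_len(nrow(j)), j$cluster)
  rows <- lapply(parts, function(idx) {
    reads <- unique(j$read_id[idx])
    p1 <- median_low(j$pos1[idx])
    p2 <- median_low(j$pos2[idx])
    g <- median_low(j$gap[idx])
    c1 <- j$chrom1[idx][1]; c2 <- j$chrom2[idx][1]
    o1 <- j$ori1[idx][1]; o2 <- j$ori2[idx][1]
    l <- abs(p2 - p1)
    svtype <- if (c1 != c2) "BND"
      else if (o1 == o2) "INV"
      else if (o1 == "+" && o2 == "-") { if (g > l) "INS" else "DEL" }
      else "DUP"
    data.frame(cluster = j$cluster[idx][1],
               chrom1 = c1, pos1 = p1, ori1 = o1,
               chrom2 = c2, pos2 = p2, ori2 = o2,
               svtype = svtype,
               svlen = if (svtype == "INS") as.integer(g) else as.integer(l),
               gap = as.integer(g),
               ci1_low = min(j$pos1[idx]), ci1_high = max(j$pos1[idx]),
               ci2_low = min(j$pos2[idx]), ci2_high = max(j$pos2[idx]),
               n_alt = length(reads),
               mapq_med = median_low(pmin(j$mapq1[idx], j$mapq2[idx])),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  alt_reads <- lapply(parts, function(idx) unique(j$read_id[idx]))
  keep <- if (strict) calls$n_alt > min_support else calls$n_alt >= min_support
  calls <- calls[keep, , drop = FALSE]
  alt_reads <- alt_reads[keep]
  if (nrow(calls) == 0) return(empty_calls())
  calls$id <- paste0("sv", seq_len(nrow(calls)))
  calls$alt_reads <- unname(alt_reads)
  calls$n_ref <- NA_integer_
  calls$ref_reads <- replicate(nrow(calls), character(0), simplify = FALSE)
  calls$genotype <- NA_character_
  calls$gq <- NA_real_
  calls$filter <- "PASS"
  calls$cluster_flag <- FALSE
  calls$link_id <- NA_character_
  rownames(calls) <- NULL
  link_inversion_pairs(calls)
}

empty_calls <- function() {
  df <- data.frame(cluster = integer(),
                   chrom1 = character(), pos1 = integer(), ori1 = character(),
                   chrom2 = character(), pos2 = integer(), ori2 = character(),
                   svtype = character(), svlen = integer(), gap = integer(),
                   ci1_low = integer(), ci1_high = integer(),
                   ci2_low = integer(), ci2_high = integer(),
                   n_alt = integer(), mapq_med = integer(),
                   id = character(), n_ref = integer(),
                   genotype = character(), gq = double(),
                   filter = character(), cluster_flag = logical(),
                   link_id = character(), stringsAsFactors = FALSE)
  df$alt_reads <- list()
  df$ref_reads <- list()
  df
}

## Link complementary inversion-type junction pairs (3'-3' with 5'-5')
## bridging the same region, within `window` bp on both sides.
link_inversion_pairs <- function(calls, window = 100) {
  inv <- which(calls$svtype == "INV")
  if (length(inv) < 2) return(calls)
  used <- rep(FALSE, length(inv))
  n_link <- sum(!is.na(calls$link_id))
  for (a in seq_along(inv)) {
    if (used[a]) next
    i <- inv[a]
    for (b in seq_along(inv)) {
      if (b == a || used[b]) next
      k <- inv[b]
      if (calls$chrom1[i] == calls$chrom1[k] &&
          calls$chrom2[i] == calls$chrom2[k] &&
          calls$ori1[i] != calls$ori1[k] &&
          abs(calls$pos1[i] - calls$pos1[k]) <= window &&
          abs(calls$pos2[i] - calls$pos2[k]) <= window) {
        n_link <- n_link + 1
        lid <- paste0("link", n_link)
        calls$link_id[c(i, k)] <- lid
        used[c(a, b)] <- TRUE
        break
      }
    }
  }
  calls
}

#' Identify reference-supporting reads per call
#'
#' A read supports the reference allele of a call when one of its aligned
#' segments crosses a breakpoint end with more than `flank` bp on *both*
#' sides of that end (either end qualifies), and the read does not support
#' the alternative allele. All other reads are ignored.
#'
#' @param calls Call `data.frame` from [derive_calls()].
#' @param segments Segment table of all reads (post [segment_reads()]).
#' @param flank Required flank on each side of the crossed breakpoint
#'   (default 100 bp, strict inequality).
#' @return `calls` with `ref_reads` (list-column) and `n_ref` filled in.
#' @export
find_reference_reads <- function(calls, segments, flank = 100) {
  if (nrow(calls) == 0) return(calls)
  ends <- data.frame(
    call = rep(seq_len(nrow(calls)), 2L),
    chrom = c(calls$chrom1, calls$chrom2),
    pos = c(calls$pos1, calls$pos2))
  seg_gr <- GenomicRanges::GRanges(
    segments$chrom,
    IRanges::IRanges(start = segments$ref_start + 1L, end = segments$ref_end))
  end_gr <- GenomicRanges::GRanges(
    ends$chrom, IRanges::IRanges(start = ends$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(end_gr, seg_gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ok <- (ends$pos[qh] - segments$ref_start[sh] > flank) &
        (segments$ref_end[sh] - ends$pos[qh] > flank)
  qh <- qh[ok]; sh <- sh[ok]
  by_call <- split(segments$read_id[sh], ends$call[qh])
  for (i in seq_len(nrow(calls))) {
    crossing <- unique(by_call[[as.character(i)]])
    if (is.null(crossing)) crossing <- character(0)
    calls$ref_reads[[i]] <- setdiff(crossing, calls$alt_reads[[i]])
    calls$n_ref[i] <- length(calls$ref_reads[[i]])
  }
  calls
}

#' Genotype one SV from allele support counts
#'
#' Binomial likelihood of the alt-read count under each genotype's expected
#' alt-allele support probability, with a flat prior:
#' `L(g) = C(A+R, A) p_g^A (1-p_g)^R`. The genotype is the maximum-posterior
#' class; `GQ = -10 log10(1 - posterior)`, capped at 99. With no informative
#' reads the genotype is `./.`.
#'
#' @param alt_count,ref_count Distinct supporting read counts (A, R).
#' @param p Alt-support probabilities for hom-ref, het, hom-alt
#'   (default `c(0.001, 0.5, 0.9)`, the split-read allele-support
#'   parameterization of the SVTyper genotyper).
#' @return List with `genotype` (`"0/0"`, `"0/1"`, `"1/1"` or `"./."`), `gq`,
#'   and the three-element posterior `posterior` (sums to 1).
#' @export
genotype_sv <- function(alt_count, ref_count, p = c(0.001, 0.5, 0.9)) {
  stopifnot(alt_count >= 0, ref_count >= 0, length(p) == 3)
  n <- alt_count + ref_count
  if (n == 0) {
    return(list(genotype = "./.", gq = 0,
                posterior = rep(1 / 3, 3)))
  }
  ll <- dbinom(alt_count, n, p)
  post <- ll / sum(ll)
  best <- which.max(post)
  gq <- min(99, -10 * log10(max(1 - post[best], 1e-10)))
  list(genotype = c("0/0", "0/1", "1/1")[best], gq = gq, posterior = post)
}

#' Genotype all calls
#'
#' Applies [genotype_sv()] to each call; optionally drops calls genotyped
#' homozygous reference (no residual alternative support).
#'
#' @param calls Call `data.frame` with `n_alt` and `n_ref` filled in.
#' @param p Genotype allele-support probabilities (see [genotype_sv()]).
#' @param drop_hom_ref Drop `0/0` calls (default `TRUE`).
#' @return Calls with `genotype` and `gq` columns set.
#' @export
genotype_calls <- function(calls, p = c(0.001, 0.5, 0.9),
                           drop_hom_ref = TRUE) {
  if (nrow(calls) == 0) return(calls)
  for (i in seq_len(nrow(calls))) {
    g <- genotype_sv(calls$n_alt[i], calls$n_ref[i], p)
    calls$genotype[i] <- g$genotype
    calls$gq[i] <- g$gq
  }
  if (drop_hom_ref) {
    calls <- calls[calls$genotype != "0/0", , drop = FALSE]
    rownames(calls) <- NULL
  }
  calls
}

#' Apply MapQual and Cluster annotations
#'
#' `MapQual` is added to the FILTER set of calls whose median supporting
#' mapping quality does not exceed `q2`. The `Cluster` INFO flag marks calls
#' in SV-dense regions: a call is flagged when any sliding window of
#' `cluster_window` bp contains breakpoints of at least `cluster_min`
#' distinct calls, one of which is this call.
#'
#' @param calls Call `data.frame`.
#' @param q2 Median mapq threshold (default 80; flag when `median <= q2`).
#' @param cluster_window Window size in bp (default 1000).
#' @param cluster_min Minimum number of distinct calls with a breakpoint in
#'   the window (default 3).
#' @return Calls with `filter` and `cluster_flag` updated.
#' @export
apply_flags <- function(calls, q2 = 80, cluster_window = 1000,
                        cluster_min = 3) {
  if (nrow(calls) == 0) return(calls)
  low <- calls$mapq_med <= q2
  calls$filter <- ifelse(low,
    ifelse(calls$filter %in% c("PASS", ""), "MapQual",
           paste(calls$filter, "MapQual", sep = ";")),
    calls$filter)
  ends <- data.frame(call = rep(seq_len(nrow(calls)), 2L),
                     chrom = c(calls$chrom1, calls$chrom2),
                     pos = c(calls$pos1, calls$pos2))
  calls$cluster_flag <- FALSE
  for (idx in split(seq_len(nrow(ends)), ends$chrom)) {
    o <- idx[order(ends$pos[idx])]
    pos <- ends$pos[o]
    who <- ends$call[o]
    jmax <- 1L
    for (a in seq_along(o)) {
      while (jmax < length(o) && pos[jmax + 1] - pos[a] <= cluster_window)
        jmax <- jmax + 1L
      if (jmax < a) jmax <- a
      members <- unique(who[a:jmax])
      if (length(members) >= cluster_min)
        calls$cluster_flag[members] <- TRUE
    }
  }
  calls
}

#' Call structural variants from a segment table
#'
#' Full caller pipeline on segmented reads: junction extraction,
#' canonicalization, clustering at distance `d`, call derivation at
#' `min_support`, reference-read discovery, genotyping (dropping `0/0` by
#' default) and flag annotation.
#'
#' @param segments Segment table (already filtered at `q1`, e.g. from
#'   [load_reads()] or [oracle_align()]).
#' @param d Clustering distance threshold in bp (default 10).
#' @param min_support Minimum distinct supporting reads (default 2).
#' @param strict Strict support comparison (see [derive_calls()]).
#' @param flank Reference-read flank (default 100 bp).
#' @param q2 MapQual threshold (default 80).
#' @param cluster_window,cluster_min Cluster-flag parameters (1000 bp, 3).
#' @param p_genotype Genotype support probabilities.
#' @param drop_hom_ref Drop calls genotyped `0/0` (default `TRUE`).
#' @param chrom_order Chromosome order for canonicalization (default
#'   [default_chrom_order()]).
#' @return List with `calls` (call `data.frame`) and `junctions` (clustered
#'   member junctions, for feature extraction).
#' @export
call_svs <- function(segments, d = 10, min_support = 2, strict = FALSE,
                     flank = 100, q2 = 80, cluster_window = 1000,
                     cluster_min = 3, p_genotype = c(0.001, 0.5, 0.9),
                     drop_hom_ref = TRUE, chrom_order = NULL) {
  j <- extract_junctions(segments)
  j <- canonicalize_junctions(j, chrom_order)
  j <- cluster_junctions(j, d = d)
  calls <- derive_calls(j, min_support = min_support, strict = strict)
  calls <- find_reference_reads(calls, segments, flank = flank)
  calls <- genotype_calls(calls, p = p_genotype, drop_hom_ref = drop_hom_ref)
  calls <- apply_flags(calls, q2 = q2, cluster_window = cluster_window,
                       cluster_min = cluster_min)
  list(calls = calls, junctions = j)
}
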