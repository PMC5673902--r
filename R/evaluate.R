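## Scoring call sets against simulated truth, and the generic SV-set
## intersection rule (confidence-interval proximity + reciprocal overlap).

#' Event size of a junction
#'
#' Interchromosomal junctions have infinite size. For intrachromosomal
#' deletion-type junctions (`+`/`-`) the size is the number of reference
#' bases between the two breakends (`|p2 - p1| - 1`); for other orientations
#' it is `|p2 - p1|`.
#'
#' @param junctions `data.frame` with `chrom1`, `pos1`, `ori1`, `chrom2`,
#'   `pos2`, `ori2`.
#' @return Numeric vector of sizes in bp.
#' @export
junction_size <- function(junctions) {
  ifelse(junctions$chrom1 != junctions$chrom2, Inf,
         ifelse(junctions$ori1 == "+" & junctions$ori2 == "-",
                abs(junctions$pos2 - junctions$pos1) - 1,
                abs(junctions$pos2 - junctions$pos1)))
}

## greedy one-to-one matching by ascending distance over candidate pairs
greedy_match <- function(cand) {
  if (nrow(cand) == 0)
    return(cand[integer(0), , drop = FALSE])
  cand <- cand[order(cand$dist, cand$a, cand$b), , drop = FALSE]
  used_a <- used_b <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$a[i] %in% used_a || cand$b[i] %in% used_b) next
    keep[i] <- TRUE
    used_a <- c(used_a, cand$a[i])
    used_b <- c(used_b, cand$b[i])
  }
  cand[keep, , drop = FALSE]
}

#' Evaluate a call set against simulated truth junctions
#'
#' A truth junction is recovered when a call matches it on both sides:
#' equal chromosomes and breakend orientations, and both coordinates within
#' `match_window` bp. Matching is greedy one-to-one by total coordinate
#' distance. Recall is recovered truth over all truth; the false-positive
#' rate (FDR of the call set) is the fraction of calls matching no truth
#' junction.
#'
#' @param calls Call `data.frame` (or any junction-shaped table).
#' @param truth Truth junction `data.frame` (e.g. `shatter()$truth`).
#' @param match_window Maximum per-side distance in bp (default 100; a call
#'   shifted by 101 bp does not match).
#' @param size_breaks Size-stratum boundaries for the per-size breakdown
#'   (default `c(0, 50, 100, 1000, Inf)`).
#' @return List: `recall`, `fdr`, `n_truth`, `n_calls`, `matches`
#'   (`data.frame` of matched call/truth indices and distances), `by_size`
#'   (per-stratum truth counts and recall), `truth_size`.
#' @export
evaluate_calls <- function(calls, truth, match_window = 100,
                           size_breaks = c(0, 50, 100, 1000, Inf)) {
  nt <- nrow(truth); nc <- nrow(calls)
  cand <- if (nt == 0 || nc == 0) {
    data.frame(a = integer(), b = integer(), dist = double())
  } else {
    pairs <- expand.grid(a = seq_len(nc), b = seq_len(nt))
    ok <- calls$chrom1[pairs$a] == truth$chrom1[pairs$b] &
      calls$chrom2[pairs$a] == truth$chrom2[pairs$b] &
      calls$ori1[pairs$a] == truth$ori1[pairs$b] &
      calls$ori2[pairs$a] == truth$ori2[pairs$b] &
      abs(calls$pos1[pairs$a] - truth$pos1[pairs$b]) <= match_window &
      abs(calls$pos2[pairs$a] - truth$pos2[pairs$b]) <= match_window
    pairs <- pairs[ok, , drop = FALSE]
    pairs$dist <- abs(calls$pos1[pairs$a] - truth$pos1[pairs$b]) +
      abs(calls$pos2[pairs$a] - truth$pos2[pairs$b])
    pairs
  }
  m <- greedy_match(cand)
  tsize <- if (nt > 0) junction_size(truth) else numeric(0)
  strata <- cut(tsize, size_breaks, right = FALSE,
                include.lowest = TRUE)
  recovered <- seq_len(nt) %in% m$b
  by_size <- if (nt > 0) {
    agg <- data.frame(stratum = levels(strata),
                      n = as.integer(table(strata)),
                      recovered = as.integer(tapply(recovered, strata, sum,
                                                    default = 0L)))
    agg$recall <- ifelse(agg$n > 0, agg$recovered / agg$n, NA)
    agg
  } else {
    data.frame(stratum = character(), n = integer(),
               recovered = integer(), recall = double())
  }
  list(recall = if (nt > 0) sum(recovered) / nt else NA_real_,
       fdr = if (nc > 0) (nc - nrow(m)) / nc else NA_real_,
       n_truth = nt, n_calls = nc,
       matches = data.frame(call = m$a, truth = m$b, dist = m$dist),
       by_size = by_size, truth_size = tsize)
}

#' Recall restricted to truth junctions of at least a given size
#'
#' @param evaluation Result of [evaluate_calls()].
#' @param min_size Size floor in bp (default 50).
#' @return Recall over the qualifying truth junctions.
#' @export
recall_min_size <- function(evaluation, min_size = 50) {
  keep <- evaluation$truth_size >= min_size
  if (!any(keep)) return(NA_real_)
  sum(evaluation$matches$truth %in% which(keep)) / sum(keep)
}

#' Intersect two SV call sets
#'
#' Two calls match when, at both the start and the end breakpoint, their
#' confidence intervals are closer together than `proximity` bp (overlapping
#' intervals count as distance 0), chromosomes agree on both sides, and —
#' for events smaller than `size_cut` bp, insertions excepted — the two
#' reference intervals `[pos1, pos2]` overlap reciprocally by at least
#' `recip`. Matching is greedy one-to-one by CI distance.
#'
#' @param set_a,set_b Call `data.frame`s carrying `ci1_low`, `ci1_high`,
#'   `ci2_low`, `ci2_high` and `svtype`.
#' @param proximity CI distance threshold in bp (default 101: a gap of
#'   exactly 101 bp does not match).
#' @param recip Reciprocal-overlap threshold (default 0.70).
#' @param size_cut Size below which reciprocal overlap is required
#'   (default 1000 bp).
#' @return List: `matches` (`data.frame` of indices `a`, `b` and `dist`),
#'   `only_a`, `only_b` (unmatched indices).
#' @export
intersect_sv_sets <- function(set_a, set_b, proximity = 101, recip = 0.70,
                              size_cut = 1000) {
  na <- nrow(set_a); nb <- nrow(set_b)
  if (na == 0 || nb == 0) {
    return(list(matches = data.frame(a = integer(), b = integer(),
                                     dist = double()),
                only_a = seq_len(na), only_b = seq_len(nb)))
  }
  pairs <- expand.grid(a = seq_len(na), b = seq_len(nb))
  a <- pairs$a; b <- pairs$b
  gap_start <- interval_gap(set_a$ci1_low[a], set_a$ci1_high[a],
                            set_b$ci1_low[b], set_b$ci1_high[b])
  gap_end <- interval_gap(set_a$ci2_low[a], set_a$ci2_high[a],
                          set_b$ci2_low[b], set_b$ci2_high[b])
  ok <- set_a$chrom1[a] == set_b$chrom1[b] &
    set_a$chrom2[a] == set_b$chrom2[b] &
    gap_start < proximity & gap_end < proximity
  size_a <- abs(set_a$pos2[a] - set_a$pos1[a])
  size_b <- abs(set_b$pos2[b] - set_b$pos1[b])
  needs_recip <- (pmin(size_a, size_b) < size_cut) &
    set_a$svtype[a] != "INS" & set_b$svtype[b] != "INS" &
    set_a$chrom1[a] == set_a$chrom2[a]
  lo_a <- pmin(set_a$pos1[a], set_a$pos2[a])
  hi_a <- pmax(set_a$pos1[a], set_a$pos2[a])
  lo_b <- pmin(set_b$pos1[b], set_b$pos2[b])
  hi_b <- pmax(set_b$pos1[b], set_b$pos2[b])
  ov <- pmax(0, pmin(hi_a, hi_b) - pmax(lo_a, lo_b))
  recip_ok <- ov / pmax(hi_a - lo_a, 1) >= recip &
    ov / pmax(hi_b - lo_b, 1) >= recip
  ok <- ok & (!needs_recip | recip_ok)
  cand <- data.frame(a = a[ok], b = b[ok],
                     dist = gap_start[ok] + gap_end[ok])
  m <- greedy_match(cand)
  list(matches = m,
       only_a = setdiff(seq_len(na), m$a),
       only_b = setdiff(seq_len(nb), m$b))
}
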