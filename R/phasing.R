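## Read-backed phasing of reads and SVs from phased heterozygous SNVs.
##
## Phased SNVs are a data.frame: chrom, pos (0-based), paternal, maternal
## (differing bases). A pileup is a data.frame: read_id, chrom, pos
## (0-based), base, qual. All likelihoods are kept in log space; the paper
## formulation's raw products underflow for reads spanning many SNVs.

#' Probability that a base call supports a phased allele
#'
#' `P(b | base) = 1 - 10^(-q/10)` when the call matches the allele and
#' `10^(-q/10)` otherwise.
#'
#' @param base Observed base call(s).
#' @param qual Phred base quality(ies), `>= 0`.
#' @param allele Allele base(s) of the haplotype under evaluation.
#' @return Numeric vector of probabilities.
#' @export
snv_support_prob <- function(base, qual, allele) {
  stopifnot(all(qual >= 0))
  perr <- 10^(-qual / 10)
  ifelse(toupper(base) == toupper(allele), 1 - perr, perr)
}

#' Phase reads against a panel of phased heterozygous SNVs
#'
#' For each read, multiplies the support probabilities of its base calls at
#' the overlapped phase-informative SNVs under the paternal and the maternal
#' allele assignment, in log space. Deleted bases do not appear in the
#' pileup and contribute nothing; base calls with quality 0 (or missing) are
#' skipped as uninformative (the support formula degenerates there).
#'
#' @param pileup Pileup `data.frame` (`read_id`, `chrom`, `pos`, `base`,
#'   `qual`), e.g. from [pileup_at_sites()].
#' @param snvs Phased SNV `data.frame` (`chrom`, `pos`, `paternal`,
#'   `maternal`).
#' @param min_informative Minimum number of informative SNVs for a phase to
#'   be assigned (default 0; reads below it are `unknown`).
#' @return `data.frame`: `read_id`, `log_lp`, `log_lm`, `n_snvs`, `phase`
#'   (`"paternal"`, `"maternal"` or `"unknown"`; ties are `unknown`).
#' @export
phase_reads <- function(pileup, snvs, min_informative = 0) {
  stopifnot(all(snvs$paternal != snvs$maternal))
  key_p <- paste(pileup$chrom, pileup$pos)
  key_s <- paste(snvs$chrom, snvs$pos)
  hit <- match(key_p, key_s)
  use <- !is.na(hit) & !is.na(pileup$qual) & pileup$qual > 0 &
    !is.na(pileup$base)
  df <- pileup[use, , drop = FALSE]
  hit <- hit[use]
  lp <- log(snv_support_prob(df$base, df$qual, snvs$paternal[hit]))
  lm <- log(snv_support_prob(df$base, df$qual, snvs$maternal[hit]))
  ids <- unique(pileup$read_id)
  agg_lp <- tapply(lp, df$read_id, sum)
  agg_lm <- tapply(lm, df$read_id, sum)
  agg_n <- tapply(lp, df$read_id, length)
  out <- data.frame(read_id = ids,
                    log_lp = unname(agg_lp[ids]),
                    log_lm = unname(agg_lm[ids]),
                    n_snvs = unname(agg_n[ids]),
                    stringsAsFactors = FALSE)
  out$log_lp[is.na(out$log_lp)] <- 0
  out$log_lm[is.na(out$log_lm)] <- 0
  out$n_snvs[is.na(out$n_snvs)] <- 0L
  uninformative <- out$n_snvs == 0 | out$n_snvs < min_informative
  out$phase <- ifelse(uninformative, "unknown",
    ifelse(out$log_lp > out$log_lm, "paternal",
      ifelse(out$log_lm > out$log_lp, "maternal", "unknown")))
  out
}

## log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Phase an SV from its supporting and reference read sets
#'
#' Per-set likelihoods are the products of the member reads' haplotype
#' likelihoods (log-space sums), normalized to probabilities summing to 1.
#' Each set's phase is the maximum-probability haplotype; the SV counts as
#' phased iff the two sets' phases are known and differ (a heterozygous SV
#' separates its alt reads from its reference reads by haplotype). The
#' phasing quality is
#' `PP = -10 log10(max(Pp(SV), Pm(SV)) * max(Pp(REF), Pm(REF)))`,
#' computed from the normalized maxima (0 at maximal confidence).
#'
#' @param read_phases Output of [phase_reads()].
#' @param alt_reads,ref_reads Read-id sets of the SV's supporting and
#'   reference-spanning reads.
#' @param sv_id Optional identifier copied to the output.
#' @return One-row `data.frame`: `sv_id`, `alt_phase`, `ref_phase`, `pp`,
#'   `phased`, `reason` (`NA` when phased).
#' @export
phase_sv <- function(read_phases, alt_reads, ref_reads, sv_id = NA_character_) {
  set_phase <- function(ids) {
    rp <- read_phases[read_phases$read_id %in% ids &
                        read_phases$n_snvs > 0, , drop = FALSE]
    if (nrow(rp) == 0)
      return(list(phase = "unknown", prob = NA_real_, n = 0L))
    lp <- sum(rp$log_lp); lm <- sum(rp$log_lm)
    z <- logsumexp(c(lp, lm))
    probs <- exp(c(lp, lm) - z)
    phase <- if (lp > lm) "paternal" else if (lm > lp) "maternal"
      else "unknown"
    list(phase = phase, prob = max(probs), n = nrow(rp))
  }
  if (length(alt_reads) == 0 || length(ref_reads) == 0) {
    return(data.frame(sv_id = sv_id, alt_phase = "unknown",
                      ref_phase = "unknown", pp = NA_real_, phased = FALSE,
                      reason = "empty alt or ref read set",
                      stringsAsFactors = FALSE))
  }
  alt <- set_phase(alt_reads)
  ref <- set_phase(ref_reads)
  phased <- alt$phase != "unknown" && ref$phase != "unknown" &&
    alt$phase != ref$phase
  pp <- if (alt$n > 0 && ref$n > 0)
    -10 * log10(alt$prob * ref$prob) else NA_real_
  reason <- if (phased) NA_character_
    else if (alt$n == 0 || ref$n == 0) "no informative SNVs in a read set"
    else if (alt$phase == ref$phase) "alt and ref reads share a haplotype"
    else "ambiguous haplotype likelihoods"
  data.frame(sv_id = sv_id, alt_phase = alt$phase, ref_phase = ref$phase,
             pp = pp, phased = phased, reason = reason,
             stringsAsFactors = FALSE)
}

#' Phase every call in a call set
#'
#' Applies [phase_sv()] to each call's `alt_reads`/`ref_reads`.
#'
#' @param calls Call `data.frame` with read-set list columns filled in.
#' @param read_phases Output of [phase_reads()].
#' @return `data.frame` with one row per call.
#' @export
phase_calls <- function(calls, read_phases) {
  do.call(rbind, lapply(seq_len(nrow(calls)), function(i)
    phase_sv(read_phases, calls$alt_reads[[i]], calls$ref_reads[[i]],
             sv_id = calls$id[i])))
}

#' Read phased heterozygous SNVs from a VCF
#'
#' Keeps bi-allelic SNVs with a phased heterozygous genotype (`0|1` or
#' `1|0`). By convention the first allele of the phased genotype is the
#' paternal one (configurable).
#'
#' @param path VCF path.
#' @param sample Sample column to use (default: first).
#' @param first_allele Which haplotype the first phased allele belongs to:
#'   `"paternal"` (default) or `"maternal"`.
#' @return Phased SNV `data.frame` (`chrom`, `pos` 0-based, `paternal`,
#'   `maternal`).
#' @export
read_phased_snvs <- function(path, sample = NULL, first_allele = "paternal") {
  stopifnot(first_allele %in% c("paternal", "maternal"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      paternal = character(), maternal = character()))
  gt <- vcfR::extract.gt(v)[, if (is.null(sample)) 1L else sample]
  snv <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT) & gt %in% c("0|1", "1|0")
  fix <- fix[snv, , drop = FALSE]
  gt <- gt[snv]
  first <- ifelse(gt == "0|1", fix$REF, fix$ALT)
  second <- ifelse(gt == "0|1", fix$ALT, fix$REF)
  if (first_allele == "paternal") {
    pat <- first; mat <- second
  } else {
    pat <- second; mat <- first
  }
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
             paternal = pat, maternal = mat, stringsAsFactors = FALSE)
}

#' Extract a base-call pileup at given sites from a BAM file
#'
#' Walks each record's CIGAR to find the query base and quality aligned at
#' every requested reference position. Deletions and reference skips at a
#' site yield no row; soft clips are handled; secondary alignments are
#' ignored.
#'
#' @param path BAM (or SAM) file.
#' @param sites `data.frame` with `chrom` and `pos` (0-based) columns.
#' @return Pileup `data.frame`: `read_id`, `chrom`, `pos`, `base`, `qual`.
#' @export
pileup_at_sites <- function(path, sites) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  out <- list()
  site_by_chrom <- split(sites$pos, sites$chrom)
  for (i in seq_along(res$qname)) {
    chrom <- as.character(res$rname[i])
    pos_list <- site_by_chrom[[chrom]]
    if (is.null(pos_list) || is.na(res$cigar[i])) next
    ref0 <- res$pos[i] - 1L
    ops <- GenomicAlignments::explodeCigarOps(res$cigar[i])[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(res$cigar[i])[[1]]
    rpos <- ref0; qpos <- 0L
    seqc <- as.character(res$seq[i])
    qualc <- as.integer(charToRaw(as.character(res$qual[i]))) - 33L
    for (k in seq_along(ops)) {
      op <- ops[k]; l <- lens[k]
      if (op %in% c("M", "=", "X")) {
        sel <- pos_list[pos_list >= rpos & pos_list < rpos + l]
        if (length(sel) > 0) {
          off <- qpos + (sel - rpos) + 1L
          out[[length(out) + 1]] <- data.frame(
            read_id = res$qname[i], chrom = chrom, pos = sel,
            base = substring(seqc, off, off), qual = qualc[off],
            stringsAsFactors = FALSE)
        }
        rpos <- rpos + l; qpos <- qpos + l
      } else if (op %in% c("I", "S")) {
        qpos <- qpos + l
      } else if (op %in% c("D", "N")) {
        rpos <- rpos + l
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(read_id = character(), chrom = character(),
                      pos = integer(), base = character(), qual = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
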