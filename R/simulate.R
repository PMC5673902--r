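## Breakpoint simulator: shatter a chromosome, simulate error-injected long
## reads for a heterozygous genome, and emit oracle split alignments.
##
## The simulator is layered. `shatter()` and `simulate_reads()` always
## produce an exact *layout*: the true source interval of every read
## segment, together with per-segment mismatch/deletion/insertion counts
## drawn binomially at the error-model rates, from which read offsets, read
## lengths, percent identity and base qualities follow. Sequence strings are
## materialized on demand (`sim_read_sequences()`, `write_fastq()`) by
## placing exactly those error counts; the split-read caller consumes only
## layout-level quantities, so both layers describe the same simulated data.

#' Nanopore-style sequencing error model
#'
#' Default rates reflect R9.4-era nanopore data: 15.1% per-base error
#' dominated by deletions (9.1%), then mismatches (5.1%) and insertions
#' (0.9%). An optional homopolymer deletion multiplier (e.g. 2.6) inflates
#' the deletion rate inside homopolymer regions when sequence context is
#' available.
#'
#' @param mismatch,deletion,insertion Per-base rates (must sum below 1).
#' @param hp_del_multiplier Deletion-rate multiplier inside homopolymers
#'   (default 1 = off; applied only when the genome carries sequence).
#' @return List of class `"error_model"`.
#' @export
error_model <- function(mismatch = 0.051, deletion = 0.091,
                        insertion = 0.009, hp_del_multiplier = 1) {
  stopifnot(mismatch >= 0, deletion >= 0, insertion >= 0,
            mismatch + deletion + insertion < 1, hp_del_multiplier >= 0)
  structure(list(mismatch = mismatch, deletion = deletion,
                 insertion = insertion,
                 hp_del_multiplier = hp_del_multiplier),
            class = "error_model")
}

#' Generate a random reference chromosome
#'
#' @param length Sequence length in bp.
#' @param gc GC fraction (default 0.4).
#' @param seed RNG seed.
#' @param name Chromosome name (default `"chrS"`).
#' @return `DNAStringSet` of one sequence.
#' @export
random_genome <- function(length, gc = 0.4, seed = NULL, name = "chrS") {
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    s <- paste(sample(names(p), length, replace = TRUE, prob = p),
               collapse = "")
    setNames(Biostrings::DNAStringSet(s), name)
  })
}

#' Shatter a chromosome into a randomly reshuffled derivative
#'
#' Introduces `n_breakpoints` cut positions (minimum spacing enforced, also
#' from the region edges), permutes the resulting segments into a new order,
#' flips each independently with probability 0.5, and derives the canonical
#' truth junctions from the adjacencies of the permutation. Adjacencies that
#' restore reference collinearity (identity permutation stretches, in either
#' orientation) produce no junction.
#'
#' @param reference `DNAStringSet`/`DNAString`/character sequence, a FASTA
#'   path, or a single integer length for sequence-free simulation.
#' @param n_breakpoints Number of cuts.
#' @param region Optional `c(start, end)` (0-based half-open) within the
#'   chromosome; default the whole sequence.
#' @param min_spacing Minimum distance between cuts and from region edges
#'   (default 1000 bp).
#' @param seed RNG seed (reproducible shatter per seed).
#' @param name Chromosome name when `reference` is a bare length.
#' @return Object of class `"shattered_genome"`: `chrom`, `ref_length`,
#'   `region`, `cuts`, `pieces` (reference segments in derived order, with
#'   derived coordinates and flips), `truth` (canonical junction
#'   `data.frame`), `reference` (`DNAStringSet` or `NULL`), `derived`
#'   (`DNAStringSet` or `NULL`), `seed`.
#' @export
shatter <- function(reference, n_breakpoints, region = NULL,
                    min_spacing = 1000, seed = NULL, name = "chrS") {
  ref_seq <- NULL
  if (is.numeric(reference) && length(reference) == 1) {
    ref_length <- as.integer(reference)
    chrom <- name
  } else {
    if (is.character(reference) && length(reference) == 1 &&
        file.exists(reference))
      reference <- Biostrings::readDNAStringSet(reference)
    if (is.character(reference))
      reference <- Biostrings::DNAStringSet(setNames(reference, name))
    if (is(reference, "DNAString"))
      reference <- Biostrings::DNAStringSet(setNames(list(reference), name))
    names(reference) <- sub("\\s.*", "", names(reference))
    ref_seq <- reference[1]
    ref_length <- Biostrings::width(ref_seq)[1]
    chrom <- names(ref_seq)[1]
  }
  if (is.null(region)) region <- c(0L, ref_length)
  region <- as.integer(region)
  L <- region[2] - region[1]
  n <- as.integer(n_breakpoints)
  if (n > 0 && L < (n + 1) * min_spacing)
    stop("region too small for ", n, " breakpoints at spacing ", min_spacing)
  with_seed(seed, {
    if (n > 0) {
      slack <- sort(runif(n, 0, L - (n + 1) * min_spacing))
      cuts <- as.integer(region[1] + min_spacing * seq_len(n) + floor(slack))
    } else {
      cuts <- integer(0)
    }
    bounds <- c(region[1], cuts, region[2])
    pieces <- data.frame(ref_start = bounds[-length(bounds)],
                         ref_end = bounds[-1])
    perm <- sample(nrow(pieces))
    flip <- runif(nrow(pieces)) < 0.5
    pieces <- pieces[perm, , drop = FALSE]
    pieces$flip <- flip
    ## prefix/suffix outside the region are fixed, unflipped
    pre <- if (region[1] > 0)
      data.frame(ref_start = 0L, ref_end = region[1], flip = FALSE) else NULL
    post <- if (region[2] < ref_length)
      data.frame(ref_start = region[2], ref_end = ref_length, flip = FALSE)
      else NULL
    pieces <- rbind(pre, pieces, post)
    pieces$chrom <- chrom
    w <- pieces$ref_end - pieces$ref_start
    pieces$derived_end <- cumsum(w)
    pieces$derived_start <- pieces$derived_end - w
    rownames(pieces) <- NULL
    truth <- derive_truth_junctions(pieces)
    derived <- NULL
    if (!is.null(ref_seq)) {
      parts <- lapply(seq_len(nrow(pieces)), function(i) {
        s <- Biostrings::subseq(ref_seq[[1]], pieces$ref_start[i] + 1L,
                                pieces$ref_end[i])
        if (pieces$flip[i]) Biostrings::reverseComplement(s) else s
      })
      derived <- setNames(
        Biostrings::DNAStringSet(do.call(Biostrings::xscat, parts)),
        chrom)
    }
    structure(list(chrom = chrom, ref_length = ref_length, region = region,
                   cuts = cuts, pieces = pieces, truth = truth,
                   reference = ref_seq, derived = derived, seed = seed),
              class = "shattered_genome")
  })
}

## truth junctions from the adjacencies of a derived piece order
derive_truth_junctions <- function(pieces) {
  n <- nrow(pieces)
  if (n < 2) {
    tj <- empty_junctions()
    tj$canonical <- logical(0)
    return(tj[c("chrom1", "pos1", "ori1", "chrom2", "pos2", "ori2",
                "canonical")])
  }
  a <- seq_len(n - 1); b <- a + 1L
  collinear <- pieces$chrom[a] == pieces$chrom[b] & (
    (!pieces$flip[a] & !pieces$flip[b] &
       pieces$ref_end[a] == pieces$ref_start[b]) |
      (pieces$flip[a] & pieces$flip[b] &
         pieces$ref_start[a] == pieces$ref_end[b]))
  a <- a[!collinear]; b <- b[!collinear]
  if (length(a) == 0)
    return(derive_truth_junctions(pieces[1, , drop = FALSE]))
  j <- data.frame(
    chrom1 = pieces$chrom[a],
    pos1 = ifelse(pieces$flip[a], pieces$ref_start[a],
                  pieces$ref_end[a] - 1L),
    ori1 = ifelse(pieces$flip[a], "-", "+"),
    chrom2 = pieces$chrom[b],
    pos2 = ifelse(pieces$flip[b], pieces$ref_end[b] - 1L,
                  pieces$ref_start[b]),
    ori2 = ifelse(pieces$flip[b], "+", "-"),
    stringsAsFactors = FALSE)
  j <- canonicalize_junctions(j)
  j <- j[!duplicated(j[c("chrom1", "pos1", "ori1",
                         "chrom2", "pos2", "ori2")]), , drop = FALSE]
  rownames(j) <- NULL
  j
}

#' Simulate a genome carrying small deletions
#'
#' Companion generator for the small-event blind spot of split-read calling:
#' deletes segments of the given sizes at well-separated positions and
#' returns the same `"shattered_genome"` structure (the deleted pieces are
#' absent from the derived order; truth junctions are deletion-type).
#'
#' @param reference Same as in [shatter()].
#' @param sizes Integer vector of deletion sizes in bp.
#' @param min_spacing Minimum distance between deletions and chromosome ends
#'   (default 20000 bp).
#' @param seed RNG seed.
#' @param name Chromosome name when `reference` is a bare length.
#' @return `"shattered_genome"` object.
#' @export
simulate_deletion_genome <- function(reference, sizes, min_spacing = 20000,
                                     seed = NULL, name = "chrS") {
  ref_seq <- NULL
  if (is.numeric(reference) && length(reference) == 1) {
    ref_length <- as.integer(reference)
    chrom <- name
  } else {
    if (is.character(reference))
      reference <- Biostrings::DNAStringSet(setNames(reference, name))
    if (is(reference, "DNAString"))
      reference <- Biostrings::DNAStringSet(setNames(list(reference), name))
    ref_seq <- reference[1]
    ref_length <- Biostrings::width(ref_seq)[1]
    chrom <- names(ref_seq)[1]
  }
  k <- length(sizes)
  stopifnot(ref_length > (k + 1) * min_spacing + sum(sizes))
  with_seed(seed, {
    slack <- sort(runif(k, 0, ref_length - (k + 1) * min_spacing -
                          sum(sizes)))
    starts <- as.integer(min_spacing * seq_len(k) +
                           cumsum(c(0, sizes[-k]))[seq_len(k)] + floor(slack))
    ends <- starts + as.integer(sizes)
    bounds_lo <- c(0L, ends)
    bounds_hi <- c(starts, ref_length)
    pieces <- data.frame(ref_start = bounds_lo, ref_end = bounds_hi,
                         flip = FALSE, chrom = chrom)
    w <- pieces$ref_end - pieces$ref_start
    pieces$derived_end <- cumsum(w)
    pieces$derived_start <- pieces$derived_end - w
    truth <- derive_truth_junctions(pieces)
    derived <- NULL
    if (!is.null(ref_seq)) {
      parts <- lapply(seq_len(nrow(pieces)), function(i)
        Biostrings::subseq(ref_seq[[1]], pieces$ref_start[i] + 1L,
                           pieces$ref_end[i]))
      derived <- setNames(
        Biostrings::DNAStringSet(do.call(Biostrings::xscat, parts)), chrom)
    }
    structure(list(chrom = chrom, ref_length = ref_length,
                   region = c(0L, ref_length), cuts = starts,
                   pieces = pieces, truth = truth, reference = ref_seq,
                   derived = derived, seed = seed),
              class = "shattered_genome")
  })
}

#' Simulate long reads from a heterozygous simulated genome
#'
#' Reads are sampled uniformly (position and strand) from the derived and
#' the reference haplotype at `coverage / 2` each — heterozygosity by
#' equal-coverage mixing. Read lengths are log-normal with the given mean.
#' Per aligned source segment, mismatch/deletion/insertion counts are drawn
#' binomially at the error-model rates; read offsets, read length, percent
#' identity and a per-read base quality consistent with the realized error
#' rate follow deterministically.
#'
#' @param genome `"shattered_genome"` from [shatter()] or
#'   [simulate_deletion_genome()].
#' @param coverage Total depth across both haplotypes.
#' @param mean_length Mean read length in bp (default 16200).
#' @param sdlog Log-scale standard deviation of the length distribution
#'   (default 0.6).
#' @param min_length Shortest read emitted (default 200 bp).
#' @param model `"error_model"` (default [error_model()]).
#' @param haplotypes Which haplotypes to sample (default both).
#' @param seed RNG seed; identical seeds give identical read sets.
#' @return Object of class `"sim_reads"`: `reads` (`data.frame`), `pieces`
#'   (provenance: one row per true source segment of each read, with error
#'   counts and read offsets in sequenced orientation), `model`, `genome`
#'   summary, `seed`.
#' @export
simulate_reads <- function(genome, coverage, mean_length = 16200,
                           sdlog = 0.6, min_length = 200,
                           model = error_model(),
                           haplotypes = c("derived", "reference"),
                           seed = NULL) {
  stopifnot(is(genome, "shattered_genome"), is(model, "error_model"))
  derived_len <- sum(genome$pieces$ref_end - genome$pieces$ref_start)
  hap_len <- c(derived = derived_len, reference = genome$ref_length)
  meanlog <- log(mean_length) - sdlog^2 / 2
  with_seed(seed, {
    reads_list <- list()
    pieces_list <- list()
    for (hap in haplotypes) {
      len_h <- hap_len[[hap]]
      n <- max(1L, round(coverage / 2 * len_h / mean_length))
      rl <- pmax(min_length, pmin(len_h, round(rlnorm(n, meanlog, sdlog))))
      start <- floor(runif(n, 0, len_h - rl + 1))
      strand <- sample(c("+", "-"), n, replace = TRUE)
      id <- sprintf("%s_%s_%06d", genome$chrom, substr(hap, 1, 3),
                    seq_len(n))
      reads <- data.frame(read_id = id, haplotype = hap,
                          hap_start = as.integer(start),
                          hap_end = as.integer(start + rl),
                          strand = strand, stringsAsFactors = FALSE)
      pieces <- read_pieces(reads, genome, hap)
      ## error counts per source segment
      plen <- pieces$ref_end - pieces$ref_start
      del_rate <- effective_deletion_rate(pieces, genome, model)
      n_del <- rbinom(length(plen), plen, del_rate)
      n_mis <- rbinom(length(plen), plen, model$mismatch)
      over <- n_del + n_mis > plen
      n_mis[over] <- plen[over] - n_del[over]
      n_ins <- rbinom(length(plen), plen, model$insertion)
      pieces$n_del <- n_del; pieces$n_mis <- n_mis; pieces$n_ins <- n_ins
      pieces$read_span <- plen - n_del + n_ins
      pieces$pid <- (plen - n_del - n_mis) / (plen + n_ins)
      ## read offsets in sequenced orientation
      pieces <- pieces[order(pieces$read_id,
                             ifelse(pieces$strand_read == "-",
                                    -pieces$order, pieces$order)), ,
                       drop = FALSE]
      ends <- stats::ave(pieces$read_span, pieces$read_id, FUN = cumsum)
      pieces$read_start <- as.integer(ends - pieces$read_span)
      pieces$read_end <- as.integer(ends)
      rl_real <- tapply(pieces$read_span, pieces$read_id, sum)
      reads$read_length <- as.integer(rl_real[reads$read_id])
      total_rate <- model$mismatch + model$deletion + model$insertion
      reads$qual <- if (total_rate > 0)
        as.integer(round(-10 * log10(total_rate))) else 40L
      reads_list[[hap]] <- reads
      pieces_list[[hap]] <- pieces
    }
    reads <- do.call(rbind, reads_list)
    pieces <- do.call(rbind, pieces_list)
    rownames(reads) <- rownames(pieces) <- NULL
    structure(list(reads = reads, pieces = pieces, model = model,
                   chrom = genome$chrom, ref_length = genome$ref_length,
                   seed = seed),
              class = "sim_reads")
  })
}

## map read intervals on a haplotype to true source reference segments
read_pieces <- function(reads, genome, hap) {
  if (hap == "reference") {
    out <- data.frame(read_id = reads$read_id, order = 1L,
                      chrom = genome$chrom,
                      ref_start = reads$hap_start, ref_end = reads$hap_end,
                      strand_piece = "+", strand_read = reads$strand,
                      stringsAsFactors = FALSE)
    out$strand <- ifelse(out$strand_read == "-",
                         ifelse(out$strand_piece == "+", "-", "+"),
                         out$strand_piece)
    return(out)
  }
  p <- genome$pieces
  ## for each read, overlapped derived pieces
  first <- findInterval(reads$hap_start, p$derived_start)
  last <- findInterval(reads$hap_end - 1L, p$derived_start)
  idx <- sequence(last - first + 1L, from = first)
  rid <- rep(seq_len(nrow(reads)), last - first + 1L)
  ord <- sequence(last - first + 1L)
  ov_start <- pmax(reads$hap_start[rid], p$derived_start[idx])
  ov_end <- pmin(reads$hap_end[rid], p$derived_end[idx])
  ref_start <- ifelse(p$flip[idx],
                      p$ref_start[idx] + (p$derived_end[idx] - ov_end),
                      p$ref_start[idx] + (ov_start - p$derived_start[idx]))
  ref_end <- ref_start + (ov_end - ov_start)
  out <- data.frame(read_id = reads$read_id[rid], order = ord,
                    chrom = genome$chrom,
                    ref_start = as.integer(ref_start),
                    ref_end = as.integer(ref_end),
                    strand_piece = ifelse(p$flip[idx], "-", "+"),
                    strand_read = reads$strand[rid],
                    stringsAsFactors = FALSE)
  out$strand <- ifelse(out$strand_read == "-",
                       ifelse(out$strand_piece == "+", "-", "+"),
                       out$strand_piece)
  out
}

## deletion rate per piece, inflated inside homopolymers when requested
effective_deletion_rate <- function(pieces, genome, model) {
  base <- model$deletion
  if (model$hp_del_multiplier == 1 || is.null(genome$reference))
    return(rep(base, nrow(pieces)))
  hp <- homopolymer_track(genome$reference)
  gr <- GenomicRanges::GRanges(pieces$chrom,
    IRanges::IRanges(start = pieces$ref_start + 1L, end = pieces$ref_end))
  ov <- GenomicRanges::findOverlaps(gr, hp)
  inter <- IRanges::width(IRanges::pintersect(
    gr[S4Vectors::queryHits(ov)], hp[S4Vectors::subjectHits(ov)]))
  frac <- rep(0, nrow(pieces))
  agg <- tapply(inter, S4Vectors::queryHits(ov), sum)
  frac[as.integer(names(agg))] <- agg / IRanges::width(gr)[
    as.integer(names(agg))]
  pmin(0.95, base * (1 - frac) + base * model$hp_del_multiplier * frac)
}

#' Materialize simulated read sequences
#'
#' Builds the error-injected sequence of each simulated read by placing the
#' layout's per-segment mismatch, deletion and insertion counts at random
#' positions (deterministic given the simulation seed).
#'
#' @param sim `"sim_reads"` object.
#' @param genome The `"shattered_genome"` the reads were simulated from
#'   (must carry sequence).
#' @param ids Optional subset of read ids.
#' @return Named character vector of read sequences (sequenced orientation).
#' @export
sim_read_sequences <- function(sim, genome, ids = NULL) {
  stopifnot(is(genome, "shattered_genome"), !is.null(genome$reference))
  pieces <- sim$pieces
  if (!is.null(ids)) pieces <- pieces[pieces$read_id %in% ids, , drop = FALSE]
  refseq <- genome$reference[[1]]
  mat_seed <- if (is.null(sim$seed)) NULL else sim$seed + 7L
  with_seed(mat_seed, {
    bases <- c("A", "C", "G", "T")
    per_piece <- vapply(seq_len(nrow(pieces)), function(i) {
      src <- Biostrings::subseq(refseq, pieces$ref_start[i] + 1L,
                                pieces$ref_end[i])
      if (pieces$strand[i] == "-")
        src <- Biostrings::reverseComplement(src)
      ch <- strsplit(as.character(src), "", fixed = TRUE)[[1]]
      n <- length(ch)
      if (pieces$n_mis[i] > 0) {
        at <- sample(n, pieces$n_mis[i])
        ch[at] <- vapply(ch[at], function(b)
          sample(setdiff(bases, b), 1), "")
      }
      if (pieces$n_del[i] > 0) {
        at <- sample(n, pieces$n_del[i])
        ch <- ch[-at]
      }
      if (pieces$n_ins[i] > 0) {
        at <- sort(sample(length(ch) + 1L, pieces$n_ins[i], replace = TRUE))
        for (k in rev(seq_along(at)))
          ch <- append(ch, sample(bases, 1), after = at[k] - 1L)
      }
      paste(ch, collapse = "")
    }, "")
    ord <- order(pieces$read_id, pieces$read_start)
    seqs <- tapply(per_piece[ord], pieces$read_id[ord],
                   paste, collapse = "")
    setNames(as.character(seqs), names(seqs))
  })
}

#' Write simulated reads to FASTQ
#'
#' @param sim `"sim_reads"` object.
#' @param genome Sequence-carrying `"shattered_genome"`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, genome, path) {
  seqs <- sim_read_sequences(sim, genome)
  qual <- setNames(sim$reads$qual, sim$reads$read_id)[names(seqs)]
  lines <- as.vector(rbind(paste0("@", names(seqs)), seqs, "+",
                           vapply(seq_along(seqs), function(i)
                             strrep(rawToChar(as.raw(qual[i] + 33L)),
                                    nchar(seqs[i])), "")))
  writeLines(lines, path)
  invisible(path)
}

#' Oracle split alignments of simulated reads
#'
#' Emits one aligned segment per true source segment of each read, with the
#' exact reference interval, strand and read offsets from the simulation
#' provenance — an idealized aligner with no mapping noise. Two realistic
#' limits of split alignment are emulated: consecutive collinear segments
#' whose reference discontinuity is shorter than `min_split` bp are aligned
#' through as one segment (the discontinuity absorbed as a deletion), and
#' segments occupying fewer than `min_anchor` bp of the read are not
#' reported (their span stays unaligned).
#'
#' @param sim `"sim_reads"` object.
#' @param min_split Smallest reference discontinuity that causes a split
#'   (default 50 bp).
#' @param min_anchor Minimum aligned read span of a reported segment
#'   (default 50 bp).
#' @param mapq Reported mapping quality (default 60).
#' @param mapq_jitter Uniform +/- jitter on mapq for robustness tests
#'   (default 0).
#' @param seed Seed for the jitter.
#' @return Segment `data.frame` (same shape as [read_alignments()] output).
#' @export
oracle_align <- function(sim, min_split = 50, min_anchor = 50, mapq = 60,
                         mapq_jitter = 0, seed = NULL) {
  p <- sim$pieces[order(sim$pieces$read_id, sim$pieces$read_start), ,
                  drop = FALSE]
  n <- nrow(p)
  if (n == 0) return(empty_segments())
  ## merge collinear neighbours with small reference discontinuity
  same_read <- c(FALSE, p$read_id[-1] == p$read_id[-n])
  gap_fwd <- c(NA, p$ref_start[-1] - p$ref_end[-n])   # for '+' strand pairs
  gap_rev <- c(NA, p$ref_end[-1] - p$ref_start[-n])   # for '-' strand pairs
  same_strand <- c(FALSE, p$strand[-1] == p$strand[-n])
  refgap <- ifelse(p$strand == "+", gap_fwd, -gap_rev)
  mergeable <- same_read & same_strand & !is.na(refgap) &
    refgap >= 0 & refgap < min_split
  grp <- cumsum(!mergeable)
  merged <- data.frame(
    read_id = tapply(p$read_id, grp, `[`, 1),
    chrom = tapply(p$chrom, grp, `[`, 1),
    ref_start = as.integer(tapply(p$ref_start, grp, min)),
    ref_end = as.integer(tapply(p$ref_end, grp, max)),
    strand = tapply(p$strand, grp, `[`, 1),
    read_start = as.integer(tapply(p$read_start, grp, min)),
    read_end = as.integer(tapply(p$read_end, grp, max)),
    n_err = as.numeric(tapply(p$n_mis + p$n_ins + p$n_del, grp, sum)),
    stringsAsFactors = FALSE)
  rownames(merged) <- NULL
  ref_span <- merged$ref_end - merged$ref_start
  merged$pid <- pmax(0, pmin(1, 1 - merged$n_err / pmax(ref_span, 1)))
  rl <- tapply(sim$pieces$read_span, sim$pieces$read_id, sum)
  merged$read_length <- as.integer(rl[merged$read_id])
  keep <- (merged$read_end - merged$read_start) >= min_anchor
  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) == 0) return(empty_segments())
  with_seed(seed, {
    mq <- rep(as.integer(mapq), nrow(merged))
    if (mapq_jitter > 0)
      mq <- pmax(0L, mq + sample(seq(-mapq_jitter, mapq_jitter),
                                 nrow(merged), replace = TRUE))
    merged$mapq <- mq
  })
  out <- merged[c("read_id", "chrom", "ref_start", "ref_end", "strand",
                  "mapq", "read_start", "read_end", "read_length", "pid")]
  out <- out[order(out$chrom, out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a segment table as SAM
#'
#' Minimal SAM 1.6 output of split alignments (no sequence): one record per
#' segment, supplementary flag on all but the first segment of each read,
#' CIGAR reconstructed from read offsets and reference span (clips plus an
#' M run padded with I or D), NM derived from the segment PID.
#'
#' @param segments Segment `data.frame`.
#' @param chrom_lengths Named vector of reference lengths.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(segments, chrom_lengths, path) {
  s <- segments[order(segments$chrom, segments$ref_start), , drop = FALSE]
  first_of_read <- !duplicated(s$read_id)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  read_span <- s$read_end - s$read_start
  ref_span <- s$ref_end - s$ref_start
  m <- pmin(read_span, ref_span)
  ins <- read_span - m
  del <- ref_span - m
  lead <- ifelse(s$strand == "+", s$read_start,
                 s$read_length - s$read_end)
  trail <- s$read_length - lead - read_span
  cigar <- paste0(
    ifelse(lead > 0, paste0(lead, "S"), ""),
    m, "M",
    ifelse(ins > 0, paste0(ins, "I"), ""),
    ifelse(del > 0, paste0(del, "D"), ""),
    ifelse(trail > 0, paste0(trail, "S"), ""))
  cols <- m + ins + del
  nm <- pmax(0L, as.integer(round(cols - s$pid * cols)))
  flag <- ifelse(s$strand == "-", 16L, 0L) +
    ifelse(first_of_read, 0L, 2048L)
  rec <- paste(s$read_id, flag, s$chrom, s$ref_start + 1L, s$mapq, cigar,
               "*", 0L, 0L, "*", "*", paste0("NM:i:", nm), sep = "\t")
  writeLines(c(header, rec), path)
  invisible(path)
}
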