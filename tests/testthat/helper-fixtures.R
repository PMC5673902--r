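## Shared fixtures and independent oracles for the test suite.

## build a segment table row with sensible defaults
seg_row <- function(read_id, chrom, ref_start, ref_end, strand = "+",
                    mapq = 60L, read_start = 0L,
                    read_end = read_start + (ref_end - ref_start),
                    read_length = read_end, pid = 0.9) {
  data.frame(read_id = read_id, chrom = chrom,
             ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
             strand = strand, mapq = as.integer(mapq),
             read_start = as.integer(read_start),
             read_end = as.integer(read_end),
             read_length = as.integer(read_length), pid = pid,
             stringsAsFactors = FALSE)
}

## a canonical junction row
junc_row <- function(read_id, chrom1, pos1, ori1, chrom2, pos2, ori2,
                     gap = 0L, mapq = 60L, pid = 0.9, plen = 0.5) {
  data.frame(read_id = read_id,
             chrom1 = chrom1, pos1 = as.integer(pos1), ori1 = ori1,
             chrom2 = chrom2, pos2 = as.integer(pos2), ori2 = ori2,
             gap = as.integer(gap), mapq1 = mapq, mapq2 = mapq,
             pid1 = pid, pid2 = pid, plen1 = plen, plen2 = plen,
             canonical = TRUE, stringsAsFactors = FALSE)
}

## random canonical junction set for property tests
random_junctions <- function(n, chroms = c("chr1", "chr2"), span = 2000,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  j <- do.call(rbind, lapply(seq_len(n), function(i) {
    c1 <- sample(chroms, 1)
    junc_row(paste0("r", i), c1, sample(span, 1),
             sample(c("+", "-"), 1), c1, span + sample(span, 1),
             sample(c("+", "-"), 1), gap = sample(0:20, 1))
  }))
  canonicalize_junctions(j)
}

## O(n^2) transitive-closure clustering oracle (independent of the
## union-find path): explicit boolean closure over the pairwise relation
bf_cluster <- function(j, d = 10) {
  n <- nrow(j)
  m <- matrix(FALSE, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      m[a, b] <- j$chrom1[a] == j$chrom1[b] & j$chrom2[a] == j$chrom2[b] &
        j$ori1[a] == j$ori1[b] & j$ori2[a] == j$ori2[b] &
        abs(j$pos1[a] - j$pos1[b]) <= d & abs(j$pos2[a] - j$pos2[b]) <= d
    }
  }
  repeat {
    m2 <- m | (m %*% m > 0)
    if (identical(m2, m)) break
    m <- m2
  }
  ## component label = smallest member index
  vapply(seq_len(n), function(i) min(which(m[i, ])), 1L)
}

## are two cluster labelings the same partition?
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

## naive per-base homopolymer scanner (independent oracle for the rle path)
naive_homopolymers <- function(seq, min_run = 5, border = 1) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(ch)
  runs <- list()
  i <- 1
  while (i <= n) {
    k <- i
    while (k < n && ch[k + 1] == ch[i]) k <- k + 1
    if (k - i + 1 >= min_run && ch[i] %in% c("A", "C", "G", "T"))
      runs[[length(runs) + 1]] <- c(max(1, i - border), min(n, k + border))
    i <- k + 1
  }
  if (length(runs) == 0) return(matrix(numeric(0), ncol = 2))
  m <- do.call(rbind, runs)
  ## merge overlapping/adjacent
  out <- m[1, , drop = FALSE]
  for (r in seq_len(nrow(m))[-1]) {
    if (m[r, 1] <= out[nrow(out), 2] + 1) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[r, 2])
    } else {
      out <- rbind(out, m[r, ])
    }
  }
  out
}

## write a small SAM file from explicit record lines
write_test_sam <- function(records, path,
                           contigs = c(chr1 = 1000000L, chr2 = 1000000L)) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                      as.integer(contigs)))
  writeLines(c(header, records), path)
  path
}

## a small simulated call set for VCF round-trip tests
fixture_calls <- function(n_per_type = 5, seed = 42) {
  set.seed(seed)
  g <- shatter(4e5, 18, min_spacing = 1000, seed = seed)
  sim <- simulate_reads(g, coverage = 25, seed = seed + 1)
  seg <- oracle_align(sim)
  res <- call_svs(seg)
  calls <- res$calls
  ## add an interchromosomal pair by hand
  bnd <- calls[1, ]
  bnd$chrom2 <- "chrT"
  bnd$svtype <- "BND"
  bnd$id <- "svbnd1"
  calls <- rbind(calls, bnd)
  rownames(calls) <- NULL
  calls
}

## merge reference-collinear consecutive pieces of a derived layout
## (adjacencies that produce no junction leave no boundary for the chain
## builder to see)
collapse_collinear <- function(layout) {
  out <- layout[1, , drop = FALSE]
  for (i in seq_len(nrow(layout))[-1]) {
    last <- nrow(out)
    if (!out$flip[last] && !layout$flip[i] &&
        layout$ref_start[i] == out$ref_end[last]) {
      out$ref_end[last] <- layout$ref_end[i]
    } else if (out$flip[last] && layout$flip[i] &&
               layout$ref_end[i] == out$ref_start[last]) {
      out$ref_start[last] <- layout$ref_start[i]
    } else {
      out <- rbind(out, layout[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}
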