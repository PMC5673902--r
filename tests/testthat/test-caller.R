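test_that("consecutive segment pairs become junctions with the strand rule", {
  seg <- rbind(
    seg_row("r1", "chr1", 100, 600, "+", read_start = 0, read_end = 500,
            read_length = 1000),
    seg_row("r1", "chr1", 1100, 1600, "+", read_start = 500,
            read_end = 1000, read_length = 1000))
  j <- extract_junctions(seg)
  expect_equal(nrow(j), 1)
  expect_equal(j$pos1, 599L)
  expect_equal(j$ori1, "+")
  expect_equal(j$pos2, 1100L)
  ## breakend orientation: the second segment continues rightward from 1100
  expect_equal(j$ori2, "-")
  expect_equal(j$gap, 0L)

  ## N = 3 segments give exactly 2 junctions; N = 1 gives none
  seg3 <- rbind(seg,
    seg_row("r1", "chr1", 5000, 5500, "+", read_start = 1000,
            read_end = 1500, read_length = 1500))
  seg3$read_length <- 1500L
  expect_equal(nrow(extract_junctions(seg3)), 2)
  expect_equal(nrow(extract_junctions(seg[1, ])), 0)

  ## + then - on one chromosome: 3'-3' inversion-type orientations
  seginv <- rbind(
    seg_row("r2", "chr1", 100, 600, "+", read_start = 0, read_end = 500,
            read_length = 1000),
    seg_row("r2", "chr1", 1100, 1600, "-", read_start = 500,
            read_end = 1000, read_length = 1000))
  jinv <- extract_junctions(seginv)
  expect_equal(c(jinv$ori1, jinv$ori2), c("+", "+"))
})

test_that("canonicalization orders sides and is idempotent", {
  j <- junc_row("r", "chr1", 5000, "+", "chr1", 1000, "-")
  j$canonical <- NULL
  c1 <- canonicalize_junctions(j)
  expect_equal(c1$pos1, 1000L)
  expect_equal(c1$ori1, "-")
  expect_equal(c1$pos2, 5000L)
  expect_equal(c1$ori2, "+")

  j2 <- junc_row("r", "chr2", 100, "+", "chr1", 900, "-")
  j2$canonical <- NULL
  c2 <- canonicalize_junctions(j2)
  expect_equal(c2$chrom1, "chr1")

  j3 <- junc_row("r", "chr1", 1000, "+", "chr1", 5000, "-")
  j3$canonical <- NULL
  c3 <- canonicalize_junctions(j3)
  expect_equal(c3$pos1, 1000L)

  ## idempotence on random junctions
  set.seed(7)
  jr <- random_junctions(50)
  expect_equal(canonicalize_junctions(jr), jr)

  expect_error(
    canonicalize_junctions(junc_row("r", "chrZZ", 1, "+", "chrQQ", 2, "-"),
                           chrom_order = c("chr1")),
    "chromosome")
})

test_that("clustering respects the distance threshold at the boundary", {
  j <- rbind(junc_row("a", "chr1", 100, "+", "chr1", 900, "-"),
             junc_row("b", "chr1", 110, "+", "chr1", 910, "-"))
  expect_equal(length(unique(cluster_junctions(j, d = 10)$cluster)), 1)
  j$pos2[2] <- 911L
  expect_equal(length(unique(cluster_junctions(j, d = 10)$cluster)), 2)
  j$pos2[2] <- 910L
  j$pos1[2] <- 111L
  expect_equal(length(unique(cluster_junctions(j, d = 10)$cluster)), 2)
})

test_that("clustering is transitive through chains", {
  j <- rbind(junc_row("a", "chr1", 100, "+", "chr1", 900, "-"),
             junc_row("b", "chr1", 108, "+", "chr1", 908, "-"),
             junc_row("c", "chr1", 115, "+", "chr1", 915, "-"))
  cl <- cluster_junctions(j, d = 10)
  expect_equal(length(unique(cl$cluster)), 1)
  expect_true(same_partition(cl$cluster, bf_cluster(j, 10)))
})

test_that("clustering equals the quadratic closure oracle and is
           permutation invariant", {
  for (seed in c(11, 12)) {
    j <- random_junctions(200, span = 500, seed = seed)
    cl <- cluster_junctions(j, d = 10)
    expect_true(same_partition(cl$cluster, bf_cluster(j, 10)))
    perm <- sample(nrow(j))
    clp <- cluster_junctions(j[perm, ], d = 10)
    expect_true(same_partition(clp$cluster[order(perm)], cl$cluster))
    ## every junction in exactly one cluster; members conserved
    expect_equal(sum(table(cl$cluster)), nrow(j))
  }
})

test_that("raising d never increases the cluster count", {
  j <- random_junctions(120, span = 400, seed = 13)
  counts <- vapply(c(0, 5, 10, 20, 50),
                   function(d) length(unique(cluster_junctions(j, d)$cluster)),
                   1)
  expect_true(all(diff(counts) <= 0))
})

test_that("orientation and gap-vs-span decide the SV type", {
  mk <- function(ori1, ori2, gap, pos2 = 520, reads = c("a", "b")) {
    j <- do.call(rbind, lapply(reads, function(r)
      junc_row(r, "chr1", 500, ori1, "chr1", pos2, ori2, gap = gap)))
    j$cluster <- 1L
    derive_calls(j)
  }
  expect_equal(mk("+", "-", gap = 200)$svtype, "INS")  # g=200 > l=20
  expect_equal(mk("+", "-", gap = 0, pos2 = 1000)$svtype, "DEL")
  expect_equal(mk("-", "+", gap = 0, pos2 = 1000)$svtype, "DUP")
  expect_equal(mk("+", "+", gap = 0, pos2 = 1000)$svtype, "INV")
  expect_equal(mk("-", "-", gap = 0, pos2 = 1000)$svtype, "INV")

  jbnd <- rbind(junc_row("a", "chr1", 500, "+", "chr9", 900, "-"),
                junc_row("b", "chr1", 505, "+", "chr9", 905, "-"))
  jbnd$cluster <- 1L
  expect_equal(derive_calls(jbnd)$svtype, "BND")
})

test_that("support thresholds suppress weak candidates", {
  j1 <- junc_row("only", "chr1", 500, "+", "chr1", 1500, "-")
  j2 <- rbind(j1, junc_row("other", "chr1", 505, "+", "chr1", 1505, "-"))
  j1$cluster <- 1L
  j2$cluster <- 1L
  expect_equal(nrow(derive_calls(j1, min_support = 2)), 0)
  expect_equal(nrow(derive_calls(j2, min_support = 2)), 1)
  expect_equal(nrow(derive_calls(j2, min_support = 2, strict = TRUE)), 0)
})

test_that("medians are lower-middle elements and CIs span members", {
  j <- do.call(rbind, lapply(1:4, function(i)
    junc_row(paste0("r", i), "chr1", c(100, 104, 110, 120)[i], "+",
             "chr1", c(900, 905, 911, 921)[i], "-",
             gap = c(0, 2, 5, 9)[i])))
  j$cluster <- 1L
  call <- derive_calls(j)
  expect_equal(call$pos1, 104L)
  expect_equal(call$pos2, 905L)
  expect_equal(call$gap, 2L)
  expect_equal(c(call$ci1_low, call$ci1_high), c(100L, 120L))
  expect_equal(c(call$ci2_low, call$ci2_high), c(900L, 921L))
  expect_true(call$pos1 >= call$ci1_low && call$pos1 <= call$ci1_high)
})

test_that("reference reads must cross a breakpoint with both flanks", {
  j <- rbind(junc_row("alt1", "chr1", 5000, "+", "chr1", 20000, "-"),
             junc_row("alt2", "chr1", 5003, "+", "chr1", 20003, "-"))
  j$cluster <- 1L
  calls <- derive_calls(j)
  segs <- rbind(
    seg_row("refA", "chr1", 4500, 5500),                 # spans p1 +/-500
    seg_row("refB", "chr1", 4800, 5050),                 # ends at p1+50
    seg_row("alt1", "chr1", 19000, 21000),               # alt read spans p2
    seg_row("refC", "chr1", 19500, 20500))               # spans p2
  out <- find_reference_reads(calls, segs, flank = 100)
  expect_setequal(out$ref_reads[[1]], c("refA", "refC"))
  expect_equal(out$n_ref, 2L)
})

test_that("genotypes follow the binomial posterior", {
  expect_equal(genotype_sv(0, 20)$genotype, "0/0")
  expect_equal(genotype_sv(20, 0)$genotype, "1/1")
  expect_equal(genotype_sv(0, 0)$genotype, "./.")

  ## A = 10, R = 10: evaluate the three binomials directly
  p <- c(0.001, 0.5, 0.9)
  lik <- dbinom(10, 20, p)
  post <- lik / sum(lik)
  g <- genotype_sv(10, 10)
  expect_equal(g$genotype, "0/1")
  expect_equal(g$posterior, post)
  expect_equal(g$gq, min(99, -10 * log10(1 - max(post))))

  ## posterior normalization and argmax monotonicity in alt fraction
  prev <- 1L
  for (a in 0:30) {
    g <- genotype_sv(a, 30 - a)
    expect_equal(sum(g$posterior), 1)
    idx <- match(g$genotype, c("0/0", "0/1", "1/1"))
    expect_gte(idx, prev)
    prev <- idx
  }
})

test_that("MapQual and Cluster flags follow their window rules", {
  calls <- do.call(rbind, lapply(1:3, function(i) {
    j <- rbind(junc_row(paste0("a", i), "chr1", c(100, 500, 900)[i], "+",
                        "chr1", 50000 + i * 3000, "-", mapq = 81L),
               junc_row(paste0("b", i), "chr1", c(100, 500, 900)[i] + 2L,
                        "+", "chr1", 50002 + i * 3000, "-", mapq = 81L))
    j$cluster <- i
    derive_calls(j)
  }))
  flagged <- apply_flags(calls, q2 = 80)
  expect_true(all(flagged$cluster_flag))
  expect_false(any(grepl("MapQual", flagged$filter)))

  two <- apply_flags(calls[1:2, ], q2 = 80)
  ## 2 calls with 2 nearby breakpoints each: still 2 distinct calls in the
  ## window -> below the 3-call threshold
  expect_false(any(two$cluster_flag))

  ## median mapq equal to q2 is flagged ("not exceeding")
  callq <- calls[1, ]
  callq$mapq_med <- 80L
  expect_match(apply_flags(callq, q2 = 80)$filter, "MapQual")
})

test_that("raising the support threshold never increases emitted calls", {
  g <- shatter(2e5, 10, min_spacing = 1000, seed = 21)
  sim <- simulate_reads(g, coverage = 12, seed = 22)
  seg <- oracle_align(sim)
  n <- vapply(1:6, function(t)
    nrow(call_svs(seg, min_support = t)$calls), 1L)
  expect_true(all(diff(n) <= 0))
})
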