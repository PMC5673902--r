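test_that("shatter produces the requested breakpoints, reproducibly", {
  g0 <- shatter(1e5, 0, seed = 1)
  expect_equal(nrow(g0$truth), 0)
  expect_equal(nrow(g0$pieces), 1)

  g <- shatter(5e5, 20, min_spacing = 1000, seed = 2)
  expect_equal(length(g$cuts), 20)
  expect_true(all(diff(g$cuts) >= 1000))
  expect_lte(nrow(g$truth), 21)
  expect_gte(nrow(g$truth), 15)
  g2 <- shatter(5e5, 20, min_spacing = 1000, seed = 2)
  expect_identical(g$pieces, g2$pieces)
  expect_identical(g$truth, g2$truth)
  expect_error(shatter(1e4, 50, min_spacing = 1000, seed = 1), "too small")
})

test_that("truth junctions are canonical with no identity adjacencies", {
  g <- shatter(5e5, 20, min_spacing = 1000, seed = 3)
  expect_identical(canonicalize_junctions(g$truth[names(g$truth) !=
                                                    "canonical"]),
                   g$truth)
  ## forcing the identity permutation leaves no junctions
  pieces <- g$pieces[order(g$pieces$ref_start), ]
  pieces$flip <- FALSE
  w <- pieces$ref_end - pieces$ref_start
  pieces$derived_end <- cumsum(w)
  pieces$derived_start <- pieces$derived_end - w
  expect_equal(nrow(svkit:::derive_truth_junctions(pieces)), 0)
})

test_that("simulated coverage and read lengths match their targets", {
  g <- shatter(2e6, 10, min_spacing = 1000, seed = 4)
  sim <- simulate_reads(g, coverage = 10, seed = 5)
  total <- sum(as.numeric(sim$reads$hap_end - sim$reads$hap_start))
  expect_lt(abs(total - 10 * 2e6) / (10 * 2e6), 0.05)
  expect_equal(sort(unique(sim$reads$haplotype)),
               c("derived", "reference"))
  ## per-haplotype share is half each
  by_hap <- tapply(as.numeric(sim$reads$hap_end - sim$reads$hap_start),
                   sim$reads$haplotype, sum)
  expect_lt(abs(by_hap[["derived"]] / total - 0.5), 0.05)
})

test_that("the realized error layout matches the printed rates", {
  g <- shatter(2e6, 10, min_spacing = 1000, seed = 6)
  sim <- simulate_reads(g, coverage = 10, seed = 7)
  plen <- sum(sim$pieces$ref_end - sim$pieces$ref_start)
  rate <- (sum(sim$pieces$n_mis) + sum(sim$pieces$n_del) +
             sum(sim$pieces$n_ins)) / plen
  expect_lt(abs(rate - 0.151), 0.005)
  ## deletions shrink reads: length ratio ~ 1 - del + ins
  ratio <- sum(sim$reads$read_length) / plen
  expect_lt(abs(ratio - (1 - 0.091 + 0.009)), 0.005)
  ## mean percent identity ~ (1 - del - mis) / (1 + ins)
  expect_lt(abs(mean(sim$pieces$pid) - 0.851 / 1.009), 0.02)
})

test_that("a zero-error model yields exact substrings", {
  g <- shatter(Biostrings::DNAStringSet(
    c(chrZ = paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                   collapse = ""))), 4, min_spacing = 1000, seed = 8)
  sim <- simulate_reads(g, coverage = 3, mean_length = 2000,
                        model = error_model(0, 0, 0), seed = 9)
  seqs <- sim_read_sequences(sim, g)
  ref <- g$reference[[1]]
  der <- g$derived[[1]]
  for (id in sample(names(seqs), 10)) {
    r <- sim$reads[sim$reads$read_id == id, ]
    hap <- if (r$haplotype == "derived") der else ref
    want <- Biostrings::subseq(hap, r$hap_start + 1, r$hap_end)
    if (r$strand == "-") want <- Biostrings::reverseComplement(want)
    expect_equal(seqs[[id]], as.character(want))
  }
})

test_that("mismatch-only injection matches the hamming distance", {
  g <- shatter(Biostrings::DNAStringSet(
    c(chrZ = paste(sample(c("A", "C", "G", "T"), 50000, replace = TRUE),
                   collapse = ""))), 0, seed = 10)
  sim <- simulate_reads(g, coverage = 4, mean_length = 3000,
                        model = error_model(0.051, 0, 0),
                        haplotypes = "reference", seed = 11)
  seqs <- sim_read_sequences(sim, g)
  ref <- g$reference[[1]]
  mism <- 0; tot <- 0
  for (id in names(seqs)) {
    r <- sim$reads[sim$reads$read_id == id, ]
    want <- Biostrings::subseq(ref, r$hap_start + 1, r$hap_end)
    if (r$strand == "-") want <- Biostrings::reverseComplement(want)
    a <- strsplit(seqs[[id]], "")[[1]]
    b <- strsplit(as.character(want), "")[[1]]
    mism <- mism + sum(a != b)
    tot <- tot + length(a)
  }
  expect_lt(abs(mism / tot - 0.051), 0.01)
})

test_that("identical seeds give byte-identical FASTQ", {
  g <- shatter(Biostrings::DNAStringSet(
    c(chrZ = paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                   collapse = ""))), 3, min_spacing = 1000, seed = 12)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(g, 2, mean_length = 2000, seed = 13), g, f1)
  write_fastq(simulate_reads(g, 2, mean_length = 2000, seed = 13), g, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("oracle alignment splits exactly at true junctions", {
  g <- shatter(3e5, 10, min_spacing = 2000, seed = 14)
  sim <- simulate_reads(g, coverage = 8, seed = 15)
  seg <- oracle_align(sim)
  n_seg <- table(seg$read_id)
  pieces_per_read <- table(sim$pieces$read_id)
  ## a read inside one segment gives one record
  singles <- names(pieces_per_read)[pieces_per_read == 1]
  expect_true(all(n_seg[intersect(singles, names(n_seg))] == 1))
  ## reads spanning a junction with adequate anchors give >= 2 records
  expect_gt(sum(n_seg >= 2), 0)
})

test_that("the oracle SAM round-trips through the alignment reader", {
  g <- shatter(2e5, 6, min_spacing = 2000, seed = 16)
  sim <- simulate_reads(g, coverage = 6, seed = 17)
  seg <- oracle_align(sim)
  sam <- tempfile(fileext = ".sam")
  write_sam(seg, setNames(g$ref_length, g$chrom), sam)
  back <- load_reads(sam)
  key <- function(s) s[order(s$read_id, s$read_start),
                       c("read_id", "chrom", "ref_start", "ref_end",
                         "strand", "read_start", "read_end", "read_length")]
  expect_equal(key(back), key(seg), ignore_attr = TRUE)
})

test_that("evaluation is exact on self-comparison and window boundaries", {
  g <- shatter(3e5, 10, min_spacing = 1000, seed = 18)
  t <- g$truth
  ev <- evaluate_calls(t, t)
  expect_equal(ev$recall, 1)
  expect_equal(ev$fdr, 0)
  shifted <- t
  shifted$pos1 <- shifted$pos1 + 101L
  shifted$pos2 <- shifted$pos2 + 101L
  ev2 <- evaluate_calls(shifted, t, match_window = 100)
  expect_equal(ev2$recall, 0)
  shifted100 <- t
  shifted100$pos1 <- shifted100$pos1 + 100L
  ev3 <- evaluate_calls(shifted100, t, match_window = 100)
  expect_equal(ev3$recall, 1)
})

test_that("recall never falls as coverage rises", {
  g <- shatter(1.2e6, 25, region = c(1e5, 1.1e6), min_spacing = 1000,
               seed = 19)
  rec <- vapply(seq_along(c(2, 5, 10, 18, 27)), function(i) {
    cov <- c(2, 5, 10, 18, 27)[i]
    sim <- simulate_reads(g, coverage = cov, seed = 20 + i)
    evaluate_calls(call_svs(oracle_align(sim))$calls, g$truth)$recall
  }, 1)
  expect_true(all(diff(rec) >= -1e-9))
  expect_equal(rec[5], 1)
})

test_that("set intersection pins the proximity and overlap boundaries", {
  base <- fixture_calls()[1, ]
  mk <- function(p1, p2, ci = 0, svtype = "DEL") {
    x <- base
    x$pos1 <- p1; x$pos2 <- p2
    x$ci1_low <- p1 - ci; x$ci1_high <- p1 + ci
    x$ci2_low <- p2 - ci; x$ci2_high <- p2 + ci
    x$svtype <- svtype
    x
  }
  a <- mk(10000, 10400)
  expect_equal(nrow(intersect_sv_sets(a, a)$matches), 1)

  ## CI gap of exactly 101 bp fails; 100 passes (large event: no recip)
  big_a <- mk(10000, 60000)
  big_b <- mk(10101, 60101)
  expect_equal(nrow(intersect_sv_sets(big_a, big_b)$matches), 0)
  big_c <- mk(10100, 60100)
  expect_equal(nrow(intersect_sv_sets(big_a, big_c)$matches), 1)

  ## two 300 bp deletions offset by 200 bp: CIs within 100 but reciprocal
  ## overlap only ~33% -> no match
  small_a <- mk(10000, 10300, ci = 150)
  small_b <- mk(10200, 10500, ci = 150)
  expect_equal(nrow(intersect_sv_sets(small_a, small_b)$matches), 0)
  ## insertions are exempt from the reciprocal-overlap requirement
  ins_a <- mk(10000, 10001, ci = 60, svtype = "INS")
  ins_b <- mk(10080, 10081, ci = 60, svtype = "INS")
  expect_equal(nrow(intersect_sv_sets(ins_a, ins_b)$matches), 1)
  ## reciprocal overlap >= 70% with close CIs matches
  small_c <- mk(10000, 10300, ci = 60)
  small_d <- mk(10050, 10350, ci = 60)
  expect_equal(nrow(intersect_sv_sets(small_c, small_d)$matches), 1)
})
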