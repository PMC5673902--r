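## build a pileup table for reads with given per-site allele choices
mk_snvs <- function(n, spacing = 1500, chrom = "chr1") {
  data.frame(chrom = chrom, pos = spacing * seq_len(n),
             paternal = rep(c("A", "C"), length.out = n),
             maternal = rep(c("G", "T"), length.out = n),
             stringsAsFactors = FALSE)
}

mk_pileup <- function(read_id, snvs, from = "paternal", qual = 20,
                      flip_at = integer(0)) {
  base <- snvs[[from]]
  other <- snvs[[if (from == "paternal") "maternal" else "paternal"]]
  base[flip_at] <- other[flip_at]
  data.frame(read_id = read_id, chrom = snvs$chrom, pos = snvs$pos,
             base = base, qual = qual, stringsAsFactors = FALSE)
}

test_that("base support probability follows the quality transform", {
  expect_equal(snv_support_prob("A", 10, "A"), 0.9)
  expect_equal(snv_support_prob("C", 10, "A"), 0.1)
  expect_equal(snv_support_prob("a", 20, "A"), 0.99)
})

test_that("read phase is the product of per-site support", {
  snvs <- mk_snvs(3)
  pu <- mk_pileup("r1", snvs, "paternal", qual = 20)
  rp <- phase_reads(pu, snvs)
  expect_equal(rp$phase, "paternal")
  expect_equal(rp$n_snvs, 3L)
  expect_equal(rp$log_lp, 3 * log(0.99))
  expect_equal(rp$log_lm, 3 * log(0.01))
})

test_that("reads without informative sites are unknown", {
  snvs <- mk_snvs(3)
  pu <- data.frame(read_id = "r0", chrom = "chr1", pos = 7L, base = "A",
                   qual = 20, stringsAsFactors = FALSE)
  rp <- phase_reads(pu, snvs)
  expect_equal(rp$phase, "unknown")
  expect_equal(rp$n_snvs, 0L)
})

test_that("quality-zero calls are skipped as uninformative", {
  snvs <- mk_snvs(2)
  pu <- mk_pileup("r1", snvs, "paternal", qual = 0)
  rp <- phase_reads(pu, snvs)
  expect_equal(rp$n_snvs, 0L)
  expect_equal(rp$phase, "unknown")
})

test_that("swapping parental labels swaps every phase, pp unchanged", {
  snvs <- mk_snvs(6)
  pu <- rbind(mk_pileup("alt1", snvs[1:4, ], "paternal"),
              mk_pileup("alt2", snvs[2:5, ], "paternal", flip_at = 1),
              mk_pileup("ref1", snvs[1:4, ], "maternal"),
              mk_pileup("ref2", snvs[3:6, ], "maternal"))
  swapped <- snvs
  names(swapped)[3:4] <- c("maternal", "paternal")
  swapped <- swapped[names(snvs)]
  rp <- phase_reads(pu, snvs)
  rs <- phase_reads(pu, swapped)
  expect_equal(rp$log_lp, rs$log_lm)
  expect_equal(rp$log_lm, rs$log_lp)
  flip <- c(paternal = "maternal", maternal = "paternal",
            unknown = "unknown")
  expect_equal(unname(flip[rp$phase]), rs$phase)
  sv <- phase_sv(rp, c("alt1", "alt2"), c("ref1", "ref2"), "sv1")
  svs <- phase_sv(rs, c("alt1", "alt2"), c("ref1", "ref2"), "sv1")
  expect_true(sv$phased && svs$phased)
  expect_equal(sv$alt_phase, "paternal")
  expect_equal(svs$alt_phase, "maternal")
  expect_equal(sv$pp, svs$pp)
})

test_that("an SV is phased only when its read sets separate by haplotype", {
  snvs <- mk_snvs(4)
  pu <- rbind(mk_pileup("a1", snvs, "paternal"),
              mk_pileup("a2", snvs, "paternal"),
              mk_pileup("r1", snvs, "paternal"))
  rp <- phase_reads(pu, snvs)
  sv <- phase_sv(rp, c("a1", "a2"), "r1")
  expect_false(sv$phased)
  expect_match(sv$reason, "share")
  empty <- phase_sv(rp, character(0), "r1")
  expect_false(empty$phased)
  expect_match(empty$reason, "empty")
})

test_that("pp follows the printed transform of the normalized maxima", {
  ## equal likelihoods on both sides: both maxima 0.5, pp = -10 log10(0.25)
  snvs <- mk_snvs(2)
  pu <- rbind(
    data.frame(read_id = "a", chrom = "chr1", pos = snvs$pos[1],
               base = "T", qual = 20, stringsAsFactors = FALSE),
    data.frame(read_id = "r", chrom = "chr1", pos = snvs$pos[1],
               base = "T", qual = 20, stringsAsFactors = FALSE))
  ## T matches neither allele at site 1 (A/G): equal support either way
  rp <- phase_reads(pu, snvs)
  sv <- phase_sv(rp, "a", "r")
  expect_false(sv$phased)
  expect_equal(sv$pp, -10 * log10(0.25))
  ## maximal confidence gives pp = 0
  pu2 <- rbind(mk_pileup("a", snvs, "paternal", qual = 60),
               mk_pileup("r", snvs, "maternal", qual = 60))
  sv2 <- phase_sv(phase_reads(pu2, snvs), "a", "r")
  expect_true(sv2$phased)
  expect_lt(sv2$pp, 0.01)
})

test_that("the minimum-informative-SNV threshold gates read phases", {
  snvs <- mk_snvs(3)
  pu <- mk_pileup("r1", snvs[1:2, ], "paternal")
  expect_equal(phase_reads(pu, snvs, min_informative = 3)$phase, "unknown")
  expect_equal(phase_reads(pu, snvs, min_informative = 2)$phase, "paternal")
})

test_that("simulated heterozygous SVs recover their phase", {
  ## 1 Mb haplotype pair, het SNV every ~1500 bp, 10 kb reads with 15%
  ## per-base error, one het SV on the paternal haplotype
  set.seed(41)
  n_rep <- 200
  ok <- logical(n_rep)
  support_frac <- numeric(0)
  for (r in seq_len(n_rep)) {
    snvs <- mk_snvs(667, spacing = 1500)
    sv_pos <- 5e5
    n_alt <- 1 + rpois(1, 4)
    n_ref <- 1 + rpois(1, 4)
    read_at <- function(id, hap) {
      start <- sv_pos - sample(9000, 1)
      cover <- snvs[snvs$pos >= start & snvs$pos < start + 10000, ]
      err <- runif(nrow(cover)) < 0.15
      flip_at <- which(err)
      mk_pileup(id, cover, hap, qual = 8, flip_at = flip_at)
    }
    pu <- rbind(
      do.call(rbind, lapply(seq_len(n_alt), function(i)
        read_at(paste0("alt", i), "paternal"))),
      do.call(rbind, lapply(seq_len(n_ref), function(i)
        read_at(paste0("ref", i), "maternal"))))
    rp <- phase_reads(pu, snvs)
    sv <- phase_sv(rp, paste0("alt", seq_len(n_alt)),
                   paste0("ref", seq_len(n_ref)))
    ok[r] <- sv$phased && sv$alt_phase == "paternal" &&
      sv$ref_phase == "maternal"
    ## fraction of sites supporting the assigned phase ~ 1 - error rate
    if (r <= 20) {
      key <- paste(pu$chrom, pu$pos)
      skey <- paste(snvs$chrom, snvs$pos)
      truth_allele <- ifelse(grepl("^alt", pu$read_id),
                             snvs$paternal[match(key, skey)],
                             snvs$maternal[match(key, skey)])
      support_frac <- c(support_frac, mean(pu$base == truth_allele))
    }
  }
  expect_gte(mean(ok), 0.95)
  expect_lt(abs(mean(support_frac) - 0.85), 0.03)
})

test_that("phased SNVs load from VCF with the allele convention", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("chr1", 101, ".", "A", "G", ".", "PASS", ".", "GT", "0|1",
          sep = "\t"),
    paste("chr1", 201, ".", "C", "T", ".", "PASS", ".", "GT", "1|0",
          sep = "\t"),
    paste("chr1", 301, ".", "C", "T", ".", "PASS", ".", "GT", "0/1",
          sep = "\t"),
    paste("chr1", 401, ".", "C", "TA", ".", "PASS", ".", "GT", "0|1",
          sep = "\t")), path)
  snvs <- read_phased_snvs(path)
  expect_equal(nrow(snvs), 2)  # unphased het and non-SNV dropped
  expect_equal(snvs$pos, c(100L, 200L))
  expect_equal(snvs$paternal, c("A", "T"))
  expect_equal(snvs$maternal, c("G", "C"))
  swapped <- read_phased_snvs(path, first_allele = "maternal")
  expect_equal(swapped$paternal, c("G", "C"))
})

test_that("pileups extract the aligned base and quality at each site", {
  sam <- tempfile(fileext = ".sam")
  ## read: 2S3M1D2M, pos 101; query CCGTAAC quals 30 each
  write_test_sam(paste("p1", 0, "chr1", 101, 60,
                       "2S3M1D2M", "*", 0, 0, "GCGTAAC",
                       paste(rep("?", 7), collapse = ""),
                       sep = "\t"), sam)
  sites <- data.frame(chrom = "chr1", pos = c(100L, 101L, 103L, 104L))
  pu <- pileup_at_sites(sam, sites)
  ## pos 100 (0-based) -> first M base "G"; 101 -> "T"; 103 is deleted;
  ## 104 -> "A"
  expect_equal(pu$pos, c(100L, 101L, 104L))
  expect_equal(pu$base, c("G", "T", "A"))
  expect_equal(pu$qual, rep(30L, 3))
})
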