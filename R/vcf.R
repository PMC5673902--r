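## VCF 4.2 output of SV calls, and parsing back into the call model.
##
## Intrachromosomal calls use symbolic ALTs (<DEL>, <INS>, <DUP>, <INV>) with
## the junction orientation encoded in the Delly-style CT INFO key
## (3to5, 5to3, 3to3, 5to5); interchromosomal calls are emitted as breakend
## (BND) record pairs with bracket ALTs and MATEID. Internal 0-based
## coordinates are converted to 1-based POS/END here.

ct_of <- function(ori1, ori2) {
  paste0(ifelse(ori1 == "+", "3", "5"), "to", ifelse(ori2 == "+", "3", "5"))
}

ori_of_ct <- function(ct) {
  m <- regmatches(ct, regexec("^([35])to([35])$", ct))[[1]]
  if (length(m) != 3) stop("malformed CT value: ", ct)
  c(ifelse(m[2] == "3", "+", "-"), ifelse(m[3] == "3", "+", "-"))
}

bnd_alt <- function(ref, chrom2, pos2, ori1, ori2) {
  partner <- paste0(chrom2, ":", pos2)
  if (ori1 == "+" && ori2 == "-") paste0(ref, "[", partner, "[")
  else if (ori1 == "+" && ori2 == "+") paste0(ref, "]", partner, "]")
  else if (ori1 == "-" && ori2 == "+") paste0("]", partner, "]", ref)
  else paste0("[", partner, "[", ref)
}

sv_vcf_header <- function(contigs = NULL, sample = "SAMPLE") {
  h <- c("##fileformat=VCFv4.2",
    "##source=svkit",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Confidence interval around POS\">",
    "##INFO=<ID=CIEND,Number=2,Type=Integer,Description=\"Confidence interval around END\">",
    "##INFO=<ID=GAP,Number=1,Type=Integer,Description=\"Median unaligned gap between the junction segments\">",
    "##INFO=<ID=CT,Number=1,Type=String,Description=\"Breakend orientation (connection type)\">",
    "##INFO=<ID=MAPQ,Number=1,Type=Integer,Description=\"Median mapping quality of supporting reads\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend id\">",
    "##INFO=<ID=LINKID,Number=1,Type=String,Description=\"Identifier linking complex junction records\">",
    "##INFO=<ID=Cluster,Number=0,Type=Flag,Description=\"Call lies in an SV-dense window\">",
    "##FILTER=<ID=MapQual,Description=\"Median supporting mapping quality below threshold\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=DUP,Description=\"Tandem duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DV,Number=1,Type=Integer,Description=\"Distinct reads supporting the variant\">",
    "##FORMAT=<ID=DR,Number=1,Type=Integer,Description=\"Distinct reads supporting the reference\">")
  if (!is.null(contigs))
    h <- c(h, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                      as.integer(contigs)))
  c(h, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
             "FORMAT", sample, sep = "\t"))
}

#' Write SV calls to VCF
#'
#' @param calls Call `data.frame` (see [derive_calls()]).
#' @param path Output path.
#' @param reference Optional `DNAStringSet` (or FASTA path) used for REF
#'   bases; otherwise `N` is written.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @param sample Sample name (default `"SAMPLE"`).
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, path, reference = NULL, contigs = NULL,
                         sample = "SAMPLE") {
  if (is.character(reference) && length(reference) == 1)
    reference <- Biostrings::readDNAStringSet(reference)
  if (!is.null(reference))
    names(reference) <- sub("\\s.*", "", names(reference))
  ref_base <- function(chrom, pos0) {
    if (is.null(reference) || !(chrom %in% names(reference))) return("N")
    as.character(Biostrings::subseq(reference[[chrom]], pos0 + 1, pos0 + 1))
  }
  if (is.null(contigs) && !is.null(reference))
    contigs <- setNames(Biostrings::width(reference), names(reference))
  lines <- sv_vcf_header(contigs, sample)
  body <- character(0)
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    filt <- if (is.na(cl$filter) || cl$filter == "") "PASS" else cl$filter
    fmt <- sprintf("%s:%d:%d:%d", cl$genotype,
                   as.integer(round(cl$gq)), cl$n_alt,
                   ifelse(is.na(cl$n_ref), 0L, cl$n_ref))
    common <- sprintf("CIPOS=%d,%d;CIEND=%d,%d;GAP=%d;CT=%s;MAPQ=%d",
                      cl$ci1_low - cl$pos1, cl$ci1_high - cl$pos1,
                      cl$ci2_low - cl$pos2, cl$ci2_high - cl$pos2,
                      cl$gap, ct_of(cl$ori1, cl$ori2), cl$mapq_med)
    if (!is.na(cl$link_id)) common <- paste0(common, ";LINKID=", cl$link_id)
    if (isTRUE(cl$cluster_flag)) common <- paste0(common, ";Cluster")
    if (cl$svtype == "BND") {
      r1 <- ref_base(cl$chrom1, cl$pos1)
      r2 <- ref_base(cl$chrom2, cl$pos2)
      id1 <- paste0(cl$id, "_1"); id2 <- paste0(cl$id, "_2")
      alt1 <- bnd_alt(r1, cl$chrom2, cl$pos2 + 1L, cl$ori1, cl$ori2)
      alt2 <- bnd_alt(r2, cl$chrom1, cl$pos1 + 1L, cl$ori2, cl$ori1)
      info1 <- sprintf("SVTYPE=BND;MATEID=%s;%s", id2, common)
      info2 <- sprintf("SVTYPE=BND;MATEID=%s;%s", id1, common)
      body <- c(body,
        paste(cl$chrom1, cl$pos1 + 1L, id1, r1, alt1, ".", filt, info1,
              "GT:GQ:DV:DR", fmt, sep = "\t"),
        paste(cl$chrom2, cl$pos2 + 1L, id2, r2, alt2, ".", filt, info2,
              "GT:GQ:DV:DR", fmt, sep = "\t"))
    } else {
      r1 <- ref_base(cl$chrom1, cl$pos1)
      svlen <- if (cl$svtype == "DEL") -cl$svlen else cl$svlen
      info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d;%s",
                      cl$svtype, cl$pos2 + 1L, svlen, common)
      body <- c(body,
        paste(cl$chrom1, cl$pos1 + 1L, cl$id, r1,
              paste0("<", cl$svtype, ">"), ".", filt, info,
              "GT:GQ:DV:DR", fmt, sep = "\t"))
    }
  }
  writeLines(c(lines, body), path)
  invisible(path)
}

info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

#' Read SV calls from a VCF written by [write_sv_vcf()]
#'
#' Reconstructs the call model: breakend record pairs are re-joined via
#' MATEID, orientations recovered from the CT key, coordinates converted
#' back to 0-based. Reading a written call set returns the identical model
#' (evidence read sets excepted, which VCF does not carry).
#'
#' @param path VCF path.
#' @return Call `data.frame`.
#' @export
read_sv_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_calls())
  gt <- v@gt
  info <- fix$INFO
  svtype <- info_field(info, "SVTYPE")
  keep <- !(svtype == "BND" & grepl("_2$", fix$ID))
  rows <- lapply(which(keep), function(i) {
    ct <- ori_of_ct(info_field(info[i], "CT"))
    cip <- as.integer(strsplit(info_field(info[i], "CIPOS"), ",")[[1]])
    cie <- as.integer(strsplit(info_field(info[i], "CIEND"), ",")[[1]])
    pos1 <- as.integer(fix$POS[i]) - 1L
    if (svtype[i] == "BND") {
      mate_id <- info_field(info[i], "MATEID")
      mi <- match(mate_id, fix$ID)
      if (is.na(mi)) stop("unpaired breakend record at line ", i)
      chrom2 <- fix$CHROM[mi]
      pos2 <- as.integer(fix$POS[mi]) - 1L
      id <- sub("_1$", "", fix$ID[i])
      svlen <- NA_integer_
    } else {
      chrom2 <- fix$CHROM[i]
      pos2 <- as.integer(info_field(info[i], "END")) - 1L
      id <- fix$ID[i]
      svlen <- abs(as.integer(info_field(info[i], "SVLEN")))
    }
    fmt <- strsplit(gt[i, 2], ":")[[1]]
    link <- info_field(info[i], "LINKID")
    data.frame(cluster = NA_integer_,
               chrom1 = fix$CHROM[i], pos1 = pos1, ori1 = ct[1],
               chrom2 = chrom2, pos2 = pos2, ori2 = ct[2],
               svtype = svtype[i],
               svlen = if (is.na(svlen))
                 abs(pos2 - pos1) else svlen,
               gap = as.integer(info_field(info[i], "GAP")),
               ci1_low = pos1 + cip[1], ci1_high = pos1 + cip[2],
               ci2_low = pos2 + cie[1], ci2_high = pos2 + cie[2],
               n_alt = as.integer(fmt[3]),
               mapq_med = as.integer(info_field(info[i], "MAPQ")),
               id = id, n_ref = as.integer(fmt[4]),
               genotype = fmt[1], gq = as.numeric(fmt[2]),
               filter = fix$FILTER[i],
               cluster_flag = grepl("(^|;)Cluster($|;)", info[i]),
               link_id = link,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  calls$alt_reads <- replicate(nrow(calls), character(0), simplify = FALSE)
  calls$ref_reads <- replicate(nrow(calls), character(0), simplify = FALSE)
  rownames(calls) <- NULL
  calls
}
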