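## Shared helpers: chromosome ordering, deterministic medians, small utilities.
## All genomic coordinates inside the package are 0-based half-open; conversion
## to 1-based happens only at VCF/GRanges boundaries.

#' Default chromosome order
#'
#' Human-style natural order: autosomes 1..22 (with or without a "chr"
#' prefix), then X, Y, MT/M, then any remaining names lexicographically.
#'
#' @param chroms Character vector of chromosome names to order.
#' @return Character vector of the unique names in canonical order.
#' @export
default_chrom_order <- function(chroms) {
  u <- unique(as.character(chroms))
  core <- sub("^chr", "", u, ignore.case = TRUE)
  num <- suppressWarnings(as.integer(core))
  rank <- ifelse(!is.na(num), num,
    ifelse(toupper(core) == "X", 23L,
      ifelse(toupper(core) == "Y", 24L,
        ifelse(toupper(core) %in% c("M", "MT"), 25L, NA_integer_))))
  known <- u[!is.na(rank)][order(rank[!is.na(rank)])]
  other <- sort(u[is.na(rank)])
  c(known, other)
}

## integer rank of chromosomes under a total order; errors on unknown names
chrom_rank <- function(chroms, chrom_order) {
  r <- match(as.character(chroms), chrom_order)
  if (anyNA(r)) {
    bad <- unique(chroms[is.na(r)])
    stop("chromosome(s) absent from chromosome order: ",
         paste(bad, collapse = ", "))
  }
  r
}

#' Lower-middle median
#'
#' Median that returns the lower-middle element for even-sized inputs, so that
#' medians of integer coordinates stay integral and deterministic.
#'
#' @param x Numeric vector.
#' @return Single element of `x` (the lower-middle order statistic).
#' @export
median_low <- function(x) {
  stopifnot(length(x) >= 1)
  sort(x)[ceiling(length(x) / 2)]
}

## set RNG state locally when a seed is supplied, restore on exit
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

## distance between two closed intervals [a1,a2], [b1,b2]; 0 when overlapping
interval_gap <- function(a1, a2, b1, b2) {
  pmax(0, pmax(a1, b1) - pmin(a2, b2))
}

## validate the canonical aligned-segment data.frame
segment_columns <- c("read_id", "chrom", "ref_start", "ref_end", "strand",
                     "mapq", "read_start", "read_end", "read_length", "pid")

check_segments <- function(segments) {
  missing <- setdiff(segment_columns, names(segments))
  if (length(missing) > 0)
    stop("segment table lacks column(s): ", paste(missing, collapse = ", "))
  stopifnot(all(segments$ref_start < segments$ref_end),
            all(segments$read_start < segments$read_end),
            all(segments$read_end <= segments$read_length),
            all(segments$strand %in% c("+", "-")))
  invisible(segments)
}

empty_segments <- function() {
  data.frame(read_id = character(), chrom = character(),
             ref_start = integer(), ref_end = integer(),
             strand = character(), mapq = integer(),
             read_start = integer(), read_end = integer(),
             read_length = integer(), pid = double(),
             stringsAsFactors = FALSE)
}
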