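# Internal coordinate convention: 0-based, half-open [start, end).
# GFF3 is ingested as 1-based inclusive, VCF POS as 1-based; conversion
# happens only at the I/O edges.

#' Construct a genomic interval
#'
#' Intervals are 0-based and half-open: `start` is the first base included,
#' `end` the first base excluded, so `end - start` is the length.
#'
#' @param chrom Chromosome / contig name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `0 <= start < end`.
#' @return A `genomic_interval` object.
#' @export
genomic_interval <- function(chrom, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
length.genomic_interval <- function(x) x$end - x$start

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:[%d,%d)\n", x$chrom, x$start, x$end))
  invisible(x)
}

# Overlap of two half-open integer ranges.
ranges_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
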