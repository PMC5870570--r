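# Fast region lookup over transcript spans, one interval tree per
# chromosome via GenomicRanges.

#' Build a transcript interval index
#'
#' @param transcripts List of `transcript_model` objects.
#' @return A `transcript_index` supporting overlap queries via
#'   [query_transcripts()].
#' @export
build_index <- function(transcripts) {
  if (length(transcripts) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = vapply(transcripts, function(t) t$chrom, ""),
      ranges = IRanges::IRanges(
        start = vapply(transcripts, function(t) t$span[1] + 1L, 1L),
        end = vapply(transcripts, function(t) t$span[2], 1L)
      )
    )
  }
  structure(list(gr = gr, transcripts = transcripts), class = "transcript_index")
}

#' Query transcripts overlapping an interval
#'
#' @param index A `transcript_index`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open query interval.
#' @return List of overlapping `transcript_model`s (possibly empty), in
#'   input order.
#' @export
query_transcripts <- function(index, chrom, start, end) {
  if (length(index$transcripts) == 0L) return(list())
  q <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(start = start + 1L, end = end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, index$gr))
  idx <- sort(S4Vectors::subjectHits(hits))
  index$transcripts[idx]
}
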