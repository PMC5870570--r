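# Random-access reference sequence. Sequences are held as a DNAStringSet;
# names are truncated at the first whitespace, matching samtools faidx.

#' Load a reference FASTA
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A `reference_fasta` object for use with [fetch_reference()].
#' @export
reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  structure(list(seqs = seqs, path = path), class = "reference_fasta")
}

#' Fetch reference sequence
#'
#' @param ref A `reference_fasta` object.
#' @param chrom Contig name.
#' @param start,end 0-based half-open interval within the contig.
#' @return Uppercase nucleotide string of length `end - start`.
#' @export
fetch_reference <- function(ref, chrom, start, end) {
  if (!chrom %in% names(ref$seqs))
    stop("unknown contig '", chrom, "': not present in FASTA (have: ",
         paste(utils::head(names(ref$seqs), 5), collapse = ", "), ")")
  clen <- length(ref$seqs[[chrom]])
  if (start < 0 || end > clen || start >= end)
    stop("interval [", start, ",", end, ") out of bounds for contig '", chrom,
         "' of length ", clen)
  toupper(as.character(Biostrings::subseq(ref$seqs[[chrom]], start + 1L, end)))
}

contig_length <- function(ref, chrom) {
  if (!chrom %in% names(ref$seqs)) stop("unknown contig '", chrom, "'")
  length(ref$seqs[[chrom]])
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
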