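# Spliced CDS reconstruction and haplotype application. All editing is
# done on the concatenated CDS in genomic orientation; orientation
# (reverse complement for "-" transcripts) and 5' phase trimming are
# applied afterwards, so the same coordinate arithmetic serves both
# strands.

#' Reconstruct the spliced coding sequence of a transcript
#'
#' CDS segments are concatenated in transcript order, the 5'-most segment's
#' phase is trimmed, and "-" strand transcripts are reverse-complemented,
#' so the result reads 5'->3' in transcript orientation and starts at the
#' annotated start codon.
#'
#' @param tx A coding `transcript_model`.
#' @param ref A `reference_fasta`.
#' @return A `spliced_cds` object: `seq` (oriented, phase-trimmed coding
#'   sequence), the genomic-orientation concatenation and the
#'   genomic-to-spliced coordinate map.
#' @export
splice_cds <- function(tx, ref) {
  if (!tx$coding) stop("transcript ", tx$transcript_id, " is non-coding")
  segs <- tx$cds
  pieces <- vapply(seq_len(nrow(segs)), function(i)
    fetch_reference(ref, tx$chrom, segs[i, "start"], segs[i, "end"]), "")
  gseq <- paste(pieces, collapse = "")
  L <- nchar(gseq)
  lens <- segs[, "end"] - segs[, "start"]
  cum <- c(0L, cumsum(lens))[seq_len(nrow(segs))]
  trim <- cds_phase_trim(segs, tx$strand)
  oriented <- if (tx$strand == "+") gseq else revcomp(gseq)
  seq <- substr(oriented, trim + 1L, L)
  if ((L - trim) %% 3L != 0L)
    warning("transcript ", tx$transcript_id, ": CDS length ", L - trim,
            " not divisible by 3 after phase trimming; trailing remainder dropped ",
            "in translation")
  structure(list(
    tx = tx, strand = tx$strand, gseq = gseq, L = L, trim = as.integer(trim),
    seg_start = segs[, "start"], seg_end = segs[, "end"], cum = cum,
    seq = seq
  ), class = "spliced_cds")
}

# genomic position (0-based) -> index in the genomic-orientation
# concatenation, NA outside the CDS
g2c <- function(sp, gpos) {
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_along(sp$seg_start)) {
    inside <- gpos >= sp$seg_start[i] & gpos < sp$seg_end[i]
    out[inside] <- sp$cum[i] + (gpos[inside] - sp$seg_start[i])
  }
  out
}

# concatenation index -> 0-based position in the oriented, phase-trimmed
# coding sequence (negative inside the trimmed phase overhang)
c2s <- function(sp, cidx) {
  o <- if (sp$strand == "+") cidx else sp$L - 1L - cidx
  o - sp$trim
}

# spliced (oriented, trimmed) position of a normalized variant's changed
# bases; list(start, end, in_cds, net). Insertions occupy their anchor base.
variant_spliced_span <- function(sp, v) {
  p0 <- v$pos - 1L
  len <- nchar(v$ref)
  c1 <- g2c(sp, p0)
  c2 <- g2c(sp, p0 + len - 1L)
  in_cds <- !is.na(c1) && !is.na(c2) && (c2 - c1 == len - 1L)
  if (!in_cds) return(list(in_cds = FALSE))
  s <- sort(c(c2s(sp, c1), c2s(sp, c2)))
  list(in_cds = TRUE, start = s[1], end = s[2], net = nchar(v$alt) - len)
}

#' Apply a haplotype's variants to a spliced coding sequence
#'
#' Substitutions, insertions and deletions are applied jointly,
#' right-to-left in splice coordinates, so earlier edits never shift later
#' ones. Variants whose changed bases are not fully contained in the CDS
#' are skipped here (they are classified by region instead). The result
#' length is the original plus the summed length change of the applied
#' variants.
#'
#' @param sp A `spliced_cds`.
#' @param variant_set List of normalized variants `list(pos, ref, alt)`
#'   (1-based genomic `pos`).
#' @return The alternate coding sequence, oriented and phase-trimmed like
#'   `sp$seq`.
#' @export
apply_haplotype <- function(sp, variant_set) {
  if (length(variant_set) == 0L) return(sp$seq)
  edits <- list()
  for (v in variant_set) {
    p0 <- v$pos - 1L
    len <- nchar(v$ref)
    c1 <- g2c(sp, p0)
    c2 <- g2c(sp, p0 + len - 1L)
    if (is.na(c1) || is.na(c2) || (c2 - c1) != len - 1L) next  # not fully in CDS
    have <- substr(sp$gseq, c1 + 1L, c2 + 1L)
    if (have != v$ref)
      stop("reference mismatch at ", sp$tx$chrom, ":", v$pos, ": expected '",
           v$ref, "', spliced sequence has '", have, "'")
    edits[[length(edits) + 1L]] <- list(a = c1, b = c2, alt = v$alt)
  }
  if (length(edits) == 0L) return(sp$seq)
  ord <- order(vapply(edits, function(e) e$a, 0L), decreasing = TRUE)
  g <- sp$gseq
  for (e in edits[ord]) {
    g <- paste0(substr(g, 1L, e$a), e$alt, substr(g, e$b + 2L, nchar(g)))
  }
  oriented <- if (sp$strand == "+") g else revcomp(g)
  substr(oriented, sp$trim + 1L, nchar(oriented))
}

#' Translate a coding nucleotide sequence
#'
#' Standard genetic code; stops are rendered `*` and translation continues
#' past internal stops (premature stops are handled by classification, not
#' here). A trailing partial codon is ignored; codons containing N
#' translate to `X`.
#'
#' @param cds Nucleotide string, length >= 3.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  if (!grepl("^[ACGTNacgtn]*$", cds)) stop("non-ACGTN character in CDS")
  n <- nchar(cds) - nchar(cds) %% 3L
  if (n < 3L) stop("CDS shorter than one codon")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, n)),
    if.fuzzy.codon = "solve", no.init.codon = TRUE
  ))
}
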