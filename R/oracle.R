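# Independent brute-force consequence oracle. Instead of editing the
# spliced CDS, it rebuilds the entire alternate chromosome, shifts the CDS
# segment boundaries past each indel, re-extracts and re-splices the CDS,
# translates both sequences with its own codon table and classifies from a
# minimal ungapped-ends protein diff. It shares no classification,
# splicing or translation code with the consequence engine, so agreement
# between the two is a meaningful end-to-end check.

ORACLE_CODONS <- local({
  b <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  eg <- expand.grid(b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
  names(aa) <- paste0(eg$b1, eg$b2, eg$b3)
  aa
})

oracle_translate <- function(s) {
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) return("")
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- ORACLE_CODONS[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

oracle_read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- which(startsWith(lines, ">"))
  seqs <- lapply(seq_along(hdr), function(i) {
    from <- hdr[i] + 1L
    to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    toupper(paste(lines[from:to], collapse = ""))
  })
  names(seqs) <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
  seqs
}

#' Whole-protein diff consequence oracle
#'
#' Classifies the joint effect of a haplotype variant set on a
#' single-transcript fixture by brute force: the full alternate chromosome
#' string is rebuilt, CDS segment boundaries are shifted past each indel,
#' the alternate CDS is re-extracted, spliced and translated, and terms
#' are derived from the protein-level diff and the net length change.
#'
#' @param fasta_path,gff3_path Fixture files.
#' @param variant_set List of `list(pos, ref, alt)` on one haplotype
#'   (1-based genomic positions).
#' @param transcript_id Transcript to classify against (default: first).
#' @return `list(terms, aa_change)`; empty variant sets give
#'   `list(character(0), "")`.
#' @export
oracle_consequence <- function(fasta_path, gff3_path, variant_set,
                               transcript_id = NULL) {
  if (length(variant_set) == 0L) return(list(terms = character(), aa_change = ""))
  txs <- parse_gff3(gff3_path)
  if (!is.null(transcript_id)) {
    txs <- txs[vapply(txs, function(t) t$transcript_id, "") == transcript_id]
  }
  tx <- txs[[1]]
  chrom_seq <- oracle_read_fasta(fasta_path)[[tx$chrom]]

  vs <- lapply(variant_set, function(v) {
    n <- norm_allele(v$pos, toupper(v$ref), toupper(v$alt))
    n$net <- nchar(n$alt) - nchar(n$ref)
    n
  })
  vs <- vs[order(vapply(vs, function(v) v$pos, 0L))]

  # alternate chromosome, edits applied right-to-left
  alt_chrom <- chrom_seq
  for (v in rev(vs)) {
    stopifnot(substr(alt_chrom, v$pos, v$pos + nchar(v$ref) - 1L) == v$ref)
    alt_chrom <- paste0(substr(alt_chrom, 1L, v$pos - 1L), v$alt,
                        substr(alt_chrom, v$pos + nchar(v$ref), nchar(alt_chrom)))
  }

  # shift a 0-based boundary past every variant whose reference span ends
  # at or before it
  shift <- function(b) {
    b + sum(vapply(vs, function(v)
      if ((v$pos - 1L) + nchar(v$ref) <= b) v$net else 0L, 0L))
  }

  extract_cds <- function(chrom_str, segs) {
    paste(vapply(seq_len(nrow(segs)), function(i)
      substr(chrom_str, segs[i, 1] + 1L, segs[i, 2]), ""), collapse = "")
  }
  ref_segs <- tx$cds[, c("start", "end"), drop = FALSE]
  alt_segs <- cbind(vapply(ref_segs[, 1], shift, 0L),
                    vapply(ref_segs[, 2], shift, 0L))
  trim <- if (tx$strand == "+") tx$cds[1, "phase"] else tx$cds[nrow(tx$cds), "phase"]

  orient <- function(s) {
    o <- if (tx$strand == "+") s else oracle_revcomp(s)
    substr(o, trim + 1L, nchar(o))
  }
  ref_cds <- orient(extract_cds(chrom_seq, ref_segs))
  alt_cds <- orient(extract_cds(alt_chrom, alt_segs))

  p_ref <- oracle_translate(ref_cds)
  p_alt <- oracle_translate(alt_cds)
  net <- sum(vapply(vs, function(v) {
    # only count length change of variants inside the CDS
    inside <- any(v$pos - 1L >= ref_segs[, 1] &
                  (v$pos - 1L + nchar(v$ref)) <= ref_segs[, 2])
    if (inside) v$net else 0L
  }, 0L))

  cut_stop <- function(p) {
    i <- regexpr("*", p, fixed = TRUE)
    if (i > 0) substr(p, 1L, i) else p
  }
  stop_at <- function(p) {
    i <- regexpr("*", p, fixed = TRUE)
    if (i > 0) as.numeric(i) else Inf
  }
  # frameshifts are diffed on stop-truncated proteins, in-frame changes on
  # the full readthrough translations
  if (net %% 3L != 0L) {
    pr <- cut_stop(p_ref)
    pa <- cut_stop(p_alt)
  } else {
    pr <- p_ref
    pa <- p_alt
  }

  rr <- strsplit(pr, "", fixed = TRUE)[[1]]
  aa <- strsplit(pa, "", fixed = TRUE)[[1]]
  nmin <- min(length(rr), length(aa))
  pre <- 0L
  while (pre < nmin && rr[pre + 1L] == aa[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < nmin - pre && rr[length(rr) - suf] == aa[length(aa) - suf])
    suf <- suf + 1L
  ref_run <- paste(rr[setdiff(seq_len(length(rr) - suf), seq_len(pre))], collapse = "")
  alt_run <- paste(aa[setdiff(seq_len(length(aa) - suf), seq_len(pre))], collapse = "")

  # oracle spliced positions of changed bases, for stop-codon touch checks
  g2sp <- function(g0) {  # 0-based genomic -> 0-based trimmed spliced, or NA
    off <- 0L
    hit <- NA_integer_
    for (i in seq_len(nrow(ref_segs))) {
      if (g0 >= ref_segs[i, 1] && g0 < ref_segs[i, 2])
        hit <- off + (g0 - ref_segs[i, 1])
      off <- off + ref_segs[i, 2] - ref_segs[i, 1]
    }
    if (is.na(hit)) return(NA_integer_)
    o <- if (tx$strand == "+") hit else off - 1L - hit
    o - trim
  }
  ref_stop <- stop_at(p_ref)
  touches_stop <- is.finite(ref_stop) && any(vapply(vs, function(v) {
    sp <- c(g2sp(v$pos - 1L), g2sp(v$pos - 1L + nchar(v$ref) - 1L))
    any(!is.na(sp) & sp %/% 3L >= ref_stop - 1)
  }, TRUE))

  terms <- if (net %% 3L != 0L) {
    "frameshift"
  } else if (ref_run == "" && alt_run == "") {
    if (touches_stop) "stop_retained" else "synonymous"
  } else {
    t <- character()
    new_stop <- stop_at(p_alt) < ref_stop + net / 3
    lost_stop <- is.finite(ref_stop) && stop_at(p_alt) > ref_stop + net / 3
    if (new_stop) t <- c(t, "stop_gained")
    if (lost_stop) t <- c(t, "stop_lost")
    if (pre == 0L) t <- c(t, "start_lost")
    if (net > 0L) {
      t <- c(t, "inframe_insertion")
      if (ref_run != "" && !new_stop && !lost_stop) t <- c(t, "missense")
    } else if (net < 0L) {
      t <- c(t, "inframe_deletion")
      if (alt_run != "" && !new_stop && !lost_stop) t <- c(t, "missense")
    } else if (length(t) == 0L) {
      altered <- sum(strsplit(ref_run, "")[[1]] != strsplit(alt_run, "")[[1]])
      t <- if (length(vs) > 1L && altered > 1L) "inframe_altering" else "missense"
    }
    if (length(t) == 0L) t <- "coding_sequence"
    t
  }
  aa_change <- if (ref_run == "" && alt_run == "") "" else
    paste0(pre + 1L, ref_run, ">", pre + 1L, alt_run)
  list(terms = order_terms(terms), aa_change = aa_change)
}
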