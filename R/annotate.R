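# End-to-end annotation: stream the VCF against the transcript index,
# classify per haplotype (or per record in localized mode), and write the
# per-site consequence list plus per-sample interleaved bitmasks.

#' Annotate a phased VCF with haplotype-aware consequences
#'
#' Streams through the sorted VCF, maintaining the set of transcripts
#' overlapping the current position; when the stream passes a transcript's
#' end, its accumulated records are classified. In `haplotype` mode a
#' haplotype tree over all samples' phased genotypes is built per
#' transcript and each unique haplotype is classified jointly; in
#' `localized` mode every record is classified in isolation, the way
#' single-record annotators operate.
#'
#' All unique consequences of a site are written to the INFO tag
#' (comma-separated, pipe-delimited fields); each sample's FORMAT tag holds
#' an integer bitmask with bit `2*i + h` set when consequence `i` applies
#' to haplotype `h`. A compound consequence spanning several sites is
#' reported in full at its anchor (leftmost member) site; the other member
#' sites carry `@<anchor_pos>`.
#'
#' @param vcf_path,gff3_path,fasta_path Input files.
#' @param out_path Output VCF path.
#' @param mode "haplotype" (joint, phase-aware) or "localized".
#' @param strictness Unphased-heterozygote policy, see [read_phased_vcf()].
#' @param tag INFO/FORMAT tag name.
#' @param splice_exon,splice_intron Splice-region window sizes.
#' @return Invisibly, a list with counts: records read, records annotated,
#'   compound consequences emitted.
#' @export
annotate_vcf <- function(vcf_path, gff3_path, fasta_path, out_path,
                         mode = c("haplotype", "localized"),
                         strictness = c("require", "skip", "take"),
                         tag = "BCSQ", splice_exon = 3L, splice_intron = 8L) {
  mode <- match.arg(mode)
  strictness <- match.arg(strictness)
  if (mode == "localized") strictness <- "take"  # phase is irrelevant per record
  transcripts <- parse_gff3(gff3_path)
  index <- build_index(transcripts)
  ref <- reference_fasta(fasta_path)
  vcf <- read_phased_vcf(vcf_path, strictness)
  n_samples <- length(vcf$samples)
  if (mode == "haplotype" && n_samples == 0L) {
    warning("no samples in VCF; haplotype mode reduces to localized calling")
    mode <- "localized"
  }

  n_rec <- length(vcf$records)
  site_entries <- vector("list", n_rec)  # per record: list of (str, membership)
  n_compound <- 0L

  add_entry <- function(rec_idx, str, membership) {
    e <- site_entries[[rec_idx]]
    site_entries[[rec_idx]] <<- c(e, list(list(str = str, membership = membership)))
  }

  emit_consequence <- function(cons, membership) {
    anchor_idx <- cons$members[[which.min(
      vapply(cons$members, function(m) m$orig_pos, 0L))]]$record_index
    add_entry(anchor_idx, csq_string(cons), membership)
    if (length(cons$members) > 1L) {
      n_compound <<- n_compound + 1L
      for (m in cons$members) {
        if (m$record_index != anchor_idx)
          add_entry(m$record_index, paste0("@", cons$anchor_pos), membership)
      }
    }
  }

  spliced_cache <- new.env(parent = emptyenv())
  get_spliced <- function(tx) {
    if (!tx$coding) return(NULL)
    key <- tx$transcript_id
    if (is.null(spliced_cache[[key]])) spliced_cache[[key]] <- splice_cds(tx, ref)
    spliced_cache[[key]]
  }

  process_transcript <- function(entry) {
    usable <- !vapply(entry$records, function(r) r$symbolic, TRUE)
    records <- entry$records[usable]
    gts <- entry$gts[usable]
    if (length(records) == 0L) return(invisible())
    tree <- build_haplotype_tree(records, gts, n_samples)
    sp <- get_spliced(entry$tx)
    for (leaf in tree$leaves) {
      vs <- lapply(seq_len(nrow(leaf$variants)), function(i)
        make_engine_variant(records[[leaf$variants[i, "record"]]],
                            leaf$variants[i, "allele"]))
      for (cons in classify_haplotype(entry$tx, sp, vs, splice_exon, splice_intron))
        emit_consequence(cons, leaf$membership)
    }
  }

  if (mode == "haplotype") {
    buffer <- new_transcript_buffer()
    for (i in seq_len(n_rec)) {
      r <- vcf$records[[i]]
      if (r$symbolic) {
        warning("symbolic/non-sequence alt at ", r$chrom, ":", r$pos,
                "; record passed through unannotated")
      }
      for (fl in accumulate(buffer, r, vcf$gt[[i]], index)) process_transcript(fl)
    }
    for (fl in flush_buffer(buffer)) process_transcript(fl)
  } else {
    for (i in seq_len(n_rec)) {
      r <- vcf$records[[i]]
      if (r$symbolic) {
        warning("symbolic/non-sequence alt at ", r$chrom, ":", r$pos,
                "; record passed through unannotated")
        next
      }
      txs <- query_transcripts(index, r$chrom, r$pos - 1L,
                               r$pos - 1L + nchar(r$ref))
      if (length(txs) == 0L) next
      g <- vcf$gt[[i]]
      for (allele in seq_along(r$alts)) {
        conss <- localized_call(r, allele, txs, ref, splice_exon, splice_intron)
        membership <- which(g$alleles == allele, arr.ind = TRUE)
        membership <- cbind(sample = membership[, 1],
                            hap = membership[, 2] - 1L)
        for (cons in conss) add_entry(i, csq_string(cons), membership)
      }
    }
  }

  annotations <- lapply(seq_len(n_rec), function(i) {
    entries <- site_entries[[i]]
    if (is.null(entries)) return(NULL)
    strs <- vapply(entries, function(e) e$str, "")
    uniq <- unique(strs)
    masks <- numeric(n_samples)
    if (n_samples > 0L) {
      assign_rows <- do.call(rbind, lapply(seq_along(entries), function(k) {
        m <- entries[[k]]$membership
        if (is.null(m) || nrow(m) == 0L) return(NULL)
        cbind(sample = m[, "sample"], cons = match(strs[k], uniq) - 1L,
              hap = m[, "hap"])
      }))
      if (!is.null(assign_rows)) {
        for (s in unique(assign_rows[, "sample"])) {
          rows <- assign_rows[assign_rows[, "sample"] == s, , drop = FALSE]
          masks[s] <- encode_mask(rows[, c("cons", "hap"), drop = FALSE])
        }
      }
    }
    list(consequences = uniq, sample_masks = masks)
  })

  write_annotated_vcf(vcf, annotations, out_path, tag)
  invisible(list(
    n_records = n_rec,
    n_annotated = sum(!vapply(annotations, is.null, TRUE)),
    n_compound = n_compound,
    out = out_path
  ))
}

#' Decode per-sample consequence bitmasks to a table
#'
#' Translates the FORMAT tag of an annotated VCF back into one row per
#' (site, haplotype, consequence) for one sample — the human-readable view
#' of the interleaved bitmask encoding. Sites where the sample's mask is 0
#' produce no rows.
#'
#' @param vcf_path An annotated VCF (output of [annotate_vcf()]).
#' @param sample Sample name.
#' @param tag Tag name used at annotation time.
#' @return A data.frame with columns chrom, pos, hap, consequence.
#' @export
decode_annotations <- function(vcf_path, sample, tag = "BCSQ") {
  vcf <- read_phased_vcf(vcf_path, strictness = "take")
  s <- match(sample, vcf$samples)
  if (is.na(s))
    stop("unknown sample '", sample, "'; available: ",
         paste(vcf$samples, collapse = ", "))
  out <- list()
  info_re <- paste0("(^|;)", tag, "=([^;]*)")
  for (r in vcf$records) {
    f <- strsplit(r$line, "\t", fixed = TRUE)[[1]]
    m <- regmatches(f[8], regexec(info_re, f[8]))[[1]]
    if (length(m) < 3L) next
    conss <- strsplit(m[3], ",", fixed = TRUE)[[1]]
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    ti <- match(tag, fmt)
    if (is.na(ti)) next
    val <- strsplit(f[9L + s], ":", fixed = TRUE)[[1]][ti]
    mask <- suppressWarnings(as.numeric(val))
    if (is.na(mask) || mask == 0) next
    dec <- decode_mask(mask)
    for (k in seq_len(nrow(dec))) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = r$chrom, pos = r$pos, hap = dec[k, "hap"],
        consequence = conss[dec[k, "cons"] + 1L], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), pos = integer(), hap = integer(),
                      consequence = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
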