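# Joint consequence classification. Variants carried on one haplotype are
# partitioned into compound groups (same codon in the spliced frame, or
# chained frame-disturbing indels), each group is applied jointly and the
# reference and alternate proteins are diffed. Consequence terms follow
# Sequence Ontology naming; the severity order is explicit and test-pinned.

#' Consequence terms in ascending severity order
#'
#' The position of a term in this vector is its severity rank (0-based);
#' the most severe term of a consequence's term set defines its severity.
#' @export
CONSEQUENCE_TERMS <- c(
  "intergenic", "intron", "non_coding", "3_prime_utr", "5_prime_utr",
  "coding_sequence", "synonymous", "stop_retained", "missense",
  "splice_region", "inframe_deletion", "inframe_insertion",
  "inframe_altering", "splice_acceptor", "splice_donor", "start_lost",
  "stop_lost", "stop_gained", "frameshift"
)

#' Severity rank of a consequence term
#'
#' @param term A term from [CONSEQUENCE_TERMS].
#' @return Integer rank 0..18, ascending with severity.
#' @export
severity_rank <- function(term) {
  r <- match(term, CONSEQUENCE_TERMS) - 1L
  if (anyNA(r)) stop("unknown consequence term: ", term[is.na(r)][1])
  r
}

order_terms <- function(terms) {
  terms <- unique(terms)
  terms[order(severity_rank(terms), decreasing = TRUE)]
}

# minimal ungapped-ends diff: longest common prefix, then longest common
# suffix of the remainders
protein_diff <- function(pr, pa) {
  r <- strsplit(pr, "", fixed = TRUE)[[1]]
  a <- strsplit(pa, "", fixed = TRUE)[[1]]
  nmin <- min(length(r), length(a))
  pre <- 0L
  while (pre < nmin && r[pre + 1L] == a[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < nmin - pre &&
         r[length(r) - suf] == a[length(a) - suf]) suf <- suf + 1L
  list(pre = pre,
       ref_run = paste(r[seq_len(length(r) - suf)][-seq_len(pre)], collapse = ""),
       alt_run = paste(a[seq_len(length(a) - suf)][-seq_len(pre)], collapse = ""))
}

truncate_at_stop <- function(p) {
  i <- regexpr("*", p, fixed = TRUE)
  if (i > 0) substr(p, 1L, i) else p
}

first_stop_pos <- function(p) {
  i <- regexpr("*", p, fixed = TRUE)
  if (i > 0) as.numeric(i) else Inf
}

format_aa_change <- function(d) {
  if (d$ref_run == "" && d$alt_run == "") return("")
  paste0(d$pre + 1L, d$ref_run, ">", d$pre + 1L, d$alt_run)
}

# Terms for one compound group from the protein-level diff. In-frame
# changes are diffed on the full translations (readthrough past internal
# stops), so the reported window is the minimal changed run; stop gain and
# loss are detected by comparing the first stop position of the alternate
# protein against where the reference stop lands after the net length
# change. Frameshifts are diffed on stop-truncated proteins, so the
# reported run stops at the first novel stop.
classify_group_terms <- function(p_ref, p_alt, net, n_members, touches_stop) {
  if (net %% 3L != 0L) {
    d <- protein_diff(truncate_at_stop(p_ref), truncate_at_stop(p_alt))
    return(list(terms = "frameshift", diff = d))
  }
  d <- protein_diff(p_ref, p_alt)
  if (d$ref_run == "" && d$alt_run == "") {
    term <- if (touches_stop &&
                substr(p_ref, first_stop_pos(p_ref), first_stop_pos(p_ref)) == "*")
      "stop_retained" else "synonymous"
    return(list(terms = term, diff = d))
  }
  rstop <- first_stop_pos(p_ref)
  astop <- first_stop_pos(p_alt)
  new_stop <- astop < rstop + net / 3
  lost_stop <- is.finite(rstop) && astop > rstop + net / 3
  terms <- character()
  if (new_stop) terms <- c(terms, "stop_gained")
  if (lost_stop) terms <- c(terms, "stop_lost")
  if (d$pre == 0L) terms <- c(terms, "start_lost")
  if (net > 0L) {
    terms <- c(terms, "inframe_insertion")
    if (d$ref_run != "" && !new_stop && !lost_stop) terms <- c(terms, "missense")
  } else if (net < 0L) {
    terms <- c(terms, "inframe_deletion")
    if (d$alt_run != "" && !new_stop && !lost_stop) terms <- c(terms, "missense")
  } else if (length(terms) == 0L) {
    n_altered <- sum(strsplit(d$ref_run, "")[[1]] != strsplit(d$alt_run, "")[[1]])
    terms <- if (n_members > 1L && n_altered > 1L) "inframe_altering" else "missense"
  }
  if (length(terms) == 0L) terms <- "coding_sequence"
  list(terms = terms, diff = d)
}

#' Partition a haplotype's CDS variants into compound groups
#'
#' Two variants join a group when they touch the same codon in the spliced
#' frame (which captures codons split across introns), or when both are
#' frame-disturbing indels connected by an uninterrupted chain of
#' frame-disturbed sequence (the cumulative frameshift between them is
#' nonzero). Any variant lying inside such a chain joins it. Grouping is
#' transitive; everything else is a singleton group.
#'
#' @param variant_set List of normalized variants, CDS-contained.
#' @param sp The transcript's `spliced_cds`.
#' @return List of integer vectors indexing `variant_set`.
#' @export
group_compound <- function(variant_set, sp) {
  n <- length(variant_set)
  if (n == 0L) return(list())
  spans <- lapply(variant_set, function(v) variant_spliced_span(sp, v))
  starts <- vapply(spans, function(s) s$start, 0L)
  ends <- vapply(spans, function(s) s$end, 0L)
  nets <- vapply(spans, function(s) s$net, 0L)
  ord <- order(starts)

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }

  codon_lo <- pmax(starts, 0L) %/% 3L
  codon_hi <- pmax(ends, 0L) %/% 3L
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (codon_lo[i] <= codon_hi[j] && codon_lo[j] <= codon_hi[i]) union_(i, j)
  }

  # chain frame-disturbing indels while the cumulative frame is disturbed
  fs <- ord[nets[ord] %% 3L != 0L]
  if (length(fs) > 1L) {
    cum <- 0L
    for (k in seq_len(length(fs) - 1L)) {
      cum <- (cum + nets[fs[k]]) %% 3L
      if (cum != 0L) {
        union_(fs[k], fs[k + 1L])
        # variants located inside the frame-disturbed stretch join the chain
        lo <- ends[fs[k]]; hi <- starts[fs[k + 1L]]
        inside <- which(starts > lo & ends < hi)
        for (m in inside) union_(fs[k], m)
      } else cum <- 0L
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  groups <- split(seq_len(n), roots)
  groups <- lapply(groups, function(g) g[order(starts[g])])
  unname(groups[order(vapply(groups, function(g) min(starts[g]), 0L))])
}

# --- regional (non-CDS) classification -------------------------------------

# strand-aware splice windows: donor = first 2 intronic bases, acceptor =
# last 2; splice_region = intronic bases 3-8 and exonic bases 1-3 from a
# junction (exon/intron window sizes are configurable)
region_terms_for_span <- function(tx, s, e, splice_exon = 3L, splice_intron = 8L) {
  terms <- character()
  ex <- tx$exons
  within_exon <- any(ranges_overlap(s, e, ex[, "start"], ex[, "end"]))
  if (nrow(tx$cds) && any(ranges_overlap(s, e, tx$cds[, "start"], tx$cds[, "end"])))
    terms <- c(terms, "coding_sequence")
  if (nrow(tx$utr5) && any(ranges_overlap(s, e, tx$utr5[, "start"], tx$utr5[, "end"])))
    terms <- c(terms, "5_prime_utr")
  if (nrow(tx$utr3) && any(ranges_overlap(s, e, tx$utr3[, "start"], tx$utr3[, "end"])))
    terms <- c(terms, "3_prime_utr")
  if (!tx$coding && within_exon) terms <- c(terms, "non_coding")
  if (nrow(ex) > 1L) {
    for (i in seq_len(nrow(ex) - 1L)) {
      is_ <- ex[i, "end"]; ie <- ex[i + 1L, "start"]  # intron [is_, ie)
      if (ranges_overlap(s, e, is_, ie)) terms <- c(terms, "intron")
      left2 <- ranges_overlap(s, e, is_, min(is_ + 2L, ie))
      right2 <- ranges_overlap(s, e, max(ie - 2L, is_), ie)
      if (tx$strand == "+") {
        if (left2) terms <- c(terms, "splice_donor")
        if (right2) terms <- c(terms, "splice_acceptor")
      } else {
        if (left2) terms <- c(terms, "splice_acceptor")
        if (right2) terms <- c(terms, "splice_donor")
      }
      if (ranges_overlap(s, e, min(is_ + 2L, ie), min(is_ + splice_intron, ie)) ||
          ranges_overlap(s, e, max(ie - splice_intron, is_), max(ie - 2L, is_)))
        terms <- c(terms, "splice_region")
      # exonic side of the junction
      if (ranges_overlap(s, e, max(is_ - splice_exon, ex[i, "start"]), is_) ||
          ranges_overlap(s, e, ie, min(ie + splice_exon, ex[i + 1L, "end"])))
        terms <- c(terms, "splice_region")
    }
  }
  unique(terms)
}

# single most severe region term for a variant not classified at codon level
classify_regional <- function(tx, v, splice_exon = 3L, splice_intron = 8L) {
  s <- v$pos - 1L
  e <- s + nchar(v$ref)
  terms <- region_terms_for_span(tx, s, e, splice_exon, splice_intron)
  if (length(terms) == 0L)
    terms <- if (tx$coding) "coding_sequence" else "non_coding"
  terms[which.max(severity_rank(terms))]
}

# does a CDS-contained variant sit within `splice_exon` bases of an
# internal splice junction?
near_junction <- function(tx, v, splice_exon = 3L) {
  ex <- tx$exons
  if (nrow(ex) < 2L) return(FALSE)
  s <- v$pos - 1L
  e <- s + nchar(v$ref)
  for (i in seq_len(nrow(ex) - 1L)) {
    is_ <- ex[i, "end"]; ie <- ex[i + 1L, "start"]
    if (ranges_overlap(s, e, max(is_ - splice_exon, ex[i, "start"]), is_) ||
        ranges_overlap(s, e, ie, min(ie + splice_exon, ex[i + 1L, "end"])))
      return(TRUE)
  }
  FALSE
}

# --- haplotype classification ----------------------------------------------

new_consequence <- function(terms, tx, aa_change, dna_change, members) {
  structure(list(
    terms = order_terms(terms),
    gene_name = tx$gene_name, transcript_id = tx$transcript_id,
    biotype = tx$biotype, strand = tx$strand,
    aa_change = aa_change, dna_change = dna_change,
    members = members,
    anchor_pos = min(vapply(members, function(m) m$orig_pos, 0L))
  ), class = "consequence")
}

#' @export
print.consequence <- function(x, ...) {
  cat(csq_string(x), "\n")
  invisible(x)
}

#' Serialize a consequence to its VCF INFO representation
#'
#' Fields, pipe-delimited: `term&term2|gene|transcript|biotype|strand|`
#' `aa_change|dna_change`.
#'
#' @param cons A `consequence` object.
#' @return A single string.
#' @export
csq_string <- function(cons) {
  paste(paste(cons$terms, collapse = "&"), cons$gene_name, cons$transcript_id,
        cons$biotype, cons$strand, cons$aa_change, cons$dna_change, sep = "|")
}

dna_change_string <- function(members) {
  paste(vapply(members, function(m) paste0(m$pos, m$ref, ">", m$alt), ""),
        collapse = "+")
}

# engine variant unit: list(pos, ref, alt [normalized], orig_pos,
# record_index, allele)
make_engine_variant <- function(record, allele) {
  nv <- if (!is.null(record$norm)) record$norm[[allele]]
        else norm_allele(record$pos, record$ref, record$alts[allele])
  list(pos = nv$pos, ref = nv$ref, alt = nv$alt,
       orig_pos = record$pos, record_index = record$record_index,
       allele = allele)
}

# first-wins resolution of variants overlapping on one haplotype
resolve_overlaps <- function(variant_set) {
  if (length(variant_set) < 2L) return(variant_set)
  ord <- order(vapply(variant_set, function(v) v$pos, 0L))
  kept <- list()
  last_end <- -1L
  for (v in variant_set[ord]) {
    s <- v$pos - 1L
    if (s < last_end) {
      warning("overlap_conflict: variant at ", v$pos,
              " overlaps an earlier variant on the same haplotype; dropped")
      next
    }
    kept[[length(kept) + 1L]] <- v
    last_end <- s + nchar(v$ref)
  }
  kept
}

#' Classify the joint consequence of one haplotype in one transcript
#'
#' Variants are split into CDS-contained and regional sets; CDS variants
#' are partitioned into compound groups ([group_compound()]), each group is
#' applied jointly to the spliced CDS and classified by diffing the
#' reference and alternate proteins. Regional variants are classified by
#' their most severe overlapping region. A group with more than one member
#' yields a compound consequence anchored at its smallest member position.
#'
#' @param tx A `transcript_model`.
#' @param sp The transcript's `spliced_cds` (NULL for non-coding).
#' @param variant_set List of engine variants (normalized), one haplotype.
#' @param splice_exon,splice_intron Splice-region window sizes (exonic /
#'   intronic bases from the junction).
#' @return List of `consequence` objects.
#' @export
classify_haplotype <- function(tx, sp, variant_set,
                               splice_exon = 3L, splice_intron = 8L) {
  variant_set <- resolve_overlaps(variant_set)
  out <- list()
  if (!tx$coding || is.null(sp)) {
    for (v in variant_set) {
      term <- classify_regional(tx, v, splice_exon, splice_intron)
      out[[length(out) + 1L]] <- new_consequence(term, tx, "",
                                                 dna_change_string(list(v)), list(v))
    }
    return(out)
  }
  in_cds <- vapply(variant_set, function(v) variant_spliced_span(sp, v)$in_cds, TRUE)
  straddle <- vapply(variant_set, function(v) {
    s <- v$pos - 1L; e <- s + nchar(v$ref)
    !variant_spliced_span(sp, v)$in_cds &&
      any(ranges_overlap(s, e, tx$cds[, "start"], tx$cds[, "end"]))
  }, TRUE)
  for (v in variant_set[!in_cds]) {
    term <- classify_regional(tx, v, splice_exon, splice_intron)
    out[[length(out) + 1L]] <- new_consequence(term, tx, "",
                                               dna_change_string(list(v)), list(v))
  }
  if (any(straddle))
    warning("variant(s) straddling a CDS boundary in ", tx$transcript_id,
            " classified by region and excluded from compound grouping")

  cds_vars <- variant_set[in_cds]
  if (length(cds_vars) == 0L) return(out)
  groups <- group_compound(cds_vars, sp)
  p_ref <- translate_cds(sp$seq)
  n_codons <- nchar(truncate_at_stop(p_ref))
  for (g in groups) {
    members <- cds_vars[g]
    alt_seq <- apply_haplotype(sp, members)
    p_alt <- translate_cds(alt_seq)
    net <- sum(vapply(members, function(v) nchar(v$alt) - nchar(v$ref), 0L))
    touches_stop <- any(vapply(members, function(v) {
      s <- variant_spliced_span(sp, v)
      s$end %/% 3L >= n_codons - 1L
    }, TRUE))
    cls <- classify_group_terms(p_ref, p_alt, net, length(members), touches_stop)
    terms <- cls$terms
    if (any(vapply(members, function(v) near_junction(tx, v, splice_exon), TRUE)))
      terms <- c(terms, "splice_region")
    out[[length(out) + 1L]] <- new_consequence(
      terms, tx, format_aa_change(cls$diff), dna_change_string(members), members)
  }
  out
}

#' Localized (single-record) consequence calling
#'
#' Classifies one alt allele of one record in isolation, exactly as
#' [classify_haplotype()] would with a singleton variant set. This is the
#' mode in which conventional single-record annotators operate and serves
#' as the comparison baseline for haplotype-aware calls.
#'
#' @param record A variant record.
#' @param allele Alt allele index (1-based).
#' @param transcripts List of `transcript_model`s to classify against.
#' @param ref A `reference_fasta`.
#' @param splice_exon,splice_intron Splice-region window sizes.
#' @return List of `consequence` objects (one or more per overlapping
#'   transcript).
#' @export
localized_call <- function(record, allele, transcripts, ref,
                           splice_exon = 3L, splice_intron = 8L) {
  v <- make_engine_variant(record, allele)
  out <- list()
  for (tx in transcripts) {
    s <- v$pos - 1L
    if (tx$chrom != record$chrom ||
        !ranges_overlap(s, s + nchar(v$ref), tx$span[1], tx$span[2])) next
    sp <- if (tx$coding) splice_cds(tx, ref) else NULL
    out <- c(out, classify_haplotype(tx, sp, list(v), splice_exon, splice_intron))
  }
  out
}
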