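# minimal coding transcript model on an explicit sequence
mini_tx <- function(cds, strand = "+", chrom = "chrT") {
  exons <- cds[, c("start", "end"), drop = FALSE]
  structure(list(transcript_id = "tx1", gene_id = "g1", gene_name = "G1",
                 biotype = "protein_coding", strand = strand, chrom = chrom,
                 span = c(min(exons[, "start"]), max(exons[, "end"])),
                 exons = exons, cds = cds,
                 utr5 = matrix(integer(), ncol = 2),
                 utr3 = matrix(integer(), ncol = 2), coding = TRUE),
            class = "transcript_model")
}

ref_from_seq <- function(seq) {
  reference_fasta(write_tmp(c(">chrT", seq), ".fa"))
}

test_that("splicing concatenates CDS segments and honors strand", {
  ref <- ref_from_seq("AAATGGTTCTAGCCC")
  sp <- splice_cds(mini_tx(cbind(start = 2L, end = 11L, phase = 0L)), ref)
  expect_identical(sp$seq, "ATGGTTCTA")

  # two segments on "-": reverse complement of the genomic concatenation
  ref2 <- ref_from_seq("GGATCCACGGTGCATA")
  cds <- cbind(start = c(2L, 10L), end = c(8L, 16L), phase = c(0L, 0L))
  sp2 <- splice_cds(mini_tx(cds, strand = "-"), ref2)
  # genomic pieces: ATCCAC + TGCATA -> revcomp("ATCCACTGCATA") = "TATGCAGTGGAT"
  expect_identical(sp2$seq, "TATGCAGTGGAT")
})

test_that("a codon split across an intron maps to consecutive spliced positions", {
  cds <- cbind(start = c(0L, 10L), end = c(5L, 14L), phase = c(0L, 1L))
  tx <- mini_tx(cds)
  ref <- ref_from_seq("ATGCANNNNNTGAAA")
  sp <- splice_cds(tx, ref)
  # genomic bases 3,4 (exon 1) and 10 (exon 2) form codon 1 (spliced 3,4,5)
  g <- c(3L, 4L, 10L)
  spliced <- hapcsq:::c2s(sp, hapcsq:::g2c(sp, g))
  expect_equal(spliced, c(3L, 4L, 5L))
  expect_equal(unique(spliced %/% 3L), 1L)
})

test_that("translation follows the standard code with readthrough", {
  expect_identical(translate_cds("ATG"), "M")
  expect_identical(translate_cds("ATGTAA"), "M*")
  expect_identical(translate_cds("ATGTAACGA"), "M*R")
  expect_identical(translate_cds("ATGNNNTAA"), "MX*")
  expect_error(translate_cds("ATQ"), "non-ACGTN")
  set.seed(9)
  for (i in 1:37) {
    s <- paste(sample(c("A", "C", "G", "T"), 81, replace = TRUE), collapse = "")
    expect_identical(translate_cds(s), hapcsq:::oracle_translate(s))
  }
})

test_that("joint application merges same-codon substitutions and preserves length", {
  ref <- ref_from_seq("AATGCACTAAGGG")
  sp <- splice_cds(mini_tx(cbind(start = 1L, end = 10L, phase = 0L)), ref)
  expect_identical(apply_haplotype(sp, list()), sp$seq)
  # CAC codon -> TAG via two in-phase SNVs (1-based positions 5 and 7)
  alt <- apply_haplotype(sp, list(list(pos = 5L, ref = "C", alt = "T"),
                                  list(pos = 7L, ref = "C", alt = "G")))
  expect_identical(substr(alt, 4, 6), "TAG")
  # insertion + deletion, net zero
  alt2 <- apply_haplotype(sp, list(list(pos = 3L, ref = "T", alt = "TA"),
                                   list(pos = 6L, ref = "AC", alt = "A")))
  expect_equal(nchar(alt2), nchar(sp$seq))
  expect_error(apply_haplotype(sp, list(list(pos = 4L, ref = "T", alt = "C"))),
               "reference mismatch")
})

test_that("severity ranks form the pinned total order", {
  expect_equal(sort(severity_rank(CONSEQUENCE_TERMS)), 0:18)
  expect_gt(severity_rank("frameshift"), severity_rank("inframe_altering"))
  expect_gt(severity_rank("missense"), severity_rank("synonymous"))
  expect_gt(severity_rank("stop_gained"), severity_rank("missense"))
})

test_that("same-codon and frame-chain rules drive compound grouping", {
  codons <- paste(c("ATG", rep("GCT", 28), "TAA"), collapse = "")
  ref <- ref_from_seq(paste0(codons, "GGGGG"))
  sp <- splice_cds(mini_tx(cbind(start = 0L, end = 90L, phase = 0L)), ref)

  # spliced positions 10 and 11 share codon 4 (1-based genomic 11 and 12)
  same_codon <- list(list(pos = 11L, ref = "C", alt = "A"),
                     list(pos = 12L, ref = "T", alt = "C"))
  expect_length(group_compound(same_codon, sp), 1L)

  # nearby but different codons, no indel: separate groups
  apart <- list(list(pos = 11L, ref = "C", alt = "A"),
                list(pos = 16L, ref = "G", alt = "A"))
  expect_length(group_compound(apart, sp), 2L)

  # frameshifting insertion at 31, restoring deletion at 43, SNV between:
  # all one group via the frame-disturbed chain
  chain <- list(list(pos = 31L, ref = "G", alt = "GT"),
                list(pos = 37L, ref = "G", alt = "A"),
                list(pos = 43L, ref = "GC", alt = "G"))
  groups <- group_compound(chain, sp)
  expect_length(groups, 1L)
  expect_length(groups[[1]], 3L)

  # frame fully restored between two indels: the chain breaks
  restored <- list(list(pos = 31L, ref = "G", alt = "GT"),
                   list(pos = 37L, ref = "GC", alt = "G"),
                   list(pos = 55L, ref = "G", alt = "GA"))
  groups2 <- group_compound(restored, sp)
  expect_length(groups2, 2L)
})

test_that("intron-separated SNVs in one spliced codon form a compound call", {
  fx <- make_fixture("fig1c", tempfile(), seed = 5)
  txs <- parse_gff3(fx$paths$gff3)
  ref <- reference_fasta(fx$paths$fasta)
  sp <- splice_cds(txs[[1]], ref)
  vs <- lapply(fx$variants, function(v) c(v, orig_pos = v$pos, record_index = 1L))
  groups <- group_compound(fx$variants, sp)
  expect_length(groups, 1L)
  cons <- classify_haplotype(txs[[1]], sp, vs)
  expect_length(cons, 1L)
  expect_length(cons[[1]]$members, 2L)
  # the exon-edge SNV also earns a splice_region co-term; the protein-level
  # call must match the oracle
  expect_identical(setdiff(cons[[1]]$terms, "splice_region"),
                   fx$expect$joint$terms)
})

test_that("localized equals haplotype-aware on singleton haplotypes", {
  set.seed(71)
  checked <- 0L
  seed <- 0L
  while (checked < 200L) {
    seed <- seed + 1L
    fx <- make_fixture("random", tempfile(), seed = 1000L + seed)
    txs <- parse_gff3(fx$paths$gff3)
    ref <- reference_fasta(fx$paths$fasta)
    for (v in fx$variants) {
      rec <- list(chrom = "chrT", pos = v$pos, ref = v$ref, alts = v$alt,
                  record_index = 1L)
      loc <- localized_call(rec, 1L, txs, ref)
      hap <- list()
      for (tx in txs) {
        s <- v$pos - 1L
        if (!(s < tx$span[2] && tx$span[1] < s + nchar(v$ref))) next
        sp <- if (tx$coding) splice_cds(tx, ref) else NULL
        hap <- c(hap, classify_haplotype(tx, sp,
                                         list(hapcsq:::make_engine_variant(rec, 1L))))
      }
      expect_identical(lapply(loc, csq_string), lapply(hap, csq_string))
      checked <- checked + length(loc)
    }
  }
  expect_gte(checked, 200L)
})

test_that("variants in non-coding regions classify by region", {
  # coding tx with two exons and an intron [20, 40)
  cds <- cbind(start = c(5L, 40L), end = c(20L, 61L), phase = c(0L, 0L))
  tx <- mini_tx(cds)
  ref <- ref_from_seq(paste(rep("ACGT", 20), collapse = ""))
  sp <- splice_cds(tx, ref)
  v_at <- function(pos, ref_b) list(pos = pos, ref = ref_b, alt = "N",
                                    orig_pos = pos, record_index = 1L)
  term_at <- function(pos) {
    b <- substr(paste(rep("ACGT", 20), collapse = ""), pos, pos)
    cons <- classify_haplotype(tx, sp, list(v_at(pos, b)))
    cons[[1]]$terms
  }
  expect_identical(term_at(21L), "splice_donor")      # first 2 intronic bases
  expect_identical(term_at(40L), "splice_acceptor")   # last 2 intronic bases
  expect_identical(term_at(25L), "splice_region")     # intronic base 5
  expect_identical(term_at(30L), "intron")            # deep intron
})

test_that("reverse-complement mirroring leaves consequence terms unchanged", {
  for (seed in 1:15) {
    fx <- make_fixture("random", tempfile(), seed = 5000L + seed)
    if (length(fx$variants) == 0L) next
    mir <- mirror_fixture(fx, tempfile())
    out1 <- tempfile(fileext = ".vcf")
    out2 <- tempfile(fileext = ".vcf")
    suppressWarnings(annotate_vcf(fx$paths$vcf, fx$paths$gff3, fx$paths$fasta, out1))
    suppressWarnings(annotate_vcf(mir$vcf, mir$gff3, mir$fasta, out2))
    pull_terms <- function(path) {
      anns <- unlist(lapply(annotated_body(path), info_tag))
      anns <- anns[!startsWith(anns, "@")]
      sort(vapply(strsplit(anns, "|", fixed = TRUE), function(p)
        paste(p[1], p[3], p[6]), ""))
    }
    expect_identical(pull_terms(out2), pull_terms(out1))
  }
})

test_that("identical inputs produce byte-identical annotated output", {
  fx <- make_fixture("son_like", tempfile(), seed = 3)
  out1 <- tempfile(fileext = ".vcf")
  out2 <- tempfile(fileext = ".vcf")
  annotate_vcf(fx$paths$vcf, fx$paths$gff3, fx$paths$fasta, out1)
  annotate_vcf(fx$paths$vcf, fx$paths$gff3, fx$paths$fasta, out2)
  expect_identical(readLines(out1), readLines(out2))
})

test_that("overlapping variants on one haplotype resolve first-wins", {
  codons <- paste(c("ATG", rep("GCT", 28), "TAA"), collapse = "")
  ref <- ref_from_seq(paste0(codons, "GGGGG"))
  tx <- mini_tx(cbind(start = 0L, end = 90L, phase = 0L))
  sp <- splice_cds(tx, ref)
  vs <- list(list(pos = 10L, ref = "GCTGC", alt = "G", orig_pos = 10L, record_index = 1L),
             list(pos = 12L, ref = "T", alt = "A", orig_pos = 12L, record_index = 2L))
  expect_warning(cons <- classify_haplotype(tx, sp, vs), "overlap_conflict")
  expect_length(cons, 1L)
  expect_length(cons[[1]]$members, 1L)
  expect_equal(cons[[1]]$members[[1]]$pos, 10L)
})
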