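# Shared test helpers: tiny in-code GFF3/FASTA/VCF writers and brute-force
# oracles for index and streaming checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tmp <- function(lines, ext = "") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

toy_gff3 <- function() {
  write_tmp(c(
    "##gff-version 3",
    "chrT\ttoy\tgene\t100\t400\t.\t+\t.\tID=gene1;Name=G1",
    "chrT\ttoy\tmRNA\t100\t400\t.\t+\t.\tID=tx1;Parent=gene1;biotype=protein_coding",
    "chrT\ttoy\texon\t100\t200\t.\t+\t.\tParent=tx1",
    "chrT\ttoy\texon\t301\t400\t.\t+\t.\tParent=tx1",
    "chrT\ttoy\tCDS\t150\t200\t.\t+\t0\tParent=tx1",
    "chrT\ttoy\tCDS\t301\t350\t.\t+\t0\tParent=tx1"
  ), ".gff3")
}

toy_vcf <- function(body, samples = c("S1"), format = "GT") {
  write_tmp(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body
  ), ".vcf")
}

# brute-force transcript overlap scan, the oracle for the interval index
brute_overlap <- function(transcripts, chrom, start, end) {
  hit <- vapply(transcripts, function(t)
    t$chrom == chrom && t$span[1] < end && start < t$span[2], TRUE)
  which(hit)
}

# random transcript models on one contig for index / streaming tests
random_tx_models <- function(n, contig_len = 10000L) {
  lapply(seq_len(n), function(i) {
    s <- sample.int(contig_len - 200L, 1)
    e <- s + sample(50:400, 1)
    structure(list(transcript_id = paste0("t", i), gene_id = paste0("g", i),
                   gene_name = paste0("G", i), biotype = "protein_coding",
                   strand = "+", chrom = "chrT", span = c(s, min(e, contig_len)),
                   exons = cbind(start = s, end = min(e, contig_len)),
                   cds = cbind(start = s, end = min(e, contig_len), phase = 0L),
                   utr5 = NULL, utr3 = NULL, coding = FALSE),
              class = "transcript_model")
  })
}

# reverse-complement mirror of a fixture: genome revcomp'd, annotation and
# variant coordinates mirrored, variant alleles revcomp'd
mirror_fixture <- function(fx, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seq <- hapcsq:::oracle_read_fasta(fx$paths$fasta)[[1]]
  L <- nchar(seq)
  rc <- hapcsq:::oracle_revcomp(seq)

  gff <- readLines(fx$paths$gff3)
  out_gff <- vapply(gff, function(l) {
    if (startsWith(l, "#")) return(l)
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    s <- as.integer(f[4]); e <- as.integer(f[5])
    f[4] <- as.character(L - e + 1L); f[5] <- as.character(L - s + 1L)
    f[7] <- if (f[7] == "+") "-" else "+"
    paste(f, collapse = "\t")
  }, "", USE.NAMES = FALSE)

  vcf <- readLines(fx$paths$vcf)
  hdr <- vcf[startsWith(vcf, "#")]
  body <- vcf[!startsWith(vcf, "#")]
  mirrored <- lapply(body, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    pos <- as.integer(f[2]); ref <- f[4]; alt <- f[5]
    newpos <- L - (pos + nchar(ref) - 1L) + 1L
    f[2] <- as.character(newpos)
    f[4] <- hapcsq:::oracle_revcomp(ref)
    f[5] <- hapcsq:::oracle_revcomp(alt)
    f
  })
  ord <- order(vapply(mirrored, function(f) as.integer(f[2]), 0L))
  body <- vapply(mirrored[ord], paste, "", collapse = "\t")

  paths <- list(fasta = file.path(outdir, "ref.fa"),
                gff3 = file.path(outdir, "annot.gff3"),
                vcf = file.path(outdir, "sites.vcf"))
  hapcsq:::write_fasta(rc, paths$fasta)
  writeLines(out_gff, paths$gff3)
  writeLines(c(hdr, body), paths$vcf)
  paths
}

# pull the tag values out of an annotated VCF body line
info_tag <- function(line, tag = "BCSQ") {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  m <- regmatches(f[8], regexec(paste0("(^|;)", tag, "=([^;]*)"), f[8]))[[1]]
  if (length(m) < 3L) return(character())
  strsplit(m[3], ",", fixed = TRUE)[[1]]
}

annotated_body <- function(path) {
  l <- readLines(path)
  l[!startsWith(l, "#")]
}
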