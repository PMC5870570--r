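# Self-contained toy fixtures: reference FASTA + GFF3 + phased VCF triples
# on a single contig "chrT", with deterministic reconstructions of the
# three compound-variant scenarios (same-codon MNV, frame-restoring indel
# pair, intron-split codon) and seeded randomized cases for oracle testing.
# Planted regions use fixed codons (GCT/GAA fillers, no stop in any frame)
# so scenario outcomes are guaranteed; everything else is random background.

SAFE_CODONS <- c("GCT", "GCA", "GGC", "AAA", "CTG", "GAT", "TTC", "CCT")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

write_fasta <- function(seq, path, name = "chrT", width = 60L) {
  n <- nchar(seq)
  starts <- seq(1L, n, by = width)
  lines <- c(paste0(">", name),
             vapply(starts, function(s) substr(seq, s, min(s + width - 1L, n)), ""))
  writeLines(lines, path)
}

fixture_gff3_lines <- function(txs) {
  lines <- "##gff-version 3"
  for (tx in txs) {
    lines <- c(lines,
      sprintf("chrT\tfixture\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
              tx$span[1], tx$span[2], tx$strand, tx$gene_id, tx$gene_name),
      sprintf("chrT\tfixture\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;biotype=protein_coding",
              tx$span[1], tx$span[2], tx$strand, tx$id, tx$gene_id))
    for (i in seq_len(nrow(tx$exons)))
      lines <- c(lines, sprintf("chrT\tfixture\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                tx$exons[i, 1], tx$exons[i, 2], tx$strand, tx$id))
    for (i in seq_len(nrow(tx$cds)))
      lines <- c(lines, sprintf("chrT\tfixture\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
                                tx$cds[i, 1], tx$cds[i, 2], tx$strand,
                                tx$cds[i, 3], tx$id))
  }
  lines
}

fixture_vcf_lines <- function(variants, gts, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chrT>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(variants), function(i) {
    v <- variants[[i]]
    paste(c("chrT", v$pos, ".", v$ref, v$alt, ".", ".", ".", "GT", gts[[i]]),
          collapse = "\t")
  }, "")
  c(hdr, body)
}

# a simple fixture transcript description (1-based inclusive coordinates,
# as written to GFF3)
fixture_tx <- function(id, gene_id, gene_name, strand, exons, cds) {
  list(id = id, gene_id = gene_id, gene_name = gene_name, strand = strand,
       exons = exons, cds = cds,
       span = c(min(exons[, 1]), max(exons[, 2])))
}

plant <- function(seq, pos1, s) {
  paste0(substr(seq, 1L, pos1 - 1L), s, substr(seq, pos1 + nchar(s), nchar(seq)))
}

#' Generate a toy fixture (reference FASTA + GFF3 + phased VCF)
#'
#' Scenario `fig1a` plants two phased SNVs in one codon whose joint codon
#' is TAG while each single substitution is a non-stop amino-acid change;
#' `fig1b` plants a frame-shifting deletion followed by a frame-restoring
#' deletion (net -6); `fig1c` plants a two-exon transcript with a codon
#' split 2|1 across the intron and one SNV in each part, jointly TAG;
#' `son_like` plants a 1-bp insertion (G>GA) and a 1-bp deletion (GA>G)
#' 12 bp apart on one haplotype (net 0); `random` draws transcripts and
#' phased variants at the requested density. The same seed produces
#' byte-identical files. Expected joint and per-variant classifications in
#' the manifest are computed by the independent whole-protein diff oracle
#' at generation time, never assumed.
#'
#' @param scenario One of fig1a, fig1b, fig1c, son_like, random.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_samples Number of diploid samples (scenario fixtures use the
#'   first sample's haplotype 1 as the compound carrier).
#' @param n_transcripts Number of transcripts (random scenario).
#' @param contig_length Contig length in bases.
#' @param variant_density Variants per CDS kilobase (random scenario).
#' @return A list with file `paths`, the planted `variants`, per-scenario
#'   `expect`ations (oracle-computed), and the carrier haplotype.
#' @export
make_fixture <- function(scenario = c("fig1a", "fig1b", "fig1c", "son_like", "random"),
                         outdir, seed = 1L, n_samples = 3L, n_transcripts = 2L,
                         contig_length = 3000L, variant_density = 8) {
  scenario <- match.arg(scenario)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  if (scenario == "random")
    return(make_random_fixture(outdir, n_samples, n_transcripts, contig_length,
                               variant_density))
  if (contig_length < 400L) stop("contig too short for scenario transcript")
  seq <- random_dna(contig_length)

  if (scenario == "fig1a") {
    cds_start <- 101L
    codons <- c("ATG", sample(SAFE_CODONS, 28, replace = TRUE), "TAA")
    codons[10] <- "CAC"
    seq <- plant(seq, cds_start, paste(codons, collapse = ""))
    cds_end <- cds_start + 90L - 1L
    tx <- fixture_tx("tx1", "gene1", "GENE1", "+",
                     cbind(cds_start, cds_end), cbind(cds_start, cds_end, 0L))
    p1 <- cds_start + 27L  # codon 10 base 1
    variants <- list(list(pos = p1, ref = "C", alt = "T"),
                     list(pos = p1 + 2L, ref = "C", alt = "G"))
  } else if (scenario == "fig1b") {
    cds_start <- 101L
    codons <- c("ATG", rep("GCT", 28), "TAA")
    seq <- plant(seq, cds_start, paste(codons, collapse = ""))
    cds_end <- cds_start + 90L - 1L
    tx <- fixture_tx("tx1", "gene1", "GENE1", "+",
                     cbind(cds_start, cds_end), cbind(cds_start, cds_end, 0L))
    d1 <- cds_start + 21L  # codon 8 boundary
    variants <- list(
      list(pos = d1, ref = substr(seq, d1, d1 + 4L), alt = substr(seq, d1, d1)),
      list(pos = d1 + 12L, ref = substr(seq, d1 + 12L, d1 + 14L),
           alt = substr(seq, d1 + 12L, d1 + 12L)))
  } else if (scenario == "fig1c") {
    e1 <- c(101L, 150L); e2 <- c(201L, 249L)  # CDS lengths 50 + 49 = 99
    spliced <- paste(c("ATG", rep("GCT", 15), "CAC", rep("GCT", 15), "TAA"),
                     collapse = "")
    seq <- plant(seq, e1[1], substr(spliced, 1L, 50L))
    seq <- plant(seq, e2[1], substr(spliced, 51L, 99L))
    tx <- fixture_tx("tx1", "gene1", "GENE1", "+",
                     rbind(e1, e2), cbind(rbind(e1, e2), c(0L, 1L)))
    # split codon CAC: spliced 49,50 in exon 1 (genomic 149,150), 51 in exon 2
    variants <- list(list(pos = 149L, ref = "C", alt = "T"),
                     list(pos = 201L, ref = "C", alt = "G"))
  } else {  # son_like
    cds_start <- 101L
    codons <- c("ATG", rep("GAA", 38), "TAA")
    seq <- plant(seq, cds_start, paste(codons, collapse = ""))
    cds_end <- cds_start + 120L - 1L
    tx <- fixture_tx("tx1", "gene1", "GENE1", "+",
                     cbind(cds_start, cds_end), cbind(cds_start, cds_end, 0L))
    p <- cds_start + 30L  # codon-start G
    variants <- list(list(pos = p, ref = "G", alt = "GA"),
                     list(pos = p + 12L, ref = "GA", alt = "G"))
  }

  # sample 1 haplotype 1 carries both variants; sample 2 haplotype 1 carries
  # the first variant alone; remaining samples are reference
  gts <- lapply(seq_along(variants), function(i) {
    g <- rep("0|0", n_samples)
    g[1] <- "0|1"
    if (n_samples >= 2L && i == 1L) g[2] <- "0|1"
    g
  })
  samples <- paste0("S", seq_len(n_samples))
  paths <- write_fixture_files(outdir, seq, list(tx), variants, gts, samples)

  expect <- list(
    joint = oracle_consequence(paths$fasta, paths$gff3, variants),
    single = lapply(variants, function(v)
      oracle_consequence(paths$fasta, paths$gff3, list(v)))
  )
  write_manifest(file.path(outdir, "manifest.txt"), scenario, variants, expect)
  paths$manifest <- file.path(outdir, "manifest.txt")
  list(paths = paths, variants = variants, expect = expect,
       samples = samples, scenario = scenario)
}

write_fixture_files <- function(outdir, seq, txs, variants, gts, samples) {
  fasta <- file.path(outdir, "ref.fa")
  gff3 <- file.path(outdir, "annot.gff3")
  vcf <- file.path(outdir, "sites.vcf")
  write_fasta(seq, fasta)
  writeLines(fixture_gff3_lines(txs), gff3)
  writeLines(fixture_vcf_lines(variants, gts, samples), vcf)
  list(fasta = fasta, gff3 = gff3, vcf = vcf)
}

write_manifest <- function(path, scenario, variants, expect) {
  lines <- c(paste0("scenario=", scenario),
             paste0("joint_terms=", paste(expect$joint$terms, collapse = "&")),
             paste0("joint_aa=", expect$joint$aa_change))
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    lines <- c(lines,
               sprintf("var%d=%d %s %s", i, v$pos, v$ref, v$alt),
               sprintf("var%d_terms=%s", i,
                       paste(expect$single[[i]]$terms, collapse = "&")))
  }
  writeLines(lines, path)
}

# Random transcripts (mixed strand, 1-3 exons) and phased variants at the
# requested density; variants are kept clear of segment edges and of each
# other so that classifications are comparable base by base.
make_random_fixture <- function(outdir, n_samples, n_transcripts, contig_length,
                                variant_density) {
  seq <- random_dna(contig_length)
  txs <- list()
  cursor <- 51L
  for (t in seq_len(n_transcripts)) {
    n_exons <- sample(1:3, 1)
    exons <- NULL
    estart <- cursor
    for (e in seq_len(n_exons)) {
      elen <- 3L * sample(20:40, 1)
      exons <- rbind(exons, c(estart, estart + elen - 1L))
      estart <- estart + elen + sample(25:60, 1)  # intron
    }
    if (max(exons[, 2]) + 100L > contig_length)
      stop("contig too short for requested transcripts")
    strand <- sample(c("+", "-"), 1)
    total <- sum(exons[, 2] - exons[, 1] + 1L)
    total_keep <- total - total %% 3L
    # trim the 3'-most exon so the CDS is a codon multiple
    drop <- total %% 3L
    if (drop > 0L) {
      if (strand == "+") exons[nrow(exons), 2] <- exons[nrow(exons), 2] - drop
      else exons[1, 1] <- exons[1, 1] + drop
    }
    phases <- integer(nrow(exons))
    ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
    acc <- 0L
    for (k in ord) {
      phases[k] <- (3L - acc %% 3L) %% 3L
      if (acc == 0L) phases[k] <- 0L
      acc <- acc + exons[k, 2] - exons[k, 1] + 1L
    }
    txs[[t]] <- fixture_tx(paste0("tx", t), paste0("gene", t), paste0("GENE", t),
                           strand, exons, cbind(exons, phases))
    cursor <- max(exons[, 2]) + sample(60:120, 1)
  }

  # candidate variant positions: inside CDS, >= 6 bases from segment edges
  variants <- list()
  for (tx in txs) {
    for (i in seq_len(nrow(tx$cds))) {
      s <- tx$cds[i, 1] + 6L
      e <- tx$cds[i, 2] - 6L
      if (e <= s) next
      n_var <- stats::rpois(1, (e - s + 1L) / 1000 * variant_density)
      if (n_var == 0L) next
      pos <- sort(sample(seq(s, e), min(n_var, max(1L, (e - s) %/% 12L))))
      pos <- pos[c(TRUE, diff(pos) >= 12L)]
      for (p in pos) {
        type <- sample(c("snv", "ins", "del"), 1, prob = c(0.7, 0.15, 0.15))
        rb <- substr(seq, p, p)
        if (type == "snv") {
          alt <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
          v <- list(pos = p, ref = rb, alt = alt)
        } else if (type == "ins") {
          v <- list(pos = p, ref = rb, alt = paste0(rb, random_dna(sample(1:2, 1))))
        } else {
          dl <- sample(1:2, 1)
          v <- list(pos = p, ref = substr(seq, p, p + dl), alt = rb)
        }
        variants[[length(variants) + 1L]] <- v
      }
    }
  }
  if (length(variants) > 1L) {
    ord <- order(vapply(variants, function(v) v$pos, 0L))
    variants <- variants[ord]
  }

  samples <- paste0("S", seq_len(n_samples))
  gts <- lapply(variants, function(v) {
    carried <- matrix(stats::runif(2L * n_samples) < 0.4, ncol = 2L)
    vapply(seq_len(n_samples), function(s)
      paste0(as.integer(carried[s, 1]), "|", as.integer(carried[s, 2])), "")
  })
  paths <- write_fixture_files(outdir, seq, txs, variants, gts, samples)
  paths$manifest <- NA_character_
  list(paths = paths, variants = variants, expect = NULL, samples = samples,
       scenario = "random", transcripts = txs)
}
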