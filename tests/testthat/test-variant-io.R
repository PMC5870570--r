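test_that("an empty VCF body yields an empty stream", {
  vcf <- read_phased_vcf(toy_vcf(character()))
  expect_length(vcf$records, 0L)
  expect_identical(vcf$samples, "S1")
})

test_that("phased genotype lines parse by the format definition", {
  vcf <- read_phased_vcf(toy_vcf("chr1\t5\t.\tC\tT\t.\t.\t.\tGT\t0|1"))
  r <- vcf$records[[1]]
  expect_identical(r$chrom, "chr1")
  expect_identical(r$pos, 5L)
  expect_identical(r$ref, "C")
  expect_identical(r$alts, "T")
  g <- vcf$gt[[1]]
  expect_equal(g$alleles[1, ], c(0L, 1L))
  expect_true(g$phased[1])
})

test_that("unphased heterozygotes follow the strictness decision table", {
  path <- toy_vcf("chr1\t5\t.\tC\tT\t.\t.\t.\tGT\t1/0")
  expect_error(read_phased_vcf(path, "require"), "S1.*chr1:5")
  g_skip <- read_phased_vcf(path, "skip")$gt[[1]]
  expect_true(g_skip$excluded[1])
  g_take <- read_phased_vcf(path, "take")$gt[[1]]
  expect_false(g_take$excluded[1])
  expect_equal(g_take$alleles[1, ], c(1L, 0L))
  # unphased homozygotes carry no phase information and always pass
  hom <- toy_vcf("chr1\t5\t.\tC\tT\t.\t.\t.\tGT\t1/1")
  expect_equal(read_phased_vcf(hom, "require")$gt[[1]]$alleles[1, ], c(1L, 1L))
})

test_that("unsorted input and excess ploidy are rejected", {
  unsorted <- toy_vcf(c("chr1\t10\t.\tC\tT\t.\t.\t.\tGT\t0|0",
                        "chr1\t5\t.\tA\tG\t.\t.\t.\tGT\t0|0"))
  expect_error(read_phased_vcf(unsorted), "unsorted")
  revisit <- toy_vcf(c("chr1\t10\t.\tC\tT\t.\t.\t.\tGT\t0|0",
                       "chr2\t5\t.\tA\tG\t.\t.\t.\tGT\t0|0",
                       "chr1\t20\t.\tA\tG\t.\t.\t.\tGT\t0|0"))
  expect_error(read_phased_vcf(revisit), "revisited")
  triploid <- toy_vcf("chr1\t5\t.\tC\tT\t.\t.\t.\tGT\t0|1|1")
  expect_error(read_phased_vcf(triploid), "ploidy")
})

test_that("normalization trims shared bases and is idempotent", {
  r <- list(chrom = "c", pos = 100L, ref = "GAT", alts = "GCT", record_index = 1L)
  n <- normalize_variant(r)
  expect_identical(n$pos, 101L)
  expect_identical(n$ref, "A")
  expect_identical(n$alts, "C")

  ins <- list(chrom = "c", pos = 100L, ref = "G", alts = "GA", record_index = 1L)
  n2 <- normalize_variant(ins)
  expect_identical(n2$pos, 100L)
  expect_identical(n2$ref, "G")
  expect_identical(n2$alts, "GA")

  set.seed(3)
  for (i in 1:100) {
    core <- list(ref = paste(sample(c("A", "C", "G", "T"), sample(1:5, 1), TRUE),
                             collapse = ""),
                 alt = paste(sample(c("A", "C", "G", "T"), sample(1:5, 1), TRUE),
                             collapse = ""))
    if (core$ref == core$alt) next
    pad <- function(s) paste0("AC", s, "GT")
    r <- list(chrom = "c", pos = 50L, ref = pad(core$ref), alts = pad(core$alt),
              record_index = 1L)
    once <- normalize_variant(r)
    twice <- normalize_variant(once)
    expect_identical(twice[c("pos", "ref", "alts")], once[c("pos", "ref", "alts")])
  }
})

test_that("the interleave rule maps (consequence, haplotype) to bit 2i+h", {
  expect_equal(encode_mask(list()), 0)
  expect_equal(encode_mask(list(c(0, 0))), 1)
  expect_equal(encode_mask(list(c(0, 1))), 2)
  expect_equal(encode_mask(list(c(1, 0))), 4)
  expect_equal(encode_mask(list(c(1, 1))), 8)
  # duplicates collapse
  expect_equal(encode_mask(list(c(2, 1), c(2, 1))), 32)
})

test_that("mask decoding inverts encoding", {
  expect_equal(nrow(decode_mask(0)), 0L)
  expect_equal(unname(decode_mask(9)), cbind(c(0L, 1L), c(0L, 1L)))
  set.seed(5)
  for (mask in sample.int(2^16, 1000L) - 1L) {
    expect_equal(encode_mask(decode_mask(mask)), mask)
  }
})

test_that("sites with at most four consequences fit every mask in 8 bits", {
  # every possible assignment subset over 4 consequences x 2 haplotypes
  combos <- expand.grid(cons = 0:3, hap = 0:1)
  for (k in 0:(2^8 - 1)) {
    rows <- which(bitwAnd(k, bitwShiftL(1L, 0:7)) != 0L)
    m <- encode_mask(as.matrix(combos[rows, , drop = FALSE]))
    expect_lt(m, 256)
  }
})

test_that("annotated records serialize the documented INFO/FORMAT contract", {
  rec <- list(chrom = "chr1", pos = 100L, ref = "A", alts = "G",
              line = "chr1\t100\t.\tA\tG\t.\t.\t.\tGT\t0|1", record_index = 1L)
  ann <- list(consequences = "missense|GENE1|tx1|protein_coding|+|5R>5W|100A>G",
              sample_masks = 1)
  line <- hapcsq:::render_annotated_line(rec, ann, 1L)
  expect_match(line, "BCSQ=missense\\|GENE1\\|tx1\\|protein_coding\\|\\+\\|5R>5W\\|100A>G",
               fixed = FALSE)
  expect_match(line, "GT:BCSQ\t0\\|1:1$")

  member <- list(consequences = "@150", sample_masks = 1)
  expect_match(hapcsq:::render_annotated_line(rec, member, 1L), "BCSQ=@150")

  expect_identical(hapcsq:::render_annotated_line(rec, NULL, 1L), rec$line)
  expect_identical(hapcsq:::render_annotated_line(
    rec, list(consequences = character(), sample_masks = numeric()), 1L), rec$line)
})

test_that("annotated output survives a write/read cycle and keeps sample order", {
  fx <- make_fixture("fig1a", tempfile(), seed = 2, n_samples = 5)
  out <- tempfile(fileext = ".vcf")
  annotate_vcf(fx$paths$vcf, fx$paths$gff3, fx$paths$fasta, out)
  re <- read_phased_vcf(out)
  expect_identical(re$samples, paste0("S", 1:5))
  expect_length(re$records, 2L)
  body <- annotated_body(out)
  expect_true(any(grepl("stop_gained", body)))
  # carrier is sample 1, haplotype 1; other samples keep zero masks
  f <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  masks <- as.numeric(vapply(strsplit(f[10:14], ":"), `[`, "", 2))
  expect_true(all(masks[3:5] == 0))
  expect_true(masks[1] > 0)
})

test_that("annotated output parses under an independent VCF reader", {
  skip_if_not_installed("vcfR")
  fx <- make_fixture("fig1a", tempfile(), seed = 2)
  out <- tempfile(fileext = ".vcf")
  annotate_vcf(fx$paths$vcf, fx$paths$gff3, fx$paths$fasta, out)
  v <- suppressWarnings(vcfR::read.vcfR(out, verbose = FALSE))
  expect_equal(nrow(v@fix), 2L)
  expect_true(any(grepl("BCSQ=", v@fix[, "INFO"])))
})

test_that("symbolic alleles pass through unannotated with a warning", {
  fx <- make_fixture("fig1a", tempfile(), seed = 2)
  lines <- readLines(fx$paths$vcf)
  sym <- "chrT\t140\t.\tA\t<DEL>\t.\t.\t.\tGT\t0|0\t0|0\t0|0"
  writeLines(append(lines, sym), fx$paths$vcf)
  out <- tempfile(fileext = ".vcf")
  expect_warning(annotate_vcf(fx$paths$vcf, fx$paths$gff3, fx$paths$fasta, out),
                 "symbolic")
  body <- annotated_body(out)
  expect_identical(body[grepl("<DEL>", body)], sym)
})
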