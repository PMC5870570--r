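# Phased VCF streaming, allele normalization and annotated output.
# Records are kept as raw text lines alongside parsed fields so that
# unannotated records are echoed byte-identically and annotated ones only
# gain the INFO/FORMAT tag.

#' Read a phased multi-sample VCF
#'
#' Parses a sorted VCF v4.2 text file. Multi-allelic sites are kept intact.
#' `|`-separated genotypes are phased, `/`-separated unphased. Handling of
#' unphased heterozygotes is controlled by `strictness`:
#' \describe{
#'   \item{require}{error naming the sample and position (default);}
#'   \item{skip}{the sample's haplotypes at that site are excluded from
#'     haplotype trees (localized calling still annotates them);}
#'   \item{take}{the listed allele order is taken as the phase.}
#' }
#'
#' @param path Path to a VCF text file.
#' @param strictness One of "require", "skip", "take".
#' @return A list with elements `samples` (character), `meta` (header lines),
#'   `records` (list of variant records) and `gt` (per-record genotype
#'   tables: an n x 2 allele-index matrix plus phased/excluded flags).
#' @export
read_phased_vcf <- function(path, strictness = c("require", "skip", "take")) {
  strictness <- match.arg(strictness)
  lines <- readLines(path, warn = FALSE)
  hdr_end <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_end) != 1L) stop("invalid VCF: no #CHROM header line in ", path)
  meta <- lines[seq_len(hdr_end - 1L)]
  hdr <- strsplit(lines[hdr_end], "\t", fixed = TRUE)[[1]]
  samples <- if (length(hdr) > 9L) hdr[-(1:9)] else character()
  body <- lines[-seq_len(hdr_end)]
  body <- body[nzchar(body)]

  records <- vector("list", length(body))
  gts <- vector("list", length(body))
  prev_chrom <- NULL
  prev_pos <- -Inf
  seen_chroms <- character()
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop("malformed VCF record at line ", hdr_end + i, ": fewer than 8 columns")
    chrom <- f[1]
    pos <- as.integer(f[2])
    if (!identical(chrom, prev_chrom)) {
      if (chrom %in% seen_chroms)
        stop("unsorted VCF: contig '", chrom, "' revisited at position ", pos)
      seen_chroms <- c(seen_chroms, chrom)
      prev_chrom <- chrom
      prev_pos <- -Inf
    }
    if (pos < prev_pos)
      stop("unsorted VCF: ", chrom, ":", pos, " follows position ", prev_pos)
    prev_pos <- pos
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    symbolic <- grepl("[][<>]", f[5]) || any(alts == "*") ||
      !grepl("^[ACGTNacgtn]+$", f[4])
    records[[i]] <- list(
      chrom = chrom, pos = pos, id = f[3], ref = toupper(f[4]),
      alts = toupper(alts), record_index = i, line = body[i],
      symbolic = symbolic
    )
    gts[[i]] <- parse_genotypes(f, samples, chrom, pos, strictness)
  }
  list(samples = samples, meta = meta, records = records, gt = gts, path = path)
}

parse_genotypes <- function(f, samples, chrom, pos, strictness) {
  n <- length(samples)
  alleles <- matrix(NA_integer_, nrow = n, ncol = 2L)
  phased <- rep(TRUE, n)
  excluded <- rep(FALSE, n)
  if (n == 0L || length(f) < 10L)
    return(list(alleles = alleles, phased = phased, excluded = excluded))
  fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
  gt_i <- match("GT", fmt)
  if (is.na(gt_i)) return(list(alleles = alleles, phased = phased, excluded = excluded))
  n_alt <- length(strsplit(f[5], ",", fixed = TRUE)[[1]])
  for (s in seq_len(n)) {
    gt <- strsplit(f[9L + s], ":", fixed = TRUE)[[1]][gt_i]
    is_phased <- grepl("|", gt, fixed = TRUE)
    parts <- strsplit(gt, "[|/]")[[1]]
    if (length(parts) > 2L)
      stop("ploidy ", length(parts), " not supported (sample ", samples[s],
           " at ", chrom, ":", pos, ")")
    a <- suppressWarnings(as.integer(parts))
    a[parts == "."] <- NA_integer_
    if (length(a) == 1L) a <- c(a, NA_integer_)  # haploid: second haplotype absent
    if (any(!is.na(a) & a > n_alt))
      stop("allele index out of range at ", chrom, ":", pos, " for sample ", samples[s])
    het <- !is.na(a[1]) && !is.na(a[2]) && a[1] != a[2]
    if (!is_phased && het) {
      if (strictness == "require")
        stop("unphased heterozygous genotype '", gt, "' for sample ", samples[s],
             " at ", chrom, ":", pos, " (phase-strictness 'require')")
      if (strictness == "skip") excluded[s] <- TRUE
      # "take": listed order treated as phase
      phased[s] <- strictness == "take"
    }
    alleles[s, ] <- a
  }
  list(alleles = alleles, phased = phased, excluded = excluded)
}

# Normalize one (pos, ref, alt) allele pair: trim the shared suffix, then
# the shared prefix keeping at least one base. Idempotent.
norm_allele <- function(pos, ref, alt) {
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Normalize a variant record
#'
#' Trims shared trailing bases, then shared leading bases (keeping at least
#' one), adjusting `pos`. For multi-allelic records each alt is normalized
#' independently and stored in the `norm` element; `pos`/`ref` of the record
#' itself are only rewritten for biallelic records.
#'
#' @param record A variant record as produced by [read_phased_vcf()].
#' @return The normalized record, with `norm`: a list of
#'   `(pos, ref, alt)` per alt allele.
#' @export
normalize_variant <- function(record) {
  norm <- lapply(record$alts, function(alt) norm_allele(record$pos, record$ref, alt))
  record$norm <- norm
  if (length(record$alts) == 1L) {
    record$pos <- norm[[1]]$pos
    record$ref <- norm[[1]]$ref
    record$alts <- norm[[1]]$alt
  }
  record
}

#' Encode haplotype consequence assignments as an interleaved bitmask
#'
#' Bit `2*i + h` is set when consequence index `i` (0-based, indexing the
#' site's unique-consequence list) applies to haplotype `h` (0 or 1).
#' With at most 4 unique consequences at a site every mask fits in 8 bits.
#' Duplicate assignments collapse. Masks are exact up to bit position 52
#' (26 consequences per site); beyond that an error is raised.
#'
#' @param assignments A two-column matrix or list of pairs
#'   `(consequence-index, haplotype-index)`.
#' @return A single non-negative numeric mask.
#' @export
encode_mask <- function(assignments) {
  if (is.list(assignments)) assignments <- do.call(rbind, assignments)
  if (is.null(assignments) || length(assignments) == 0L) return(0)
  stopifnot(ncol(assignments) == 2L)
  if (any(assignments[, 2] > 1L | assignments[, 2] < 0L))
    stop("haplotype index must be 0 or 1")
  bits <- unique(2 * assignments[, 1] + assignments[, 2])
  if (any(bits > 52)) stop("mask bit position ", max(bits), " exceeds exact double range")
  sum(2^bits)
}

#' Decode an interleaved consequence bitmask
#'
#' Inverse of [encode_mask()]: `decode_mask(encode_mask(x))` recovers the
#' assignment set.
#'
#' @param mask Non-negative numeric mask.
#' @return Two-column integer matrix with columns `cons` (consequence index)
#'   and `hap` (haplotype 0/1), ordered by bit position.
#' @export
decode_mask <- function(mask) {
  stopifnot(mask >= 0)
  bits <- integer()
  b <- 0L
  while (mask > 0) {
    if (mask %% 2 == 1) bits <- c(bits, b)
    mask <- mask %/% 2
    b <- b + 1L
  }
  cbind(cons = bits %/% 2L, hap = bits %% 2L)
}

# --- annotated output -------------------------------------------------------

vcf_tag_headers <- function(tag) {
  c(sprintf(paste0("##INFO=<ID=%s,Number=.,Type=String,Description=\"",
                   "Haplotype-aware consequence: terms|gene|transcript|biotype|",
                   "strand|aa_change|dna_change, or @POS for a compound member ",
                   "anchored elsewhere\">"), tag),
    sprintf(paste0("##FORMAT=<ID=%s,Number=.,Type=Integer,Description=\"",
                   "Bitmask of indexes into INFO/%s, interleaved per haplotype ",
                   "(bit 2*i+h)\">"), tag, tag))
}

# Render one record with its site annotation appended. A site with no
# consequences is echoed unmodified.
render_annotated_line <- function(record, annotation, n_samples, tag = "BCSQ") {
  if (is.null(annotation) || length(annotation$consequences) == 0L)
    return(record$line)
  f <- strsplit(record$line, "\t", fixed = TRUE)[[1]]
  info_val <- paste0(tag, "=", paste(annotation$consequences, collapse = ","))
  f[8] <- if (f[8] %in% c(".", "")) info_val else paste0(f[8], ";", info_val)
  if (n_samples > 0L && length(f) >= 10L) {
    fmt_missing <- f[9] == "."
    f[9] <- if (fmt_missing) tag else paste0(f[9], ":", tag)
    masks <- annotation$sample_masks
    for (s in seq_len(n_samples)) {
      v <- format(if (s <= length(masks)) masks[s] else 0, scientific = FALSE)
      f[9L + s] <- if (fmt_missing) v else paste0(f[9L + s], ":", v)
    }
  }
  paste(f, collapse = "\t")
}

write_annotated_vcf <- function(vcf, annotations, path, tag = "BCSQ") {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- vcf$meta
  writeLines(meta, con)
  writeLines(vcf_tag_headers(tag), con)
  hdr <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(vcf$samples)) hdr <- c(hdr, "FORMAT", vcf$samples)
  writeLines(paste(hdr, collapse = "\t"), con)
  for (i in seq_along(vcf$records)) {
    ann <- if (i <= length(annotations)) annotations[[i]] else NULL
    writeLines(render_annotated_line(vcf$records[[i]], ann, length(vcf$samples), tag),
               con)
  }
  invisible(path)
}
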