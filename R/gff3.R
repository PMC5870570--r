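# GFF3 ingestion: gene/transcript/exon/CDS/UTR features become transcript
# models in the internal 0-based half-open frame. Only feature types that
# describe transcript structure are used; everything else is skipped.

TRANSCRIPT_CHILD_TYPES <- c("exon", "CDS",
                            "five_prime_UTR", "three_prime_UTR",
                            "five_prime_utr", "three_prime_utr")

gff3_attrs <- function(s) {
  if (is.na(s) || s == "." || s == "") return(character())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  kv <- regmatches(parts, regexpr("=", parts), invert = TRUE)
  vals <- vapply(kv, function(p) if (length(p) == 2) p[2] else "", "")
  names(vals) <- vapply(kv, `[`, "", 1)
  vals
}

attr_get <- function(attrs, key) {
  if (key %in% names(attrs)) attrs[[key]] else NA_character_
}

#' Parse a GFF3 annotation into transcript models
#'
#' Reads a GFF3 file (tab-separated, nine columns, `##` directives allowed)
#' and returns one transcript model per transcript feature that has at least
#' one exon or CDS child. A transcript feature is any feature whose ID is
#' referenced as `Parent` by an exon/CDS/UTR line, so Ensembl- and NCBI-style
#' dialects both work. Coordinates are converted from GFF3's 1-based
#' inclusive frame to the internal 0-based half-open frame.
#'
#' Unsupported feature types are skipped. A CDS segment not contained in any
#' exon triggers a warning and a covering exon is synthesized. CDS phases
#' inconsistent with cumulative segment length are recomputed from the
#' 5'-most segment with a warning. Strand "." is treated as "+" with a
#' warning.
#'
#' @param path Path to a GFF3 file.
#' @param verbose Emit a message for each skipped feature type.
#' @return A list of `transcript_model` objects.
#' @export
parse_gff3 <- function(path, verbose = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) return(list())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1]
    stop("malformed GFF3 line ", lineno[bad], ": expected 9 tab-separated columns, got ",
         nf[bad])
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  feat <- data.frame(
    seqid = m[, 1], type = m[, 3],
    start = as.integer(m[, 4]), end = as.integer(m[, 5]),
    strand = m[, 7], phase = m[, 8], attrs = m[, 9],
    line = lineno, stringsAsFactors = FALSE
  )
  if (anyNA(feat$start) || anyNA(feat$end)) {
    bad <- which(is.na(feat$start) | is.na(feat$end))[1]
    stop("malformed GFF3 line ", feat$line[bad], ": non-numeric coordinates")
  }

  al <- lapply(feat$attrs, gff3_attrs)
  ids <- vapply(al, attr_get, "", key = "ID")
  parents <- lapply(al, function(a) {
    p <- attr_get(a, "Parent")
    if (is.na(p)) character() else strsplit(p, ",", fixed = TRUE)[[1]]
  })

  is_child <- feat$type %in% TRANSCRIPT_CHILD_TYPES
  if (verbose) {
    skipped <- setdiff(unique(feat$type[!is_child]), c("gene"))
    for (s in skipped) message("parse_gff3: skipping unsupported feature type '", s, "'")
  }
  tx_ids <- unique(unlist(parents[is_child]))
  tx_ids <- tx_ids[nzchar(tx_ids)]

  orphan_cds <- which(feat$type == "CDS" & lengths(parents) == 0L)
  if (length(orphan_cds))
    stop("GFF3 line ", feat$line[orphan_cds[1]],
         ": CDS feature with no resolvable transcript parent (missing Parent attribute)")

  id_row <- match(tx_ids, ids)  # transcript feature line, if present

  out <- vector("list", length(tx_ids))
  for (k in seq_along(tx_ids)) {
    tid <- tx_ids[k]
    child_idx <- which(is_child & vapply(parents, function(p) tid %in% p, TRUE))
    rows <- feat[child_idx, , drop = FALSE]
    cattrs <- al[child_idx]

    trow <- id_row[k]
    tattrs <- if (!is.na(trow)) al[[trow]] else list()
    gene_id <- if (!is.na(trow) && length(parents[[trow]])) parents[[trow]][1]
               else { g <- attr_get(tattrs, "gene_id"); if (is.na(g)) "" else g }
    grow <- if (nzchar(gene_id)) match(gene_id, ids) else NA_integer_
    gattrs <- if (!is.na(grow)) al[[grow]] else list()
    gene_name <- attr_get(gattrs, "Name")
    if (is.na(gene_name)) gene_name <- attr_get(gattrs, "gene_name")
    if (is.na(gene_name)) gene_name <- attr_get(tattrs, "gene_name")
    if (is.na(gene_name)) gene_name <- if (nzchar(gene_id)) gene_id else tid

    biotype <- attr_get(tattrs, "biotype")
    if (is.na(biotype)) biotype <- attr_get(tattrs, "transcript_type")
    if (is.na(biotype)) biotype <- if (!is.na(trow)) feat$type[trow] else "transcript"

    strand <- if (!is.na(trow)) feat$strand[trow] else rows$strand[1]
    if (!strand %in% c("+", "-")) {
      warning("transcript ", tid, ": unplaced strand '", strand, "' treated as '+'")
      strand <- "+"
    }
    chrom <- rows$seqid[1]

    ex <- rows[rows$type == "exon", , drop = FALSE]
    cd <- rows[rows$type == "CDS", , drop = FALSE]
    u5 <- rows[rows$type %in% c("five_prime_UTR", "five_prime_utr"), , drop = FALSE]
    u3 <- rows[rows$type %in% c("three_prime_UTR", "three_prime_utr"), , drop = FALSE]

    exons <- cbind(start = ex$start - 1L, end = ex$end)
    cds_m <- cbind(start = cd$start - 1L, end = cd$end,
                   phase = suppressWarnings(as.integer(cd$phase)))
    cds_m[is.na(cds_m[, "phase"]), "phase"] <- 0L

    # synthesize exons for CDS segments not contained in any exon
    if (nrow(cds_m)) {
      for (i in seq_len(nrow(cds_m))) {
        contained <- nrow(exons) > 0 &&
          any(exons[, "start"] <= cds_m[i, "start"] & cds_m[i, "end"] <= exons[, "end"])
        if (!contained) {
          warning("transcript ", tid, ": CDS [", cds_m[i, "start"] + 1L, ",",
                  cds_m[i, "end"], "] not contained in any exon; exon synthesized")
          exons <- rbind(exons, cds_m[i, c("start", "end"), drop = FALSE])
        }
      }
    }
    if (nrow(exons) == 0L) next  # nothing usable
    exons <- exons[order(exons[, "start"]), , drop = FALSE]
    # merge any overlapping/touching exons (invariant: non-overlapping, sorted)
    if (nrow(exons) > 1L) {
      merged <- exons[1, , drop = FALSE]
      for (i in 2:nrow(exons)) {
        j <- nrow(merged)
        if (exons[i, "start"] <= merged[j, "end"]) {
          merged[j, "end"] <- max(merged[j, "end"], exons[i, "end"])
        } else merged <- rbind(merged, exons[i, , drop = FALSE])
      }
      exons <- merged
    }
    if (nrow(cds_m)) cds_m <- cds_m[order(cds_m[, "start"]), , drop = FALSE]
    cds_m <- check_cds_phase(cds_m, strand, tid)

    span <- if (!is.na(trow)) c(feat$start[trow] - 1L, feat$end[trow])
            else c(min(exons[, "start"]), max(exons[, "end"]))
    span[1] <- min(span[1], exons[, "start"])
    span[2] <- max(span[2], exons[, "end"])

    coding <- nrow(cds_m) > 0L
    if (coding) {
      tot <- sum(cds_m[, "end"] - cds_m[, "start"]) - cds_phase_trim(cds_m, strand)
      if (tot < 3L) {
        warning("transcript ", tid, ": CDS shorter than one codon after phase trimming; ",
                "treated as non-coding")
        coding <- FALSE
        cds_m <- cds_m[0, , drop = FALSE]
      }
    }
    utr5 <- cbind(start = u5$start - 1L, end = u5$end)
    utr3 <- cbind(start = u3$start - 1L, end = u3$end)
    if (coding && nrow(utr5) == 0L && nrow(utr3) == 0L) {
      u <- derive_utrs(exons, cds_m, strand)
      utr5 <- u$utr5; utr3 <- u$utr3
    }

    out[[k]] <- structure(list(
      transcript_id = tid, gene_id = gene_id, gene_name = gene_name,
      biotype = biotype, strand = strand, chrom = chrom,
      span = as.integer(span), exons = exons, cds = cds_m,
      utr5 = utr5, utr3 = utr3, coding = coding
    ), class = "transcript_model")
  }
  out[!vapply(out, is.null, TRUE)]
}

# phase of the 5'-most CDS segment = number of bases to skip before the
# first complete codon
cds_phase_trim <- function(cds_m, strand) {
  if (nrow(cds_m) == 0L) return(0L)
  if (strand == "+") cds_m[1, "phase"] else cds_m[nrow(cds_m), "phase"]
}

# Trust the 5'-most phase; verify the rest against cumulative length and
# recompute on mismatch.
check_cds_phase <- function(cds_m, strand, tid) {
  n <- nrow(cds_m)
  if (n <= 1L) return(cds_m)
  ord <- if (strand == "+") seq_len(n) else rev(seq_len(n))  # transcript order
  lens <- cds_m[ord, "end"] - cds_m[ord, "start"]
  p0 <- cds_m[ord[1], "phase"]
  expected <- integer(n)
  expected[1] <- p0
  acc <- lens[1] - p0
  for (i in 2:n) {
    expected[i] <- (3L - acc %% 3L) %% 3L
    acc <- acc + lens[i] - 0L  # phase does not remove bases from internal segments
  }
  given <- cds_m[ord, "phase"]
  if (!all(given == expected)) {
    warning("transcript ", tid, ": CDS phases inconsistent with cumulative length; ",
            "recomputed from the 5'-most segment")
    cds_m[ord, "phase"] <- expected
  }
  cds_m
}

# UTRs from exon structure minus the CDS extent when not annotated explicitly
derive_utrs <- function(exons, cds_m, strand) {
  cs <- min(cds_m[, "start"]); ce <- max(cds_m[, "end"])
  left <- right <- NULL
  for (i in seq_len(nrow(exons))) {
    s <- exons[i, "start"]; e <- exons[i, "end"]
    if (s < cs) left <- rbind(left, c(start = s, end = min(e, cs)))
    if (e > ce) right <- rbind(right, c(start = max(s, ce), end = e))
  }
  empty <- matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end")))
  if (is.null(left)) left <- empty
  if (is.null(right)) right <- empty
  if (strand == "+") list(utr5 = left, utr3 = right)
  else list(utr5 = right, utr3 = left)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d [%s] %d exon(s), %d CDS segment(s)%s\n",
              x$transcript_id, x$gene_name, x$chrom, x$span[1], x$span[2], x$strand,
              nrow(x$exons), nrow(x$cds), if (x$coding) ", coding" else ""))
  invisible(x)
}

#' Write transcript models back to GFF3
#'
#' Emits gene, mRNA/transcript, exon, CDS and UTR lines in the 1-based
#' inclusive GFF3 frame. Together with [parse_gff3()] this forms a
#' round-trip: the coordinate conversion is self-inverse.
#'
#' @param transcripts List of `transcript_model` objects.
#' @param path Output path.
#' @export
write_gff3 <- function(transcripts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  seen_gene <- character()
  for (tx in transcripts) {
    gid <- if (nzchar(tx$gene_id)) tx$gene_id else paste0(tx$transcript_id, ".gene")
    if (!gid %in% seen_gene) {
      writeLines(sprintf("%s\thapcsq\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                         tx$chrom, tx$span[1] + 1L, tx$span[2], tx$strand, gid,
                         tx$gene_name), con)
      seen_gene <- c(seen_gene, gid)
    }
    ttype <- if (tx$coding) "mRNA" else "transcript"
    writeLines(sprintf("%s\thapcsq\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;biotype=%s",
                       tx$chrom, ttype, tx$span[1] + 1L, tx$span[2], tx$strand,
                       tx$transcript_id, gid, tx$biotype), con)
    for (i in seq_len(nrow(tx$exons)))
      writeLines(sprintf("%s\thapcsq\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         tx$chrom, tx$exons[i, "start"] + 1L, tx$exons[i, "end"],
                         tx$strand, tx$transcript_id), con)
    for (i in seq_len(nrow(tx$cds)))
      writeLines(sprintf("%s\thapcsq\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
                         tx$chrom, tx$cds[i, "start"] + 1L, tx$cds[i, "end"],
                         tx$strand, tx$cds[i, "phase"], tx$transcript_id), con)
  }
  invisible(path)
}
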