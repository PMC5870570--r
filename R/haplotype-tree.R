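# Per-transcript haplotype tree over phased genotypes. Nodes correspond to
# VCF records with one child per observed allele; each sample haplotype
# traces a root-to-leaf path, so the number of leaves is bounded by the
# number of unique haplotypes (at most two per sample), never exponential
# in the number of sites.

#' Build the haplotype tree for one transcript's records
#'
#' Each diploid sample contributes two haplotypes (the two alleles of its
#' phased GT fields, in order). Haplotypes sharing an allele prefix share a
#' path; leaves hold the unique non-reference haplotypes with their
#' sample/haplotype membership. Missing alleles and samples excluded at a
#' site (phase-strictness "skip") contribute nothing at that record.
#' All-reference haplotypes yield no leaf.
#'
#' @param records List of variant records (one transcript's sites, sorted).
#' @param gts Matching list of genotype tables from [read_phased_vcf()].
#' @param n_samples Number of samples.
#' @return A list with `root` (nested node structure) and `leaves`, each
#'   leaf a list with `variants` (two-column matrix `record`/`allele`,
#'   allele >= 1) and `membership` (two-column matrix `sample` (1-based) /
#'   `hap` (0/1)).
#' @export
build_haplotype_tree <- function(records, gts, n_samples) {
  n_rec <- length(records)
  n_hap <- 2L * n_samples
  if (n_rec == 0L || n_hap == 0L)
    return(list(root = NULL, leaves = list()))
  # allele matrix: one row per haplotype, one column per record
  A <- matrix(0L, nrow = n_hap, ncol = n_rec)
  for (r in seq_len(n_rec)) {
    g <- gts[[r]]
    a <- g$alleles
    a[is.na(a)] <- 0L
    a[g$excluded, ] <- 0L
    n_all <- 1L + length(records[[r]]$alts)
    if (any(a >= n_all))
      stop("allele index out of range at record ", records[[r]]$chrom, ":",
           records[[r]]$pos)
    A[seq(1L, n_hap, by = 2L), r] <- a[, 1]
    A[seq(2L, n_hap, by = 2L), r] <- a[, 2]
  }

  leaves <- list()
  grow <- function(depth, rows) {
    if (depth > n_rec) {
      path <- A[rows[1], , drop = TRUE]
      nonref <- which(path > 0L)
      if (length(nonref)) {
        leaves[[length(leaves) + 1L]] <<- list(
          variants = cbind(record = nonref, allele = path[nonref]),
          membership = cbind(sample = (rows - 1L) %/% 2L + 1L,
                             hap = (rows - 1L) %% 2L)
        )
      }
      return(list(record = NULL, children = list(), membership = rows,
                  leaf = length(nonref) > 0L))
    }
    al <- A[rows, depth]
    children <- list()
    for (v in sort(unique(al))) {
      children[[as.character(v)]] <- grow(depth + 1L, rows[al == v])
    }
    list(record = records[[depth]], children = children, membership = rows)
  }
  root <- grow(1L, seq_len(n_hap))
  list(root = root, leaves = leaves)
}

#' Check the haplotype-tree leaf bound
#'
#' The leaf count of a haplotype tree is bounded by the number of unique
#' haplotypes, at most two per diploid sample.
#'
#' @param samples Number of samples.
#' @param leaves Leaf list from [build_haplotype_tree()].
#' @return `TRUE` when `length(leaves) <= 2 * samples`.
#' @export
leaf_count_bound <- function(samples, leaves) {
  length(leaves) <= 2L * samples
}

# --- streaming transcript buffer -------------------------------------------

#' Create an empty active-transcript buffer
#'
#' Transcripts overlapping the variants being streamed are held active,
#' ordered by end coordinate, and flushed (with their accumulated records)
#' exactly when the stream passes their end or changes chromosome, so peak
#' memory is bounded by the set of concurrently overlapping transcripts.
#'
#' @return A `transcript_buffer` environment.
#' @export
new_transcript_buffer <- function() {
  b <- new.env(parent = emptyenv())
  b$active <- list()   # keyed by transcript_id
  structure(b, class = "transcript_buffer")
}

#' Feed one record to the streaming buffer
#'
#' Flushes active transcripts that end before the record's start (or lie on
#' a previous chromosome), activates index hits not yet active, and appends
#' the record to every active transcript it overlaps.
#'
#' @param buffer A `transcript_buffer`.
#' @param record A variant record (sorted stream).
#' @param gt The record's genotype table.
#' @param index A `transcript_index`.
#' @return List of flushed entries, each `list(tx, records, gts)`.
#' @export
accumulate <- function(buffer, record, gt, index) {
  pos0 <- record$pos - 1L
  span_end <- pos0 + nchar(record$ref)
  flushed <- list()
  keep <- list()
  for (e in buffer$active) {
    if (e$tx$chrom != record$chrom || e$tx$span[2] <= pos0) {
      flushed[[length(flushed) + 1L]] <- e
    } else keep[[e$tx$transcript_id]] <- e
  }
  buffer$active <- keep
  for (tx in query_transcripts(index, record$chrom, pos0, span_end)) {
    tid <- tx$transcript_id
    if (is.null(buffer$active[[tid]]))
      buffer$active[[tid]] <- list(tx = tx, records = list(), gts = list())
    e <- buffer$active[[tid]]
    e$records[[length(e$records) + 1L]] <- record
    e$gts[[length(e$gts) + 1L]] <- gt
    buffer$active[[tid]] <- e
  }
  flushed
}

#' Flush all remaining active transcripts
#'
#' @param buffer A `transcript_buffer`.
#' @return List of flushed entries, each `list(tx, records, gts)`.
#' @export
flush_buffer <- function(buffer) {
  out <- unname(buffer$active)
  buffer$active <- list()
  out
}
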