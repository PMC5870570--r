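---
title: "Haplotype-aware consequence calling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-aware consequence calling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapcsq)
```

## The problem and the model

Single-record consequence predictors treat every VCF record as an
isolated event. When two or more variants lie in phase on the same
haplotype within one transcript, their joint protein-level effect can
differ qualitatively from the union of their individual effects: two SNVs
can complete a stop codon that neither creates alone; a frame-shifting
indel can be cancelled by a downstream frame-restoring indel; and a codon
split across an intron can be altered by SNVs on both sides of the
junction. `hapcsq` classifies the *joint* effect of each observed
haplotype, and offers a `localized` mode that reproduces the conventional
single-record behaviour for comparison.

The procedure per transcript is:

1. **Streaming.** Records are streamed in sorted order against an
   interval index of transcript spans. Transcripts overlapping the
   current position are held in an active buffer and classified (then
   released) exactly when the stream passes their end or the chromosome
   changes, so peak memory is bounded by the largest set of concurrently
   overlapping transcripts, not the file.
2. **Haplotype tree.** For the records of one transcript, each sample's
   two phased alleles trace a path through a tree whose nodes are VCF
   records and whose children are alleles (reference included, so shared
   prefixes compress). Leaves are the distinct haplotypes, carrying the
   set of `(sample, haplotype)` pairs that share them. The leaf count is
   bounded by the number of distinct haplotypes — at most two per diploid
   sample — so classification cost does not grow with the combinatorics
   of sites. All-reference paths produce no leaf.
3. **Spliced application.** The transcript's CDS segments are
   concatenated in transcript order, the 5'-most segment's phase is
   trimmed, and minus-strand transcripts are reverse-complemented. A
   haplotype's variants are applied jointly, right-to-left, so earlier
   edits never shift later coordinates.
4. **Compound grouping.** CDS variants of one haplotype are partitioned:
   two variants join a group when they touch the same codon *in the
   spliced frame* (this is what captures intron-split codons), or when
   both are frame-disturbing indels connected by a stretch in which the
   cumulative frameshift never returns to zero; any variant inside that
   stretch joins the chain. Grouping is transitive; everything else is a
   singleton.
5. **Classification by protein diff.** Each group is applied on its own
   and the reference and alternate proteins are compared by a minimal
   ungapped-ends diff (longest common prefix, then longest common suffix
   of the remainders). A group with net length change not divisible by 3
   is a `frameshift`. Otherwise, a changed single codon is `missense`; a
   multi-variant group with net-zero length change altering more than one
   codon is `inframe_altering`; net nonzero multiples of 3 are
   `inframe_deletion`/`inframe_insertion`, with a `missense` co-term when
   a flanking codon is substituted as well. Stop gain/loss is detected by
   comparing the position of the alternate protein's first stop against
   where the reference stop lands after the net length change; a change
   in residue 1 is `start_lost`; a silent change in the terminal stop
   codon is `stop_retained`. Non-CDS variants are classified by their
   most severe overlapping region (UTRs, intron, splice windows,
   non-coding exon).

In-frame changes are diffed on the full readthrough translations, so the
reported `aa_change` window is minimal even when a premature stop is
introduced; frameshifts are diffed on stop-truncated proteins, so the
reported run stops at the first novel stop.

### Assumptions

Phase is taken as given; the package performs no phasing inference.
Ploidy is 2 (haploid GTs contribute a single haplotype); symbolic and
breakend alleles are passed through unannotated with a warning. Input VCF
must be coordinate sorted. Overlapping transcripts of one gene are
reported separately, one consequence per transcript, which keeps the
output compositional rather than forcing a merge policy.

## Output encoding

All unique consequences of a site go into `INFO/BCSQ`
(`terms|gene|transcript|biotype|strand|aa_change|dna_change`). The
per-sample `FORMAT/BCSQ` integer has bit `2·i + h` set when consequence
`i` applies to haplotype `h`; interleaving haplotypes keeps the common
case (≤ 4 unique consequences) within 8 bits. The bit order — haplotype
in the low bit — is a documented convention of this implementation.
Masks are carried as doubles and are exact up to bit position 52, i.e. 26
unique consequences at one site; `encode_mask()` refuses anything
larger rather than silently losing precision. A compound consequence is
anchored at its leftmost member's site; other members write
`@<anchor_pos>` and share the anchor's per-sample bits.

## Tunable parameters

* `splice_exon` (default 3 bases) and `splice_intron` (default 8 bases):
  the exonic/intronic extent of the `splice_region` window around each
  junction, with the first/last 2 intronic bases always `splice_donor` /
  `splice_acceptor`. The defaults match common annotator practice; both
  are flags on the CLI.
* `strictness` for unphased heterozygotes: `require` (error; the
  default, since silent phase assumptions corrupt compound calls),
  `skip` (exclude that sample's haplotypes at that site from trees) or
  `take` (accept GT order as phase). Localized mode ignores phase
  entirely.
* `tag`: the INFO/FORMAT tag name, default `BCSQ`.

## Severity order

The term order, ascending — intergenic, intron, non_coding, 3_prime_utr,
5_prime_utr, coding_sequence, synonymous, stop_retained, missense,
splice_region, inframe_deletion, inframe_insertion, inframe_altering,
splice_acceptor, splice_donor, start_lost, stop_lost, stop_gained,
frameshift — is an explicit, test-pinned design choice modelled on
Sequence Ontology conventions. Only the existence of an order is forced
by the method (frame restoration must rank below frameshift, which the
order guarantees); the exact sequence is this package's documented
dialect, as annotators differ on the fine ranking.

## The synthetic-data generator and the oracle

`make_fixture()` writes a reference FASTA, GFF3 and phased VCF on a
single contig `chrT` (uppercase, GC fraction 0.5). Four deterministic
scenarios plant the compound cases on fixed filler codons so the outcome
is provable regardless of the random background: a `CAC` codon hit by
`C>T`/`C>G` giving `TAG` (whole-codon MNV, and the same codon split 2|1
across an intron); a −4/−2 deletion pair in a GCT (Ala) repeat; and a
1-bp insertion (`G>GA`) with a 1-bp deletion (`GA>G`) 12 bp downstream
in a GAA (Glu) repeat — the Glu filler guarantees matching reference
bases at both indels and no stop codon in any frame of the shifted
interval. Expected classifications in the manifest are computed at
generation time by the oracle, never hard-coded, since the altered
residue run depends on the local sequence. The `random` scenario draws
1–3-exon transcripts of mixed strand and phased SNVs/indels at a default
density of 8 variants per CDS kilobase across 4 samples — dense enough
that chained and same-codon groups actually occur — with variants kept
6 bases clear of segment edges and 12 bases apart so classifications are
comparable base by base.

What the fixtures deliberately do **not** emulate: switch errors and
statistical-phasing artefacts, population-scale allele-frequency
structure, multi-allelic sites, overlapping genes, trans-splicing, and
annotation dialect quirks beyond the Ensembl-style attribute chain.
Passing tests therefore demonstrate correctness of the coordinate
arithmetic and classification logic, not robustness to upstream phasing
error.

`oracle_consequence()` is the independent referee: it rebuilds the
*entire alternate chromosome*, shifts CDS boundaries past each indel,
re-extracts and re-splices the CDS, translates with its own hand-coded
codon table and classifies from the protein diff. It shares no
splicing, application, translation or classification code with the
engine. The equivalence suite compares the engine against the oracle per
compound group (the oracle run on exactly that group's variants):
a single global diff over a haplotype carrying several independent
variant clusters is not well-defined as one (terms, aa_change) pair, so
group-level comparison is the faithful granularity; the grouping rule
itself is pinned by direct unit tests.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open; GFF3 (1-based inclusive)
  and VCF POS (1-based) are converted only at the I/O edges.
* Alleles are normalized by trimming the shared suffix, then the shared
  prefix, keeping at least one base (idempotent); this makes indel pairs
  written in different but equivalent forms compare consistently.
* CDS phases are trusted at the 5'-most segment and recomputed (with a
  warning) when later segments disagree with cumulative length; CDS
  length not divisible by 3 after phase trimming drops the trailing
  remainder with a warning; a CDS not contained in any exon gets a
  synthesized covering exon; strand `.` is treated as `+` with a
  warning; transcripts whose trimmed CDS is shorter than one codon are
  demoted to non-coding.
* Variants overlapping on one haplotype (e.g. a deletion spanning a
  later SNV) resolve deterministically first-wins with an
  `overlap_conflict` warning; variants straddling a CDS/intron boundary
  are classified by their most severe overlapping region and excluded
  from codon-level grouping.
* Ties in severity cannot occur (the rank is a bijection); consequence
  order within a site is first-emission order, which is deterministic,
  so identical inputs produce byte-identical output.

## Problem sizes used in the checks

The test suite exercises: ≥ 500 engine-vs-oracle group comparisons over
~150 seeded random fixtures; 200 localized-vs-haplotype singleton cases;
100 haplotype-tree cases against a string-hashing brute force (up to 25
samples × 7 sites); 50 streaming-vs-global joins; 50 reverse-complement
mirror fixtures; full encode/decode round-trips for all masks below
2^16; and 20 seeds per scenario for the planted-scenario guarantees.
These sizes give each property multiple independent random draws while
keeping the default suite in the minutes range on one CPU.

## Known limitations

* Haplotype-aware calls are only as good as the input phase; with
  statistically phased data, switch errors translate directly into
  wrong compound groupings. The package neither detects nor models this.
* No protein-impact scoring, no regulatory annotation, no GTF input, no
  binary BCF output, ploidy ≤ 2 only.
* The `@anchor` cross-reference is by position; if several records share
  a position, the reference is ambiguous to downstream parsers (the
  annotation itself remains correct).
* Start-codon logic treats any change of residue 1 as `start_lost`; it
  does not search for downstream rescue AUGs.
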