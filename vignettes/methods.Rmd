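---
title: "Methods: splice-junction neoantigen evaluation with PHBR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splice-junction neoantigen evaluation with PHBR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A tumor alternative splicing event (ASE) is an exon–exon junction given
by its intron coordinates. All junction coordinates in this package use
the STAR `SJ.out.tab` convention — 1-based first and last intronic
base — because the aligner's junction catalog is the pipeline's only
junction source; event labels written as `chrom:start-end` elsewhere are
normalized to this convention on input.

The quantity the pipeline reports for an event is the Patient
Harmonic-mean Best Rank (PHBR). For one patient, each junction-spanning
peptide k-mer receives a binding rank percentile per HLA allele from a
predictor; per allele the *best* (minimum) rank over k-mers is kept, and
the per-allele bests $r_1,\dots,r_n$ are aggregated as the harmonic mean
$n / \sum_i 1/r_i$. The harmonic mean is dominated by its smallest term:
one allele that presents the peptide well keeps the patient-level score
low even if the other alleles do not, which is the intended biology — a
peptide needs only one presenting allele to be visible to T cells.
Homozygous class-I alleles are listed twice and counted twice, following
the PHBR method's convention, so a homozygous presenter weighs double.

Event-level scores are arithmetic means of per-sample PHBR over the
non-excluded expressing samples; the matched wild-type (WT) score is the
mean of the WT junction's k-mer PHBR evaluated against *every tumor
genotype* (the WT peptide is one sequence, but presentability varies by
patient). An event is a principal candidate when it binds (PHBR below
the relevant threshold), a WT alternative exists and binds *worse*
(larger PHBR), the event occurs in more than half the cohort, and the
upstream caller flagged outlier overexpression in at least one tumor.

## Stage-by-stage assumptions

**WT identification.** Among normal-sample junctions sharing the ASE's
start or end (never both — that is the ASE itself), the one expressed in
the most normal samples wins. "Expressed" means at least `min_reads`
uniquely-mapped reads (default 1); multimapped counts are ignored as the
conservative default. Ties break by total unique reads across normals,
then lexicographically by coordinates, making the result deterministic
and invariant to the order of the normal catalogs. Strand agreement is
required when both strands are known; unknown strands match anything.
Finding no WT alternative is a valid outcome, not an error — many
tumor-specific events simply have none.

**Read extraction.** A read supports the junction only if its CIGAR
contains a skipped-region (`N`) operation whose reference span equals
the intron exactly; reads that merely bridge the locus without the
splice carry no isoform information and are excluded. Mates of selected
reads are always included, even mates that themselves contradict the
junction — they extend the assembled contig into flanking exons.
Secondary/supplementary alignments and PCR duplicates are dropped by
default. In region mode, selection is a one-base closed-interval overlap
of the read's reference span with the region.

**Read boost.** Duplicating every extracted read `factor` times (the
conventional choice is 10) raises k-mer counts above the assembler's
coverage floor when junction coverage is sparse. Boosting fabricates no
new sequence; for error-free input it provably does not change the
contig set once coverage is above the floor (property-tested). It does
amplify any real sequencing error equally, so boosted assemblies of
noisy data deserve more skepticism — this is inherent to the approach.

**Assembly.** The built-in assembler builds a de Bruijn graph over
canonical k-mers (default k = 25, odd so no k-mer is its own reverse
complement), prunes k-mers seen fewer than twice (floor 1 when fewer
than 10 reads), collapses unbranched paths and emits every maximal
simple path. Output order is deterministic (length descending, then
lexicographic) and each contig is emitted in the orientation supported
by more read k-mers as given. The assembler exists so tests and
desk-scale runs need no external binary; any FASTA-in/FASTA-out
assembler can be swapped in through `external_assembler()` without
changing the downstream contract.

**Frame selection.** Each contig is translated in all six frames
(three when the strand is known and restriction is enabled), truncated
at the first stop codon, and scored by Smith–Waterman-style local
alignment against the WT protein with match +2, mismatch −5, gap open
−1 charged on the gap's first symbol and −0.5 per further symbol (a
length-1 gap costs 1, length-2 costs 1.5). Under this scoring a
substitution (−5) is dominated by a paired insertion/deletion (−2),
which is deliberate: frame choice should reward runs of identity, not
tolerate mismatches. Only the single best (contig, frame) pair per
sample survives — the rationale being that only one frame actually
produces protein in that sample, and choosing per sample lets genuine
sample-specific frame shifts surface. Ties prefer the longer peptide,
then the assembler's deterministic contig order. The alignment is
delegated to `Biostrings::pairwiseAlignment` with parameters that
reproduce this convention exactly; the test suite verifies exact score
equality against an independent brute-force affine-gap dynamic program
on random pairs.

**Breakpoint location.** Rather than whole-genome realignment, the
reference exonic flanks (default 100 nt each side of the intron) are
anchored in the contig without gaps (+1/−1 scoring). The junction
offset is where the upstream flank's best anchor ends; the two contig
nucleotides flanking that offset map through the chosen frame to one or
two adjacent peptide residues — the breakpoint residues. If either
flank scores below half its maximum (≈75% identity over the full
overlap), the breakpoint is unresolvable and the sample is excluded.
For an inserted sequence between the flanks, the breakpoint residues
cover the last upstream-encoded and first inserted-encoded residue.

**K-mer enumeration.** Junction mode keeps every peptide window of
length 8–11 (MHC-I) or 15 (MHC-II) containing *all* breakpoint
residues; region mode relaxes containment to one-residue overlap with
the region's residue range. Duplicate peptide strings are collapsed
before prediction. A peptide shorter than the smallest window is
excluded as `short_peptide`; a stop codon truncating the peptide before
any window can span the junction is excluded as `premature_stop`; no
assembled contig is `assembly_failure`. Excluded samples drop out of
all averages, and a group whose members are all excluded reports `NA`
rather than a number.

## Classification boundaries

Thresholds are strict as written: MHC-I strong < 0.5, weak < 2; MHC-II
strong < 1, relevant < 5. A score exactly at a boundary falls to the
weaker class, so PHBR = 2 is a non-binder. In the responder versus
nonresponder comparison, `binder_in_R_only` fires when responders bind
and the nonresponder average is either a non-binder or absent entirely;
`stronger_category_in_R` requires both averages and a strictly stronger
class on the order strong > weak/relevant > non. When reproducing
published responder-only counts, note that an absent (all-excluded)
nonresponder average is conventionally *not* counted as "no binding
seen" — the worked-example test intersects the flag with
nonresponder-average-present for that reason.

## Statistics

Expression-loss association uses a two-sided Fisher exact test per
event on the 2×2 of (lost vs maintained) × (responder vs nonresponder),
via the point-probability method: the p-value sums hypergeometric
probabilities of all tables no more probable than the observed one
(relative tie tolerance 1e-7, the conventional choice). Numerator
binomial coefficients are exact integers in double precision at the
margin sizes involved, so the enumeration is exact; degenerate margins
return p = 1 by convention. Adjustment across events is
Benjamini–Hochberg (`stats::p.adjust`), and a pooled test on the summed
table asks the cohort-level question.

## The synthetic cohort: what it does and does not emulate

`generate_cohort()` fabricates the complete input surface — reference
FASTA, spliced paired-end SAM alignments, STAR-style junction catalogs,
HLA genotypes, WT protein FASTA, event table — for genes with three
180-nt exons and 150-nt introns. Exon lengths are multiples of three so
the planted exon-skip stays in frame, coding sequence is built from
non-stop codons, reads are error-free 100-nt pairs (optional
substitution noise) tiled evenly so every k-mer in the assembled window
is covered at least twice, and every random choice is a deterministic
function of the seed (two runs with one seed are byte-identical).

This emulates the *structure* of real data, not its difficulty: there
are no alignment artifacts, no expression-level variation, no
multimapping, no fusion or antisense transcription, and the planted
reading frame is never genuinely ambiguous. A green end-to-end test
therefore establishes that the machinery is wired correctly — the
planted junction peptide and a planted rank come back exactly — and
says nothing about predictor quality or about robustness to noisy real
cohorts. Cohort-scale published numbers that depend on restricted
patient data and a neural binding predictor are out of reach at desk
scale by design; what the suite reproduces instead is the complete
classification and filtering structure of the published worked-example
tables from their printed PHBR values.

The mock predictor maps a stable 31-bit polynomial hash of
(peptide, allele, seed) into [0.05, 100], with a plant-override table,
so tests can place exact ranks while everything else stays deterministic
without any serialization or RNG-state dependence.

## Numerical and design choices

- Coordinates: STAR SJ convention everywhere; both shared-start and
  shared-end WT candidates compete in one pool (a `site` option forces
  per-site selection).
- The WT peptide derives from the WT junction's reference exon flanks;
  a user-supplied protein FASTA keyed by gene overrides the fallback
  (longest ORF of the flank concatenation) for frame scoring.
- Non-positive predictor ranks are clamped to 0.001 with a warning to
  keep the harmonic mean finite; a predictor returning *no* rank for a
  requested pair is a hard error, never silently imputed.
- Outlier-overexpression flags come from the upstream caller and are
  never recomputed; "has outlier overexpression" defaults to any
  flagged tumor (> 0), configurable.
- Unresolvable mates are logged and skipped rather than failing the
  sample.

## Known limitations

Breakpoint location by flank anchoring assumes the contig retains
recognizable flank sequence; heavily rearranged contigs are excluded
rather than rescued by realignment. The built-in assembler handles
desk-scale read sets; it is not a replacement for a production
assembler on deep data. Class-II allele pairing combinatorics are not
modeled — class-II alleles are taken as predictor-ready names. No
proteasomal-cleavage or TAP-transport modeling is included; the score
is rank aggregation only.
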