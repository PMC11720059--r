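# spliceneo

Splice-junction neoantigen candidate evaluation with Patient
Harmonic-mean Best Rank (PHBR) scores.

## The problem

Tumors with a low mutational burden can still present novel peptides when
aberrant splicing joins exons that are never joined in normal tissue. A
junction-spanning peptide from such a neojunction is a neoantigen
candidate if the patient's MHC molecules can present it — and it is an
especially attractive candidate when the corresponding *wild-type* (WT)
junction, the splice form normal tissue actually expresses, yields no
presentable peptide at all.

`spliceneo` evaluates a list of tumor splice events (e.g. the outlier
events an upstream caller such as OutSplice flags) end to end:

1. **WT identification** — from STAR `SJ.out.tab` catalogs of normal
   controls, find the most commonly expressed junction sharing the
   event's donor or acceptor site.
2. **Read extraction** — pull reads whose spliced CIGAR (`N` operation)
   matches the event's intron exactly, plus their mates; optionally
   duplicate them (read boost) when coverage is too thin to assemble.
3. **Assembly** — a small built-in de Bruijn assembler (or any external
   FASTA-to-FASTA assembler via an adapter) turns the reads into
   per-sample isoform contigs.
4. **Frame selection** — every contig is translated in all six frames and
   the frame with the best local alignment to the WT protein is kept
   (match +2, mismatch −5, gap −1 to open and −0.5 to extend), so
   sample-specific frame shifts are honored.
5. **Junction k-mers** — all peptide windows of MHC-I binding length
   (8–11; 15 for MHC-II) that span the junction breakpoint.
6. **PHBR** — each k-mer is ranked against every HLA allele of the
   patient (up to six class-I alleles, homozygotes counted twice) by a
   pluggable predictor; the per-allele best ranks `r_1..r_n` are
   aggregated as the harmonic mean

   ```
   PHBR = n / (1/r_1 + ... + 1/r_n)
   ```

   Lower is better. MHC-I events classify as strong (< 0.5), weak (< 2)
   or non-binders; MHC-II as strong (< 1), relevant (< 5) or non-binders.
7. **Candidate filtering and group comparison** — principal candidates
   bind (PHBR < 2), have a WT alternative with a *larger* PHBR, occur in
   a majority of tumors and show outlier overexpression. For
   treated cohorts, responder/nonresponder group averages, differential
   binding flags, and Fisher exact + Benjamini–Hochberg tests of
   expression loss are provided.

A deterministic mock rank predictor ships with the package so the whole
pipeline runs with no external tools; an adapter wraps a real
command-line predictor (e.g. netMHCpan-style rank output) for production
use.

## Worked example

Everything below is synthetic and seed-deterministic — the package can
fabricate a full desk-scale cohort (toy genome, spliced SAM reads, SJ
catalogs, HLA genotypes) to exercise itself:

```r
library(spliceneo)

co <- generate_cohort(seed = 42, n_tumor = 4, n_normal = 3)
cfg <- run_config(mode = "junction", mhc_class = "I",
                  events        = co$paths$events,
                  alignments_dir = co$paths$alignments_dir,
                  reference     = co$paths$reference,
                  genotypes     = co$paths$genotypes,
                  normals_sj_dir = co$paths$sj_dir,
                  wt_proteins   = co$paths$wt_proteins,
                  seed = 42)
res <- run_pipeline(cfg)
res$candidates
#>          event  ase_phbr  wt_phbr    best_peptide_hla pct_samples gene_symbol
#> 1 chr1:381-860 0.7947813 4.411663 SQHSVVDV HLA-B08:01           1       GENE1
#>   pct_outlier_oe binder_class principal
#> 1              1         weak      TRUE
res$wt_calls[[1]]
#> WTJunctionCall: chr1:381-530 (shared start; 3 normals, 21 reads)
```

Reading the row: the planted exon-skip junction `chr1:381-860` yields a
junction-spanning peptide in all four tumors (`pct_samples = 1`), with a
cohort-average PHBR of 0.79 — a weak MHC-I binder — while the WT
junction `chr1:381-530` (the canonical exon 1 to exon 2 splice, found
expressed in all 3 normals) averages PHBR 4.41, a non-binder. Because
the event binds, the WT binds worse, and the event is expressed and
outlier-overexpressed in a majority of tumors, it is flagged
`principal`. The best single peptide/allele combination across the
cohort is `SQHSVVDV` on `HLA-B08:01` (rank 0.071). Under the mock
predictor these ranks are arbitrary but reproducible; swap in a real
predictor via `external_rank_predictor()` for meaningful affinities.

`run_pipeline()` writes `candidates.tsv` (two-decimal PHBR, percentage
columns), `principal_candidates.tsv`, `exclusions.tsv` (per-sample
exclusion reasons: `assembly_failure`, `short_peptide`,
`premature_stop`, `breakpoint_unresolved`) and a `manifest.txt` into the
output directory.

A command-line wrapper with `run`, `wt-scan`, `score`, `simulate` and
`report` subcommands is installed at
`system.file("cli", "spliceneo", package = "spliceneo")`.

## Scope

The package consumes upstream outputs (aligner junctions, outlier flags,
HLA types) and delegates binding-rank prediction to an external tool or
the mock; it does not re-implement alignment, outlier detection, HLA
typing or a neural binding predictor. See `vignettes/methods.Rmd` for
the model, parameter and design discussion.
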