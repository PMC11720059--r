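# codons excluding the three stop codons, used to build open reading frames
NONSTOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# map a transcript interval [a,b] to genome CIGAR + position, given exon
# blocks (data.frame t_start, t_end, g_start)
transcript_to_cigar <- function(a, b, blocks) {
  ops <- character()
  pos <- NA_integer_
  for (i in seq_len(nrow(blocks))) {
    blk <- blocks[i, ]
    lo <- max(a, blk$t_start); hi <- min(b, blk$t_end)
    if (lo > hi) next
    gpos <- blk$g_start + (lo - blk$t_start)
    if (is.na(pos)) pos <- gpos
    if (length(ops)) {
      # intron gap between previous block end and this block start
      prev_end <- blocks$g_start[i - 1L] +
        (blocks$t_end[i - 1L] - blocks$t_start[i - 1L])
      ops <- c(ops, paste0(gpos - prev_end - 1L, "N"))
    }
    ops <- c(ops, paste0(hi - lo + 1L, "M"))
  }
  list(pos = pos, cigar = paste(ops, collapse = ""))
}

#' Generate a fully synthetic splice-neoantigen cohort
#'
#' Emits a toy genome of small multi-exon genes, tumor samples expressing
#' a planted aberrant junction (exon skipping) and normal samples
#' expressing the canonical junctions, as the file set the pipeline
#' consumes: reference FASTA, per-sample SAM alignments with spliced
#' CIGARs, STAR-style `SJ.out.tab` catalogs for the normals, an HLA
#' genotype table, a WT protein FASTA and an event table. Everything is
#' deterministic in `seed`.
#'
#' Genes have three exons of 180 nt separated by 150-nt introns; exon
#' lengths are multiples of three so the planted exon-skip product stays
#' in frame, and all coding sequence is built from non-stop codons. Reads
#' are error-free 100-nt pairs (configurable substitution noise), with
#' junction reads guaranteed at least a 10-nt overhang.
#'
#' @param seed Integer seed controlling every random choice.
#' @param n_tumor,n_normal Cohort sizes (>= 1).
#' @param events List of event specs: each
#'   `list(gene =, expressing_fraction =, oe_fraction =)`; default one
#'   fully expressed exon-skip event on gene 1.
#' @param dir Output directory (created).
#' @param n_genes Number of genes/chromosomes (default 2).
#' @param read_length,fragment_length Read geometry (default 100/220).
#' @param n_read_pairs Read pairs per expressing sample per event
#'   (default 12).
#' @param class1_per_patient Class-I alleles per tumor patient (1-6,
#'   default 6).
#' @param error_rate Per-base substitution probability (default 0).
#' @return A `SyntheticCohort` list: `dir`, `paths` (named file paths),
#'   `events` (planted `JunctionEvent`s), `wt_junctions`, `genes` (exon
#'   coordinates), `tumor_samples`, `normal_samples`,
#'   `expected_peptides` (per event: full ASE peptide, breakpoint
#'   residues, WT protein), and `seed`.
#' @export
generate_cohort <- function(seed, n_tumor, n_normal, events = NULL,
                            dir = tempfile("cohort"), n_genes = 2L,
                            read_length = 100L, fragment_length = 220L,
                            n_read_pairs = 12L, class1_per_patient = 6L,
                            error_rate = 0) {
  stopifnot(n_tumor >= 1L, n_normal >= 1L, n_genes >= 1L,
            class1_per_patient >= 1L, class1_per_patient <= 6L)
  if (is.null(events)) {
    events <- list(list(gene = 1L, expressing_fraction = 1,
                        oe_fraction = 1))
  }
  for (ev in events) {
    if (ev$gene < 1L || ev$gene > n_genes) {
      stop("event spec references gene ", ev$gene, " outside 1..", n_genes)
    }
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  dir.create(file.path(dir, "normals_sj"), showWarnings = FALSE)

  exon_len <- 180L; intron_len <- 150L; pad <- 200L
  tumor_samples <- sprintf("T%02d", seq_len(n_tumor))
  normal_samples <- sprintf("N%02d", seq_len(n_normal))

  with_seed(seed, {
    # --- genome & gene models ---------------------------------------------
    genes <- list()
    chrom_seq <- list()
    for (g in seq_len(n_genes)) {
      chrom <- paste0("chr", g)
      e1 <- pad + 1L
      starts <- e1 + (0:2) * (exon_len + intron_len)
      exons <- data.frame(start = starts, end = starts + exon_len - 1L)
      cds <- paste(sample(NONSTOP_CODONS, 3L * exon_len / 3L,
                          replace = TRUE), collapse = "")
      exon_seqs <- substring(cds, (0:2) * exon_len + 1L,
                             (1:3) * exon_len)
      chrom_len <- exons$end[3L] + pad
      seqv <- rep("A", chrom_len)
      # random intergenic/intronic background
      bg <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
      seqv <- bg
      for (i in 1:3) {
        seqv[exons$start[i]:exons$end[i]] <-
          strsplit(exon_seqs[i], "")[[1L]]
      }
      full_seq <- paste(seqv, collapse = "")
      genes[[g]] <- list(chrom = chrom, exons = exons, cds = cds,
                         gene_symbol = paste0("GENE", g),
                         wt_protein = as.character(
                           Biostrings::translate(Biostrings::DNAString(cds))))
      chrom_seq[[chrom]] <- full_seq
    }

    # --- planted events ----------------------------------------------------
    planted <- list()
    for (ei in seq_along(events)) {
      spec <- events[[ei]]
      gene <- genes[[spec$gene]]
      ex <- gene$exons
      ase_intron <- c(ex$end[1L] + 1L, ex$start[3L] - 1L)   # skip exon 2
      wt1 <- c(ex$end[1L] + 1L, ex$start[2L] - 1L)
      wt2 <- c(ex$end[2L] + 1L, ex$start[3L] - 1L)
      frac <- if (is.null(spec$expressing_fraction)) 1
              else spec$expressing_fraction
      oefrac <- if (is.null(spec$oe_fraction)) 1 else spec$oe_fraction
      n_expr <- round(frac * n_tumor)
      expr <- sort(sample(tumor_samples, n_expr))
      oe <- sort(sample(expr, round(oefrac * n_expr)))
      skip_tx <- paste0(substring(gene$cds, 1L, exon_len),
                        substring(gene$cds, 2L * exon_len + 1L))
      pep <- as.character(Biostrings::translate(
        Biostrings::DNAString(skip_tx)))
      br <- c(exon_len %/% 3L, exon_len %/% 3L + 1L)
      planted[[ei]] <- list(
        event = junction_event(gene$chrom, ase_intron[1L], ase_intron[2L],
                               strand = "+",
                               gene_symbol = gene$gene_symbol,
                               expressing_samples = expr,
                               outlier_oe_samples = oe),
        wt_junctions = list(
          junction_event(gene$chrom, wt1[1L], wt1[2L], strand = "+"),
          junction_event(gene$chrom, wt2[1L], wt2[2L], strand = "+")),
        gene = spec$gene,
        skip_transcript = skip_tx,
        expected_peptide = pep,
        breakpoint_residues = br,
        wt_protein = gene$wt_protein)
    }

    # --- reads -------------------------------------------------------------
    mutate_seq <- function(s) {
      if (error_rate <= 0) return(s)
      v <- strsplit(s, "")[[1L]]
      hit <- runif(length(v)) < error_rate
      if (any(hit)) {
        v[hit] <- vapply(v[hit], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, "")
      }
      paste(v, collapse = "")
    }
    sam_records <- setNames(vector("list", n_tumor + n_normal),
                            c(tumor_samples, normal_samples))
    sj_counts <- list()  # per normal sample: key -> count
    add_pair <- function(sample_id, qname, tx, blocks, offset) {
      r1 <- c(offset, offset + read_length - 1L)
      r2 <- c(offset + fragment_length - read_length,
              offset + fragment_length - 1L)
      recs <- lapply(list(c(r1, 99L), c(r2, 147L)), function(z) {
        cg <- transcript_to_cigar(z[1L], z[2L], blocks)
        seq <- mutate_seq(substring(tx, z[1L], z[2L]))
        sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t0\t%s\t*",
                qname, z[3L], blocks$chrom[1L], cg$pos, cg$cigar,
                cg$pos, seq)
      })
      sam_records[[sample_id]] <<- c(sam_records[[sample_id]], unlist(recs))
      # return junction keys spanned by either read, for SJ accounting
      keys <- character()
      for (z in list(r1, r2)) {
        cg <- transcript_to_cigar(z[1L], z[2L], blocks)
        introns <- cigar_introns(cg$pos, cg$cigar)
        if (nrow(introns)) {
          keys <- c(keys, paste(blocks$chrom[1L], introns[, 1L],
                                introns[, 2L], sep = "\t"))
        }
      }
      keys
    }
    blocks_for <- function(gene, exon_idx) {
      ex <- gene$exons[exon_idx, , drop = FALSE]
      widths <- ex$end - ex$start + 1L
      t_end <- cumsum(widths)
      data.frame(chrom = gene$chrom,
                 t_start = t_end - widths + 1L, t_end = t_end,
                 g_start = ex$start, stringsAsFactors = FALSE)
    }

    # tumor reads: aberrant skip transcript around the junction
    for (ei in seq_along(planted)) {
      pl <- planted[[ei]]
      gene <- genes[[pl$gene]]
      blocks <- blocks_for(gene, c(1L, 3L))
      jpos <- exon_len  # junction after this transcript base
      lo <- max(1L, jpos - read_length + 10L)
      hi <- min(jpos - 9L,
                nchar(pl$skip_transcript) - fragment_length + 1L)
      # even tiling: every junction-window k-mer is covered at least
      # twice, so the coverage-floor prune cannot split the contig
      offs <- round(seq(lo, hi, length.out = n_read_pairs))
      for (s in pl$event$expressing_samples) {
        for (i in seq_len(n_read_pairs)) {
          add_pair(s, sprintf("%s_e%d_r%03d", s, ei, i),
                   pl$skip_transcript, blocks, offs[i])
        }
      }
    }
    # normal reads: canonical transcript tiling both junctions
    for (s in normal_samples) {
      counts <- list()
      for (g in seq_len(n_genes)) {
        gene <- genes[[g]]
        blocks <- blocks_for(gene, 1:3)
        tx <- gene$cds
        max_off <- nchar(tx) - fragment_length + 1L
        offs <- unique(round(seq(1L, max_off,
                                 length.out = n_read_pairs)))
        for (i in seq_along(offs)) {
          keys <- add_pair(s, sprintf("%s_g%d_r%03d", s, g, i),
                           tx, blocks, offs[i])
          for (k in keys) {
            counts[[k]] <- (counts[[k]] %||% 0L) + 1L
          }
        }
      }
      sj_counts[[s]] <- counts
    }

    # --- write files -------------------------------------------------------
    ref_path <- file.path(dir, "ref.fasta")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(unlist(chrom_seq)), ref_path)

    sam_header <- c("@HD\tVN:1.6\tSO:coordinate",
                    vapply(names(chrom_seq), function(ch) {
                      sprintf("@SQ\tSN:%s\tLN:%d", ch,
                              nchar(chrom_seq[[ch]]))
                    }, ""))
    aln_paths <- setNames(character(0), character(0))
    for (s in c(tumor_samples, normal_samples)) {
      p <- file.path(dir, "alignments", paste0(s, ".sam"))
      recs <- sam_records[[s]] %||% character()
      writeLines(c(sam_header, recs), p)
      aln_paths[s] <- p
    }
    sj_paths <- character()
    for (s in normal_samples) {
      p <- file.path(dir, "normals_sj", paste0(s, ".SJ.out.tab"))
      counts <- sj_counts[[s]]
      keys <- sort(names(counts))
      lines <- vapply(keys, function(k) {
        parts <- strsplit(k, "\t", fixed = TRUE)[[1L]]
        sprintf("%s\t%s\t%s\t1\t1\t1\t%d\t0\t%d", parts[1L], parts[2L],
                parts[3L], counts[[k]], read_length %/% 2L)
      }, "")
      writeLines(lines, p)
      sj_paths[s] <- p
    }

    # --- genotypes ---------------------------------------------------------
    panel1 <- c("HLA-A01:01", "HLA-A02:01", "HLA-B07:02", "HLA-B08:01",
                "HLA-B27:05", "HLA-C04:01", "HLA-C07:01", "HLA-C07:02")
    panel2 <- c("DRB1_0101", "DRB1_0301", "DRB1_1501")
    geno_rows <- list()
    for (s in tumor_samples) {
      a1 <- sample(panel1, class1_per_patient, replace = TRUE)
      a2 <- sample(panel2, 2L, replace = TRUE)
      geno_rows[[s]] <- rbind(
        data.frame(patient_id = s, class = "I", allele = a1,
                   stringsAsFactors = FALSE),
        data.frame(patient_id = s, class = "II", allele = a2,
                   stringsAsFactors = FALSE))
    }
    geno_path <- file.path(dir, "genotypes.tsv")
    write.table(do.call(rbind, geno_rows), geno_path, sep = "\t",
                quote = FALSE, row.names = FALSE)

    # --- WT proteins -------------------------------------------------------
    prot_path <- file.path(dir, "wt_proteins.fasta")
    prots <- Biostrings::AAStringSet(vapply(genes, `[[`, "", "wt_protein"))
    names(prots) <- vapply(genes, `[[`, "", "gene_symbol")
    Biostrings::writeXStringSet(prots, prot_path)

    # --- events table ------------------------------------------------------
    ev_df <- do.call(rbind, lapply(planted, function(pl) {
      data.frame(chrom = pl$event$chrom,
                 intron_start = pl$event$intron_start,
                 intron_end = pl$event$intron_end,
                 strand = pl$event$strand,
                 gene = pl$event$gene_symbol,
                 expressing_samples =
                   paste(pl$event$expressing_samples, collapse = ","),
                 outlier_oe_samples =
                   paste(pl$event$outlier_oe_samples, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    ev_path <- file.path(dir, "events.tsv")
    write.table(ev_df, ev_path, sep = "\t", quote = FALSE,
                row.names = FALSE)

    structure(list(
      dir = dir,
      paths = list(reference = ref_path, events = ev_path,
                   genotypes = geno_path, wt_proteins = prot_path,
                   alignments = aln_paths, normals_sj = sj_paths,
                   sj_dir = file.path(dir, "normals_sj"),
                   alignments_dir = file.path(dir, "alignments")),
      events = lapply(planted, `[[`, "event"),
      wt_junctions = lapply(planted, `[[`, "wt_junctions"),
      genes = genes,
      tumor_samples = tumor_samples,
      normal_samples = normal_samples,
      expected_peptides = lapply(planted, function(pl) {
        list(peptide = pl$expected_peptide,
             breakpoint_residues = pl$breakpoint_residues,
             wt_protein = pl$wt_protein)
      }),
      seed = seed), class = "SyntheticCohort")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf(
    "SyntheticCohort (seed %d): %d tumors, %d normals, %d event(s) in %s\n",
    x$seed, length(x$tumor_samples), length(x$normal_samples),
    length(x$events), x$dir))
  invisible(x)
}

#' Bundled worked-example PHBR value tables
#'
#' Two small value tables used by the worked-example and acceptance tests:
#' the candidate summary of the oropharyngeal carcinoma (OPSCC) discovery
#' cohort (12 principal events: ASE and WT average PHBR, best
#' peptide/HLA, cohort percentages) and the responder/nonresponder
#' region-of-interest summary of the anti-PD1-treated melanoma cohort
#' (30 events: group-average PHBR per arm, one NA caused by a premature
#' stop codon). The classification and differential-binding logic in this
#' package reproduces the published categorical structure of both tables.
#'
#' @return List with data.frames `opscc` and `melanoma`.
#' @export
packaged_tables <- function() {
  p1 <- system.file("extdata", "opscc_candidates.tsv",
                    package = "spliceneo", mustWork = TRUE)
  p3 <- system.file("extdata", "melanoma_groups.tsv",
                    package = "spliceneo", mustWork = TRUE)
  list(opscc = read.delim(p1, stringsAsFactors = FALSE),
       melanoma = read.delim(p3, stringsAsFactors = FALSE))
}
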