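#' Build and validate a pipeline run configuration
#'
#' Collects every path and tunable the pipeline needs and validates the
#' paths up front (a missing input fails here, before any work). All
#' thresholds default to the published values: MHC-I binder classes at
#' PHBR 0.5/2 and k-mer sizes 8-11, MHC-II at 1/5 and size 15, 100-nt
#' reference flanks, read boost off (factor 1; 10 is the usual choice for
#' sparse region-of-interest data).
#'
#' @param mode `"junction"` (WT identification + junction-spanning
#'   k-mers) or `"region"` (region-of-interest workflow; WT step skipped,
#'   k-mers overlap the region).
#' @param mhc_class `"I"` or `"II"`.
#' @param events Path to the event TSV (see [read_event_table()]).
#' @param alignments_dir Directory of per-sample `<sample>.sam`/`.bam`.
#' @param reference Reference genome FASTA path.
#' @param genotypes HLA genotype TSV path.
#' @param normals_sj_dir Directory of normal-sample `SJ.out.tab` files
#'   (required in junction mode).
#' @param wt_proteins Optional WT protein FASTA keyed by gene symbol;
#'   when absent the WT protein falls back to the longest open reading
#'   frame of the WT (or event) flank concatenation.
#' @param output_dir Report/manifest directory (created).
#' @param predictor Rank predictor function; default
#'   `mock_rank_predictor(seed)`.
#' @param assembler `"builtin"` or a function `(reads) -> ContigSet`
#'   (see [external_assembler()]).
#' @param read_boost_factor Integer >= 1.
#' @param flank_length Reference flank length in nt (default 100).
#' @param assembly_k De Bruijn k-mer size (default 25).
#' @param min_reads Expression floor for WT identification (default 1).
#' @param restrict_strand Restrict translation frames to the junction
#'   strand when known.
#' @param min_pct_samples,min_pct_oe Principal-candidate thresholds.
#' @param seed Seed for the default mock predictor and manifest record.
#' @return A validated `RunConfig` list.
#' @export
run_config <- function(mode = c("junction", "region"),
                       mhc_class = c("I", "II"),
                       events, alignments_dir, reference, genotypes,
                       normals_sj_dir = NULL, wt_proteins = NULL,
                       output_dir = tempfile("spliceneo_run"),
                       predictor = NULL, assembler = "builtin",
                       read_boost_factor = 1L, flank_length = 100L,
                       assembly_k = 25L, min_reads = 1L,
                       restrict_strand = FALSE,
                       min_pct_samples = 0.5, min_pct_oe = 0,
                       seed = 1L) {
  mode <- match.arg(mode)
  mhc_class <- match.arg(mhc_class)
  need <- c(events = events, alignments_dir = alignments_dir,
            reference = reference, genotypes = genotypes)
  if (mode == "junction") {
    if (is.null(normals_sj_dir)) {
      stop("junction mode requires normals_sj_dir")
    }
    need <- c(need, normals_sj_dir = normals_sj_dir)
  }
  if (!is.null(wt_proteins)) need <- c(need, wt_proteins = wt_proteins)
  for (nm in names(need)) {
    if (!file.exists(need[[nm]])) {
      stop("config path does not exist (", nm, "): ", need[[nm]])
    }
  }
  if (read_boost_factor < 1L) stop("read_boost_factor must be >= 1")
  if (is.null(predictor)) predictor <- mock_rank_predictor(seed)
  structure(list(mode = mode, mhc_class = mhc_class,
                 class_mode = paste0("MHC-", mhc_class),
                 kmer_sizes = if (mhc_class == "I") 8:11 else 15L,
                 relevant_threshold = if (mhc_class == "I") 2 else 5,
                 events = events, alignments_dir = alignments_dir,
                 reference = reference, genotypes = genotypes,
                 normals_sj_dir = normals_sj_dir,
                 wt_proteins = wt_proteins, output_dir = output_dir,
                 predictor = predictor, assembler = assembler,
                 read_boost_factor = as.integer(read_boost_factor),
                 flank_length = as.integer(flank_length),
                 assembly_k = as.integer(assembly_k),
                 min_reads = as.integer(min_reads),
                 restrict_strand = restrict_strand,
                 min_pct_samples = min_pct_samples,
                 min_pct_oe = min_pct_oe, seed = as.integer(seed)),
            class = "RunConfig")
}

# reference slice helper (1-based closed coordinates, clipped to contig)
ref_slice <- function(ref, chrom, start, end) {
  if (!chrom %in% names(ref)) stop("contig not in reference: ", chrom)
  L <- Biostrings::width(ref[chrom])
  start <- max(1L, start); end <- min(L, end)
  if (start > end) return("")
  as.character(Biostrings::subseq(ref[[chrom]], start, end))
}

# longest ORF (between stops, any of 6 frames) of a nucleotide sequence
longest_orf_protein <- function(nt) {
  best <- ""
  for (f in c(1:3, -1:-3)) {
    tr <- translate_frame(nt, f)
    # translate_frame truncates at first stop; re-run on full frame
    s <- toupper(nt)
    if (f < 0) s <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    s <- substring(s, abs(f))
    n3 <- nchar(s) %/% 3L
    if (n3 == 0L) next
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substring(s, 1L, n3 * 3L))))
    for (frag in strsplit(aa, "*", fixed = TRUE)[[1L]]) {
      if (nchar(frag) > nchar(best)) best <- frag
    }
  }
  best
}

# locate a region's residue range inside an oriented call by anchoring the
# region sequence; returns c(lo, hi) residues or NULL when unresolved
region_residue_range <- function(call, region_seq) {
  s <- anchor_flank(call$contig, region_seq, side = "start")
  if (s$score < s$max_score / 2) return(NULL)
  lo_nt <- s$pos
  hi_nt <- min(nchar(call$contig), s$pos + nchar(region_seq) - 1L)
  r <- residues_for_nts(c(lo_nt, hi_nt), call$frame, nchar(call$contig))
  if (!length(r)) return(NULL)
  c(min(r), max(r))
}

find_alignment_file <- function(dir, sample) {
  for (ext in c(".sam", ".bam")) {
    p <- file.path(dir, paste0(sample, ext))
    if (file.exists(p)) return(p)
  }
  NULL
}

# score one sample for one event; returns list(result=PHBRResult|NULL,
# reason=NA|exclusion reason)
score_sample <- function(cfg, ref, ase, sample, wt_protein, up, dn,
                         genotype, region_seq = NULL) {
  aln <- find_alignment_file(cfg$alignments_dir, sample)
  if (is.null(aln)) return(list(result = NULL, reason = "no_alignment"))
  reads <- extract_reads(aln, ase, mode = cfg$mode, sample_id = sample)
  if (cfg$read_boost_factor > 1L && nrow(reads) > 0L) {
    reads <- boost_reads(reads, cfg$read_boost_factor)
  }
  contigs <- if (identical(cfg$assembler, "builtin")) {
    suppressWarnings(assemble_contigs(reads, k = cfg$assembly_k))
  } else {
    cfg$assembler(reads)
  }
  call <- select_best_isoform(contigs, wt_protein, strand = ase$strand,
                              restrict_strand = cfg$restrict_strand)
  if (call$excluded) return(list(result = NULL, reason = call$reason))
  region_residues <- NULL
  if (cfg$mode == "junction") {
    call <- locate_breakpoint(call, up, dn)
    if (call$excluded) return(list(result = NULL, reason = call$reason))
  } else {
    call <- orient_call(call)
    region_residues <- region_residue_range(call, region_seq)
    if (is.null(region_residues)) {
      return(list(result = NULL, reason = "breakpoint_unresolved"))
    }
  }
  ks <- junction_kmers(call, sizes = cfg$kmer_sizes,
                       class_mode = cfg$class_mode,
                       region_residues = region_residues)
  if (ks$excluded) return(list(result = NULL, reason = ks$reason))
  ks$event <- event_id(ase)
  list(result = sample_phbr(ks, genotype, cfg$predictor), reason = NA)
}

#' Run the full neoantigen evaluation pipeline
#'
#' For each event and expressing tumor sample: (junction mode) identify
#' the WT alternative junction from the normal catalogs, extract
#' junction-spanning reads and mates, optionally boost, assemble, select
#' the best-aligned reading frame, locate the breakpoint, enumerate
#' junction-spanning k-mers and score PHBR against the patient's HLA
#' genotype. WT junction k-mers (derived from the reference exon flanks
#' of the WT junction) are scored against every tumor genotype and
#' averaged. Event summaries then pass through the principal-candidate
#' filter and reports are written to the output directory.
#'
#' Per-sample failures are recorded as exclusions with their reason
#' (`assembly_failure`, `short_peptide`, `premature_stop`,
#' `breakpoint_unresolved`) and drop out of event averages; a hard error
#' in one event aborts only that event, and an empty final report is a
#' valid outcome.
#'
#' @param config A validated `RunConfig` from [run_config()].
#' @return List with `summaries` (per event), `candidates` (data.frame),
#'   `per_sample` (list of per-event `PHBRResult` lists), `wt_calls`,
#'   `exclusions` (data.frame event/sample/reason), `failed_events`, and
#'   `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  cfg <- config
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  events <- read_event_table(cfg$events)
  genos <- read_hla_table(cfg$genotypes)
  ref <- Biostrings::readDNAStringSet(cfg$reference)
  names(ref) <- sub("\\s.*$", "", names(ref))
  prot_db <- NULL
  if (!is.null(cfg$wt_proteins)) {
    aas <- Biostrings::readAAStringSet(cfg$wt_proteins)
    prot_db <- setNames(as.character(aas), sub("\\s.*$", "", names(aas)))
  }
  normals <- NULL
  if (cfg$mode == "junction") {
    sj_files <- sort(list.files(cfg$normals_sj_dir,
                                pattern = "\\.SJ\\.out\\.tab$",
                                full.names = TRUE))
    if (length(sj_files) == 0L) stop("no SJ.out.tab files in ",
                                     cfg$normals_sj_dir)
    normals <- lapply(sj_files, function(p) {
      parse_sj_file(p, sub("\\.SJ\\.out\\.tab$", "", basename(p)))
    })
  }
  cohort <- sort(names(genos))

  summaries <- list()
  per_sample_all <- list()
  wt_calls <- list()
  excl_rows <- list()
  failed <- character()

  for (ase in events) {
    eid <- event_id(ase)
    res <- tryCatch({
      flank <- cfg$flank_length
      up <- ref_slice(ref, ase$chrom, ase$intron_start - flank,
                      ase$intron_start - 1L)
      dn <- ref_slice(ref, ase$chrom, ase$intron_end + 1L,
                      ase$intron_end + flank)
      region_seq <- if (cfg$mode == "region") {
        ref_slice(ref, ase$chrom, ase$intron_start, ase$intron_end)
      } else NULL

      wt_call <- NULL
      wt_contig <- NULL
      if (cfg$mode == "junction") {
        wt_call <- identify_wt_junction(ase, normals,
                                        min_reads = cfg$min_reads)
        if (wt_call$found) {
          wj <- wt_call$wt_junction
          wt_up <- ref_slice(ref, wj$chrom, wj$intron_start - flank,
                             wj$intron_start - 1L)
          wt_dn <- ref_slice(ref, wj$chrom, wj$intron_end + 1L,
                             wj$intron_end + flank)
          wt_contig <- list(up = wt_up, dn = wt_dn)
        }
      }

      wt_protein <- if (!is.null(prot_db) && !is.na(ase$gene_symbol) &&
                        ase$gene_symbol %in% names(prot_db)) {
        prot_db[[ase$gene_symbol]]
      } else if (!is.null(wt_contig)) {
        longest_orf_protein(paste0(wt_contig$up, wt_contig$dn))
      } else {
        longest_orf_protein(paste0(up, dn))
      }
      if (!nzchar(wt_protein)) stop("no WT protein available for ", eid)

      expressing <- intersect(ase$expressing_samples, cohort)
      results <- list()
      n_excl <- 0L
      for (s in expressing) {
        out <- score_sample(cfg, ref, ase, s, wt_protein, up, dn,
                            genos[[s]], region_seq)
        if (is.null(out$result)) {
          n_excl <- n_excl + 1L
          excl_rows[[length(excl_rows) + 1L]] <-
            data.frame(event = eid, sample = s, reason = out$reason,
                       stringsAsFactors = FALSE)
          sn_log("event %s sample %s excluded: %s", eid, s, out$reason)
        } else {
          results[[s]] <- out$result
        }
      }

      wt_per_sample <- NULL
      if (!is.null(wt_contig)) {
        wt_seq <- paste0(wt_contig$up, wt_contig$dn)
        wt_contigs <- new_contig_set(
          data.frame(sequence = wt_seq, support = NA_integer_,
                     assembler_id = "reference-flanks",
                     stringsAsFactors = FALSE), "WT")
        wt_isoform <- select_best_isoform(wt_contigs, wt_protein)
        if (!wt_isoform$excluded) {
          wt_isoform <- locate_breakpoint(wt_isoform, wt_contig$up,
                                          wt_contig$dn)
        }
        if (!wt_isoform$excluded) {
          wks <- junction_kmers(wt_isoform, sizes = cfg$kmer_sizes,
                                class_mode = cfg$class_mode)
          if (!wks$excluded) {
            wks$event <- eid
            wt_per_sample <- lapply(cohort, function(p) {
              w <- wks; w$sample_id <- p
              sample_phbr(w, genos[[p]], cfg$predictor)
            })
          }
        }
      }

      summ <- summarize_event(unname(results), wt_per_sample,
                              cohort_size = length(cohort),
                              n_excluded = n_excl)
      summ$event <- eid
      summ$gene_symbol <- ase$gene_symbol
      summ$pct_outlier_oe <-
        length(intersect(ase$outlier_oe_samples, cohort)) / length(cohort)
      summ$wt_found <- !is.null(wt_call) && isTRUE(wt_call$found)
      list(summary = summ, per_sample = results, wt_call = wt_call)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, eid)
      sn_log("event %s failed: %s", eid, conditionMessage(res),
             level = "warn")
      next
    }
    summaries[[eid]] <- res$summary
    per_sample_all[[eid]] <- res$per_sample
    wt_calls[[eid]] <- res$wt_call
  }

  candidates <- filter_candidates(summaries,
                                  min_pct_samples = cfg$min_pct_samples,
                                  min_pct_oe = cfg$min_pct_oe,
                                  relevant_threshold = cfg$relevant_threshold)
  if (nrow(candidates)) {
    write_event_report(candidates, file.path(cfg$output_dir,
                                             "candidates.tsv"))
    principal <- candidates[candidates$principal, , drop = FALSE]
    if (nrow(principal)) {
      write_event_report(principal,
                         file.path(cfg$output_dir,
                                   "principal_candidates.tsv"))
    }
  }
  exclusions <- if (length(excl_rows)) do.call(rbind, excl_rows) else
    data.frame(event = character(), sample = character(),
               reason = character(), stringsAsFactors = FALSE)
  write.table(exclusions, file.path(cfg$output_dir, "exclusions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(cfg, failed, file.path(cfg$output_dir, "manifest.txt"))

  list(summaries = summaries, candidates = candidates,
       per_sample = per_sample_all, wt_calls = wt_calls,
       exclusions = exclusions, failed_events = failed,
       output_dir = cfg$output_dir)
}

write_manifest <- function(cfg, failed, path) {
  keys <- c("mode", "mhc_class", "events", "alignments_dir", "reference",
            "genotypes", "normals_sj_dir", "wt_proteins",
            "read_boost_factor", "flank_length", "assembly_k",
            "min_reads", "restrict_strand", "min_pct_samples",
            "min_pct_oe", "seed")
  lines <- c(paste0("package_version\t",
                    as.character(utils::packageVersion("spliceneo"))),
             paste0("kmer_sizes\t", paste(cfg$kmer_sizes, collapse = ",")),
             paste0("relevant_threshold\t", cfg$relevant_threshold),
             vapply(keys, function(k) {
               v <- cfg[[k]]
               paste0(k, "\t", if (is.null(v)) "" else as.character(v))
             }, ""),
             paste0("failed_events\t", paste(failed, collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}
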