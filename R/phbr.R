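#' Patient Harmonic-mean Best Rank
#'
#' Aggregates one best (minimum) binding rank per HLA allele into a single
#' patient-level presentation score: the harmonic mean
#' `n / sum(1 / r_i)`. The harmonic mean is dominated by the smallest rank,
#' so a peptide strongly presented on even one allele keeps a low (good)
#' PHBR, while a non-binding allele barely moves it.
#'
#' @param best_ranks Non-empty numeric vector of per-allele best rank
#'   percentiles; homozygous alleles appear twice. Ranks must be positive;
#'   non-positive values are clamped to 0.001 with a warning so the mean
#'   stays finite.
#' @return The PHBR score (positive numeric scalar).
#' @export
compute_phbr <- function(best_ranks) {
  if (length(best_ranks) == 0L) stop("best_ranks must be non-empty")
  if (any(is.na(best_ranks))) stop("best_ranks contains NA")
  if (any(best_ranks <= 0)) {
    warning("non-positive rank(s) clamped to 0.001")
    best_ranks[best_ranks <= 0] <- 0.001
  }
  length(best_ranks) / sum(1 / best_ranks)
}

#' Read patient HLA genotypes
#'
#' TSV with header columns `patient_id`, `class` (`"I"` or `"II"`),
#' `allele`. Class-I genotypes carry up to six alleles, homozygous alleles
#' listed twice; class-II alleles are predictor-ready names.
#'
#' @param path Genotype TSV path.
#' @return Named list of `HLAGenotype` objects (one per patient), each with
#'   `patient_id`, `class1_alleles`, `class2_alleles`.
#' @export
read_hla_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "class", "allele")
  if (!all(need %in% names(df))) {
    stop("genotype table needs columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(df, df$patient_id), function(d) {
    g <- hla_genotype(d$patient_id[1L],
                      class1_alleles = d$allele[d$class == "I"],
                      class2_alleles = d$allele[d$class == "II"])
    g
  })
  out[order(names(out))]
}

#' Construct an HLA genotype
#'
#' @param patient_id Patient identifier.
#' @param class1_alleles Class-I allele names (1-6, duplicates meaningful).
#' @param class2_alleles Class-II allele names (may be empty).
#' @return An `HLAGenotype` object.
#' @export
hla_genotype <- function(patient_id, class1_alleles,
                         class2_alleles = character()) {
  class1_alleles <- as.character(class1_alleles)
  if (length(class1_alleles) < 1L || length(class1_alleles) > 6L) {
    stop("class1_alleles must have 1-6 entries")
  }
  if (any(!nzchar(c(class1_alleles, class2_alleles)))) {
    stop("allele names must be non-empty")
  }
  structure(list(patient_id = as.character(patient_id),
                 class1_alleles = class1_alleles,
                 class2_alleles = as.character(class2_alleles)),
            class = "HLAGenotype")
}

# alleles for a class mode; errors when a class-II run has no alleles
genotype_alleles <- function(genotype, class_mode) {
  al <- if (class_mode == "MHC-I") genotype$class1_alleles
        else genotype$class2_alleles
  if (length(al) == 0L) {
    stop("patient ", genotype$patient_id, " has no ", class_mode, " alleles")
  }
  al
}

#' Score a k-mer set against one patient's HLA genotype
#'
#' Runs every (k-mer, allele) pair through the rank predictor, takes the
#' best (minimum) rank per allele, and aggregates with [compute_phbr()].
#' Homozygous alleles are listed twice in the genotype and therefore count
#' twice in the harmonic mean. The reported best peptide/allele is the pair
#' attaining the global minimum rank (ties: lexicographic peptide, then
#' allele).
#'
#' @param kmers A non-excluded `KmerSet`.
#' @param genotype An `HLAGenotype`.
#' @param predictor A rank predictor: `function(peptides, alleles)`
#'   returning a data.frame `peptide, allele, rank` covering the full
#'   cross-product (see [mock_rank_predictor()]).
#' @return A `PHBRResult` with `phbr`, `best_peptide`, `best_allele`,
#'   `best_rank`, `per_allele_best`, `class_mode`, `sample_id`.
#' @export
sample_phbr <- function(kmers, genotype, predictor) {
  stopifnot(inherits(kmers, "KmerSet"), inherits(genotype, "HLAGenotype"))
  if (kmers$excluded || nrow(kmers$kmers) == 0L) {
    stop("cannot score an excluded/empty KmerSet")
  }
  alleles <- genotype_alleles(genotype, kmers$class_mode)
  peptides <- unique(kmers$kmers$peptide)
  tab <- predictor(peptides, unique(alleles))
  key <- paste(tab$peptide, tab$allele, sep = "\r")
  lookup <- setNames(tab$rank, key)
  per_allele <- vapply(seq_along(alleles), function(i) {
    r <- lookup[paste(peptides, alleles[i], sep = "\r")]
    if (any(is.na(r))) {
      miss <- peptides[which(is.na(r))[1L]]
      stop("predictor returned no rank for (", miss, ", ", alleles[i], ")")
    }
    min(r)
  }, numeric(1))
  names(per_allele) <- alleles
  # global best pair with deterministic tie-break
  grid <- expand.grid(peptide = peptides, allele = unique(alleles),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rank <- lookup[paste(grid$peptide, grid$allele, sep = "\r")]
  ord <- order(grid$rank, grid$peptide, grid$allele)
  best <- grid[ord[1L], ]
  structure(list(event = kmers$event,
                 sample_id = kmers$sample_id,
                 phbr = compute_phbr(unname(per_allele)),
                 best_peptide = best$peptide,
                 best_allele = best$allele,
                 best_rank = best$rank,
                 per_allele_best = per_allele,
                 class_mode = kmers$class_mode),
            class = "PHBRResult")
}

#' @export
print.PHBRResult <- function(x, ...) {
  cat(sprintf("PHBRResult '%s' (%s): PHBR %.4g, best %s / %s (rank %.3g)\n",
              x$sample_id, x$class_mode, x$phbr, x$best_peptide,
              x$best_allele, x$best_rank))
  invisible(x)
}

#' Classify a PHBR score into binder categories
#'
#' MHC-I: strong `< 0.5`, weak `< 2`, non-binder otherwise (a score of
#' exactly 2 is a non-binder). MHC-II: strong `< 1`, relevant `< 5`,
#' non-binder otherwise. Thresholds are strict: a value exactly at a
#' boundary falls into the weaker class.
#'
#' @param phbr Positive PHBR score (vectorized).
#' @param class_mode `"MHC-I"` or `"MHC-II"`.
#' @return Character vector in `c("strong", "weak", "non")` for MHC-I or
#'   `c("strong", "relevant", "non")` for MHC-II.
#' @export
classify_binder <- function(phbr, class_mode = c("MHC-I", "MHC-II")) {
  class_mode <- match.arg(class_mode)
  stopifnot(all(phbr > 0, na.rm = TRUE))
  if (class_mode == "MHC-I") {
    ifelse(phbr < 0.5, "strong", ifelse(phbr < 2, "weak", "non"))
  } else {
    ifelse(phbr < 1, "strong", ifelse(phbr < 5, "relevant", "non"))
  }
}

# numeric strength for ordering binder classes (strong > weak/relevant > non)
binder_strength <- function(class) {
  unname(c(strong = 3L, weak = 2L, relevant = 2L, non = 1L)[class])
}

#' Summarize PHBR results for one event across the cohort
#'
#' The event-level (ASE) average PHBR is the arithmetic mean over
#' non-excluded expressing samples; the WT average is the mean of the WT
#' k-mers' PHBR scored against every tumor genotype. `pct_samples` is the
#' fraction of the cohort that both expresses the event and yielded a
#' junction-spanning peptide of scoreable length.
#'
#' @param per_sample List of `PHBRResult` for the ASE (excluded samples
#'   already dropped).
#' @param wt_per_sample List of `PHBRResult` for the WT junction k-mers
#'   scored per tumor genotype, or `NULL` when no WT junction was found.
#' @param cohort_size Number of tumor samples in the cohort.
#' @param n_excluded Number of expressing samples dropped by exclusions.
#' @return An `EventSummary` list: `ase_phbr`, `wt_phbr` (NA when absent),
#'   `best_peptide`, `best_allele`, `pct_samples`, `n_samples`,
#'   `n_excluded`, `class_mode`, `unreportable`.
#' @export
summarize_event <- function(per_sample, wt_per_sample = NULL, cohort_size,
                            n_excluded = 0L) {
  if (length(per_sample) == 0L) {
    return(structure(list(ase_phbr = NA_real_, wt_phbr = NA_real_,
                          best_peptide = NA_character_,
                          best_allele = NA_character_,
                          pct_samples = 0, n_samples = 0L,
                          n_excluded = n_excluded,
                          class_mode = NA_character_, unreportable = TRUE),
                     class = "EventSummary"))
  }
  phbrs <- vapply(per_sample, `[[`, numeric(1), "phbr")
  ranks <- vapply(per_sample, `[[`, numeric(1), "best_rank")
  ord <- order(ranks,
               vapply(per_sample, `[[`, character(1), "best_peptide"),
               vapply(per_sample, `[[`, character(1), "best_allele"))
  best <- per_sample[[ord[1L]]]
  wt <- if (length(wt_per_sample)) {
    mean(vapply(wt_per_sample, `[[`, numeric(1), "phbr"))
  } else NA_real_
  structure(list(ase_phbr = mean(phbrs),
                 wt_phbr = wt,
                 best_peptide = best$best_peptide,
                 best_allele = best$best_allele,
                 pct_samples = length(per_sample) / cohort_size,
                 n_samples = length(per_sample),
                 n_excluded = as.integer(n_excluded),
                 class_mode = per_sample[[1L]]$class_mode,
                 unreportable = FALSE),
            class = "EventSummary")
}
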