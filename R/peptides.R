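#' Translate a contig in one reading frame
#'
#' Frames `+1,+2,+3` translate the sequence as given starting at offsets
#' 1..3; `-1,-2,-3` translate the reverse complement at the same offsets.
#' Translation uses the standard genetic code and stops being reported at
#' the first stop codon.
#'
#' @param sequence DNA string over ACGT(N).
#' @param frame Integer in `c(1:3, -1:-3)`.
#' @return List with `peptide` (up to but excluding the first stop),
#'   `premature_stop` (TRUE when a stop codon occurs before the end of the
#'   frame) and `full_length` (residues the frame could encode, ignoring
#'   stops).
#' @export
translate_frame <- function(sequence, frame) {
  stopifnot(frame %in% c(1:3, -1:-3))
  s <- toupper(sequence)
  if (frame < 0) {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  off <- abs(frame)
  s <- substring(s, off)
  n3 <- nchar(s) %/% 3L
  if (n3 == 0L) {
    return(list(peptide = "", premature_stop = FALSE, full_length = 0L))
  }
  s <- substring(s, 1L, n3 * 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           if.fuzzy.codon = "solve"))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) {
    list(peptide = substring(aa, 1L, stop_at - 1L),
         premature_stop = stop_at < nchar(aa),
         full_length = n3)
  } else {
    list(peptide = aa, premature_stop = FALSE, full_length = n3)
  }
}

new_isoform_call <- function(sample_id, contig = NA_character_,
                             frame = NA_integer_, peptide = NA_character_,
                             alignment_score = NA_real_,
                             breakpoint_nt = NA_integer_,
                             breakpoint_residues = integer(),
                             premature_stop = FALSE,
                             excluded = FALSE, reason = NA_character_) {
  structure(list(sample_id = sample_id, contig = contig, frame = frame,
                 peptide = peptide, alignment_score = alignment_score,
                 breakpoint_nt = breakpoint_nt,
                 breakpoint_residues = breakpoint_residues,
                 premature_stop = premature_stop,
                 excluded = excluded, reason = reason),
            class = "IsoformCall")
}

#' @export
print.IsoformCall <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("IsoformCall '%s': excluded (%s)\n", x$sample_id, x$reason))
  } else {
    cat(sprintf(
      "IsoformCall '%s': frame %+d, score %.1f, peptide %d aa%s\n",
      x$sample_id, x$frame, x$alignment_score, nchar(x$peptide),
      if (length(x$breakpoint_residues))
        paste0(", breakpoint residues ",
               paste(x$breakpoint_residues, collapse = ","))
      else ""))
  }
  invisible(x)
}

#' Select the per-sample isoform by best alignment to the WT protein
#'
#' Each contig is translated in all permitted reading frames (six by
#' default; the three frames of the junction strand when `strand` is
#' supplied and restriction is requested), translation is truncated at the
#' first stop codon, and the (contig, frame) pair whose peptide attains
#' the best [local_align()] score against the wild-type protein is
#' retained. Only one frame truly produces protein in the sample, and the
#' WT alignment is the evidence for which one it is; this also lets
#' sample-specific frame shifts be picked up. Ties are broken by longer
#' peptide, then by contig order (the assembler's deterministic order),
#' then by frame order.
#'
#' @param contigs A `ContigSet` (possibly empty).
#' @param wt_protein Non-empty WT protein string.
#' @param strand `"+"`, `"-"` or `"*"`; used only when
#'   `restrict_strand = TRUE`.
#' @param restrict_strand Translate only the junction strand's three
#'   frames when the strand is known.
#' @return An `IsoformCall`; `excluded = TRUE` with reason
#'   `"assembly_failure"` when no contigs were provided.
#' @export
select_best_isoform <- function(contigs, wt_protein, strand = "*",
                                restrict_strand = FALSE) {
  if (!nzchar(wt_protein)) stop("wt_protein must be non-empty")
  sample_id <- attr(contigs, "sample_id")
  if (is.null(sample_id)) sample_id <- NA_character_
  if (NROW(contigs) == 0L) {
    return(new_isoform_call(sample_id, excluded = TRUE,
                            reason = "assembly_failure"))
  }
  frames <- c(1:3, -1:-3)
  if (restrict_strand && strand %in% c("+", "-")) {
    frames <- if (strand == "+") 1:3 else -1:-3
  }
  best <- NULL
  for (ci in seq_len(nrow(contigs))) {
    for (f in frames) {
      tr <- translate_frame(contigs$sequence[ci], f)
      if (!nzchar(tr$peptide)) next
      sc <- local_align(tr$peptide, wt_protein)$score
      cand <- list(ci = ci, frame = f, peptide = tr$peptide, score = sc,
                   premature_stop = tr$premature_stop)
      if (is.null(best) ||
          sc > best$score ||
          (sc == best$score && nchar(cand$peptide) > nchar(best$peptide))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(new_isoform_call(sample_id, excluded = TRUE,
                            reason = "assembly_failure"))
  }
  new_isoform_call(sample_id,
                   contig = contigs$sequence[best$ci],
                   frame = best$frame,
                   peptide = best$peptide,
                   alignment_score = best$score,
                   premature_stop = best$premature_stop)
}

# orient the call's contig so the chosen frame is forward; returns the call
# with contig possibly reverse-complemented and frame made positive
orient_call <- function(call) {
  if (!is.na(call$frame) && call$frame < 0) {
    call$contig <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(call$contig)))
    call$frame <- -call$frame
  }
  call
}

#' Locate the junction breakpoint inside a selected contig
#'
#' The reference exonic flanks immediately upstream and downstream of the
#' intron are anchored in the contig without gaps (match +1 / mismatch -1).
#' `breakpoint_nt` is the 0-based offset at which the upstream flank ends;
#' the two nucleotides flanking the junction are contig positions
#' `breakpoint_nt` and `breakpoint_nt + 1` (1-based), and
#' `breakpoint_residues` are the 1-2 adjacent peptide positions whose
#' codons cover them in the selected frame. If either flank scores below
#' half its maximum the call is excluded with reason
#' `"breakpoint_unresolved"`.
#'
#' Negative-strand calls are normalized first ([orient_call()]), so flanks
#' must be supplied in the contig's oriented sense.
#'
#' @param call A non-excluded `IsoformCall`.
#' @param upstream_flank,downstream_flank Reference exon sequence directly
#'   before/after the intron (>= 20 nt each).
#' @return The `IsoformCall` with breakpoint fields populated (or excluded).
#' @export
locate_breakpoint <- function(call, upstream_flank, downstream_flank) {
  stopifnot(inherits(call, "IsoformCall"))
  if (call$excluded) stop("cannot locate breakpoint on an excluded call")
  if (nchar(upstream_flank) < 20L || nchar(downstream_flank) < 20L) {
    stop("flanks must be at least 20 nt")
  }
  call <- orient_call(call)
  up <- anchor_flank(call$contig, toupper(upstream_flank), side = "end")
  dn <- anchor_flank(call$contig, toupper(downstream_flank), side = "start")
  if (up$score < up$max_score / 2 || dn$score < dn$max_score / 2) {
    call$excluded <- TRUE
    call$reason <- "breakpoint_unresolved"
    return(call)
  }
  call$breakpoint_nt <- up$pos  # nt of contig preceding the junction
  call$breakpoint_residues <- residues_for_nts(
    c(up$pos, up$pos + 1L), call$frame, nchar(call$contig))
  call
}

# peptide residue indices (1-based, frame-relative) covering given contig
# nucleotide positions; positions outside the frame are dropped
residues_for_nts <- function(nts, frame, contig_len) {
  stopifnot(frame %in% 1:3)
  nts <- nts[nts >= frame & nts <= contig_len]
  r <- ((nts - frame) %/% 3L) + 1L
  sort(unique(r))
}

new_kmer_set <- function(sample_id, kmers, class_mode,
                         excluded = FALSE, reason = NA_character_,
                         event = NA_character_) {
  structure(list(event = event, sample_id = sample_id, kmers = kmers,
                 class_mode = class_mode, excluded = excluded,
                 reason = reason),
            class = "KmerSet")
}

#' @export
print.KmerSet <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("KmerSet '%s' (%s): excluded (%s)\n", x$sample_id,
                x$class_mode, x$reason))
  } else {
    cat(sprintf("KmerSet '%s' (%s): %d k-mers\n", x$sample_id,
                x$class_mode, nrow(x$kmers)))
  }
  invisible(x)
}

#' Enumerate junction-spanning peptide k-mers
#'
#' All substrings of the selected peptide with length in `sizes` that
#' contain every breakpoint residue (junction mode), deduplicated by
#' peptide string. For the region-of-interest workflow the containment
#' condition is relaxed to overlapping the region's residue range by at
#' least one position. MHC-I uses sizes 8-11, MHC-II size 15.
#'
#' A peptide too short for the smallest size, or truncated by a stop codon
#' before any window can span the junction, yields an excluded `KmerSet`
#' with reason `"short_peptide"` or `"premature_stop"` respectively; these
#' are the exclusions later dropped from event averages.
#'
#' @param call An `IsoformCall` with breakpoint fields populated.
#' @param sizes Integer vector of k-mer lengths, default `8:11`.
#' @param class_mode `"MHC-I"` or `"MHC-II"` (label carried on the result).
#' @param region_residues Optional `c(lo, hi)` residue range for region
#'   mode; when supplied, overlap replaces breakpoint containment.
#' @return A `KmerSet` whose `kmers` data.frame has columns `peptide`,
#'   `start`, `length`.
#' @export
junction_kmers <- function(call, sizes = 8:11,
                           class_mode = c("MHC-I", "MHC-II"),
                           region_residues = NULL) {
  class_mode <- match.arg(class_mode)
  stopifnot(inherits(call, "IsoformCall"))
  if (call$excluded) stop("cannot enumerate k-mers for an excluded call")
  sizes <- sort(unique(as.integer(sizes)))
  pep <- call$peptide
  L <- nchar(pep)
  empty <- data.frame(peptide = character(), start = integer(),
                      length = integer(), stringsAsFactors = FALSE)
  if (L < min(sizes)) {
    return(new_kmer_set(call$sample_id, empty, class_mode, excluded = TRUE,
                        reason = "short_peptide"))
  }
  if (is.null(region_residues)) {
    br <- call$breakpoint_residues
    if (!length(br)) stop("breakpoint_residues not populated")
    lo <- min(br); hi <- max(br)
    contain <- TRUE
  } else {
    lo <- min(region_residues); hi <- max(region_residues)
    contain <- FALSE
  }
  rows <- list()
  for (k in sizes) {
    if (k > L) next
    starts <- seq_len(L - k + 1L)
    ok <- if (contain) {
      starts <= lo & (starts + k - 1L) >= hi
    } else {
      starts <= hi & (starts + k - 1L) >= lo
    }
    if (any(ok)) {
      s <- starts[ok]
      rows[[length(rows) + 1L]] <-
        data.frame(peptide = substring(pep, s, s + k - 1L),
                   start = s, length = k, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    reason <- if (isTRUE(call$premature_stop)) "premature_stop"
              else "short_peptide"
    return(new_kmer_set(call$sample_id, empty, class_mode, excluded = TRUE,
                        reason = reason))
  }
  km <- do.call(rbind, rows)
  km <- km[!duplicated(km$peptide), , drop = FALSE]
  rownames(km) <- NULL
  new_kmer_set(call$sample_id, km, class_mode)
}
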