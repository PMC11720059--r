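# SAM flag bits
FLAG_PAIRED <- 0x1L
FLAG_UNMAPPED <- 0x4L
FLAG_REVERSE <- 0x10L
FLAG_FIRST <- 0x40L
FLAG_SECOND <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_DUP <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Read a SAM (or BAM) alignment file
#'
#' Parses the text SAM format directly; a `.bam` input is converted with
#' `Rsamtools::asSam()` first. Only the fields the pipeline needs are kept.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return List with `header` (character vector of header lines, possibly
#'   empty), `contigs` (reference names declared by `@SQ` lines) and
#'   `reads` (data.frame: qname, flag, rname, pos, cigar, seq).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (tolower(tools::file_ext(path)) == "bam") {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("reading BAM requires the Rsamtools package")
    }
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asSam(path, dest)
  }
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  contigs <- character()
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq)) {
    contigs <- sub("^SN:", "", regmatches(sq, regexpr("SN:[^\t]+", sq)))
  }
  if (length(body) == 0L) {
    reads <- data.frame(qname = character(), flag = integer(),
                        rname = character(), pos = integer(),
                        cigar = character(), seq = character(),
                        stringsAsFactors = FALSE)
    return(list(header = hdr, contigs = contigs, reads = reads))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 11L)
  if (length(bad)) {
    stop(sprintf("malformed SAM record at body line %d: %d fields", bad[1L],
                 nf[bad[1L]]))
  }
  g <- function(i) vapply(fields, `[[`, "", i)
  reads <- data.frame(
    qname = g(1L),
    flag = as.integer(g(2L)),
    rname = g(3L),
    pos = as.integer(g(4L)),
    cigar = g(6L),
    seq = toupper(g(10L)),
    stringsAsFactors = FALSE)
  list(header = hdr, contigs = contigs, reads = reads)
}

# Parse a CIGAR string into op/length vectors; "*" -> zero-length result.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    return(list(op = character(), len = integer()))
  }
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  toks <- regmatches(cigar, list(m))[[1L]]
  if (sum(nchar(toks)) != nchar(cigar)) stop("bad CIGAR: ", cigar)
  list(op = substring(toks, nchar(toks), nchar(toks)),
       len = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}

# Reference span consumed by an alignment (M/D/N/=/X ops).
cigar_ref_width <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")])
}

# Intron intervals implied by N operations: matrix with columns start,end
# (1-based first/last skipped base), possibly zero rows.
cigar_introns <- function(pos, cigar) {
  cg <- parse_cigar(cigar)
  out <- matrix(integer(), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  ref <- pos
  for (i in seq_along(cg$op)) {
    op <- cg$op[i]; len <- cg$len[i]
    if (op == "N") {
      out <- rbind(out, c(ref, ref + len - 1L))
    }
    if (op %in% c("M", "D", "N", "=", "X")) ref <- ref + len
  }
  out
}

#' Extract junction-spanning or region-overlapping reads with their mates
#'
#' In `junction` mode a read is selected iff its CIGAR contains a skipped
#' region (`N` operation) whose reference span equals the event's intron
#' exactly; reads merely bridging the locus without the splice are not
#' isoform evidence and are excluded. In `region` mode a read is selected
#' iff its reference span overlaps the target interval by at least one
#' base. In both modes the mate of every selected read is included
#' regardless of its own placement; unresolvable mates are logged and
#' skipped.
#'
#' Secondary and supplementary alignments and PCR-duplicate-flagged reads
#' are dropped up front (configurable).
#'
#' @param alignments Result of [read_sam()], or a path to a SAM/BAM file.
#' @param target A `JunctionEvent` (junction mode) or, in region mode, any
#'   object with `chrom`, `intron_start`, `intron_end` interpreted as the
#'   region's 1-based closed interval.
#' @param mode `"junction"` or `"region"`.
#' @param sample_id Sample label for the resulting `ReadSet`.
#' @param keep_secondary,keep_duplicates Keep flagged records (default
#'   FALSE).
#' @return A `ReadSet`: data.frame (qname, mate, seq, cigar, pos, selected)
#'   with attributes `sample_id` and `source_mode`.
#' @export
extract_reads <- function(alignments, target,
                          mode = c("junction", "region"),
                          sample_id = "sample",
                          keep_secondary = FALSE, keep_duplicates = FALSE) {
  mode <- match.arg(mode)
  if (is.character(alignments)) alignments <- read_sam(alignments)
  reads <- alignments$reads
  if (length(alignments$contigs) &&
      !(target$chrom %in% alignments$contigs)) {
    stop("target contig not in alignment header: ", target$chrom)
  }
  if (nrow(reads)) {
    drop <- rep(FALSE, nrow(reads))
    if (!keep_secondary) {
      drop <- drop | has_flag(reads$flag, FLAG_SECONDARY) |
        has_flag(reads$flag, FLAG_SUPPLEMENTARY)
    }
    if (!keep_duplicates) drop <- drop | has_flag(reads$flag, FLAG_DUP)
    reads <- reads[!drop, , drop = FALSE]
  }
  mate_of <- function(flag) {
    ifelse(!has_flag(flag, FLAG_PAIRED), 0L,
           ifelse(has_flag(flag, FLAG_FIRST), 1L, 2L))
  }
  if (nrow(reads) == 0L) {
    return(new_read_set(empty_reads_df(), sample_id, mode))
  }
  reads$mate <- mate_of(reads$flag)
  mapped <- !has_flag(reads$flag, FLAG_UNMAPPED) & reads$rname == target$chrom

  sel <- rep(FALSE, nrow(reads))
  if (mode == "junction") {
    for (i in which(mapped)) {
      introns <- cigar_introns(reads$pos[i], reads$cigar[i])
      if (nrow(introns) &&
          any(introns[, "start"] == target$intron_start &
              introns[, "end"] == target$intron_end)) {
        sel[i] <- TRUE
      }
    }
  } else {
    for (i in which(mapped)) {
      w <- cigar_ref_width(reads$cigar[i])
      if (w == 0L) next
      s <- reads$pos[i]; e <- reads$pos[i] + w - 1L
      if (s <= target$intron_end && e >= target$intron_start) sel[i] <- TRUE
    }
  }
  if (!any(sel)) {
    return(new_read_set(empty_reads_df(), sample_id, mode))
  }
  # include mates of selected reads by (qname, other-mate) lookup
  sel_names <- unique(reads$qname[sel])
  want_mate <- sel & reads$mate != 0L
  keep <- sel
  for (i in which(want_mate)) {
    other <- which(reads$qname == reads$qname[i] &
                     reads$mate == (3L - reads$mate[i]))
    if (length(other)) {
      keep[other[1L]] <- TRUE
    } else {
      sn_log("mate of %s/%d not found; skipped", reads$qname[i],
             reads$mate[i], level = "warn")
    }
  }
  out <- reads[keep, c("qname", "mate", "seq", "cigar", "pos"), drop = FALSE]
  out$selected <- sel[keep]
  # deterministic order; de-duplicate (qname, mate)
  out <- out[!duplicated(paste(out$qname, out$mate)), , drop = FALSE]
  out <- out[order(out$qname, out$mate), , drop = FALSE]
  rownames(out) <- NULL
  new_read_set(out, sample_id, mode)
}

empty_reads_df <- function() {
  data.frame(qname = character(), mate = integer(), seq = character(),
             cigar = character(), pos = integer(), selected = logical(),
             stringsAsFactors = FALSE)
}

new_read_set <- function(df, sample_id, mode) {
  attr(df, "sample_id") <- as.character(sample_id)
  attr(df, "source_mode") <- mode
  class(df) <- c("ReadSet", "data.frame")
  df
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet '%s' (%s mode): %d reads\n", attr(x, "sample_id"),
              attr(x, "source_mode"), nrow(x)))
  invisible(x)
}

#' Duplicate reads to aid assembly at low coverage
#'
#' Every read is replicated `factor` times, with duplicate copies suffixed
#' by a replicate index in the read name so downstream stages never see
#' colliding identifiers. Boosting is used when junction coverage is too
#' sparse for de novo assembly (default in the field: 10-fold).
#'
#' @param reads A `ReadSet`.
#' @param factor Positive integer replication factor.
#' @return Boosted `ReadSet` with `factor * nrow(reads)` rows.
#' @export
boost_reads <- function(reads, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("boost factor must be >= 1")
  if (factor == 1L || nrow(reads) == 0L) return(reads)
  idx <- rep(seq_len(nrow(reads)), times = factor)
  rep_id <- rep(seq_len(factor), each = nrow(reads))
  out <- as.data.frame(reads)[idx, , drop = FALSE]
  boosted <- rep_id > 1L
  out$qname[boosted] <- paste0(out$qname[boosted], ".rep", rep_id[boosted])
  rownames(out) <- NULL
  new_read_set(out, attr(reads, "sample_id"), attr(reads, "source_mode"))
}

#' Write a ReadSet as FASTA for an assembler
#'
#' @param reads A `ReadSet`.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_reads_fasta <- function(reads, path) {
  ids <- paste0(reads$qname, "/", reads$mate)
  writeLines(paste0(">", ids, "\n", reads$seq), path)
  invisible(path)
}
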