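# reverse complement for plain character DNA
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, "", USE.NAMES = FALSE))
}

# all k-mers of a set of sequences (windows containing N are dropped)
seq_kmers <- function(seqs, k) {
  out <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1L), k:n)
  })
  km <- unlist(out, use.names = FALSE)
  km[!grepl("N", km, fixed = TRUE)]
}

#' Assemble reads into contigs with a small de Bruijn assembler
#'
#' Builds a de Bruijn graph over canonical read k-mers (a k-mer and its
#' reverse complement are counted as one), prunes k-mers below a coverage
#' floor, collapses unbranched paths, and emits every maximal simple path
#' as a contig. The assembler is deterministic: contigs are ordered by
#' length (descending) then lexicographically, and each contig is emitted
#' in the orientation supported by more k-mers of the input reads as
#' given (ties broken toward the lexicographically smaller strand).
#'
#' This stage stands in for a full external assembler at desk scale; an
#' external tool can be substituted via [external_assembler()].
#'
#' @param reads A `ReadSet` (or data.frame with a `seq` column).
#' @param k Odd k-mer size in `[15, 31]`; default 25.
#' @param coverage_floor Minimum canonical k-mer count to keep a k-mer;
#'   default 2 when there are at least 10 reads, else 1.
#' @return A `ContigSet` data.frame (columns `sequence`, `support`,
#'   `assembler_id`) with a `sample_id` attribute. Empty, with a warning,
#'   when no read reaches length `k` (the assembly-failure case).
#' @export
assemble_contigs <- function(reads, k = 25L, coverage_floor = NULL) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 15L || k > 31L) {
    stop("k must be odd and within [15, 31]")
  }
  seqs <- toupper(reads$seq)
  sample_id <- attr(reads, "sample_id")
  if (is.null(sample_id)) sample_id <- NA_character_
  if (is.null(coverage_floor)) {
    coverage_floor <- if (length(seqs) >= 10L) 2L else 1L
  }
  empty <- new_contig_set(
    data.frame(sequence = character(), support = integer(),
               assembler_id = character(), stringsAsFactors = FALSE),
    sample_id)
  if (length(seqs) == 0L) return(empty)
  km <- seq_kmers(seqs, k)
  if (length(km) == 0L) {
    warning("no read reaches k-mer size ", k, "; assembly failed")
    return(empty)
  }
  canon_of <- function(x) pmin(x, revcomp(x))
  counts <- table(canon_of(km))
  keep_canon <- names(counts)[counts >= coverage_floor]
  if (length(keep_canon) == 0L) {
    warning("all k-mers below coverage floor ", coverage_floor,
            "; assembly failed")
    return(empty)
  }
  # both orientations enter the graph as edges prefix->suffix
  edges <- unique(c(keep_canon, revcomp(keep_canon)))
  canon_counts <- as.integer(counts[canon_of(edges)])
  pref <- substring(edges, 1L, k - 1L)
  suff <- substring(edges, 2L, k)
  nodes <- unique(c(pref, suff))
  pi <- match(pref, nodes)
  si <- match(suff, nodes)
  outdeg <- tabulate(pi, nbins = length(nodes))
  indeg <- tabulate(si, nbins = length(nodes))
  # adjacency: for each node, indices of outgoing edges
  adj <- split(seq_along(edges), factor(pi, levels = seq_along(nodes)))
  simple <- indeg == 1L & outdeg == 1L

  used <- rep(FALSE, length(edges))
  contigs <- character()
  supports <- integer()
  walk_from <- function(e) {
    # extend a unitig forward from edge index e
    path <- e
    used[e] <<- TRUE
    repeat {
      v <- si[path[length(path)]]
      if (!simple[v]) break
      nxt <- adj[[v]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0L) break
      used[nxt[1L]] <<- TRUE
      path <- c(path, nxt[1L])
    }
    path
  }
  starts <- which(!simple[pi])
  for (e in order(edges)[order(edges) %in% starts]) {
    if (used[e]) next
    path <- walk_from(e)
    seq_out <- paste0(edges[path[1L]],
                      paste(substring(edges[path[-1L]], k, k), collapse = ""))
    contigs <- c(contigs, seq_out)
    supports <- c(supports, sum(canon_counts[path]))
  }
  # remaining edges form pure cycles; emit each once
  for (e in order(edges)) {
    if (used[e]) next
    path <- walk_from(e)
    seq_out <- paste0(edges[path[1L]],
                      paste(substring(edges[path[-1L]], k, k), collapse = ""))
    contigs <- c(contigs, seq_out)
    supports <- c(supports, sum(canon_counts[path]))
  }
  # each contig exists on both strands; de-duplicate canonically, then
  # orient by direct k-mer support from the reads as given
  canon_seq <- canon_of(contigs)
  first <- !duplicated(canon_seq)
  contigs <- contigs[first]
  supports <- supports[first]
  km_set <- unique(km)
  orient <- vapply(contigs, function(s) {
    fwd <- sum(seq_kmers(s, k) %in% km_set)
    rc <- revcomp(s)
    rev <- sum(seq_kmers(rc, k) %in% km_set)
    if (fwd > rev) s
    else if (rev > fwd) rc
    else min(s, rc)
  }, "", USE.NAMES = FALSE)
  ord <- order(-nchar(orient), orient)
  df <- data.frame(sequence = orient[ord],
                   support = supports[ord],
                   assembler_id = "builtin-debruijn",
                   stringsAsFactors = FALSE)
  new_contig_set(df, sample_id)
}

new_contig_set <- function(df, sample_id) {
  attr(df, "sample_id") <- as.character(sample_id)
  class(df) <- c("ContigSet", "data.frame")
  df
}

#' @export
print.ContigSet <- function(x, ...) {
  cat(sprintf("ContigSet '%s': %d contigs (lengths %s)\n",
              attr(x, "sample_id"), nrow(x),
              paste(nchar(x$sequence), collapse = ", ")))
  invisible(x)
}

#' Adapter for an external FASTA-in/FASTA-out assembler
#'
#' Wraps any executable that reads a FASTA of reads and writes a FASTA of
#' contigs, preserving the built-in assembler's contract so the two are
#' interchangeable in the pipeline. The command is invoked as
#' `cmd [args...] <reads.fasta> <contigs.fasta>`.
#'
#' @param cmd Path to the executable.
#' @param args Extra arguments passed verbatim before the two paths.
#' @param timeout Seconds before the subprocess is killed (default 600).
#' @return A function `(reads) -> ContigSet`.
#' @export
external_assembler <- function(cmd, args = character(), timeout = 600) {
  force(cmd); force(args); force(timeout)
  function(reads) {
    fin <- tempfile(fileext = ".fasta")
    fout <- tempfile(fileext = ".fasta")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    write_reads_fasta(reads, fin)
    status <- system2(cmd, c(args, fin, fout), timeout = timeout)
    if (status != 0L) stop("external assembler failed (exit ", status, ")")
    if (!file.exists(fout)) stop("external assembler wrote no output")
    fa <- Biostrings::readDNAStringSet(fout)
    df <- data.frame(sequence = as.character(fa),
                     support = NA_integer_,
                     assembler_id = basename(cmd),
                     stringsAsFactors = FALSE)
    ord <- order(-nchar(df$sequence), df$sequence)
    new_contig_set(df[ord, , drop = FALSE], attr(reads, "sample_id"))
  }
}
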