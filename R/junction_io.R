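#' Construct a splice-junction event
#'
#' A `JunctionEvent` describes one exon-exon junction by its intron
#' coordinates, following the STAR `SJ.out.tab` convention: `intron_start`
#' is the 1-based first base of the intron and `intron_end` the 1-based
#' last base. The same representation is used for tumor alternative
#' splicing events (ASEs) and for wild-type (WT) junctions identified in
#' normal controls.
#'
#' @param chrom Chromosome name.
#' @param intron_start 1-based first intronic base.
#' @param intron_end 1-based last intronic base; must exceed `intron_start`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unknown).
#' @param gene_symbol Optional gene label.
#' @param expressing_samples Character vector of sample IDs expressing the
#'   junction.
#' @param outlier_oe_samples Character vector of tumor sample IDs flagged as
#'   overexpression outliers by an upstream caller (e.g. OutSplice). These
#'   flags are consumed as-is, never recomputed.
#' @return An object of class `JunctionEvent`.
#' @export
junction_event <- function(chrom, intron_start, intron_end, strand = "*",
                           gene_symbol = NA_character_,
                           expressing_samples = character(),
                           outlier_oe_samples = character()) {
  intron_start <- as.integer(intron_start)
  intron_end <- as.integer(intron_end)
  stopifnot(length(chrom) == 1L, nchar(chrom) > 0L)
  if (is.na(intron_start) || is.na(intron_end) ||
      intron_start <= 0L || intron_end <= 0L) {
    stop("intron coordinates must be positive integers")
  }
  if (intron_start >= intron_end) {
    stop("intron_start must be < intron_end (got ",
         intron_start, " >= ", intron_end, ")")
  }
  strand <- match.arg(strand, c("+", "-", "*"))
  structure(
    list(chrom = as.character(chrom),
         intron_start = intron_start,
         intron_end = intron_end,
         strand = strand,
         gene_symbol = as.character(gene_symbol),
         expressing_samples = unique(as.character(expressing_samples)),
         outlier_oe_samples = unique(as.character(outlier_oe_samples))),
    class = "JunctionEvent")
}

#' @export
print.JunctionEvent <- function(x, ...) {
  cat(sprintf("JunctionEvent %s:%d-%d(%s)%s\n", x$chrom, x$intron_start,
              x$intron_end, x$strand,
              if (!is.na(x$gene_symbol)) paste0(" [", x$gene_symbol, "]")
              else ""))
  invisible(x)
}

#' Event identifier string
#'
#' Canonical `chrom:start-end` label used to key per-event results.
#'
#' @param event A `JunctionEvent`.
#' @return Character scalar.
#' @export
event_id <- function(event) {
  sprintf("%s:%d-%d", event$chrom, event$intron_start, event$intron_end)
}

#' Parse a STAR SJ.out.tab splice-junction catalog
#'
#' Reads the 9-column tab-separated junction catalog emitted by the STAR
#' aligner. Columns are: chromosome, intron start (1-based), intron end
#' (1-based), strand code (0 undefined, 1 `+`, 2 `-`), intron motif,
#' annotation flag, number of uniquely mapping reads, number of
#' multimapping reads, and maximum spliced-alignment overhang.
#'
#' @param path Path to an `SJ.out.tab` file.
#' @param sample_id Sample identifier to attach to the catalog.
#' @return A `JunctionCatalog`: a data.frame with columns `chrom`,
#'   `intron_start`, `intron_end`, `strand`, `unique_reads`,
#'   `multimapped_reads`, `max_overhang`, plus a `sample_id` attribute.
#' @export
parse_sj_file <- function(path, sample_id) {
  if (!file.exists(path)) stop("SJ file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(chrom = character(), intron_start = integer(),
                      intron_end = integer(), strand = character(),
                      unique_reads = integer(), multimapped_reads = integer(),
                      max_overhang = integer(), stringsAsFactors = FALSE)
  if (length(lines) == 0L) {
    return(new_junction_catalog(empty, sample_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 9L)
  if (length(bad)) {
    stop(sprintf("malformed SJ line %d in %s: expected >=9 tab-separated columns, got %d",
                 bad[1L], path, nf[bad[1L]]))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:9))
  ints <- suppressWarnings(apply(m[, 2:9, drop = FALSE], 2L, as.integer))
  if (length(lines) == 1L) ints <- matrix(ints, nrow = 1L)
  bad <- which(apply(is.na(ints[, 1:2, drop = FALSE]), 1L, any))
  if (length(bad)) {
    stop(sprintf("malformed SJ line %d in %s: non-integer coordinate", bad[1L], path))
  }
  df <- data.frame(
    chrom = m[, 1L],
    intron_start = ints[, 1L],
    intron_end = ints[, 2L],
    strand = c("*", "+", "-")[ints[, 3L] + 1L],
    unique_reads = ints[, 6L],
    multimapped_reads = ints[, 7L],
    max_overhang = ints[, 8L],
    stringsAsFactors = FALSE)
  key <- paste(df$chrom, df$intron_start, df$intron_end)
  if (anyDuplicated(key)) stop("duplicate junction keys in ", path)
  new_junction_catalog(df, sample_id)
}

new_junction_catalog <- function(df, sample_id) {
  attr(df, "sample_id") <- as.character(sample_id)
  class(df) <- c("JunctionCatalog", "data.frame")
  df
}

#' @export
print.JunctionCatalog <- function(x, ...) {
  cat(sprintf("JunctionCatalog '%s': %d junctions\n",
              attr(x, "sample_id"), nrow(x)))
  NextMethod()
}

#' Read a splice-event table
#'
#' Event lists are TSV with header columns `chrom`, `intron_start`,
#' `intron_end`, `strand`, `gene`, `expressing_samples` (comma-separated)
#' and `outlier_oe_samples` (comma-separated). Empty sample lists are
#' allowed.
#'
#' @param path Path to the events TSV.
#' @return List of `JunctionEvent` objects.
#' @export
read_event_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "intron_start", "intron_end", "strand", "gene",
            "expressing_samples", "outlier_oe_samples")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("event table lacks columns: ", paste(missing, collapse = ", "))
  }
  split_ids <- function(x) {
    if (is.na(x) || !nzchar(x)) character() else
      trimws(strsplit(x, ",", fixed = TRUE)[[1L]])
  }
  lapply(seq_len(nrow(df)), function(i) {
    junction_event(df$chrom[i], df$intron_start[i], df$intron_end[i],
                   strand = if (df$strand[i] %in% c("+", "-")) df$strand[i]
                            else "*",
                   gene_symbol = df$gene[i],
                   expressing_samples = split_ids(df$expressing_samples[i]),
                   outlier_oe_samples = split_ids(df$outlier_oe_samples[i]))
  })
}

#' Identify the wild-type alternative junction for an ASE
#'
#' Scans normal-sample junction catalogs for junctions sharing the ASE's
#' intron start OR end (but not both), and returns the candidate expressed
#' (`unique_reads >= min_reads`) in the greatest number of normal samples.
#' Ties are broken by total unique reads across normals, then
#' lexicographically by (chrom, start, end). Strand agreement is required
#' when both the ASE and candidate strands are known.
#'
#' Absence of any candidate is a valid result (`found = FALSE`), not an
#' error: many tumor-specific events have no expressed WT alternative.
#'
#' @param ase A `JunctionEvent` for the tumor splicing event.
#' @param normals Non-empty list of `JunctionCatalog` objects from normal
#'   controls.
#' @param min_reads Minimum unique reads for a normal sample to count as
#'   expressing the candidate junction (default 1).
#' @param site Restrict the candidate pool to junctions sharing the
#'   `"start"` or `"end"` site only; default `"any"` pools both.
#' @return A `WTJunctionCall` list with elements `found`, `wt_junction`,
#'   `shared_site` (`"start"` or `"end"`), `n_expressing_normals`,
#'   `total_unique_reads`.
#' @export
identify_wt_junction <- function(ase, normals, min_reads = 1L,
                                 site = c("any", "start", "end")) {
  site <- match.arg(site)
  stopifnot(inherits(ase, "JunctionEvent"))
  if (length(normals) == 0L) stop("normals must be non-empty")
  min_reads <- as.integer(min_reads)

  tabs <- lapply(normals, function(cat) {
    hit_start <- cat$chrom == ase$chrom & cat$intron_start == ase$intron_start
    hit_end <- cat$chrom == ase$chrom & cat$intron_end == ase$intron_end
    keep <- switch(site,
                   any = hit_start | hit_end,
                   start = hit_start,
                   end = hit_end)
    # exclude the ASE itself
    keep <- keep & !(hit_start & hit_end)
    # strand agreement when both known
    if (ase$strand %in% c("+", "-")) {
      keep <- keep & (cat$strand == "*" | cat$strand == ase$strand)
    }
    keep <- keep & cat$unique_reads >= min_reads
    cat[keep, , drop = FALSE]
  })
  pool <- do.call(rbind, lapply(tabs, as.data.frame))
  if (is.null(pool) || nrow(pool) == 0L) {
    return(structure(list(found = FALSE, wt_junction = NULL,
                          shared_site = NA_character_,
                          n_expressing_normals = 0L,
                          total_unique_reads = 0L),
                     class = "WTJunctionCall"))
  }
  key <- paste(pool$chrom, pool$intron_start, pool$intron_end)
  n_samples <- tapply(rep(1L, nrow(pool)), key, sum)
  tot_reads <- tapply(pool$unique_reads, key, sum)
  idx <- match(names(n_samples), key)
  cand <- data.frame(chrom = pool$chrom[idx],
                     intron_start = pool$intron_start[idx],
                     intron_end = pool$intron_end[idx],
                     strand = pool$strand[idx],
                     n = as.integer(n_samples),
                     reads = as.integer(tot_reads),
                     stringsAsFactors = FALSE)
  ord <- order(-cand$n, -cand$reads, cand$chrom, cand$intron_start,
               cand$intron_end)
  best <- cand[ord[1L], ]
  shared <- if (best$intron_start == ase$intron_start) "start" else "end"
  wt <- junction_event(best$chrom, best$intron_start, best$intron_end,
                       strand = best$strand,
                       gene_symbol = ase$gene_symbol)
  structure(list(found = TRUE, wt_junction = wt, shared_site = shared,
                 n_expressing_normals = best$n,
                 total_unique_reads = best$reads),
            class = "WTJunctionCall")
}

#' @export
print.WTJunctionCall <- function(x, ...) {
  if (!x$found) {
    cat("WTJunctionCall: no WT alternative found\n")
  } else {
    cat(sprintf("WTJunctionCall: %s (shared %s; %d normals, %d reads)\n",
                event_id(x$wt_junction), x$shared_site,
                x$n_expressing_normals, x$total_unique_reads))
  }
  invisible(x)
}
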