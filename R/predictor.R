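# stable 31-bit polynomial hash of a string; pure arithmetic, identical
# across platforms and sessions (no serialization involved)
stable_hash31 <- function(s, init = 7L) {
  h <- as.numeric(init)
  for (c in utf8ToInt(s)) {
    h <- (h * 131 + c) %% 2147483647
  }
  h
}

#' Deterministic mock binding-rank predictor
#'
#' Stands in for an external MHC binding predictor so that tests and
#' desk-scale runs need no external tool. The rank of a (peptide, allele)
#' pair is a stable hash mapped into `[0.05, 100]` -- identical across
#' runs and platforms for a given `seed` -- unless the pair appears in the
#' `plants` override table, in which case the planted rank is returned.
#'
#' @param seed Integer mixed into the hash, so different seeds give
#'   different (but each fully deterministic) rank landscapes.
#' @param plants Named numeric vector of planted ranks; names are
#'   `"PEPTIDE|ALLELE"`. All planted ranks must be positive.
#' @param default Optional fixed rank returned for every unplanted pair
#'   (overrides the hash; used to build fully controlled fixtures).
#' @return A predictor `function(peptides, alleles)` returning the full
#'   cross-product data.frame with columns `peptide`, `allele`, `rank`.
#' @export
mock_rank_predictor <- function(seed = 1L, plants = numeric(),
                                default = NULL) {
  if (length(plants) && any(plants <= 0)) stop("planted ranks must be > 0")
  seed <- as.integer(seed)
  force(default)
  function(peptides, alleles) {
    grid <- expand.grid(peptide = as.character(peptides),
                        allele = as.character(alleles),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    key <- paste0(grid$peptide, "|", grid$allele)
    rank <- if (is.null(default)) {
      vapply(key, function(k) {
        h <- stable_hash31(k, init = 7L + seed)
        0.05 + (h / 2147483646) * (100 - 0.05)
      }, numeric(1), USE.NAMES = FALSE)
    } else {
      rep(as.numeric(default), nrow(grid))
    }
    if (length(plants)) {
      hit <- match(key, names(plants))
      rank[!is.na(hit)] <- plants[hit[!is.na(hit)]]
    }
    grid$rank <- rank
    grid
  }
}

#' Adapter for an external binding-rank predictor
#'
#' Wraps a command-line predictor that reads a peptide list (one peptide
#' per line) and an allele name, and prints a tabular result. The command
#' is invoked once per allele as `cmd [args...] <peptide_file> <allele>`
#' and must write lines `peptide<TAB>rank` to stdout (header lines
#' starting with `#` are ignored). Any missing pair is a hard error --
#' ranks are never silently imputed.
#'
#' @param cmd Path to the executable.
#' @param args Extra arguments placed before the peptide file and allele.
#' @param timeout Seconds before the subprocess is killed (default 600).
#' @return A predictor `function(peptides, alleles)`.
#' @export
external_rank_predictor <- function(cmd, args = character(), timeout = 600) {
  force(cmd); force(args); force(timeout)
  function(peptides, alleles) {
    peptides <- as.character(peptides)
    out <- list()
    for (al in as.character(alleles)) {
      pf <- tempfile(fileext = ".txt")
      writeLines(peptides, pf)
      res <- system2(cmd, c(args, pf, al), stdout = TRUE, timeout = timeout)
      unlink(pf)
      status <- attr(res, "status")
      if (!is.null(status) && status != 0L) {
        stop("predictor failed for allele ", al, " (exit ", status, ")")
      }
      res <- res[!startsWith(res, "#") & nzchar(res)]
      parts <- strsplit(res, "\t", fixed = TRUE)
      df <- data.frame(peptide = vapply(parts, `[[`, "", 1L),
                       allele = al,
                       rank = as.numeric(vapply(parts, `[[`, "", 2L)),
                       stringsAsFactors = FALSE)
      miss <- setdiff(peptides, df$peptide)
      if (length(miss)) {
        stop("predictor returned no rank for (", miss[1L], ", ", al, ")")
      }
      out[[al]] <- df
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  }
}
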