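# amino-acid alphabet accepted by local_align (X scores as mismatch)
AA_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "*")

# substitution matrix: +2 identical, -5 otherwise (including X vs anything)
aa_submat <- local({
  m <- matrix(-5, length(AA_CHARS), length(AA_CHARS),
              dimnames = list(AA_CHARS, AA_CHARS))
  diag(m) <- 2
  m["X", ] <- -5; m[, "X"] <- -5
  m
})

#' Local protein alignment with the pipeline's scoring convention
#'
#' Best local (Smith-Waterman style) alignment under match = +2,
#' mismatch = -5, and affine gaps where the first symbol of a gap costs 1
#' and every further symbol 0.5 (so a length-1 gap scores -1, length-2
#' scores -1.5). The heavy substitution penalty relative to the gap cost
#' means a substitution is modelled as a paired insertion/deletion; this
#' is the convention used when ranking translated contigs against the
#' wild-type protein.
#'
#' @param a,b Non-empty amino-acid strings (standard alphabet; `X` allowed
#'   and always scores as a mismatch).
#' @return List with `score` (numeric, >= 0) and `span`: a list of
#'   `a = c(start, end)`, `b = c(start, end)` giving the 1-based aligned
#'   spans (all zeros when the best score is 0).
#' @export
local_align <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  a <- toupper(a); b <- toupper(b)
  bad <- setdiff(unique(strsplit(paste0(a, b), "")[[1L]]), AA_CHARS)
  if (length(bad)) stop("unsupported residue(s): ", paste(bad, collapse = ""))
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = aa_submat,
    gapOpening = 0.5, gapExtension = 0.5)
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(list(score = max(0, sc), span = list(a = c(0L, 0L), b = c(0L, 0L))))
  }
  pr <- pa@pattern@range
  sr <- pa@subject@range
  list(score = sc,
       span = list(a = c(IRanges::start(pr), IRanges::end(pr)),
                   b = c(IRanges::start(sr), IRanges::end(sr))))
}

# Best ungapped anchoring of `flank` in `contig`.
# side = "end": returns e maximizing the match(+1)/mismatch(-1) score of the
# flank aligned so its LAST base sits at contig position e (flank may hang
# off the left edge). side = "start": symmetric, first base at position s.
# Returns list(pos, score, max_score = nchar(flank)).
anchor_flank <- function(contig, flank, side = c("end", "start")) {
  side <- match.arg(side)
  cc <- strsplit(contig, "", fixed = TRUE)[[1L]]
  fc <- strsplit(flank, "", fixed = TRUE)[[1L]]
  L <- length(cc); Fn <- length(fc)
  best_pos <- 0L; best_score <- -Inf
  if (side == "end") {
    for (e in seq_len(L)) {
      ov <- min(e, Fn)
      sc <- sum((cc[(e - ov + 1L):e] == fc[(Fn - ov + 1L):Fn]) * 2L - 1L)
      if (sc > best_score) { best_score <- sc; best_pos <- e }
    }
  } else {
    for (s in seq_len(L)) {
      ov <- min(L - s + 1L, Fn)
      sc <- sum((cc[s:(s + ov - 1L)] == fc[1:ov]) * 2L - 1L)
      if (sc > best_score) { best_score <- sc; best_pos <- s }
    }
  }
  list(pos = best_pos, score = best_score, max_score = Fn)
}
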