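# Independent oracles used across the suite. These deliberately do not
# share code with the package implementation.

# Brute-force affine-gap local alignment DP (Gotoh with three states,
# gap's first symbol -1, each extension -0.5, match +2, mismatch -5).
# Gap-to-gap transitions between the two gap states are permitted (a
# substitution may be modelled as a deletion followed by an insertion).
oracle_local_align <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consumes b)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) 2 else -5
      M[i + 1L, j + 1L] <- s + max(0, M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - 1,
                                Iy[i, j + 1L] - 1,
                                Ix[i, j + 1L] - 0.5)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - 1,
                                Ix[i + 1L, j] - 1,
                                Iy[i + 1L, j] - 0.5)
      best <- max(best, M[i + 1L, j + 1L])
    }
  }
  best
}

# Exact-rational harmonic mean: ranks are ratios p/q of small integers, so
# n / sum(q_i / p_i) = n * prod(p) / sum(q_i * prod(p_{-i})) with every
# intermediate an exact integer in double precision.
oracle_harmonic_mean_rational <- function(p, q) {
  n <- length(p)
  prod_all <- prod(p)
  den <- sum(vapply(seq_len(n), function(i) {
    q[i] * prod(p[-i])
  }, numeric(1)))
  n * prod_all / den
}

# random protein string
random_protein <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# DNA with all k-mers unique on both strands (repeat-free for assembly)
random_repeat_free_dna <- function(len, k, max_tries = 50L) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  for (t in seq_len(max_tries)) {
    s <- random_dna(len)
    km <- substring(s, 1:(len - k + 1L), k:len)
    both <- c(km, vapply(km, rc, ""))
    if (!anyDuplicated(both)) return(s)
  }
  stop("could not generate repeat-free sequence")
}

# build a ReadSet directly from sequences (bypasses SAM parsing)
make_read_set <- function(seqs, sample_id = "S", mode = "junction") {
  df <- data.frame(qname = sprintf("r%03d", seq_along(seqs)),
                   mate = 1L, seq = seqs, cigar = "*",
                   pos = NA_integer_, selected = TRUE,
                   stringsAsFactors = FALSE)
  attr(df, "sample_id") <- sample_id
  attr(df, "source_mode") <- mode
  class(df) <- c("ReadSet", "data.frame")
  df
}

# error-free tiling reads over a sequence
tile_reads <- function(s, read_len, step) {
  n <- nchar(s)
  offs <- seq(1L, max(1L, n - read_len + 1L), by = step)
  if (offs[length(offs)] != n - read_len + 1L) {
    offs <- c(offs, n - read_len + 1L)
  }
  substring(s, offs, offs + read_len - 1L)
}

# write a small SAM file from a record list; records are lists with
# qname, flag, rname, pos, cigar, seq
write_test_sam <- function(records, contigs = c(chr1 = 100000L),
                           path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  body <- vapply(records, function(r) {
    sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
            r$qname, r$flag, r$rname, r$pos, r$cigar, r$seq)
  }, "")
  writeLines(c(hdr, body), path)
  path
}
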