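# helpers local to this file
make_contigs <- function(seqs, sample_id = "S") {
  df <- data.frame(sequence = seqs, support = rep(1L, length(seqs)),
                   assembler_id = rep("test", length(seqs)),
                   stringsAsFactors = FALSE)
  attr(df, "sample_id") <- sample_id
  df
}

mk_call <- function(contig, frame = 1L, peptide = NULL,
                    breakpoint_residues = integer(),
                    premature_stop = FALSE) {
  if (is.null(peptide)) peptide <- translate_frame(contig, frame)$peptide
  spliceneo:::new_isoform_call("S", contig = contig, frame = frame,
                               peptide = peptide, alignment_score = 1,
                               breakpoint_residues = breakpoint_residues,
                               premature_stop = premature_stop)
}

rc <- function(s) chartr("ACGT", "TGCA",
                         paste(rev(strsplit(s, "")[[1]]), collapse = ""))

# 30 stop-free codons -> 30-aa protein, hand-checkable prefix
CDS <- paste0("ATGGCTTGGAAACTG",
              paste(rep(c("GAT", "CGT", "TTC", "CAA", "GGA"), 5),
                    collapse = ""))

test_that("translation follows the standard genetic code and stop policy", {
  expect_identical(translate_frame("ATGGCTTGGAAACTG", 1)$peptide, "MAWKL")
  tr <- translate_frame("ATGTAATGGGGG", 1)
  expect_identical(tr$peptide, "M")
  expect_true(tr$premature_stop)
  # terminal stop is not premature
  tr2 <- translate_frame("ATGGCTTAA", 1)
  expect_identical(tr2$peptide, "MA")
  expect_false(tr2$premature_stop)
  # frame 2 skips the first base; negative frames read the other strand
  expect_identical(translate_frame(paste0("G", "ATGGCTTGG"), 2)$peptide,
                   "MAW")
  expect_identical(translate_frame(rc("ATGGCTTGG"), -1)$peptide, "MAW")
})

test_that("select_best_isoform finds the encoding frame", {
  wt <- translate_frame(CDS, 1)$peptide
  call <- select_best_isoform(make_contigs(paste0("G", CDS)), wt)
  expect_equal(call$frame, 2L)
  expect_identical(call$peptide, wt)
  expect_equal(call$alignment_score, 2 * nchar(wt))

  # reverse-complemented coding sequence selects a negative frame
  call2 <- select_best_isoform(make_contigs(rc(CDS)), wt)
  expect_lt(call2$frame, 0)
  expect_identical(call2$peptide, wt)
})

test_that("no contigs means an assembly-failure exclusion", {
  call <- select_best_isoform(make_contigs(character()), "MAWKL")
  expect_true(call$excluded)
  expect_identical(call$reason, "assembly_failure")
})

test_that("strand restriction limits the frame search", {
  wt <- translate_frame(CDS, 1)$peptide
  call <- select_best_isoform(make_contigs(rc(CDS)), wt, strand = "+",
                              restrict_strand = TRUE)
  # forced to the wrong strand: cannot reach the identity score
  expect_lt(call$alignment_score, 2 * nchar(wt))
})

test_that("locate_breakpoint finds the flank junction", {
  set.seed(51)
  up <- random_repeat_free_dna(60, 15)
  dn <- random_repeat_free_dna(60, 15)
  call <- mk_call(paste0(up, dn))
  out <- locate_breakpoint(call, up, dn)
  expect_false(out$excluded)
  expect_equal(out$breakpoint_nt, 60L)
  expect_equal(out$breakpoint_residues, c(20L, 21L))

  # 12-nt insertion between the flanks: junction after the last upstream nt
  ins <- random_dna(12)
  call2 <- mk_call(paste0(up, ins, dn))
  out2 <- locate_breakpoint(call2, up, dn)
  expect_false(out2$excluded)
  expect_equal(out2$breakpoint_nt, 60L)
  expect_equal(out2$breakpoint_residues, c(20L, 21L))

  # unrelated sequence cannot anchor
  call3 <- mk_call(random_dna(120))
  out3 <- locate_breakpoint(call3, up, dn)
  expect_true(out3$excluded)
  expect_identical(out3$reason, "breakpoint_unresolved")

  expect_error(locate_breakpoint(call, substring(up, 1, 19), dn), "20 nt")
})

test_that("negative-frame calls are oriented before anchoring", {
  set.seed(52)
  up <- random_repeat_free_dna(60, 15)
  dn <- random_repeat_free_dna(60, 15)
  fwd <- paste0(up, dn)
  call <- mk_call(rc(fwd), frame = -2L,
                  peptide = translate_frame(rc(fwd), -2)$peptide)
  out <- locate_breakpoint(call, up, dn)
  expect_false(out$excluded)
  expect_identical(out$contig, fwd)
  expect_equal(out$frame, 2L)
  expect_equal(out$breakpoint_nt, 60L)
})

test_that("junction_kmers enumerates spanning windows per size", {
  set.seed(53)
  call <- mk_call("ATG", peptide = random_protein(20),
                  breakpoint_residues = c(10L, 11L))
  ks <- junction_kmers(call, sizes = 8:11)
  expect_false(ks$excluded)
  counts <- table(ks$kmers$length)
  expect_equal(as.integer(counts[as.character(8:11)]), c(7L, 8L, 9L, 10L))
  expect_equal(nrow(ks$kmers), 34L)
  ok <- ks$kmers$start <= 10 & ks$kmers$start + ks$kmers$length - 1 >= 11
  expect_true(all(ok))
})

test_that("short peptides and pre-junction stops are excluded with reasons", {
  short <- mk_call("ATG", peptide = random_protein(7),
                   breakpoint_residues = c(3L, 4L))
  ks <- junction_kmers(short, sizes = 8:11)
  expect_true(ks$excluded)
  expect_identical(ks$reason, "short_peptide")

  # peptide long enough, but truncated by a stop before the junction
  stopped <- mk_call("ATG", peptide = random_protein(12),
                     breakpoint_residues = c(20L, 21L),
                     premature_stop = TRUE)
  ks2 <- junction_kmers(stopped, sizes = 8:11)
  expect_true(ks2$excluded)
  expect_identical(ks2$reason, "premature_stop")

  # MHC-II: a single 15-mer when the peptide is exactly 15 long
  full <- mk_call("ATG", peptide = random_protein(15),
                  breakpoint_residues = 8L)
  ks3 <- junction_kmers(full, sizes = 15, class_mode = "MHC-II")
  expect_equal(nrow(ks3$kmers), 1L)
  expect_identical(ks3$kmers$peptide, full$peptide)
})

test_that("region mode requires overlap, not containment", {
  call <- mk_call("ATG", peptide = random_protein(20),
                  breakpoint_residues = integer())
  ks <- junction_kmers(call, sizes = 8, region_residues = c(1L, 2L))
  # windows overlapping residues 1-2: starts 1 and 2
  expect_equal(sort(ks$kmers$start), 1:2)
})

test_that("duplicate k-mer strings are collapsed", {
  pep <- strrep("A", 20)
  call <- mk_call("ATG", peptide = pep, breakpoint_residues = c(10L, 11L))
  ks <- junction_kmers(call, sizes = 8:11)
  expect_equal(nrow(ks$kmers), 4L)  # one distinct string per size
})
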