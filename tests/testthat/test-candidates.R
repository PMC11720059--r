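mk_summary <- function(event, ase, wt, pct, oe, gene = "G",
                       pep = "AAAA", al = "A01:01") {
  structure(list(event = event, ase_phbr = ase, wt_phbr = wt,
                 best_peptide = pep, best_allele = al,
                 pct_samples = pct, n_samples = 1L, n_excluded = 0L,
                 class_mode = "MHC-I", unreportable = FALSE,
                 gene_symbol = gene, pct_outlier_oe = oe),
            class = "EventSummary")
}

test_that("filter_candidates applies all four criteria", {
  summaries <- list(
    mk_summary("e1", 0.38, 3.12, 1.00, 0.617),   # principal, strong
    mk_summary("e2", 0.43, 0.44, 1.00, 0.574),   # principal (WT larger)
    mk_summary("e3", 0.61, 1.34, 0.66, 0.404),   # principal
    mk_summary("e4", 0.70, NA, 1.00, 0.447),     # no WT -> not principal
    mk_summary("e5", 2.27, 9.00, 1.00, 0.50),    # non-binder
    mk_summary("e6", 0.50, 4.00, 0.40, 0.50),    # minority of samples
    mk_summary("e7", 0.50, 4.00, 0.90, 0.00),    # no outlier OE
    mk_summary("e8", 1.00, 0.90, 0.90, 0.50))    # WT smaller
  out <- filter_candidates(summaries)
  expect_identical(out$event[out$principal], c("e1", "e2", "e3"))
  expect_identical(out$ase_phbr, sort(out$ase_phbr))
  expect_identical(out$binder_class[out$event == "e1"], "strong")

  # idempotent and order-invariant
  out2 <- filter_candidates(rev(summaries))
  expect_identical(out, out2)
})

test_that("differential_binding reproduces the flag semantics", {
  expect_setequal(differential_binding(0.58, 2.18),
                  c("binder_in_R_only", "stronger_category_in_R"))
  expect_identical(differential_binding(0.44, 1.57),
                   "stronger_category_in_R")
  expect_length(differential_binding(0.04, 0.04), 0)
  # absent nonresponder average counts as no binding seen
  expect_identical(differential_binding(1.67, NA_real_), "binder_in_R_only")
  expect_length(differential_binding(3.5, NA_real_), 0)
})

test_that("stronger_category_in_R is antisymmetric", {
  set.seed(71)
  for (i in 1:50) {
    r <- runif(1, 0.01, 8); nr <- runif(1, 0.01, 8)
    f1 <- "stronger_category_in_R" %in% differential_binding(r, nr)
    f2 <- "stronger_category_in_R" %in% differential_binding(nr, r)
    expect_false(f1 && f2)
  }
})

test_that("cohort_group_average respects exclusions", {
  vals <- c(S1 = 0.5, S2 = 1.5)
  expect_equal(cohort_group_average(vals, c("S1", "S2")), 1.0)
  expect_true(is.na(cohort_group_average(vals, c("S1", "S2"),
                                         exclusions = c("S1", "S2"))))
  vals3 <- c(S1 = 2, S2 = 4)
  expect_equal(cohort_group_average(vals3, c("S1", "S2", "S3"),
                                    exclusions = c(S3 = "assembly_failure")),
               3.0)
  # members never scored are simply not averaged
  expect_true(is.na(cohort_group_average(vals, "S9")))
})

test_that("fisher_exact_2x2 handles the worked examples", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)),
               1 / 3)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)),
               1 / choose(10, 5) * 2)
})

test_that("BH adjustment matches the hand-computed step-up", {
  p <- c(0.01, 0.02, 0.04)
  expect_equal(p.adjust(p, method = "BH"), c(0.03, 0.03, 0.04))
})

test_that("loss_association_test builds per-event and pooled results", {
  m <- rbind(ev1 = c("lost", "lost", "maintained", "maintained"),
             ev2 = c("lost", "absent", "maintained", "lost"),
             ev3 = c("maintained", "maintained", "maintained", "maintained"))
  colnames(m) <- c("R1", "R2", "N1", "N2")
  resp <- c(R1 = "responder", R2 = "responder",
            N1 = "nonresponder", N2 = "nonresponder")
  out <- loss_association_test(m, resp)
  expect_equal(nrow(out$per_event), 3L)
  expect_equal(out$per_event$p[1], 1 / 3)          # [[2,0],[0,2]]
  expect_equal(out$per_event$p[3], 1)              # degenerate margin
  expect_equal(out$per_event$p_adj,
               p.adjust(out$per_event$p, method = "BH"))
  expect_equal(sum(out$pooled$table), sum(m != "absent"))
  expect_lte(out$pooled$p, 1)
  # absent flags leave that sample out
  expect_equal(out$per_event$lost_R[2] + out$per_event$maintained_R[2], 1L)
})

test_that("loss matrix round-trips through TSV", {
  m <- rbind(e1 = c("lost", "maintained"), e2 = c("absent", "lost"))
  colnames(m) <- c("S1", "S2")
  p <- tempfile(fileext = ".tsv")
  df <- data.frame(event = rownames(m), m, check.names = FALSE)
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(read_loss_matrix(p), m)
})

test_that("write_event_report emits the fixed candidate layout", {
  rows <- filter_candidates(list(mk_summary("e1", 0.377, 3.123, 1, 0.617)))
  p <- tempfile(fileext = ".tsv")
  write_event_report(rows, p)
  got <- read.delim(p, stringsAsFactors = FALSE, colClasses = "character")
  expect_identical(names(got),
                   c("event", "ase_phbr", "wt_phbr", "best_peptide_hla",
                     "pct_samples", "gene_symbol", "pct_outlier_oe"))
  expect_identical(got$ase_phbr, "0.38")
  expect_identical(got$wt_phbr, "3.12")
  expect_identical(got$pct_samples, "100.0%")

  cmp <- data.frame(event = "e1", responder_phbr = 0.444,
                    responder_best_peptide_hla = "PEP HLA-A01:01",
                    nonresponder_phbr = NA_real_, gene_symbol = "G",
                    stringsAsFactors = FALSE)
  write_event_report(cmp, p)
  got2 <- read.delim(p, stringsAsFactors = FALSE, colClasses = "character",
                     na.strings = character())
  expect_identical(names(got2),
                   c("event", "responder_phbr",
                     "responder_best_peptide_hla", "nonresponder_phbr",
                     "gene_symbol"))
  expect_identical(got2$responder_phbr, "0.44")
  expect_identical(got2$nonresponder_phbr, "NA")

  expect_error(write_event_report(rows[0, ], p), "empty")
})
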