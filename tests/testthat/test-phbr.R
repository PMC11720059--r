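mk_kmers <- function(peptides, sample_id = "P1", class_mode = "MHC-I") {
  spliceneo:::new_kmer_set(
    sample_id,
    data.frame(peptide = peptides, start = seq_along(peptides),
               length = nchar(peptides), stringsAsFactors = FALSE),
    class_mode)
}

test_that("compute_phbr is the harmonic mean of best ranks", {
  expect_equal(compute_phbr(c(3, 3, 3)), 3)
  expect_equal(compute_phbr(c(0.5, 2)), 0.8)
  expect_equal(compute_phbr(c(1, 1, 1, 1, 1, 100)), 6 / 5.01)
  expect_equal(compute_phbr(0.38), 0.38)
  expect_error(compute_phbr(numeric()), "non-empty")
  expect_warning(v <- compute_phbr(c(0, 1)), "clamped")
  expect_equal(v, 2 / (1 / 0.001 + 1))
})

test_that("compute_phbr matches the exact-rational oracle", {
  set.seed(61)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    p <- sample(1:50, n, replace = TRUE)
    q <- sample(1:50, n, replace = TRUE)
    expect_lt(abs(compute_phbr(p / q) -
                    oracle_harmonic_mean_rational(p, q)), 1e-12)
  }
})

test_that("PHBR bounds and monotonicity hold", {
  set.seed(62)
  for (i in 1:50) {
    n <- sample(1:6, 1)
    r <- runif(n, 0.01, 100)
    v <- compute_phbr(r)
    expect_gte(v, min(r))
    expect_lte(v, min(r) * n + 1e-12)
    # decreasing one rank never increases PHBR
    j <- sample(n, 1)
    r2 <- r; r2[j] <- r2[j] * 0.5
    expect_lte(compute_phbr(r2), v + 1e-12)
  }
})

test_that("sample_phbr recovers a planted best combination", {
  geno <- hla_genotype("P1", c("A02:01", "A01:01", "B07:02", "B27:05",
                               "C04:01", "C07:01"))
  kmers <- mk_kmers(c("QRWDSHFLL", "AAAAAAAA", "CCCCCCCC"))
  pred <- mock_rank_predictor(plants = c("QRWDSHFLL|B27:05" = 0.2),
                              default = 50)
  res <- sample_phbr(kmers, geno, pred)
  expect_identical(res$best_peptide, "QRWDSHFLL")
  expect_identical(res$best_allele, "B27:05")
  expect_equal(res$phbr, 6 / (1 / 0.2 + 5 / 50))
})

test_that("single-allele and homozygous genotypes are handled", {
  pred <- mock_rank_predictor(plants = c("PEPTIDEX|A01:01" = 0.38,
                                         "PEPTIDEX|A02:01" = 1.0),
                              default = 50)
  res <- sample_phbr(mk_kmers("PEPTIDEX"),
                     hla_genotype("P1", "A01:01"), pred)
  expect_equal(res$phbr, 0.38)

  hom <- sample_phbr(mk_kmers("PEPTIDEX"),
                     hla_genotype("P2", c("A02:01", "A02:01")), pred)
  expect_equal(hom$phbr, 1.0)
  expect_length(hom$per_allele_best, 2L)
})

test_that("sample_phbr is invariant to k-mer and allele order", {
  pred <- mock_rank_predictor(seed = 9)
  peps <- c("MAWKLDRT", "DRTFCAAQ", "QGAMAWKL")
  g1 <- hla_genotype("P", c("A01:01", "B08:01", "C04:01"))
  g2 <- hla_genotype("P", rev(c("A01:01", "B08:01", "C04:01")))
  r1 <- sample_phbr(mk_kmers(peps), g1, pred)
  r2 <- sample_phbr(mk_kmers(rev(peps)), g2, pred)
  expect_equal(r1$phbr, r2$phbr)
  expect_identical(r1$best_peptide, r2$best_peptide)
  expect_identical(r1$best_allele, r2$best_allele)
})

test_that("predictor gaps are hard errors", {
  bad <- function(peptides, alleles) {
    data.frame(peptide = peptides[1], allele = alleles[1], rank = 1)
  }
  expect_error(
    sample_phbr(mk_kmers(c("AAAA", "CCCC")),
                hla_genotype("P", c("A01:01", "B08:01")), bad),
    "no rank")
})

test_that("planted-binder recovery holds for random fixtures", {
  set.seed(63)
  alleles <- c("A01:01", "A02:01", "B07:02", "B08:01", "C04:01", "C07:01")
  for (i in 1:20) {
    peps <- unique(replicate(5, random_protein(9)))
    plant_p <- sample(peps, 1)
    plant_a <- sample(alleles, 1)
    plants <- setNames(runif(1, 0.01, 0.49),
                       paste0(plant_p, "|", plant_a))
    pred <- mock_rank_predictor(plants = plants, default = 50 + i)
    res <- sample_phbr(mk_kmers(peps), hla_genotype("P", alleles), pred)
    expect_identical(res$best_peptide, plant_p)
    expect_identical(res$best_allele, plant_a)
  }
})

test_that("classify_binder uses strict thresholds in both classes", {
  expect_identical(classify_binder(0.38), "strong")
  expect_identical(classify_binder(3.12), "non")
  expect_identical(classify_binder(1.35), "weak")
  expect_identical(classify_binder(0.5), "weak")
  expect_identical(classify_binder(2), "non")
  expect_identical(classify_binder(0.99, "MHC-II"), "strong")
  expect_identical(classify_binder(4.9, "MHC-II"), "relevant")
  expect_identical(classify_binder(5.0, "MHC-II"), "non")
  expect_identical(classify_binder(c(0.1, 1, 7)), c("strong", "weak", "non"))
})

test_that("summarize_event averages and percentages follow the contract", {
  mk_res <- function(phbr, rank, pep = "AAAA", al = "A01:01", id = "T") {
    structure(list(event = "e", sample_id = id, phbr = phbr,
                   best_peptide = pep, best_allele = al, best_rank = rank,
                   per_allele_best = rank, class_mode = "MHC-I"),
              class = "PHBRResult")
  }
  s <- summarize_event(list(mk_res(0.3, 0.3), mk_res(0.5, 0.5)),
                       list(mk_res(3.0, 3), mk_res(3.1, 3), mk_res(3.26, 3)),
                       cohort_size = 2)
  expect_equal(s$ase_phbr, 0.4)
  expect_equal(s$wt_phbr, 3.12)
  expect_equal(s$pct_samples, 1)

  s2 <- summarize_event(lapply(1:46, function(i) mk_res(1, 1)),
                        NULL, cohort_size = 47, n_excluded = 1)
  expect_equal(round(100 * s2$pct_samples, 1), 97.9)
  expect_true(is.na(s2$wt_phbr))

  s3 <- summarize_event(list(), NULL, cohort_size = 5, n_excluded = 5)
  expect_true(s3$unreportable)
})
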