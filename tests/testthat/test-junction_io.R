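test_that("parse_sj_file maps STAR columns and strand codes", {
  p <- tempfile()
  writeLines(c("chr19\t2037830\t2040133\t1\t1\t1\t42\t0\t38",
               "chr19\t100\t200\t2\t2\t0\t7\t3\t25",
               "chr2\t50\t80\t0\t0\t0\t1\t0\t10"), p)
  cat_ <- parse_sj_file(p, "S1")
  expect_s3_class(cat_, "JunctionCatalog")
  expect_identical(attr(cat_, "sample_id"), "S1")
  expect_equal(nrow(cat_), 3L)
  expect_equal(cat_$intron_start[1], 2037830L)
  expect_equal(cat_$intron_end[1], 2040133L)
  expect_identical(cat_$strand, c("+", "-", "*"))
  expect_equal(cat_$unique_reads, c(42L, 7L, 1L))
  expect_equal(cat_$multimapped_reads, c(0L, 3L, 0L))
})

test_that("parse_sj_file handles empty files and malformed lines", {
  p <- tempfile()
  file.create(p)
  expect_equal(nrow(parse_sj_file(p, "S")), 0L)

  writeLines("chr1\t1\t2\t1\t1\t1\t5\t0", p)  # 8 columns
  expect_error(parse_sj_file(p, "S"), "line 1")

  writeLines(c("chr1\t10\t20\t1\t1\t1\t5\t0\t9",
               "chr1\tx\t20\t1\t1\t1\t5\t0\t9"), p)
  expect_error(parse_sj_file(p, "S"), "line 2")
})

test_that("junction_event validates coordinates", {
  expect_error(junction_event("chr1", 500, 100), "intron_start")
  expect_error(junction_event("chr1", -5, 100), "positive")
  ev <- junction_event("chr1", 100, 500, gene_symbol = "G")
  expect_identical(event_id(ev), "chr1:100-500")
})

make_catalog <- function(sample_id, rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r[[1]], intron_start = as.integer(r[[2]]),
               intron_end = as.integer(r[[3]]), strand = "*",
               unique_reads = as.integer(r[[4]]),
               multimapped_reads = 0L, max_overhang = 30L,
               stringsAsFactors = FALSE)
  }))
  attr(df, "sample_id") <- sample_id
  class(df) <- c("JunctionCatalog", "data.frame")
  df
}

test_that("identify_wt_junction picks most commonly expressed alternative", {
  ase <- junction_event("chr1", 100, 500)
  normals <- list(
    make_catalog("S1", list(list("chr1", 100, 300, 10),
                            list("chr1", 100, 500, 2))),
    make_catalog("S2", list(list("chr1", 100, 300, 8))),
    make_catalog("S3", list(list("chr1", 200, 500, 5))))
  wc <- identify_wt_junction(ase, normals)
  expect_true(wc$found)
  expect_equal(wc$wt_junction$intron_start, 100L)
  expect_equal(wc$wt_junction$intron_end, 300L)
  expect_identical(wc$shared_site, "start")
  expect_equal(wc$n_expressing_normals, 2L)
  expect_equal(wc$total_unique_reads, 18L)
})

test_that("identify_wt_junction excludes the ASE itself", {
  ase <- junction_event("chr1", 100, 500)
  normals <- list(make_catalog("S1", list(list("chr1", 100, 500, 50))))
  wc <- identify_wt_junction(ase, normals)
  expect_false(wc$found)
})

test_that("ties break by total unique reads across normals", {
  ase <- junction_event("chr1", 100, 500)
  normals <- list(
    make_catalog("S1", list(list("chr1", 100, 300, 9),
                            list("chr1", 250, 500, 20))),
    make_catalog("S2", list(list("chr1", 100, 300, 9),
                            list("chr1", 250, 500, 10))))
  wc <- identify_wt_junction(ase, normals)
  expect_equal(wc$wt_junction$intron_start, 250L)
  expect_identical(wc$shared_site, "end")
  expect_equal(wc$total_unique_reads, 30L)
})

test_that("WT call shares exactly one coordinate and is permutation invariant", {
  set.seed(41)
  for (rep in 1:20) {
    ase <- junction_event("chr1", 100, 500)
    n_samp <- sample(2:10, 1)
    normals <- lapply(seq_len(n_samp), function(s) {
      n_j <- sample(1:20, 1)
      rows <- lapply(seq_len(n_j), function(i) {
        share <- sample(c("start", "end", "none"), 1)
        if (share == "start") {
          list("chr1", 100, sample(setdiff(150:600, 500), 1), sample(0:9, 1))
        } else if (share == "end") {
          list("chr1", sample(setdiff(50:450, 100), 1), 500, sample(0:9, 1))
        } else {
          list("chr1", 700, sample(800:900, 1), sample(0:9, 1))
        }
      })
      # unique keys per catalog
      keys <- vapply(rows, function(r) paste(r[[2]], r[[3]]), "")
      make_catalog(paste0("S", s), rows[!duplicated(keys)])
    })
    wc <- identify_wt_junction(ase, normals)

    # brute-force oracle over all (junction, sample) pairs
    pool <- do.call(rbind, lapply(normals, function(cat) {
      df <- as.data.frame(cat)
      df$sample <- attr(cat, "sample_id")
      df
    }))
    shares_start <- pool$intron_start == 100
    shares_end <- pool$intron_end == 500
    cand <- pool[(shares_start | shares_end) &
                   !(shares_start & shares_end) &
                   pool$unique_reads >= 1, , drop = FALSE]
    if (nrow(cand) == 0) {
      expect_false(wc$found)
      next
    }
    agg_n <- tapply(cand$sample, paste(cand$intron_start, cand$intron_end),
                    function(x) length(unique(x)))
    agg_r <- tapply(cand$unique_reads,
                    paste(cand$intron_start, cand$intron_end), sum)
    key <- names(agg_n)
    coords <- do.call(rbind, strsplit(key, " "))
    o <- order(-as.integer(agg_n), -as.integer(agg_r),
               as.integer(coords[, 1]), as.integer(coords[, 2]))
    expect_true(wc$found)
    expect_equal(wc$wt_junction$intron_start, as.integer(coords[o[1], 1]))
    expect_equal(wc$wt_junction$intron_end, as.integer(coords[o[1], 2]))
    # exactly one shared coordinate, never the ASE
    shared <- (wc$wt_junction$intron_start == 100) +
      (wc$wt_junction$intron_end == 500)
    expect_equal(shared, 1)

    # permutation invariance
    wc2 <- identify_wt_junction(ase, rev(normals))
    expect_equal(wc2$wt_junction[1:3], wc$wt_junction[1:3])
  }
})

test_that("strand agreement is required when both strands are known", {
  ase <- junction_event("chr1", 100, 500, strand = "+")
  minus <- make_catalog("S1", list(list("chr1", 100, 300, 10)))
  minus$strand <- "-"
  expect_false(identify_wt_junction(ase, list(minus))$found)
  minus$strand <- "+"
  expect_true(identify_wt_junction(ase, list(minus))$found)
})

test_that("read_event_table round-trips sample sets", {
  p <- tempfile()
  writeLines(c("chrom\tintron_start\tintron_end\tstrand\tgene\texpressing_samples\toutlier_oe_samples",
               "chr1\t100\t500\t+\tG1\tT1,T2\tT1",
               "chr2\t30\t60\t*\tG2\t\t"), p)
  evs <- read_event_table(p)
  expect_length(evs, 2)
  expect_identical(evs[[1]]$expressing_samples, c("T1", "T2"))
  expect_identical(evs[[1]]$outlier_oe_samples, "T1")
  expect_length(evs[[2]]$expressing_samples, 0)
})
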