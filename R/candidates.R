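#' Filter event summaries down to principal neoantigen candidates
#'
#' An event is a principal candidate when it (i) shows relevant binding
#' (ASE average PHBR below the relevant-binder threshold), (ii) has an
#' identified WT alternative junction whose average PHBR is larger than
#' the ASE's, (iii) occurs in more than `min_pct_samples` of the tumor
#' cohort, and (iv) shows outlier overexpression in more than
#' `min_pct_oe` of tumors (any overexpression by default; the upstream
#' outlier caller decides significance).
#'
#' @param summaries List of `EventSummary` objects, each additionally
#'   carrying `event`, `gene_symbol` and `pct_outlier_oe` elements (the
#'   pipeline attaches these).
#' @param min_pct_samples Minimum cohort fraction (exclusive), default 0.5.
#' @param min_pct_oe Minimum outlier-overexpressed fraction (exclusive),
#'   default 0.
#' @param relevant_threshold PHBR ceiling for relevant binding; default 2
#'   (MHC-I). Use 5 for MHC-II runs.
#' @return Data.frame of `CandidateRow`s sorted by ascending ASE PHBR:
#'   columns `event`, `ase_phbr`, `wt_phbr`, `best_peptide_hla`,
#'   `pct_samples`, `gene_symbol`, `pct_outlier_oe`, `binder_class`,
#'   `principal`.
#' @export
filter_candidates <- function(summaries, min_pct_samples = 0.5,
                              min_pct_oe = 0, relevant_threshold = 2) {
  summaries <- Filter(function(s) !isTRUE(s$unreportable), summaries)
  if (length(summaries) == 0L) {
    return(data.frame(event = character(), ase_phbr = numeric(),
                      wt_phbr = numeric(), best_peptide_hla = character(),
                      pct_samples = numeric(), gene_symbol = character(),
                      pct_outlier_oe = numeric(), binder_class = character(),
                      principal = logical(), stringsAsFactors = FALSE))
  }
  g <- function(name, default) {
    vapply(summaries, function(s) {
      v <- s[[name]]
      if (is.null(v) || length(v) == 0L) default else v
    }, default)
  }
  df <- data.frame(
    event = g("event", NA_character_),
    ase_phbr = g("ase_phbr", NA_real_),
    wt_phbr = g("wt_phbr", NA_real_),
    best_peptide_hla = paste(g("best_peptide", NA_character_),
                             g("best_allele", NA_character_)),
    pct_samples = g("pct_samples", NA_real_),
    gene_symbol = g("gene_symbol", NA_character_),
    pct_outlier_oe = g("pct_outlier_oe", NA_real_),
    stringsAsFactors = FALSE)
  class_mode <- g("class_mode", NA_character_)
  df$binder_class <- vapply(seq_len(nrow(df)), function(i) {
    cm <- if (is.na(class_mode[i])) "MHC-I" else class_mode[i]
    classify_binder(df$ase_phbr[i], cm)
  }, character(1))
  df$principal <- !is.na(df$ase_phbr) &
    df$ase_phbr < relevant_threshold &
    !is.na(df$wt_phbr) & df$wt_phbr > df$ase_phbr &
    df$pct_samples > min_pct_samples &
    !is.na(df$pct_outlier_oe) & df$pct_outlier_oe > min_pct_oe
  df <- df[order(df$ase_phbr, df$event), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Differential-binding flags between responders and nonresponders
#'
#' Compares the responder group's average PHBR against the nonresponder
#' group's for one event. `binder_in_R_only` is set when the responders
#' show binding (strong or weak/relevant) while the nonresponders show
#' none -- either a non-binding average or no average at all (every
#' nonresponder excluded). `stronger_category_in_R` is set when both
#' averages exist and the responder class is strictly stronger on the
#' order strong > weak/relevant > non.
#'
#' @param r_avg Responder-group average PHBR (> 0).
#' @param nr_avg Nonresponder-group average PHBR, or `NA` when absent.
#' @param class_mode `"MHC-I"` or `"MHC-II"`.
#' @return Character vector: subset of
#'   `c("binder_in_R_only", "stronger_category_in_R")`.
#' @export
differential_binding <- function(r_avg, nr_avg = NA_real_,
                                 class_mode = c("MHC-I", "MHC-II")) {
  class_mode <- match.arg(class_mode)
  stopifnot(length(r_avg) == 1L, r_avg > 0)
  rc <- classify_binder(r_avg, class_mode)
  nc <- if (is.na(nr_avg)) NA_character_ else classify_binder(nr_avg, class_mode)
  flags <- character()
  if (rc != "non" && (is.na(nc) || nc == "non")) {
    flags <- c(flags, "binder_in_R_only")
  }
  if (!is.na(nc) && binder_strength(rc) > binder_strength(nc)) {
    flags <- c(flags, "stronger_category_in_R")
  }
  flags
}

#' Group-average PHBR with exclusions
#'
#' Arithmetic mean of per-sample PHBR over the members of one group,
#' dropping excluded samples (premature stop, short peptide, assembly
#' failure). When every member is excluded the average is absent (`NA`),
#' mirroring a reported-as-NA event.
#'
#' @param per_sample Named numeric vector of per-sample PHBR scores, or a
#'   list of `PHBRResult` objects (names/sample_ids identify samples).
#' @param group_members Character vector of sample IDs forming the group.
#' @param exclusions Character vector of excluded sample IDs (or a named
#'   character vector of reasons, names = sample IDs).
#' @return Numeric scalar, or `NA_real_` when no member remains.
#' @export
cohort_group_average <- function(per_sample, group_members,
                                 exclusions = character()) {
  if (is.list(per_sample) && length(per_sample) &&
      inherits(per_sample[[1L]], "PHBRResult")) {
    vals <- vapply(per_sample, `[[`, numeric(1), "phbr")
    names(vals) <- vapply(per_sample, `[[`, character(1), "sample_id")
    per_sample <- vals
  }
  excl_ids <- if (!is.null(names(exclusions)) && any(nzchar(names(exclusions))))
    names(exclusions) else as.character(exclusions)
  keep <- intersect(setdiff(group_members, excl_ids), names(per_sample))
  if (length(keep) == 0L) return(NA_real_)
  mean(per_sample[keep])
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability method: the p-value is the sum of hypergeometric
#' probabilities of all tables (with the observed margins) whose
#' probability does not exceed the observed table's. For the margin sizes
#' this pipeline sees, numerator binomial coefficients are exact integers
#' in double precision, so the enumeration is exact; a tiny relative
#' tolerance (1e-7) guards ties against floating-point noise, matching
#' the conventional implementation. A degenerate margin (all lost or all
#' maintained, or one group empty) yields p = 1.
#'
#' @param tab 2x2 integer matrix (rows: lost/maintained; columns:
#'   responder/nonresponder), or a length-4 vector in row-major order.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(tab) {
  x <- as.integer(tab)
  stopifnot(length(x) == 4L, all(x >= 0L))
  if (is.matrix(tab)) {
    a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  } else {
    a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  }
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  if (r1 == 0L || r2 == 0L || c1 == 0L || c1 == n) {
    sn_log("degenerate 2x2 margin; p = 1", level = "info")
    return(1)
  }
  support <- max(0L, c1 - r2):min(r1, c1)
  num <- choose(r1, support) * choose(r2, c1 - support)
  obs <- choose(r1, a) * choose(r2, c1 - a)
  sum(num[num <= obs * (1 + 1e-7)]) / choose(n, c1)
}

#' Per-event and pooled loss-association testing
#'
#' For each event, tests whether post-treatment expression loss is
#' associated with therapy response: a two-sided Fisher exact test on the
#' 2x2 of (lost vs maintained) x (responder vs nonresponder), with
#' Benjamini-Hochberg adjustment across events. A pooled test on the
#' summed 2x2 asks whether loss is associated with response over all
#' events together. Samples with flag `"absent"` (or `NA`) do not enter
#' the table for that event.
#'
#' @param loss_matrix Character matrix (events x samples) with values in
#'   `c("lost", "maintained", "absent")`; row names are event IDs, column
#'   names sample IDs. Logical matrices are accepted (TRUE = lost).
#' @param response Named character vector mapping sample ID to
#'   `"responder"` or `"nonresponder"`.
#' @return List with `per_event` (data.frame: event, lost_R, lost_NR,
#'   maintained_R, maintained_NR, p, p_adj) and `pooled` (list: table, p).
#' @export
loss_association_test <- function(loss_matrix, response) {
  if (is.logical(loss_matrix)) {
    lm2 <- ifelse(loss_matrix, "lost", "maintained")
    dimnames(lm2) <- dimnames(loss_matrix)
    loss_matrix <- lm2
  }
  samples <- colnames(loss_matrix)
  if (is.null(samples) || !all(samples %in% names(response))) {
    stop("every loss-matrix column needs a response label")
  }
  is_r <- response[samples] == "responder"
  per <- lapply(seq_len(nrow(loss_matrix)), function(i) {
    flags <- loss_matrix[i, ]
    use <- !is.na(flags) & flags != "absent"
    lost <- flags == "lost" & use
    maint <- flags == "maintained" & use
    tab <- matrix(c(sum(lost & is_r), sum(lost & !is_r),
                    sum(maint & is_r), sum(maint & !is_r)),
                  nrow = 2L, byrow = TRUE,
                  dimnames = list(c("lost", "maintained"),
                                  c("responder", "nonresponder")))
    list(tab = tab, p = fisher_exact_2x2(tab))
  })
  tabs <- lapply(per, `[[`, "tab")
  p <- vapply(per, `[[`, numeric(1), "p")
  events <- rownames(loss_matrix)
  if (is.null(events)) events <- paste0("event", seq_len(nrow(loss_matrix)))
  per_event <- data.frame(
    event = events,
    lost_R = vapply(tabs, function(t) t[1, 1], integer(1)),
    lost_NR = vapply(tabs, function(t) t[1, 2], integer(1)),
    maintained_R = vapply(tabs, function(t) t[2, 1], integer(1)),
    maintained_NR = vapply(tabs, function(t) t[2, 2], integer(1)),
    p = p,
    p_adj = p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE)
  pooled_tab <- Reduce(`+`, tabs)
  list(per_event = per_event,
       pooled = list(table = pooled_tab, p = fisher_exact_2x2(pooled_tab)))
}

#' Write an event report TSV
#'
#' Candidate rows are written with the fixed column order
#' `event, ase_phbr, wt_phbr, best_peptide_hla, pct_samples, gene_symbol,
#' pct_outlier_oe`; group-comparison rows with
#' `event, responder_phbr, responder_best_peptide_hla, nonresponder_phbr,
#' gene_symbol`. PHBR values are printed to two decimals, percentages to
#' one; row order follows the input (which the producing functions make
#' deterministic).
#'
#' @param rows Non-empty data.frame of candidate or group-comparison rows.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_event_report <- function(rows, path) {
  if (NROW(rows) == 0L) stop("refusing to write an empty report")
  fmt2 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
  pct <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f%%", 100 * x))
  if ("responder_phbr" %in% names(rows)) {
    out <- data.frame(
      event = rows$event,
      responder_phbr = fmt2(rows$responder_phbr),
      responder_best_peptide_hla = rows$responder_best_peptide_hla,
      nonresponder_phbr = fmt2(rows$nonresponder_phbr),
      gene_symbol = rows$gene_symbol,
      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      event = rows$event,
      ase_phbr = fmt2(rows$ase_phbr),
      wt_phbr = fmt2(rows$wt_phbr),
      best_peptide_hla = rows$best_peptide_hla,
      pct_samples = pct(rows$pct_samples),
      gene_symbol = rows$gene_symbol,
      pct_outlier_oe = pct(rows$pct_outlier_oe),
      stringsAsFactors = FALSE)
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write report to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read an event-by-sample loss matrix
#'
#' TSV with events as rows (first column `event`) and sample IDs as the
#' remaining column names; values in `c("lost", "maintained", "absent")`.
#'
#' @param path Path to the TSV.
#' @return Character matrix with event row names and sample column names.
#' @export
read_loss_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "event") stop("first column must be 'event'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$event
  bad <- setdiff(unique(as.vector(m)), c("lost", "maintained", "absent", NA))
  if (length(bad)) stop("unknown loss flags: ", paste(bad, collapse = ", "))
  m
}
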