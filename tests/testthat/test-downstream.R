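simple_tx <- function() {
  # single-exon coding transcript: 5'UTR 0..99, CDS 100..299, 3'UTR 300..399
  tx <- data.frame(tx_id = "tx1", contig = "tx1", strand = "+", tss = 0L,
                   cds_start = 100L, cds_end = 300L, stringsAsFactors = FALSE)
  tx$exons <- list(cbind(start = 0L, end = 400L))
  tx
}

test_that("metagene assigns boundary and intronic sites correctly", {
  tx <- simple_tx()
  sites <- data.frame(contig = "tx1", strand = "+",
                      pos = c(100L, 0L, 399L), stringsAsFactors = FALSE)
  prof <- metagene_profile(sites, tx, bins_per_segment = 10L)
  expect_equal(sum(prof$density), 1, tolerance = 1e-9)
  # first CDS base falls in the first CDS bin
  expect_identical(prof$counts[11], 1L)
  # TSS falls in the first 5'UTR bin, last base in the last 3'UTR bin
  expect_identical(prof$counts[1], 1L)
  expect_identical(prof$counts[30], 1L)
})

test_that("metagene excludes non-exonic sites and reports them", {
  tx <- data.frame(tx_id = "tx2", contig = "chrT", strand = "+", tss = 0L,
                   cds_start = 10L, cds_end = 90L, stringsAsFactors = FALSE)
  tx$exons <- list(cbind(start = c(0L, 60L), end = c(40L, 110L)))
  sites <- data.frame(contig = "chrT", strand = "+",
                      pos = c(20L, 50L), stringsAsFactors = FALSE)
  expect_message(prof <- metagene_profile(sites, tx, 5L), "excluded")
  expect_identical(prof$n_sites, 1L)
  expect_identical(prof$n_excluded, 1L)
  expect_error(metagene_profile(sites[2, , drop = FALSE], tx, 5L),
               "no sites mappable")
})

test_that("uniform exonic sites give per-segment uniform metagene bins", {
  tx <- simple_tx()
  set.seed(31)
  sites <- data.frame(contig = "tx1", strand = "+",
                      pos = sample(0:399, 4000, replace = TRUE))
  prof <- metagene_profile(sites, tx, bins_per_segment = 10L)
  for (seg in c("5'UTR", "CDS", "3'UTR")) {
    cnt <- prof$counts[prof$segment == seg]
    expect_gt(chisq.test(cnt)$p.value, 0.01)
  }
  # permutation invariance
  prof2 <- metagene_profile(sites[sample(nrow(sites)), , drop = FALSE],
                            tx, bins_per_segment = 10L)
  expect_identical(prof2$counts, prof$counts)
})

test_that("metagene resolves multi-transcript sites to the longest CDS", {
  tx <- rbind(simple_tx(), simple_tx())
  tx$tx_id <- c("short", "long")
  tx$cds_start <- c(190L, 100L)  # short CDS 190..300, long CDS 100..300
  # site at 150: 5'UTR of 'short', CDS of 'long' -> longest CDS wins
  sites <- data.frame(contig = "tx1", strand = "+", pos = 150L)
  prof <- metagene_profile(sites, tx, bins_per_segment = 4L)
  expect_identical(sum(prof$counts[prof$segment == "CDS"]), 1L)
})

test_that("TSS alignment bins strand-aware offsets with overflow", {
  tss <- data.frame(contig = c("tx1", "tx1"), pos = c(100L, 500L),
                    strand = c("+", "-"), stringsAsFactors = FALSE)
  sites <- data.frame(contig = "tx1",
                      strand = c("+", "+", "-", "+"),
                      pos = c(100L, 102L, 503L, 200L),
                      stringsAsFactors = FALSE)
  h <- tss_alignment(sites, tss, max_offset = 5L)
  expect_identical(unname(h[["0"]]), 1L)
  expect_identical(unname(h[["2"]]), 1L)
  # minus strand: a higher genomic coordinate is 5' of the TSS
  expect_identical(unname(h[["-3"]]), 1L)
  expect_identical(unname(h[["beyond"]]), 1L)
  expect_error(tss_alignment(sites, tss[0, ]), "empty")
})

test_that("TSS alignment is translation invariant", {
  set.seed(5)
  tss <- data.frame(contig = "tx1", pos = sample(100:900, 20), strand = "+")
  sites <- data.frame(contig = "tx1", strand = "+",
                      pos = sample(100:900, 50, replace = TRUE))
  h1 <- tss_alignment(sites, tss)
  tss$pos <- tss$pos + 1000L
  sites$pos <- sites$pos + 1000L
  expect_identical(tss_alignment(sites, tss), h1)
})

test_that("hypergeometric overlap matches exact values and enumeration", {
  u <- paste0("s", 1:10)
  ov <- overlap_significance(u[1:5], u[1:5], u)
  expect_equal(ov$p_value, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(ov$p_value, 1 / 252, tolerance = 1e-9)
  # empty overlap: the upper tail from 0 is the whole space
  ov0 <- overlap_significance(u[1:5], u[6:10], u)
  expect_identical(ov0$k, 0L)
  expect_equal(ov0$p_value, 1)
  expect_error(overlap_significance(c(u[1], "alien"), u[1:2], u),
               "subset")
  # exhaustive enumeration oracle for N <= 12
  set.seed(13)
  for (trial in 1:5) {
    N <- sample(6:12, 1)
    uni <- paste0("x", seq_len(N))
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    A <- sample(uni, K)
    B <- sample(uni, n)
    k_obs <- length(intersect(A, B))
    draws <- combn(N, n)
    tail_frac <- mean(apply(draws, 2, function(ix)
      length(intersect(uni[ix], A)) >= k_obs))
    p <- overlap_significance(A, B, uni)$p_value
    expect_equal(p, tail_frac, tolerance = 1e-9)
  }
})

make_wt_sites <- function(ids, padj, pass) {
  data.frame(site_id = ids, padj = padj,
             filter_status = ifelse(pass, "pass", "not_enriched"),
             stringsAsFactors = FALSE)
}

test_that("ROC is perfect when regulation coincides with WT insignificance", {
  ids <- paste0("s", 1:40)
  padj <- c(runif(20, 0.5, 1), runif(20, 0, 1e-4))  # first 20 insignificant
  wt <- make_wt_sites(ids, padj, pass = padj < 0.05)
  reg <- data.frame(site_id = ids[1:20], lfc = 2, p_value = 0.001,
                    stringsAsFactors = FALSE)
  roc <- roc_regulated_vs_unmethylated(wt, reg)
  expect_true(all(roc$auc == 1))
  expect_identical(unname(roc$n_positive["lfc_1.5"]), 20L)
})

test_that("ROC AUC equals the tie-corrected Mann-Whitney statistic", {
  set.seed(23)
  n <- 200
  ids <- paste0("s", seq_len(n))
  padj <- round(runif(n), 2)  # coarse values force ties
  truth <- runif(n) < 0.3
  wt <- make_wt_sites(ids, padj, pass = !truth | runif(n) < 0.5)
  reg <- data.frame(site_id = ids[truth], lfc = 2, p_value = 0.001,
                    stringsAsFactors = FALSE)
  roc <- roc_regulated_vs_unmethylated(wt, reg, lfc_strata = 0)
  universe <- roc$universe
  lab <- universe %in% ids[truth]
  score <- padj[match(universe, ids)]
  w <- wilcox.test(score[lab], score[!lab], exact = FALSE)$statistic
  expect_equal(unname(roc$auc), unname(w / (sum(lab) * sum(!lab))),
               tolerance = 1e-12)
})

test_that("randomly labelled regulation gives chance-level AUC", {
  set.seed(47)
  n <- 1000
  ids <- paste0("s", seq_len(n))
  padj <- runif(n)
  wt <- make_wt_sites(ids, padj, pass = TRUE)
  aucs <- replicate(60, {
    reg <- data.frame(site_id = sample(ids, 200), lfc = 2, p_value = 0.001,
                      stringsAsFactors = FALSE)
    roc_regulated_vs_unmethylated(wt, reg, lfc_strata = 0)$auc
  })
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("ROC strata without positives report an undefined AUC", {
  ids <- paste0("s", 1:10)
  wt <- make_wt_sites(ids, runif(10), pass = TRUE)
  reg <- data.frame(site_id = ids[1:3], lfc = 0.6, p_value = 0.001,
                    stringsAsFactors = FALSE)
  roc <- roc_regulated_vs_unmethylated(wt, reg)
  expect_false(is.na(roc$auc[["lfc_0.5"]]))
  expect_true(is.na(roc$auc[["lfc_1.0"]]))
  # curves are monotone non-decreasing
  for (cv in roc$curves) {
    expect_true(all(diff(cv$fpr) >= 0))
    expect_true(all(diff(cv$tpr) >= 0))
  }
})

test_that("consensus PFM recovers the planted DRACH context", {
  sc <- cached_scenario("basic", 1)
  sites <- sc$methylome$sites
  pfm <- consensus_pfm(sites, sc$reference, flank = 5L)
  expect_equal(unname(pfm$pfm["A", "0"]), 1)
  expect_equal(unname(pfm$pfm["C", "1"]), 1)
  expect_identical(substr(pfm$consensus, 6, 7), "AC")
  expect_equal(colSums(pfm$pfm), rep(1, 11), ignore_attr = TRUE)
})

test_that("consensus PFM skips truncated flanks and errors when empty", {
  ref <- ReferenceSet(c(chrT = "GGACTGGACTT"))
  sites <- data.frame(contig = "chrT", strand = "+", pos = c(2L, 7L))
  expect_message(pfm <- consensus_pfm(sites, ref, flank = 3L), "skipped")
  expect_identical(pfm$n_sites, 1L)
  expect_error(suppressMessages(
    consensus_pfm(sites[1, , drop = FALSE], ref, flank = 6L)))
})
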