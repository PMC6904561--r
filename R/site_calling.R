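#' Configuration for the m6ACE-vs-input enrichment test
#'
#' @param min_fold Minimum fold enrichment of m6ACE over input for a
#'   site to be called (default 2).
#' @param padj_cutoff BH-adjusted p-value cutoff (default 0.05).
#' @param fdr Target false-discovery rate of the BH family (default
#'   0.1; recorded alongside `padj_cutoff`).
#' @param dispersion One of `"shrink"` (per-site method-of-moments
#'   dispersion shrunk halfway toward the trimmed-mean dispersion
#'   across sites) or `"per-site"` (no shrinkage).
#' @param pseudocount Added to both normalised means when reporting
#'   log2 fold change (not used in testing). Default 0.5.
#' @param cluster_window,cluster_max_starts,cluster_dominance
#'   Clustered-noise filter constants, see [filter_clustered_noise()].
#' @return A list of class `EnrichmentTestConfig`.
#' @export
enrichment_config <- function(min_fold = 2, padj_cutoff = 0.05, fdr = 0.1,
                              dispersion = c("shrink", "per-site"),
                              pseudocount = 0.5,
                              cluster_window = 25L,
                              cluster_max_starts = 10L,
                              cluster_dominance = 0.5) {
  stopifnot(min_fold >= 1, padj_cutoff > 0, padj_cutoff < 1,
            fdr > 0, fdr < 1, pseudocount >= 0)
  structure(list(min_fold = min_fold, padj_cutoff = padj_cutoff, fdr = fdr,
                 dispersion = match.arg(dispersion),
                 pseudocount = pseudocount,
                 cluster_window = as.integer(cluster_window),
                 cluster_max_starts = as.integer(cluster_max_starts),
                 cluster_dominance = cluster_dominance),
            class = "EnrichmentTestConfig")
}

#' DESeq-style median-of-ratios size factors
#'
#' Computed over the candidate count matrix; sites with a zero in any
#' sample are excluded from the geometric means. The median of ratios
#' is only meaningful when the usable sites are mostly unenriched, so
#' when fewer than `min_sites` survive the zero exclusion the fallback
#' is total-count ratios (library sizes scaled to geometric mean 1).
#'
#' @param counts Numeric matrix, sites x samples.
#' @param library_sizes Named totals used for the fallback.
#' @param min_sites Minimum number of all-positive sites required for
#'   the median-of-ratios estimate (default 10).
#' @return Named numeric vector of size factors (geometric mean 1).
#' @export
size_factors <- function(counts, library_sizes = colSums(counts),
                         min_sites = 10L) {
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (sum(use) >= min_sites) {
    geo <- exp(log_geo[use])
    sf <- apply(counts[use, , drop = FALSE], 2L, function(cj)
      stats::median(cj / geo))
    sf <- exp(log(sf) - mean(log(sf)))
  } else {
    ls <- as.numeric(library_sizes)
    if (any(ls <= 0)) stop("zero library size; cannot normalise")
    sf <- ls / exp(mean(log(ls)))
    names(sf) <- colnames(counts)
  }
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factors; check count table")
  sf
}

# Per-site method-of-moments NB dispersion on normalised counts.
# xi corrects the Poisson component for unequal size factors.
mom_dispersion <- function(q, group, xi) {
  m <- tapply(q, group, mean)
  if (all(m == 0)) return(0)
  dev <- q - m[group]
  v <- sum(dev^2) / (length(q) - length(m))
  mbar <- mean(q)
  max(0, (v - mbar * xi) / mbar^2)
}

# One-sided exact conditional NB test of m6ACE enrichment: the m6ACE
# group sum is compared to its conditional distribution given the
# site total, with group sums moment-matched to negative binomials
# under unequal size factors. The mid-p correction removes the
# conservatism of the discrete tail.
exact_nb_test <- function(y, is_m6, sf, alpha) {
  s1 <- sum(y[is_m6])
  total <- s1 + sum(y[!is_m6])
  if (total == 0L) return(1)
  n1 <- sum(sf[is_m6]); n2 <- sum(sf[!is_m6])
  mu <- total / (n1 + n2)
  a <- max(alpha, 1e-10)
  size1 <- n1^2 / (a * sum(sf[is_m6]^2))
  size2 <- n2^2 / (a * sum(sf[!is_m6]^2))
  k <- 0:total
  lp <- stats::dnbinom(k, size = size1, mu = mu * n1, log = TRUE) +
    stats::dnbinom(total - k, size = size2, mu = mu * n2, log = TRUE)
  lp <- lp - max(lp)
  pr <- exp(lp); pr <- pr / sum(pr)
  min(1, sum(pr[k > s1]) + 0.5 * pr[k == s1])
}

#' Test per-site m6ACE-over-input enrichment
#'
#' For each candidate adenosine start site, the m6ACE and input counts
#' are compared with a one-sided (enrichment only) exact conditional
#' negative-binomial test: the m6ACE group sum is referred to its
#' distribution given the site's total count, with group sums
#' moment-matched for the median-of-ratios size factors and a mid-p
#' correction for discreteness. Dispersions are per-site
#' method-of-moments estimates shrunk halfway toward the 20%-trimmed
#' mean across sites. p-values are BH-adjusted across all tested
#' sites; a site is `enriched` iff `log2FC >= log2(min_fold)` and
#' `padj < padj_cutoff`.
#'
#' @param candidates A candidate `ReadStartTable` (see
#'   [candidate_sites()]).
#' @param config An [enrichment_config()].
#' @return Data frame, one row per site: `contig`, `strand`, `pos`,
#'   `site_id`, `mean_m6ACE`, `mean_input` (normalised means),
#'   `log2FC`, `p_value`, `padj`, `enriched`, `filter_status`
#'   (`"pass"`/`"not_enriched"` at this stage).
#' @export
test_enrichment <- function(candidates, config = enrichment_config()) {
  samp <- candidates$samples
  for (lib in LIBRARY_LEVELS)
    if (sum(samp$library == lib) < 2L)
      stop("need >= 2 replicates of the ", lib, " library")
  if (any(candidates$library_sizes <= 0))
    stop("zero library size; cannot normalise")
  cnt <- candidates$counts
  n_sites <- nrow(cnt)
  if (n_sites == 0L) stop("no candidate sites to test")
  Y <- as.matrix(cnt[, samp$sample, with = FALSE])
  sf <- size_factors(Y, candidates$library_sizes[samp$sample])
  group <- factor(samp$library, levels = c("input", "m6ACE"))
  is_m6 <- group == "m6ACE"
  xi <- mean(1 / sf)
  Q <- sweep(Y, 2L, sf, "/")
  alpha <- vapply(seq_len(n_sites), function(i) mom_dispersion(Q[i, ], group, xi), 0)
  if (config$dispersion == "shrink" && n_sites > 1L) {
    alpha_prior <- mean(alpha, trim = 0.2)
    alpha <- 0.5 * alpha + 0.5 * alpha_prior
  }
  alpha <- pmin(alpha, 10)
  p_value <- vapply(seq_len(n_sites), function(i)
    exact_nb_test(Y[i, ], is_m6, sf, alpha[i]), 0)
  mean_m6 <- rowMeans(Q[, group == "m6ACE", drop = FALSE])
  mean_in <- rowMeans(Q[, group == "input", drop = FALSE])
  log2FC <- log2((mean_m6 + config$pseudocount) /
                 (mean_in + config$pseudocount))
  padj <- stats::p.adjust(p_value, method = "BH")
  enriched <- log2FC >= log2(config$min_fold) & padj < config$padj_cutoff
  out <- data.frame(contig = cnt$contig, strand = cnt$strand, pos = cnt$pos,
                    site_id = paste(cnt$contig, cnt$pos, cnt$strand, sep = ":"),
                    mean_m6ACE = mean_m6, mean_input = mean_in,
                    log2FC = log2FC, p_value = p_value, padj = padj,
                    enriched = enriched,
                    filter_status = ifelse(enriched, "pass", "not_enriched"),
                    stringsAsFactors = FALSE)
  out[order(out$contig, out$pos, out$strand), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Filter exonuclease shadow sites
#'
#' Imperfect 5'->3' exonuclease stoppage leaves a mild pileup of read
#' starts a few nucleotides 5' of genuine methylated sites. An
#' enriched site S is marked `shadow_filtered` when another enriched
#' site T lies 1-4 nt 3' of it (strand-aware offset S->T in 1..4) and
#' T sits in an R-A-C context on the reference (R = A/G at offset -1,
#' A at 0, C at +1, strand-aware).
#'
#' @param sites Data frame from [test_enrichment()].
#' @param reference A `ReferenceSet`.
#' @param max_offset Largest shadow offset considered (default 4).
#' @return `sites` with updated `filter_status`.
#' @export
filter_shadow_sites <- function(sites, reference, max_offset = 4L) {
  enr <- sites[sites$enriched, , drop = FALSE]
  if (nrow(enr) < 2L) return(sites)
  ctx <- site_context(reference, enr$contig, enr$pos, enr$strand, -1L, 1L)
  is_rac <- grepl("^[AG]AC$", ctx)
  shadowed <- character(0)
  for (i in seq_len(nrow(enr))) {
    dir <- if (enr$strand[i] == "+") 1L else -1L
    nb_pos <- enr$pos[i] + dir * seq_len(max_offset)
    hit <- enr$contig == enr$contig[i] & enr$strand == enr$strand[i] &
      enr$pos %in% nb_pos & is_rac
    if (any(hit)) shadowed <- c(shadowed, enr$site_id[i])
  }
  mark <- sites$site_id %in% shadowed & sites$filter_status == "pass"
  sites$filter_status[mark] <- "shadow_filtered"
  sites
}

#' Filter sites inside clustered read-start noise
#'
#' Spurious enrichment sometimes arises inside diffuse clusters of
#' read starts rather than the sharp pileup genuine methylation
#' produces. An enriched site is marked `cluster_filtered` when,
#' within `window` nt either side in the pooled m6ACE libraries, more
#' than `max_distinct_starts` distinct positions carry reads and the
#' site's own read-start signature -- the strand-aware offsets -4..0
#' that constitute a genuine site's pileup, imperfect exonuclease
#' stoppage included -- holds less than `dominance` of the pooled
#' window counts.
#'
#' @param sites Data frame from [test_enrichment()].
#' @param full_table The FULL `ReadStartTable` (all positions).
#' @param window Half-width of the window in nt (default 25).
#' @param max_distinct_starts Distinct-position threshold (default 10).
#' @param dominance Minimum fraction of pooled window counts the
#'   site's -4..0 signature must carry to escape filtering (default
#'   0.5).
#' @return `sites` with updated `filter_status`.
#' @export
filter_clustered_noise <- function(sites, full_table, window = 25L,
                                   max_distinct_starts = 10L,
                                   dominance = 0.5) {
  enr_idx <- which(sites$enriched)
  if (length(enr_idx) == 0L) return(sites)
  m6cols <- sample_columns(full_table, "m6ACE")
  cnt <- full_table$counts
  pooled <- rowSums(as.matrix(cnt[, m6cols, with = FALSE]))
  signature_pos <- function(pos, strand)
    if (strand == "+") pos - 4L:0L else pos + 4L:0L
  for (i in enr_idx) {
    sel <- cnt$contig == sites$contig[i] & cnt$strand == sites$strand[i] &
      abs(cnt$pos - sites$pos[i]) <= window
    w <- pooled[sel]
    wpos <- cnt$pos[sel]
    n_distinct <- sum(w > 0)
    own_pos <- signature_pos(sites$pos[i], sites$strand[i])
    # a nearby *enriched* site's pileup is signal, not noise: its
    # signature does not count against this site's dominance
    others <- which(sites$enriched & sites$contig == sites$contig[i] &
                    sites$strand == sites$strand[i] &
                    sites$pos != sites$pos[i] &
                    abs(sites$pos - sites$pos[i]) <= window + 4L)
    other_pos <- setdiff(unlist(lapply(others, function(j)
      signature_pos(sites$pos[j], sites$strand[j]))), own_pos)
    total <- sum(w[!wpos %in% other_pos])
    own <- sum(w[wpos %in% own_pos])
    if (n_distinct > max_distinct_starts && total > 0 &&
        own < dominance * total &&
        sites$filter_status[i] == "pass")
      sites$filter_status[i] <- "cluster_filtered"
  }
  sites
}

#' Call m6A/m6Am sites from aligned reads
#'
#' End-to-end site calling: deduplicate, collate strand-aware read
#' starts, restrict to candidate adenosine starts (mean m6ACE count
#' across replicates >= `min_mean_count`), test m6ACE-over-input
#' enrichment, then apply the shadow-site and clustered-noise filters.
#'
#' @param reads Aligned-read data.frame (deduplicated or not).
#' @param reference A `ReferenceSet`.
#' @param config An [enrichment_config()].
#' @param min_mean_count Candidate threshold on mean m6ACE counts
#'   (default 1).
#' @return List with `sites` (full audit table with `filter_status`),
#'   `pass` (the subset with `filter_status == "pass"`), and `table`
#'   (the FULL `ReadStartTable`).
#' @export
call_sites <- function(reads, reference, config = enrichment_config(),
                       min_mean_count = 1) {
  reads <- deduplicate(reads)
  full <- collate_read_starts(reads, reference)
  cand <- candidate_sites(full, reference, min_mean_count)
  sites <- test_enrichment(cand, config)
  sites <- filter_shadow_sites(sites, reference)
  sites <- filter_clustered_noise(sites, full,
                                  window = config$cluster_window,
                                  max_distinct_starts = config$cluster_max_starts,
                                  dominance = config$cluster_dominance)
  list(sites = sites,
       pass = sites[sites$filter_status == "pass", , drop = FALSE],
       table = full)
}
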