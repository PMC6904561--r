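#' Metagene profile of sites over a scaled 5'UTR|CDS|3'UTR axis
#'
#' Each site is assigned to a coding transcript containing it (the
#' longest-CDS transcript when several match), located within the
#' 5'UTR, CDS or 3'UTR segment of the spliced transcript, scaled to
#' `[0, 1)` within that segment, and binned. The three segments are
#' concatenated, so the profile has `3 * bins_per_segment` bins and
#' the densities sum to 1. Sites on non-coding transcripts only, or in
#' introns, are excluded and counted.
#'
#' @param sites Data frame with `contig`, `strand`, `pos`.
#' @param transcripts Transcript data.frame from [read_transcripts()].
#' @param bins_per_segment Bins per segment (default 100).
#' @return List of class `MetageneProfile`: `density` (length
#'   `3 * bins_per_segment`, sums to 1), `counts`, `segment` (factor
#'   labels per bin), `n_sites` used, `n_excluded`.
#' @export
metagene_profile <- function(sites, transcripts, bins_per_segment = 100L) {
  bins_per_segment <- as.integer(bins_per_segment)
  coding <- transcripts[!is.na(transcripts$cds_start), , drop = FALSE]
  if (nrow(coding) == 0L) stop("no coding transcripts supplied")
  # spliced CDS extent in transcript coordinates, per transcript
  tx_info <- lapply(seq_len(nrow(coding)), function(i) {
    tx <- coding[i, ]
    len <- tx_length(tx)
    c1 <- tx_coord(tx, tx$cds_start)
    c2 <- tx_coord(tx, tx$cds_end - 1L)
    cds_lo <- min(c1, c2); cds_hi <- max(c1, c2)
    list(len = len, cds_lo = cds_lo, cds_hi = cds_hi,
         cds_len = cds_hi - cds_lo + 1L)
  })
  assign_one <- function(contig, strand, pos) {
    hits <- which(coding$contig == contig & coding$strand == strand)
    hits <- hits[vapply(hits, function(i)
      !is.na(tx_coord(coding[i, ], pos)), TRUE)]
    if (length(hits) == 0L) return(NA_real_)
    best <- hits[which.max(vapply(hits, function(i)
      tx_info[[i]]$cds_len, 0L))]
    info <- tx_info[[best]]
    tc <- tx_coord(coding[best, ], pos)
    if (tc < info$cds_lo) {            # 5'UTR
      seg <- 0L; frac <- tc / max(info$cds_lo, 1L)
    } else if (tc <= info$cds_hi) {    # CDS
      seg <- 1L; frac <- (tc - info$cds_lo) / info$cds_len
    } else {                           # 3'UTR
      seg <- 2L
      utr3 <- info$len - info$cds_hi - 1L
      frac <- (tc - info$cds_hi - 1L) / max(utr3, 1L)
    }
    seg + min(frac, 1 - 1e-12)
  }
  scaled <- vapply(seq_len(nrow(sites)), function(j)
    assign_one(sites$contig[j], sites$strand[j], sites$pos[j]), 0)
  used <- !is.na(scaled)
  if (!any(used)) stop("no sites mappable to coding transcripts")
  if (any(!used))
    message(sum(!used), " site(s) excluded: not exonic on a coding transcript")
  bin <- pmin(floor(scaled[used] * bins_per_segment),
              3L * bins_per_segment - 1L)
  counts <- tabulate(bin + 1L, nbins = 3L * bins_per_segment)
  structure(list(density = counts / sum(counts), counts = counts,
                 segment = factor(rep(c("5'UTR", "CDS", "3'UTR"),
                                      each = bins_per_segment),
                                  levels = c("5'UTR", "CDS", "3'UTR")),
                 n_sites = sum(used), n_excluded = sum(!used)),
            class = "MetageneProfile")
}

#' @export
print.MetageneProfile <- function(x, ...) {
  seg_mass <- tapply(x$density, x$segment, sum)
  cat("MetageneProfile:", x$n_sites, "sites (",
      x$n_excluded, "excluded );",
      paste(sprintf("%s=%.2f", names(seg_mass), seg_mass), collapse = " "),
      "\n")
  invisible(x)
}

#' Strand-aware site offsets relative to the nearest TSS
#'
#' For each site the nearest transcription start site on the same
#' contig and strand is found and the strand-aware offset (positive =
#' 3' of the TSS) recorded. Offsets beyond `max_offset` fall in a
#' `"beyond"` overflow bin. Used to show that m6Am calls coincide with
#' annotated transcription start sites.
#'
#' @param sites Data frame with `contig`, `strand`, `pos`.
#' @param tss Data frame with `contig`, `pos`, `strand`.
#' @param max_offset Histogram half-width (default 5).
#' @return Named integer vector over
#'   `(-max_offset .. +max_offset, "beyond")`.
#' @export
tss_alignment <- function(sites, tss, max_offset = 5L) {
  if (nrow(tss) == 0L) stop("empty TSS list")
  offs <- vapply(seq_len(nrow(sites)), function(i) {
    cand <- tss[tss$contig == sites$contig[i] &
                tss$strand == sites$strand[i], , drop = FALSE]
    if (nrow(cand) == 0L) return(NA_integer_)
    d <- if (sites$strand[i] == "+") sites$pos[i] - cand$pos
         else cand$pos - sites$pos[i]
    d[which.min(abs(d))]
  }, 0L)
  levels <- c(as.character(seq(-max_offset, max_offset)), "beyond")
  lab <- ifelse(is.na(offs) | abs(offs) > max_offset, "beyond",
                as.character(offs))
  table(factor(lab, levels = levels))
}

#' Hypergeometric significance of the overlap of two site sets
#'
#' Upper-tail hypergeometric probability of observing at least the
#' seen overlap when drawing `|B|` sites from a universe of `N`
#' containing `|A|` marked sites: `p = P(X >= k)`.
#'
#' @param set_a,set_b Character vectors of site ids; must be subsets
#'   of `universe`.
#' @param universe Character vector of all eligible site ids.
#' @return List of class `OverlapTest`: `N`, `K`, `n`, `k`,
#'   `p_value`.
#' @export
overlap_significance <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe)) stop("set A is not a subset of the universe")
  if (!all(set_b %in% universe)) stop("set B is not a subset of the universe")
  N <- length(universe); K <- length(set_a); n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  structure(list(N = N, K = K, n = n, k = k, p_value = p),
            class = "OverlapTest")
}

#' @export
print.OverlapTest <- function(x, ...) {
  cat(sprintf("OverlapTest: k = %d of K = %d, n = %d (N = %d), p = %.4g\n",
              x$k, x$K, x$n, x$N, x$p_value))
  invisible(x)
}

#' ROC of demethylase regulation predicting WT-insignificant status
#'
#' The universe (WT-significant sites plus sites accumulating RML on
#' demethylase knockout) is ranked most-insignificant-first by WT
#' adjusted p-value. For each LFC stratum, the positive class is the
#' sites regulated at least that strongly (accumulation
#' `lfc >= stratum`, t-test `p < p_cutoff`); the ROC measures how well
#' a site's WT insignificance predicts regulated status. Sites absent
#' from the WT results (never candidates in WT) rank maximally
#' insignificant (`padj = 1`). Tied padj values share one curve step;
#' the AUC is the trapezoidal area, identical to the tie-corrected
#' Mann-Whitney statistic.
#'
#' @param wt_sites WT site-calling results ([call_sites()]`$sites`):
#'   needs `site_id`, `padj`, `filter_status`.
#' @param regulated_calls Differential table from
#'   [differential_table()] run with `direction = "accumulation"`:
#'   needs `site_id`, `lfc`, `p_value`.
#' @param lfc_strata Numeric strata (default `c(0, 0.5, 1, 1.5)`).
#' @param p_cutoff Regulation t-test cutoff (default 0.05).
#' @return List of class `RocResult`: `auc` (named by stratum),
#'   `curves` (per stratum, data.frame of `fpr`, `tpr`), `universe`
#'   (ranked site ids), `n_positive` (per stratum).
#' @export
roc_regulated_vs_unmethylated <- function(wt_sites, regulated_calls,
                                          lfc_strata = c(0, 0.5, 1, 1.5),
                                          p_cutoff = 0.05) {
  wt_pass <- wt_sites$site_id[wt_sites$filter_status == "pass"]
  accum <- regulated_calls$site_id[regulated_calls$lfc >= 0 &
                                   regulated_calls$p_value < p_cutoff]
  universe <- union(wt_pass, accum)
  if (length(universe) == 0L) stop("empty ROC universe")
  padj <- stats::setNames(rep(1, length(universe)), universe)
  in_wt <- universe %in% wt_sites$site_id
  padj[universe[in_wt]] <-
    wt_sites$padj[match(universe[in_wt], wt_sites$site_id)]
  # deterministic ranking: descending padj, ties broken by site id for
  # output ordering only (tied sites still share one ROC step)
  ord <- order(-padj, universe)
  ranked <- universe[ord]
  score <- padj[ord]
  auc <- numeric(length(lfc_strata))
  names(auc) <- sprintf("lfc_%.1f", lfc_strata)
  curves <- vector("list", length(lfc_strata))
  names(curves) <- names(auc)
  n_pos <- integer(length(lfc_strata))
  for (s in seq_along(lfc_strata)) {
    pos_ids <- regulated_calls$site_id[
      regulated_calls$lfc >= lfc_strata[s] &
      regulated_calls$p_value < p_cutoff]
    truth <- ranked %in% pos_ids
    n1 <- sum(truth); n0 <- sum(!truth)
    n_pos[s] <- n1
    if (n1 == 0L || n0 == 0L) {
      auc[s] <- NA_real_
      curves[[s]] <- data.frame(fpr = c(0, 1), tpr = c(0, 1))
      next
    }
    # walk down the ranking, advancing one step per tied-score group
    ends <- cumsum(rle(score)$lengths)
    cum_t <- cumsum(truth)
    tp <- c(0, cum_t[ends])
    fp <- c(0, ends - cum_t[ends])
    tpr <- tp / n1; fpr <- fp / n0
    auc[s] <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    curves[[s]] <- data.frame(fpr = unname(fpr), tpr = unname(tpr))
  }
  structure(list(auc = auc, curves = curves, universe = ranked,
                 n_positive = stats::setNames(n_pos, names(auc))),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat("RocResult over", length(x$universe), "sites\n")
  for (nm in names(x$auc))
    cat(sprintf("  %s: AUC = %s (n+ = %d)\n", nm,
                ifelse(is.na(x$auc[nm]), "undefined",
                       sprintf("%.3f", x$auc[nm])), x$n_positive[nm]))
  invisible(x)
}

IUPAC_CODE <- c(A = "A", C = "C", G = "G", T = "T",
                AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Position frequency matrix and consensus around sites
#'
#' Strand-aware base frequencies at offsets `-flank..+flank` around
#' each site (offset 0 is the methylated adenosine by construction).
#' The consensus string uses the IUPAC letter covering every base with
#' frequency >= 0.25 in its column. Sites whose flank runs off the
#' contig are skipped and counted.
#'
#' @param sites Data frame with `contig`, `strand`, `pos`.
#' @param reference A `ReferenceSet`.
#' @param flank Flank width in nt (default 5).
#' @return List of class `ConsensusPFM`: `pfm` (4 x (2*flank+1)
#'   matrix of frequencies, rows A/C/G/T, columns named by offset),
#'   `consensus` (IUPAC string), `n_sites`, `n_skipped`.
#' @export
consensus_pfm <- function(sites, reference, flank = 5L) {
  flank <- as.integer(flank)
  ctx <- site_context(reference, sites$contig, sites$pos, sites$strand,
                      -flank, flank)
  ok <- !grepl("N", ctx, fixed = TRUE)
  if (any(!ok))
    message(sum(!ok), " site(s) skipped: flank extends beyond the contig")
  ctx <- ctx[ok]
  if (length(ctx) == 0L) stop("no sites with complete flanks")
  mat <- do.call(rbind, strsplit(ctx, ""))
  pfm <- apply(mat, 2L, function(col)
    table(factor(col, levels = c("A", "C", "G", "T"))) / length(col))
  colnames(pfm) <- as.character(seq(-flank, flank))
  consensus <- paste(apply(pfm, 2L, function(f) {
    keep <- names(f)[f >= 0.25]
    if (length(keep) == 0L) keep <- names(f)[which.max(f)]
    IUPAC_CODE[[paste(sort(keep), collapse = "")]]
  }), collapse = "")
  structure(list(pfm = pfm, consensus = consensus,
                 n_sites = length(ctx), n_skipped = sum(!ok)),
            class = "ConsensusPFM")
}

#' @export
print.ConsensusPFM <- function(x, ...) {
  cat("ConsensusPFM over", x$n_sites, "sites (", x$n_skipped,
      "skipped ): consensus", x$consensus, "\n")
  invisible(x)
}
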