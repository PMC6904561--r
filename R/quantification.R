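#' Per-replicate relative methylation level (RML) at sites
#'
#' For each site and replicate the enrichment ratio
#' `X = sum(m6ACE counts, offsets -4..0) / sum(input counts, offsets
#' -51..0)` is normalised to the same ratio at the spike-in's
#' methylated base, `Y = sum(spike m6ACE, -4..0) / sum(spike input,
#' -21..0)`, giving `RML = X / Y`. The spike-in, added at fixed mass to
#' every library, cancels between-sample differences in crosslinking,
#' capture and digestion efficiency, so RML is proportional to the
#' methylated fraction of transcripts at the site. Ratios with a zero
#' denominator are undefined (`NA`), never zero.
#'
#' @param full_table The FULL `ReadStartTable` of one condition.
#' @param sites Data frame with `contig`, `strand`, `pos`, `site_id`.
#' @param spike_site List/row with `contig`, `strand`, `pos` locating
#'   the spike-in's methylated adenosine (see [spike_site()]).
#' @return Data frame in long form: `site_id`, `replicate`, `X`, `Y`,
#'   `RML`.
#' @export
compute_rml <- function(full_table, sites, spike_site) {
  spike_df <- data.frame(contig = spike_site$contig,
                         strand = spike_site$strand,
                         pos = spike_site$pos, stringsAsFactors = FALSE)
  sy_num <- window_sums(full_table, spike_df, -4L, 0L, "m6ACE")[1L, ]
  sy_den <- window_sums(full_table, spike_df, -21L, 0L, "input")[1L, ]
  if (any(sy_num == 0) || any(sy_den == 0))
    stop("spike-in read-start counts missing in replicate(s): ",
         paste(names(sy_num)[sy_num == 0 | sy_den == 0], collapse = ", "),
         " (spike-in is mandatory for RML)")
  Y <- sy_num / sy_den
  x_num <- window_sums(full_table, sites, -4L, 0L, "m6ACE")
  x_den <- window_sums(full_table, sites, -51L, 0L, "input")
  reps <- colnames(x_num)
  X <- x_num / x_den
  X[x_den == 0] <- NA_real_
  rml <- sweep(X, 2L, Y, "/")
  data.frame(site_id = rep(sites$site_id, times = length(reps)),
             replicate = rep(reps, each = nrow(sites)),
             X = as.vector(X),
             Y = rep(unname(Y), each = nrow(sites)),
             RML = as.vector(rml),
             stringsAsFactors = FALSE)
}

#' Per-site RML matrix and condition means
#'
#' @param rml_long Output of [compute_rml()].
#' @return List with `rml` (matrix sites x replicates) and `mean`
#'   (named vector of per-site means over defined replicates).
#' @export
rml_matrix <- function(rml_long) {
  reps <- unique(rml_long$replicate)
  ids <- unique(rml_long$site_id)
  m <- matrix(NA_real_, length(ids), length(reps),
              dimnames = list(ids, reps))
  m[cbind(match(rml_long$site_id, ids), match(rml_long$replicate, reps))] <-
    rml_long$RML
  list(rml = m, mean = rowMeans(m, na.rm = TRUE))
}

#' Locate the methylated spike-in site of a reference
#'
#' @param reference A `ReferenceSet` with a flagged spike-in contig.
#' @param pos_1based 1-based position of the methylated adenosine on
#'   the spike-in oligo (default 21).
#' @return List `contig`, `strand`, `pos` (0-based).
#' @export
spike_site <- function(reference, pos_1based = 21L) {
  if (is.null(reference$spike_in_name))
    stop("reference has no spike-in contig flagged")
  list(contig = reference$spike_in_name, strand = "+",
       pos = as.integer(pos_1based) - 1L)
}

#' Differential methylation between two conditions at one site
#'
#' Condition means are taken over defined replicate RMLs. The log2
#' fold change is oriented by `direction` so that called sites always
#' report a non-negative LFC: `log2(meanA / meanB)` for `reduction`
#' (writer knockout or eraser overexpression lowering RML in B) and
#' `log2(meanB / meanA)` for `accumulation` (eraser knockout raising
#' RML in B). A small epsilon (1e-6) guards empty means. Significance
#' is a one-tailed two-sample t test in the stated direction (Welch by
#' default). Categories: `dependent` (reduction, `LFC >= lfc_cutoff`,
#' `p < p_cutoff`), `regulated` (accumulation, likewise),
#' `independent` otherwise, `untestable` when either condition has
#' fewer than two defined replicates.
#'
#' @param rml_a,rml_b Numeric vectors of per-replicate RMLs for the
#'   reference (A) and perturbed (B) conditions; `NA` = undefined.
#' @param direction `"reduction"` or `"accumulation"`.
#' @param lfc_cutoff Minimum LFC to call (paper defaults: 2.0 for
#'   reductions, 1.0 for accumulations).
#' @param p_cutoff One-tailed p-value cutoff (default 0.05).
#' @param var_equal Pool variances (classic Student) instead of Welch.
#' @return List of class `DifferentialCall`: `lfc`, `p_value`,
#'   `category`, `mean_a`, `mean_b`, `direction`.
#' @export
differential_methylation <- function(rml_a, rml_b,
                                     direction = c("reduction", "accumulation"),
                                     lfc_cutoff = NULL, p_cutoff = 0.05,
                                     var_equal = FALSE) {
  direction <- match.arg(direction)
  if (is.null(lfc_cutoff))
    lfc_cutoff <- if (direction == "reduction") 2.0 else 1.0
  a <- rml_a[!is.na(rml_a)]
  b <- rml_b[!is.na(rml_b)]
  out <- list(lfc = NA_real_, p_value = NA_real_, category = "untestable",
              mean_a = NA_real_, mean_b = NA_real_, direction = direction)
  class(out) <- "DifferentialCall"
  if (length(a) < 2L || length(b) < 2L) return(out)
  eps <- 1e-6
  ma <- mean(a); mb <- mean(b)
  lfc <- if (direction == "reduction") log2((ma + eps) / (mb + eps))
         else log2((mb + eps) / (ma + eps))
  alt <- if (direction == "reduction") "greater" else "less"
  p <- tryCatch(
    stats::t.test(a, b, alternative = alt, var.equal = var_equal)$p.value,
    error = function(e) 1)  # zero-variance ties: no evidence of change
  category <- if (lfc >= lfc_cutoff && p < p_cutoff) {
    if (direction == "reduction") "dependent" else "regulated"
  } else "independent"
  out$lfc <- lfc; out$p_value <- p; out$category <- category
  out$mean_a <- ma; out$mean_b <- mb
  out
}

#' @export
print.DifferentialCall <- function(x, ...) {
  cat(sprintf("DifferentialCall (%s): LFC = %.3f, p = %.3g, category = %s\n",
              x$direction, x$lfc, x$p_value, x$category))
  invisible(x)
}

#' Differential methylation table across many sites
#'
#' @param rml_a,rml_b Matrices (sites x replicates) of per-replicate
#'   RML for conditions A (reference) and B (perturbed); rownames are
#'   site ids and must match.
#' @param direction,lfc_cutoff,p_cutoff,var_equal See
#'   [differential_methylation()].
#' @return Data frame: `site_id`, `mean_a`, `mean_b`, `lfc`,
#'   `p_value`, `category`.
#' @export
differential_table <- function(rml_a, rml_b,
                               direction = c("reduction", "accumulation"),
                               lfc_cutoff = NULL, p_cutoff = 0.05,
                               var_equal = FALSE) {
  direction <- match.arg(direction)
  stopifnot(identical(rownames(rml_a), rownames(rml_b)))
  calls <- lapply(seq_len(nrow(rml_a)), function(i)
    differential_methylation(rml_a[i, ], rml_b[i, ], direction,
                             lfc_cutoff, p_cutoff, var_equal))
  data.frame(site_id = rownames(rml_a),
             mean_a = vapply(calls, `[[`, 0, "mean_a"),
             mean_b = vapply(calls, `[[`, 0, "mean_b"),
             lfc = vapply(calls, `[[`, 0, "lfc"),
             p_value = vapply(calls, `[[`, 0, "p_value"),
             category = vapply(calls, `[[`, "", "category"),
             stringsAsFactors = FALSE)
}

#' Linearity of RML across a WT/KO mixing series
#'
#' Emulates the mixing experiment: per site, the RML in each mixture
#' is normalised to its RML in the 100% WT condition, all site-level
#' points are pooled, and normalised RML is regressed on the WT
#' fraction by least squares. A slope near 1 with high R-squared
#' demonstrates that RML responds linearly to the underlying
#' methylated fraction.
#'
#' @param series Data frame with columns `wt_fraction` (in `[0, 1]`),
#'   `site_id`, `rml` (per-site mean RML in that mixture). The
#'   `wt_fraction == 1` condition must be present.
#' @return List of class `MixingSeries`: `slope`, `intercept`,
#'   `r_squared`, `points` (the pooled normalised data frame),
#'   `n_sites`.
#' @export
mixing_linearity <- function(series) {
  fr <- sort(unique(series$wt_fraction))
  if (length(fr) < 3L) stop("need >= 3 distinct WT fractions")
  if (!any(series$wt_fraction == 1))
    stop("the 100% WT condition (wt_fraction = 1) is required")
  ref <- series[series$wt_fraction == 1, c("site_id", "rml")]
  ref <- stats::setNames(ref$rml, ref$site_id)
  usable <- names(ref)[!is.na(ref) & ref > 0]
  pts <- series[series$site_id %in% usable & !is.na(series$rml), , drop = FALSE]
  pts$norm_rml <- pts$rml / ref[pts$site_id]
  fit <- stats::lm(norm_rml ~ wt_fraction, data = pts)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared,
                 points = pts[, c("site_id", "wt_fraction", "norm_rml")],
                 n_sites = length(unique(pts$site_id))),
            class = "MixingSeries")
}

#' @export
print.MixingSeries <- function(x, ...) {
  cat(sprintf(
    "MixingSeries: %d sites, slope = %.3f, intercept = %.3f, R^2 = %.3f\n",
    x$n_sites, x$slope, x$intercept, x$r_squared))
  invisible(x)
}
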