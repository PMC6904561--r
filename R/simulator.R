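# Synthetic spike-in stand-in: 41 nt, single DRACH (TGACT) whose
# methylated adenosine sits at 1-based position 21, plus one A at
# 1-based 18 so the exonuclease shadow offsets (-3/-4) land on an
# adenosine and exercise the shadow filter.
SPIKE_SEQ <- "CTGCGTCGTCGGCTCTCATGACTGGTCGTTCGGTCTGCGTC"
SPIKE_NAME <- "spike"
SPIKE_POS_1BASED <- 21L

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is validated
#' under: triplicate m6ACE/input libraries, ~100x capture depth per
#' fully methylated site, per-site stoichiometries of at least 0.3,
#' the exonuclease stop profile concentrated at the methylated base
#' with a minor 7.5% leak to each of offsets -3 and -4, diffuse
#' clustered read-start noise, and 30% PCR duplication.
#'
#' @param seed Integer seed (mandatory; every simulator entry point
#'   derives its RNG stream from it).
#' @param n_transcripts Number of transcript contigs.
#' @param transcript_length Length range (nt), sampled uniformly.
#' @param utr5_frac,utr3_frac Fractions of the transcript assigned to
#'   the untranslated regions.
#' @param methylation_fraction Fraction of DRACH adenosines planted as
#'   m6A sites.
#' @param stoichiometry_range Per-site methylated fraction, drawn
#'   uniformly from this range.
#' @param region_weights Sampling weights for planting sites in
#'   5'UTR/CDS/3'UTR (methylation is biased toward the CDS and 3'UTR).
#' @param m6ace_depth Expected m6ACE reads captured per replicate at a
#'   fully methylated site (before stoichiometry/capture thinning).
#' @param capture_efficiency Antibody capture probability.
#' @param stop_profile Named probability vector over strand-aware read
#'   start offsets relative to the methylated base.
#' @param m6ace_background Expected nonspecific m6ACE reads per nt per
#'   replicate.
#' @param input_depth Expected input reads per nt per replicate.
#' @param noise_loci_per_transcript Expected clustered-noise loci per
#'   transcript (positions shared across replicates).
#' @param noise_reads Expected m6ACE reads per noise locus per
#'   replicate, spread over `+/- noise_halfwidth` nt.
#' @param noise_halfwidth Half-width of a noise cluster (nt).
#' @param duplication_rate Fraction of final reads that are PCR
#'   duplicates.
#' @param replicates Replicates per condition (>= 2; default 3).
#' @param read_length Fragment length for the `end` coordinate.
#' @param spike_m6ace_depth Expected m6ACE reads at the spike-in site
#'   per replicate.
#' @param spike_input_reads Expected input reads on the spike-in
#'   contig per replicate.
#' @param m6am_fraction Fraction of transcripts starting with A that
#'   receive a TSS m6Am site (used by the `tss-m6am` scenario).
#' @return List of class `SimConfig`.
#' @export
sim_config <- function(seed,
                       n_transcripts = 30L,
                       transcript_length = c(300L, 600L),
                       utr5_frac = 0.15, utr3_frac = 0.25,
                       methylation_fraction = 0.05,
                       stoichiometry_range = c(0.3, 1),
                       region_weights = c(utr5 = 0.1, cds = 0.55, utr3 = 0.35),
                       m6ace_depth = 100L,
                       capture_efficiency = 0.8,
                       stop_profile = c(`0` = 0.85, `-3` = 0.075, `-4` = 0.075),
                       m6ace_background = 0.3,
                       input_depth = 2,
                       noise_loci_per_transcript = 0.5,
                       noise_reads = 40,
                       noise_halfwidth = 12L,
                       duplication_rate = 0.3,
                       replicates = 3L,
                       read_length = 75L,
                       spike_m6ace_depth = 300L,
                       spike_input_reads = 400L,
                       m6am_fraction = 0.5) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(abs(sum(stop_profile) - 1) < 1e-9,
            capture_efficiency >= 0, capture_efficiency <= 1,
            duplication_rate >= 0, duplication_rate < 1,
            replicates >= 2L)
  structure(as.list(environment()), class = "SimConfig")
}

# offset k (default 0) decorrelates the RNG streams of the simulator
# entry points while keeping everything a pure function of the seed
sim_seed <- function(config, k = 0L) (as.integer(config$seed) + k) %% .Machine$integer.max

#' Simulate a reference and transcript models
#'
#' Generates `n_transcripts` single-exon transcript contigs with
#' 5'UTR/CDS/3'UTR structure (DRACH motifs arise naturally in the
#' random sequence) and appends the 41-nt spike-in stand-in whose
#' methylated adenosine sits at 1-based position 21.
#'
#' @param config A [sim_config()].
#' @return List with `reference` (a `ReferenceSet`, spike-in flagged)
#'   and `transcripts` (data frame per [read_transcripts()]).
#' @export
simulate_reference <- function(config) {
  withr::with_seed(sim_seed(config, 1L), {
    n <- config$n_transcripts
    contigs <- character(0)
    rows <- list()
    for (i in seq_len(n)) {
      len <- sample(config$transcript_length[1L]:config$transcript_length[2L], 1L)
      seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      # half the transcripts start with A so TSS m6Am sites are possible
      if (stats::runif(1) < 0.5) substr(seq, 1L, 1L) <- "A"
      u5 <- max(1L, round(config$utr5_frac * len))
      u3 <- max(1L, round(config$utr3_frac * len))
      contigs[paste0("tx", i)] <- seq
      rows[[i]] <- data.frame(tx_id = paste0("tx", i),
                              contig = paste0("tx", i), strand = "+",
                              tss = 0L, cds_start = u5,
                              cds_end = len - u3,
                              stringsAsFactors = FALSE)
      rows[[i]]$exons <- list(cbind(start = 0L, end = len))
    }
    contigs[SPIKE_NAME] <- SPIKE_SEQ
    tx <- do.call(rbind, rows)
    if (is.null(tx)) tx <- data.frame(tx_id = character(0),
                                      contig = character(0),
                                      strand = character(0), tss = integer(0),
                                      cds_start = integer(0),
                                      cds_end = integer(0))
    list(reference = ReferenceSet(contigs, SPIKE_NAME), transcripts = tx)
  })
}

#' Positions of DRACH-context adenosines on the plus strand
#'
#' @param reference A `ReferenceSet`.
#' @param contigs Contigs to scan (default: all but the spike-in).
#' @return Data frame `contig`, `pos` (0-based position of the A),
#'   `strand`.
#' @export
drach_positions <- function(reference, contigs = NULL) {
  if (is.null(contigs))
    contigs <- setdiff(names(reference$contigs), reference$spike_in_name)
  out <- list()
  for (ct in contigs) {
    s <- reference$contigs[[ct]]
    m <- gregexpr("(?=[AGT][AG]AC[ACT])", s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    out[[ct]] <- data.frame(contig = ct, pos = as.integer(m) + 1L,
                            strand = "+", stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(contig = character(0), pos = integer(0),
                      strand = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a ground-truth methylome
#'
#' Selects a fraction of DRACH adenosines as m6A sites (biased toward
#' the CDS and 3'UTR), assigns each a stoichiometry, and always
#' includes the spike-in site at stoichiometry 1. Selected sites are
#' spaced at least 6 nt apart so planted sites never shadow each
#' other.
#'
#' @param sim Output of [simulate_reference()].
#' @param config A [sim_config()].
#' @param condition Condition label (default `"WT"`).
#' @return List of class `TrueMethylome`: `sites` (data frame
#'   `site_id`, `contig`, `pos`, `strand`) and `stoichiometry` (matrix
#'   sites x conditions).
#' @export
simulate_methylome <- function(sim, config, condition = "WT") {
  withr::with_seed(sim_seed(config, 2L), {
    dr <- drach_positions(sim$reference)
    tx <- sim$transcripts
    n_pick <- round(config$methylation_fraction * nrow(dr))
    picked <- dr[0, ]
    if (n_pick > 0L && nrow(dr) > 0L) {
      region <- rep("cds", nrow(dr))
      cs <- tx$cds_start[match(dr$contig, tx$contig)]
      ce <- tx$cds_end[match(dr$contig, tx$contig)]
      region[dr$pos < cs] <- "utr5"
      region[dr$pos >= ce] <- "utr3"
      w <- config$region_weights[c(utr5 = "utr5", cds = "cds",
                                   utr3 = "utr3")[region]]
      ord <- sample(nrow(dr), nrow(dr), prob = w / sum(w))
      keep <- integer(0)
      for (i in ord) {     # greedy min-spacing 6 nt
        if (length(keep) == n_pick) break
        close_by <- any(dr$contig[keep] == dr$contig[i] &
                        abs(dr$pos[keep] - dr$pos[i]) < 6L)
        if (!close_by) keep <- c(keep, i)
      }
      picked <- dr[sort(keep), , drop = FALSE]
    }
    sites <- rbind(picked,
                   data.frame(contig = SPIKE_NAME,
                              pos = SPIKE_POS_1BASED - 1L, strand = "+",
                              stringsAsFactors = FALSE))
    sites$site_id <- paste(sites$contig, sites$pos, sites$strand, sep = ":")
    rownames(sites) <- NULL
    stoich <- stats::runif(nrow(sites), config$stoichiometry_range[1L],
                           config$stoichiometry_range[2L])
    stoich[sites$contig == SPIKE_NAME] <- 1
    m <- matrix(stoich, ncol = 1L,
                dimnames = list(sites$site_id, condition))
    structure(list(sites = sites[, c("site_id", "contig", "pos", "strand")],
                   stoichiometry = m),
              class = "TrueMethylome")
  })
}

#' @export
print.TrueMethylome <- function(x, ...) {
  cat("TrueMethylome:", nrow(x$sites), "sites x",
      ncol(x$stoichiometry), "condition(s) (",
      paste(colnames(x$stoichiometry), collapse = ", "), ")\n")
  invisible(x)
}

#' Add a derived condition to a methylome
#'
#' @param methylome A `TrueMethylome`.
#' @param condition New condition label.
#' @param from Condition the new one is copied from.
#' @param zero_sites Site ids whose stoichiometry is set to 0 (e.g.
#'   writer-dependent sites in a writer knockout).
#' @param stoichiometry Optional named vector of explicit
#'   stoichiometries overriding the copy.
#' @return The updated `TrueMethylome`.
#' @export
add_condition <- function(methylome, condition, from = "WT",
                          zero_sites = character(0),
                          stoichiometry = NULL) {
  v <- methylome$stoichiometry[, from]
  v[names(v) %in% zero_sites] <- 0
  if (!is.null(stoichiometry))
    v[names(stoichiometry)] <- stoichiometry
  v[methylome$sites$contig == SPIKE_NAME] <- 1
  methylome$stoichiometry <- cbind(methylome$stoichiometry,
                                   matrix(v, ncol = 1L,
                                          dimnames = list(names(v), condition)))
  methylome
}

#' Mixture conditions of two methylomes
#'
#' Per WT fraction `f`, stoichiometry is exactly
#' `f * WT + (1 - f) * KO` at every site, mirroring RNA mixing
#' experiments.
#'
#' @param methylome A `TrueMethylome` carrying both `wt` and `ko`
#'   conditions.
#' @param fractions Numeric WT fractions in `[0, 1]`.
#' @param wt,ko Condition labels to mix.
#' @return The methylome with one added condition per fraction, named
#'   `mix_<fraction>`.
#' @export
simulate_mixture <- function(methylome, fractions, wt = "WT", ko = "KO") {
  st <- methylome$stoichiometry
  if (!all(c(wt, ko) %in% colnames(st)))
    stop("methylome lacks condition(s): ",
         paste(setdiff(c(wt, ko), colnames(st)), collapse = ", "))
  for (f in fractions) {
    v <- f * st[, wt] + (1 - f) * st[, ko]
    v[methylome$sites$contig == SPIKE_NAME] <- 1
    methylome$stoichiometry <- cbind(methylome$stoichiometry,
                                     matrix(v, ncol = 1L,
                                            dimnames = list(names(v),
                                                            paste0("mix_", f))))
  }
  methylome
}

random_umis <- function(n) {
  if (n == 0L) return(character(0))
  body <- matrix(sample(c("A", "C", "G", "T"), 7L * n, replace = TRUE), ncol = 7L)
  last <- sample(c("C", "G", "T"), n, replace = TRUE)
  paste0(apply(body, 1L, paste, collapse = ""), last)
}

# noise loci are a property of the sequence world, shared across
# replicates and conditions; derived from the seed alone
noise_loci <- function(sim, config) {
  withr::with_seed(sim_seed(config, 3L), {
    tx <- sim$transcripts
    out <- list()
    for (i in seq_len(nrow(tx))) {
      n <- stats::rpois(1L, config$noise_loci_per_transcript)
      if (n == 0L) next
      len <- contig_length(sim$reference, tx$contig[i])
      out[[length(out) + 1L]] <-
        data.frame(contig = tx$contig[i],
                   pos = sample(seq(config$noise_halfwidth,
                                    len - config$noise_halfwidth - 1L), n),
                   stringsAsFactors = FALSE)
    }
    if (length(out) == 0L)
      data.frame(contig = character(0), pos = integer(0))
    else do.call(rbind, out)
  })
}

#' Simulate m6ACE and input libraries for one condition
#'
#' Generative mirror of the assay: methylated fragments are captured
#' with probability `stoichiometry * capture_efficiency`, digested to
#' the crosslink so their read starts follow the exonuclease stop
#' profile around the methylated base; nonspecific background and
#' clustered noise are added to the m6ACE libraries; input libraries
#' start uniformly over each contig; UMIs are drawn from N7B and PCR
#' duplicates appended at the configured rate.
#'
#' @param sim Output of [simulate_reference()].
#' @param methylome A `TrueMethylome`.
#' @param config A [sim_config()].
#' @param condition Condition column of the methylome to simulate.
#' @return Aligned-read data.frame (all replicates, both libraries).
#' @export
simulate_libraries <- function(sim, methylome, config, condition = "WT") {
  st <- methylome$stoichiometry
  if (!condition %in% colnames(st))
    stop("unknown condition: ", condition)
  cond_off <- sum(utf8ToInt(condition)) %% 10000L
  loci <- noise_loci(sim, config)
  ref <- sim$reference
  withr::with_seed(sim_seed(config, 100L + cond_off), {
    parts <- list()
    emit <- function(contig, start5, replicate, library) {
      # start5 is the strand-aware 5' read start on the + strand
      len <- contig_length(ref, contig[1L])
      start5 <- pmax(0L, pmin(as.integer(start5), len - 1L))
      data.frame(contig = contig, strand = "+", start = start5,
                 end = pmin(start5 + config$read_length, len),
                 umi = random_umis(length(start5)),
                 replicate = replicate, library = library,
                 stringsAsFactors = FALSE)
    }
    offsets <- as.integer(names(config$stop_profile))
    for (r in seq_len(config$replicates)) {
      rep_id <- paste0("rep", r)
      # --- m6ACE: site-directed signal
      for (i in seq_len(nrow(methylome$sites))) {
        site <- methylome$sites[i, ]
        theta <- st[site$site_id, condition]
        depth <- if (site$contig == SPIKE_NAME) config$spike_m6ace_depth
                 else config$m6ace_depth
        n <- stats::rbinom(1L, depth, theta * config$capture_efficiency)
        if (n == 0L) next
        off <- sample(offsets, n, replace = TRUE, prob = config$stop_profile)
        parts[[length(parts) + 1L]] <-
          emit(rep(site$contig, n), site$pos + off, rep_id, "m6ACE")
      }
      # --- m6ACE: nonspecific background + clustered noise
      for (ct in names(ref$contigs)) {
        len <- contig_length(ref, ct)
        if (ct != SPIKE_NAME) {
          n_bg <- stats::rpois(1L, config$m6ace_background * len)
          if (n_bg > 0L)
            parts[[length(parts) + 1L]] <-
              emit(rep(ct, n_bg), sample(0:(len - 1L), n_bg, replace = TRUE),
                   rep_id, "m6ACE")
        }
        n_in <- if (ct == SPIKE_NAME) stats::rpois(1L, config$spike_input_reads)
                else stats::rpois(1L, config$input_depth * len)
        if (n_in > 0L)
          parts[[length(parts) + 1L]] <-
            emit(rep(ct, n_in), sample(0:(len - 1L), n_in, replace = TRUE),
                 rep_id, "input")
      }
      if (nrow(loci) > 0L) {
        for (i in seq_len(nrow(loci))) {
          n <- stats::rpois(1L, config$noise_reads)
          if (n == 0L) next
          jitter <- sample(seq(-config$noise_halfwidth,
                               config$noise_halfwidth), n, replace = TRUE)
          parts[[length(parts) + 1L]] <-
            emit(rep(loci$contig[i], n), loci$pos[i] + jitter, rep_id, "m6ACE")
        }
      }
    }
    reads <- do.call(rbind, parts)
    rownames(reads) <- NULL
    # PCR duplicates: copies of existing molecules (same UMI + coords)
    if (config$duplication_rate > 0 && nrow(reads) > 0L) {
      d <- config$duplication_rate
      n_dup <- round(nrow(reads) * d / (1 - d))
      if (n_dup > 0L) {
        dup <- reads[sample(nrow(reads), n_dup, replace = TRUE), , drop = FALSE]
        reads <- rbind(reads, dup)
        rownames(reads) <- NULL
      }
    }
    reads
  })
}

#' Run a named simulation scenario end to end
#'
#' Scenarios:
#' \describe{
#'   \item{basic}{WT methylome and triplicate libraries.}
#'   \item{mixture}{WT plus writer-KO (all sites to 0) mixed at WT
#'     fractions 1, 0.75, 0.5, 0.25, 0; libraries per mixture.}
#'   \item{demethylase-ko}{Half the sites are eraser-suppressed in WT
#'     (WT stoichiometry scaled down by a per-site suppression `u`,
#'     restored in the KO), so regulation strength anti-correlates
#'     with WT methylation; libraries for WT and KO.}
#'   \item{tss-m6am}{As basic, plus m6Am sites planted at A-starting
#'     TSSs.}
#' }
#'
#' @param scenario Scenario name.
#' @param seed Integer seed.
#' @param config Optional [sim_config()] (its seed is overridden by
#'   `seed` when both are given).
#' @return List with `reference`, `transcripts`, `methylome`,
#'   `config`, and `reads` (named list of aligned-read tables, one per
#'   condition). The `demethylase-ko` scenario adds `regulated_sites`
#'   (ids) and `suppression` (named per-site `u`); `tss-m6am` adds
#'   `tss` (data frame) and `m6am_sites`.
#' @export
simulate_scenario <- function(scenario = c("basic", "mixture",
                                           "demethylase-ko", "tss-m6am"),
                              seed, config = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(config)) config <- sim_config(seed = seed)
  else if (!missing(seed)) config$seed <- seed
  sim <- simulate_reference(config)
  meth <- simulate_methylome(sim, config)
  out <- list(reference = sim$reference, transcripts = sim$transcripts,
              config = config)
  if (scenario == "basic") {
    out$methylome <- meth
    out$reads <- list(WT = simulate_libraries(sim, meth, config, "WT"))
  } else if (scenario == "mixture") {
    genomic <- meth$sites$site_id[meth$sites$contig != SPIKE_NAME]
    meth <- add_condition(meth, "KO", zero_sites = genomic)
    fractions <- c(1, 0.75, 0.5, 0.25, 0)
    meth <- simulate_mixture(meth, fractions)
    out$methylome <- meth
    out$fractions <- fractions
    out$reads <- stats::setNames(
      lapply(fractions, function(f)
        simulate_libraries(sim, meth, config, paste0("mix_", f))),
      paste0("mix_", fractions))
  } else if (scenario == "demethylase-ko") {
    genomic <- meth$sites$site_id[meth$sites$contig != SPIKE_NAME]
    withr::with_seed(sim_seed(config, 4L), {
      reg <- sample(genomic, floor(length(genomic) / 2))
      u <- stats::setNames(stats::runif(length(reg), 0.2, 0.95), reg)
    })
    # KO restores full methylation; WT is suppressed by u at regulated
    # sites, so higher u -> weaker WT signal and larger KO accumulation
    ko <- meth$stoichiometry[, "WT"]
    wt <- ko
    wt[reg] <- wt[reg] * (1 - u[reg])
    meth$stoichiometry[, "WT"] <- wt
    meth <- add_condition(meth, "KO", stoichiometry = ko)
    out$methylome <- meth
    out$regulated_sites <- reg
    out$suppression <- u
    out$reads <- list(WT = simulate_libraries(sim, meth, config, "WT"),
                      KO = simulate_libraries(sim, meth, config, "KO"))
  } else { # tss-m6am
    tx <- sim$transcripts
    first_base <- ref_base(sim$reference, tx$contig, tx$tss, tx$strand)
    cand <- which(first_base == "A")
    withr::with_seed(sim_seed(config, 5L), {
      pick <- cand[stats::runif(length(cand)) < config$m6am_fraction]
      m6am <- data.frame(site_id = paste(tx$contig[pick], tx$tss[pick],
                                         tx$strand[pick], sep = ":"),
                         contig = tx$contig[pick], pos = tx$tss[pick],
                         strand = tx$strand[pick], stringsAsFactors = FALSE)
      stoich <- stats::runif(nrow(m6am), config$stoichiometry_range[1L],
                             config$stoichiometry_range[2L])
    })
    meth$sites <- rbind(meth$sites, m6am)
    meth$stoichiometry <- rbind(meth$stoichiometry,
                                matrix(stoich, ncol = 1L,
                                       dimnames = list(m6am$site_id, "WT")))
    out$methylome <- meth
    out$m6am_sites <- m6am$site_id
    out$tss <- data.frame(contig = tx$contig, pos = tx$tss,
                          strand = tx$strand, stringsAsFactors = FALSE)
    out$reads <- list(WT = simulate_libraries(sim, meth, config, "WT"))
  }
  out
}

#' Write a methylome's ground truth to TSV
#'
#' @param methylome A `TrueMethylome`.
#' @param path Output path (columns: site_id, contig, pos, strand,
#'   one stoichiometry column per condition).
#' @return `path`, invisibly.
#' @export
write_methylome <- function(methylome, path) {
  df <- cbind(methylome$sites,
              as.data.frame(methylome$stoichiometry))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
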