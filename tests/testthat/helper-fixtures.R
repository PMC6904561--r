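# Shared fixture builders for the test suite. Everything is generated
# in code; no files ship with the package.

# A ReadStartTable built directly from a counts data.frame whose extra
# columns are named "<replicate>:<library>". Library sizes default to
# column sums (the collation invariant) but can be overridden to model
# externally known totals.
make_table <- function(counts_df, library_sizes = NULL) {
  stopifnot(all(c("contig", "strand", "pos") %in% names(counts_df)))
  sample_cols <- setdiff(names(counts_df), c("contig", "strand", "pos"))
  parts <- strsplit(sample_cols, ":", fixed = TRUE)
  samples <- data.frame(sample = sample_cols,
                        replicate = vapply(parts, `[`, "", 1L),
                        library = vapply(parts, `[`, "", 2L),
                        stringsAsFactors = FALSE)
  dt <- data.table::as.data.table(counts_df)
  data.table::setkeyv(dt, c("contig", "strand", "pos"))
  if (is.null(library_sizes))
    library_sizes <- vapply(sample_cols, function(s) sum(dt[[s]]), 0)
  structure(list(counts = dt, samples = samples,
                 library_sizes = library_sizes),
            class = "ReadStartTable")
}

# Counts data.frame with triplicate m6ACE/input columns from matrices
# (rows = positions).
triplicate_counts <- function(contig, strand, pos, m6ace, input) {
  df <- data.frame(contig = contig, strand = strand, pos = pos,
                   stringsAsFactors = FALSE)
  for (r in 1:3) df[[paste0("rep", r, ":m6ACE")]] <- m6ace[, r]
  for (r in 1:3) df[[paste0("rep", r, ":input")]] <- input[, r]
  df
}

# Aligned-read rows with defaults, vectorised over arguments.
make_reads <- function(contig = "chrT", strand = "+", start = 0L,
                       end = start + 50L, umi = "AAAAAAC",
                       replicate = "rep1", library = "m6ACE") {
  data.frame(contig = contig, strand = strand,
             start = as.integer(start), end = as.integer(end),
             umi = paste0(substr(umi, 1, 7),
                          ifelse(nchar(umi) >= 8, substr(umi, 8, 8), "C")),
             replicate = replicate, library = library,
             stringsAsFactors = FALSE)
}

# Mirror a world: reverse-complement every contig and flip reads to
# the minus strand, mapping the plus-strand interval [s, e) on a
# contig of length L to [L - e, L - s) on the minus strand.
mirror_reference <- function(reference) {
  rc <- vapply(reference$contigs, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))), "")
  ReferenceSet(rc, reference$spike_in_name)
}

mirror_reads <- function(reads, reference) {
  len <- nchar(reference$contigs[reads$contig])
  out <- reads
  out$start <- as.integer(len - reads$end)
  out$end <- as.integer(len - reads$start)
  out$strand <- ifelse(reads$strand == "+", "-", "+")
  out
}

mirror_pos <- function(pos, contig, reference) {
  as.integer(nchar(reference$contigs[contig]) - 1L - pos)
}

# Cached simulation scenarios shared across test files.
.sim_cache <- new.env(parent = emptyenv())
cached_scenario <- function(scenario, seed, config = NULL) {
  key <- paste(scenario, seed, is.null(config))
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_scenario(scenario, seed = seed,
                                           config = config)
  .sim_cache[[key]]
}

cached_call <- function(scenario, seed, condition = "WT") {
  key <- paste("call", scenario, seed, condition)
  if (is.null(.sim_cache[[key]])) {
    sc <- cached_scenario(scenario, seed)
    .sim_cache[[key]] <- call_sites(sc$reads[[condition]], sc$reference)
  }
  .sim_cache[[key]]
}

# A hand-built world for RML arithmetic: one genomic site plus the
# spike-in, counts placed so the window sums are exact round numbers.
rml_fixture <- function(scale = 1) {
  rows <- list(
    # genomic site at chrT:100 (+): m6ACE -4..0 sums to 50,
    # input -51..0 sums to 200, per replicate
    data.frame(contig = "chrT", strand = "+", pos = c(96L, 100L),
               m6 = c(10L, 40L), inp = 0L),
    data.frame(contig = "chrT", strand = "+", pos = c(60L, 80L, 100L),
               m6 = 0L, inp = c(100L, 60L, 40L)),
    # spike site at spike:20 (+): m6ACE -4..0 = 80, input -21..0 = 160
    data.frame(contig = "spike", strand = "+", pos = c(18L, 20L),
               m6 = c(20L, 60L), inp = 0L),
    data.frame(contig = "spike", strand = "+", pos = c(5L, 15L),
               m6 = 0L, inp = c(100L, 60L)))
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(m6, inp) ~ contig + strand + pos, df, sum)
  counts <- data.frame(contig = agg$contig, strand = agg$strand,
                       pos = agg$pos, stringsAsFactors = FALSE)
  for (r in 1:3) counts[[paste0("rep", r, ":m6ACE")]] <-
    as.integer(agg$m6 * scale)
  for (r in 1:3) counts[[paste0("rep", r, ":input")]] <- as.integer(agg$inp)
  make_table(counts)
}

# Enriched-site pair for the shadow filter: an A at shadow_pos and a
# configurable context around neighbour_pos (context[2] is the
# neighbour's base).
shadow_fixture <- function(neighbour_pos, context = "GAC",
                           shadow_pos = 100L) {
  s <- strrep("T", 200)
  substr(s, shadow_pos + 1, shadow_pos + 1) <- "A"
  substr(s, neighbour_pos, neighbour_pos + 2) <- context
  ref <- ReferenceSet(c(chrT = s))
  sites <- data.frame(
    contig = "chrT", strand = "+", pos = c(shadow_pos, neighbour_pos),
    site_id = paste("chrT", c(shadow_pos, neighbour_pos), "+", sep = ":"),
    log2FC = c(3, 4), p_value = c(1e-6, 1e-8), padj = c(1e-5, 1e-7),
    enriched = c(TRUE, TRUE), filter_status = c("pass", "pass"),
    stringsAsFactors = FALSE)
  list(ref = ref, sites = sites)
}

# Window of read-start counts around a focal site for the cluster
# filter: site_count at the site, noise_count at each noise position.
cluster_fixture <- function(site_count, noise_positions, noise_count,
                            site_pos = 100L) {
  pos <- c(site_pos, noise_positions)
  counts <- data.frame(contig = "chrT", strand = "+", pos = pos,
                       stringsAsFactors = FALSE)
  counts[["rep1:m6ACE"]] <- c(site_count, rep(noise_count,
                                              length(noise_positions)))
  counts[["rep1:input"]] <- 1L
  make_table(counts)
}

# Tiny two-contig reference: 100 nt transcript-like contig and the
# 41-nt spike stand-in (A at 1-based 21 inside TGACT).
tiny_reference <- function() {
  set.seed(42)
  base <- paste(sample(c("C", "G", "T"), 100, replace = TRUE), collapse = "")
  # plant an adenosine in RAC context at 0-based 20 and a lone A at 50
  substr(base, 20, 20) <- "G"  # 0-based 19
  substr(base, 21, 21) <- "A"  # 0-based 20
  substr(base, 22, 22) <- "C"
  substr(base, 51, 51) <- "A"  # 0-based 50, context not RAC
  spike <- "CTGCGTCGTCGGCTCTCATGACTGGTCGTTCGGTCTGCGTC"
  ReferenceSet(c(chrT = base, spike = spike), "spike")
}
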