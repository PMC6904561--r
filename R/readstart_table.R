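#' Collate deduplicated read starts into a count table
#'
#' Builds the pipeline's central container: per-position, per-sample
#' counts of strand-aware read starts (the exonuclease stop positions),
#' one column per `replicate:library` combination, plus per-sample
#' library sizes (total retained reads). Reads whose start falls
#' outside the contig are rejected with a warning.
#'
#' @param reads Deduplicated aligned-read data.frame.
#' @param reference A `ReferenceSet`; used for bounds checking.
#' @return A `ReadStartTable`: list with
#'   \describe{
#'     \item{counts}{data.table keyed by `(contig, strand, pos)` with
#'       one integer count column per sample.}
#'     \item{samples}{data.frame of `sample`, `replicate`, `library`.}
#'     \item{library_sizes}{named numeric, total reads per sample.}
#'   }
#' @export
collate_read_starts <- function(reads, reference) {
  validate_reads(reads)
  pos <- read_start_position(reads)
  len <- contig_length(reference, reads$contig)
  ok <- pos >= 0L & pos < len
  if (any(!ok)) {
    warning(sum(!ok), " read(s) rejected: start outside contig bounds")
    reads <- reads[ok, , drop = FALSE]
    pos <- pos[ok]
  }
  sample_id <- paste(reads$replicate, reads$library, sep = ":")
  dt <- data.table::data.table(contig = reads$contig, strand = reads$strand,
                               pos = as.integer(pos), sample = sample_id)
  samples <- unique(data.frame(sample = sample_id,
                               replicate = reads$replicate,
                               library = reads$library,
                               stringsAsFactors = FALSE))
  samples <- samples[order(samples$library, samples$replicate), , drop = FALSE]
  rownames(samples) <- NULL
  counts <- data.table::dcast(dt, contig + strand + pos ~ sample,
                              fun.aggregate = length, value.var = "sample")
  for (s in setdiff(samples$sample, names(counts))) counts[[s]] <- 0L
  data.table::setcolorder(counts, c("contig", "strand", "pos", samples$sample))
  data.table::setkeyv(counts, c("contig", "strand", "pos"))
  lib_sizes <- vapply(samples$sample, function(s) sum(counts[[s]]), 0)
  structure(list(counts = counts, samples = samples,
                 library_sizes = lib_sizes),
            class = "ReadStartTable")
}

#' @export
print.ReadStartTable <- function(x, ...) {
  cat("ReadStartTable:", nrow(x$counts), "positions x",
      nrow(x$samples), "samples\n")
  cat("  library sizes:",
      paste(sprintf("%s=%d", names(x$library_sizes), x$library_sizes),
            collapse = ", "), "\n")
  invisible(x)
}

sample_columns <- function(table, library = NULL) {
  s <- table$samples
  if (!is.null(library)) s <- s[s$library == library, , drop = FALSE]
  s$sample
}

#' Read-start counts in reads per million mapped (RPM)
#'
#' @param table A `ReadStartTable`.
#' @return The count table with each sample column scaled by
#'   `1e6 / library_size`.
#' @export
rpm <- function(table) {
  out <- data.table::copy(table$counts)
  for (s in table$samples$sample) {
    ls <- table$library_sizes[[s]]
    out[[s]] <- if (ls > 0) out[[s]] * 1e6 / ls else out[[s]] * 0
  }
  out[]
}

#' Restrict a ReadStartTable to candidate adenosine start sites
#'
#' Candidate m6A/m6Am positions are read starts whose strand-aware
#' reference base is adenosine and whose mean m6ACE count across
#' replicates reaches `min_mean_count`. Input libraries are not
#' thresholded: the methylation signal lives in the m6ACE libraries.
#'
#' @param table A full `ReadStartTable`.
#' @param reference A `ReferenceSet`.
#' @param min_mean_count Minimum mean m6ACE read count across
#'   replicates (default 1, the collation rule).
#' @return A `ReadStartTable` restricted to candidate positions
#'   (library sizes retain the full-table totals).
#' @export
candidate_sites <- function(table, reference, min_mean_count = 1) {
  cnt <- table$counts
  base <- ref_base(reference, cnt$contig, cnt$pos, cnt$strand)
  m6 <- sample_columns(table, "m6ACE")
  if (length(m6) == 0L) stop("no m6ACE libraries in table")
  mean_m6 <- rowMeans(as.matrix(cnt[, m6, with = FALSE]))
  keep <- !is.na(base) & base == "A" & mean_m6 >= min_mean_count
  out <- table
  out$counts <- cnt[keep]
  out
}

#' Sum read-start counts over a strand-aware offset window
#'
#' Offsets follow transcript orientation: offset `-k` is `k` nt 5' of
#' the site (genomic `pos - k` on `+`, `pos + k` on `-`); offset 0 is
#' the site itself. Positions off the contig contribute 0.
#'
#' @param table A `ReadStartTable`.
#' @param contig,strand,pos Site location (0-based genomic).
#' @param from,to Inclusive offset range (e.g. `-4, 0`).
#' @param sample Sample column name (`"rep1:m6ACE"`), or `NULL` to
#'   return the vector over all samples.
#' @return Numeric window sum (named vector over samples when
#'   `sample = NULL`).
#' @export
window_sum <- function(table, contig, strand, pos, from, to, sample = NULL) {
  stopifnot(from <= to)
  offs <- from:to
  gpos <- if (strand == "+") pos + offs else pos - offs
  # build the query table first: inside `[` the i-expression would
  # resolve `contig`/`strand` against the count table's own columns
  q <- data.table::data.table(contig = rep(contig, length(offs)),
                              strand = rep(strand, length(offs)),
                              pos = as.integer(gpos))
  sel <- table$counts[q, on = c("contig", "strand", "pos"), nomatch = NULL]
  cols <- if (is.null(sample)) table$samples$sample else sample
  res <- vapply(cols, function(s) sum(sel[[s]]), 0)
  if (is.null(sample)) res else unname(res)
}

#' Window sums for many sites at once
#'
#' @param table A `ReadStartTable`.
#' @param sites Data frame with `contig`, `strand`, `pos`.
#' @param from,to Inclusive strand-aware offset range.
#' @param library `"m6ACE"` or `"input"`.
#' @return Numeric matrix, sites x replicates (columns named by
#'   replicate).
#' @export
window_sums <- function(table, sites, from, to, library) {
  stopifnot(from <= to)
  samp <- table$samples[table$samples$library == library, , drop = FALSE]
  offs <- from:to
  n <- nrow(sites)
  idx <- rep(seq_len(n), each = length(offs))
  gpos <- ifelse(rep(sites$strand, each = length(offs)) == "+",
                 rep(sites$pos, each = length(offs)) + offs,
                 rep(sites$pos, each = length(offs)) - offs)
  q <- data.table::data.table(contig = rep(sites$contig, each = length(offs)),
                              strand = rep(sites$strand, each = length(offs)),
                              pos = as.integer(gpos), site = idx)
  hit <- table$counts[q, on = c("contig", "strand", "pos"), nomatch = NULL]
  out <- matrix(0, nrow = n, ncol = nrow(samp),
                dimnames = list(NULL, samp$replicate))
  if (nrow(hit)) {
    for (j in seq_len(nrow(samp))) {
      agg <- hit[, list(v = sum(.SD[[1L]])), by = "site",
                 .SDcols = samp$sample[j]]
      out[agg$site, j] <- agg$v
    }
  }
  out
}

#' Write a ReadStartTable to TSV
#'
#' @param table A `ReadStartTable`.
#' @param path Output path. Library sizes are stored in a `#` header
#'   line so the table round-trips.
#' @return `path`, invisibly.
#' @export
write_readstart_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#library_sizes\t",
                    paste(names(table$library_sizes),
                          table$library_sizes, sep = "=", collapse = "\t")),
             con)
  utils::write.table(table$counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a ReadStartTable written by [write_readstart_table()]
#'
#' @param path Input path.
#' @return A `ReadStartTable`.
#' @export
read_readstart_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#library_sizes"))
    stop("not a read-start table: missing #library_sizes header")
  kv <- strsplit(strsplit(first, "\t")[[1L]][-1L], "=", fixed = TRUE)
  lib_sizes <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                               vapply(kv, `[`, "", 1L))
  counts <- data.table::fread(path, skip = 1L, sep = "\t", header = TRUE)
  rl <- strsplit(names(lib_sizes), ":", fixed = TRUE)
  samples <- data.frame(sample = names(lib_sizes),
                        replicate = vapply(rl, `[`, "", 1L),
                        library = vapply(rl, `[`, "", 2L),
                        stringsAsFactors = FALSE)
  data.table::setkeyv(counts, c("contig", "strand", "pos"))
  structure(list(counts = counts, samples = samples,
                 library_sizes = lib_sizes),
            class = "ReadStartTable")
}
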