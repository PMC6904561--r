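#' Write site calls to BED6+ format
#'
#' Standard BED columns (`chrom`, `chromStart`, `chromEnd`, `name`,
#' `score`, `strand`) followed by every additional column of `sites`
#' (statistics, filter status, RML fields). Coordinates are 0-based
#' half-open with `chromEnd = pos + 1`; `score` is
#' `-10 * log10(padj)` capped at 1000 (0 when `padj` is missing). A
#' `#`-prefixed header line names all columns so the file round-trips
#' through [read_sites()]. Records are sorted by
#' `(contig, position, strand)`.
#'
#' @param sites Data frame with at least `contig`, `strand`, `pos`,
#'   `site_id`; typically the output of [test_enrichment()] or
#'   [call_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  sites <- sites[order(sites$contig, sites$pos, sites$strand), , drop = FALSE]
  score <- rep(0, nrow(sites))
  if ("padj" %in% names(sites)) {
    ok <- !is.na(sites$padj)
    score[ok] <- pmin(1000, -10 * log10(pmax(sites$padj[ok], 1e-100)))
    score[ok & sites$padj == 0] <- 1000
  }
  extra <- setdiff(names(sites), c("contig", "strand", "pos", "site_id"))
  bed <- data.frame(chrom = sites$contig, chromStart = sites$pos,
                    chromEnd = sites$pos + 1L, name = sites$site_id,
                    score = sub("\\.?0+$", "",
                                sprintf("%.2f", round(score, 2L))),
                    strand = sites$strand,
                    stringsAsFactors = FALSE)
  for (col in extra) bed[[col]] <- sites[[col]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(bed), collapse = "\t")), con)
  utils::write.table(format(bed, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read site calls written by [write_sites()]
#'
#' @param path BED6+ path with the `#` column header.
#' @return Data frame with `contig`, `strand`, `pos`, `site_id` and all
#'   extra columns restored to their original types.
#' @export
read_sites <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#"))
    stop("not a m6ace BED6+ file: missing # header line")
  cols <- strsplit(sub("^#", "", header), "\t")[[1L]]
  bed <- utils::read.table(path, sep = "\t", header = FALSE, skip = 1L,
                           col.names = cols, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  out <- data.frame(contig = bed$chrom, strand = bed$strand,
                    pos = bed$chromStart, site_id = bed$name,
                    stringsAsFactors = FALSE)
  for (col in setdiff(cols, c("chrom", "chromStart", "chromEnd", "name",
                              "score", "strand")))
    out[[col]] <- bed[[col]]
  out
}

#' Read a TSS list from BED
#'
#' @param path BED file; each record's strand-aware first base is taken
#'   as the TSS (start on `+`, `end - 1` on `-`).
#' @return Data frame `contig`, `pos` (0-based), `strand`.
#' @export
read_tss <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) stop("empty TSS list: ", path)
  strand <- as.character(BiocGenerics::strand(gr))
  pos <- ifelse(strand == "+", BiocGenerics::start(gr) - 1L,
                BiocGenerics::end(gr) - 1L)
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             pos = as.integer(pos), strand = strand,
             stringsAsFactors = FALSE)
}
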