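#' Read transcript models from BED12 (or GTF)
#'
#' Parses transcript models into the internal representation used for
#' metagene and TSS analyses. All coordinates are converted to 0-based
#' half-open. The TSS is the strand-aware first exonic base (for minus
#' strand transcripts, `end - 1` of the last block). Records whose CDS
#' falls outside the exon union are rejected with a warning.
#'
#' @param path Path to a BED12 file (`.bed`) or GTF/GFF file (`.gtf`,
#'   `.gff`); the format is inferred from the extension.
#' @return A data.frame with one row per transcript: `tx_id`, `contig`,
#'   `strand`, `tss`, `cds_start`, `cds_end` (genomic 0-based half-open;
#'   `NA` for non-coding), and a list-column `exons` of two-column
#'   matrices (`start`, `end`), sorted and non-overlapping.
#' @export
read_transcripts <- function(path) {
  fmt <- if (grepl("\\.g[tf]f[3]?$", path, ignore.case = TRUE)) "GTF" else "BED"
  if (fmt == "BED") {
    gr <- rtracklayer::import(path, format = "BED")
    if (length(gr) == 0L) stop("no transcript records in ", path)
    blk <- rtracklayer::blocks(gr)
    exons <- lapply(seq_along(gr), function(i) {
      b <- blk[[i]]
      m <- cbind(start = BiocGenerics::start(b) - 1L, end = BiocGenerics::end(b))
      m[order(m[, 1L]), , drop = FALSE]
    })
    thick <- gr$thick
    cds_start <- BiocGenerics::start(thick) - 1L
    cds_end <- BiocGenerics::end(thick)
    noncoding <- BiocGenerics::width(thick) == 0L
    cds_start[noncoding] <- NA_integer_
    cds_end[noncoding] <- NA_integer_
    tx <- data.frame(
      tx_id = if (!is.null(gr$name)) gr$name else paste0("tx", seq_along(gr)),
      contig = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(BiocGenerics::strand(gr)),
      cds_start = cds_start, cds_end = cds_end,
      stringsAsFactors = FALSE
    )
    tx$exons <- exons
  } else {
    gr <- rtracklayer::import(path, format = "GTF")
    ex <- gr[gr$type == "exon"]
    cds <- gr[gr$type == "CDS"]
    ids <- unique(ex$transcript_id)
    if (length(ids) == 0L) stop("no exon records in ", path)
    rows <- lapply(ids, function(id) {
      e <- ex[ex$transcript_id == id]
      m <- cbind(start = BiocGenerics::start(e) - 1L, end = BiocGenerics::end(e))
      m <- m[order(m[, 1L]), , drop = FALSE]
      cc <- cds[cds$transcript_id == id]
      list(tx_id = id,
           contig = as.character(GenomicRanges::seqnames(e))[1L],
           strand = as.character(BiocGenerics::strand(e))[1L],
           cds_start = if (length(cc)) min(BiocGenerics::start(cc)) - 1L else NA_integer_,
           cds_end = if (length(cc)) max(BiocGenerics::end(cc)) else NA_integer_,
           exons = m)
    })
    tx <- data.frame(
      tx_id = vapply(rows, `[[`, "", "tx_id"),
      contig = vapply(rows, `[[`, "", "contig"),
      strand = vapply(rows, `[[`, "", "strand"),
      cds_start = vapply(rows, `[[`, 1L, "cds_start"),
      cds_end = vapply(rows, `[[`, 1L, "cds_end"),
      stringsAsFactors = FALSE
    )
    tx$exons <- lapply(rows, `[[`, "exons")
  }
  tx$tss <- ifelse(tx$strand == "+",
                   vapply(tx$exons, function(m) m[1L, 1L], 1L),
                   vapply(tx$exons, function(m) m[nrow(m), 2L] - 1L, 1L))
  ok <- vapply(seq_len(nrow(tx)), function(i) {
    if (is.na(tx$cds_start[i])) return(TRUE)
    cds_in_exons(tx$exons[[i]], tx$cds_start[i], tx$cds_end[i])
  }, TRUE)
  if (any(!ok)) {
    warning(sum(!ok), " transcript(s) rejected: CDS outside exon union (",
            paste(tx$tx_id[!ok], collapse = ", "), ")")
    tx <- tx[ok, , drop = FALSE]
    rownames(tx) <- NULL
  }
  tx[, c("tx_id", "contig", "strand", "tss", "cds_start", "cds_end", "exons")]
}

cds_in_exons <- function(exons, cds_start, cds_end) {
  # CDS endpoints must fall inside exon blocks and the CDS must not
  # span intronic sequence beyond block boundaries
  in_block <- function(p) any(p >= exons[, 1L] & p < exons[, 2L])
  in_block(cds_start) && in_block(cds_end - 1L)
}

#' Write transcript models to BED12
#'
#' @param transcripts Data frame as returned by [read_transcripts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path) {
  lines <- vapply(seq_len(nrow(transcripts)), function(i) {
    ex <- transcripts$exons[[i]]
    chrom_start <- ex[1L, 1L]
    chrom_end <- ex[nrow(ex), 2L]
    thick_s <- transcripts$cds_start[i]
    thick_e <- transcripts$cds_end[i]
    if (is.na(thick_s)) { thick_s <- chrom_end; thick_e <- chrom_end }
    paste(transcripts$contig[i], chrom_start, chrom_end,
          transcripts$tx_id[i], 0L, transcripts$strand[i],
          thick_s, thick_e, "0", nrow(ex),
          paste0(paste(ex[, 2L] - ex[, 1L], collapse = ","), ","),
          paste0(paste(ex[, 1L] - chrom_start, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Map a genomic position to a transcript-relative exonic coordinate
#'
#' @param tx One row of a transcript data.frame (list-like).
#' @param pos 0-based genomic position.
#' @return 0-based position along the spliced transcript (strand-aware,
#'   0 = TSS), or `NA` if `pos` is not exonic.
#' @keywords internal
tx_coord <- function(tx, pos) {
  ex <- tx$exons[[1L]]
  if (is.null(dim(ex))) ex <- tx$exons  # allow bare matrix
  hit <- which(pos >= ex[, 1L] & pos < ex[, 2L])
  if (length(hit) == 0L) return(NA_integer_)
  plus_coord <- pos - ex[hit, 1L] +
    if (hit > 1L) sum(ex[seq_len(hit - 1L), 2L] - ex[seq_len(hit - 1L), 1L]) else 0L
  total <- sum(ex[, 2L] - ex[, 1L])
  if (tx$strand == "+") as.integer(plus_coord) else as.integer(total - 1L - plus_coord)
}

#' Spliced transcript length
#' @keywords internal
tx_length <- function(tx) {
  ex <- tx$exons[[1L]]
  if (is.null(dim(ex))) ex <- tx$exons
  sum(ex[, 2L] - ex[, 1L])
}
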