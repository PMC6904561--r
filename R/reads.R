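#' Extract the N7B unique molecular identifier from a read sequence
#'
#' The UMI occupies the first 8 nucleotides of read 1: seven fully
#' random bases followed by one of C/G/T (pattern "N7B"). The final
#' non-A base prevents the UMI from extending a poly(A) ligation
#' junction.
#'
#' @param read1_sequence Nucleotide string, length >= 9.
#' @return List with `umi` (first 8 characters), `remainder` (rest of
#'   the sequence) and `valid` (logical, `TRUE` iff the UMI matches
#'   N7B).
#' @export
extract_umi <- function(read1_sequence) {
  if (nchar(read1_sequence) < 9L)
    stop("read too short to carry an 8-nt UMI plus insert: ",
         nchar(read1_sequence), " nt")
  umi <- toupper(substr(read1_sequence, 1L, 8L))
  list(umi = umi,
       remainder = substr(read1_sequence, 9L, nchar(read1_sequence)),
       valid = umi_valid(umi))
}

#' Validate UMIs against the N7B pattern
#'
#' @param umi Character vector of 8-mers.
#' @return Logical vector: positions 1-7 in A/C/G/T and position 8 in
#'   C/G/T.
#' @export
umi_valid <- function(umi) {
  grepl("^[ACGT]{7}[CGT]$", umi)
}

READ_COLUMNS <- c("contig", "strand", "start", "end", "umi", "replicate", "library")
LIBRARY_LEVELS <- c("m6ACE", "input")

validate_reads <- function(reads) {
  missing_cols <- setdiff(READ_COLUMNS, names(reads))
  if (length(missing_cols))
    stop("aligned-read table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!all(reads$library %in% LIBRARY_LEVELS))
    stop("unknown library label(s): ",
         paste(unique(setdiff(reads$library, LIBRARY_LEVELS)), collapse = ", "),
         " (expected m6ACE or input)")
  if (!all(reads$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(reads$start >= reads$end))
    stop("aligned reads must satisfy start < end (0-based half-open)")
  invisible(reads)
}

#' Read an aligned-read table (TSV)
#'
#' The canonical aligner-independent input: one row per deduplicable
#' mapped fragment with header
#' `contig  strand  start  end  umi  replicate  library`. Coordinates
#' are 0-based half-open genomic; the strand-aware read start (the
#' exonuclease stop position) is `start` on `+` and `end - 1` on `-`.
#' Rows whose UMI fails the N7B pattern are dropped with a message.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of aligned reads (`library` one of
#'   `"m6ACE"`/`"input"`).
#' @export
read_aligned_table <- function(path) {
  reads <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = c(contig = "character",
                                            strand = "character",
                                            start = "integer",
                                            end = "integer",
                                            umi = "character",
                                            replicate = "character",
                                            library = "character"),
                             stringsAsFactors = FALSE)
  bad <- !umi_valid(reads$umi)
  if (any(bad)) {
    message(sum(bad), " read(s) rejected: UMI fails N7B pattern")
    reads <- reads[!bad, , drop = FALSE]
    rownames(reads) <- NULL
  }
  validate_reads(reads)
  reads
}

#' Write an aligned-read table (TSV)
#'
#' @param reads Data frame of aligned reads.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_table <- function(reads, path) {
  utils::write.table(reads[, READ_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove PCR duplicates from aligned reads
#'
#' Aligned fragments sharing mapping coordinates and UMI are PCR
#' duplicates of one molecule; exactly one representative per key
#' `(contig, strand, start, end, umi, replicate, library)` is kept.
#' Output is sorted by key, so the operation is deterministic and
#' idempotent.
#'
#' @param reads Data frame of aligned reads.
#' @return Deduplicated data.frame.
#' @export
deduplicate <- function(reads) {
  validate_reads(reads)
  if (nrow(reads) == 0L) return(reads)
  dt <- data.table::as.data.table(reads[, READ_COLUMNS])
  out <- unique(dt, by = READ_COLUMNS)
  data.table::setorderv(out, READ_COLUMNS)
  as.data.frame(out)
}

#' Strand-aware read-start (exonuclease stop) position
#'
#' @param reads Data frame of aligned reads.
#' @return Integer vector: `start` for plus-strand fragments,
#'   `end - 1` for minus-strand fragments (0-based genomic).
#' @export
read_start_position <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}

#' Import aligned read pairs from BAM into the aligned-read table
#'
#' Optional convenience reader for aligner output: properly paired
#' primary alignments are collapsed to one record per fragment using
#' the fragment's genomic extent; the UMI is taken from the read name
#' suffix after the last `_` (the convention of common UMI-aware
#' trimmers). The TSV table remains the canonical tested input path.
#'
#' @param path BAM file path.
#' @param replicate,library Labels to assign to every fragment.
#' @return Data frame of aligned reads.
#' @export
read_aligned_bam <- function(path, replicate, library) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required for BAM input")
  p <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isPaired = TRUE, isFirstMateRead = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isNotPassingQualityControls = FALSE),
    what = c("qname", "rname", "strand", "pos", "isize", "qwidth"))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  keep <- !is.na(b$pos) & !is.na(b$isize) & b$isize != 0L
  frag_start <- ifelse(b$isize[keep] > 0L, b$pos[keep] - 1L,
                       b$pos[keep] - 1L + b$qwidth[keep] + b$isize[keep])
  frag_end <- frag_start + abs(b$isize[keep])
  umi <- sub(".*_", "", b$qname[keep])
  reads <- data.frame(contig = as.character(b$rname[keep]),
                      strand = as.character(b$strand[keep]),
                      start = as.integer(frag_start),
                      end = as.integer(frag_end),
                      umi = umi, replicate = replicate, library = library,
                      stringsAsFactors = FALSE)
  bad <- !umi_valid(reads$umi)
  if (any(bad)) {
    message(sum(bad), " fragment(s) rejected: UMI fails N7B pattern")
    reads <- reads[!bad, , drop = FALSE]
  }
  validate_reads(reads)
  reads
}
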