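#' Read a reference FASTA with a designated spike-in contig
#'
#' Loads reference sequences (transcript contigs plus the methylated
#' spike-in control) into a `ReferenceSet`. Sequences are uppercased;
#' `N` is permitted. The spike-in contig carries the single methylated
#' adenosine used to normalise relative methylation levels across
#' libraries.
#'
#' @param path Path to a FASTA file.
#' @param spike_in_name Name of the contig to flag as the spike-in
#'   control, or `NULL` if no spike-in is present.
#' @return A `ReferenceSet`: list with `contigs` (named character vector
#'   of uppercase sequences) and `spike_in_name`.
#' @export
read_reference <- function(path, spike_in_name = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L)
    stop("reference FASTA contains no sequences: ", path)
  contigs <- toupper(as.character(seqs))
  # FASTA headers may carry descriptions; contig name is the first word
  names(contigs) <- vapply(strsplit(names(seqs), "[ \t]"), `[`, "", 1L)
  ReferenceSet(contigs, spike_in_name)
}

#' Construct a ReferenceSet from in-memory sequences
#'
#' @param contigs Named character vector of nucleotide sequences
#'   (A/C/G/T/N; lowercase accepted and uppercased).
#' @param spike_in_name Contig name to flag as spike-in, or `NULL`.
#' @return A `ReferenceSet` object.
#' @export
ReferenceSet <- function(contigs, spike_in_name = NULL) {
  if (is.null(names(contigs)) || anyNA(names(contigs)) || any(names(contigs) == ""))
    stop("all contigs must be named")
  contigs <- toupper(contigs)
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop("contig(s) contain non-ACGTN characters: ",
         paste(names(contigs)[bad], collapse = ", "))
  if (!is.null(spike_in_name) && !spike_in_name %in% names(contigs))
    stop("spike-in contig '", spike_in_name, "' not found in reference")
  structure(list(contigs = contigs, spike_in_name = spike_in_name),
            class = "ReferenceSet")
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat("ReferenceSet:", length(x$contigs), "contig(s),",
      sum(nchar(x$contigs)), "nt total\n")
  if (!is.null(x$spike_in_name))
    cat("  spike-in:", x$spike_in_name,
        sprintf("(%d nt)\n", nchar(x$contigs[[x$spike_in_name]])))
  invisible(x)
}

#' Write a ReferenceSet to FASTA
#'
#' @param reference A `ReferenceSet`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  ss <- Biostrings::DNAStringSet(reference$contigs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

contig_length <- function(reference, contig) {
  s <- reference$contigs[contig]
  if (anyNA(s)) stop("unknown contig(s): ",
                     paste(contig[is.na(s)], collapse = ", "))
  nchar(s)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Strand-aware reference base at a genomic position
#'
#' @param reference A `ReferenceSet`.
#' @param contig,pos,strand Parallel vectors: contig name, 0-based
#'   genomic position, strand (`"+"`/`"-"`). On the minus strand the
#'   complement of the plus-strand base is returned.
#' @return Character vector of bases; `NA` for positions off the contig.
#' @export
ref_base <- function(reference, contig, pos, strand) {
  seqs <- reference$contigs[contig]
  len <- nchar(seqs)
  b <- rep(NA_character_, length(pos))
  ok <- !is.na(seqs) & pos >= 0L & pos < len
  b[ok] <- substr(seqs[ok], pos[ok] + 1L, pos[ok] + 1L)
  minus <- ok & strand == "-"
  b[minus] <- COMPLEMENT[b[minus]]
  b
}

#' Strand-aware sequence context around a site
#'
#' Returns the transcript-orientation sequence spanning strand-aware
#' offsets `from..to` (offset 0 = the site base; negative = 5' of it).
#' Positions off the contig are filled with `N`.
#'
#' @param reference A `ReferenceSet`.
#' @param contig,pos,strand Parallel site vectors (0-based positions).
#' @param from,to Inclusive strand-aware offsets, `from <= to`.
#' @return Character vector of contexts, each `to - from + 1` long.
#' @export
site_context <- function(reference, contig, pos, strand, from = -1L, to = 1L) {
  stopifnot(from <= to)
  offs <- from:to
  vapply(seq_along(pos), function(i) {
    gpos <- if (strand[i] == "+") pos[i] + offs else pos[i] - offs
    b <- ref_base(reference, rep(contig[i], length(offs)), gpos,
                  rep(strand[i], length(offs)))
    b[is.na(b)] <- "N"
    paste(b, collapse = "")
  }, "")
}
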