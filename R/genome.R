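#' Genome container
#'
#' A genome is stored as a named character vector of uppercase A/C/G/T/N
#' contig sequences (class `thermedit_genome`). Plain character storage keeps
#' the hot substring operations of the aligner and pileup vectorised;
#' conversion to [Biostrings::DNAStringSet] happens at the format boundary.
#'
#' @param seqs Named character vector of contig sequences.
#' @return A `thermedit_genome` object.
#' @export
genome <- function(seqs) {
  if (length(seqs) == 0) abort("genome must contain at least one contig")
  if (is.null(names(seqs)) || any(names(seqs) == "")) abort("contigs must be named")
  if (anyDuplicated(names(seqs))) abort("duplicate contig names")
  seqs <- toupper(unlist(seqs))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) abort(sprintf("contig %s contains non-ACGTN characters",
                              names(seqs)[bad][1]))
  structure(seqs, class = "thermedit_genome")
}

#' @export
print.thermedit_genome <- function(x, ...) {
  cat(sprintf("<thermedit_genome> %d contig(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  for (nm in names(x)) cat(sprintf("  %s: %s bp\n", nm, format(nchar(x[[nm]]), big.mark = ",")))
  invisible(x)
}

#' Contig lengths of a genome
#' @param genome A `thermedit_genome`.
#' @return Named integer vector.
#' @export
genome_lengths <- function(genome) {
  setNames(nchar(unclass(genome)), names(genome))
}

#' Extract a strand-aware genomic subsequence
#'
#' Coordinates are 1-based closed. On the minus strand the reverse complement
#' is returned.
#'
#' @param genome A `thermedit_genome`.
#' @param contig Contig name.
#' @param start,end 1-based inclusive coordinates (vectorised).
#' @param strand `"+"` or `"-"` (vectorised, recycled).
#' @return Character vector of sequences.
#' @export
genome_subseq <- function(genome, contig, start, end, strand = "+") {
  if (!all(contig %in% names(genome))) {
    abort(sprintf("unknown contig: %s", setdiff(contig, names(genome))[1]))
  }
  len <- genome_lengths(genome)[contig]
  if (any(start < 1) || any(end > len) || any(end < start)) {
    abort("genome_subseq: query outside contig bounds")
  }
  out <- unname(substring(unclass(genome)[contig], start, end))
  neg <- rep_len(strand, length(out)) == "-"
  if (any(neg)) out[neg] <- revcomp(out[neg])
  out
}

#' Read a reference genome from FASTA
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A `thermedit_genome`.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) abort(sprintf("reference FASTA not found: %s", path))
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) abort(sprintf("empty FASTA: %s", path))
  nms <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nms)) abort(sprintf("duplicate contig names in %s", path))
  genome(setNames(as.character(ss), nms))
}

#' Write a genome to FASTA
#'
#' @param genome A `thermedit_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
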