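# Format boundary: FASTQ via Biostrings, BED/GTF/wig via rtracklayer,
# site tables as 1-based TSV. BED is 0-based half-open on disk; everything
# in memory is 1-based closed, converted only here.

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads Tibble with columns `read_id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  lines <- character(4L * nrow(reads))
  lines[seq(1, by = 4, length.out = nrow(reads))] <- paste0("@", reads$read_id)
  lines[seq(2, by = 4, length.out = nrow(reads))] <- reads$seq
  lines[seq(3, by = 4, length.out = nrow(reads))] <- "+"
  lines[seq(4, by = 4, length.out = nrow(reads))] <- reads$qual
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path Path to an uncompressed FASTQ file (Phred+33).
#' @return Tibble with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTQ not found: %s", path))
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(read_id = sub("\\s.*$", "", names(ss)),
         seq = unname(as.character(ss)),
         qual = unname(as.character(S4Vectors::mcols(ss)$qualities)))
}

#' Load genomic intervals from BED or GTF
#'
#' BED input (0-based half-open on disk) is converted to 1-based closed
#' coordinates; GTF input is returned keyed by feature type with gene and
#' transcript identifiers when present.
#'
#' @param path File path.
#' @param format `"bed"` or `"gtf"` (default: guessed from the extension).
#' @return Tibble with columns `contig`, `start`, `end`, `strand` plus,
#'   for GTF, `feature`, `gene_id`, `transcript_id`; for BED, `name` when
#'   present.
#' @export
load_intervals <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("interval file not found: %s", path))
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(format, c("bed", "gtf", "gff"))
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gff") "gff" else format),
    error = function(e) abort(sprintf("failed to parse %s as %s: %s",
                                      path, format, conditionMessage(e))))
  out <- tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (format %in% c("gtf", "gff")) {
    out$feature <- as.character(mc$type)
    out$gene_id <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else NA_character_
    out$transcript_id <- if ("transcript_id" %in% names(mc)) as.character(mc$transcript_id) else NA_character_
  } else if ("name" %in% names(mc)) {
    out$name <- as.character(mc$name)
  }
  out
}

#' Write intervals to BED (0-based half-open)
#'
#' @param x Tibble with `contig`, `start`, `end` (1-based closed) and
#'   optionally `name`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("contig", "start", "end") %in% names(x)))
  df <- tibble(chrom = x$contig, chromStart = x$start - 1L, chromEnd = x$end,
               name = if ("name" %in% names(x)) x$name else ".",
               score = 0L,
               strand = if ("strand" %in% names(x)) x$strand else ".")
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Write a gene model to GTF
#'
#' @param genes Tibble as produced by [generate_genome()] (`contig`,
#'   `feature`, `start`, `end`, `strand`, `gene_id`, `transcript_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   genes$gene_id, genes$transcript_id)
  lines <- paste(genes$contig, "thermedit", genes$feature, genes$start,
                 genes$end, ".", genes$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a site table to TSV (1-based positions)
#'
#' @param sites Tibble with at least `contig`, `pos`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  stopifnot(all(c("contig", "pos", "strand") %in% names(sites)))
  readr::write_tsv(sites, path)
  invisible(path)
}

#' Read a site table written by [write_sites()]
#'
#' @param path TSV path.
#' @return Tibble; malformed rows raise an error naming the line.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) abort(sprintf("site table not found: %s", path))
  out <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("contig", "pos", "strand")
  if (!all(need %in% names(out))) {
    abort(sprintf("site table %s lacks columns: %s", path,
                  paste(setdiff(need, names(out)), collapse = ", ")))
  }
  bad <- which(!is.finite(out$pos) | !(out$strand %in% c("+", "-")))
  if (length(bad)) {
    abort(sprintf("malformed site record at line %d of %s", bad[1] + 1L, path))
  }
  out$pos <- as.integer(out$pos)
  out
}

#' Read a per-base conservation track
#'
#' Accepts a fixed-step wiggle file or a 3-column TSV
#' (contig, 1-based position, score).
#'
#' @param path File path.
#' @param format `"wig"` or `"tsv"` (default: guessed from the extension).
#' @return Tibble with columns `contig`, `pos`, `score`.
#' @export
read_track <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("track not found: %s", path))
  format <- format %||% tolower(tools::file_ext(path))
  if (format == "wig") {
    gr <- rtracklayer::import(path, format = "wig")
    pos <- unlist(mapply(seq, GenomicRanges::start(gr), GenomicRanges::end(gr),
                         SIMPLIFY = FALSE))
    widths <- GenomicRanges::width(gr)
    tibble(contig = rep(as.character(GenomicRanges::seqnames(gr)), widths),
           pos = as.integer(pos),
           score = rep(S4Vectors::mcols(gr)$score, widths))
  } else {
    out <- readr::read_tsv(path, col_names = c("contig", "pos", "score"),
                           show_col_types = FALSE)
    if (is.character(out$pos)) {
      abort(sprintf("malformed track line 1 of %s (expected numeric position)", path))
    }
    out
  }
}
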