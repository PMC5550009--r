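# Per-site editing-level quantification against a combined site list,
# pooled editing index, and genomic-location annotation.

#' Union of editing-site lists with provenance flags
#'
#' Exact-coordinate deduplication of several site lists. Sites present at the
#' same contig and position on conflicting strands are flagged and kept once
#' with both provenances.
#'
#' @param ... Named site tibbles (each with contig, pos, strand).
#' @return Tibble: contig, pos, strand, one logical `in_<name>` column per
#'   input, `provenance` (comma-joined source names), `strand_conflict`.
#' @examples
#' a <- tibble::tibble(contig = "c", pos = c(1L, 5L), strand = "+")
#' b <- tibble::tibble(contig = "c", pos = c(5L, 9L), strand = "+")
#' union_site_lists(known = a, novel = b)
#' @export
union_site_lists <- function(...) {
  lists <- list(...)
  if (length(lists) == 0) abort("union_site_lists needs at least one list")
  if (is.null(names(lists)) || any(names(lists) == "")) {
    names(lists) <- paste0("list", seq_along(lists))
  }
  tagged <- imap_dfr(lists, function(x, nm) {
    if (nrow(x) == 0) return(tibble(contig = character(), pos = integer(),
                                    strand = character(), source = character()))
    x |> select("contig", "pos", "strand") |> mutate(source = nm)
  })
  if (nrow(tagged) == 0) {
    return(tibble(contig = character(), pos = integer(), strand = character()))
  }
  out <- tagged |>
    group_by(.data$contig, .data$pos) |>
    summarise(strand_conflict = n_distinct(.data$strand) > 1L,
              strand = first(.data$strand),
              provenance = paste(sort(unique(.data$source)), collapse = ","),
              .groups = "drop")
  for (nm in names(lists)) {
    out[[paste0("in_", nm)]] <- stringr::str_detect(
      out$provenance, stringr::fixed(nm))
  }
  arrange(out, .data$contig, .data$pos)
}

#' Per-site base pileup from ungapped alignments
#'
#' Counts, per site and sample, reads supporting the reference A versus the
#' edited G at the site (oriented to the site strand: on minus-strand sites
#' the plus-reference T and C are the A- and G-reads). Bases within `trim`
#' bases of either read end or below `quality_min` are ignored; bases that
#' are neither A nor G are tallied as `other` and excluded from the editing
#' level.
#'
#' @param alignments Tibble from [align_reads()] (unique rows are used), with
#'   an optional `sample` column; absent, all reads form sample "s1".
#' @param sites Tibble with contig, pos, strand.
#' @param quality_min Minimum base quality (default 30).
#' @param trim Bases ignored at both read ends (default 6).
#' @return Tibble: contig, pos, strand, sample, a_count, g_count, other,
#'   coverage (= a + g), level (= g / (a + g), NA at zero coverage).
#' @export
pileup_sites <- function(alignments, sites, quality_min = 30, trim = 6) {
  aln <- alignments |> filter(.data$status == "unique")
  if (!"sample" %in% names(aln)) aln$sample <- "s1"
  samples <- unique(aln$sample)
  base_grid <- crossing(sites |> select("contig", "pos", "strand"),
                        sample = samples)
  if (nrow(aln) == 0 || nrow(sites) == 0) {
    return(base_grid |> mutate(a_count = 0L, g_count = 0L, other = 0L,
                               coverage = 0L, level = NA_real_))
  }
  L <- nchar(aln$seq_aligned[1])
  known <- sites$contig %in% unique(aln$contig)
  n_skipped <- sum(!known)
  res <- vector("list", nrow(sites))
  ord <- order(aln$contig, aln$start)
  aln_s <- aln[ord, ]
  by_ctg <- split(seq_len(nrow(aln_s)), aln_s$contig)
  for (k in seq_len(nrow(sites))) {
    ctg <- sites$contig[k]; p <- sites$pos[k]
    idxs <- by_ctg[[ctg]]
    if (is.null(idxs)) next
    ss <- aln_s$start[idxs]
    i1 <- findInterval(p - L, ss) + 1L
    i2 <- findInterval(p, ss)
    if (i2 < i1) next
    rows <- idxs[i1:i2]
    off <- p - aln_s$start[rows] + 1L
    # read-end distance in original read coordinates (symmetric under
    # orientation, so plus-oriented offsets serve both strands)
    keep <- off > trim & off <= L - trim
    rows <- rows[keep]; off <- off[keep]
    if (!length(rows)) next
    q <- as.integer(charToRaw(paste0(substring(aln_s$qual_aligned[rows], off, off),
                                     collapse = ""))) - 33L
    keep <- q >= quality_min
    rows <- rows[keep]; off <- off[keep]
    if (!length(rows)) next
    b <- substring(aln_s$seq_aligned[rows], off, off)
    if (sites$strand[k] == "-") b <- complement_base(b)
    res[[k]] <- tibble(contig = ctg, pos = p, strand = sites$strand[k],
                       sample = aln_s$sample[rows], base = b)
  }
  counts <- bind_rows(res)
  if (nrow(counts) == 0) {
    out <- base_grid |> mutate(a_count = 0L, g_count = 0L, other = 0L,
                               coverage = 0L, level = NA_real_)
  } else {
    out <- counts |>
      group_by(.data$contig, .data$pos, .data$strand, .data$sample) |>
      summarise(a_count = sum(.data$base == "A"),
                g_count = sum(.data$base == "G"),
                other = sum(!.data$base %in% c("A", "G")),
                .groups = "drop") |>
      right_join(base_grid, by = c("contig", "pos", "strand", "sample")) |>
      mutate(across(c("a_count", "g_count", "other"),
                    ~ coalesce(.x, 0L))) |>
      mutate(coverage = .data$a_count + .data$g_count,
             level = ifelse(.data$coverage > 0,
                            .data$g_count / .data$coverage, NA_real_))
  }
  if (n_skipped > 0) {
    warn(sprintf("%d site(s) on contigs absent from the alignments", n_skipped))
  }
  arrange(out, .data$contig, .data$pos, .data$sample)
}

#' Keep sites with supported editing
#'
#' A site survives when, in at least one sample, at least `min_reads` reads
#' support the G variant at an editing level of at least `min_level`.
#'
#' @param pileups Tibble from [pileup_sites()].
#' @param min_reads Minimum G-supporting reads (default 2).
#' @param min_level Minimum editing level (default 0.01).
#' @return Filtered pileup tibble (all samples of surviving sites).
#' @export
filter_supported <- function(pileups, min_reads = 2, min_level = 0.01) {
  keep <- pileups |>
    filter(.data$g_count >= min_reads,
           !is.na(.data$level), .data$level >= min_level) |>
    distinct(.data$contig, .data$pos, .data$strand)
  semi_join(pileups, keep, by = c("contig", "pos", "strand"))
}

#' Pooled editing index over a site set
#'
#' The fraction of inosines among all expressed adenosines: total G-reads
#' over total (A+G)-reads across the sites, i.e. the coverage-weighted mean
#' of per-site editing levels.
#'
#' @param pileups Tibble from [pileup_sites()] (optionally pre-filtered to a
#'   subset of sites/samples).
#' @return Tibble with one row per sample: sample, numerator, denominator,
#'   index.
#' @examples
#' p <- tibble::tibble(contig = "c", pos = c(1L, 2L), strand = "+",
#'                     sample = "s1", a_count = c(8L, 5L), g_count = c(2L, 5L))
#' editing_index(p)  # 7 / 20
#' @export
editing_index <- function(pileups) {
  if (nrow(pileups) == 0) abort("editing_index needs a non-empty site subset")
  pileups |>
    group_by(.data$sample) |>
    summarise(numerator = sum(.data$g_count),
              denominator = sum(.data$a_count) + sum(.data$g_count),
              .groups = "drop") |>
    mutate(index = ifelse(.data$denominator > 0,
                          .data$numerator / .data$denominator, NA_real_))
}

#' Annotate sites by genomic location
#'
#' Assigns exactly one category per site with precedence
#' CDS > 5'UTR / 3'UTR > noncoding exon > intron > intergenic; the first
#' transcript wins ties. Introns are gene-body positions not covered by an
#' exon of the same gene. Sites on contigs absent from the gene model are
#' intergenic.
#'
#' @param sites Tibble with contig, pos, strand (strand is not used for
#'   assignment; editing is annotated by position).
#' @param genes Gene-model tibble (as from [generate_genome()] or
#'   [load_intervals()] on a GTF).
#' @return `sites` with added `category` and `gene_id` columns, plus a
#'   `category_distribution` attribute (tibble of counts per category).
#' @export
annotate_sites <- function(sites, genes) {
  cats <- c("CDS", "5'UTR", "3'UTR", "noncoding-exon", "intron", "intergenic")
  if (nrow(sites) == 0) {
    out <- sites |> mutate(category = character(0), gene_id = character(0))
    attr(out, "category_distribution") <- tibble(category = cats, n = 0L)
    return(out)
  }
  site_gr <- GenomicRanges::GRanges(sites$contig,
                                    IRanges::IRanges(sites$pos, sites$pos))
  feature_cat <- c(CDS = "CDS", five_prime_utr = "5'UTR",
                   three_prime_utr = "3'UTR", exon = "noncoding-exon")
  category <- rep("intergenic", nrow(sites))
  gene_id <- rep(NA_character_, nrow(sites))
  assign_level <- function(feat_tbl, label) {
    if (nrow(feat_tbl) == 0) return()
    gr <- GenomicRanges::GRanges(feat_tbl$contig,
                                 IRanges::IRanges(feat_tbl$start, feat_tbl$end))
    ov <- GenomicRanges::findOverlaps(site_gr, gr, select = "first")
    hit <- !is.na(ov) & category == "intergenic"
    category[hit] <<- label
    gene_id[hit] <<- feat_tbl$gene_id[ov[hit]]
  }
  for (feat in names(feature_cat)) {
    assign_level(genes |> filter(.data$feature == feat), feature_cat[[feat]])
  }
  # introns: within a gene body but not yet assigned
  bodies <- genes |>
    group_by(.data$gene_id) |>
    summarise(contig = first(.data$contig), start = min(.data$start),
              end = max(.data$end), .groups = "drop")
  assign_level(bodies, "intron")
  out <- sites |> mutate(category = factor(category, levels = cats),
                         gene_id = gene_id)
  attr(out, "category_distribution") <- out |>
    count(.data$category, .drop = FALSE, name = "n") |>
    mutate(category = as.character(.data$category))
  out
}
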