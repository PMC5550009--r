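# Embedded seed-and-extend read aligner (ungapped, desk scale).
#
# Exact placements are found with Biostrings::matchPDict; remaining reads are
# seeded with max_mm + 1 disjoint k-mers, which by pigeonhole guarantees that
# every placement with <= max_mm mismatches is enumerated. Uniqueness means
# the best placement is strictly better (fewer mismatches) than the second
# best. Reads whose best placement exceeds the budget (or that have no
# candidate at all) form the unaligned pool that feeds hyper-editing
# detection.

# enumerate candidate placements for a set of equal-length reads.
# reads_by_strand: named list("+" = oriented seqs matched to the plus genome,
# "-" = ...); a read aligned via the "-" entry is a minus-strand alignment.
# Returns tibble(read = index, contig, start, strand, mm).
align_candidates <- function(reads_by_strand, gen_seqs, max_mm) {
  reads_by_strand <- lapply(reads_by_strand, unname)
  n <- length(reads_by_strand[[1]])
  widths <- nchar(reads_by_strand[[1]])
  if (length(unique(widths)) != 1L) {
    abort("align_candidates expects equal-length reads")
  }
  L <- widths[1]
  gen_raw <- lapply(gen_seqs, charToRaw)

  cand <- list()
  exact_hit <- rep(FALSE, n)
  # pass 1: exact full-length matches
  for (st in names(reads_by_strand)) {
    ok <- !grepl("[^ACGT]", reads_by_strand[[st]])
    if (!any(ok)) next
    dss <- Biostrings::DNAStringSet(reads_by_strand[[st]][ok])
    pd <- Biostrings::PDict(dss)
    idx_ok <- which(ok)
    for (ctg in names(gen_seqs)) {
      m <- Biostrings::matchPDict(pd, Biostrings::DNAString(gen_seqs[[ctg]]))
      starts <- Biostrings::startIndex(m)
      nh <- S4Vectors::elementNROWS(m)
      if (sum(nh) == 0) next
      hit <- which(nh > 0)
      cand[[length(cand) + 1L]] <- tibble(
        read = rep(idx_ok[hit], nh[hit]),
        contig = ctg,
        start = unlist(starts[hit], use.names = FALSE),
        strand = st, mm = 0L)
      exact_hit[idx_ok[hit]] <- TRUE
    }
  }

  # pass 2: seeded search for reads without an exact placement
  todo <- which(!exact_hit)
  if (length(todo) && max_mm > 0) {
    k <- max(7L, L %/% (max_mm + 1L))
    n_seeds <- min(max_mm + 1L, L %/% k)
    offs <- (seq_len(n_seeds) - 1L) * k + 1L
    for (st in names(reads_by_strand)) {
      seqs <- reads_by_strand[[st]][todo]
      ok <- !grepl("[^ACGT]", seqs)
      if (!any(ok)) next
      sub <- todo[ok]
      seeds <- unlist(lapply(offs, function(o) substr(seqs[ok], o, o + k - 1L)))
      seed_read <- rep(sub, times = n_seeds)
      seed_off <- rep(offs, each = length(sub))
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
      for (ctg in names(gen_seqs)) {
        Lc <- nchar(gen_seqs[[ctg]])
        m <- Biostrings::matchPDict(pd, Biostrings::DNAString(gen_seqs[[ctg]]))
        starts <- Biostrings::startIndex(m)
        nh <- S4Vectors::elementNROWS(m)
        if (sum(nh) == 0) next
        hit <- which(nh > 0)
        cs <- unlist(starts[hit], use.names = FALSE) - rep(seed_off[hit], nh[hit]) + 1L
        cr <- rep(seed_read[hit], nh[hit])
        keep <- cs >= 1L & cs + L - 1L <= Lc
        if (!any(keep)) next
        cc <- tibble(read = cr[keep], contig = ctg, start = cs[keep], strand = st)
        cc <- distinct(cc)
        # mismatch counts, block-vectorised against the raw genome
        ori <- reads_by_strand[[st]]
        mm <- integer(nrow(cc))
        block <- 50000L
        for (b0 in seq(1L, nrow(cc), by = block)) {
          b1 <- min(b0 + block - 1L, nrow(cc))
          bs <- cc$start[b0:b1]
          gidx <- rep(bs, each = L) + seq_len(L) - 1L
          gmat <- matrix(gen_raw[[ctg]][gidx], nrow = L)
          rmat <- matrix(unlist(lapply(ori[cc$read[b0:b1]], charToRaw)), nrow = L)
          mm[b0:b1] <- colSums(gmat != rmat)
        }
        cc$mm <- mm
        cand[[length(cand) + 1L]] <- cc
      }
    }
  }
  if (!length(cand)) {
    return(tibble(read = integer(), contig = character(), start = integer(),
                  strand = character(), mm = integer()))
  }
  distinct(bind_rows(cand))
}

# pick per-read best placement; returns tibble(read, contig, start, strand,
# mm, n_best) with one row per read that has any candidate
best_placements <- function(cand) {
  if (nrow(cand) == 0) {
    return(tibble(read = integer(), contig = character(), start = integer(),
                  strand = character(), mm = integer(), n_best = integer()))
  }
  cand |>
    group_by(.data$read) |>
    arrange(.data$mm, .data$contig, .data$start, .data$strand,
            .by_group = TRUE) |>
    summarise(n_best = sum(.data$mm == min(.data$mm)),
              contig = first(.data$contig), start = first(.data$start),
              strand = first(.data$strand), mm = first(.data$mm),
              .groups = "drop")
}

#' Align reads to a genome, keeping unique placements and an unaligned pool
#'
#' Ungapped seed-and-extend alignment at desk scale. A read is `unique` when
#' its best placement has strictly fewer mismatches than any other placement
#' and is within the mismatch budget; `multi` when two or more placements tie
#' at the best mismatch count; `unaligned` when no placement is within budget.
#' The three statuses partition the input read set; the unaligned pool is the
#' input to [detect_hyper_edited_reads()].
#'
#' @param reads Tibble with `read_id`, `seq`, `qual` (equal-length reads).
#' @param gen A `thermedit_genome`.
#' @param max_mm_per_100 Mismatch budget per 100 read bases (default 4).
#' @return Tibble with one row per read: `read_id`, `status`
#'   (`unique`/`multi`/`unaligned`), and for placed reads `contig`, `start`,
#'   `strand`, `n_mismatch`, plus `seq_aligned`/`qual_aligned` oriented to
#'   the plus strand of the reference.
#' @export
align_reads <- function(reads, gen, max_mm_per_100 = 4) {
  stopifnot(is_tibble(reads) || is.data.frame(reads))
  if (length(gen) == 0 || all(nchar(unclass(gen)) == 0)) abort("empty genome")
  if (nrow(reads) == 0) {
    return(tibble(read_id = character(), status = character(),
                  contig = character(), start = integer(), strand = character(),
                  n_mismatch = integer(), seq_aligned = character(),
                  qual_aligned = character()))
  }
  L <- nchar(reads$seq[1])
  budget <- max(1L, round(max_mm_per_100 * L / 100))
  rbs <- list("+" = reads$seq, "-" = revcomp(reads$seq))
  cand <- align_candidates(rbs, as.list(unclass(gen)), budget)
  best <- best_placements(cand)

  out <- tibble(read_id = reads$read_id, status = "unaligned",
                contig = NA_character_, start = NA_integer_,
                strand = NA_character_, n_mismatch = NA_integer_)
  if (nrow(best)) {
    placed <- best$mm <= budget
    i <- best$read[placed]
    out$status[i] <- ifelse(best$n_best[placed] > 1L, "multi", "unique")
    out$contig[i] <- best$contig[placed]
    out$start[i] <- as.integer(best$start[placed])
    out$strand[i] <- best$strand[placed]
    out$n_mismatch[i] <- as.integer(best$mm[placed])
  }
  neg <- !is.na(out$strand) & out$strand == "-"
  out$seq_aligned <- ifelse(out$status == "unaligned", NA_character_, reads$seq)
  out$qual_aligned <- ifelse(out$status == "unaligned", NA_character_, reads$qual)
  out$seq_aligned[neg] <- revcomp(out$seq_aligned[neg])
  out$qual_aligned[neg] <- vapply(out$qual_aligned[neg], function(q)
    intToUtf8(rev(utf8ToInt(q))), character(1))
  out
}

#' Extract the unaligned pool from an alignment table
#' @param alignments Output of [align_reads()].
#' @param reads The read tibble given to [align_reads()].
#' @return Tibble of unaligned reads (`read_id`, `seq`, `qual`).
#' @export
unaligned_pool <- function(alignments, reads) {
  reads |> semi_join(filter(alignments, .data$status == "unaligned"), by = "read_id")
}
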