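# Hyper-editing detection by base-transformed realignment.
#
# Reads that standard alignment rejects because they carry dense A-to-G
# mismatch clusters become alignable once every A is collapsed to G in both
# the reads and the reference. After unique transformed placement the
# original sequences are restored and the A-to-G mismatches recovered.
# Minus-strand events are caught by the complementary transformation (T-to-C
# on the plus reference) and reported as A-to-G sites on the minus strand.

MISMATCH_TYPES <- c("AC", "AG", "AT", "CA", "CG", "CT",
                    "GA", "GC", "GT", "TA", "TC", "TG")

#' Collapse one base into another throughout a sequence
#'
#' The core step of transformed realignment: all `from` bases are replaced by
#' `to`, removing the mismatch type of interest from both reads and
#' reference so that hyper-edited reads become alignable.
#'
#' @param x Character vector of sequences (A/C/G/T/N).
#' @param from,to Single distinct bases.
#' @return Character vector with every `from` replaced by `to`.
#' @examples
#' transform_bases("GATTACA", "A", "G")
#' @export
transform_bases <- function(x, from, to) {
  from <- toupper(from); to <- toupper(to)
  if (!from %in% c("A", "C", "G", "T") || !to %in% c("A", "C", "G", "T")) {
    abort("`from` and `to` must be single bases in A/C/G/T")
  }
  if (from == to) abort("`from` and `to` must differ")
  chartr(from, to, x)
}

#' Detect hyper-edited reads by transformed realignment
#'
#' Transforms the unaligned read pool and the reference (`from -> to`),
#' realigns requiring a unique best placement, restores the original
#' sequences, and collects mismatches of the target type with base quality
#' `>= quality_min`. Mismatches within `end_exclusion` bases of either read
#' end are discarded (they are enriched for alignment artefacts at splice
#' boundaries); a read yields a cluster when at least `min_edits` mismatches
#' remain and their genomic span covers at least 10 percent of the read
#' length. For `mismatch_type = "AG"`, plus-pass hits are A-to-G sites on the
#' plus strand and T-to-C pass hits are A-to-G sites on the minus strand.
#'
#' @param pool Tibble of unaligned reads (`read_id`, `seq`, `qual`).
#' @param gen A `thermedit_genome`.
#' @param mismatch_type Two-letter code among the 12 ordered base pairs
#'   (default `"AG"`, the only type retained as editing; the others are run
#'   for QC).
#' @param quality_min Minimum Phred quality of a counted mismatch.
#' @param min_edits Minimum number of retained mismatches per read cluster.
#' @param end_exclusion Read-end exclusion zone in bases.
#' @param max_mm_per_100 Mismatch budget per 100 bases for the transformed
#'   realignment (residual errors only).
#' @return List with `clusters` (tibble: read_id, contig, start, end, strand,
#'   n_edits, read_length), `events` (tibble: read_id, contig, pos, read_pos,
#'   ref, alt, qual, strand; one row per retained mismatch), `placements`
#'   (tibble of every uniquely realigned pool read, whether or not it passed
#'   the cluster rules, in the layout of [align_reads()] so it can be pooled
#'   with ordinary alignments for pileups), and `stats` (reads in, placed,
#'   ambiguous, clusters called).
#' @export
detect_hyper_edited_reads <- function(pool, gen, mismatch_type = "AG",
                                      quality_min = 30, min_edits = 4,
                                      end_exclusion = 6, max_mm_per_100 = 4) {
  mismatch_type <- match.arg(mismatch_type, MISMATCH_TYPES)
  from <- substr(mismatch_type, 1, 1)
  to <- substr(mismatch_type, 2, 2)
  cfrom <- complement_base(from)
  cto <- complement_base(to)

  empty <- list(
    clusters = tibble(read_id = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      n_edits = integer(), read_length = integer()),
    events = tibble(read_id = character(), contig = character(),
                    pos = integer(), read_pos = integer(), ref = character(),
                    alt = character(), qual = integer(), strand = character()),
    placements = tibble(read_id = character(), status = character(),
                        contig = character(), start = integer(),
                        strand = character(), n_mismatch = integer(),
                        seq_aligned = character(), qual_aligned = character()),
    stats = tibble(reads_in = 0L, placed = 0L, ambiguous = 0L, clusters = 0L))
  if (nrow(pool) == 0) return(empty)

  L <- nchar(pool$seq[1])
  budget <- max(1L, round(max_mm_per_100 * L / 100))
  gseqs <- as.list(unclass(gen))

  # "+": reads as-is under from->to vs the from->to reference;
  # "-": reverse-complemented reads under cfrom->cto vs the cfrom->cto
  # reference (an A-to-G edit on the minus strand is T-to-C on plus).
  rbs <- list("+" = transform_bases(pool$seq, from, to),
              "-" = transform_bases(revcomp(pool$seq), cfrom, cto))
  gens <- list("+" = lapply(gseqs, transform_bases, from = from, to = to),
               "-" = lapply(gseqs, transform_bases, from = cfrom, to = cto))
  cand <- bind_rows(
    align_candidates(rbs["+"], gens[["+"]], budget),
    align_candidates(rbs["-"], gens[["-"]], budget))
  best <- best_placements(cand)
  placed <- best |> filter(.data$mm <= budget)
  ambiguous <- sum(placed$n_best > 1L)
  placed <- placed |> filter(.data$n_best == 1L)

  if (nrow(placed) == 0) {
    empty$stats$reads_in <- nrow(pool)
    empty$stats$ambiguous <- ambiguous
    return(empty)
  }

  # restore originals, oriented to the reference plus strand
  ori_seq <- ifelse(placed$strand == "+", pool$seq[placed$read],
                    revcomp(pool$seq[placed$read]))
  ori_qual <- pool$qual[placed$read]
  ori_qual[placed$strand == "-"] <- vapply(
    ori_qual[placed$strand == "-"],
    function(q) intToUtf8(rev(utf8ToInt(q))), character(1))
  ref_seq <- substring(unlist(gseqs[placed$contig]), placed$start,
                       placed$start + L - 1L)
  want_ref <- ifelse(placed$strand == "+", from, cfrom)
  want_alt <- ifelse(placed$strand == "+", to, cto)
  span_min <- ceiling(0.10 * L)

  ev <- vector("list", nrow(placed))
  cl <- vector("list", nrow(placed))
  for (i in seq_len(nrow(placed))) {
    mmp <- string_mismatches(ori_seq[i], ref_seq[i])
    if (!length(mmp)) next
    refb <- substring(ref_seq[i], mmp, mmp)
    altb <- substring(ori_seq[i], mmp, mmp)
    hit <- refb == want_ref[i] & altb == want_alt[i]
    q <- utf8ToInt(substr(ori_qual[i], 1, L))[mmp] - 33L
    keep <- hit & q >= quality_min & mmp > end_exclusion & mmp <= L - end_exclusion
    if (sum(keep) < min_edits) next
    kp <- mmp[keep]
    if (kp[length(kp)] - kp[1] + 1L < span_min) next
    gpos <- placed$start[i] + kp - 1L
    rid <- pool$read_id[placed$read[i]]
    ev[[i]] <- tibble(read_id = rid, contig = placed$contig[i], pos = gpos,
                      read_pos = kp, ref = from, alt = to, qual = q[keep],
                      strand = placed$strand[i])
    cl[[i]] <- tibble(read_id = rid, contig = placed$contig[i],
                      start = gpos[1], end = gpos[length(gpos)],
                      strand = placed$strand[i], n_edits = length(kp),
                      read_length = L)
  }
  clusters <- bind_rows(cl)
  events <- bind_rows(ev)
  if (nrow(clusters) == 0) clusters <- empty$clusters
  if (nrow(events) == 0) events <- empty$events
  placements <- tibble(read_id = pool$read_id[placed$read], status = "unique",
                       contig = placed$contig, start = as.integer(placed$start),
                       strand = placed$strand,
                       n_mismatch = as.integer(placed$mm),
                       seq_aligned = ori_seq, qual_aligned = ori_qual)
  list(clusters = clusters, events = events, placements = placements,
       stats = tibble(reads_in = nrow(pool), placed = nrow(placed),
                      ambiguous = ambiguous, clusters = nrow(clusters)))
}

#' Merge read-level clusters into genomic hyper-edited regions
#'
#' Clusters on the same contig and strand that overlap or are separated by at
#' most `max_gap` bases (gap measured as `next start - previous end - 1`) are
#' merged. A region spans from the first base of its upstream cluster to the
#' last base of its downstream cluster.
#'
#' @param clusters Cluster tibble from [detect_hyper_edited_reads()].
#' @param max_gap Maximum gap between merged clusters, bases (default 20).
#' @return Tibble: contig, start, end, strand, n_clusters, n_events,
#'   member_ids (semicolon-joined read ids).
#' @export
merge_clusters_to_regions <- function(clusters, max_gap = 20) {
  if (nrow(clusters) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), n_clusters = integer(),
                  n_events = integer(), member_ids = character()))
  }
  clusters |>
    group_by(.data$contig, .data$strand) |>
    arrange(.data$start, .data$end, .by_group = TRUE) |>
    mutate(new_region = cumsum(
      c(TRUE, (.data$start[-1] - cummax(.data$end)[-n()] - 1L) > max_gap))) |>
    group_by(.data$contig, .data$strand, .data$new_region) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_clusters = n(), n_events = sum(.data$n_edits),
              member_ids = paste(.data$read_id, collapse = ";"),
              .groups = "drop") |>
    select("contig", "start", "end", "strand", "n_clusters", "n_events",
           "member_ids") |>
    arrange(.data$contig, .data$start)
}

#' Collapse read-level events into unique editing-site calls
#'
#' @param detection Result of [detect_hyper_edited_reads()], or an event
#'   tibble with columns contig, pos, strand (and optionally condition).
#' @return List with `sites` (tibble: contig, pos, strand, n_events and, when
#'   present in the input, the conditions each site was seen in) and
#'   `summary` (unique sites, total events, events per site, mean sites per
#'   cluster, mean cluster length — per condition when available).
#' @export
collect_sites <- function(detection) {
  events <- if (is.data.frame(detection)) detection else detection$events
  clusters <- if (is.data.frame(detection)) NULL else detection$clusters
  if (is.null(events) || nrow(events) == 0) {
    return(list(sites = tibble(contig = character(), pos = integer(),
                               strand = character(), n_events = integer()),
                summary = tibble(n_sites = 0L, n_events = 0L,
                                 events_per_site = NA_real_)))
  }
  grp <- c("contig", "pos", "strand")
  sites <- events |>
    group_by(across(all_of(grp))) |>
    summarise(n_events = n(),
              conditions = if ("condition" %in% names(events))
                paste(sort(unique(.data$condition)), collapse = ",") else NA_character_,
              .groups = "drop") |>
    arrange(.data$contig, .data$pos)
  if (all(is.na(sites$conditions))) sites$conditions <- NULL
  summary <- tibble(
    n_sites = nrow(sites),
    n_events = nrow(events),
    events_per_site = nrow(events) / nrow(sites),
    mean_sites_per_cluster = if (!is.null(clusters) && nrow(clusters))
      mean(clusters$n_edits) else NA_real_,
    mean_cluster_length = if (!is.null(clusters) && nrow(clusters))
      mean(clusters$end - clusters$start + 1) else NA_real_)
  list(sites = sites, summary = summary)
}

#' Mismatch-type spectrum, strand split and read-position QC
#'
#' Runs transformed-realignment detection for all 12 ordered mismatch types
#' on the same pool. In clean data, A-to-G dominates the spectrum and its
#' sites split roughly 50/50 between strands, while artefact types
#' concentrate on one strand or at particular read positions.
#'
#' @inheritParams detect_hyper_edited_reads
#' @param ... Passed to [detect_hyper_edited_reads()].
#' @return List of tibbles: `spectrum` (type, n_sites, n_events, share of
#'   sites), `strand_split` (type, strand, n_sites, fraction), `read_pos`
#'   (type, read_pos, n_events).
#' @export
qc_mismatch_spectrum <- function(pool, gen, ...) {
  per_type <- map(setNames(MISMATCH_TYPES, MISMATCH_TYPES), function(ty) {
    det <- detect_hyper_edited_reads(pool, gen, mismatch_type = ty, ...)
    list(sites = collect_sites(det)$sites, events = det$events)
  })
  spectrum <- imap_dfr(per_type, function(x, ty)
    tibble(type = ty, n_sites = nrow(x$sites), n_events = nrow(x$events)))
  spectrum$share <- if (sum(spectrum$n_sites) > 0)
    spectrum$n_sites / sum(spectrum$n_sites) else NA_real_
  strand_split <- imap_dfr(per_type, function(x, ty) {
    if (nrow(x$sites) == 0) return(tibble(type = character(), strand = character(),
                                          n_sites = integer(), fraction = double()))
    x$sites |> count(strand, name = "n_sites") |>
      mutate(type = ty, fraction = .data$n_sites / sum(.data$n_sites)) |>
      select("type", "strand", "n_sites", "fraction")
  })
  read_pos <- imap_dfr(per_type, function(x, ty) {
    if (nrow(x$events) == 0) return(tibble(type = character(),
                                           read_pos = integer(), n_events = integer()))
    x$events |> count(.data$read_pos, name = "n_events") |> mutate(type = ty) |>
      select("type", "read_pos", "n_events")
  })
  list(spectrum = spectrum, strand_split = strand_split, read_pos = read_pos)
}

#' Position frequency matrix around editing sites
#'
#' Extracts `2 * flank + 1` bases centred on each site, oriented to the site
#' strand, and tabulates base frequencies per offset. Offset 0 is the edited
#' adenosine (frequency of A at offset 0 is 1 by construction). ADAR targets
#' show G depletion at offset -1 and G enrichment at +1.
#'
#' @param sites Tibble with contig, pos, strand.
#' @param gen A `thermedit_genome`.
#' @param flank Bases on each side (default 5).
#' @return Tibble: offset, A, C, G, T (row frequencies summing to 1), with
#'   attribute `n_skipped` counting sites whose flank exits the contig.
#' @export
compute_motif <- function(sites, gen, flank = 5) {
  if (nrow(sites) == 0) abort("compute_motif needs at least one site")
  lens <- genome_lengths(gen)[sites$contig]
  ok <- sites$pos - flank >= 1 & sites$pos + flank <= lens
  n_skipped <- sum(!ok)
  s <- sites[ok, ]
  if (nrow(s) == 0) abort("all sites have flanks outside their contig")
  win <- genome_subseq(gen, s$contig, s$pos - flank, s$pos + flank, s$strand)
  off <- seq(-flank, flank)
  mat <- map_dfr(seq_along(off), function(j) {
    b <- substring(win, j, j)
    tb <- table(factor(b, levels = c("A", "C", "G", "T")))
    tibble(offset = off[j], A = tb[["A"]], C = tb[["C"]],
           G = tb[["G"]], T = tb[["T"]])
  })
  tot <- rowSums(mat[, c("A", "C", "G", "T")])
  mat <- mat |> mutate(across(c("A", "C", "G", "T"), ~ .x / tot))
  attr(mat, "n_skipped") <- n_skipped
  attr(mat, "n_sites") <- nrow(s)
  mat
}
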