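# Conservation context: per-base score profiles around sites, stratified by
# event support, against a seeded random-adenosine background; overlap of
# sites with conserved-fold intervals.

#' Conservation profile around editing sites
#'
#' Means of a per-base conservation track at offsets `-window..window`
#' around each site (offsets follow the site strand), stratified into sites
#' supported by more than one event, sites supported by a single event, and
#' a seeded random-adenosine background of matched size.
#'
#' @param sites Tibble with contig, pos, strand and (for stratification)
#'   `n_events`; without it all sites form one stratum.
#' @param track Tibble from [read_track()] (contig, pos, score).
#' @param gen A `thermedit_genome` (for background adenosine sampling).
#' @param window Half-width of the profile, bases (default 20).
#' @param background_regions Optional tibble (contig, start, end) to sample
#'   background adenosines from (e.g. expressed gene bodies); default whole
#'   genome.
#' @param background_n Background size; default `nrow(sites)`.
#' @param seed Seed for background sampling.
#' @return Tibble: stratum, offset, mean_score, n (positions averaged);
#'   positions absent from the track are skipped and counted in attribute
#'   `n_missing`.
#' @export
conservation_profile <- function(sites, track, gen, window = 20,
                                 background_regions = NULL,
                                 background_n = NULL, seed = 1) {
  if (nrow(sites) == 0) abort("conservation_profile needs sites")
  stratum <- if ("n_events" %in% names(sites)) {
    ifelse(sites$n_events > 1, "support>1", "support==1")
  } else rep("sites", nrow(sites))
  bg_n <- background_n %||% nrow(sites)
  bg <- sample_background_adenosines(gen, bg_n, regions = background_regions,
                                     seed = seed)
  all_sites <- bind_rows(
    sites |> select("contig", "pos", "strand") |> mutate(stratum = stratum),
    bg |> mutate(stratum = "background"))
  prof <- crossing(all_sites, offset = seq(-window, window)) |>
    mutate(qpos = ifelse(.data$strand == "+", .data$pos + .data$offset,
                         .data$pos - .data$offset)) |>
    left_join(track, by = c("contig", "qpos" = "pos"))
  n_missing <- sum(is.na(prof$score))
  out <- prof |>
    filter(!is.na(.data$score)) |>
    group_by(.data$stratum, .data$offset) |>
    summarise(mean_score = mean(.data$score), n = n(), .groups = "drop")
  empty <- setdiff(unique(c("support>1", "support==1")[
    c("n_events" %in% names(sites), "n_events" %in% names(sites))]),
    unique(out$stratum))
  if (length(empty)) {
    inform(sprintf("empty stratum omitted: %s", paste(empty, collapse = ", ")))
  }
  attr(out, "n_missing") <- n_missing
  out
}

# sample n reference adenosines (A on +, T on + for minus-strand adenosines),
# uniformly from the given regions, deterministic given seed
sample_background_adenosines <- function(gen, n, regions = NULL, seed = 1) {
  contig <- names(gen)[1]
  seqchr <- unclass(gen)[[contig]]
  if (is.null(regions)) {
    regions <- tibble(contig = contig, start = 1L, end = nchar(seqchr))
  }
  withr::with_seed(as.integer(seed), {
    pos_a <- integer(0); pos_t <- integer(0)
    for (r in seq_len(nrow(regions))) {
      sub <- substr(seqchr, regions$start[r], regions$end[r])
      raw <- charToRaw(sub)
      pos_a <- c(pos_a, which(raw == charToRaw("A")) + regions$start[r] - 1L)
      pos_t <- c(pos_t, which(raw == charToRaw("T")) + regions$start[r] - 1L)
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    n_plus <- sum(strand == "+")
    if (length(pos_a) == 0 || length(pos_t) == 0) {
      abort("no adenosines available for background sampling")
    }
    tibble(contig = contig,
           pos = c(sample(pos_a, n_plus, replace = n_plus > length(pos_a)),
                   sample(pos_t, n - n_plus, replace = (n - n_plus) > length(pos_t))),
           strand = c(rep("+", n_plus), rep("-", n - n_plus)))
  })
}

#' Overlap of editing sites with conserved-fold intervals
#'
#' @param sites Tibble with contig, pos.
#' @param folds Tibble of intervals (contig, start, end; 1-based closed, as
#'   returned by [load_intervals()] on a BED file).
#' @return One-row tibble: n_sites, n_in_folds, percent (rounded to 2
#'   decimals).
#' @examples
#' sites <- tibble::tibble(contig = "c", pos = 1:100)
#' folds <- tibble::tibble(contig = "c", start = 1L, end = 10L)
#' evofold_overlap(sites, folds)  # 10.00 percent
#' @export
evofold_overlap <- function(sites, folds) {
  n <- nrow(sites)
  if (n == 0) return(tibble(n_sites = 0L, n_in_folds = 0L, percent = NA_real_))
  if (nrow(folds) == 0) {
    return(tibble(n_sites = n, n_in_folds = 0L, percent = 0))
  }
  sg <- GenomicRanges::GRanges(sites$contig, IRanges::IRanges(sites$pos, sites$pos))
  fg <- GenomicRanges::GRanges(folds$contig, IRanges::IRanges(folds$start, folds$end))
  inside <- GenomicRanges::countOverlaps(sg, fg) > 0
  tibble(n_sites = n, n_in_folds = sum(inside),
         percent = round(100 * sum(inside) / n, 2))
}
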