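# Inverted-repeat (dsRNA) context: 40-nt windows centred on edited sites are
# aligned against their +/- 2 kb flanks. The antisense search (flank
# reverse-complemented) finds sequence able to base-pair with the edited
# region; the sense search is the negative control. A blastn-like seeded
# local aligner (7-mer exact seeds, match +2, mismatch -3, affine gaps
# open 2 / extend 2) scores candidates; a match requires >= 70% identity
# over >= 70% of the window.

#' Extract a strand-oriented window centred on a site
#'
#' For even `width` the site sits left of centre, at oriented position
#' `width / 2`. Windows running off the contig are truncated and flagged.
#'
#' @param sites Tibble with contig, pos, strand.
#' @param gen A `thermedit_genome`.
#' @param width Window width, bases (default 40).
#' @return `sites` with added columns `window` (oriented sequence),
#'   `win_start`, `win_end` (plus-strand genomic bounds), `site_offset`
#'   (1-based position of the site inside the oriented window), `truncated`.
#' @export
extract_window <- function(sites, gen, width = 40) {
  k <- floor(width / 2)
  lens <- genome_lengths(gen)[sites$contig]
  ws <- ifelse(sites$strand == "+", sites$pos - k + 1L, sites$pos - (width - k))
  we <- ws + width - 1L
  trunc <- ws < 1L | we > lens
  ws_c <- pmax(ws, 1L)
  we_c <- pmin(we, as.integer(lens))
  win <- genome_subseq(gen, sites$contig, ws_c, we_c, sites$strand)
  off <- ifelse(sites$strand == "+", sites$pos - ws_c + 1L, we_c - sites$pos + 1L)
  sites |>
    mutate(window = win, win_start = as.integer(ws_c), win_end = as.integer(we_c),
           site_offset = as.integer(off), truncated = trunc)
}

# --- Gotoh local alignment, columns vectorised over the query -------------

# returns list(score, q_start, q_end, s_start, s_end, matches, cols,
# q_cols) for the best local alignment of q vs s; the DP loops over the
# (short) query and vectorises along the subject
sw_align <- function(q, s, match = 2, mismatch = -3, gap_open = 2,
                     gap_extend = 2) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  if (m == 0 || n == 0) return(list(score = 0))
  go <- gap_open; ge <- gap_extend
  H <- matrix(0, m + 1L, n + 1L)
  E <- matrix(-Inf, m + 1L, n + 1L)   # gap in query (subject consumed)
  F_ <- matrix(-Inf, m + 1L, n + 1L)  # gap in subject (query consumed)
  jv <- seq_len(n)
  for (i in seq_len(m)) {
    sub <- ifelse(sc == qc[i], match, mismatch)
    diag <- H[i, jv] + sub
    F_[i + 1L, jv + 1L] <- pmax(H[i, jv + 1L] - go - ge, F_[i, jv + 1L] - ge)
    G <- pmax(0, diag, F_[i + 1L, jv + 1L])
    run <- cummax(c(-Inf, G[-n] + ge * jv[-n]))
    E[i + 1L, jv + 1L] <- run - go - ge * jv
    H[i + 1L, jv + 1L] <- pmax(G, E[i + 1L, jv + 1L])
  }
  best <- which(H == max(H), arr.ind = TRUE)[1, ]
  score <- max(H)
  if (score <= 0) return(list(score = 0))
  # traceback
  i <- best[1] - 1L; j <- best[2] - 1L
  q_end <- i; s_end <- j
  matches <- 0L; cols <- 0L; q_cols <- 0L
  state <- "H"
  while (i > 0 || j > 0) {
    if (state == "H") {
      h <- H[i + 1L, j + 1L]
      if (h == 0) break
      sub <- if (i > 0 && j > 0 && qc[i] == sc[j]) match else mismatch
      if (i > 0 && j > 0 && h == H[i, j] + sub) {
        matches <- matches + (qc[i] == sc[j])
        cols <- cols + 1L; q_cols <- q_cols + 1L
        i <- i - 1L; j <- j - 1L
      } else if (h == E[i + 1L, j + 1L]) {
        state <- "E"
      } else if (h == F_[i + 1L, j + 1L]) {
        state <- "F"
      } else break
    } else if (state == "E") {
      cols <- cols + 1L
      if (j > 1L && E[i + 1L, j + 1L] == E[i + 1L, j] - ge) {
        j <- j - 1L
      } else {
        j <- j - 1L; state <- "H"
      }
    } else {                       # F: gap in subject, query consumed
      cols <- cols + 1L; q_cols <- q_cols + 1L
      if (i > 1L && F_[i + 1L, j + 1L] == F_[i, j + 1L] - ge) {
        i <- i - 1L
      } else {
        i <- i - 1L; state <- "H"
      }
    }
  }
  list(score = score, q_start = i + 1L, q_end = q_end,
       s_start = j + 1L, s_end = s_end,
       matches = matches, cols = cols, q_cols = q_cols)
}

# seeded best local alignment of `window` against `subject`; seeds are
# word_size-mer exact matches, each extended by sw_align on a padded segment
seeded_best_hsp <- function(window, subject, word_size = 7, score_floor = 14,
                            pad = NULL) {
  m <- nchar(window)
  n <- nchar(subject)
  if (m < word_size || n < word_size) return(NULL)
  pad <- pad %||% (2L * m + 10L)
  words <- unique(substring(window, seq_len(m - word_size + 1L),
                            seq_len(m - word_size + 1L) + word_size - 1L))
  words <- words[!grepl("[^ACGT]", words)]
  if (!length(words)) return(NULL)
  starts <- unlist(lapply(words, function(wd) {
    g <- gregexpr(wd, subject, fixed = TRUE)[[1]]
    if (g[1] == -1L) integer(0) else as.integer(g)
  }))
  starts <- sort(unique(starts))
  if (!length(starts)) return(NULL)
  # merge overlapping padded segments to avoid rescoring the same region
  seg_s <- pmax(1L, starts - pad)
  seg_e <- pmin(n, starts + word_size - 1L + pad)
  keep <- c(TRUE, seg_s[-1] > cummax(seg_e)[-length(seg_e)])
  grpid <- cumsum(keep)
  segs <- tibble(s = seg_s, e = seg_e, g = grpid) |>
    group_by(.data$g) |>
    summarise(s = min(.data$s), e = max(.data$e), .groups = "drop")
  best <- NULL
  for (r in seq_len(nrow(segs))) {
    al <- sw_align(window, substr(subject, segs$s[r], segs$e[r]))
    if (al$score > 0 && (is.null(best) || al$score > best$score)) {
      al$s_start <- al$s_start + segs$s[r] - 1L
      al$s_end <- al$s_end + segs$s[r] - 1L
      best <- al
    }
  }
  if (is.null(best) || best$score < score_floor) return(NULL)
  best
}

#' Search the flanks of edited windows for inverted complements
#'
#' For each site (or region midpoint), aligns the `width`-nt window against
#' the sequence within `flank` bases on either side, window excluded.
#' `antisense` mode aligns against the reverse complement of the same-strand
#' flank — a hit means the flank can base-pair with the edited region into a
#' dsRNA stem. `sense` mode aligns against the flank as-is and acts as the
#' random-expectation control. The `*-edited` modes first substitute G at
#' every known edited position inside the window (the sequencer-visible form
#' of inosine) and repeat the search.
#'
#' @param sites Tibble with contig, pos, strand; for the edited modes, all
#'   rows of `sites` falling inside a window are treated as edited positions
#'   of that window.
#' @param gen A `thermedit_genome`.
#' @param width Window width (default 40).
#' @param flank Flank length on each side, bases (default 2000).
#' @param modes Subset of `c("antisense", "sense", "antisense-edited",
#'   "sense-edited")`.
#' @param min_identity,min_coverage Match thresholds, percent (default 70/70).
#' @param word_size Seed word size (default 7).
#' @param score_floor Minimum raw HSP score (default 14, seven matched bases).
#' @return Tibble: one row per site x mode with identity, coverage
#'   (percent), score, matched, partner_start, partner_end (plus-strand
#'   genomic coordinates of the matched flank sequence; NA when unmatched),
#'   truncated.
#' @export
search_inverted_complement <- function(sites, gen, width = 40, flank = 2000,
                                       modes = c("antisense", "sense"),
                                       min_identity = 70, min_coverage = 70,
                                       word_size = 7, score_floor = 14) {
  modes <- match.arg(modes, c("antisense", "sense", "antisense-edited",
                              "sense-edited"), several.ok = TRUE)
  wins <- extract_window(sites, gen, width = width)
  lens <- genome_lengths(gen)
  out <- vector("list", nrow(wins) * length(modes))
  oi <- 0L
  for (k in seq_len(nrow(wins))) {
    w <- wins[k, ]
    Lc <- lens[[w$contig]]
    # plus-strand flank segments, window excluded
    lf_s <- max(1L, w$win_start - flank); lf_e <- w$win_start - 1L
    rf_s <- w$win_end + 1L; rf_e <- min(Lc, w$win_end + flank)
    segs <- list()
    if (lf_e >= lf_s) segs$left <- c(lf_s, lf_e)
    if (rf_e >= rf_s) segs$right <- c(rf_s, rf_e)
    win_seq <- w$window
    # edited form: G at every known edited position inside the window
    ed_seq <- win_seq
    in_win <- sites$contig == w$contig & sites$pos >= w$win_start &
      sites$pos <= w$win_end & sites$strand == w$strand
    if (any(in_win)) {
      p <- sites$pos[in_win]
      offw <- if (w$strand == "+") p - w$win_start + 1L else w$win_end - p + 1L
      ed_seq <- str_replace_at_many(ed_seq, offw, "G")
    }
    for (mode in modes) {
      oi <- oi + 1L
      qry <- if (grepl("edited", mode)) ed_seq else win_seq
      anti <- grepl("antisense", mode)
      best <- NULL; best_seg <- NULL
      for (sg in names(segs)) {
        b <- segs[[sg]]
        subj <- genome_subseq(gen, w$contig, b[1], b[2], w$strand)
        if (anti) subj <- revcomp(subj)
        hsp <- seeded_best_hsp(qry, subj, word_size = word_size,
                               score_floor = score_floor)
        if (!is.null(hsp) && (is.null(best) || hsp$score > best$score)) {
          best <- hsp; best_seg <- b
          best$oriented_rc <- anti
          best$seg_len <- b[2] - b[1] + 1L
        }
      }
      row <- tibble(contig = w$contig, pos = w$pos, strand = w$strand,
                    mode = mode, identity = NA_real_, coverage = NA_real_,
                    score = NA_real_, matched = FALSE,
                    partner_start = NA_integer_, partner_end = NA_integer_,
                    truncated = w$truncated)
      if (!is.null(best)) {
        identity <- 100 * best$matches / best$cols
        coverage <- 100 * best$q_cols / width
        # map subject coordinates back to plus-strand genomic positions
        ss <- best$s_start; se <- best$s_end
        if (best$oriented_rc) { tmp <- ss; ss <- best$seg_len - se + 1L
                                se <- best$seg_len - tmp + 1L }
        if (w$strand == "-") { tmp <- ss; ss <- best$seg_len - se + 1L
                               se <- best$seg_len - tmp + 1L }
        row$identity <- identity
        row$coverage <- coverage
        row$score <- best$score
        row$matched <- identity >= min_identity & coverage >= min_coverage
        row$partner_start <- as.integer(best_seg[1] + ss - 1L)
        row$partner_end <- as.integer(best_seg[1] + se - 1L)
      }
      out[[oi]] <- row
    }
  }
  bind_rows(out)
}

#' Fraction of sites with a structure match, per mode
#'
#' @param matches Tibble from [search_inverted_complement()] (optionally with
#'   a `condition` column).
#' @return Tibble of counts and matched fractions per mode (x condition),
#'   plus the antisense-minus-sense excess as attribute `antisense_excess`.
#' @export
structure_summary <- function(matches) {
  grp <- intersect(c("condition", "mode"), names(matches))
  out <- matches |>
    group_by(across(all_of(grp))) |>
    summarise(n = n(), n_matched = sum(.data$matched),
              fraction_matched = mean(.data$matched), .groups = "drop")
  wide <- out |> filter(.data$mode %in% c("antisense", "sense"))
  if (nrow(wide) > 0 && all(c("antisense", "sense") %in% wide$mode)) {
    anti <- wide$fraction_matched[wide$mode == "antisense"]
    sens <- wide$fraction_matched[wide$mode == "sense"]
    attr(out, "antisense_excess") <- mean(anti) - mean(sens)
  }
  out
}
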