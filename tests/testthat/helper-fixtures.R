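# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small planted study used across modules: 50 kb, 10 clusters, two regimes
small_study <- function() {
  cached("small_study", function() {
    cfg <- sim_config(genome_length = 5e4, n_genes = 10, n_clusters = 10,
                      sites_per_cluster = c(6L, 8L),
                      per_site_edit_rate = c(T18 = 0.8, T29 = 0.2),
                      ir_fraction = 0.5, coverage = 30, seed = 101)
    gg <- generate_genome(cfg)
    pl <- plant_editing_clusters(gg, cfg)
    sim <- simulate_reads(pl$genome, pl$truth, "T18", cfg)
    aln <- align_reads(sim$reads, pl$genome)
    pool <- unaligned_pool(aln, sim$reads)
    det <- detect_hyper_edited_reads(pool, pl$genome)
    list(cfg = cfg, genes = gg$genes, genome = pl$genome,
         truth = pl$truth, sim = sim, aln = aln, pool = pool, det = det)
  })
}

# random genome string with a fixed seed (plain character)
random_seq <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# full-enumeration Smith-Waterman with traceback (independent oracle for the
# seeded aligner): plain Gotoh DP, cell by cell
sw_oracle <- function(q, s, match = 2, mismatch = -3, go = 2, ge = 2) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F_ <- matrix(-Inf, m + 1, n + 1)
  for (i in 1:m) for (j in 1:n) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - go - ge, E[i + 1, j] - ge)
    F_[i + 1, j + 1] <- max(H[i, j + 1] - go - ge, F_[i, j + 1] - ge)
    sub <- if (qc[i] == sc[j]) match else mismatch
    H[i + 1, j + 1] <- max(0, H[i, j] + sub, E[i + 1, j + 1], F_[i + 1, j + 1])
  }
  score <- max(H)
  # traceback to find the longest run of consecutive diagonal matches
  best <- which(H == score, arr.ind = TRUE)[1, ]
  i <- best[1] - 1; j <- best[2] - 1
  run <- 0; best_run <- 0
  while (i > 0 && j > 0 && H[i + 1, j + 1] > 0) {
    sub <- if (qc[i] == sc[j]) match else mismatch
    if (H[i + 1, j + 1] == H[i, j] + sub) {
      run <- if (qc[i] == sc[j]) run + 1 else 0
      best_run <- max(best_run, run)
      i <- i - 1; j <- j - 1
    } else if (H[i + 1, j + 1] == E[i + 1, j + 1]) {
      run <- 0
      while (j > 1 && E[i + 1, j + 1] == E[i + 1, j] - ge) j <- j - 1
      j <- j - 1
    } else if (H[i + 1, j + 1] == F_[i + 1, j + 1]) {
      run <- 0
      while (i > 1 && F_[i + 1, j + 1] == F_[i, j + 1] - ge) i <- i - 1
      i <- i - 1
    } else break
  }
  list(score = score, longest_match_run = best_run)
}

# brute-force hyper-editing scanner (independent oracle for detection):
# enumerates every placement of every pool read at every offset in both
# plus-space transforms, picks the unique best, applies the cluster rules
brute_force_clusters <- function(pool, gen, quality_min = 30, min_edits = 4,
                                 end_exclusion = 6, max_mm_per_100 = 4) {
  contig <- names(gen)[1]
  gchr <- unclass(gen)[[contig]]
  Lg <- nchar(gchr)
  out <- list()
  for (r in seq_len(nrow(pool))) {
    rl <- nchar(pool$seq[r])
    budget <- max(1, round(max_mm_per_100 * rl / 100))
    span_min <- ceiling(0.10 * rl)
    streams <- list(
      list(ori = pool$seq[r], gt = chartr("A", "G", gchr),
           rt = chartr("A", "G", pool$seq[r]), strand = "+",
           want_ref = "A", want_alt = "G"),
      list(ori = revcomp(pool$seq[r]), gt = chartr("T", "C", gchr),
           rt = chartr("T", "C", revcomp(pool$seq[r])), strand = "-",
           want_ref = "T", want_alt = "C"))
    hits <- list()
    for (st in streams) {
      starts <- seq_len(Lg - rl + 1)
      graw <- charToRaw(st$gt)
      rraw <- charToRaw(st$rt)
      mm <- vapply(starts, function(p)
        sum(graw[p:(p + rl - 1)] != rraw), numeric(1))
      for (p in starts[mm <= budget]) {
        hits[[length(hits) + 1]] <- list(start = p, mm = mm[p], st = st)
      }
    }
    if (!length(hits)) next
    mms <- vapply(hits, `[[`, numeric(1), "mm")
    if (sum(mms == min(mms)) != 1) next   # ambiguous: dropped
    h <- hits[[which.min(mms)]]
    ref <- substr(gchr, h$start, h$start + rl - 1)
    pos <- which(strsplit(h$st$ori, "")[[1]] != strsplit(ref, "")[[1]])
    refb <- substring(ref, pos, pos)
    altb <- substring(h$st$ori, pos, pos)
    qv <- utf8ToInt(pool$qual[r]) - 33
    keep <- refb == h$st$want_ref & altb == h$st$want_alt &
      qv[pos] >= quality_min & pos > end_exclusion & pos <= rl - end_exclusion
    kp <- pos[keep]
    if (length(kp) < min_edits) next
    if (kp[length(kp)] - kp[1] + 1 < span_min) next
    out[[length(out) + 1]] <- tibble::tibble(
      read_id = pool$read_id[r], contig = contig,
      start = h$start + kp[1] - 1, end = h$start + kp[length(kp)] - 1,
      strand = h$st$strand, n_edits = length(kp), read_length = rl)
  }
  dplyr::bind_rows(out)
}

# closed-form BH step-up (oracle for bh_fdr)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# build a pileup-style count table directly from binomial draws
binom_pileups <- function(n_sites, cov, p_a, p_b, seed,
                          conds = c("A", "B")) {
  withr::with_seed(seed, {
    ga <- rbinom(n_sites, cov, p_a)
    gb <- rbinom(n_sites, cov, p_b)
    dplyr::bind_rows(
      tibble::tibble(contig = "c", pos = seq_len(n_sites), strand = "+",
                     sample = "s1", condition = conds[1],
                     g_count = ga, a_count = cov - ga),
      tibble::tibble(contig = "c", pos = seq_len(n_sites), strand = "+",
                     sample = "s1", condition = conds[2],
                     g_count = gb, a_count = cov - gb))
  })
}
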