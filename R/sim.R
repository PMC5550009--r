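# Synthetic-data generator: random annotated genome, planted editing clusters
# with ADAR-like context, strand-balanced reads with per-condition edit rates.

# replace single characters at position `at` (vectorised over x/at)
str_replace_at <- function(x, at, value) {
  paste0(substr(x, 1L, at - 1L), value, substr(x, at + 1L, nchar(x)))
}

#' Generate a random annotated genome
#'
#' Draws a uniform-composition A/C/G/T genome and tiles `n_genes` genes onto
#' it, each with exons, introns and terminal UTRs, covering
#' `genic_fraction` of the sequence. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (a `thermedit_genome`, single contig
#'   `"chrS1"`) and `genes` (tibble: contig, feature, start, end, strand,
#'   gene_id, transcript_id; features are exon, CDS, five_prime_utr,
#'   three_prime_utr).
#' @examples
#' gg <- generate_genome(sim_config(genome_length = 2e4, n_genes = 4, seed = 1))
#' genome_lengths(gg$genome)
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed <- derive_seeds(config$seed, 2)[1]
  L <- config$genome_length
  withr::with_seed(seed, {
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    genes <- sim_gene_model(L, config$n_genes, config$genic_fraction)
  })
  list(genome = genome(c(chrS1 = seq)), genes = genes)
}

sim_gene_model <- function(L, n_genes, genic_fraction) {
  if (n_genes < 1) return(tibble(
    contig = character(), feature = character(), start = integer(),
    end = integer(), strand = character(), gene_id = character(),
    transcript_id = character()))
  slot <- floor(L / n_genes)
  glen <- max(800L, floor(slot * genic_fraction))
  glen <- min(glen, slot - 100L)
  pad <- floor((slot - glen) / 2)
  rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    gs <- (i - 1L) * slot + pad + 1L
    ge <- gs + glen - 1L
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("g%03d", i)
    tid <- sprintf("t%03d", i)
    n_ex <- sample(2:4, 1L)
    ex_len <- sample(150:400, n_ex, replace = TRUE)
    intron_total <- glen - sum(ex_len)
    if (intron_total < 50L * (n_ex - 1L)) {        # shrink exons to fit
      ex_len <- rep(150L, n_ex)
      intron_total <- glen - sum(ex_len)
    }
    cuts <- if (n_ex > 2L) sort(sample.int(intron_total - 1L, n_ex - 2L)) else integer(0)
    in_len <- if (n_ex > 1L) pmax(diff(c(0L, cuts, intron_total)), 1L) else integer(0)
    ex_start <- gs + cumsum(c(0L, ex_len[-n_ex] + in_len))
    ex_end <- ex_start + ex_len - 1L
    ex_end[n_ex] <- ge                              # last exon absorbs rounding
    ex_len[n_ex] <- ex_end[n_ex] - ex_start[n_ex] + 1L
    # transcription order
    ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    u5 <- min(100L, floor(ex_len[ord[1]] / 2))
    u3 <- min(150L, floor(ex_len[ord[n_ex]] / 2))
    feat <- list(tibble(feature = "exon", start = ex_start, end = ex_end))
    for (j in seq_len(n_ex)) {
      s <- ex_start[j]; e <- ex_end[j]
      is_first <- j == ord[1]; is_last <- j == ord[n_ex]
      cds_s <- s; cds_e <- e
      if (is_first) {
        if (strand == "+") { feat <- c(feat, list(tibble(feature = "five_prime_utr", start = s, end = s + u5 - 1L))); cds_s <- s + u5 }
        else { feat <- c(feat, list(tibble(feature = "five_prime_utr", start = e - u5 + 1L, end = e))); cds_e <- e - u5 }
      }
      if (is_last) {
        if (strand == "+") { feat <- c(feat, list(tibble(feature = "three_prime_utr", start = e - u3 + 1L, end = e))); cds_e <- e - u3 }
        else { feat <- c(feat, list(tibble(feature = "three_prime_utr", start = s, end = s + u3 - 1L))); cds_s <- s + u3 }
      }
      if (cds_e >= cds_s) feat <- c(feat, list(tibble(feature = "CDS", start = cds_s, end = cds_e)))
    }
    rows[[i]] <- bind_rows(feat) |>
      mutate(contig = "chrS1", strand = strand, gene_id = gid, transcript_id = tid)
  }
  bind_rows(rows) |>
    select("contig", "feature", "start", "end", "strand", "gene_id", "transcript_id") |>
    arrange(.data$start, .data$feature)
}

#' Plant clustered editing sites (with ADAR-like context) into a genome
#'
#' Places `n_clusters` non-overlapping clusters of adenosines inside gene
#' bodies (cluster strand = host-gene strand, so site strands are balanced),
#' spreads each cluster's sites over `cluster_span` bases (at least 10
#' percent of the read length), writes the ADAR-like context around every
#' site (G at -1 with probability `motif_bias["g_minus1"]`, G at +1 with
#' `motif_bias["g_plus1"]`, other bases uniform), and for `ir_fraction` of
#' clusters copies the reverse complement of the `ir_length`-nt cluster core
#' to a position within `ir_max_distance`, creating a perfect inverted
#' repeat. Because the planted bases are written into the returned genome,
#' every truth site is a reference adenosine on its strand by construction.
#'
#' @param genome_obj Output of [generate_genome()] (list with `genome` and
#'   `genes`), or a bare `thermedit_genome` (then clusters are placed
#'   uniformly with random strand).
#' @param config A [sim_config()].
#' @return A list with `genome` (the updated `thermedit_genome`) and `truth`,
#'   itself a list of tibbles: `sites` (contig, pos, strand, cluster_id, one
#'   `rate_<condition>` column per condition), `clusters` (contig, start,
#'   end, strand, cluster_id, n_sites), `inverted_repeats` (contig, start,
#'   end, partner_start, partner_end, strand, cluster_id).
#' @export
plant_editing_clusters <- function(genome_obj, config) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(genome_obj, "thermedit_genome")) {
    gen <- genome_obj; genes <- NULL
  } else {
    gen <- genome_obj$genome; genes <- genome_obj$genes
  }
  contig <- names(gen)[1]
  seq <- unclass(gen)[[contig]]
  L <- nchar(seq)
  rl <- config$read_length
  w <- config$cluster_span
  seed <- derive_seeds(config$seed, 2)[2]

  withr::with_seed(seed, {
    # candidate gene bodies (plus margin checks)
    if (!is.null(genes) && nrow(genes) > 0) {
      bodies <- genes |>
        group_by(.data$gene_id) |>
        summarise(start = min(.data$start), end = max(.data$end),
                  strand = first(.data$strand), .groups = "drop")
    } else {
      bodies <- tibble(gene_id = "none", start = rl + 10L, end = L - rl - 10L,
                       strand = NA_character_)
    }
    bodies <- bodies |> filter(.data$end - .data$start + 1 >= w + 20)

    sep <- rl + 40L   # keep clusters from sharing reads or merged regions
    # exactly balanced cluster strands (the strand split the QC stage
    # expects); each cluster is hosted by a gene of its strand when one
    # exists, so site strand and transcript strand agree
    want_strand <- sample(rep(c("+", "-"), length.out = config$n_clusters))
    starts <- integer(0); strands <- character(0)
    tries <- 0L; max_tries <- 500L * config$n_clusters
    while (length(starts) < config$n_clusters && tries < max_tries) {
      tries <- tries + 1L
      target <- want_strand[length(starts) + 1L]
      eligible <- if (any(!is.na(bodies$strand) & bodies$strand == target)) {
        bodies[!is.na(bodies$strand) & bodies$strand == target, ]
      } else bodies
      b <- eligible[sample.int(nrow(eligible), 1L), ]
      lo <- max(b$start, rl + 10L)
      hi <- min(b$end - w + 1L, L - rl - w - 10L)
      if (hi <= lo) next
      ws <- sample_range(lo, hi)
      if (all(abs(ws - starts) >= w + sep)) {
        starts <- c(starts, ws)
        strands <- c(strands, target)
      }
    }
    if (length(starts) < config$n_clusters) {
      abort(sprintf(paste0(
        "could not place %d non-overlapping clusters of span %d separated by ",
        ">= %d bases in %d bp of eligible gene territory"),
        config$n_clusters, w, sep, sum(bodies$end - bodies$start + 1)))
    }
    ord <- order(starts); starts <- starts[ord]; strands <- strands[ord]

    sites_list <- vector("list", length(starts))
    writes_pos <- vector("list", length(starts))
    writes_base <- vector("list", length(starts))
    for (ci in seq_along(starts)) {
      ws <- starts[ci]
      n_s <- sample_range(config$sites_per_cluster[1], config$sites_per_cluster[2])
      n_s <- min(n_s, (w - 1L) %/% 3L + 1L)
      if (n_s >= 2L) {
        # first site at the window start, last at its end (span = w), the
        # rest at random positions with a minimum gap of 3 so site contexts
        # never overlap
        extra <- (w - 1L) - 3L * (n_s - 1L)
        gaps <- 3L + as.integer(stats::rmultinom(1L, extra,
                                                 rep(1, n_s - 1L))[, 1])
        pos <- ws + cumsum(c(0L, gaps))
      } else {
        pos <- ws
      }
      st <- strands[ci]
      n_s <- length(pos)
      # write the edited adenosine and its biased context on the site strand
      site_base <- if (st == "+") "A" else "T"
      up <- if (st == "+") pos - 1L else pos + 1L     # -1 on site strand
      dn <- if (st == "+") pos + 1L else pos - 1L     # +1 on site strand
      up_g <- runif(n_s) < config$motif_bias[["g_minus1"]]
      dn_g <- runif(n_s) < config$motif_bias[["g_plus1"]]
      up_base <- ifelse(up_g, "G", sample(c("A", "C", "T"), n_s, replace = TRUE))
      dn_base <- ifelse(dn_g, "G", sample(c("A", "C", "T"), n_s, replace = TRUE))
      if (st == "-") { up_base <- complement_base(up_base); dn_base <- complement_base(dn_base) }
      writes_pos[[ci]] <- c(pos, up, dn)
      writes_base[[ci]] <- c(rep(site_base, n_s), up_base, dn_base)
      sites_list[[ci]] <- tibble(contig = contig, pos = pos, strand = st,
                                 cluster_id = sprintf("c%04d", ci))
    }
    raw <- charToRaw(seq)
    raw[unlist(writes_pos)] <- charToRaw(paste(unlist(writes_base), collapse = ""))
    seq <- rawToChar(raw)
    sites <- bind_rows(sites_list)
    for (cond in config$condition_labels) {
      sites[[paste0("rate_", cond)]] <- unname(config$per_site_edit_rate[[cond]])
    }
    clusters <- sites |>
      group_by(.data$cluster_id) |>
      summarise(contig = first(.data$contig), start = min(.data$pos),
                end = max(.data$pos), strand = first(.data$strand),
                n_sites = n(), .groups = "drop") |>
      select("contig", "start", "end", "strand", "cluster_id", "n_sites")

    # inverted repeats: copy the reverse complement of the cluster core nearby
    n_ir <- round(config$ir_fraction * nrow(clusters))
    irs <- tibble(contig = character(), start = integer(), end = integer(),
                  partner_start = integer(), partner_end = integer(),
                  strand = character(), cluster_id = character())
    if (n_ir > 0) {
      ir_cl <- sort(sample.int(nrow(clusters), n_ir))
      keepout_s <- starts - rl - 20L
      keepout_e <- starts + w + rl + 20L
      placed_s <- integer(0); placed_e <- integer(0)
      half <- floor(config$ir_length / 2)
      for (ci in ir_cl) {
        mid <- floor((clusters$start[ci] + clusters$end[ci]) / 2)
        core_s <- mid - half + 1L
        core_e <- core_s + config$ir_length - 1L
        ok <- FALSE
        for (try in 1:200) {
          d <- sample_range(200L, config$ir_max_distance - config$ir_length)
          dir <- sample(c(-1L, 1L), 1L)
          ps <- if (dir > 0) core_e + d else core_s - d - config$ir_length
          pe <- ps + config$ir_length - 1L
          if (ps < 1L || pe > L) next
          if (any(ps <= keepout_e & pe >= keepout_s)) next
          if (length(placed_s) && any(ps <= placed_e + 10L & pe >= placed_s - 10L)) next
          ok <- TRUE; break
        }
        if (!ok) {
          abort(sprintf(
            "could not place inverted-repeat partner for cluster %s within %d bases",
            clusters$cluster_id[ci], config$ir_max_distance))
        }
        core <- substr(seq, core_s, core_e)
        seq <- paste0(substr(seq, 1L, ps - 1L), revcomp(core),
                      substr(seq, pe + 1L, L))
        placed_s <- c(placed_s, ps); placed_e <- c(placed_e, pe)
        irs <- bind_rows(irs, tibble(
          contig = contig, start = core_s, end = core_e,
          partner_start = ps, partner_end = pe,
          strand = clusters$strand[ci], cluster_id = clusters$cluster_id[ci]))
      }
    }
  })
  out_gen <- unclass(gen); out_gen[[contig]] <- seq
  list(genome = genome(out_gen),
       truth = list(sites = sites, clusters = clusters, inverted_repeats = irs))
}

# replace bases at several positions of one long string
str_replace_at_many <- function(seq, pos, base) {
  base <- rep_len(base, length(pos))
  for (k in seq_along(pos)) {
    substr(seq, pos[k], pos[k]) <- base[k]
  }
  seq
}

#' Simulate strand-balanced reads with planted editing and uniform error
#'
#' Samples read start positions uniformly and assigns each read to the plus
#' or minus strand with probability 1/2, emulating a strand-specific
#' library: reads overlapping a planted cluster carry the cluster
#' (transcript) strand, and since clusters are strand-balanced so are the
#' reads. Each overlapped truth site is converted A->G (on the site strand)
#' with its per-condition rate, then independent uniform sequencing errors
#' and constant Phred qualities are applied.
#'
#' @param gen A `thermedit_genome` (the planted genome).
#' @param truth Truth list from [plant_editing_clusters()].
#' @param condition One of the configured condition labels.
#' @param config A [sim_config()].
#' @param n_reads Number of reads; default `coverage * genome_length /
#'   read_length`, rounded.
#' @return A list with `reads` (tibble: read_id, seq, qual, contig, start,
#'   strand — the true origin of each read) and `read_edits` (tibble:
#'   read_id, contig, pos, strand — every editing event actually written
#'   into a read).
#' @export
simulate_reads <- function(gen, truth, condition, config, n_reads = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!condition %in% config$condition_labels) {
    abort(sprintf("unknown condition label '%s' (have: %s)", condition,
                  paste(config$condition_labels, collapse = ", ")))
  }
  if (config$coverage <= 0) abort("coverage must be positive")
  contig <- names(gen)[1]
  seq <- unclass(gen)[[contig]]
  L <- nchar(seq)
  rl <- config$read_length
  n_reads <- n_reads %||% round(config$coverage * L / rl)
  cond_idx <- match(condition, config$condition_labels)
  seed <- derive_seeds(config$seed, 2L + length(config$condition_labels))[2L + cond_idx]

  withr::with_seed(seed, {
    starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    # stranded library: a read drawn from an edited transcript carries that
    # transcript's strand, so reads overlapping a planted cluster adopt the
    # cluster strand (clusters themselves are strand-balanced)
    if (!is.null(truth$clusters) && nrow(truth$clusters) > 0) {
      ordr0 <- order(starts)
      ss0 <- starts[ordr0]
      for (k in seq_len(nrow(truth$clusters))) {
        i1 <- findInterval(truth$clusters$start[k] - rl, ss0) + 1L
        i2 <- findInterval(truth$clusters$end[k], ss0)
        if (i2 >= i1) strand[ordr0[i1:i2]] <- truth$clusters$strand[k]
      }
    }
    frags <- substring(seq, starts, starts + rl - 1L)

    # planted edits, plus-space, before orientation
    edits_read <- integer(0); edits_pos <- integer(0); edits_strand <- character(0)
    sites <- truth$sites
    if (!is.null(sites) && nrow(sites) > 0) {
      rate_col <- paste0("rate_", condition)
      ordr <- order(starts)
      ss <- starts[ordr]
      for (k in seq_len(nrow(sites))) {
        p <- sites$pos[k]
        i1 <- findInterval(p - rl, ss) + 1L
        i2 <- findInterval(p, ss)
        if (i2 < i1) next
        cover <- ordr[i1:i2]
        hit <- cover[runif(length(cover)) < sites[[rate_col]][k]]
        if (!length(hit)) next
        off <- p - starts[hit] + 1L
        new_base <- if (sites$strand[k] == "+") "G" else "C"
        frags[hit] <- str_replace_at(frags[hit], off, new_base)
        edits_read <- c(edits_read, hit)
        edits_pos <- c(edits_pos, rep(p, length(hit)))
        edits_strand <- c(edits_strand, rep(sites$strand[k], length(hit)))
      }
    }

    neg <- strand == "-"
    if (any(neg)) frags[neg] <- revcomp(frags[neg])

    # uniform sequencing errors in read space
    n_err <- rbinom(1L, n_reads * rl, config$seq_error_rate)
    if (n_err > 0) {
      er <- sample.int(n_reads, n_err, replace = TRUE)
      ep <- sample.int(rl, n_err, replace = TRUE)
      dup <- duplicated(paste(er, ep))
      er <- er[!dup]; ep <- ep[!dup]
      while (length(er)) {
        first <- !duplicated(er)
        i <- er[first]; p <- ep[first]
        cur <- substring(frags[i], p, p)
        alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                      nrow = 3, dimnames = list(NULL, c("A","C","G","T")))
        new <- alt[cbind(sample.int(3L, length(i), replace = TRUE), match(cur, colnames(alt)))]
        frags[i] <- str_replace_at(frags[i], p, new)
        er <- er[!first]; ep <- ep[!first]
      }
    }
  })

  ids <- sprintf("%s_r%07d", condition, seq_len(n_reads))
  reads <- tibble(read_id = ids, seq = frags,
                  qual = strrep(rawToChar(as.raw(config$phred + 33L)), rl),
                  contig = contig, start = starts, strand = strand)
  read_edits <- tibble(read_id = ids[edits_read], contig = contig,
                       pos = edits_pos, strand = edits_strand)
  list(reads = reads, read_edits = read_edits)
}
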