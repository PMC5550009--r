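test_that("base transformation replaces every occurrence and only that base", {
  expect_identical(transform_bases("GATTACA", "A", "G"), "GGTTGCG")
  expect_identical(transform_bases("CCGGTT", "A", "G"), "CCGGTT")
  out <- transform_bases(c("AAAA", "ACGT"), "A", "G")
  expect_false(any(grepl("A", out)))
  expect_equal(nchar(out), c(4L, 4L))
  expect_error(transform_bases("ACGT", "A", "A"), "differ")
  expect_error(transform_bases("ACGT", "A", "X"), "bases")
})

# build one synthetic pool read carrying chosen plus-space A->G edits
pooled_read <- function(g, start, edit_offsets, rl = 100, qual = "I") {
  frag <- genome_subseq(g, names(genome_lengths(g))[1], start, start + rl - 1)
  for (o in edit_offsets) {
    if (substring(frag, o, o) != "A") stop("offset is not an A")
    substr(frag, o, o) <- "G"
  }
  tibble::tibble(read_id = "p1", seq = frag, qual = strrep(qual, rl))
}

a_offsets <- function(g, start, rl = 100) {
  frag <- genome_subseq(g, names(genome_lengths(g))[1], start, start + rl - 1)
  which(strsplit(frag, "")[[1]] == "A")
}

test_that("a dense edited read yields one cluster with all its events", {
  g <- genome(c(chrA = random_seq(6000, seed = 21)))
  offs <- a_offsets(g, 2001)
  pick <- offs[offs >= 30 & offs <= 64][1:6]    # 6 edits within 35 nt
  expect_equal(length(pick), 6L)
  pool <- pooled_read(g, 2001, pick)
  det <- detect_hyper_edited_reads(pool, g)
  expect_equal(nrow(det$clusters), 1L)
  expect_equal(det$clusters$n_edits, 6L)
  expect_equal(nrow(det$events), 6L)
  expect_equal(sort(det$events$pos), 2000L + pick)
  expect_true(all(det$events$strand == "+"))
})

test_that("edits confined to a read end are excluded by the end rule", {
  g <- genome(c(chrA = random_seq(6000, seed = 22)))
  offs <- a_offsets(g, 3001)
  pick <- offs[offs >= 96]                       # only in the last 5 nt
  pool <- pooled_read(g, 3001, pick)
  det <- detect_hyper_edited_reads(pool, g, end_exclusion = 6)
  expect_equal(nrow(det$clusters), 0L)
})

test_that("a narrow two-edit run fails the 10% span rule", {
  g <- genome(c(chrA = random_seq(6000, seed = 23)))
  offs <- a_offsets(g, 1001)
  mid <- offs[offs >= 20 & offs <= 80]
  close_pair <- which(diff(mid) <= 4)[1]         # two As within 4 nt
  pick <- mid[close_pair + 0:1]
  expect_lte(diff(pick), 4)
  pool <- pooled_read(g, 1001, pick)
  det <- detect_hyper_edited_reads(pool, g, min_edits = 2)
  expect_equal(nrow(det$clusters), 0L)
  # the same number of edits spread over >= 10 nt passes
  pick2 <- c(mid[1], mid[mid >= mid[1] + 10][1])
  pool2 <- pooled_read(g, 1001, pick2)
  det2 <- detect_hyper_edited_reads(pool2, g, min_edits = 2)
  expect_equal(nrow(det2$clusters), 1L)
})

test_that("low-quality mismatches do not count as events", {
  g <- genome(c(chrA = random_seq(6000, seed = 24)))
  offs <- a_offsets(g, 2501)
  pick <- offs[offs >= 20 & offs <= 80][1:5]
  pool <- pooled_read(g, 2501, pick, qual = "5")  # Phred 20 < 30
  det <- detect_hyper_edited_reads(pool, g, quality_min = 30)
  expect_equal(nrow(det$clusters), 0L)
})

test_that("minus-strand editing is reported as A-to-G on the minus strand", {
  g <- genome(c(chrA = random_seq(6000, seed = 25)))
  frag <- genome_subseq(g, "chrA", 4001, 4100)
  t_offs <- which(strsplit(frag, "")[[1]] == "T")
  pick <- t_offs[t_offs >= 20 & t_offs <= 80][1:5]  # T->C in plus space
  for (o in pick) substr(frag, o, o) <- "C"
  pool <- tibble::tibble(read_id = "m1", seq = revcomp(frag),
                         qual = strrep("I", 100))
  det <- detect_hyper_edited_reads(pool, g)
  expect_equal(nrow(det$clusters), 1L)
  expect_true(all(det$events$strand == "-"))
  expect_equal(sort(det$events$pos), 4000L + pick)
  base <- genome_subseq(g, "chrA", det$events$pos, det$events$pos, "-")
  expect_true(all(base == "A"))
})

test_that("cluster merge respects the 20-base gap boundary", {
  mk <- function(s1, e1, s2, e2) tibble::tibble(
    read_id = c("a", "b"), contig = "c", start = c(s1, s2), end = c(e1, e2),
    strand = "+", n_edits = c(4L, 5L), read_length = 100L)
  r <- merge_clusters_to_regions(mk(100, 140, 150, 180))   # gap 9
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(100, 180))
  expect_equal(r$n_events, 9L)
  r20 <- merge_clusters_to_regions(mk(100, 140, 161, 180))  # gap exactly 20
  expect_equal(nrow(r20), 1L)
  r21 <- merge_clusters_to_regions(mk(100, 140, 162, 180))  # gap 21
  expect_equal(nrow(r21), 2L)
  one <- merge_clusters_to_regions(mk(100, 140, 150, 180)[1, ])
  expect_equal(c(one$start, one$end, one$n_clusters), c(100, 140, 1))
  # opposite strands never merge
  two <- mk(100, 140, 150, 180)
  two$strand <- c("+", "-")
  expect_equal(nrow(merge_clusters_to_regions(two)), 2L)
  expect_equal(nrow(merge_clusters_to_regions(two[0, ])), 0L)
})

test_that("site collection counts events per unique site", {
  ev <- tibble::tibble(read_id = c("a", "b"), contig = "c",
                       pos = c(50L, 50L), read_pos = c(10L, 40L),
                       ref = "A", alt = "G", qual = 40L, strand = "+")
  cs <- collect_sites(ev)
  expect_equal(nrow(cs$sites), 1L)
  expect_equal(cs$sites$n_events, 2L)
  expect_equal(cs$summary$events_per_site, 2)
  ten <- tibble::tibble(read_id = "a", contig = "c", pos = 1:10 * 10L,
                        read_pos = 1:10, ref = "A", alt = "G", qual = 40L,
                        strand = "+")
  expect_equal(collect_sites(ten)$summary$events_per_site, 1)
})

test_that("detection matches the brute-force oracle on a small genome", {
  cfg <- sim_config(genome_length = 1e4, n_genes = 3, n_clusters = 3,
                    sites_per_cluster = c(6L, 8L),
                    per_site_edit_rate = c(hot = 0.8),
                    seq_error_rate = 0.002, coverage = 20, seed = 26)
  pl <- plant_editing_clusters(generate_genome(cfg), cfg)
  sim <- simulate_reads(pl$genome, pl$truth, "hot", cfg)
  aln <- align_reads(sim$reads, pl$genome)
  pool <- unaligned_pool(aln, sim$reads)
  expect_gt(nrow(pool), 10)
  det <- detect_hyper_edited_reads(pool, pl$genome)
  oracle <- brute_force_clusters(pool, pl$genome)
  a <- det$clusters |> dplyr::arrange(read_id) |> as.data.frame()
  b <- oracle |> dplyr::arrange(read_id) |> as.data.frame()
  expect_equal(a, b)
})

test_that("detection is deterministic and monotone in its thresholds", {
  st <- small_study()
  d1 <- detect_hyper_edited_reads(st$pool, st$genome)
  d2 <- detect_hyper_edited_reads(st$pool, st$genome)
  expect_identical(d1$clusters, d2$clusters)
  strict_q <- detect_hyper_edited_reads(st$pool, st$genome, quality_min = 41)
  strict_e <- detect_hyper_edited_reads(st$pool, st$genome, min_edits = 6)
  expect_lte(nrow(strict_q$clusters), nrow(d1$clusters))
  expect_lte(nrow(strict_e$clusters), nrow(d1$clusters))
  expect_equal(nrow(strict_q$clusters), 0L)  # constant Phred 40 data
})

test_that("every site lies in a region and event totals are conserved", {
  st <- small_study()
  regions <- merge_clusters_to_regions(st$det$clusters)
  expect_equal(sum(regions$n_events), sum(st$det$clusters$n_edits))
  expect_equal(sum(regions$n_events), nrow(st$det$events))
  sites <- collect_sites(st$det)$sites
  covered <- vapply(seq_len(nrow(sites)), function(i)
    any(regions$contig == sites$contig[i] & regions$strand == sites$strand[i] &
          regions$start <= sites$pos[i] & regions$end >= sites$pos[i]),
    logical(1))
  expect_true(all(covered))
})

test_that("an empty pool yields an all-zero mismatch spectrum", {
  g <- genome(c(chrA = random_seq(2000, seed = 27)))
  pool <- tibble::tibble(read_id = character(), seq = character(),
                         qual = character())
  qc <- qc_mismatch_spectrum(pool, g)
  expect_equal(nrow(qc$spectrum), 12L)
  expect_true(all(qc$spectrum$n_sites == 0L))
  expect_true(all(qc$spectrum$n_events == 0L))
})

test_that("the motif matrix is a frequency matrix anchored on A", {
  st <- small_study()
  m <- compute_motif(st$truth$sites, st$genome, flank = 5)
  expect_equal(m$offset, -5:5)
  expect_equal(rowSums(m[, c("A", "C", "G", "T")]), rep(1, 11),
               tolerance = 1e-12)
  expect_equal(m$A[m$offset == 0], 1)
  # sites at the contig edge are skipped with a count
  g <- genome(c(chrA = random_seq(100, seed = 28)))
  raw <- strsplit(unclass(g)[[1]], "")[[1]]
  apos <- which(raw == "A")
  sites <- tibble::tibble(contig = "chrA", pos = c(apos[apos > 10][1], 2L),
                          strand = "+")
  m2 <- compute_motif(sites, g, flank = 5)
  expect_equal(attr(m2, "n_skipped"), 1L)
  expect_error(compute_motif(sites[0, ], g), "at least one site")
})
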