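test_that("site-list union deduplicates with provenance", {
  s1 <- tibble::tibble(contig = "c", pos = c(10L, 20L, 30L), strand = "+")
  s2 <- tibble::tibble(contig = "c", pos = c(30L, 40L, 50L), strand = "+")
  u <- union_site_lists(a = s1, b = s2)
  expect_equal(nrow(u), 5L)
  expect_equal(sum(u$in_a & u$in_b), 1L)
  expect_equal(u$provenance[u$pos == 30], "a,b")
  # identical lists collapse to either one
  same <- union_site_lists(x = s1, y = s1)
  expect_equal(nrow(same), 3L)
  # empty is the identity
  empty <- s1[0, ]
  expect_equal(nrow(union_site_lists(e = empty, l = s1)), 3L)
  # strand conflicts are flagged and kept once
  s3 <- s1; s3$strand <- "-"
  cf <- union_site_lists(p = s1, m = s3)
  expect_equal(nrow(cf), 3L)
  expect_true(all(cf$strand_conflict))
})

# hand-built ungapped alignments over a toy genome: every read covers the
# site with a chosen base at a chosen read offset
toy_alignments <- function(g, site_pos, bases, offsets, qual_char = "I",
                           rl = 100L) {
  start <- site_pos - offsets + 1L
  seq <- genome_subseq(g, "chrA", start, start + rl - 1L)
  for (i in seq_along(seq)) substr(seq[i], offsets[i], offsets[i]) <- bases[i]
  tibble::tibble(read_id = paste0("t", seq_along(seq)), status = "unique",
                 contig = "chrA", start = start, strand = "+",
                 n_mismatch = 0L, seq_aligned = seq,
                 qual_aligned = strrep(qual_char, rl))
}

test_that("pileups count site-strand A and G reads after trim and quality filters", {
  g <- genome(c(chrA = random_seq(5000, seed = 31)))
  pos <- which(strsplit(unclass(g)[[1]], "")[[1]] == "A")
  p <- pos[pos > 200 & pos < 4000][1]
  site <- tibble::tibble(contig = "chrA", pos = p, strand = "+")
  aln <- toy_alignments(g, p, c(rep("A", 8), rep("G", 2)),
                        offsets = seq(10L, 55L, by = 5L))
  pu <- pileup_sites(aln, site)
  expect_equal(pu$a_count, 8L)
  expect_equal(pu$g_count, 2L)
  expect_equal(pu$coverage, 10L)
  expect_equal(pu$level, 0.2)
  # a supporting base at read position 3 is trimmed away
  aln3 <- toy_alignments(g, p, "G", offsets = 3L)
  pu3 <- pileup_sites(aln3, site, trim = 6)
  expect_equal(pu3$coverage, 0L)
  expect_true(is.na(pu3$level))
  # low-quality bases are ignored
  alq <- toy_alignments(g, p, "G", offsets = 50L, qual_char = "5")
  puq <- pileup_sites(alq, site, quality_min = 30)
  expect_equal(puq$coverage, 0L)
  # non-A/G bases are tallied as other and excluded from the level
  alo <- toy_alignments(g, p, c("G", "C"), offsets = c(40L, 50L))
  puo <- pileup_sites(alo, site)
  expect_equal(puo$other, 1L)
  expect_equal(puo$level, 1)
})

test_that("minus-strand sites count complement bases", {
  g <- genome(c(chrA = random_seq(5000, seed = 32)))
  tpos <- which(strsplit(unclass(g)[[1]], "")[[1]] == "T")
  p <- tpos[tpos > 200 & tpos < 4000][1]
  site <- tibble::tibble(contig = "chrA", pos = p, strand = "-")
  # plus-space T reads are A on the minus strand; C reads are G
  aln <- toy_alignments(g, p, c("T", "T", "C"), offsets = c(20L, 30L, 40L))
  pu <- pileup_sites(aln, site)
  expect_equal(pu$a_count, 2L)
  expect_equal(pu$g_count, 1L)
  expect_equal(pu$level, 1 / 3)
})

test_that("support filtering applies both thresholds", {
  base <- tibble::tibble(contig = "c", strand = "+", sample = "s1", other = 0L)
  p <- dplyr::bind_rows(
    base |> dplyr::mutate(pos = 1L, a_count = 500L, g_count = 2L),
    base |> dplyr::mutate(pos = 2L, a_count = 100L, g_count = 2L),
    base |> dplyr::mutate(pos = 3L, a_count = 10L, g_count = 1L)) |>
    dplyr::mutate(coverage = a_count + g_count, level = g_count / coverage)
  kept <- filter_supported(p, min_reads = 2, min_level = 0.01)
  expect_equal(kept$pos, 2L)
  # monotonicity: raising min_level never keeps more sites
  n1 <- nrow(filter_supported(p, min_level = 0.001))
  n2 <- nrow(filter_supported(p, min_level = 0.01))
  n3 <- nrow(filter_supported(p, min_level = 0.1))
  expect_true(n1 >= n2 && n2 >= n3)
})

test_that("editing index pools counts and equals the weighted mean of levels", {
  p <- tibble::tibble(contig = "c", pos = c(1L, 2L), strand = "+",
                      sample = "s1", a_count = c(8L, 5L), g_count = c(2L, 5L),
                      coverage = c(10L, 10L), level = c(0.2, 0.5))
  ei <- editing_index(p)
  expect_equal(ei$index, 7 / 20)
  expect_equal(ei$index, sum(p$level * p$coverage) / sum(p$coverage))
  # all G = 0 gives index 0
  p0 <- p |> dplyr::mutate(g_count = 0L)
  expect_equal(editing_index(p0)$index, 0)
  # invariant to ordering and to splitting then pooling
  expect_equal(editing_index(p[2:1, ])$index, ei$index)
  split_idx <- editing_index(p |> dplyr::mutate(sample = "s1"))
  expect_equal(split_idx$index, ei$index)
  expect_error(editing_index(p[0, ]), "non-empty")
})

test_that("editing levels recover the planted rate", {
  cfg <- sim_config(genome_length = 2e4, n_genes = 4, n_clusters = 4,
                    sites_per_cluster = c(6L, 8L),
                    per_site_edit_rate = c(mid = 0.30), coverage = 200,
                    seed = 33)
  pl <- plant_editing_clusters(generate_genome(cfg), cfg)
  sim <- simulate_reads(pl$genome, pl$truth, "mid", cfg)
  aln <- align_reads(sim$reads, pl$genome)
  det <- detect_hyper_edited_reads(unaligned_pool(aln, sim$reads), pl$genome)
  aug <- dplyr::bind_rows(dplyr::filter(aln, status == "unique"),
                          det$placements)
  pu <- pileup_sites(aug, pl$truth$sites)
  well <- pu |> dplyr::filter(coverage >= 150)
  expect_gt(nrow(well), 5)
  expect_true(all(well$level > 0.22 & well$level < 0.38))
})

test_that("annotation assigns one category per site with CDS precedence", {
  genes <- tibble::tibble(
    contig = "c",
    feature = c("exon", "five_prime_utr", "CDS", "exon", "CDS",
                "exon", "three_prime_utr", "exon"),
    start = c(100L, 100L, 150L, 500L, 500L, 900L, 950L, 2000L),
    end = c(300L, 149L, 300L, 700L, 700L, 1000L, 1000L, 2200L),
    strand = "+",
    gene_id = c(rep("gX", 7), "gY"),
    transcript_id = c(rep("tX", 7), "tY"))
  sites <- tibble::tibble(
    contig = "c", pos = c(200L, 120L, 980L, 400L, 5000L, 2100L),
    strand = "+")
  ann <- annotate_sites(sites, genes)
  expect_equal(as.character(ann$category),
               c("CDS", "5'UTR", "3'UTR", "intron", "intergenic",
                 "noncoding-exon"))
  expect_equal(ann$gene_id[1], "gX")
  expect_equal(ann$gene_id[4], "gX")
  expect_true(is.na(ann$gene_id[5]))
  dist <- attr(ann, "category_distribution")
  expect_equal(sum(dist$n), nrow(sites))
  # a site in the CDS of gX and the intron of an overlapping gY goes to CDS
  genes2 <- dplyr::bind_rows(genes, tibble::tibble(
    contig = "c", feature = "exon", start = 50L, end = 80L, strand = "+",
    gene_id = "gY", transcript_id = "tY"))
  site2 <- tibble::tibble(contig = "c", pos = 200L, strand = "+")
  expect_equal(as.character(annotate_sites(site2, genes2)$category), "CDS")
})
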