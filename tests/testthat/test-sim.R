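test_that("genome generation is deterministic, exact-length and uniform", {
  cfg <- sim_config(genome_length = 1e5, n_genes = 10, seed = 1)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(unclass(g1$genome), unclass(g2$genome))
  expect_identical(g1$genes, g2$genes)
  expect_equal(unname(genome_lengths(g1$genome)), 1e5)
  # FASTA bytes identical too
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_reference(g1$genome, f1); write_reference(g2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  # base composition: each frequency within 0.25 +/- 0.02 at 100 kb
  freqs <- table(strsplit(unclass(g1$genome)[[1]], "")[[1]]) / 1e5
  expect_true(all(abs(freqs - 0.25) < 0.02))
})

test_that("configuration errors are caught", {
  expect_error(sim_config(genome_length = 500), "genome_length")
  expect_error(sim_config(read_length = -5), "positive")
  expect_error(sim_config(seq_error_rate = 2), "probability")
  expect_error(sim_config(per_site_edit_rate = c(0.5)), "named")
})

test_that("planted truth satisfies its structural invariants", {
  st <- small_study()
  sites <- st$truth$sites
  clusters <- st$truth$clusters
  # conservation: site count equals the sum of cluster site counts
  expect_equal(nrow(sites), sum(clusters$n_sites))
  # every site inside exactly one cluster
  owners <- vapply(seq_len(nrow(sites)), function(i)
    sum(sites$pos[i] >= clusters$start & sites$pos[i] <= clusters$end),
    numeric(1))
  expect_true(all(owners == 1))
  # every truth position is an adenosine on its annotated strand
  base <- genome_subseq(st$genome, sites$contig, sites$pos, sites$pos,
                        sites$strand)
  expect_true(all(base == "A"))
  # cluster span covers at least 10% of the read length
  expect_true(all(clusters$end - clusters$start + 1 >=
                    0.1 * st$cfg$read_length))
})

test_that("fixed sites_per_cluster is honoured exactly and ir_fraction = 0 plants nothing", {
  cfg <- sim_config(genome_length = 3e4, n_genes = 6, n_clusters = 5,
                    sites_per_cluster = c(8L, 8L), ir_fraction = 0, seed = 2)
  pl <- plant_editing_clusters(generate_genome(cfg), cfg)
  expect_true(all(pl$truth$clusters$n_sites == 8L))
  expect_equal(nrow(pl$truth$inverted_repeats), 0L)
})

test_that("motif bias is planted at the configured probabilities", {
  cfg <- sim_config(genome_length = 6e5, n_genes = 60, n_clusters = 150,
                    sites_per_cluster = c(8L, 8L),
                    motif_bias = c(g_minus1 = 0.05, g_plus1 = 0.35), seed = 3)
  pl <- plant_editing_clusters(generate_genome(cfg), cfg)
  sites <- pl$truth$sites
  expect_gte(nrow(sites), 1000)
  up <- genome_subseq(pl$genome, sites$contig,
                      ifelse(sites$strand == "+", sites$pos - 1L, sites$pos + 1L),
                      ifelse(sites$strand == "+", sites$pos - 1L, sites$pos + 1L),
                      sites$strand)
  dn <- genome_subseq(pl$genome, sites$contig,
                      ifelse(sites$strand == "+", sites$pos + 1L, sites$pos - 1L),
                      ifelse(sites$strand == "+", sites$pos + 1L, sites$pos - 1L),
                      sites$strand)
  expect_gt(mean(up == "G"), 0.03)
  expect_lt(mean(up == "G"), 0.08)
  expect_gt(mean(dn == "G"), 0.30)
  expect_lt(mean(dn == "G"), 0.40)
})

test_that("noise-free reads are exact genome substrings and errors are planted at rate", {
  cfg <- sim_config(genome_length = 2e4, n_genes = 4, n_clusters = 2,
                    per_site_edit_rate = c(off = 0), seq_error_rate = 0,
                    coverage = 5, seed = 4)
  pl <- plant_editing_clusters(generate_genome(cfg), cfg)
  sim <- simulate_reads(pl$genome, pl$truth, "off", cfg)
  frag <- genome_subseq(pl$genome, sim$reads$contig, sim$reads$start,
                        sim$reads$start + cfg$read_length - 1L,
                        sim$reads$strand)
  expect_identical(sim$reads$seq, frag)
  expect_equal(nrow(sim$read_edits), 0L)
})

test_that("per-site edited-read fraction matches the planted rate", {
  cfg <- sim_config(genome_length = 1e4, n_genes = 2, n_clusters = 1,
                    sites_per_cluster = c(6L, 6L),
                    per_site_edit_rate = c(hot = 0.8), seq_error_rate = 0,
                    seed = 5)
  pl <- plant_editing_clusters(generate_genome(cfg), cfg)
  sim <- simulate_reads(pl$genome, pl$truth, "hot", cfg, n_reads = 100000)
  site <- pl$truth$sites[3, ]
  covering <- sum(sim$reads$start <= site$pos &
                    sim$reads$start + cfg$read_length - 1L >= site$pos)
  edited <- sum(sim$read_edits$pos == site$pos)
  expect_gt(covering, 500)
  frac <- edited / covering
  expect_gt(frac, 0.76)   # binomial 99% band around 0.8
  expect_lt(frac, 0.84)
})

test_that("reads are strand-balanced", {
  st <- small_study()
  expect_gte(nrow(st$sim$reads), 10000)
  frac_minus <- mean(st$sim$reads$strand == "-")
  expect_gt(frac_minus, 0.48)
  expect_lt(frac_minus, 0.52)
})

test_that("simulation is byte-deterministic given the seed", {
  cfg <- sim_config(genome_length = 2e4, n_genes = 4, n_clusters = 3, seed = 6)
  pl <- plant_editing_clusters(generate_genome(cfg), cfg)
  s1 <- simulate_reads(pl$genome, pl$truth, "T18", cfg)
  s2 <- simulate_reads(pl$genome, pl$truth, "T18", cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$read_edits, s2$read_edits)
  expect_error(simulate_reads(pl$genome, pl$truth, "T99", cfg), "unknown condition")
})
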