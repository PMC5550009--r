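test_that("window extraction centres the site with the stated convention", {
  g <- genome(c(chrA = random_seq(1000, seed = 51)))
  s <- tibble::tibble(contig = "chrA", pos = 100L, strand = "+")
  w <- extract_window(s, g, width = 40)
  expect_equal(c(w$win_start, w$win_end), c(81L, 120L))
  expect_equal(w$site_offset, 20L)
  expect_equal(substring(w$window, 20, 20),
               genome_subseq(g, "chrA", 100, 100))
  expect_false(w$truncated)
  # minus-strand windows are reverse-complemented, site still at 20
  m <- extract_window(tibble::tibble(contig = "chrA", pos = 100L,
                                     strand = "-"), g, width = 40)
  expect_equal(m$window, revcomp(genome_subseq(g, "chrA", 80, 119)))
  expect_equal(substring(m$window, 20, 20),
               genome_subseq(g, "chrA", 100, 100, "-"))
  # near the contig start the window truncates and flags
  t <- extract_window(tibble::tibble(contig = "chrA", pos = 10L,
                                     strand = "+"), g, width = 40)
  expect_true(t$truncated)
  expect_equal(t$win_start, 1L)
})

test_that("a planted perfect inverted repeat is found in antisense mode only", {
  base <- random_seq(5000, seed = 52)
  core <- substr(base, 2481, 2520)              # site 2500 at window pos 20
  gseq <- paste0(substr(base, 1, 3299), revcomp(core), substr(base, 3340, 5000))
  g <- genome(c(chrA = gseq))
  s <- tibble::tibble(contig = "chrA", pos = 2500L, strand = "+")
  m <- search_inverted_complement(s, g, modes = c("antisense", "sense"))
  anti <- m[m$mode == "antisense", ]
  expect_true(anti$matched)
  expect_equal(anti$identity, 100)
  expect_equal(anti$coverage, 100)
  expect_equal(c(anti$partner_start, anti$partner_end), c(3300L, 3339L))
  # edited-form identity never exceeds the unedited identity against the
  # unedited partner
  me <- search_inverted_complement(s, g, modes = "antisense-edited")
  expect_lte(me$identity, anti$identity)
})

test_that("random flanks rarely reach the 70/70 match thresholds", {
  g <- genome(c(chrA = random_seq(2e5, seed = 53)))
  pos <- seq(3000L, 197000L, length.out = 60)
  s <- tibble::tibble(contig = "chrA", pos = as.integer(pos), strand = "+")
  m <- search_inverted_complement(s, g, modes = c("antisense", "sense"))
  fr <- structure_summary(m)
  expect_lt(fr$fraction_matched[fr$mode == "antisense"], 0.10)
  expect_lt(fr$fraction_matched[fr$mode == "sense"], 0.10)
})

test_that("the seeded aligner equals full Smith-Waterman when a seed lies on the optimal path", {
  withr::with_seed(54, {
    n_checked <- 0
    for (i in 1:60) {
      w <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
      fl <- paste(sample(c("A", "C", "G", "T"),
                         sample(100:500, 1), TRUE), collapse = "")
      # sometimes embed a mutated copy so strong alignments are represented
      if (i %% 3 == 0) {
        mut <- strsplit(w, "")[[1]]
        k <- sample(0:8, 1)
        if (k > 0) {
          at <- sample(40, k)
          mut[at] <- sample(c("A", "C", "G", "T"), k, TRUE)
        }
        at0 <- sample(nchar(fl) - 45, 1)
        fl <- paste0(substr(fl, 1, at0), paste(mut, collapse = ""),
                     substr(fl, at0 + 41, nchar(fl)))
      }
      oracle <- sw_oracle(w, fl)
      hsp <- thermedit:::seeded_best_hsp(w, fl, score_floor = 1)
      if (oracle$longest_match_run >= 7) {
        n_checked <- n_checked + 1
        expect_equal(hsp$score, oracle$score)
      } else if (!is.null(hsp)) {
        expect_lte(hsp$score, oracle$score)
      }
    }
    expect_gt(n_checked, 10)
  })
})

test_that("match flags are monotone in the identity and coverage thresholds", {
  base <- random_seq(6000, seed = 55)
  core <- substr(base, 2981, 3020)
  mut <- strsplit(revcomp(core), "")[[1]]
  mut[c(5, 15, 25)] <- c("A", "C", "G")       # a partner with mismatches
  gseq <- paste0(substr(base, 1, 3999), paste(mut, collapse = ""),
                 substr(base, 4040, 6000))
  g <- genome(c(chrA = gseq))
  s <- tibble::tibble(contig = "chrA", pos = 3000L, strand = "+")
  loose <- search_inverted_complement(s, g, modes = "antisense",
                                      min_identity = 70, min_coverage = 70)
  strict <- search_inverted_complement(s, g, modes = "antisense",
                                       min_identity = 95, min_coverage = 95)
  expect_true(loose$matched)
  expect_gte(as.integer(loose$matched), as.integer(strict$matched))
})

test_that("structure summaries report matched fractions per mode", {
  m <- tibble::tibble(mode = rep(c("antisense", "sense"), each = 100),
                      matched = c(rep(TRUE, 30), rep(FALSE, 70),
                                  rep(FALSE, 100)))
  s <- structure_summary(m)
  expect_equal(s$fraction_matched[s$mode == "antisense"], 0.30)
  expect_equal(s$fraction_matched[s$mode == "sense"], 0)
  expect_equal(attr(s, "antisense_excess"), 0.30)
})

test_that("higher planted inverted-repeat fractions raise the matched fraction", {
  run_fraction <- function(ir_fraction, seed) {
    cfg <- sim_config(genome_length = 1.5e5, n_genes = 20, n_clusters = 12,
                      ir_fraction = ir_fraction, seed = seed)
    pl <- plant_editing_clusters(generate_genome(cfg), cfg)
    mids <- pl$truth$clusters |>
      dplyr::mutate(pos = as.integer(floor((start + end) / 2))) |>
      dplyr::select(contig, pos, strand)
    m <- search_inverted_complement(mids, pl$genome, modes = "antisense")
    mean(m$matched)
  }
  expect_gt(run_fraction(0.9, seed = 56), run_fraction(0.1, seed = 56))
})
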