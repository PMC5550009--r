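# Differential editing between conditions: per-site Pearson chi-square on
# the 2x2 G/A table, BH FDR, coverage and effect-size filters, gene-set
# editing-index bootstrap, and distribution comparison.

#' Pearson chi-square on a 2x2 editing table
#'
#' Tests whether the G fraction differs between two conditions at one site.
#' No continuity correction; df = 1. Equivalent to the square of the
#' two-proportion z statistic.
#'
#' @param g_a,a_a G- and A-read counts in condition A.
#' @param g_b,a_b G- and A-read counts in condition B.
#' @return Tibble with `statistic` and `p_value`; both NA (test undefined)
#'   when a table margin is zero.
#' @examples
#' chi2_site_test(30, 70, 10, 90)  # statistic 12.5
#' @export
chi2_site_test <- function(g_a, a_a, g_b, a_b) {
  if (any(c(g_a, a_a, g_b, a_b) < 0)) abort("counts must be non-negative")
  n1 <- g_a + a_a
  n2 <- g_b + a_b
  g <- g_a + g_b
  a <- a_a + a_b
  n <- n1 + n2
  undef <- n1 == 0 | n2 == 0 | g == 0 | a == 0
  stat <- ifelse(undef, NA_real_,
                 n * (g_a * a_b - g_b * a_a)^2 / (n1 * n2 * g * a))
  tibble(statistic = stat,
         p_value = ifelse(is.na(stat), NA_real_, pchisq(stat, df = 1,
                                                        lower.tail = FALSE)))
}

#' Benjamini-Hochberg adjustment with a rejection mask
#'
#' @param p Numeric vector of p-values (NA excluded from the family size).
#' @param q FDR level (default 0.05).
#' @return Tibble with `p`, `q_value` (BH-adjusted), `significant`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  tibble(p = p, q_value = adj, significant = !is.na(adj) & adj <= q)
}

#' Differential editing between condition pairs
#'
#' For every site and every pair of conditions, tests the G/A counts with
#' [chi2_site_test()], adjusts p-values by Benjamini-Hochberg within the
#' pair, and flags sites with adequate coverage (`>= min_cov` in both
#' conditions) and a meaningful effect (`|delta| > min_delta`). A site is
#' `significant` only when all three flags hold.
#'
#' @param pileups Pileup tibble with a `condition` column (counts pooled per
#'   condition; if a `sample` column is present, samples of a condition are
#'   summed first).
#' @param min_cov Minimum (A+G) coverage per condition (default 50).
#' @param min_delta Minimum absolute editing-level difference (default 0.20).
#' @param q FDR level (default 0.05).
#' @return A tibble of class `thermedit_diff`: site coordinates, condition
#'   pair, counts, levels, delta (level_b - level_a), statistic, p_value,
#'   q_value, coverage_ok, delta_ok, significant.
#' @export
differential_sites <- function(pileups, min_cov = 50, min_delta = 0.20,
                               q = 0.05) {
  if (!"condition" %in% names(pileups)) {
    abort("`pileups` must carry a `condition` column")
  }
  pooled <- pileups |>
    group_by(.data$contig, .data$pos, .data$strand, .data$condition) |>
    summarise(a_count = sum(.data$a_count), g_count = sum(.data$g_count),
              .groups = "drop")
  conds <- sort(unique(pooled$condition))
  if (length(conds) < 2) abort("need at least two conditions")
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  out <- map(pairs, function(pr) {
    wide <- pooled |>
      filter(.data$condition %in% pr) |>
      pivot_wider(names_from = "condition",
                  values_from = c("a_count", "g_count"), values_fill = 0L)
    aa <- wide[[paste0("a_count_", pr[1])]]
    ga <- wide[[paste0("g_count_", pr[1])]]
    ab <- wide[[paste0("a_count_", pr[2])]]
    gb <- wide[[paste0("g_count_", pr[2])]]
    test <- chi2_site_test(ga, aa, gb, ab)
    cov_a <- aa + ga
    cov_b <- ab + gb
    level_a <- ifelse(cov_a > 0, ga / cov_a, NA_real_)
    level_b <- ifelse(cov_b > 0, gb / cov_b, NA_real_)
    adj <- bh_fdr(test$p_value, q = q)
    coverage_ok <- cov_a >= min_cov & cov_b >= min_cov
    delta_ok <- !is.na(level_a) & !is.na(level_b) &
      abs(level_b - level_a) > min_delta
    tibble(contig = wide$contig, pos = wide$pos, strand = wide$strand,
           condition_a = pr[1], condition_b = pr[2],
           a_count_a = aa, g_count_a = ga, a_count_b = ab, g_count_b = gb,
           level_a = level_a, level_b = level_b, delta = level_b - level_a,
           statistic = test$statistic, p_value = test$p_value,
           q_value = adj$q_value,
           coverage_ok = coverage_ok, delta_ok = delta_ok,
           significant = adj$significant & coverage_ok & delta_ok)
  }) |> list_rbind()
  class(out) <- c("thermedit_diff", class(out))
  out
}

#' Gene-set editing-index bootstrap
#'
#' Tests whether a target gene set is more edited than expected by drawing
#' `B` equally sized gene sets without replacement from a control pool
#' (typically the most-expressed genes) and recomputing the pooled editing
#' index for each. One-sided add-one p-value:
#' `p = (1 + #\{null >= observed\}) / (B + 1)`.
#'
#' @param target_genes Character vector of gene ids.
#' @param control_pool Character vector of gene ids to resample from (must be
#'   at least as large as the target set).
#' @param gene_counts Tibble with `gene_id`, `a_count`, `g_count` (site
#'   counts already aggregated per gene; see [pileup_sites()] +
#'   [annotate_sites()]).
#' @param B Number of bootstrap draws (default 10000).
#' @param seed Integer seed; the draw sequence is reproducible bit for bit.
#' @return Object of class `thermedit_bootstrap`: list with `observed`,
#'   `null` (numeric vector of length `B`), `p_value`, `B`, `n_target`.
#' @export
geneset_editing_bootstrap <- function(target_genes, control_pool, gene_counts,
                                      B = 10000, seed = 1) {
  target_genes <- unique(target_genes)
  control_pool <- unique(control_pool)
  if (length(target_genes) == 0) abort("target gene set is empty")
  if (length(control_pool) < length(target_genes)) {
    abort("control pool is smaller than the target set")
  }
  idx <- function(genes) {
    gc <- gene_counts |> filter(.data$gene_id %in% genes)
    den <- sum(gc$a_count) + sum(gc$g_count)
    if (den == 0) return(NA_real_)
    sum(gc$g_count) / den
  }
  observed <- idx(target_genes)
  # fast lookup vectors for the null draws
  a <- setNames(gene_counts$a_count, gene_counts$gene_id)
  g <- setNames(gene_counts$g_count, gene_counts$gene_id)
  a_pool <- ifelse(control_pool %in% names(a), a[control_pool], 0)
  g_pool <- ifelse(control_pool %in% names(g), g[control_pool], 0)
  k <- length(target_genes)
  null <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(B), function(b) {
      take <- sample.int(length(control_pool), k)
      den <- sum(a_pool[take]) + sum(g_pool[take])
      if (den == 0) NA_real_ else sum(g_pool[take]) / den
    }, double(1))
  })
  p <- (1 + sum(null >= observed, na.rm = TRUE)) / (B + 1)
  structure(list(observed = observed, null = null, p_value = p, B = B,
                 n_target = k),
            class = "thermedit_bootstrap")
}

#' @export
print.thermedit_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<thermedit_bootstrap> observed index %.4f vs %d null draws (n = %d genes): p = %.4g\n",
    x$observed, x$B, x$n_target, x$p_value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the null distribution of an editing bootstrap
#' @param x A `thermedit_bootstrap`.
#' @param ... Unused.
#' @return Tibble with one row per null draw.
#' @export
tidy.thermedit_bootstrap <- function(x, ...) {
  tibble(draw = seq_len(x$B), null_index = x$null)
}

#' One-row summary of an editing bootstrap
#' @param x A `thermedit_bootstrap`.
#' @param ... Unused.
#' @return One-row tibble: observed, null_mean, null_sd, p_value, B, n_target.
#' @export
glance.thermedit_bootstrap <- function(x, ...) {
  tibble(observed = x$observed, null_mean = mean(x$null, na.rm = TRUE),
         null_sd = stats::sd(x$null, na.rm = TRUE), p_value = x$p_value,
         B = x$B, n_target = x$n_target)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param a,b Numeric vectors (each with at least 2 values).
#' @return Tibble with `statistic` (D) and `p_value`.
#' @export
ks_compare <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("ks_compare needs n >= 2 per side")
  kt <- suppressWarnings(ks.test(a, b))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value)
}
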