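#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The generator plants
#' clustered A-to-G editing into a random genome so that each downstream
#' stage (transformed realignment, pileup quantification, differential
#' testing, inverted-repeat search) sees data with the statistical structure
#' it assumes: clustered edits with condition-dependent per-site rates, an
#' ADAR-like sequence context (G depleted at -1, enriched at +1 relative to
#' the edited adenosine), strand-balanced reads, uniform sequencing error,
#' and inverted repeats within 2 kb of a subset of clusters.
#'
#' @param genome_length Genome size in bases (>= 10000).
#' @param n_genes Number of genes tiled onto the genome.
#' @param n_clusters Number of planted editing clusters.
#' @param sites_per_cluster Length-2 integer vector `c(min, max)`; the number
#'   of edited adenosines per cluster is drawn uniformly from this range.
#' @param per_site_edit_rate Named numeric vector, one editing probability per
#'   condition label, e.g. `c(T18 = 0.6, T29 = 0.2)`. The names define the
#'   condition labels.
#' @param motif_bias Named numeric vector `c(g_minus1 = , g_plus1 = )`:
#'   probability that the base immediately upstream (resp. downstream) of a
#'   planted site, on the site strand, is G. ADAR targets are depleted of G
#'   at -1 and enriched at +1; defaults 0.05 and 0.35.
#' @param ir_fraction Fraction of clusters whose 40-nt core is paired with a
#'   reverse-complement copy planted within 2 kb on the same strand, creating
#'   a perfect inverted repeat (dsRNA stem).
#' @param ir_length Length of the planted inverted-repeat core, bases.
#' @param ir_max_distance Maximum distance (bases) between a cluster core and
#'   its planted partner.
#' @param seq_error_rate Per-base probability of a uniform sequencing error.
#' @param read_length Read length in bases.
#' @param coverage Mean sequencing depth (reads per base).
#' @param cluster_span Genomic span (bases) over which each cluster's sites
#'   are spread; must be at least 10 percent of `read_length` so a single
#'   read can carry a rule-passing cluster.
#' @param genic_fraction Fraction of the genome covered by gene bodies.
#' @param phred Constant Phred quality assigned to every base (the error
#'   process is explicit, not quality-driven).
#' @param seed Master integer seed; every stage derives its own sub-stream
#'   from it, so a fixed config is byte-reproducible.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(genome_length = 2e4, n_clusters = 4, seed = 1)
#' cfg$condition_labels
#' @export
sim_config <- function(genome_length = 1e5,
                       n_genes = 20,
                       n_clusters = 30,
                       sites_per_cluster = c(6L, 10L),
                       per_site_edit_rate = c(T18 = 0.6, T29 = 0.2),
                       motif_bias = c(g_minus1 = 0.05, g_plus1 = 0.35),
                       ir_fraction = 0.25,
                       ir_length = 40,
                       ir_max_distance = 2000,
                       seq_error_rate = 0.001,
                       read_length = 100,
                       coverage = 30,
                       cluster_span = NULL,
                       genic_fraction = 0.6,
                       phred = 40,
                       seed = 1) {
  if (genome_length < 10000) abort("`genome_length` must be >= 10000 bases")
  if (read_length > genome_length) abort("`read_length` cannot exceed `genome_length`")
  if (read_length <= 0 || coverage <= 0) abort("`read_length` and `coverage` must be positive")
  if (is.null(names(per_site_edit_rate)) || any(names(per_site_edit_rate) == "")) {
    abort("`per_site_edit_rate` must be named by condition label")
  }
  assert_prob(per_site_edit_rate, "per_site_edit_rate")
  assert_prob(motif_bias, "motif_bias")
  assert_prob(ir_fraction, "ir_fraction")
  assert_prob(seq_error_rate, "seq_error_rate")
  assert_prob(genic_fraction, "genic_fraction")
  sites_per_cluster <- as.integer(sites_per_cluster)
  if (length(sites_per_cluster) == 1L) sites_per_cluster <- rep(sites_per_cluster, 2L)
  if (sites_per_cluster[1] < 1L || sites_per_cluster[2] < sites_per_cluster[1]) {
    abort("`sites_per_cluster` must be c(min, max) with 1 <= min <= max")
  }
  cluster_span <- cluster_span %||% max(ceiling(0.4 * read_length), 20)
  if (cluster_span < ceiling(0.1 * read_length)) {
    abort("`cluster_span` must be at least 10% of `read_length`")
  }
  structure(
    list(
      genome_length = as.integer(genome_length),
      n_genes = as.integer(n_genes),
      n_clusters = as.integer(n_clusters),
      sites_per_cluster = sites_per_cluster,
      per_site_edit_rate = per_site_edit_rate,
      condition_labels = names(per_site_edit_rate),
      motif_bias = motif_bias,
      ir_fraction = ir_fraction,
      ir_length = as.integer(ir_length),
      ir_max_distance = as.integer(ir_max_distance),
      seq_error_rate = seq_error_rate,
      read_length = as.integer(read_length),
      coverage = coverage,
      cluster_span = as.integer(cluster_span),
      genic_fraction = genic_fraction,
      phred = as.integer(phred),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %s bp, %d genes, %d clusters (%d-%d sites each)\n",
              format(x$genome_length, big.mark = ","), x$n_genes, x$n_clusters,
              x$sites_per_cluster[1], x$sites_per_cluster[2]))
  cat(sprintf("  conditions: %s\n",
              paste(sprintf("%s (rate %.2f)", x$condition_labels, x$per_site_edit_rate),
                    collapse = ", ")))
  cat(sprintf("  reads: %d bp at %gx, error %g, Phred %d, seed %d\n",
              x$read_length, x$coverage, x$seq_error_rate, x$phred, x$seed))
  invisible(x)
}
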