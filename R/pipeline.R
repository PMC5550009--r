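# End-to-end orchestration: one config, fixed seeds, stage outputs written
# as TSV, and a report bundle reproducing the figure-level summaries
# (mismatch spectrum, editing index, site/cluster statistics, motif,
# category distribution, structure fractions, conservation profile,
# differential table, bootstrap).

#' Pipeline run configuration
#'
#' All stage parameters with their defaults; paths name the inputs. Any
#' field can be overridden via arguments or loaded from YAML with
#' [load_run_config()].
#'
#' @param genome Path to the reference FASTA.
#' @param gtf Path to the gene-model GTF.
#' @param reads Named list of FASTQ paths, one per condition.
#' @param known_sites Optional named list of site-table TSV paths merged
#'   into the quantification site list.
#' @param track Optional conservation track (wig or TSV).
#' @param folds Optional conserved-fold intervals (BED).
#' @param target_genes Optional character vector (or file of one gene id per
#'   line) for the editing-index bootstrap.
#' @param out_dir Output directory (created if missing); `NULL` disables
#'   file output.
#' @param quality_min,min_edits,end_exclusion,max_gap Detection parameters
#'   (Phred floor, minimum edits per read cluster, read-end exclusion,
#'   cluster merge gap).
#' @param max_mm_per_100 Aligner mismatch budget per 100 bases.
#' @param trim,min_reads,min_level Quantification parameters (read-end trim,
#'   minimum supporting G reads, minimum editing level).
#' @param min_cov,min_delta,q Differential parameters (coverage floor,
#'   minimum level difference, FDR level).
#' @param width,flank,min_identity,min_coverage Structure-search parameters.
#' @param cons_window Conservation profile half-width.
#' @param structure_max_sites Structure search is reported on at most this
#'   many sites (seeded subsample) to keep runtime proportionate.
#' @param expressed_fraction Fraction of most-expressed genes forming the
#'   bootstrap control pool.
#' @param B Bootstrap draws.
#' @param run_qc Whether to run the 12-type mismatch spectrum.
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(genome = NULL, gtf = NULL, reads = list(),
                       known_sites = list(), track = NULL, folds = NULL,
                       target_genes = NULL, out_dir = NULL,
                       quality_min = 30, min_edits = 4, end_exclusion = 6,
                       max_gap = 20, max_mm_per_100 = 4,
                       trim = 6, min_reads = 2, min_level = 0.01,
                       min_cov = 50, min_delta = 0.20, q = 0.05,
                       width = 40, flank = 2000, min_identity = 70,
                       min_coverage = 70, cons_window = 20,
                       structure_max_sites = 200, expressed_fraction = 0.6,
                       B = 10000, run_qc = TRUE, seed = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full editing pipeline
#'
#' Loads the inputs, aligns each condition's reads, detects hyper-edited
#' clusters by transformed realignment, merges regions, quantifies editing
#' levels and the editing index over the union site list, annotates genomic
#' locations, tests differential editing, searches flanks for inverted
#' complements, profiles conservation (when a track is given) and runs the
#' gene-set bootstrap. Stage outputs are written as TSV under
#' `config$out_dir` together with the verbatim config and a manifest; the
#' same tables are returned as the report bundle.
#'
#' @param config A [run_config()].
#' @return A list of class `thermedit_report` with one element per report
#'   section plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$genome, config$gtf, unlist(config$reads),
              unlist(config$known_sites), config$track, config$folds)) {
    if (!is.null(p) && !file.exists(p)) abort(sprintf("missing input: %s", p))
  }
  if (is.null(config$genome)) abort("missing input: genome FASTA path")
  if (length(config$reads) == 0) abort("missing input: reads")
  if (is.null(names(config$reads))) {
    names(config$reads) <- paste0("cond", seq_along(config$reads))
  }
  seeds <- derive_seeds(config$seed, 3)

  gen <- load_reference(config$genome)
  genes <- if (!is.null(config$gtf)) load_intervals(config$gtf, "gtf") else NULL

  conds <- names(config$reads)
  per_cond <- map(setNames(conds, conds), function(cd) {
    reads <- read_fastq(config$reads[[cd]])
    aln <- align_reads(reads, gen, max_mm_per_100 = config$max_mm_per_100)
    pool <- unaligned_pool(aln, reads)
    det <- detect_hyper_edited_reads(
      pool, gen, "AG", quality_min = config$quality_min,
      min_edits = config$min_edits, end_exclusion = config$end_exclusion,
      max_mm_per_100 = config$max_mm_per_100)
    list(reads = reads, aln = aln, pool = pool, det = det)
  })

  # per-condition site calls, clusters, regions
  site_calls <- imap_dfr(per_cond, function(x, cd)
    collect_sites(x$det)$sites |> mutate(condition = cd))
  site_summary <- imap_dfr(per_cond, function(x, cd)
    collect_sites(x$det)$summary |> mutate(condition = cd))
  regions <- imap_dfr(per_cond, function(x, cd)
    merge_clusters_to_regions(x$det$clusters, max_gap = config$max_gap) |>
      mutate(condition = cd))
  region_summary <- regions |>
    group_by(.data$condition) |>
    summarise(n_regions = n(),
              mean_region_length = mean(.data$end - .data$start + 1),
              .groups = "drop") |>
    left_join(site_summary, by = "condition")

  qc <- NULL
  if (isTRUE(config$run_qc)) {
    qc <- imap_dfr(per_cond, function(x, cd) {
      s <- qc_mismatch_spectrum(
        x$pool, gen, quality_min = config$quality_min,
        min_edits = config$min_edits, end_exclusion = config$end_exclusion,
        max_mm_per_100 = config$max_mm_per_100)
      s$spectrum |> mutate(condition = cd)
    })
  }
  strand_split <- site_calls |>
    group_by(.data$condition, .data$strand) |>
    summarise(n_sites = n(), .groups = "drop_last") |>
    mutate(fraction = .data$n_sites / sum(.data$n_sites)) |>
    ungroup()

  all_sites <- site_calls |> distinct(.data$contig, .data$pos, .data$strand)
  motif <- if (nrow(all_sites)) compute_motif(all_sites, gen) else NULL

  # union with any known lists, then per-condition pileups (ordinary unique
  # alignments plus the realigned hyper-edited reads, so heavily edited
  # reads still contribute to editing levels)
  site_lists <- list(hyper = all_sites)
  for (nm in names(config$known_sites)) {
    site_lists[[nm]] <- read_sites(config$known_sites[[nm]])
  }
  union_sites <- do.call(union_site_lists, site_lists)

  pileups <- imap_dfr(per_cond, function(x, cd) {
    aln <- bind_rows(x$aln |> filter(.data$status == "unique"),
                     x$det$placements)
    pileup_sites(aln, union_sites, quality_min = config$quality_min,
                 trim = config$trim) |> mutate(condition = cd)
  })
  supported <- filter_supported(pileups, min_reads = config$min_reads,
                                min_level = config$min_level)
  index <- supported |>
    group_by(.data$condition) |>
    group_modify(~ editing_index(.x)) |>
    ungroup()

  annotated <- if (!is.null(genes)) annotate_sites(all_sites, genes) else NULL
  category_distribution <- if (!is.null(annotated))
    attr(annotated, "category_distribution") else NULL

  differential <- if (length(conds) >= 2)
    differential_sites(supported, min_cov = config$min_cov,
                       min_delta = config$min_delta, q = config$q) else NULL

  # structure search on a seeded subsample of called sites
  str_sites <- all_sites
  if (nrow(str_sites) > config$structure_max_sites) {
    str_sites <- withr::with_seed(seeds[1],
      str_sites[sort(sample.int(nrow(str_sites), config$structure_max_sites)), ])
  }
  struct <- if (nrow(str_sites)) search_inverted_complement(
    str_sites, gen, width = config$width, flank = config$flank,
    modes = c("antisense", "sense", "antisense-edited"),
    min_identity = config$min_identity, min_coverage = config$min_coverage)
  else NULL
  struct_summary <- if (!is.null(struct)) structure_summary(struct) else NULL

  conservation <- NULL
  if (!is.null(config$track) && nrow(all_sites)) {
    track <- read_track(config$track)
    bodies <- if (!is.null(genes)) genes |>
      group_by(.data$gene_id) |>
      summarise(contig = first(.data$contig), start = min(.data$start),
                end = max(.data$end), .groups = "drop") else NULL
    conservation <- conservation_profile(
      site_calls |> distinct(.data$contig, .data$pos, .data$strand,
                             .keep_all = TRUE),
      track, gen, window = config$cons_window,
      background_regions = bodies, seed = seeds[2])
  }

  fold_overlap <- NULL
  if (!is.null(config$folds) && nrow(all_sites)) {
    folds <- load_intervals(config$folds, "bed")
    fold_overlap <- evofold_overlap(all_sites, folds)
  }

  bootstrap <- NULL
  if (!is.null(annotated) && nrow(supported)) {
    gene_counts <- supported |>
      left_join(annotated |> select("contig", "pos", "strand", "gene_id"),
                by = c("contig", "pos", "strand")) |>
      filter(!is.na(.data$gene_id)) |>
      group_by(.data$gene_id) |>
      summarise(a_count = sum(.data$a_count), g_count = sum(.data$g_count),
                coverage = sum(.data$coverage), .groups = "drop")
    if (nrow(gene_counts) >= 3) {
      pool_genes <- gene_counts |>
        arrange(desc(.data$coverage)) |>
        slice_head(n = max(2L, ceiling(config$expressed_fraction *
                                         nrow(gene_counts))))
      targets <- config$target_genes %||%
        (annotated |> filter(!is.na(.data$gene_id)) |> pull(.data$gene_id) |>
           unique() |> head(max(2L, nrow(gene_counts) %/% 5)))
      if (is.character(targets) && length(targets) == 1 && file.exists(targets)) {
        targets <- readr::read_lines(targets)
      }
      targets <- intersect(targets, gene_counts$gene_id)
      if (length(targets) >= 1 &&
          length(pool_genes$gene_id) >= length(targets)) {
        bootstrap <- geneset_editing_bootstrap(
          targets, pool_genes$gene_id, gene_counts, B = config$B,
          seed = seeds[3])
      }
    }
  }

  path_fields <- c("genome", "gtf", "reads", "known_sites", "track", "folds",
                   "target_genes", "out_dir")
  manifest <- tibble(
    package_version = as.character(utils::packageVersion("thermedit")),
    r_version = R.version.string,
    seed = config$seed,
    param_hash = rlang::hash(config[sort(setdiff(names(config), path_fields))]),
    conditions = paste(conds, collapse = ","))

  report <- structure(list(
    qc_spectrum = qc,
    strand_split = strand_split,
    editing_index = index,
    site_summary = site_summary,
    region_summary = region_summary,
    motif = motif,
    category_distribution = category_distribution,
    structure_summary = struct_summary,
    conservation_profile = conservation,
    differential = differential,
    bootstrap = bootstrap,
    fold_overlap = fold_overlap,
    sites = site_calls,
    regions = regions,
    pileups = pileups,
    structure_matches = struct,
    manifest = manifest), class = "thermedit_report")

  if (!is.null(config$out_dir)) write_report(report, config)
  report
}

write_report <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  class(cfg) <- NULL
  cfg$reads <- as.list(cfg$reads)
  yaml::write_yaml(purrr::compact(cfg), file.path(config$out_dir, "config.yaml"))
  for (nm in names(report)) {
    x <- report[[nm]]
    if (is.null(x)) next
    if (inherits(x, "thermedit_bootstrap")) x <- glance(x)
    if (is.data.frame(x)) {
      readr::write_tsv(x, file.path(config$out_dir, paste0(nm, ".tsv")))
    }
  }
  invisible(config$out_dir)
}

#' @export
print.thermedit_report <- function(x, ...) {
  cat("<thermedit_report>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(v)) "(not run)"
                else if (is.data.frame(v)) sprintf("%d rows", nrow(v))
                else class(v)[1]))
  }
  invisible(x)
}

#' Simulate a study and run the pipeline against its planted truth
#'
#' Generates a genome and planted truth from `sim_cfg`, simulates reads for
#' the requested conditions, writes the inputs, runs [run_pipeline()], and
#' joins the called sites with the truth at exact coordinates to produce
#' recovery statistics.
#'
#' @param sim_cfg A [sim_config()].
#' @param conditions Conditions to simulate (default all configured).
#' @param dir Directory for the simulated inputs and pipeline outputs
#'   (default a fresh temporary directory).
#' @param ... Overrides passed to [run_config()] (e.g. `run_qc = FALSE`).
#' @return A list: `report` (the pipeline report), `truth`, and `evaluation`
#'   — a tibble per condition with true-positive/false counts, site-level
#'   sensitivity and precision, and the recovered vs planted editing index.
#' @export
simulate_and_run <- function(sim_cfg, conditions = NULL, dir = NULL, ...) {
  stopifnot(inherits(sim_cfg, "sim_config"))
  conditions <- conditions %||% sim_cfg$condition_labels
  dir <- dir %||% file.path(tempdir(), sprintf("thermedit_sim_%d", sim_cfg$seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  gg <- generate_genome(sim_cfg)
  planted <- plant_editing_clusters(gg, sim_cfg)
  fasta <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "genes.gtf")
  write_reference(planted$genome, fasta)
  write_gtf(gg$genes, gtf)
  read_paths <- list()
  truth_edits <- list()
  for (cd in conditions) {
    sim <- simulate_reads(planted$genome, planted$truth, cd, sim_cfg)
    p <- file.path(dir, paste0("reads_", cd, ".fq"))
    write_fastq(sim$reads, p)
    read_paths[[cd]] <- p
    truth_edits[[cd]] <- sim$read_edits
  }
  write_sites(planted$truth$sites, file.path(dir, "truth_sites.tsv"))
  write_bed(planted$truth$clusters |> mutate(name = .data$cluster_id),
            file.path(dir, "truth_clusters.bed"))

  cfg <- run_config(genome = fasta, gtf = gtf, reads = read_paths,
                    out_dir = file.path(dir, "out"), seed = sim_cfg$seed, ...)
  report <- run_pipeline(cfg)

  truth_sites <- planted$truth$sites
  evaluation <- map_dfr(conditions, function(cd) {
    called <- report$sites |> filter(.data$condition == cd)
    tp <- called |>
      semi_join(truth_sites, by = c("contig", "pos", "strand")) |> nrow()
    fp <- nrow(called) - tp
    rate_col <- paste0("rate_", cd)
    idx <- report$editing_index |> filter(.data$condition == cd)
    tibble(condition = cd,
           n_truth = nrow(truth_sites), n_called = nrow(called),
           tp = tp, fp = fp,
           sensitivity = tp / nrow(truth_sites),
           precision = if (nrow(called)) tp / nrow(called) else NA_real_,
           planted_rate = truth_sites[[rate_col]][1],
           editing_index = if (nrow(idx)) idx$index[1] else NA_real_)
  })
  list(report = report, truth = planted$truth, evaluation = evaluation,
       dir = dir)
}
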