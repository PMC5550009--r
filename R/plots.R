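# ggplot2 views of the report tables. Each function takes the tidy table
# its stage produced and returns a ggplot object.

#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_point geom_hline
#'   geom_vline geom_histogram facet_wrap labs theme_minimal autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the nucleotide context around editing sites
#' @param motif Tibble from [compute_motif()].
#' @return A ggplot: per-offset base frequencies; the G depletion at -1 and
#'   enrichment at +1 typical of ADAR targets stand out.
#' @export
plot_motif <- function(motif) {
  long <- motif |> pivot_longer(c("A", "C", "G", "T"),
                                names_to = "base", values_to = "frequency")
  ggplot(long, aes(x = .data$offset, y = .data$frequency,
                   colour = .data$base)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = 0, linetype = "dotted") +
    labs(x = "offset from edited adenosine (nt)", y = "base frequency",
         colour = NULL) +
    theme_minimal()
}

#' Plot the editing index per condition
#' @param index Tibble with `condition` and `index` columns (as in the
#'   pipeline report).
#' @return A ggplot bar chart.
#' @export
plot_editing_index <- function(index) {
  ggplot(index, aes(x = .data$condition, y = .data$index)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "editing index (G / (A + G))") +
    theme_minimal()
}

#' Plot the 12-type mismatch spectrum
#' @param spectrum Tibble from [qc_mismatch_spectrum()]'s `spectrum` element
#'   (optionally with a `condition` column).
#' @return A ggplot bar chart of unique sites per mismatch type.
#' @export
plot_mismatch_spectrum <- function(spectrum) {
  p <- ggplot(spectrum, aes(x = .data$type, y = .data$n_sites)) +
    geom_col(fill = "grey30") +
    labs(x = "mismatch type", y = "unique sites") +
    theme_minimal()
  if ("condition" %in% names(spectrum)) p <- p + facet_wrap(~condition)
  p
}

#' Plot conservation profiles by stratum
#' @param profile Tibble from [conservation_profile()].
#' @return A ggplot of mean score against offset, one line per stratum.
#' @export
plot_conservation_profile <- function(profile) {
  ggplot(profile, aes(x = .data$offset, y = .data$mean_score,
                      colour = .data$stratum)) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = "dotted") +
    labs(x = "offset from site (nt)", y = "mean conservation score",
         colour = NULL) +
    theme_minimal()
}

#' Volcano-style view of differential editing
#' @param object A `thermedit_diff` tibble from [differential_sites()].
#' @param ... Unused.
#' @return A ggplot of editing-level difference against -log10 q, coloured
#'   by significance.
#' @export
autoplot.thermedit_diff <- function(object, ...) {
  ggplot(object, aes(x = .data$delta, y = -log10(.data$q_value),
                     colour = .data$significant)) +
    geom_point(alpha = 0.7) +
    geom_vline(xintercept = c(-0.2, 0.2), linetype = "dotted") +
    labs(x = "editing-level difference (B - A)", y = "-log10 q",
         colour = "significant") +
    theme_minimal()
}

#' Null distribution of a gene-set editing bootstrap
#' @param object A `thermedit_bootstrap`.
#' @param ... Unused.
#' @return A ggplot histogram of the null indices with the observed index
#'   marked.
#' @export
autoplot.thermedit_bootstrap <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$null_index)) +
    geom_histogram(bins = 40, fill = "grey70") +
    geom_vline(xintercept = object$observed, colour = "firebrick") +
    labs(x = "null editing index", y = "draws") +
    theme_minimal()
}
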