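#' @importFrom ggplot2 ggplot aes geom_line geom_col geom_hline geom_point
#'   geom_boxplot facet_wrap labs theme_minimal autoplot
NULL

#' Plot a LOD curve
#'
#' LOD profile along the genome, faceted by chromosome, with an optional
#' genome-wide threshold line.
#'
#' @param scan An `epiqtl_scan`.
#' @param threshold Optional LOD threshold to draw.
#' @return A ggplot object.
#' @export
plot_lod_curve <- function(scan, threshold = NULL) {
  p <- ggplot(tibble::as_tibble(scan), aes(x = .data$cM, y = .data$lod)) +
    geom_line() +
    facet_wrap(~chrom, nrow = 1, scales = "free_x") +
    labs(x = "Position (cM)", y = "LOD") +
    theme_minimal()
  if (!is.null(threshold)) {
    p <- p + geom_hline(yintercept = as.numeric(threshold), linetype = "dashed")
  }
  p
}

#' @rdname plot_lod_curve
#' @param object An `epiqtl_scan`.
#' @param ... Passed on (`threshold`).
#' @method autoplot epiqtl_scan
#' @export
autoplot.epiqtl_scan <- function(object, ...) {
  plot_lod_curve(object, ...)
}

#' Plot remodeling scenario frequencies
#'
#' Genome-wide frequency of each of the five remodeling categories across
#' all region x family records.
#'
#' @param scenario_table Output of [classify_trios()].
#' @return A ggplot object.
#' @export
plot_scenario_frequencies <- function(scenario_table) {
  freq <- dplyr::count(scenario_table, .data$scenario)
  freq$frequency <- freq$n / sum(freq$n)
  ggplot(freq, aes(x = .data$scenario, y = .data$frequency)) +
    geom_col() +
    labs(x = NULL, y = "Frequency") +
    theme_minimal()
}

#' Plot the distribution of mid-parent heterosis across families
#'
#' @param mph_table Output of [compute_mph()].
#' @return A ggplot object.
#' @export
plot_mph_distribution <- function(mph_table) {
  d <- dplyr::arrange(mph_table, .data$mph)
  d$rank <- seq_len(nrow(d))
  ggplot(d, aes(x = .data$rank, y = .data$mph)) +
    geom_point(colour = "goldenrod") +
    geom_hline(yintercept = 0, linetype = "dashed") +
    labs(x = "Family (ranked)", y = "Mid-parent heterosis (%)") +
    theme_minimal()
}

#' Plot phenotypic QTL effects by epigenotype class
#'
#' Family MPH split by the MM/UU epigenotype at each retained QTL marker.
#'
#' @param pheno_qtl A `pheno_qtl` object.
#' @return A ggplot object.
#' @export
plot_qtl_effects <- function(pheno_qtl) {
  if (nrow(pheno_qtl$effect_data) == 0) {
    abort("No retained QTL to plot.")
  }
  ggplot(
    pheno_qtl$effect_data,
    aes(x = .data$epigenotype, y = .data$mph, fill = .data$epigenotype)
  ) +
    geom_boxplot() +
    facet_wrap(~marker_id) +
    labs(x = "Paternal epigenotype at QTL", y = "Mid-parent heterosis (%)") +
    theme_minimal()
}
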