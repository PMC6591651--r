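#' Plot per-sample heterozygosity maps
#'
#' Draws the cohort overview figure for one gene: per-position reference
#' fraction for every sample (one facet row per cohort when a sample sheet is
#' given), coloured by genotype call, with artifact-flagged positions marked.
#' An expressed heterozygous site sits near 0.5; hemizygous or silenced sites
#' sit near 1 (or 0 when only the alternative allele is expressed).
#'
#' @param map A [build_het_map()] result or calls tibble (may span samples).
#' @param samples Optional sample sheet with `sample`, `cohort` for faceting.
#' @param artifacts Optional `artifact_set`; flagged positions are drawn with
#'   an open symbol.
#' @return A ggplot object.
#' @export
plot_het_map <- function(map, samples = NULL, artifacts = NULL) {
  map <- as_tibble(map)
  if (!is.null(samples)) {
    map <- dplyr::left_join(map, as_tibble(samples)[c("sample", "cohort")],
      by = "sample"
    )
  }
  if (!is.null(artifacts)) {
    flagged_key <- paste(artifacts$flagged$gene, artifacts$flagged$pos)
    map$flagged <- paste(map$gene, map$pos) %in% flagged_key
  } else {
    map$flagged <- FALSE
  }
  p <- ggplot2::ggplot(
    map,
    ggplot2::aes(x = .data$pos, y = .data$ref_fraction, colour = .data$call)
  ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$flagged), size = 1.8) +
    ggplot2::scale_shape_manual(
      values = c(`FALSE` = 16, `TRUE` = 1),
      labels = c(`FALSE` = "kept", `TRUE` = "artifact"),
      name = NULL
    ) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "transcript position (1-based)",
      y = "reference-base fraction",
      colour = "call"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(samples)) {
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$cohort),
      cols = ggplot2::vars(.data$gene)
    )
  } else {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$gene))
  }
  p
}

#' Plot a detection-power surface
#'
#' Detection probability (per-sample, any-sample, and cohort-test rejection)
#' against the reactivation fraction `f`, one line per depth, faceted by the
#' probability type.
#'
#' @param object A `power_result` from [power_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = c("p_detect_sample", "p_detect_any", "p_reject"),
    names_to = "measure", values_to = "probability"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$y_fraction, y = .data$probability,
      colour = factor(.data$depth), group = factor(.data$depth)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "reactivation fraction f",
      y = "detection probability",
      colour = "depth"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
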