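# ggplot2 views of the package's result types.

#' MA plot of a differential-expression result
#'
#' Mean-expression vs log2 fold change, highlighting features that pass the
#' discovery filters when [apply_de_criteria()] has been run.
#'
#' @param object An `flc_de` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flc_de <- function(object, ...) {
  ct <- attr(object, "contrast")
  d <- tidy.flc_de(object)
  d$highlight <- if ("passes" %in% names(d)) d$passes else !is.na(d$fdr) & d$fdr < 0.05
  ggplot2::ggplot(d, ggplot2::aes(x = .data$base_mean, y = .data$log2fc)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlight), size = 0.6, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
      name = "passes filters"
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "mean normalized counts",
      y = "log2 fold change",
      title = paste(ct[["target"]], "vs", ct[["reference"]])
    )
}

#' Sample projection on the first two principal components
#'
#' @param object An `flc_pca` object.
#' @param labels Optional named (by sample id) vector of group labels used
#'   for colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flc_pca <- function(object, labels = NULL, ...) {
  d <- object$scores
  ev <- object$explained_variance
  if (!is.null(labels)) d$group <- unname(labels[d$sample_id])
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2])
    )
  if (!is.null(labels)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Plot a binned log-ratio profile with its segmentation
#'
#' @param profile An `flc_ratio_profile` from [compute_log_ratios()].
#' @param segments Optional segment tibble from [segment_cbs()].
#' @param target_interval Optional region (string or tibble) drawn as a
#'   shaded band.
#' @return A ggplot object.
#' @export
plot_cnv_profile <- function(profile, segments = NULL, target_interval = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = (.data$start + .data$end) / 2, y = .data$log2_ratio)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "genomic position", y = "log2 tumor/normal ratio") +
    ggplot2::facet_wrap(~chrom, scales = "free_x")
  if (!is.null(target_interval)) {
    if (is.character(target_interval)) target_interval <- parse_region(target_interval)
    p <- p + ggplot2::geom_rect(
      data = target_interval,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
      inherit.aes = FALSE
    )
  }
  if (!is.null(segments)) {
    p <- p + ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(
        x = .data$start, xend = .data$end,
        y = .data$seg_mean, yend = .data$seg_mean
      ),
      colour = "firebrick", linewidth = 1, inherit.aes = FALSE
    )
  }
  p
}

#' Plot separation margins of candidate signature features
#'
#' Shows each candidate's minimum target value against the comparator
#' quantile threshold; qualifying features sit above the diagonal.
#'
#' @param separation An `flc_separation` tibble from [quantile_separation()].
#' @return A ggplot object.
#' @export
plot_separation <- function(separation) {
  ggplot2::ggplot(
    separation,
    ggplot2::aes(x = .data$bg_upper, y = .data$min_target, colour = .data$qualifies)
  ) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "comparator quantile threshold",
      y = "minimum value across target samples"
    )
}
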