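# broom-style tidiers for the package's result objects.

#' Tidy a differential-expression result
#'
#' @param x An `flc_de` tibble.
#' @param ... Unused.
#' @return A plain tibble (one row per feature) with the test columns.
#' @export
tidy.flc_de <- function(x, ...) {
  out <- x
  attr(out, "contrast") <- NULL
  attr(out, "dispersion_trend") <- NULL
  attr(out, "size_factors") <- NULL
  class(out) <- class(tibble())
  out
}

#' Summarize a differential-expression result
#'
#' @param x An `flc_de` tibble.
#' @param ... Unused.
#' @return One-row tibble: contrast, n_tested, n_fdr05 (FDR < 0.05),
#'   n_pass (when filters were applied), and the fitted dispersion-trend
#'   coefficients.
#' @export
glance.flc_de <- function(x, ...) {
  ct <- attr(x, "contrast")
  tr <- attr(x, "dispersion_trend")
  tibble(
    contrast = paste(ct[["target"]], "vs", ct[["reference"]]),
    n_tested = sum(x$tested),
    n_fdr05 = sum(x$fdr < 0.05, na.rm = TRUE),
    n_pass = if ("passes" %in% names(x)) sum(x$passes) else NA_integer_,
    trend_a0 = tr[["a0"]], trend_a1 = tr[["a1"]]
  )
}

#' Tidy a PCA projection
#'
#' @param x An `flc_pca` object.
#' @param ... Unused.
#' @return The score tibble with one row per sample.
#' @export
tidy.flc_pca <- function(x, ...) x$scores

#' Summarize a PCA projection
#'
#' @param x An `flc_pca` object.
#' @param ... Unused.
#' @return One-row tibble of explained-variance proportions.
#' @export
glance.flc_pca <- function(x, ...) {
  ev <- x$explained_variance
  out <- as_tibble(as.list(setNames(ev, paste0("var_PC", seq_along(ev)))))
  out$zero_variance <- x$zero_variance
  out
}
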