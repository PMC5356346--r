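#' Median-of-ratios size factors
#'
#' The classic normalization of count-based RNA-seq: for each sample the size
#' factor is the median, over features with all-positive counts, of the ratio
#' of the sample's count to the feature's geometric mean across samples.
#'
#' @param counts Numeric matrix (features x samples) or a data frame with a
#'   feature column.
#' @return Named numeric vector of per-sample size factors, with the
#'   per-feature geometric means in attribute `"geomeans"`.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
#' size_factors(m) # c(1/sqrt(2), sqrt(2))
size_factors <- function(counts) {
  m <- as_count_matrix(counts)
  estimate_size_factors_mor(m)
}

estimate_size_factors_mor <- function(m) {
  logg <- rowMeans(log(m))
  use <- is.finite(logg)
  if (!any(use)) {
    data_error(paste(
      "No feature has positive counts in every sample;",
      "median-of-ratios is undefined. Filter features or supply size factors."
    ))
  }
  sf <- apply(m[use, , drop = FALSE], 2, function(k) exp(median(log(k) - logg[use])))
  attr(sf, "geomeans") <- exp(logg)
  sf
}

row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

# Fit the dispersion trend alpha(mu) = a0 + a1/mu by gamma-family regression
# on per-feature method-of-moments estimates, with iterative trimming of
# gross outliers. Falls back to trimmed least squares if the GLM fails.
fit_dispersion_trend <- function(mu, disp) {
  ok <- is.finite(disp) & disp > 1e-8 & is.finite(mu) & mu > 1
  if (sum(ok) < 10L) {
    return(c(a0 = 0.01, a1 = 1))
  }
  d <- disp[ok]
  x <- 1 / mu[ok]
  co <- NULL
  for (it in 1:10) {
    fit <- tryCatch(
      suppressWarnings(
        glm(d ~ x, family = Gamma(link = "identity"), start = co %||% c(0.1, 1))
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) break
    co_new <- coef(fit)
    pred <- pmax(co_new[1] + co_new[2] * x, 1e-10)
    keep <- d / pred > 1e-4 & d / pred < 15
    if (!is.null(co) && all(abs(co_new - co) < 1e-6 * (abs(co) + 1e-6))) {
      co <- co_new
      break
    }
    co <- co_new
    if (all(keep)) break
    d <- d[keep]
    x <- x[keep]
    if (length(d) < 10L) break
  }
  if (is.null(co) || any(!is.finite(co))) {
    # least-squares fallback
    X <- cbind(1, x)
    co <- tryCatch(qr.solve(X, d), error = function(e) c(0.01, 1))
  }
  c(a0 = max(as.numeric(co[1]), 1e-8), a1 = max(as.numeric(co[2]), 0))
}

#' Two-group negative-binomial Wald test
#'
#' Normalizes counts by median-of-ratios size factors, estimates per-feature
#' dispersions by method of moments on normalized counts, shrinks them toward
#' a fitted mean-dispersion trend \eqn{\alpha(\mu) = a_0 + a_1/\mu} using the
#' conservative rule \eqn{\alpha = \max(\alpha_{feature},
#' \alpha_{trend}(\mu))}, and tests the log2 fold change between the groups
#' with a Wald statistic whose variance is the delta-method (plug-in)
#' variance of the log normalized group means. P-values are two-sided normal;
#' the false discovery rate is Benjamini-Hochberg across features with
#' non-zero total counts.
#'
#' @param counts Numeric matrix (features x samples) or data frame with a
#'   feature column.
#' @param groups Character/factor vector assigning each sample (column) to a
#'   group.
#' @param contrast `c(target, reference)`: fold changes are reported as
#'   target over reference.
#' @param size_factors Optional per-sample size factors (otherwise estimated
#'   on the contrasted samples).
#' @param pseudocount Pseudocount `c` added to normalized group means in the
#'   fold change `(mean_target + c)/(mean_ref + c)`; default 1.
#' @param dispersion_trend Optional fixed `c(a0, a1)` (otherwise fitted).
#' @return Tibble of class `flc_de`: feature, base_mean, mean_ref,
#'   mean_target, log2fc, fold_change, dispersion, stat, p_value, fdr,
#'   tested. Attributes: `contrast`, `dispersion_trend`, `size_factors`.
#' @export
nb_test <- function(counts, groups, contrast = NULL, size_factors = NULL,
                    pseudocount = 1, dispersion_trend = NULL) {
  m <- as_count_matrix(counts)
  groups <- as.character(groups)
  if (length(groups) != ncol(m)) data_error("`groups` must have one entry per sample.")
  if (is.null(contrast)) {
    lv <- unique(groups)
    if (length(lv) != 2L) data_error("Supply `contrast = c(target, reference)` when groups has != 2 levels.")
    contrast <- c(lv[2], lv[1])
  }
  target <- contrast[1]
  ref <- contrast[2]
  sel <- groups %in% c(target, ref)
  m <- m[, sel, drop = FALSE]
  g <- groups[sel]
  n_t <- sum(g == target)
  n_r <- sum(g == ref)
  if (n_t < 2L || n_r < 2L) {
    data_error("Both groups need n >= 2; single-replicate designs are refused.")
  }
  sf <- size_factors %||% estimate_size_factors_mor(m)
  if (length(sf) != ncol(m)) {
    # caller passed factors for the full sample set
    if (!is.null(names(sf))) sf <- sf[colnames(m)] else data_error("size_factors length mismatch.")
  }
  z <- sweep(m, 2, sf, "/")
  zt <- z[, g == target, drop = FALSE]
  zr <- z[, g == ref, drop = FALSE]
  mt <- rowMeans(zt)
  mr <- rowMeans(zr)
  vt <- row_vars(zt)
  vr <- row_vars(zr)
  base_mean <- rowMeans(z)

  xi_t <- mean(1 / sf[g == target])
  xi_r <- mean(1 / sf[g == ref])
  raw_t <- ifelse(mt > 0, (vt - xi_t * mt) / mt^2, NA_real_)
  raw_r <- ifelse(mr > 0, (vr - xi_r * mr) / mr^2, NA_real_)
  w_t <- n_t - 1L
  w_r <- n_r - 1L
  raw <- dplyr::case_when(
    is.na(raw_t) & is.na(raw_r) ~ NA_real_,
    is.na(raw_t) ~ raw_r,
    is.na(raw_r) ~ raw_t,
    TRUE ~ (w_t * raw_t + w_r * raw_r) / (w_t + w_r)
  )

  trend <- dispersion_trend %||% fit_dispersion_trend(base_mean, raw)
  trend <- c(a0 = max(trend[[1]], 1e-8), a1 = max(trend[[2]], 0))
  disp_trend <- trend[["a0"]] + trend[["a1"]] / pmax(base_mean, 1e-8)
  disp <- pmax(pmin(ifelse(is.na(raw) | raw < 0, 0, raw), 50), disp_trend)

  cc <- pseudocount
  mt_c <- mt + cc
  mr_c <- mr + cc
  log2fc <- log2(mt_c / mr_c)
  var_log_t <- sum(1 / sf[g == target]) / (n_t^2 * mt_c) + disp / n_t
  var_log_r <- sum(1 / sf[g == ref]) / (n_r^2 * mr_c) + disp / n_r
  stat <- log(mt_c / mr_c) / sqrt(var_log_t + var_log_r)
  p <- 2 * pnorm(-abs(stat))
  tested <- rowSums(m) > 0
  fdr <- rep(NA_real_, length(p))
  fdr[tested] <- p.adjust(p[tested], method = "BH")

  out <- tibble(
    feature = rownames(m),
    base_mean = base_mean,
    mean_ref = mr, mean_target = mt,
    log2fc = log2fc, fold_change = 2^log2fc,
    dispersion = disp, stat = stat,
    p_value = p, fdr = fdr, tested = tested
  )
  attr(out, "contrast") <- c(target = target, reference = ref)
  attr(out, "dispersion_trend") <- trend
  attr(out, "size_factors") <- sf
  class(out) <- c("flc_de", class(out))
  out
}

#' Apply differential-expression filters
#'
#' The discovery filter applied per contrast: absolute fold change (in either
#' direction) at least `fc_min`, FDR below `fdr_max`, and — when
#' `floor_required` — more than `count_floor` normalized counts on average in
#' at least one of the two groups. The count floor is the gene-level rule;
#' lincRNA discovery drops it (`floor_required = FALSE`).
#'
#' @param result An `flc_de` tibble from [nb_test()].
#' @param fc_min Minimum fold change.
#' @param fdr_max FDR threshold.
#' @param count_floor Normalized-count floor on the larger group mean.
#' @param floor_required Enforce the count floor.
#' @return `result` with logical columns passes_fc, passes_fdr, passes_floor
#'   and passes.
#' @export
apply_de_criteria <- function(result, fc_min = 2, fdr_max = 0.05,
                              count_floor = 50, floor_required = TRUE) {
  out <- dplyr::mutate(
    result,
    passes_fc = pmax(.data$fold_change, 1 / .data$fold_change) >= fc_min,
    passes_fdr = !is.na(.data$fdr) & .data$fdr < fdr_max,
    passes_floor = !floor_required |
      pmax(.data$mean_ref, .data$mean_target) > count_floor,
    passes = .data$passes_fc & .data$passes_fdr & .data$passes_floor
  )
  class(out) <- unique(c("flc_de", class(out)))
  out
}

#' Features passing both contrasts with concordant direction
#'
#' Intersects the pass sets of two filtered contrasts (e.g. target vs each of
#' two comparator cohorts) and keeps features whose log2 fold changes have the
#' same sign in both.
#'
#' @param de_a,de_b Filtered `flc_de` tibbles (after [apply_de_criteria()]).
#' @return Tibble: feature, log2fc_a, log2fc_b, direction ("up"/"down").
#' @export
concordant_intersection <- function(de_a, de_b) {
  if (!"passes" %in% names(de_a) || !"passes" %in% names(de_b)) {
    data_error("Run apply_de_criteria() on both results first.")
  }
  a <- dplyr::select(dplyr::filter(de_a, .data$passes), "feature", log2fc_a = "log2fc")
  b <- dplyr::select(dplyr::filter(de_b, .data$passes), "feature", log2fc_b = "log2fc")
  dplyr::inner_join(a, b, by = "feature") |>
    dplyr::filter(sign(.data$log2fc_a) == sign(.data$log2fc_b), .data$log2fc_a != 0) |>
    dplyr::mutate(direction = ifelse(.data$log2fc_a > 0, "up", "down"))
}

# Two-sided Mann-Whitney p: exact enumeration when the pooled sample is small
# and untied, tie-corrected normal approximation otherwise.
rank_sum_p <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) data_error("Both groups need n >= 1.")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(1)
  }
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && length(pooled) <= 20L) {
    wilcox.test(a, b, exact = TRUE)$p.value
  } else {
    wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  }
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' The validation-cohort test: exact when the pooled sample size is at most
#' 20 with no ties, tie-corrected normal approximation otherwise.
#'
#' @param values_a,values_b Numeric vectors.
#' @return One-row tibble: n_a, n_b, statistic (U for `values_a`), p_value,
#'   method.
#' @export
#' @examples
#' validate_rank_sum(c(1, 2, 3), c(4, 5, 6)) # p = 0.1
validate_rank_sum <- function(values_a, values_b) {
  p <- rank_sum_p(values_a, values_b)
  u <- sum(rank(c(values_a, values_b))[seq_along(values_a)]) -
    length(values_a) * (length(values_a) + 1) / 2
  tibble(
    n_a = length(values_a), n_b = length(values_b),
    statistic = u, p_value = p,
    method = if (length(c(values_a, values_b)) <= 20L &&
      anyDuplicated(c(values_a, values_b)) == 0L) {
      "exact"
    } else {
      "normal approximation"
    }
  )
}
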