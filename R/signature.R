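#' Quantile-separation marker selection
#'
#' The signature rule: among candidate features, a feature up-qualifies iff
#' every target-cohort sample's normalized value exceeds the q-th empirical
#' quantile of the pooled comparator samples, and down-qualifies iff every
#' target sample lies below the (1-q)-th quantile. The quantile is the
#' linear-interpolation estimator between order statistics
#' ([stats::quantile] type 7). Run at q = 0.95 this reproduces the mRNA
#' signature rule ("all target samples beyond 95% of comparator samples");
#' relaxing q enlarges the qualify set monotonically (the 95% to 90%
#' relaxation used for lincRNAs).
#'
#' @param normalized Numeric matrix of normalized values (features x samples)
#'   or data frame with a feature column.
#' @param target_samples,comparator_samples Column names (or logical/integer
#'   indices) of the target cohort and the pooled comparators.
#' @param q Separation quantile in (0, 1).
#' @param candidate_features Optional feature subset (defaults to all rows;
#'   typically the concordant DE set).
#' @return Tibble of class `flc_separation`: feature, direction ("up",
#'   "down" or NA), min_target, max_target, bg_upper (q-quantile), bg_lower
#'   ((1-q)-quantile), margin, qualifies.
#' @export
quantile_separation <- function(normalized, target_samples, comparator_samples,
                                q = 0.95, candidate_features = NULL) {
  if (q <= 0 || q >= 1) config_error("`q` must be in (0, 1).")
  m <- as_count_matrix(normalized)
  tgt <- m[, target_samples, drop = FALSE]
  cmp <- m[, comparator_samples, drop = FALSE]
  if (ncol(tgt) < 1L || ncol(cmp) < 2L) {
    data_error("Need >= 1 target and >= 2 comparator samples.")
  }
  if (!is.null(candidate_features)) {
    if (is.data.frame(candidate_features)) candidate_features <- candidate_features$feature
    missing <- setdiff(candidate_features, rownames(m))
    if (length(missing) > 0L) {
      data_error(sprintf("%d candidate features absent from the matrix.", length(missing)))
    }
    tgt <- tgt[candidate_features, , drop = FALSE]
    cmp <- cmp[candidate_features, , drop = FALSE]
  }
  min_t <- unname(apply(tgt, 1, min))
  max_t <- unname(apply(tgt, 1, max))
  hi <- unname(apply(cmp, 1, quantile, probs = q, type = 7, names = FALSE))
  lo <- unname(apply(cmp, 1, quantile, probs = 1 - q, type = 7, names = FALSE))
  up <- min_t > hi
  down <- max_t < lo
  out <- tibble(
    feature = rownames(tgt),
    direction = dplyr::case_when(up ~ "up", down ~ "down", TRUE ~ NA_character_),
    min_target = min_t, max_target = max_t,
    bg_upper = hi, bg_lower = lo,
    margin = dplyr::case_when(up ~ min_t - hi, down ~ lo - max_t, TRUE ~ pmax(min_t - hi, lo - max_t)),
    qualifies = up | down
  )
  attr(out, "q") <- q
  class(out) <- c("flc_separation", class(out))
  out
}

#' Rank signature features across tumor types
#'
#' For each feature and tumor type, computes the fold change of mean tumor
#' expression over mean matched-normal expression (with pseudocount `c`), and
#' ranks the target tumor type (descending, rank 1 = highest) on (i) that
#' fold change and (ii) mean tumor abundance. For abundance-rank-1 features
#' the ratio of the target mean to the next-highest tumor type's mean is
#' reported; this is the statistic behind statements like "6.4-fold more
#' highly expressed than the tumor type with the next highest expression".
#' Tumor types without a matched-normal mean are excluded.
#'
#' @param per_type_means Tibble with columns feature, tumor_type, tumor_mean,
#'   normal_mean (NA normal_mean excludes the type).
#' @param target_type The tumor type whose ranks are reported (e.g. "FLC").
#' @param pseudocount Pseudocount for the fold change.
#' @return Tibble of class `flc_cross_rank`: feature, target_mean,
#'   target_fold_change, fc_rank, abundance_rank, ratio_to_next,
#'   n_tumor_types.
#' @export
cross_tumor_rank <- function(per_type_means, target_type = "FLC", pseudocount = 1) {
  need <- c("feature", "tumor_type", "tumor_mean", "normal_mean")
  if (!all(need %in% names(per_type_means))) {
    data_error("`per_type_means` needs feature, tumor_type, tumor_mean, normal_mean.")
  }
  d <- dplyr::filter(as_tibble(per_type_means), !is.na(.data$normal_mean))
  if (!target_type %in% d$tumor_type) {
    data_error(sprintf("No matched-normal mean for target type '%s'.", target_type))
  }
  cc <- pseudocount
  d <- dplyr::mutate(d, fold_change = (.data$tumor_mean + cc) / (.data$normal_mean + cc))
  out <- d |>
    dplyr::group_by(.data$feature) |>
    dplyr::group_modify(function(g, key) {
      if (!target_type %in% g$tumor_type) {
        return(tibble(
          target_mean = NA_real_, target_fold_change = NA_real_,
          fc_rank = NA_integer_, abundance_rank = NA_integer_,
          ratio_to_next = NA_real_, n_tumor_types = nrow(g)
        ))
      }
      is_t <- g$tumor_type == target_type
      fc_rank <- rank(-g$fold_change, ties.method = "min")[is_t]
      ab_rank <- rank(-g$tumor_mean, ties.method = "min")[is_t]
      others <- g$tumor_mean[!is_t]
      tibble(
        target_mean = g$tumor_mean[is_t],
        target_fold_change = g$fold_change[is_t],
        fc_rank = as.integer(fc_rank),
        abundance_rank = as.integer(ab_rank),
        ratio_to_next = if (length(others) > 0 && max(others) > 0) {
          g$tumor_mean[is_t] / max(others)
        } else {
          NA_real_
        },
        n_tumor_types = nrow(g)
      )
    }) |>
    dplyr::ungroup()
  class(out) <- c("flc_cross_rank", class(out))
  out
}

#' Contrast signature features against developmental lineage stages
#'
#' Flags each signature feature as up-regulated in a disease model (e.g. an
#' FLC patient-derived xenograft) iff its model mean exceeds the mean of
#' *every* other lineage stage (biliary tree stem cells, hepatic stem cells,
#' hepatoblasts, adult hepatocytes) by at least `fold`.
#'
#' @param expr Tibble with columns feature, stage, value (one row per
#'   replicate).
#' @param signature_features Features to report.
#' @param model_stage Stage label of the disease model.
#' @param fold Minimum fold elevation over every stage.
#' @return Tibble: feature, model_mean, max_other_mean, up.
#' @export
lineage_contrast <- function(expr, signature_features, model_stage = "FLC_PDX",
                             fold = 2) {
  if (!all(c("feature", "stage", "value") %in% names(expr))) {
    data_error("`expr` needs feature, stage, value columns.")
  }
  if (!model_stage %in% expr$stage) {
    data_error(sprintf("Stage '%s' absent from `expr`.", model_stage))
  }
  means <- expr |>
    dplyr::filter(.data$feature %in% signature_features) |>
    dplyr::group_by(.data$feature, .data$stage) |>
    dplyr::summarise(mean_value = mean(.data$value), .groups = "drop")
  means |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      model_mean = .data$mean_value[.data$stage == model_stage][1],
      max_other_mean = max(.data$mean_value[.data$stage != model_stage]),
      .groups = "drop"
    ) |>
    dplyr::mutate(up = .data$model_mean > fold * .data$max_other_mean)
}
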