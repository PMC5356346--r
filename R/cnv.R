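#' Per-bin log2 tumor/normal coverage ratios
#'
#' Computes per-bin log2 ratios \eqn{\log_2(t_b/n_b)} of tumor over
#' matched-normal coverage from a BED-like table. Bins with zero normal
#' coverage are masked (`log2_ratio = NA`). With `depth_normalize = TRUE`
#' each library is first divided by its total,
#' \eqn{\log_2((t_b/T)/(n_b/N))} — useful when the two libraries were
#' sequenced to different depths; the default is the literal matched-pair
#' ratio.
#'
#' @param bins Tibble with columns chrom, start, end, tumor_count,
#'   normal_count (e.g. from [simulate_binned_coverage()] or a BED-like TSV).
#' @param depth_normalize Divide each library by its total first.
#' @return `bins` with `log2_ratio` and `masked` columns, class
#'   `flc_ratio_profile`.
#' @export
compute_log_ratios <- function(bins, depth_normalize = FALSE) {
  need <- c("chrom", "start", "end", "tumor_count", "normal_count")
  if (!all(need %in% names(bins))) {
    data_error("`bins` needs columns chrom, start, end, tumor_count, normal_count.")
  }
  if (all(bins$normal_count == 0)) data_error("All normal counts are zero.")
  t_tot <- sum(bins$tumor_count)
  n_tot <- sum(bins$normal_count)
  scale <- if (depth_normalize) n_tot / t_tot else 1
  out <- dplyr::mutate(
    as_tibble(bins),
    masked = .data$normal_count == 0,
    log2_ratio = ifelse(.data$masked, NA_real_,
      log2(scale * .data$tumor_count / .data$normal_count)
    )
  )
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  class(out) <- c("flc_ratio_profile", setdiff(class(out), "flc_ratio_profile"))
  out
}

# Max circular two-sample statistic over arcs (i, j] of x.
# Returns list(stat, i, j) with 0-based boundaries into x.
# For every arc with min_width <= |arc| and min_width <= |complement|:
#   T = |mean(arc) - mean(complement)| / (s * sqrt(1/k + 1/(n-k)))
# with s the segment-wide sd (the permutation reference uses the same
# statistic, so the scale constant cancels).
max_arc_stat <- function(x, min_width, pairs) {
  n <- length(x)
  s <- cumsum(x)
  tot <- s[n]
  a <- c(0, s)[pairs$i + 1L]
  b <- c(0, s)[pairs$j + 1L]
  arc <- b - a
  k <- pairs$j - pairs$i
  stat <- abs(arc / k - (tot - arc) / (n - k)) / sqrt(1 / k + 1 / (n - k))
  w <- which.max(stat)
  list(stat = stat[w], i = pairs$i[w], j = pairs$j[w])
}

arc_pairs <- function(n, min_width) {
  ij <- which(upper.tri(matrix(0, n + 1L, n + 1L)), arr.ind = TRUE) - 1L
  i <- ij[, 1L]
  j <- ij[, 2L]
  k <- j - i
  keep <- k >= min_width & (n - k) >= min_width
  list(i = i[keep], j = j[keep])
}

# Recursive binary segmentation of one chromosome's bin values.
cbs_recurse <- function(x, offset, alpha, n_perm, min_width, batch = 100L) {
  n <- length(x)
  if (n < 2L * min_width || sd(x) == 0) {
    return(tibble(from = offset + 1L, to = offset + n))
  }
  pairs <- arc_pairs(n, min_width)
  if (length(pairs$i) == 0L) {
    return(tibble(from = offset + 1L, to = offset + n))
  }
  obs <- max_arc_stat(x, min_width, pairs)
  # Permutation p-value with early stopping: once the exceedance count
  # guarantees p >= alpha, the split cannot be accepted.
  stop_at <- ceiling(alpha * n_perm)
  exceed <- 0L
  done <- 0L
  while (done < n_perm && exceed < stop_at) {
    m <- min(batch, n_perm - done)
    for (b in seq_len(m)) {
      perm <- max_arc_stat(x[sample.int(n)], min_width, pairs)
      if (perm$stat >= obs$stat) exceed <- exceed + 1L
    }
    done <- done + m
    if (exceed >= stop_at) break
  }
  p <- if (done < n_perm) 1 else exceed / n_perm
  if (p >= alpha) {
    return(tibble(from = offset + 1L, to = offset + n))
  }
  # Accepted split at arc (i, j]: up to three children.
  parts <- list()
  if (obs$i > 0L) parts <- c(parts, list(c(1L, obs$i)))
  parts <- c(parts, list(c(obs$i + 1L, obs$j)))
  if (obs$j < n) parts <- c(parts, list(c(obs$j + 1L, n)))
  dplyr::bind_rows(lapply(parts, function(pr) {
    cbs_recurse(x[pr[1]:pr[2]], offset + pr[1] - 1L, alpha, n_perm, min_width, batch)
  }))
}

#' Segment a log-ratio profile by circular binary segmentation
#'
#' Recursive change-point search: within each segment the arc (i, j] that
#' maximizes the circular two-sample statistic is found, and the split is
#' accepted when its permutation p-value is below `alpha`. This is the
#' standard max-|t|-over-arcs CBS recursion with a permutation reference;
#' the pruning/undo refinements of the full published procedure are omitted,
#' which leaves the segment contract (a maximal tiling of significant
#' mean shifts) unchanged.
#'
#' @param profile An `flc_ratio_profile` from [compute_log_ratios()].
#' @param alpha Significance level for accepting a split.
#' @param n_perm Number of bin permutations per tested split.
#' @param min_width Minimum segment width in bins.
#' @param seed Integer seed for the permutation RNG.
#' @return Tibble of segments: chrom, start, end, n_bins, seg_mean, tiling
#'   each chromosome's unmasked bins.
#' @export
segment_cbs <- function(profile, alpha = 0.01, n_perm = 1000L, min_width = 3L,
                        seed = 1L) {
  if (!all(c("chrom", "start", "end", "log2_ratio") %in% names(profile))) {
    data_error("`profile` must come from compute_log_ratios().")
  }
  alpha <- check_number(alpha, "alpha", min = 0, max = 1)
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  min_width <- check_count(min_width, "min_width", min = 1L)
  prof <- dplyr::filter(profile, !isTRUE(.data$masked), is.finite(.data$log2_ratio))
  if (nrow(prof) < min_width) {
    warn("Too few unmasked bins; returning a single segment.")
    prof <- dplyr::filter(profile, is.finite(.data$log2_ratio))
  }
  withr::with_seed(seed, {
    out <- prof |>
      dplyr::group_by(.data$chrom) |>
      dplyr::group_modify(function(d, key) {
        d <- dplyr::arrange(d, .data$start)
        segs <- if (nrow(d) < 2L * min_width) {
          tibble(from = 1L, to = nrow(d))
        } else {
          cbs_recurse(d$log2_ratio, 0L, alpha, n_perm, min_width)
        }
        dplyr::mutate(segs,
          start = d$start[.data$from],
          end = d$end[.data$to],
          n_bins = .data$to - .data$from + 1L,
          seg_mean = vapply(
            seq_len(nrow(segs)),
            function(r) mean(d$log2_ratio[segs$from[r]:segs$to[r]]),
            numeric(1)
          )
        )
      }) |>
      dplyr::ungroup() |>
      dplyr::select("chrom", "start", "end", "n_bins", "seg_mean") |>
      dplyr::arrange(.data$chrom, .data$start)
  })
  class(out) <- c("flc_segments", class(out))
  out
}

#' Parse a 1-based "chrom:start-end" region into 0-based half-open form
#'
#' @param region String like `"chr19:14239803-14624494"` (1-based inclusive,
#'   the convention of the published deletion interval).
#' @return Tibble with chrom, start (0-based), end (half-open).
#' @export
parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) data_error("Region must look like 'chr19:14239803-14624494'.")
  tibble(
    chrom = m[2],
    start = as.numeric(m[3]) - 1,
    end = as.numeric(m[4])
  )
}

#' Call a focal deletion from segmented copy-ratio data
#'
#' Reproduces the deletion filter applied to segmented copy-number profiles:
#' the deletion is supported iff some segment completely encompasses the
#' target interval (segment start <= target start and segment end >= target
#' end) and has segment mean at or below `mean_threshold`.
#'
#' @param segments Segment tibble (from [segment_cbs()] or level-3 style
#'   segmented input with chrom, start, end, seg_mean).
#' @param target_interval Tibble from [parse_region()] or a region string;
#'   default the published fusion-deletion interval
#'   `chr19:14239803-14624494`.
#' @param mean_threshold Maximum segment mean (log2) for support.
#' @param sample_id Label for the output row.
#' @return One-row tibble: sample_id, supported, and the supporting segment's
#'   coordinates and mean (NA when unsupported).
#' @export
filter_deletion <- function(segments,
                            target_interval = "chr19:14239803-14624494",
                            mean_threshold = -0.1,
                            sample_id = "sample") {
  if (is.character(target_interval)) target_interval <- parse_region(target_interval)
  if (!all(c("chrom", "start", "end", "seg_mean") %in% names(segments))) {
    data_error("`segments` needs chrom, start, end, seg_mean.")
  }
  tgt <- target_interval
  if (!any(segments$chrom == tgt$chrom)) {
    data_error(sprintf("Target chromosome '%s' absent from segments.", tgt$chrom))
  }
  hits <- dplyr::filter(
    segments,
    .data$chrom == tgt$chrom,
    .data$start <= tgt$start,
    .data$end >= tgt$end,
    .data$seg_mean <= mean_threshold
  )
  if (nrow(hits) > 0L) {
    hit <- dplyr::slice_min(hits, .data$seg_mean, n = 1L, with_ties = FALSE)
    tibble(
      sample_id = sample_id, supported = TRUE,
      seg_chrom = hit$chrom, seg_start = hit$start, seg_end = hit$end,
      seg_mean = hit$seg_mean
    )
  } else {
    tibble(
      sample_id = sample_id, supported = FALSE,
      seg_chrom = NA_character_, seg_start = NA_real_, seg_end = NA_real_,
      seg_mean = NA_real_
    )
  }
}

#' Write segments in SEG format
#'
#' @param segments Segment tibble.
#' @param path Output TSV path.
#' @param sample_id Sample label for the first column.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path, sample_id = "sample") {
  seg <- tibble(
    ID = sample_id, chrom = segments$chrom,
    loc.start = segments$start, loc.end = segments$end,
    num.mark = segments$n_bins, seg.mean = segments$seg_mean
  )
  readr::write_tsv(seg, path)
  invisible(path)
}
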