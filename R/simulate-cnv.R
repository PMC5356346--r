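#' Specify simulated binned tumor/normal coverage with a planted deletion
#'
#' Emulates the 10 kb-bin coverage profiles used to confirm the focal
#' heterozygous chr19 deletion underlying the DNAJB1-PRKACA fusion: per-bin
#' tumor and matched-normal coverage where bins inside the deleted interval
#' have expected log2(tumor/normal) equal to `deletion_log2` and all other
#' bins 0, with Gaussian noise on the log2 ratio. The default planted ratio
#' (-0.15) reflects a heterozygous deletion diluted by tumor purity.
#'
#' @param n_bins Number of bins.
#' @param bin_width Bin width in bp (default 10 kb).
#' @param deleted_interval Integer `c(start_bin, end_bin)`, 0-based half-open
#'   in bin units; `NULL` for a deletion-free profile.
#' @param deletion_log2 Expected log2 tumor/normal ratio inside the deletion.
#' @param noise_sd Per-bin Gaussian noise sd on the log2 ratio.
#' @param depth_normal,depth_tumor Mean per-bin coverage.
#' @param chrom Chromosome label for the emitted bins.
#' @param chrom_offset Genomic start of bin 0 (lets the planted interval sit
#'   at arbitrary coordinates, e.g. around chr19:14.2 Mb).
#' @param seed Integer seed.
#' @return A list of class `flc_deletion_spec`.
#' @export
deletion_sim_spec <- function(n_bins = 200L,
                              bin_width = 10000L,
                              deleted_interval = c(22L, 64L),
                              deletion_log2 = -0.15,
                              noise_sd = 0.05,
                              depth_normal = 500,
                              depth_tumor = 500,
                              chrom = "chr19",
                              chrom_offset = 14000000L,
                              seed = 1L) {
  n_bins <- check_count(n_bins, "n_bins", 1L)
  bin_width <- check_count(bin_width, "bin_width", 1L)
  if (!is.null(deleted_interval)) {
    if (length(deleted_interval) != 2L ||
      deleted_interval[1] < 0L || deleted_interval[2] > n_bins ||
      deleted_interval[1] > deleted_interval[2]) {
      config_error("`deleted_interval` must be c(start_bin, end_bin) within [0, n_bins].")
    }
    deleted_interval <- as.integer(deleted_interval)
  }
  if (depth_normal <= 0 || depth_tumor <= 0) config_error("Depths must be > 0.")
  structure(list(
    n_bins = n_bins, bin_width = bin_width, deleted_interval = deleted_interval,
    deletion_log2 = check_number(deletion_log2, "deletion_log2"),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    depth_normal = depth_normal, depth_tumor = depth_tumor,
    chrom = chrom, chrom_offset = check_count(chrom_offset, "chrom_offset"),
    seed = check_count(seed, "seed")
  ), class = "flc_deletion_spec")
}

#' Simulate binned tumor/normal coverage
#'
#' Produces a BED-like tibble of fixed-width bins with tumor and normal
#' coverage. Normal coverage is held at `depth_normal`; tumor coverage is
#' `depth_tumor * 2^(mu_b + eps_b)` with `mu_b` the planted log2 ratio and
#' `eps_b ~ N(0, noise_sd)`, so the noiseless profile reproduces the planted
#' ratios exactly. Coverage values are real-valued depth estimates, not
#' integer read counts.
#'
#' @param spec A [deletion_sim_spec()].
#' @return Tibble of class `flc_bins_sim` with columns chrom, start, end,
#'   bin_id, tumor_count, normal_count, and attribute `truth` (planted
#'   interval and log2 ratio).
#' @export
simulate_binned_coverage <- function(spec) {
  if (!inherits(spec, "flc_deletion_spec")) config_error("`spec` must come from deletion_sim_spec().")
  mu <- rep(0, spec$n_bins)
  if (!is.null(spec$deleted_interval) && diff(spec$deleted_interval) > 0) {
    idx <- seq(spec$deleted_interval[1] + 1L, spec$deleted_interval[2])
    mu[idx] <- spec$deletion_log2
  }
  eps <- withr::with_seed(spec$seed, rnorm(spec$n_bins, 0, spec$noise_sd))
  start <- spec$chrom_offset + (seq_len(spec$n_bins) - 1L) * spec$bin_width
  bins <- tibble(
    chrom = spec$chrom,
    start = start,
    end = start + spec$bin_width,
    bin_id = seq_len(spec$n_bins) - 1L,
    tumor_count = spec$depth_tumor * 2^(mu + eps),
    normal_count = rep(as.numeric(spec$depth_normal), spec$n_bins)
  )
  truth <- tibble(
    deleted_start_bin = if (is.null(spec$deleted_interval)) NA_integer_ else spec$deleted_interval[1],
    deleted_end_bin = if (is.null(spec$deleted_interval)) NA_integer_ else spec$deleted_interval[2],
    deletion_log2 = spec$deletion_log2
  )
  attr(bins, "truth") <- truth
  class(bins) <- c("flc_bins_sim", class(bins))
  bins
}
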