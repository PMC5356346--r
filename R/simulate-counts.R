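#' Specify a synthetic multi-cohort RNA-seq count experiment
#'
#' Builds the specification consumed by [simulate_counts()]. The generator
#' draws negative-binomial counts with a per-sample depth factor, a per-feature
#' baseline mean, and a mean-dispersion trend \eqn{\alpha(\mu) = a_0 + a_1/\mu},
#' i.e. \eqn{Var = \mu + \alpha \mu^2} — the model family the downstream
#' differential-expression stage assumes. Selected features ("planted") are
#' up-regulated by a known log2 effect in the tumor samples of one target
#' cohort, giving every run a ground truth for precision/recall.
#'
#' The defaults emulate the study conditions the pipeline was designed for:
#' three tumor cohorts of 6 (FLC-like), 60 (HCC-like) and 30 (CCA-like)
#' samples, 10,000 features, and 16 planted FLC-up signature features at
#' log2 effect 5 — strong enough that the planted markers separate cleanly
#' from the comparator background, as the real signature genes do.
#'
#' @param cohorts Data frame with columns `name`, `n_tumor`, `n_normal`.
#' @param n_features Total number of features simulated.
#' @param planted_up Data frame with columns `feature_id`, `target_cohort`,
#'   `log2_effect` (all effects > 0; up-regulation in the target cohort's
#'   tumor samples).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters for background
#'   feature baseline means.
#' @param planted_meanlog,planted_sdlog Log-normal parameters for planted
#'   feature baseline means (kept moderately expressed so planted markers are
#'   recoverable by construction).
#' @param library_size_logsd Standard deviation (natural log scale) of the
#'   per-sample depth multipliers.
#' @param size_factors Optional explicit per-sample depth multipliers
#'   (overrides `library_size_logsd`); recycled checks apply.
#' @param dispersion_trend Numeric `c(a0, a1)` of the dispersion trend
#'   \eqn{\alpha(\mu) = a_0 + a_1/\mu}.
#' @param seed Integer seed; identical specs give bit-identical output.
#' @return A list of class `flc_cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_features = 200, seed = 1)
#' sim <- simulate_counts(spec)
#' dim(sim$counts)
cohort_spec <- function(cohorts = tibble(
                          name = c("FLC", "HCC", "CCA"),
                          n_tumor = c(6L, 60L, 30L),
                          n_normal = c(0L, 0L, 0L)
                        ),
                        n_features = 10000L,
                        planted_up = tibble(
                          feature_id = sprintf("SIG%02d", 1:16),
                          target_cohort = "FLC",
                          log2_effect = 5
                        ),
                        baseline_meanlog = log(150),
                        baseline_sdlog = 1,
                        planted_meanlog = log(100),
                        planted_sdlog = 0.5,
                        library_size_logsd = 0.25,
                        size_factors = NULL,
                        dispersion_trend = c(a0 = 0.01, a1 = 1),
                        seed = 1L) {
  cohorts <- as_tibble(cohorts)
  if (!all(c("name", "n_tumor", "n_normal") %in% names(cohorts)) || nrow(cohorts) < 1L) {
    config_error("`cohorts` needs columns name, n_tumor, n_normal and at least one row.")
  }
  if (any(cohorts$n_tumor < 2L)) {
    config_error("Every cohort needs n_tumor >= 2.")
  }
  if (anyDuplicated(cohorts$name)) config_error("Cohort names must be unique.")
  n_features <- check_count(n_features, "n_features", min = 1L)
  planted_up <- as_tibble(planted_up)
  if (nrow(planted_up) > 0L) {
    if (!all(c("feature_id", "target_cohort", "log2_effect") %in% names(planted_up))) {
      config_error("`planted_up` needs columns feature_id, target_cohort, log2_effect.")
    }
    if (any(planted_up$log2_effect <= 0)) config_error("Planted log2 effects must be > 0.")
    if (!all(planted_up$target_cohort %in% cohorts$name)) {
      config_error("Planted target cohorts must appear in `cohorts`.")
    }
    if (nrow(planted_up) > n_features) config_error("More planted features than n_features.")
    if (anyDuplicated(planted_up$feature_id)) config_error("Planted feature ids must be unique.")
  }
  n_samples <- sum(cohorts$n_tumor) + sum(cohorts$n_normal)
  if (!is.null(size_factors)) {
    if (length(size_factors) != n_samples || any(size_factors <= 0)) {
      config_error("`size_factors` must give one positive multiplier per sample.")
    }
  }
  a <- as.numeric(dispersion_trend)
  if (length(a) != 2L || any(a < 0)) config_error("`dispersion_trend` must be c(a0, a1), both >= 0.")
  structure(list(
    cohorts = cohorts, n_features = n_features, planted_up = planted_up,
    baseline_meanlog = check_number(baseline_meanlog, "baseline_meanlog"),
    baseline_sdlog = check_number(baseline_sdlog, "baseline_sdlog", min = 0),
    planted_meanlog = check_number(planted_meanlog, "planted_meanlog"),
    planted_sdlog = check_number(planted_sdlog, "planted_sdlog", min = 0),
    library_size_logsd = check_number(library_size_logsd, "library_size_logsd", min = 0),
    size_factors = size_factors,
    dispersion_trend = c(a0 = a[1], a1 = a[2]),
    seed = check_count(seed, "seed")
  ), class = "flc_cohort_spec")
}

#' Simulate a multi-cohort count matrix with planted ground truth
#'
#' Draws counts \eqn{k_{ij} \sim NB(\mu = s_j q_i 2^{e_{ij}},
#' \alpha = a_0 + a_1/q_i)} where \eqn{e_{ij}} is the planted log2 effect when
#' feature *i* is planted and sample *j* is a tumor sample of its target
#' cohort, and 0 otherwise. Dispersion is evaluated at the baseline mean, so it
#' is a feature property. When \eqn{\alpha(q_i)} is numerically zero the draw
#' falls back to Poisson.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `flc_sim` with elements `counts` (integer matrix,
#'   features x samples), `samples` (tibble: sample_id, cohort, status),
#'   `truth` (tibble of planted features), `size_factors_true`,
#'   `baseline_means`, and the `spec`.
#' @export
simulate_counts <- function(spec) {
  if (!inherits(spec, "flc_cohort_spec")) {
    config_error("`spec` must come from cohort_spec().")
  }
  ch <- spec$cohorts
  samples <- purrr::pmap_dfr(ch, function(name, n_tumor, n_normal, ...) {
    dplyr::bind_rows(
      tibble(
        sample_id = sprintf("%s_T%02d", name, seq_len(n_tumor)),
        cohort = name, status = "tumor"
      ),
      if (n_normal > 0L) {
        tibble(
          sample_id = sprintf("%s_N%02d", name, seq_len(n_normal)),
          cohort = name, status = "normal"
        )
      }
    )
  })
  n_s <- nrow(samples)
  n_f <- spec$n_features
  n_p <- nrow(spec$planted_up)

  withr::with_seed(spec$seed, {
    q <- rlnorm(n_f, spec$baseline_meanlog, spec$baseline_sdlog)
    feature_id <- sprintf("G%05d", seq_len(n_f))
    if (n_p > 0L) {
      q[seq_len(n_p)] <- rlnorm(n_p, spec$planted_meanlog, spec$planted_sdlog)
      feature_id[seq_len(n_p)] <- spec$planted_up$feature_id
    }
    s <- spec$size_factors %||% exp(rnorm(n_s, 0, spec$library_size_logsd))

    mu <- q %o% s
    if (n_p > 0L) {
      for (i in seq_len(n_p)) {
        cols <- samples$cohort == spec$planted_up$target_cohort[i] &
          samples$status == "tumor"
        mu[i, cols] <- mu[i, cols] * 2^spec$planted_up$log2_effect[i]
      }
    }
    alpha <- spec$dispersion_trend[["a0"]] + spec$dispersion_trend[["a1"]] / q
    muv <- as.vector(mu)
    av <- rep(alpha, times = n_s)
    k <- numeric(length(muv))
    pois <- av < 1e-12
    if (any(pois)) k[pois] <- rpois(sum(pois), muv[pois])
    if (any(!pois)) k[!pois] <- rnbinom(sum(!pois), mu = muv[!pois], size = 1 / av[!pois])
    counts <- matrix(as.integer(k), n_f, n_s,
      dimnames = list(feature_id, samples$sample_id)
    )
  })

  structure(list(
    counts = counts,
    samples = samples,
    truth = spec$planted_up,
    size_factors_true = setNames(s, samples$sample_id),
    baseline_means = setNames(q, feature_id),
    spec = spec
  ), class = "flc_sim")
}

#' @export
print.flc_sim <- function(x, ...) {
  cat(sprintf(
    "<flc_sim> %d features x %d samples; %d planted features; seed %d\n",
    nrow(x$counts), ncol(x$counts), nrow(x$truth), x$spec$seed
  ))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes `counts.tsv.gz` (feature column + one column per sample),
#' `samples.tsv` and `truth.tsv` into `dir`.
#'
#' @param sim An `flc_sim` from [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "flc_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts_tbl <- dplyr::bind_cols(
    tibble(feature = rownames(sim$counts)),
    as_tibble(sim$counts)
  )
  readr::write_tsv(counts_tbl, file.path(dir, "counts.tsv.gz"))
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a counts table written by [write_cohort()]
#'
#' @param path TSV (optionally gzipped) whose first column is the feature id.
#' @return Numeric matrix, features x samples.
#' @export
read_count_matrix <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_count_matrix(tbl)
}
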