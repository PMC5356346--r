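#' Configure an end-to-end pipeline run
#'
#' Collects every stage's inputs and parameters into one object. By default
#' the run is fully synthetic: a three-cohort count simulation with 16
#' planted target-up features, one fusion-positive and one fusion-negative
#' alignment set, and one deleted plus one deletion-free coverage profile.
#' All stage seeds are derived deterministically from `seed`.
#'
#' @param seed Integer master seed.
#' @param sim_spec [cohort_spec()] for the count simulation (default uses a
#'   seed derived from `seed`).
#' @param fusion_specs Named list of [fusion_sim_spec()]s, one per simulated
#'   sample.
#' @param deletion_specs Named list of [deletion_sim_spec()]s.
#' @param target,comparators Cohort labels for the discovery contrasts.
#' @param de List: fc_min, fdr_max, count_floor, floor_required, pseudocount.
#' @param fusion_call List: min_junction, min_spanning.
#' @param cnv List: target_interval (region string or tibble), mean_threshold,
#'   alpha, n_perm, min_width.
#' @param cluster List: top_k (variable features used for clustering).
#' @param signature List: q (separation quantile).
#' @param gmt Optional gene-set library: a GMT path or a named list.
#' @param min_overlap Enrichment reporting floor.
#' @param stages Character subset of
#'   `c("fusion", "cnv", "de", "cluster", "signature", "enrichment")`.
#' @return List of class `flc_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim_spec = NULL,
                            fusion_specs = NULL,
                            deletion_specs = NULL,
                            target = "FLC",
                            comparators = c("HCC", "CCA"),
                            de = list(),
                            fusion_call = list(),
                            cnv = list(),
                            cluster = list(),
                            signature = list(),
                            gmt = NULL,
                            min_overlap = 5L,
                            stages = c(
                              "fusion", "cnv", "de", "cluster",
                              "signature", "enrichment"
                            )) {
  seed <- check_count(seed, "seed")
  sim_spec <- sim_spec %||% cohort_spec(seed = derive_seed(seed, 1L))
  fusion_specs <- fusion_specs %||% list(
    positive = fusion_sim_spec(seed = derive_seed(seed, 2L)),
    negative = fusion_sim_spec(
      n_junction_reads = 0L, n_spanning_pairs = 0L,
      n_background_reads = 100L, seed = derive_seed(seed, 3L)
    )
  )
  deletion_specs <- deletion_specs %||% list(
    deleted = deletion_sim_spec(seed = derive_seed(seed, 4L)),
    flat = deletion_sim_spec(deleted_interval = NULL, seed = derive_seed(seed, 5L))
  )
  de <- utils::modifyList(list(
    fc_min = 2, fdr_max = 0.05, count_floor = 50,
    floor_required = TRUE, pseudocount = 1
  ), de)
  fusion_call <- utils::modifyList(list(min_junction = 2L, min_spanning = 1L), fusion_call)
  cnv <- utils::modifyList(list(
    target_interval = "chr19:14239803-14624494",
    mean_threshold = -0.1, alpha = 0.01, n_perm = 1000L, min_width = 3L
  ), cnv)
  cluster <- utils::modifyList(list(top_k = 1000L), cluster)
  signature <- utils::modifyList(list(q = 0.95), signature)
  known <- c("fusion", "cnv", "de", "cluster", "signature", "enrichment")
  if (!all(stages %in% known)) config_error("Unknown stage name in `stages`.")
  structure(list(
    seed = seed, sim_spec = sim_spec, fusion_specs = fusion_specs,
    deletion_specs = deletion_specs, target = target, comparators = comparators,
    de = de, fusion_call = fusion_call, cnv = cnv, cluster = cluster,
    signature = signature, gmt = gmt, min_overlap = min_overlap,
    stages = stages
  ), class = "flc_pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [pipeline_config()] (stage parameter blocks, seed, stages, target,
#' comparators, gmt path). Simulation specs given as key-value blocks are
#' passed to the corresponding spec constructors.
#'
#' @param path YAML file.
#' @return List of class `flc_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) data_error(sprintf("Config file not found: %s", path))
  y <- yaml::read_yaml(path)
  args <- list()
  for (key in c(
    "seed", "target", "comparators", "de", "fusion_call", "cnv",
    "cluster", "signature", "gmt", "min_overlap", "stages"
  )) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$sim_spec)) args$sim_spec <- do.call(cohort_spec, y$sim_spec)
  if (!is.null(y$fusion_specs)) {
    args$fusion_specs <- lapply(y$fusion_specs, function(s) do.call(fusion_sim_spec, s))
  }
  if (!is.null(y$deletion_specs)) {
    args$deletion_specs <- lapply(y$deletion_specs, function(s) do.call(deletion_sim_spec, s))
  }
  do.call(pipeline_config, args)
}

#' Run the full discovery pipeline on a synthetic cohort
#'
#' Executes, in order: fusion-evidence screening, focal-deletion confirmation,
#' two-contrast differential expression with the discovery filters, the
#' concordant intersection, variance-stabilized Ward clustering with a
#' clade-purity check and PCA, quantile-separation signature selection, and
#' (when a library is supplied) gene-set enrichment of the signature. Stages
#' can be skipped via `config$stages`; all randomness derives from
#' `config$seed`, so a config reproduces its report exactly.
#'
#' @param config An [pipeline_config()] object.
#' @return List of class `flc_run_report`; see [glance.flc_run_report()] for
#'   the one-row summary.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "flc_pipeline_config")) {
    config_error("`config` must come from pipeline_config().")
  }
  report <- list(
    version = as.character(packageVersion("flcsig")),
    seed = config$seed,
    parameters = config[c(
      "target", "comparators", "de", "fusion_call", "cnv",
      "cluster", "signature", "min_overlap", "stages"
    )]
  )
  sim <- simulate_counts(config$sim_spec)
  report$samples <- dplyr::count(sim$samples, .data$cohort, .data$status)
  report$truth_features <- sim$truth$feature_id

  if ("fusion" %in% config$stages) {
    ev <- purrr::imap_dfr(config$fusion_specs, function(spec, nm) {
      fs <- simulate_fusion_reads(spec)
      jx <- fusion_junction(
        contig = spec$contig, breakpoint = spec$breakpoint,
        min_anchor = spec$min_anchor
      )
      count_junction_evidence(fs$sam, jx, sample_id = nm)
    })
    report$fusion <- call_fusion_positive(
      ev,
      min_junction = config$fusion_call$min_junction,
      min_spanning = config$fusion_call$min_spanning
    )
  }

  if ("cnv" %in% config$stages) {
    cnv_out <- purrr::imap(config$deletion_specs, function(spec, nm) {
      bins <- simulate_binned_coverage(spec)
      prof <- compute_log_ratios(bins)
      segs <- segment_cbs(prof,
        alpha = config$cnv$alpha, n_perm = config$cnv$n_perm,
        min_width = config$cnv$min_width, seed = derive_seed(config$seed, 10L)
      )
      list(
        segments = segs,
        call = filter_deletion(segs,
          target_interval = config$cnv$target_interval,
          mean_threshold = config$cnv$mean_threshold, sample_id = nm
        )
      )
    })
    report$cnv_segments <- purrr::imap_dfr(cnv_out, ~ dplyr::mutate(.x$segments, sample_id = .y))
    report$cnv_calls <- purrr::map_dfr(cnv_out, "call")
  }

  sf_all <- estimate_size_factors_mor(sim$counts)
  norm <- sweep(sim$counts, 2, sf_all, "/")
  tumor <- sim$samples$status == "tumor"

  if (any(c("de", "signature") %in% config$stages)) {
    de_list <- lapply(config$comparators, function(cmp) {
      res <- nb_test(
        sim$counts[, tumor, drop = FALSE],
        groups = sim$samples$cohort[tumor],
        contrast = c(config$target, cmp),
        size_factors = sf_all[tumor],
        pseudocount = config$de$pseudocount
      )
      apply_de_criteria(res,
        fc_min = config$de$fc_min, fdr_max = config$de$fdr_max,
        count_floor = config$de$count_floor,
        floor_required = config$de$floor_required
      )
    })
    names(de_list) <- config$comparators
    report$de_counts <- purrr::imap_dfr(de_list, function(res, cmp) {
      tibble(contrast = paste(config$target, "vs", cmp), n_pass = sum(res$passes))
    })
    concordant <- if (length(de_list) >= 2L) {
      concordant_intersection(de_list[[1]], de_list[[2]])
    } else {
      dplyr::mutate(
        dplyr::select(dplyr::filter(de_list[[1]], .data$passes),
          "feature",
          log2fc_a = "log2fc"
        ),
        log2fc_b = .data$log2fc_a,
        direction = ifelse(.data$log2fc_a > 0, "up", "down")
      )
    }
    report$concordant <- concordant
    report$de <- de_list
  }

  if ("cluster" %in% config$stages) {
    trend <- if (!is.null(report$de)) attr(report$de[[1]], "dispersion_trend") else NULL
    vstm <- vst(sim$counts[, tumor, drop = FALSE],
      size_factors = sf_all[tumor], trend = trend
    )
    tv <- top_variable(vstm, min(config$cluster$top_k, nrow(vstm)))
    hc <- ward_cluster(vstm, tv)
    labels <- setNames(sim$samples$cohort[tumor], sim$samples$sample_id[tumor])
    report$clade <- clade_purity(hc, labels, config$target)
    report$dendrogram <- hc
    pca <- pca_project(vstm, tv, n_components = 2L)
    report$pca_explained <- pca$explained_variance
    report$pca <- pca
  }

  if ("signature" %in% config$stages) {
    candidates <- report$concordant$feature
    sep <- quantile_separation(
      norm[, tumor, drop = FALSE],
      target_samples = sim$samples$sample_id[tumor & sim$samples$cohort == config$target],
      comparator_samples = sim$samples$sample_id[tumor & sim$samples$cohort %in% config$comparators],
      q = config$signature$q,
      candidate_features = candidates
    )
    report$separation <- sep
    report$signature_features <- sep$feature[sep$qualifies]
    truth <- sim$truth$feature_id
    found <- report$signature_features
    report$signature_eval <- tibble(
      n_planted = length(truth), n_called = length(found),
      precision = if (length(found) > 0) mean(found %in% truth) else NA_real_,
      recall = if (length(truth) > 0) mean(truth %in% found) else NA_real_
    )
  }

  if ("enrichment" %in% config$stages && !is.null(config$gmt) &&
    length(report$signature_features %||% character()) > 0L) {
    lib <- if (is.character(config$gmt)) read_gmt(config$gmt) else config$gmt
    report$enrichment <- enrich(report$signature_features, lib,
      universe = rownames(sim$counts), min_overlap = config$min_overlap
    )
  }

  report$sim <- sim
  class(report) <- "flc_run_report"
  report
}

#' @export
print.flc_run_report <- function(x, ...) {
  cat(sprintf("<flc_run_report> seed %d, flcsig %s\n", x$seed, x$version))
  if (!is.null(x$fusion)) {
    cat(sprintf("  fusion-positive samples: %d/%d\n", sum(x$fusion$call), nrow(x$fusion)))
  }
  if (!is.null(x$cnv_calls)) {
    cat(sprintf(
      "  deletion-supported profiles: %d/%d\n",
      sum(x$cnv_calls$supported), nrow(x$cnv_calls)
    ))
  }
  if (!is.null(x$de_counts)) {
    for (i in seq_len(nrow(x$de_counts))) {
      cat(sprintf("  DE %s: %d features\n", x$de_counts$contrast[i], x$de_counts$n_pass[i]))
    }
    cat(sprintf("  concordant: %d features\n", nrow(x$concordant)))
  }
  if (!is.null(x$clade)) {
    cat(sprintf(
      "  target clade pure: %s (clade size %d)\n",
      x$clade$pure, x$clade$clade_size
    ))
  }
  if (!is.null(x$signature_eval)) {
    cat(sprintf(
      "  signature: %d features (precision %.2f, recall %.2f)\n",
      x$signature_eval$n_called, x$signature_eval$precision,
      x$signature_eval$recall
    ))
  }
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x An `flc_run_report`.
#' @param ... Unused.
#' @return Tibble with the run's headline numbers.
#' @export
glance.flc_run_report <- function(x, ...) {
  tibble(
    seed = x$seed,
    n_fusion_positive = if (is.null(x$fusion)) NA_integer_ else sum(x$fusion$call),
    n_deletion_supported = if (is.null(x$cnv_calls)) NA_integer_ else sum(x$cnv_calls$supported),
    n_concordant = if (is.null(x$concordant)) NA_integer_ else nrow(x$concordant),
    clade_pure = if (is.null(x$clade)) NA else x$clade$pure,
    n_signature = if (is.null(x$signature_features)) NA_integer_ else length(x$signature_features),
    signature_precision = if (is.null(x$signature_eval)) NA_real_ else x$signature_eval$precision,
    signature_recall = if (is.null(x$signature_eval)) NA_real_ else x$signature_eval$recall
  )
}

#' Check a run report against the published report schema
#'
#' Validates the structural contract of [run_pipeline()] output against the
#' JSON schema shipped in `inst/extdata/run_report_schema.json` (required
#' fields and their types).
#'
#' @param report An `flc_run_report`.
#' @return `TRUE` invisibly; errors describe any violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::fromJSON(
    system.file("extdata", "run_report_schema.json", package = "flcsig"),
    simplifyVector = TRUE
  )
  required <- schema$required
  missing <- setdiff(required, names(report))
  if (length(missing) > 0L) {
    data_error(sprintf("Report missing required fields: %s", paste(missing, collapse = ", ")))
  }
  types <- schema$properties
  for (nm in required) {
    want <- types[[nm]]$type
    ok <- switch(want,
      string = is.character(report[[nm]]),
      integer = is.numeric(report[[nm]]),
      object = is.list(report[[nm]]),
      TRUE
    )
    if (!ok) data_error(sprintf("Report field '%s' is not of type %s.", nm, want))
  }
  invisible(TRUE)
}

#' Validate signature features in an external cohort
#'
#' For each signature feature, tests target vs comparator samples in an
#' independent cohort with the two-sided Mann-Whitney rank-sum test on
#' size-factor-normalized values, with BH adjustment across the signature.
#' Features absent from the cohort are flagged missing, not fatal.
#'
#' @param counts Count matrix (features x samples) or data frame with a
#'   feature column.
#' @param samples Tibble with sample_id and cohort columns matching the
#'   count columns.
#' @param signature_features Character vector of features to validate.
#' @param target Target cohort label.
#' @param comparators Comparator cohort labels (default: all others).
#' @return Tibble: feature, present, p_value, fdr.
#' @export
validate_external_cohort <- function(counts, samples, signature_features,
                                     target, comparators = NULL) {
  if (length(signature_features) == 0L) {
    return(tibble(
      feature = character(), present = logical(),
      p_value = numeric(), fdr = numeric()
    ))
  }
  m <- as_count_matrix(counts)
  if (!all(c("sample_id", "cohort") %in% names(samples))) {
    data_error("`samples` needs sample_id and cohort columns.")
  }
  m <- m[, samples$sample_id, drop = FALSE]
  comparators <- comparators %||% setdiff(unique(samples$cohort), target)
  sf <- estimate_size_factors_mor(m)
  z <- sweep(m, 2, sf, "/")
  tcol <- samples$cohort == target
  ccol <- samples$cohort %in% comparators
  out <- purrr::map_dfr(signature_features, function(f) {
    if (!f %in% rownames(z)) {
      return(tibble(feature = f, present = FALSE, p_value = NA_real_))
    }
    tibble(
      feature = f, present = TRUE,
      p_value = rank_sum_p(z[f, tcol], z[f, ccol])
    )
  })
  out$fdr <- NA_real_
  out$fdr[out$present] <- p.adjust(out$p_value[out$present], method = "BH")
  out
}
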