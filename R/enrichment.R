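#' Read a gene-set library in GMT format
#'
#' Thin wrapper around [fgsea::gmtPathways()] returning a named list of
#' identifier vectors (set name, description, tab-separated members per
#' line).
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) data_error(sprintf("GMT file not found: %s", path))
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation of a feature list in gene sets
#'
#' For each set, tests over-representation of the query list with the
#' one-sided hypergeometric tail \eqn{P(X \ge k)} where `k` is the overlap,
#' `K` the set size within the universe, `n` the query size within the
#' universe, and `N` the universe size; BH adjustment is applied across all
#' tested sets. Identifiers are harmonized to upper case and de-duplicated;
#' query features outside the universe are dropped (with a message). A set is
#' flagged `reported` only when its overlap reaches `min_overlap` — the
#' "at least 5 genes in each category" display rule.
#'
#' This is a plain Fisher-style over-representation test; it deliberately
#' replaces the rank-blended combined score of web enrichment services with a
#' fully specified, reproducible statistic.
#'
#' @param query Character vector of feature identifiers.
#' @param library Named list of feature sets (e.g. from [read_gmt()]).
#' @param universe Background identifiers; defaults to the union of all set
#'   members and the query.
#' @param min_overlap Minimum overlap for `reported`.
#' @return Tibble of class `flc_enrichment`, ordered by p-value: set, k
#'   (overlap), set_size, query_size, universe_size, p_value, fdr, reported.
#' @export
enrich <- function(query, library, universe = NULL, min_overlap = 5L) {
  if (length(library) == 0L) data_error("`library` is empty.")
  min_overlap <- check_count(min_overlap, "min_overlap", min = 0L)
  harmonize <- function(x) unique(toupper(x))
  library <- lapply(library, harmonize)
  universe <- harmonize(universe %||% c(unlist(library, use.names = FALSE), query))
  if (length(universe) == 0L) data_error("`universe` is empty.")
  query <- harmonize(query)
  dropped <- sum(!query %in% universe)
  if (dropped > 0L) {
    inform(sprintf("%d query feature(s) outside the universe were dropped.", dropped))
  }
  query <- intersect(query, universe)
  n <- length(query)
  big_n <- length(universe)
  out <- purrr::imap_dfr(library, function(members, set_name) {
    members <- intersect(members, universe)
    k <- length(intersect(query, members))
    big_k <- length(members)
    tibble(
      set = set_name, k = k, set_size = big_k,
      query_size = n, universe_size = big_n,
      p_value = phyper(k - 1, big_k, big_n - big_k, n, lower.tail = FALSE)
    )
  })
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out$reported <- out$k >= min_overlap
  out <- dplyr::arrange(out, .data$p_value, .data$set)
  class(out) <- c("flc_enrichment", class(out))
  out
}
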