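# Internal helpers shared across modules.

# Stop with a classed condition so callers can distinguish configuration
# errors (bad specs/parameters) from data errors (bad inputs).
config_error <- function(msg) {
  abort(msg, class = "flcsig_config_error")
}

data_error <- function(msg) {
  abort(msg, class = "flcsig_data_error")
}

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    config_error(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x > max) {
    config_error(sprintf("`%s` must be a single number in [%s, %s].", name, min, max))
  }
  as.numeric(x)
}

# Coerce a counts input (matrix or feature-column data frame) to a numeric
# matrix with feature rownames. Tabular inputs carry features in the first
# column.
as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    feat <- as.character(counts[[1L]])
    m <- as.matrix(counts[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- feat
    counts <- m
  }
  if (!is.matrix(counts) || !is.numeric(counts)) {
    data_error("`counts` must be a numeric matrix or a data frame with a feature column.")
  }
  if (anyNA(counts) || any(counts < 0)) {
    data_error("`counts` must be finite and non-negative.")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("F%05d", seq_len(nrow(counts)))
  }
  counts
}

# Derive a stage seed from a base seed, kept well inside 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}
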