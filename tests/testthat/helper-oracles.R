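# Independent oracles used across the suite. These deliberately re-derive
# results by brute force or closed form, never by calling the code paths they
# check.

# Naive O(n^3) agglomerative Ward clustering (ward.D2 semantics: Euclidean
# distances in, Lance-Williams update on squared distances). Returns the
# sorted merge heights.
naive_ward_heights <- function(x) {
  # x: samples in rows
  n <- nrow(x)
  d2 <- as.matrix(dist(x))^2 # work on squared distances
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(0)
  for (step in seq_len(n - 1)) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (a < b) {
          val <- d2[active[a], active[b]]
          if (val < best[1]) best <- c(val, a, b)
        }
      }
    }
    i <- active[best[2]]
    j <- active[best[3]]
    heights <- c(heights, sqrt(best[1]))
    ni <- sizes[i]
    nj <- sizes[j]
    for (k in active) {
      if (k != i && k != j) {
        nk <- sizes[k]
        d2[i, k] <- d2[k, i] <-
          ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * best[1]) /
            (ni + nj + nk)
      }
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  sort(heights)
}

# Order-statistic quantile with linear interpolation, written from the
# definition (h = (n-1)q; interpolate between the floor(h)+1-th and next
# order statistics).
interp_quantile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * q
  lo <- floor(h)
  if (lo + 1 >= n) {
    return(s[n])
  }
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

# Brute-force separation oracle: a feature up-qualifies iff its target
# minimum exceeds the interpolated comparator quantile; down iff its target
# maximum is below the (1-q) quantile.
brute_separation <- function(tgt, cmp, q) {
  up <- apply(tgt, 1, min) > apply(cmp, 1, interp_quantile, q = q)
  down <- apply(tgt, 1, max) < apply(cmp, 1, interp_quantile, q = 1 - q)
  up | down
}

# Benjamini-Hochberg step-up from the definition.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Exact hypergeometric upper tail P(X >= k) by direct enumeration of the pmf.
hyper_tail <- function(k, big_k, big_n, n) {
  support <- max(0, n - (big_n - big_k)):min(big_k, n)
  pmf <- choose(big_k, support) * choose(big_n - big_k, n - support) / choose(big_n, n)
  sum(pmf[support >= k])
}

# Small default-structure cohort spec scaled down for unit tests.
small_cohort_spec <- function(seed = 1, n_features = 2000, n_planted = 8,
                              effect = 5) {
  cohort_spec(
    cohorts = data.frame(
      name = c("FLC", "HCC", "CCA"),
      n_tumor = c(6L, 30L, 15L), n_normal = 0L
    ),
    n_features = n_features,
    planted_up = data.frame(
      feature_id = sprintf("SIG%02d", seq_len(n_planted)),
      target_cohort = "FLC", log2_effect = effect
    ),
    seed = seed
  )
}

no_planted <- function() {
  data.frame(
    feature_id = character(), target_cohort = character(),
    log2_effect = numeric()
  )
}
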