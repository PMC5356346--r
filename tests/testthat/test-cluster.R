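test_that("the variance-stabilizing transform is monotone with the right limits", {
  k <- 0:1000
  x <- matrix(k, ncol = 1, dimnames = list(sprintf("g%04d", k), "s1"))
  for (trend in list(c(0.01, 1), c(0.5, 0.2), c(1e-3, 5))) {
    u <- vst(x, size_factors = 1, trend = trend)
    expect_true(all(diff(u[, 1]) > 0))
  }
  # Poisson limit: a0 -> 0 gives the square-root stabilizer
  u0 <- vst(x, size_factors = 1, trend = c(0, 1))
  expect_equal(unname(u0[, 1] / u0[101, 1]), sqrt(k / k[101]), tolerance = 1e-9)
})

test_that("the transform flattens the variance-mean relationship", {
  spec <- cohort_spec(
    cohorts = data.frame(name = "X", n_tumor = 60L, n_normal = 0L),
    n_features = 4000, planted_up = no_planted(), seed = 17
  )
  sim <- simulate_counts(spec)
  u <- vst(sim$counts)
  mu <- rowMeans(u)
  v <- apply(u, 1, var)
  keep <- rowMeans(sim$counts) > 5
  beta <- coef(lm(v[keep] ~ mu[keep]))[2]
  expect_lt(abs(beta), 0.1)
})

test_that("top-variable selection matches a brute-force sort with id tie-breaks", {
  set.seed(3)
  m <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(sprintf("g%02d", 1:50), NULL))
  tv <- top_variable(m, 10)
  v <- apply(m, 1, var)
  expect_equal(tv$feature, names(sort(v, decreasing = TRUE))[1:10])

  expect_equal(nrow(top_variable(m, 50)), 50L)
  expect_setequal(top_variable(m, 50)$feature, rownames(m))

  # exact ties fall back to identifier order
  tied <- rbind(b_feat = c(0, 1), a_feat = c(0, 1), c_feat = c(0, 2))
  expect_equal(top_variable(tied, 3)$feature[1], "c_feat")
  expect_equal(top_variable(tied, 3)$feature[2:3], c("a_feat", "b_feat"))

  expect_error(top_variable(m, 0), class = "flcsig_config_error")
})

test_that("Ward clustering matches the naive Lance-Williams oracle", {
  # two samples merge at their Euclidean distance
  two <- matrix(c(0, 0, 3, 4), 2, 2, dimnames = list(NULL, c("a", "b")))
  hc2 <- ward_cluster(two)
  expect_equal(hc2$height, 5)

  # three collinear points: nearest pair merges first
  three <- matrix(c(0, 1, 10), 1, 3, dimnames = list("f", c("x", "y", "z")))
  hc3 <- ward_cluster(three)
  expect_equal(sort(hc3$merge[1, ]), c(-2, -1))

  set.seed(99)
  for (i in 1:5) {
    m <- matrix(rnorm(12 * 6), nrow = 6) # 12 samples, 6 features
    colnames(m) <- sprintf("s%02d", 1:12)
    rownames(m) <- sprintf("f%d", 1:6)
    hc <- ward_cluster(m)
    expect_equal(sort(hc$height), naive_ward_heights(t(m)), tolerance = 1e-9)
    expect_true(all(diff(hc$height) >= -1e-12)) # monotone heights
  }
})

test_that("clade purity detects monophyly and ignores leaf order", {
  m <- matrix(c(1, 2, 3, 11, 12, 13), 1, 6,
    dimnames = list("f", sprintf("s%d", 1:6))
  )
  labs <- setNames(rep(c("A", "B"), each = 3), colnames(m))
  hc <- ward_cluster(m)
  expect_true(clade_purity(hc, labs, "A")$pure)
  expect_equal(clade_purity(hc, labs, "A")$clade_size, 3L)

  # interleaved points are not monophyletic
  m2 <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
    dimnames = list("f", sprintf("s%d", 1:6))
  )
  labs2 <- setNames(rep(c("A", "B"), 3), colnames(m2))
  expect_false(clade_purity(ward_cluster(m2), labs2, "A")$pure)

  # single label: the root is a pure clade
  expect_true(clade_purity(hc, setNames(rep("A", 6), colnames(m)), "A")$pure)

  # invariance to input column permutation
  perm <- sample(6)
  expect_true(clade_purity(ward_cluster(m[, perm, drop = FALSE]), labs, "A")$pure)

  expect_error(clade_purity(hc, labs, "Z"), class = "flcsig_data_error")
})

test_that("PCA projection is deterministic, orthogonal, and separates planted groups", {
  # collinear data: PC1 carries all variance
  line <- rbind(x = seq(0, 10, length.out = 8), y = 2 * seq(0, 10, length.out = 8))
  colnames(line) <- sprintf("s%d", 1:8)
  pc <- pca_project(line, n_components = 2)
  expect_equal(pc$explained_variance[1], 1, tolerance = 1e-12)

  # full-rank reconstruction
  set.seed(12)
  m <- matrix(rnorm(6 * 10), 6, 10, dimnames = list(
    sprintf("f%d", 1:6),
    sprintf("s%02d", 1:10)
  ))
  pc2 <- pca_project(m, n_components = 6)
  x <- t(m)
  xc <- scale(x, center = TRUE, scale = FALSE)
  sc <- as.matrix(pc2$scores[, -1])
  expect_equal(unname(sc %*% t(pc2$loadings)), unname(xc),
    tolerance = 1e-8, ignore_attr = TRUE
  )

  # two planted clusters separate on PC1-2 (silhouette > 0.5)
  sim <- simulate_counts(small_cohort_spec(seed = 5, n_features = 1500))
  u <- vst(sim$counts)
  pc3 <- pca_project(u, top_variable(u, 300), n_components = 2)
  labs <- as.integer(sim$samples$cohort == "FLC") + 1L
  sil <- cluster::silhouette(labs, dist(as.matrix(pc3$scores[, -1])))
  expect_gt(mean(sil[labs == 2, "sil_width"]), 0.5)
})
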