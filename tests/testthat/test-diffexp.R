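test_that("median-of-ratios size factors match closed forms and DESeq2", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
  expect_equal(as.numeric(size_factors(m)), c(1 / sqrt(2), sqrt(2)))

  ident <- matrix(rep(c(5, 10, 15), 3), ncol = 3)
  expect_equal(as.numeric(size_factors(ident)), c(1, 1, 1))

  set.seed(1)
  r <- matrix(rnbinom(2000, mu = 50, size = 5), ncol = 8)
  expect_equal(
    as.numeric(size_factors(r + 1)),
    unname(DESeq2::estimateSizeFactorsForMatrix(r + 1)),
    tolerance = 1e-10
  )

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), class = "flcsig_data_error")
})

test_that("planted depth multipliers are recovered within 2%", {
  spec <- cohort_spec(
    cohorts = data.frame(name = "X", n_tumor = 4L, n_normal = 0L),
    n_features = 3000, planted_up = no_planted(),
    size_factors = c(0.5, 1, 2, 4), seed = 11
  )
  sim <- simulate_counts(spec)
  sf <- size_factors(sim$counts)
  rel <- sf / c(0.5, 1, 2, 4)
  rel <- rel / exp(mean(log(rel))) # size factors are defined up to a constant
  expect_lt(max(abs(rel - 1)), 0.02)
})

test_that("the NB Wald test finds planted effects and refuses tiny designs", {
  sim <- simulate_counts(small_cohort_spec(seed = 21))
  res <- nb_test(sim$counts, sim$samples$cohort, contrast = c("FLC", "HCC"))
  planted <- dplyr::filter(res, .data$feature %in% sim$truth$feature_id)
  expect_true(all(planted$fdr < 0.05))
  expect_true(all(planted$fold_change >= 2))

  expect_error(
    nb_test(sim$counts[, 1:3], c("A", "A", "B")),
    class = "flcsig_data_error"
  )
})

test_that("two disjoint halves of one cohort show no discoveries", {
  spec <- cohort_spec(
    cohorts = data.frame(name = "H", n_tumor = 40L, n_normal = 0L),
    n_features = 4000, planted_up = no_planted(), seed = 31
  )
  sim <- simulate_counts(spec)
  fake <- rep(c("g1", "g2"), each = 20)
  res <- apply_de_criteria(nb_test(sim$counts, fake, contrast = c("g2", "g1")))
  expect_lte(sum(res$passes), 1L)
})

test_that("DE filters match their brute-force definition", {
  set.seed(5)
  n <- 500
  tab <- tibble::tibble(
    feature = sprintf("f%03d", 1:n),
    mean_ref = runif(n, 0, 200), mean_target = runif(n, 0, 200),
    fold_change = (runif(n, 0, 200) + 1) / (runif(n, 0, 200) + 1),
    fdr = runif(n), tested = TRUE
  )
  tab$log2fc <- log2(tab$fold_change)
  out <- apply_de_criteria(tab, fc_min = 2, fdr_max = 0.05, count_floor = 50)
  brute <- (pmax(tab$fold_change, 1 / tab$fold_change) >= 2) &
    (tab$fdr < 0.05) &
    (pmax(tab$mean_ref, tab$mean_target) > 50)
  expect_identical(out$passes, brute)

  # floor applies to group means, in at least one group
  one <- tibble::tibble(
    feature = "x", mean_ref = 10, mean_target = 60,
    fold_change = 2.5, log2fc = log2(2.5), fdr = 0.01, tested = TRUE
  )
  expect_true(apply_de_criteria(one)$passes)
  expect_false(apply_de_criteria(dplyr::mutate(one, fdr = 0.2))$passes)
  expect_false(apply_de_criteria(dplyr::mutate(one, fold_change = 3, fdr = 0.2))$passes)
  # lincRNA-style run drops the floor
  low <- dplyr::mutate(one, mean_ref = 2, mean_target = 6)
  expect_false(apply_de_criteria(low)$passes)
  expect_true(apply_de_criteria(low, floor_required = FALSE)$passes)
})

test_that("concordant intersection keeps shared features with matching sign", {
  a <- tibble::tibble(
    feature = c("f1", "f2", "f3"), log2fc = c(2, -1, 3),
    passes = c(TRUE, TRUE, TRUE)
  )
  b <- tibble::tibble(
    feature = c("f2", "f3", "f4"), log2fc = c(1, 2, 2),
    passes = c(TRUE, TRUE, TRUE)
  )
  out <- concordant_intersection(a, b)
  expect_equal(out$feature, "f3") # f2 flips sign, f1/f4 not shared
  expect_equal(out$direction, "up")

  disjoint <- concordant_intersection(
    dplyr::mutate(a, feature = c("x1", "x2", "x3")), b
  )
  expect_equal(nrow(disjoint), 0L)
})

test_that("BH adjustment agrees with the step-up definition", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(50)
    expect_equal(p.adjust(p, "BH"), brute_bh(p))
  }
})

test_that("rank-sum test is exact on small untied samples and calibrated", {
  expect_equal(validate_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(validate_rank_sum(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_equal(validate_rank_sum(c(1, 2, 3), c(4, 5, 6))$method, "exact")

  # permutation-null p-values are uniform on their support
  set.seed(13)
  pooled <- rnorm(16)
  ps <- replicate(300, {
    idx <- sample(16, 8)
    validate_rank_sum(pooled[idx], pooled[-idx])$p_value
  })
  expect_gt(mean(ps < 0.2), 0.12)
  expect_lt(mean(ps < 0.2), 0.30)
  expect_gt(min(ps), 0)
})
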