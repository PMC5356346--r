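test_that("separation requires every target sample beyond the comparator quantile", {
  m <- cbind(
    matrix(rep(c(10, 11, 12), 2), nrow = 2, byrow = TRUE),
    matrix(runif(40, 0, 5), nrow = 2)
  )
  rownames(m) <- c("hit", "almost")
  colnames(m) <- c(sprintf("t%d", 1:3), sprintf("c%02d", 1:20))
  m["almost", "t2"] <- 2 # one target sample inside the comparator bulk
  sep <- quantile_separation(m, sprintf("t%d", 1:3), sprintf("c%02d", 1:20), q = 0.95)
  expect_true(sep$qualifies[sep$feature == "hit"])
  expect_equal(sep$direction[sep$feature == "hit"], "up")
  expect_false(sep$qualifies[sep$feature == "almost"])

  expect_error(
    quantile_separation(m, sprintf("t%d", 1:3), sprintf("c%02d", 1:20), q = 1.2),
    class = "flcsig_config_error"
  )
})

test_that("separation matches the brute-force order-statistic oracle", {
  set.seed(77)
  for (i in 1:50) {
    nf <- sample(5:20, 1)
    nt <- sample(2:6, 1)
    nc <- sample(5:30, 1)
    m <- matrix(round(rlnorm(nf * (nt + nc), 2, 1), 2), nrow = nf)
    rownames(m) <- sprintf("f%02d", seq_len(nf))
    colnames(m) <- c(sprintf("t%d", 1:nt), sprintf("c%02d", 1:nc))
    for (q in c(0.9, 0.95)) {
      sep <- quantile_separation(m, sprintf("t%d", 1:nt), sprintf("c%02d", 1:nc), q = q)
      oracle <- brute_separation(
        m[, 1:nt, drop = FALSE],
        m[, nt + seq_len(nc), drop = FALSE], q
      )
      expect_identical(sep$qualifies, unname(oracle))
    }
  }
})

test_that("relaxing the quantile only enlarges the qualify set and scale cancels", {
  set.seed(21)
  m <- matrix(rlnorm(30 * 26, 3, 1), nrow = 30)
  rownames(m) <- sprintf("f%02d", 1:30)
  colnames(m) <- c(sprintf("t%d", 1:6), sprintf("c%02d", 1:20))
  tgt <- sprintf("t%d", 1:6)
  cmp <- sprintf("c%02d", 1:20)
  s95 <- quantile_separation(m, tgt, cmp, q = 0.95)
  s90 <- quantile_separation(m, tgt, cmp, q = 0.90)
  expect_true(all(s95$feature[s95$qualifies] %in% s90$feature[s90$qualifies]))

  s_scaled <- quantile_separation(m * 37.5, tgt, cmp, q = 0.95)
  expect_identical(s_scaled$qualifies, s95$qualifies)
})

test_that("cross-tumor ranking orders fold change and abundance with next-type ratios", {
  d <- tibble::tibble(
    feature = rep(c("OATlike", "shared"), each = 3),
    tumor_type = rep(c("FLC", "T2", "T3"), 2),
    tumor_mean = c(640, 100, 50, 200, 500, 100),
    normal_mean = c(20, 50, 50, 100, 100, 100)
  )
  r <- cross_tumor_rank(d, target_type = "FLC")
  oat <- r[r$feature == "OATlike", ]
  expect_equal(oat$fc_rank, 1L)
  expect_equal(oat$abundance_rank, 1L)
  expect_equal(oat$ratio_to_next, 6.4)
  sh <- r[r$feature == "shared", ]
  expect_equal(sh$abundance_rank, 2L)
  # ratio_to_next > 1 iff abundance rank is 1
  expect_true(oat$ratio_to_next > 1)
  expect_false(sh$ratio_to_next > 1)

  single <- cross_tumor_rank(
    tibble::tibble(
      feature = "f", tumor_type = "FLC",
      tumor_mean = 10, normal_mean = 2
    ),
    target_type = "FLC"
  )
  expect_equal(single$fc_rank, 1L)
  expect_equal(single$abundance_rank, 1L)

  # missing matched normal for the target is an error; other types are dropped
  expect_error(
    cross_tumor_rank(dplyr::mutate(d, normal_mean = ifelse(tumor_type == "FLC", NA, normal_mean))),
    class = "flcsig_data_error"
  )
  drop3 <- cross_tumor_rank(dplyr::mutate(d, normal_mean = ifelse(tumor_type == "T3", NA, normal_mean)))
  expect_equal(unique(drop3$n_tumor_types), 2L)
})

test_that("planted features top both cross-tumor rankings in every seed", {
  for (s in 1:3) {
    sim <- simulate_counts(small_cohort_spec(seed = s, n_features = 1000))
    z <- sweep(sim$counts, 2, size_factors(sim$counts), "/")
    means <- purrr::map_dfr(unique(sim$samples$cohort), function(co) {
      tibble::tibble(
        feature = rownames(z),
        tumor_type = co,
        tumor_mean = rowMeans(z[, sim$samples$cohort == co, drop = FALSE]),
        normal_mean = unname(sim$baseline_means) # matched-normal baseline
      )
    })
    r <- cross_tumor_rank(means, target_type = "FLC")
    planted <- r[r$feature %in% sim$truth$feature_id, ]
    expect_true(all(planted$fc_rank == 1L))
    expect_true(all(planted$abundance_rank == 1L))
  }
})

test_that("lineage contrast requires elevation over every stage", {
  expr <- tidyr::expand_grid(
    feature = c("f1", "f2", "f3"),
    stage = c("FLC_PDX", "BTSC", "HpSC", "HB", "AHEP"),
    rep = 1:3
  )
  expr$value <- 10
  expr$value[expr$feature == "f2" & expr$stage == "FLC_PDX"] <- 80 # 8-fold up
  expr$value[expr$feature == "f3" & expr$stage == "FLC_PDX"] <- 80
  expr$value[expr$feature == "f3" & expr$stage == "BTSC"] <- 100 # one stage higher

  out <- lineage_contrast(expr, c("f1", "f2", "f3"))
  expect_false(out$up[out$feature == "f1"]) # all equal
  expect_true(out$up[out$feature == "f2"])
  expect_false(out$up[out$feature == "f3"]) # fails "compared to all"

  expect_error(lineage_contrast(expr, "f1", model_stage = "NOPE"),
    class = "flcsig_data_error"
  )
})
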