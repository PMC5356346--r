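make_aln <- function(pos, cigar = "40M", flag = 0L, qname = NULL,
                     rname = "DNAJB1-PRKACA.fusion") {
  tibble::tibble(
    qname = qname %||% sprintf("r%03d", seq_along(pos)),
    flag = as.integer(flag), rname = rname, pos = as.integer(pos),
    cigar = cigar
  )
}

test_that("junction overlap requires the anchor on both sides", {
  jx <- fusion_junction(breakpoint = 1000, min_anchor = 8)
  # aligned span [bp-20, bp+20): covers both anchors
  ev <- count_junction_evidence(make_aln(pos = 1000 - 20 + 1), jx)
  expect_equal(ev$n_junction_reads, 1L)
  # span [bp-20, bp+4): only 4 bases right of the breakpoint
  ev2 <- count_junction_evidence(make_aln(pos = 1000 - 20 + 1, cigar = "24M"), jx)
  expect_equal(ev2$n_junction_reads, 0L)
  expect_equal(ev2$n_locus_reads, 1L)
})

test_that("spanning pairs need opposite-side mates and junction reads are excluded", {
  jx <- fusion_junction(breakpoint = 1000, min_anchor = 8)
  aln <- dplyr::bind_rows(
    make_aln(pos = 900, flag = 99L, qname = "p1"), # ends 939 < bp
    make_aln(pos = 1100, flag = 147L, qname = "p1"), # starts right of bp
    make_aln(pos = 800, flag = 99L, qname = "p2"), # both mates left
    make_aln(pos = 850, flag = 147L, qname = "p2")
  )
  ev <- count_junction_evidence(aln, jx)
  expect_equal(ev$n_spanning_pairs, 1L)
  expect_equal(ev$n_locus_reads, 4L)
})

test_that("counting matches the simulator truth table and is order-invariant", {
  spec <- fusion_sim_spec(
    n_junction_reads = 5, n_spanning_pairs = 3,
    n_background_reads = 92, seed = 9
  )
  fs <- simulate_fusion_reads(spec)
  jx <- fusion_junction(
    contig = spec$contig, breakpoint = spec$breakpoint,
    min_anchor = spec$min_anchor
  )
  aln <- read_alignments(fs$sam)
  ev <- count_junction_evidence(aln, jx)
  expect_equal(ev$n_junction_reads, 5L)
  expect_equal(ev$n_spanning_pairs, 3L)
  # each spanning pair contributes two primary records to the locus total
  expect_equal(ev$n_locus_reads, 5L + 2L * 3L + 92L)
  expect_equal(ev$pct_junction, 100 * 5 / 103)

  shuffled <- aln[sample.int(nrow(aln)), ]
  attr(shuffled, "contigs") <- attr(aln, "contigs")
  ev_shuf <- count_junction_evidence(shuffled, jx)
  expect_equal(
    ev_shuf[, -1],
    ev[, -1]
  )
})

test_that("anchor requirement is monotone in junction counts", {
  fs <- simulate_fusion_reads(fusion_sim_spec(
    n_junction_reads = 20, min_anchor = 1, seed = 4
  ))
  aln <- read_alignments(fs$sam)
  jx <- fusion_junction(breakpoint = 1000, min_anchor = 1)
  counts <- vapply(1:20, function(a) {
    count_junction_evidence(aln, jx, min_anchor = a)$n_junction_reads
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fusion calling applies both thresholds and negatives stay negative", {
  ev0 <- tibble::tibble(n_junction_reads = 0L, n_spanning_pairs = 0L)
  expect_false(call_fusion_positive(ev0)$call)
  ev <- tibble::tibble(n_junction_reads = 5L, n_spanning_pairs = 3L)
  expect_true(call_fusion_positive(ev)$call)
  expect_false(call_fusion_positive(ev, min_junction = 6)$call)
  expect_false(call_fusion_positive(
    tibble::tibble(n_junction_reads = 4L, n_spanning_pairs = 0L)
  )$call)

  # an evidence-free simulated sample is a negative downstream call
  fs <- simulate_fusion_reads(fusion_sim_spec(
    n_junction_reads = 0, n_spanning_pairs = 0, n_background_reads = 50, seed = 2
  ))
  ev_neg <- count_junction_evidence(fs$sam, fusion_junction())
  expect_false(call_fusion_positive(ev_neg)$call)
})

test_that("absent contig is an input error", {
  fs <- simulate_fusion_reads(fusion_sim_spec(seed = 1))
  expect_error(
    count_junction_evidence(fs$sam, fusion_junction(contig = "chrMissing")),
    class = "flcsig_data_error"
  )
})

test_that("evidence-group comparison uses the exact rank-sum test", {
  a <- tibble::tibble(pct_junction = c(1, 2, 3), pct_spanning = c(1, 2, 3))
  b <- tibble::tibble(pct_junction = c(4, 5, 6), pct_spanning = c(4, 5, 6))
  res <- compare_evidence_groups(a, b)
  expect_equal(res$p_value, c(0.1, 0.1))
  same <- compare_evidence_groups(a, a)
  expect_true(all(same$p_value == 1))
  expect_error(
    compare_evidence_groups(a[0, ], b),
    class = "flcsig_data_error"
  )
})
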