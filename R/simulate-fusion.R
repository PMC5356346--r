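#' Specify simulated read evidence at a fusion junction
#'
#' Describes a synthetic fusion contig (donor exon joined to acceptor exons,
#' as in the DNAJB1-PRKACA chimera) and how many reads of each evidence class
#' to emit: junction-overlapping reads whose aligned span crosses the
#' breakpoint with at least `min_anchor` aligned bases on each side,
#' junction-encompassing proper pairs with one mate entirely on each side, and
#' background reads confined to one side. Alignment to the contig is assumed
#' done upstream by a fusion-aware aligner; the simulator emits the resulting
#' alignment records directly.
#'
#' @param fusion_contig_length Contig length in bp.
#' @param breakpoint 0-based offset of the first acceptor base on the contig.
#' @param n_junction_reads,n_spanning_pairs,n_background_reads Evidence counts
#'   to plant.
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Fragment-size distribution for spanning pairs.
#' @param min_anchor Minimum aligned bases guaranteed on each side of the
#'   breakpoint for planted junction reads.
#' @param contig Contig name written to the SAM header.
#' @param seed Integer seed.
#' @return A list of class `flc_fusion_spec`.
#' @export
fusion_sim_spec <- function(fusion_contig_length = 2000L,
                            breakpoint = 1000L,
                            n_junction_reads = 5L,
                            n_spanning_pairs = 3L,
                            n_background_reads = 92L,
                            read_length = 50L,
                            insert_mean = 300,
                            insert_sd = 30,
                            min_anchor = 8L,
                            contig = "DNAJB1-PRKACA.fusion",
                            seed = 1L) {
  fusion_contig_length <- check_count(fusion_contig_length, "fusion_contig_length", 1L)
  breakpoint <- check_count(breakpoint, "breakpoint", 1L)
  read_length <- check_count(read_length, "read_length", 1L)
  min_anchor <- check_count(min_anchor, "min_anchor", 1L)
  if (breakpoint >= fusion_contig_length) {
    config_error("`breakpoint` must lie inside the contig.")
  }
  if (read_length >= fusion_contig_length) {
    config_error("`read_length` must be smaller than the contig.")
  }
  if (insert_mean < read_length) {
    config_error("Read geometry impossible: insert_mean < read_length.")
  }
  if (2L * min_anchor > read_length) {
    config_error("`min_anchor` cannot exceed half the read length.")
  }
  if (breakpoint < read_length || fusion_contig_length - breakpoint < read_length) {
    config_error("Breakpoint too close to a contig end for the given read length.")
  }
  structure(list(
    fusion_contig_length = fusion_contig_length, breakpoint = breakpoint,
    n_junction_reads = check_count(n_junction_reads, "n_junction_reads"),
    n_spanning_pairs = check_count(n_spanning_pairs, "n_spanning_pairs"),
    n_background_reads = check_count(n_background_reads, "n_background_reads"),
    read_length = read_length,
    insert_mean = check_number(insert_mean, "insert_mean", min = 1),
    insert_sd = check_number(insert_sd, "insert_sd", min = 0),
    min_anchor = min_anchor, contig = contig,
    seed = check_count(seed, "seed")
  ), class = "flc_fusion_spec")
}

#' Simulate alignment records at a fusion junction
#'
#' Writes a coordinate-sorted SAM file containing exactly the planted numbers
#' of junction-overlapping reads, junction-encompassing proper pairs, and
#' single-sided background reads, plus the truth counts. Junction and
#' background reads are emitted single-end; spanning evidence as proper pairs
#' (so each spanning pair contributes two records).
#'
#' @param spec A [fusion_sim_spec()].
#' @param path Output SAM path (default: a temp file).
#' @return List of class `flc_fusion_sim`: `sam` (path), `truth` (one-row
#'   tibble with planted counts, contig, breakpoint), `spec`.
#' @export
simulate_fusion_reads <- function(spec, path = tempfile(fileext = ".sam")) {
  if (!inherits(spec, "flc_fusion_spec")) config_error("`spec` must come from fusion_sim_spec().")
  len <- spec$read_length
  bp <- spec$breakpoint
  L <- spec$fusion_contig_length
  anc <- spec$min_anchor

  rec <- withr::with_seed(spec$seed, {
    recs <- list()
    # Junction reads: 0-based start in [bp + anc - len, bp - anc] guarantees
    # >= anc aligned bases on both sides of the breakpoint.
    if (spec$n_junction_reads > 0L) {
      starts <- seq(bp + anc - len, bp - anc)
      start0 <- starts[sample.int(length(starts), spec$n_junction_reads, replace = TRUE)]
      recs$junction <- tibble(
        qname = sprintf("junc%04d", seq_len(spec$n_junction_reads)),
        flag = 0L, pos = start0 + 1L
      )
    }
    # Spanning pairs: fragment insert >= 2*len + 2 so both mates clear the
    # breakpoint; left mate ends at or before bp, right mate starts at or
    # after bp.
    if (spec$n_spanning_pairs > 0L) {
      ins <- pmax(2L * len + 2L, round(rnorm(spec$n_spanning_pairs, spec$insert_mean, spec$insert_sd)))
      lo <- pmax(0L, bp - ins + len)
      hi <- bp - len
      if (any(lo > hi)) config_error("Breakpoint too close to contig start for spanning inserts.")
      s1 <- floor(runif(spec$n_spanning_pairs, lo, hi + 1))
      s2 <- pmin(s1 + ins - len, L - len)
      recs$span1 <- tibble(
        qname = sprintf("span%04d", seq_len(spec$n_spanning_pairs)),
        flag = 99L, pos = s1 + 1L, mpos = s2 + 1L, tlen = as.integer(ins)
      )
      recs$span2 <- tibble(
        qname = recs$span1$qname,
        flag = 147L, pos = s2 + 1L, mpos = s1 + 1L, tlen = -as.integer(ins)
      )
    }
    # Background: single-end reads entirely left or entirely right of the
    # breakpoint; never junction-overlapping, never in a pair.
    if (spec$n_background_reads > 0L) {
      side <- runif(spec$n_background_reads) < 0.5
      start0 <- integer(spec$n_background_reads)
      start0[side] <- floor(runif(sum(side), 0, bp - len + 1))
      start0[!side] <- floor(runif(sum(!side), bp, L - len + 1))
      recs$bg <- tibble(
        qname = sprintf("bg%05d", seq_len(spec$n_background_reads)),
        flag = 0L, pos = start0 + 1L
      )
    }
    rec <- dplyr::bind_rows(recs)
    if (nrow(rec) == 0L) {
      rec <- tibble(qname = character(), flag = integer(), pos = integer())
    }
    if (!"mpos" %in% names(rec)) rec$mpos <- NA_integer_
    if (!"tlen" %in% names(rec)) rec$tlen <- NA_integer_
    rec$seq <- vapply(
      seq_len(nrow(rec)),
      function(i) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1)
    )
    dplyr::arrange(rec, .data$pos, .data$qname)
  })

  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", spec$contig, L)
  )
  body <- if (nrow(rec) > 0L) {
    sprintf(
      "%s\t%d\t%s\t%d\t60\t%dM\t%s\t%d\t%d\t%s\t*",
      rec$qname, rec$flag, spec$contig, rec$pos, len,
      ifelse(is.na(rec$mpos), "*", "="),
      ifelse(is.na(rec$mpos), 0L, rec$mpos),
      ifelse(is.na(rec$tlen), 0L, rec$tlen),
      rec$seq
    )
  } else {
    character()
  }
  writeLines(c(header, body), path)

  structure(list(
    sam = path,
    truth = tibble(
      n_junction_reads = spec$n_junction_reads,
      n_spanning_pairs = spec$n_spanning_pairs,
      n_background_reads = spec$n_background_reads,
      contig = spec$contig, breakpoint = bp, min_anchor = anc
    ),
    spec = spec
  ), class = "flc_fusion_sim")
}
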