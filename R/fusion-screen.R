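#' Define a fusion junction on a fused reference contig
#'
#' @param contig Name of the fusion contig the reads were aligned to.
#' @param breakpoint 0-based position of the first base of the acceptor
#'   segment (e.g. the first PRKACA base after DNAJB1 exon 1).
#' @param donor,acceptor Gene labels, for reporting.
#' @param min_anchor Minimum aligned bases required on each side of the
#'   breakpoint for a read to count as junction-overlapping.
#' @return A list of class `flc_junction`.
#' @export
fusion_junction <- function(contig = "DNAJB1-PRKACA.fusion",
                            breakpoint = 1000L,
                            donor = "DNAJB1", acceptor = "PRKACA",
                            min_anchor = 8L) {
  structure(list(
    contig = contig,
    breakpoint = check_count(breakpoint, "breakpoint", min = 1L),
    donor = donor, acceptor = acceptor,
    min_anchor = check_count(min_anchor, "min_anchor", min = 1L)
  ), class = "flc_junction")
}

# Reference-consumed width of a CIGAR string (M/D/N/=/X advance the
# reference).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") {
      return(0L)
    }
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- substring(ops, nchar(ops))
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read primary alignment records from a SAM/BAM file
#'
#' Loads the fields needed for junction-evidence counting. Secondary (0x100),
#' supplementary (0x800) and unmapped (0x4) records are dropped.
#'
#' @param path SAM or BAM file. SAM input is converted with
#'   [Rsamtools::asBam()] on the fly.
#' @return Tibble with qname, flag, rname, pos (1-based), cigar, ref_width.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) data_error(sprintf("Alignment file not found: %s", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE, indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar")
    )
  )[[1]]
  tbl <- tibble(
    qname = res$qname, flag = res$flag,
    rname = as.character(res$rname), pos = res$pos, cigar = res$cigar
  )
  tbl <- dplyr::filter(tbl, bitwAnd(.data$flag, 0x904) == 0L)
  tbl$ref_width <- cigar_ref_width(tbl$cigar)
  attr(tbl, "contigs") <- names(Rsamtools::scanBamHeader(bam)[[1]]$targets)
  tbl
}

#' Count split-read and spanning-pair evidence for a fusion junction
#'
#' A read is junction-overlapping iff its aligned reference span covers
#' `[breakpoint - min_anchor, breakpoint + min_anchor)` (0-based half-open).
#' A pair is junction-encompassing iff both mates map to the contig, one
#' mate's span lies entirely left of the breakpoint and the other entirely
#' right, and neither mate is itself junction-overlapping. `n_locus_reads`
#' counts every primary read on the contig (each mate counts once), and is
#' the denominator of both percentages. Counting is invariant to record
#' order; duplicate-flagged records (0x400) are dropped when
#' `drop_duplicates = TRUE`.
#'
#' @param alignments Path to a SAM/BAM file, or a tibble from
#'   [read_alignments()].
#' @param junction A [fusion_junction()].
#' @param min_anchor Override of the junction's anchor requirement.
#' @param sample_id Label recorded in the output row.
#' @param drop_duplicates Drop records flagged as PCR/optical duplicates.
#' @return One-row tibble of class `flc_fusion_evidence`: sample_id,
#'   n_junction_reads, n_spanning_pairs, n_locus_reads, pct_junction,
#'   pct_spanning.
#' @export
count_junction_evidence <- function(alignments, junction,
                                    min_anchor = junction$min_anchor,
                                    sample_id = "sample",
                                    drop_duplicates = FALSE) {
  if (!inherits(junction, "flc_junction")) config_error("`junction` must come from fusion_junction().")
  min_anchor <- check_count(min_anchor, "min_anchor", min = 1L)
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  contigs <- attr(alignments, "contigs")
  if (!is.null(contigs) && !(junction$contig %in% contigs)) {
    data_error(sprintf("Contig '%s' absent from alignment header.", junction$contig))
  }
  if (!"ref_width" %in% names(alignments)) {
    alignments$ref_width <- cigar_ref_width(alignments$cigar)
  }
  aln <- dplyr::filter(alignments, bitwAnd(.data$flag, 0x904) == 0L)
  if (drop_duplicates) aln <- dplyr::filter(aln, bitwAnd(.data$flag, 0x400) == 0L)
  aln <- dplyr::filter(aln, .data$rname == junction$contig)

  bp <- junction$breakpoint
  start0 <- aln$pos - 1L
  end0 <- start0 + aln$ref_width # half-open end
  overlapping <- start0 <= (bp - min_anchor) & end0 >= (bp + min_anchor)
  left <- end0 <= bp
  right <- start0 >= bp

  n_locus <- nrow(aln)
  n_junction <- sum(overlapping)

  paired <- bitwAnd(aln$flag, 0x1) != 0L
  n_spanning <- 0L
  if (any(paired)) {
    pr <- tibble(
      qname = aln$qname[paired],
      left = left[paired] & !overlapping[paired],
      right = right[paired] & !overlapping[paired]
    )
    pr <- dplyr::summarise(dplyr::group_by(pr, .data$qname),
      span = dplyr::n() == 2L && any(.data$left) && any(.data$right),
      .groups = "drop"
    )
    n_spanning <- sum(pr$span)
  }

  out <- tibble(
    sample_id = sample_id,
    n_junction_reads = as.integer(n_junction),
    n_spanning_pairs = as.integer(n_spanning),
    n_locus_reads = as.integer(n_locus),
    pct_junction = if (n_locus > 0) 100 * n_junction / n_locus else 0,
    pct_spanning = if (n_locus > 0) 100 * n_spanning / n_locus else 0
  )
  class(out) <- c("flc_fusion_evidence", class(out))
  out
}

#' Call samples fusion-positive from junction evidence
#'
#' A sample is called positive iff it has at least `min_junction`
#' junction-overlapping reads and at least `min_spanning` spanning pairs.
#' The thresholds operationalize "robust evidence" and are deliberately
#' exposed; the defaults (2 split reads, 1 spanning pair) follow common
#' fusion-calling practice.
#'
#' @param evidence Tibble with columns n_junction_reads, n_spanning_pairs
#'   (one row per sample), e.g. from [count_junction_evidence()].
#' @param min_junction,min_spanning Evidence thresholds.
#' @return `evidence` with a logical `call` column appended.
#' @export
call_fusion_positive <- function(evidence, min_junction = 2L, min_spanning = 1L) {
  if (!all(c("n_junction_reads", "n_spanning_pairs") %in% names(evidence))) {
    data_error("`evidence` needs n_junction_reads and n_spanning_pairs columns.")
  }
  dplyr::mutate(
    evidence,
    call = .data$n_junction_reads >= min_junction & .data$n_spanning_pairs >= min_spanning
  )
}

#' Compare junction-evidence metrics between two sample groups
#'
#' Two-sided Mann-Whitney rank-sum test on the junction-overlap and
#' spanning-pair percentages between two groups of fusion-positive samples
#' (e.g. classical-histology vs mixed-histology tumors).
#'
#' @param evidence_a,evidence_b Evidence tibbles with pct_junction and
#'   pct_spanning columns.
#' @return Tibble with one row per metric: metric, n_a, n_b, p_value.
#' @export
compare_evidence_groups <- function(evidence_a, evidence_b) {
  if (nrow(evidence_a) < 1L || nrow(evidence_b) < 1L) {
    data_error("Both evidence groups must be non-empty.")
  }
  purrr::map_dfr(c("pct_junction", "pct_spanning"), function(metric) {
    tibble(
      metric = metric,
      n_a = nrow(evidence_a), n_b = nrow(evidence_b),
      p_value = rank_sum_p(evidence_a[[metric]], evidence_b[[metric]])
    )
  })
}
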