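#' Raw-read rejection thresholds
#'
#' The three rejection rules applied to raw reads: (1) proportion of N bases
#' `>= max_n_fraction`; (2) proportion of bases with quality below
#' `low_q_cutoff` at or above `max_low_q_fraction`; (3) mean read quality
#' strictly below `min_mean_quality`. Inequality directions are part of the
#' contract and exercised by boundary tests.
#'
#' @param max_n_fraction rule-1 N-base fraction (default 0.10, inclusive).
#' @param low_q_cutoff Phred value defining a "low quality" base (default 5,
#'   i.e. bases with Q < 5 count as low).
#' @param max_low_q_fraction rule-2 low-quality-base fraction (default 0.50,
#'   inclusive).
#' @param min_mean_quality rule-3 mean quality floor (default 10; reads with
#'   mean strictly below are rejected).
#' @param mean_quality_mode `"phred"` (arithmetic mean of Phred scores,
#'   default) or `"error"` (mean on the error-probability scale, reported
#'   back as -10 log10).
#' @return a list of class `read_filter_thresholds`.
#' @export
read_filter_thresholds <- function(max_n_fraction = 0.10,
                                   low_q_cutoff = 5L,
                                   max_low_q_fraction = 0.50,
                                   min_mean_quality = 10,
                                   mean_quality_mode = c("phred", "error")) {
  stopifnot(max_n_fraction >= 0, max_n_fraction <= 1,
            max_low_q_fraction >= 0, max_low_q_fraction <= 1,
            low_q_cutoff >= 0, min_mean_quality >= 0)
  structure(list(max_n_fraction = max_n_fraction,
                 low_q_cutoff = as.integer(low_q_cutoff),
                 max_low_q_fraction = max_low_q_fraction,
                 min_mean_quality = min_mean_quality,
                 mean_quality_mode = match.arg(mean_quality_mode)),
            class = "read_filter_thresholds")
}

#' Filter raw reads by N content and base quality
#'
#' A read is rejected iff it violates at least one rule of
#' [read_filter_thresholds()]; each rejected read is attributed to every rule
#' it violates. Zero-length reads are rejected and tallied separately
#' (denominators never divide by zero). Filtering is order-independent and
#' idempotent.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet] (see
#'   [read_fastq()]).
#' @param thresholds a [read_filter_thresholds()].
#' @return list with `passed` (the retained reads, order preserved) and
#'   `counts`, a named integer vector: `input, passed, rejected, rule1_n,
#'   rule2_low_q, rule3_mean_q, zero_length`.
#' @export
filter_reads <- function(reads, thresholds = read_filter_thresholds()) {
  n <- length(reads)
  if (n == 0) {
    return(list(passed = reads,
                counts = c(input = 0L, passed = 0L, rejected = 0L,
                           rule1_n = 0L, rule2_low_q = 0L,
                           rule3_mean_q = 0L, zero_length = 0L)))
  }
  w <- Biostrings::width(reads)
  zero <- w == 0L
  nfrac <- rep(0, n)
  lowfrac <- rep(0, n)
  meanq <- rep(Inf, n)
  if (any(!zero)) {
    nn <- as.vector(Biostrings::letterFrequency(
      as(reads, "DNAStringSet"), letters = "N"))
    quals <- as(quality(reads), "IntegerList")
    low_counts <- sum(quals < thresholds$low_q_cutoff)
    qsum <- sum(quals)
    nfrac[!zero] <- nn[!zero] / w[!zero]
    lowfrac[!zero] <- low_counts[!zero] / w[!zero]
    if (thresholds$mean_quality_mode == "phred") {
      meanq[!zero] <- qsum[!zero] / w[!zero]
    } else {
      perr <- sum(10^(-as(quals, "NumericList") / 10))
      meanq[!zero] <- -10 * log10(perr[!zero] / w[!zero])
    }
  }
  r1 <- !zero & nfrac >= thresholds$max_n_fraction
  r2 <- !zero & lowfrac >= thresholds$max_low_q_fraction
  r3 <- !zero & meanq < thresholds$min_mean_quality
  reject <- r1 | r2 | r3 | zero
  list(passed = reads[!reject],
       counts = c(input = n, passed = sum(!reject), rejected = sum(reject),
                  rule1_n = sum(r1), rule2_low_q = sum(r2),
                  rule3_mean_q = sum(r3), zero_length = sum(zero)))
}

#' Coverage summary over target regions
#'
#' Computes the mean depth over the target (`total on-target sequenced bases
#' / target size`) and, for each depth threshold, the fraction of target
#' bases at or above it. Target bases not covered by the depth table count as
#' depth 0. The depth table's `count` column is read as a constant per-base
#' depth over each interval.
#'
#' @param depth_table data.frame with `chrom, start, end, count` (1-based
#'   inclusive; see [read_depth_table()]).
#' @param targets target regions: GRanges or data.frame with
#'   `chrom, start, end` (1-based inclusive).
#' @param thresholds depth thresholds for the coverage fractions
#'   (default `c(1, 10, 20)`).
#' @return list of class `coverage_summary`: `mean_depth`, `target_size`,
#'   `coverage_fractions` (named by threshold).
#' @export
coverage_summary <- function(depth_table, targets,
                             thresholds = c(1, 10, 20)) {
  tgt <- as_granges(targets)
  if (length(tgt) == 0) stop("coverage_summary: empty target set")
  tgt <- GenomicRanges::reduce(tgt)
  target_size <- sum(GenomicRanges::width(tgt))
  dgr <- GenomicRanges::GRanges(
    depth_table$chrom,
    IRanges::IRanges(start = depth_table$start, end = depth_table$end))
  hits <- GenomicRanges::findOverlaps(dgr, tgt)
  ov <- GenomicRanges::pintersect(dgr[S4Vectors::queryHits(hits)],
                                  tgt[S4Vectors::subjectHits(hits)])
  ow <- GenomicRanges::width(ov)
  depth <- depth_table$count[S4Vectors::queryHits(hits)]
  total_bases <- sum(as.numeric(ow) * depth)
  thresholds <- sort(thresholds)
  fr <- vapply(thresholds,
               function(th) sum(as.numeric(ow)[depth >= th]) / target_size,
               numeric(1))
  structure(list(mean_depth = total_bases / target_size,
                 target_size = target_size,
                 coverage_fractions = setNames(fr, paste0(">=", thresholds, "X"))),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("coverage_summary: mean depth %.2fX over %s bp target\n",
              x$mean_depth, format(x$target_size, big.mark = ",")))
  for (i in seq_along(x$coverage_fractions))
    cat(sprintf("  %s: %.4f\n", names(x$coverage_fractions)[i],
                x$coverage_fractions[i]))
  invisible(x)
}
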