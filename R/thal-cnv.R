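#' Tile unique regions into fixed windows and attach read counts
#'
#' Windows tile each unique region left to right at `window_size` bp; a
#' short terminal remainder is kept only when it spans at least half a
#' window. Counts from the depth table are apportioned by overlap fraction
#' (each depth row's reads are assumed uniform over its interval);
#' `gc_fraction` is the overlap-weighted mean of the rows' GC.
#'
#' @param depth_table data.frame `chrom, start, end, count[, gc_fraction]`
#'   (1-based inclusive; see [read_depth_table()]).
#' @param unique_regions GRanges or data.frame (`chrom, start, end`,
#'   1-based inclusive) of uniquely mappable regions; sorted,
#'   non-overlapping.
#' @param window_size window width in bp (default 500).
#' @return data.frame of windows: `chrom, start, end, raw_count,
#'   gc_fraction`.
#' @export
bin_and_count <- function(depth_table, unique_regions, window_size = 500L) {
  stopifnot(window_size > 0)
  regions <- as_granges(unique_regions)
  if (length(regions) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), raw_count = numeric(),
                      gc_fraction = numeric()))
  wins <- lapply(seq_along(regions), function(i) {
    s <- GenomicRanges::start(regions)[i]
    e <- GenomicRanges::end(regions)[i]
    starts <- seq(s, e, by = window_size)
    ends <- pmin(starts + window_size - 1L, e)
    keep <- (ends - starts + 1L) >= window_size / 2
    data.frame(chrom = as.character(GenomicRanges::seqnames(regions))[i],
               start = starts[keep], end = ends[keep])
  })
  wins <- do.call(rbind, wins)
  wgr <- GenomicRanges::GRanges(wins$chrom,
                                IRanges::IRanges(wins$start, wins$end))
  dgr <- GenomicRanges::GRanges(
    depth_table$chrom,
    IRanges::IRanges(depth_table$start, depth_table$end))
  hits <- GenomicRanges::findOverlaps(dgr, wgr)
  ov <- GenomicRanges::pintersect(dgr[S4Vectors::queryHits(hits)],
                                  wgr[S4Vectors::subjectHits(hits)])
  frac <- GenomicRanges::width(ov) /
    GenomicRanges::width(dgr[S4Vectors::queryHits(hits)])
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  counts <- rep(0, nrow(wins))
  add <- tapply(depth_table$count[qi] * frac, si, sum)
  counts[as.integer(names(add))] <- as.numeric(add)
  gc <- rep(NA_real_, nrow(wins))
  if ("gc_fraction" %in% names(depth_table)) {
    ww <- GenomicRanges::width(ov)
    gw <- tapply(depth_table$gc_fraction[qi] * ww, si, sum)
    tw <- tapply(ww, si, sum)
    gc[as.integer(names(gw))] <- as.numeric(gw) / as.numeric(tw)
  }
  data.frame(chrom = wins$chrom, start = wins$start, end = wins$end,
             raw_count = counts, gc_fraction = gc,
             stringsAsFactors = FALSE)
}

#' GC and batch correction of window counts
#'
#' Windows are stratified into GC bins of width `gc_bin_width`; each count is
#' divided by its bin median (bins with fewer than `min_bin` windows borrow
#' the nearest populated bin) and then by the global median of those ratios,
#' centering copy-number-2 windows at ratio 1. When a reference panel is
#' supplied, each ratio is further divided by the panel's per-window
#' normalized median (batch correction); without a panel that step is
#' skipped with a warning only if `warn_no_panel`.
#'
#' @param windows output of [bin_and_count()].
#' @param panel optional numeric vector of per-window median counts from
#'   reference samples (same window order).
#' @param gc_bin_width GC stratum width (default 0.01).
#' @param min_bin minimum windows per GC stratum (default 10).
#' @param warn_no_panel warn when no panel is given (default FALSE).
#' @return `windows` with a `corrected_ratio` column added.
#' @export
gc_batch_correct <- function(windows, panel = NULL, gc_bin_width = 0.01,
                             min_bin = 10L, warn_no_panel = FALSE) {
  if (all(windows$raw_count == 0))
    stop("gc_batch_correct: all window counts are zero")
  gc <- windows$gc_fraction
  if (all(is.na(gc))) gc <- rep(0.5, nrow(windows))
  gc[is.na(gc)] <- median(gc, na.rm = TRUE)
  bin <- floor(gc / gc_bin_width)
  bin_ids <- sort(unique(bin))
  bin_n <- table(factor(bin, levels = bin_ids))
  bin_med <- tapply(windows$raw_count, factor(bin, levels = bin_ids),
                    median)
  ok <- bin_n >= min_bin & bin_med > 0
  if (!any(ok))
    stop("gc_batch_correct: no GC stratum has enough windows")
  ok_ids <- bin_ids[ok]
  nearest <- ok_ids[vapply(bin_ids, function(b)
    which.min(abs(ok_ids - b)), integer(1))]
  med_for <- setNames(as.numeric(bin_med[match(nearest, bin_ids)]),
                      bin_ids)
  ratio <- windows$raw_count / med_for[as.character(bin)]
  ratio <- ratio / median(ratio)
  if (!is.null(panel)) {
    if (length(panel) != nrow(windows))
      stop("gc_batch_correct: panel does not cover the windows")
    pnorm <- panel / median(panel)
    pnorm[pnorm <= 0] <- 1
    ratio <- ratio / pnorm
  } else if (warn_no_panel) {
    warning("gc_batch_correct: no reference panel; batch step skipped")
  }
  windows$corrected_ratio <- as.numeric(ratio)
  windows
}

#' HMM parameters for copy-number segmentation
#'
#' Gaussian emissions on the corrected depth ratio with per-state means
#' `CN/2` (CN0 floored at `cn0_mean` — a true zero would be degenerate) and
#' a shared standard deviation. The transition matrix keeps the current
#' state with probability `stay_probability` (about one breakpoint per
#' `1/(1-stay)` windows) and splits the remainder evenly; the initial
#' distribution puts `cn2_weight` on CN2.
#'
#' @param states integer copy-number states (default 0:4).
#' @param sd shared emission standard deviation (default 0.12).
#' @param stay_probability diagonal transition probability (default
#'   `1 - 1e-4`).
#' @param cn2_weight initial probability of CN2 (default 0.96).
#' @param cn0_mean emission mean for CN0 (default 0.05).
#' @return list of class `hmm_params` with `states, means, sd, log_init,
#'   log_trans`.
#' @export
hmm_params <- function(states = 0:4, sd = 0.12,
                       stay_probability = 1 - 1e-4, cn2_weight = 0.96,
                       cn0_mean = 0.05) {
  S <- length(states)
  stopifnot(S >= 2, sd > 0, stay_probability > 0, stay_probability < 1,
            cn2_weight > 0, cn2_weight < 1)
  means <- ifelse(states == 0, cn0_mean, states / 2)
  init <- rep((1 - cn2_weight) / (S - 1), S)
  init[states == 2] <- cn2_weight
  trans <- matrix((1 - stay_probability) / (S - 1), S, S)
  diag(trans) <- stay_probability
  structure(list(states = states, means = means, sd = sd,
                 log_init = log(init), log_trans = log(trans)),
            class = "hmm_params")
}

## Viterbi decoding, log space; returns the most probable state path
viterbi_path <- function(obs, params) {
  S <- length(params$states)
  T_ <- length(obs)
  lemit <- vapply(seq_len(S), function(s)
    dnorm(obs, params$means[s], params$sd, log = TRUE), numeric(T_))
  lemit <- matrix(lemit, nrow = T_)
  delta <- params$log_init + lemit[1, ]
  psi <- matrix(0L, T_, S)
  if (T_ > 1) {
    for (t in 2:T_) {
      cand <- delta + params$log_trans        # S x S: from row, to column
      psi[t, ] <- max.col(t(cand), ties.method = "first")
      delta <- cand[cbind(psi[t, ], seq_len(S))] + lemit[t, ]
    }
  }
  path <- integer(T_)
  path[T_] <- which.max(delta)
  if (T_ > 1) for (t in (T_ - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  params$states[path]
}

#' Segment corrected depth ratios into constant copy-number intervals
#'
#' Viterbi decoding of the copy-number state path per chromosome, followed
#' by merging consecutive equal-state windows into segments.
#'
#' @param windows output of [gc_batch_correct()] (needs `corrected_ratio`).
#' @param params an [hmm_params()].
#' @return data.frame of segments: `chrom, start, end, copy_number,
#'   n_windows, mean_ratio`; non-overlapping, sorted, with consecutive
#'   segments on a chromosome carrying distinct copy numbers.
#' @export
hmm_segment <- function(windows, params = hmm_params()) {
  stopifnot(all(is.finite(windows$corrected_ratio)))
  out <- lapply(split(seq_len(nrow(windows)), windows$chrom), function(idx) {
    sub <- windows[idx, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    path <- viterbi_path(sub$corrected_ratio, params)
    runs <- rle(path)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    data.frame(chrom = sub$chrom[1],
               start = sub$start[starts], end = sub$end[ends],
               copy_number = runs$values, n_windows = runs$lengths,
               mean_ratio = vapply(seq_along(starts), function(i)
                 mean(sub$corrected_ratio[starts[i]:ends[i]]), numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Assign a thalassemia genotype from copy-number segments
#'
#' Deletion segments (copy number below 2) are matched against the known
#' allele registry: a match requires reciprocal overlap of at least
#' `min_reciprocal_overlap` and both breakpoints within `breakpoint_tol`.
#' CN1 over an allele means one deleted haplotype (e.g. `--SEA/aa`), CN0
#' both (`--SEA/--SEA`); two different matched CN1 alleles form a compound
#' genotype. Unmatched deletions are reported as novel with coordinates.
#' Haplotype labels are ASCII (`aa` denotes the intact allele).
#'
#' @param segments output of [hmm_segment()].
#' @param alleles registry from [load_known_alleles()] (GRanges with
#'   `label`).
#' @param min_reciprocal_overlap default 0.8.
#' @param breakpoint_tol breakpoint tolerance in bp (default 5000).
#' @return object of class `thal_genotype`: `genotype` string, `matches`
#'   data.frame, `novel` data.frame, `ambiguous` flag.
#' @export
call_thal_genotype <- function(segments, alleles,
                               min_reciprocal_overlap = 0.8,
                               breakpoint_tol = 5000) {
  dels <- segments[segments$copy_number < 2, , drop = FALSE]
  matches <- data.frame(label = character(), copy_number = integer(),
                        chrom = character(), start = integer(),
                        end = integer(), reciprocal_overlap = numeric(),
                        stringsAsFactors = FALSE)
  novel <- dels[0, , drop = FALSE]
  ambiguous <- FALSE
  a_chrom <- as.character(GenomicRanges::seqnames(alleles))
  a_start <- GenomicRanges::start(alleles)
  a_end <- GenomicRanges::end(alleles)
  a_label <- S4Vectors::mcols(alleles)$label
  for (i in seq_len(nrow(dels))) {
    s <- dels$start[i]; e <- dels$end[i]
    ov <- pmax(0, pmin(e, a_end) - pmax(s, a_start) + 1)
    rec <- pmin(ov / (e - s + 1), ov / (a_end - a_start + 1))
    hit <- which(rec >= min_reciprocal_overlap &
                   a_chrom == dels$chrom[i] &
                   abs(s - a_start) <= breakpoint_tol &
                   abs(e - a_end) <= breakpoint_tol)
    if (length(hit) == 0) {
      novel <- rbind(novel, dels[i, , drop = FALSE])
    } else {
      if (length(hit) > 1) {
        best <- hit[order(rec[hit], decreasing = TRUE)]
        if (length(best) > 1 && rec[best[1]] == rec[best[2]])
          ambiguous <- TRUE
        hit <- best[1]
      }
      matches <- rbind(matches, data.frame(
        label = a_label[hit], copy_number = dels$copy_number[i],
        chrom = dels$chrom[i], start = s, end = e,
        reciprocal_overlap = rec[hit], stringsAsFactors = FALSE))
    }
  }
  haplos <- character()
  for (i in seq_len(nrow(matches)))
    haplos <- c(haplos,
                rep(matches$label[i], 2 - matches$copy_number[i]))
  for (i in seq_len(nrow(novel)))
    haplos <- c(haplos,
                rep(sprintf("novel_del(%s:%d-%d)", novel$chrom[i],
                            novel$start[i], novel$end[i]),
                    2 - novel$copy_number[i]))
  genotype <- if (length(haplos) == 0) "aa/aa"
  else if (length(haplos) == 1) paste0(haplos, "/aa")
  else paste(haplos[1], haplos[2], sep = "/")
  structure(list(genotype = genotype, matches = matches, novel = novel,
                 ambiguous = ambiguous),
            class = "thal_genotype")
}

#' @export
print.thal_genotype <- function(x, ...) {
  cat("thal_genotype:", x$genotype,
      if (x$ambiguous) "[ambiguous match]" else "", "\n")
  invisible(x)
}

#' @importFrom stats dnorm
NULL
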