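#' AOH detection configuration
#'
#' Sliding-window absence-of-heterozygosity detection: overlapping windows of
#' `window_snps` consecutive SNPs advance one SNP at a time; a window is
#' homozygous when it contains at most `max_het_per_window` het calls.
#' Overlapping homozygous windows are unioned into regions, nearby regions
#' merge across gaps up to `max_join_gap`, and a region is terminal when it
#' comes within `terminal_margin` of a chromosome end. Terminal regions of at
#' least `terminal_min_length` are reported; interstitial reporting is
#' disabled by default (`Inf`).
#'
#' @param window_snps SNPs per window (default 20).
#' @param max_het_per_window het calls tolerated per homozygous window
#'   (default 1).
#' @param max_join_gap merge gap in bp (default 500000).
#' @param terminal_margin bp from a chromosome end within which a region is
#'   terminal (default 1e6).
#' @param terminal_min_length reporting floor for terminal regions (default
#'   5e6 bp).
#' @param interstitial_min_length reporting floor for interstitial regions
#'   (default `Inf`, i.e. disabled).
#' @return list of class `aoh_config`.
#' @export
aoh_config <- function(window_snps = 20L, max_het_per_window = 1L,
                       max_join_gap = 5e5, terminal_margin = 1e6,
                       terminal_min_length = 5e6,
                       interstitial_min_length = Inf) {
  stopifnot(window_snps >= 2, max_het_per_window >= 0, max_join_gap >= 0,
            terminal_margin >= 0, terminal_min_length >= 0)
  structure(list(window_snps = as.integer(window_snps),
                 max_het_per_window = as.integer(max_het_per_window),
                 max_join_gap = max_join_gap,
                 terminal_margin = terminal_margin,
                 terminal_min_length = terminal_min_length,
                 interstitial_min_length = interstitial_min_length),
            class = "aoh_config")
}

#' Scan one chromosome for homozygous windows
#'
#' @param snps a [snp_table()] restricted to a single chromosome, sorted by
#'   position; missing genotypes are excluded from the scan.
#' @param config an [aoh_config()].
#' @return data.frame with one row per window: `start_idx` (index of the
#'   window's first SNP among the genotyped SNPs), `het_count`,
#'   `homozygous`.
#' @export
scan_homozygosity <- function(snps, config = aoh_config()) {
  if (length(unique(snps$chrom)) > 1)
    stop("scan_homozygosity: one chromosome at a time")
  gt <- snps$genotype[snps$genotype != "missing"]
  w <- config$window_snps
  nwin <- length(gt) - w + 1L
  if (nwin < 1L)
    return(data.frame(start_idx = integer(), het_count = integer(),
                      homozygous = logical()))
  het <- as.integer(gt == "het")
  cs <- c(0L, cumsum(het))
  counts <- cs[(w + 1):(length(gt) + 1)] - cs[1:nwin]
  data.frame(start_idx = seq_len(nwin), het_count = counts,
             homozygous = counts <= config$max_het_per_window)
}

#' Assemble homozygous windows into candidate AOH regions
#'
#' Maximal unions of overlapping homozygous windows become regions; leading
#' and trailing het SNPs inside a union are trimmed so that regions start and
#' end on homozygous calls. Region coordinates then extend across the
#' uninformative flanks — from just after the previous het SNP to just before
#' the next one (the first/last homozygous SNP positions are kept as
#' `snp_start`/`snp_end`); a region reaching the first or last genotyped SNP
#' is marked open-ended so classification can clamp it to the chromosome end.
#' Regions separated by at most `max_join_gap` bp are merged.
#'
#' @param snps single-chromosome [snp_table()] (sorted).
#' @param flags output of [scan_homozygosity()] on the same SNPs.
#' @param config an [aoh_config()].
#' @return data.frame of candidate regions: `chrom, start, end, snp_start,
#'   snp_end, n_snps, n_het, open_left, open_right`.
#' @export
assemble_regions <- function(snps, flags, config = aoh_config()) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), snp_start = numeric(),
                      snp_end = numeric(), n_snps = integer(),
                      n_het = integer(), open_left = logical(),
                      open_right = logical())
  hom_idx <- flags$start_idx[flags$homozygous]
  if (length(hom_idx) == 0) return(empty)
  keep <- snps$genotype != "missing"
  pos <- snps$pos[keep]
  gt <- snps$genotype[keep]
  w <- config$window_snps
  ## windows at indices i, j (i < j) overlap iff j - i < w
  brk <- which(diff(hom_idx) >= w)
  grp_start <- hom_idx[c(1L, brk + 1L)]
  grp_end <- hom_idx[c(brk, length(hom_idx))] + w - 1L
  regions <- lapply(seq_along(grp_start), function(g) {
    i <- grp_start[g]; j <- grp_end[g]
    span <- i:j
    hom_in <- span[gt[span] != "het"]
    if (length(hom_in) == 0) return(NULL)
    i <- min(hom_in); j <- max(hom_in)
    open_l <- i == 1L
    open_r <- j == length(pos)
    data.frame(
      chrom = snps$chrom[1],
      start = if (open_l) pos[i] else pos[i - 1L] + 1,
      end = if (open_r) pos[j] else pos[j + 1L] - 1,
      snp_start = pos[i], snp_end = pos[j],
      n_snps = j - i + 1L, n_het = sum(gt[i:j] == "het"),
      open_left = open_l, open_right = open_r)
  })
  out <- do.call(rbind, regions)
  if (is.null(out) || nrow(out) == 0) return(empty)
  out <- out[order(out$start), , drop = FALSE]
  ## merge across small gaps
  merged <- out[1, , drop = FALSE]
  if (nrow(out) > 1) {
    for (r in 2:nrow(out)) {
      last <- nrow(merged)
      gap <- out$start[r] - merged$end[last] - 1
      if (gap <= config$max_join_gap) {
        merged$end[last] <- out$end[r]
        merged$snp_end[last] <- out$snp_end[r]
        merged$open_right[last] <- out$open_right[r]
        merged$n_snps[last] <- merged$n_snps[last] + out$n_snps[r]
        merged$n_het[last] <- merged$n_het[last] + out$n_het[r]
      } else {
        merged <- rbind(merged, out[r, , drop = FALSE])
      }
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Classify candidate regions and apply the reporting rules
#'
#' A region is terminal when its start is within `terminal_margin` of
#' position 1 or its end within `terminal_margin` of the chromosome length;
#' open-ended regions are first clamped to the chromosome ends. Reported
#' regions are terminal regions of at least `terminal_min_length`, plus
#' interstitial regions of at least `interstitial_min_length` when that rule
#' is enabled. Regions on a chromosome of unknown length are classified
#' interstitial with a warning.
#'
#' @param regions output of [assemble_regions()] (any number of
#'   chromosomes).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param config an [aoh_config()].
#' @return the regions data.frame with `length`, `classification`
#'   (`terminal`/`interstitial`) and `reported` columns added.
#' @export
classify_and_report <- function(regions, chrom_lengths,
                                config = aoh_config()) {
  if (nrow(regions) == 0) {
    regions$length <- numeric()
    regions$classification <- character()
    regions$reported <- logical()
    return(regions)
  }
  len <- chrom_lengths[regions$chrom]
  unknown <- is.na(len)
  if (any(unknown))
    warning("classify_and_report: unknown length for chromosome(s) ",
            paste(unique(regions$chrom[unknown]), collapse = ", "),
            "; classified interstitial")
  regions$start[regions$open_left & !unknown] <- 1
  regions$end[regions$open_right & !unknown] <-
    len[regions$open_right & !unknown]
  regions$length <- regions$end - regions$start + 1
  terminal <- !unknown &
    (regions$start <= 1 + config$terminal_margin |
       regions$end >= len - config$terminal_margin)
  regions$classification <- ifelse(terminal, "terminal", "interstitial")
  regions$reported <-
    (terminal & regions$length >= config$terminal_min_length) |
    (!terminal & regions$length >= config$interstitial_min_length)
  regions
}

#' Detect absence-of-heterozygosity regions genome-wide
#'
#' Runs the window scan, region assembly and classification per chromosome
#' and aggregates the genome-wide proportion of homozygous sites
#' (homozygous genotyped SNPs / all genotyped SNPs; missing excluded).
#'
#' @param snps a [snp_table()] (any number of chromosomes).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param config an [aoh_config()].
#' @return object of class `aoh_result`: `regions` (classified data.frame,
#'   sorted, non-overlapping), `proportion_homozygous`, `config`.
#' @export
detect_aoh <- function(snps, chrom_lengths, config = aoh_config()) {
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  per_chrom <- lapply(split(seq_len(nrow(snps)), snps$chrom), function(idx) {
    sub <- snps[idx, , drop = FALSE]
    flags <- scan_homozygosity(sub, config)
    assemble_regions(sub, flags, config)
  })
  regions <- do.call(rbind, per_chrom)
  if (is.null(regions))
    regions <- assemble_regions(
      snp_table(character(), integer(), character(), character(),
                integer(), integer()),
      data.frame(start_idx = integer(), het_count = integer(),
                 homozygous = logical()), config)
  rownames(regions) <- NULL
  regions <- classify_and_report(regions, chrom_lengths, config)
  genotyped <- snps$genotype[snps$genotype != "missing"]
  prop_hom <- if (length(genotyped) == 0) NA_real_ else
    mean(genotyped != "het")
  structure(list(regions = regions, proportion_homozygous = prop_hom,
                 config = config),
            class = "aoh_result")
}

#' Write AOH regions as BED (0-based half-open)
#'
#' @param result an `aoh_result` from [detect_aoh()].
#' @param path output path.
#' @param reported_only write only reported regions (default TRUE).
#' @return `path`, invisibly.
#' @export
write_aoh_bed <- function(result, path, reported_only = TRUE) {
  r <- result$regions
  if (reported_only) r <- r[r$reported, , drop = FALSE]
  df <- data.frame(chrom = r$chrom, start = format(r$start - 1,
                                                   scientific = FALSE),
                   end = format(r$end, scientific = FALSE),
                   name = paste0("AOH_", r$classification))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @export
print.aoh_result <- function(x, ...) {
  rep_r <- x$regions[x$regions$reported, , drop = FALSE]
  cat(sprintf(
    "aoh_result: %d candidate region(s), %d reported; %.1f%% homozygous sites\n",
    nrow(x$regions), nrow(rep_r), 100 * x$proportion_homozygous))
  for (i in seq_len(nrow(rep_r)))
    cat(sprintf("  %s:%.0f-%.0f  %.2f Mb  %s\n", rep_r$chrom[i],
                rep_r$start[i], rep_r$end[i], rep_r$length[i] / 1e6,
                rep_r$classification[i]))
  invisible(x)
}
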