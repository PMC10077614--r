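#' Default model genome for synthetic data
#'
#' Six autosomes of 60 Mb — a deliberately scaled-down stand-in for a human
#' genome that keeps every detector's statistics in their operating regime
#' (hundreds to thousands of het sites per chromosome at 40X) while staying
#' fast to simulate.
#'
#' @return named numeric vector of chromosome lengths (bp).
#' @export
model_genome <- function() {
  setNames(rep(6e7, 6), paste0("chr", 1:6))
}

## dosage -> expected alt-read fraction, with per-read error eps
dosage_to_p <- function(dosage, copies, eps) {
  p <- dosage / copies
  p[p == 0] <- eps
  p[p == 1] <- 1 - eps
  p
}

#' Simulate a genome-wide SNP table under a ploidy / AOH / contamination
#' state
#'
#' Site positions are uniform over each chromosome (about one SNP per
#' `snp_spacing` bp); population allele frequencies are Uniform(0.1, 0.9)
#' and genotypes Hardy-Weinberg. Per-site depth is Poisson with mean scaled
#' by the chromosome copy number (40X diploid baseline by default) and alt
#' counts are Binomial in the allele dosage: het-site fractions center on
#' 1/2 for diploid chromosomes and 1/3 or 2/3 for trisomic chromosomes or a
#' triploid genome. AOH regions force homozygous genotypes. Contamination
#' mixes a second genotype draw into the binomial success probability with
#' weight `alpha`. Identical seeds give identical tables.
#'
#' @param seed integer seed (all randomness flows from it).
#' @param chrom_lengths named vector of chromosome lengths
#'   (default [model_genome()]).
#' @param snp_spacing mean bp between SNPs (default 5000).
#' @param mean_depth diploid-baseline mean depth (default 40).
#' @param ploidy either the string `"triploid"` (genome-wide) or a named
#'   character vector per chromosome over
#'   `c("diploid","trisomy","monosomy")`; unnamed chromosomes are diploid.
#' @param aoh_regions data.frame `chrom, start, end` (1-based inclusive) of
#'   regions forced homozygous; must not overlap.
#' @param contamination_alpha contamination fraction in `[0, 0.5]`
#'   (default 0).
#' @param contaminant_relation `"unrelated"` or `"maternal"`.
#' @param error per-read sequencing error rate (default 0.002).
#' @return list with `snps` (a [snp_table()]; zero-depth sites dropped),
#'   `pop_af` (data.frame `chrom, pos, alt_af`) and `truth` (latent states:
#'   per-chromosome ploidy, AOH regions, alpha).
#' @export
simulate_snp_table <- function(seed = 1L,
                               chrom_lengths = model_genome(),
                               snp_spacing = 5000,
                               mean_depth = 40,
                               ploidy = character(),
                               aoh_regions = NULL,
                               contamination_alpha = 0,
                               contaminant_relation = c("unrelated",
                                                        "maternal"),
                               error = 0.002) {
  contaminant_relation <- match.arg(contaminant_relation)
  stopifnot(mean_depth > 0, contamination_alpha >= 0,
            contamination_alpha <= 0.5)
  genome_triploid <- identical(unname(ploidy), "triploid") &&
    length(ploidy) == 1 && is.null(names(ploidy))
  if (!is.null(aoh_regions) && nrow(aoh_regions) > 1) {
    gr <- as_granges(aoh_regions)
    if (length(GenomicRanges::reduce(gr)) < length(gr))
      stop("simulate_snp_table: overlapping AOH regions")
  }
  withr::with_seed(seed, {
    per_chrom <- lapply(names(chrom_lengths), function(ch) {
      len <- chrom_lengths[[ch]]
      n <- max(1L, round(len / snp_spacing))
      pos <- sort(sample.int(len, n))
      af <- runif(n, 0.1, 0.9)
      state <- if (genome_triploid) "triploid"
      else if (ch %in% names(ploidy)) unname(ploidy[ch]) else "diploid"
      copies <- switch(state, diploid = 2L, triploid = 3L, trisomy = 3L,
                       monosomy = 1L,
                       stop("unknown ploidy state '", state, "'"))
      dosage <- rbinom(n, copies, af)
      if (!is.null(aoh_regions)) {
        regs <- aoh_regions[aoh_regions$chrom == ch, , drop = FALSE]
        for (r in seq_len(nrow(regs))) {
          inside <- pos >= regs$start[r] & pos <= regs$end[r]
          dosage[inside] <- copies * rbinom(sum(inside), 1, af[inside])
        }
      }
      p_s <- dosage_to_p(dosage, copies, error)
      mu <- p_s
      if (contamination_alpha > 0) {
        if (contaminant_relation == "unrelated") {
          dos_c <- rbinom(n, 2, af)
        } else {
          ## the sample is the fetus; re-derive it from the mother so the
          ## pair shares a transmitted allele
          dos_m <- rbinom(n, 2, af)
          transmitted <- rbinom(n, 1, dos_m / 2)
          dosage <- transmitted + rbinom(n, 1, af)
          p_s <- dosage_to_p(dosage, 2L, error)
          dos_c <- dos_m
        }
        p_c <- dosage_to_p(dos_c, 2L, error)
        mu <- (1 - contamination_alpha) * p_s + contamination_alpha * p_c
      }
      depth <- rpois(n, mean_depth * copies / 2)
      alt <- rbinom(n, depth, mu)
      gt <- rep("het", n)
      gt[dosage == 0L] <- "hom_ref"
      gt[dosage == copies] <- "hom_alt"
      keep <- depth > 0L
      list(df = data.frame(chrom = ch, pos = pos[keep], af = af[keep],
                           depth = depth[keep], alt = alt[keep],
                           gt = gt[keep], stringsAsFactors = FALSE),
           state = state)
    })
    df <- do.call(rbind, lapply(per_chrom, `[[`, "df"))
    states <- setNames(vapply(per_chrom, `[[`, "", "state"),
                       names(chrom_lengths))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nrow(df), replace = TRUE)
    alt_base <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    snps <- snp_table(df$chrom, df$pos, ref, alt_base,
                      ref_depth = df$depth - df$alt, alt_depth = df$alt,
                      genotype = df$gt)
    list(snps = snps,
         pop_af = data.frame(chrom = df$chrom, pos = df$pos,
                             alt_af = df$af, stringsAsFactors = FALSE),
         truth = list(ploidy = states, aoh_regions = aoh_regions,
                      contamination_alpha = contamination_alpha,
                      genome_triploid = genome_triploid))
  })
}

#' Simulate per-chromosome mean depths under a ploidy state
#'
#' Windowed Poisson depths averaged per chromosome; a trisomic chromosome
#' runs at 1.5x the diploid baseline, a monosomic one at 0.5x, a triploid
#' genome uniformly at baseline (triploidy leaves depth *ratios* flat, which
#' is why it needs allele-fraction evidence).
#'
#' @param seed integer seed.
#' @param chrom_lengths named lengths (default [model_genome()]).
#' @param mean_depth diploid baseline (default 40).
#' @param ploidy as in [simulate_snp_table()].
#' @param n_windows depth windows per chromosome (default 200).
#' @return named numeric vector of per-chromosome mean depths.
#' @export
simulate_chrom_depth <- function(seed = 1L,
                                 chrom_lengths = model_genome(),
                                 mean_depth = 40, ploidy = character(),
                                 n_windows = 200L) {
  genome_triploid <- identical(unname(ploidy), "triploid") &&
    is.null(names(ploidy))
  withr::with_seed(seed, {
    vapply(names(chrom_lengths), function(ch) {
      state <- if (genome_triploid) "triploid"
      else if (ch %in% names(ploidy)) unname(ploidy[ch]) else "diploid"
      cn <- switch(state, diploid = 2, trisomy = 3, monosomy = 1,
                   triploid = 2)  # ratio-flat by construction
      mean(rpois(n_windows, mean_depth * cn / 2))
    }, numeric(1))
  })
}

#' Simulate contamination-model input sites
#'
#' Biallelic sites with Uniform(0.1, 0.9) population allele frequencies,
#' Hardy-Weinberg genotypes, Poisson depth, and alt counts Binomial in
#' `(1 - alpha) * m(g_sample) + alpha * m(g_contaminant)` — the exact
#' generative counterpart of the estimator's model.
#'
#' @param n_sites number of sites (default 10000).
#' @param alpha true contamination fraction.
#' @param mean_depth Poisson mean depth (default 40).
#' @param relation `"unrelated"` or `"maternal"` contaminant.
#' @param error per-read error rate (default 0.002).
#' @param seed integer seed.
#' @return list with `snps` (a [snp_table()]) and `pop_af`.
#' @export
simulate_contamination_sites <- function(n_sites = 10000L, alpha = 0,
                                         mean_depth = 40,
                                         relation = c("unrelated",
                                                      "maternal"),
                                         error = 0.002, seed = 1L) {
  relation <- match.arg(relation)
  stopifnot(alpha >= 0, alpha <= 0.5)
  withr::with_seed(seed, {
    af <- runif(n_sites, 0.1, 0.9)
    if (relation == "unrelated") {
      dos_s <- rbinom(n_sites, 2, af)
      dos_c <- rbinom(n_sites, 2, af)
    } else {
      dos_c <- rbinom(n_sites, 2, af)               # mother
      transmitted <- rbinom(n_sites, 1, dos_c / 2)
      dos_s <- transmitted + rbinom(n_sites, 1, af)  # fetus
    }
    mu <- (1 - alpha) * dosage_to_p(dos_s, 2L, error) +
      alpha * dosage_to_p(dos_c, 2L, error)
    depth <- rpois(n_sites, mean_depth)
    alt <- rbinom(n_sites, depth, mu)
    keep <- depth > 0L
    gt <- c("hom_ref", "het", "hom_alt")[dos_s + 1L]
    n_keep <- sum(keep)
    snps <- snp_table(rep("chrS", n_keep), seq_len(n_sites)[keep] * 100L,
                      rep("A", n_keep), rep("G", n_keep),
                      ref_depth = (depth - alt)[keep],
                      alt_depth = alt[keep], genotype = gt[keep])
    list(snps = snps,
         pop_af = data.frame(chrom = "chrS",
                             pos = seq_len(n_sites)[keep] * 100L,
                             alt_af = af[keep], stringsAsFactors = FALSE))
  })
}

#' Simulate a windowed depth profile with GC bias and CNV events
#'
#' Window counts are Poisson with mean
#' `mean_count * (CN/2) * (1 + gc_bias_slope * (gc - 0.5))`; GC fractions
#' are Uniform(0.3, 0.6) per window. Planted events override the diploid
#' copy number. Truth segments are returned alongside.
#'
#' @param regions data.frame `chrom, start, end` (1-based inclusive) to
#'   tile.
#' @param window_size bp per window (default 500).
#' @param mean_count expected reads per diploid window (default 100,
#'   i.e. roughly a 40X genome at 500 bp windows and short reads).
#' @param cnv_events optional data.frame `chrom, start, end, copy_number`.
#' @param gc_bias_slope linear GC bias slope (default 0).
#' @param seed integer seed.
#' @return list with `depth_table` (`chrom, start, end, count,
#'   gc_fraction`, 1-based inclusive) and `truth` (the events).
#' @export
simulate_depth_profile <- function(regions, window_size = 500L,
                                   mean_count = 100, cnv_events = NULL,
                                   gc_bias_slope = 0, seed = 1L) {
  withr::with_seed(seed, {
    wins <- lapply(seq_len(nrow(regions)), function(i) {
      starts <- seq(regions$start[i], regions$end[i], by = window_size)
      ends <- pmin(starts + window_size - 1L, regions$end[i])
      keep <- (ends - starts + 1L) >= window_size / 2
      data.frame(chrom = regions$chrom[i], start = starts[keep],
                 end = ends[keep], stringsAsFactors = FALSE)
    })
    wins <- do.call(rbind, wins)
    n <- nrow(wins)
    gc <- runif(n, 0.3, 0.6)
    cn <- rep(2, n)
    if (!is.null(cnv_events)) {
      for (i in seq_len(nrow(cnv_events))) {
        hit <- wins$chrom == cnv_events$chrom[i] &
          wins$start >= cnv_events$start[i] &
          wins$end <= cnv_events$end[i]
        cn[hit] <- cnv_events$copy_number[i]
      }
    }
    lambda <- mean_count * (cn / 2) * (1 + gc_bias_slope * (gc - 0.5))
    counts <- rpois(n, pmax(lambda, 0))
    list(depth_table = data.frame(chrom = wins$chrom, start = wins$start,
                                  end = wins$end, count = counts,
                                  gc_fraction = gc,
                                  stringsAsFactors = FALSE),
         truth = cnv_events)
  })
}

#' Simulate a PSV depth table for a given SMN copy-number state
#'
#' Combined PSV depth is Poisson with mean `mean_depth * total_cn / 2`;
#' SMN1-base support is Binomial in `smn1_cn / total_cn`; a small
#' `error` rate generates non-matching (`other`) reads.
#'
#' @param smn1_cn,smn2_cn integer copy numbers.
#' @param mean_depth genome mean depth (default 40).
#' @param psv PSV registry (default [smn_psv_sites()]).
#' @param error per-read error rate for `other` reads (default 0.002).
#' @param seed integer seed.
#' @return data.frame in the [psv_depth_from_alleles()] layout.
#' @export
simulate_psv_table <- function(smn1_cn, smn2_cn, mean_depth = 40,
                               psv = smn_psv_sites(), error = 0.002,
                               seed = 1L) {
  total <- smn1_cn + smn2_cn
  stopifnot(total > 0)
  withr::with_seed(seed, {
    n <- nrow(psv)
    combined <- rpois(n, mean_depth * total / 2)
    g1 <- rbinom(n, combined, smn1_cn / total)
    oth <- rpois(n, combined * error)
    data.frame(pos = psv$pos, exon_group = psv$exon_group,
               gene1_support = g1, gene2_support = combined - g1,
               other = oth, stringsAsFactors = FALSE)
  })
}

#' Simulate reads with controlled N content and quality
#'
#' Builds reads that hit (or avoid) each raw-read rejection rule on demand:
#' a chosen fraction of N bases, a chosen fraction of low-quality bases, and
#' a base quality for the remainder.
#'
#' @param n_reads number of reads.
#' @param read_length bases per read (default 100).
#' @param n_fraction fraction of N bases per read (default 0).
#' @param base_quality Phred score of ordinary bases (default 35).
#' @param low_q_fraction fraction of bases at `low_q_value` (default 0).
#' @param low_q_value Phred score of the low-quality bases (default 2).
#' @param seed integer seed.
#' @return a [Biostrings::QualityScaledDNAStringSet].
#' @export
simulate_reads <- function(n_reads, read_length = 100L, n_fraction = 0,
                           base_quality = 35L, low_q_fraction = 0,
                           low_q_value = 2L, seed = 1L) {
  withr::with_seed(seed, {
    n_n <- round(n_fraction * read_length)
    n_low <- round(low_q_fraction * read_length)
    seqs <- vapply(seq_len(n_reads), function(i) {
      b <- sample(c("A", "C", "G", "T"), read_length, replace = TRUE)
      if (n_n > 0) b[sample.int(read_length, n_n)] <- "N"
      paste(b, collapse = "")
    }, "")
    quals <- vapply(seq_len(n_reads), function(i) {
      q <- rep(as.integer(base_quality), read_length)
      if (n_low > 0) q[sample.int(read_length, n_low)] <-
          as.integer(low_q_value)
      rawToChar(as.raw(q + 33L))
    }, "")
    reads <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
    names(reads) <- sprintf("read_%d", seq_len(n_reads))
    reads
  })
}
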