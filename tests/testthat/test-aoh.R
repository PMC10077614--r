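test_that("window flags follow the het-count tolerance", {
  # 20 consecutive hom SNPs, window 20 -> a single homozygous window
  s <- make_aoh_chrom("chr1", 4e4, spacing = 2000,
                      hom_runs = data.frame(start = 1, end = 4e4))
  flags <- scan_homozygosity(s)
  expect_equal(nrow(flags), 1L)
  expect_true(flags$homozygous)

  # a window holding 5 hets is not homozygous
  gt <- rep("hom_alt", 20)
  gt[c(3, 7, 11, 15, 19)] <- "het"
  s5 <- snp_table(rep("chr1", 20), 1:20 * 1000, rep("A", 20), rep("G", 20),
                  ref_depth = ifelse(gt == "het", 20, 0),
                  alt_depth = ifelse(gt == "het", 20, 40), genotype = gt)
  expect_false(scan_homozygosity(s5)$homozygous)

  # fewer SNPs than one window is an empty flag list, not an error
  expect_equal(nrow(scan_homozygosity(s5[1:10, ])), 0L)
})

test_that("window flags equal a brute-force recount on a mixed fixture", {
  withr::with_seed(8, {
    gt <- sample(c("het", "hom_ref", "hom_alt"), 200, replace = TRUE)
  })
  gt[70:129] <- "hom_alt"   # planted 60-SNP homozygous run
  s <- snp_table(rep("chr1", 200), 1:200 * 2000, rep("A", 200),
                 rep("G", 200),
                 ref_depth = ifelse(gt == "hom_alt", 0, 20),
                 alt_depth = ifelse(gt == "hom_ref", 0, 20), genotype = gt)
  flags <- scan_homozygosity(s)
  oracle <- vapply(seq_len(181), function(i)
    sum(gt[i:(i + 19)] == "het") <= 1L, logical(1))
  expect_equal(flags$homozygous, oracle)
})

test_that("region assembly unions overlapping windows and merges across small gaps", {
  # two hom runs separated by ~2 Mb of hets stay separate
  far <- make_aoh_chrom("chr1", 3e7, hom_runs = data.frame(
    start = c(2e6, 10e6), end = c(4e6, 12e6)))
  rf <- assemble_regions(far, scan_homozygosity(far))
  expect_equal(nrow(rf), 2L)

  # separated by 100 kb (< max_join_gap) they merge into one region
  near <- make_aoh_chrom("chr1", 1e7, hom_runs = data.frame(
    start = c(2e6, 4.1e6), end = c(4e6, 6e6)))
  rn <- assemble_regions(near, scan_homozygosity(near))
  expect_equal(nrow(rn), 1L)
  expect_lte(rn$start, 2e6 + 2000)
  expect_gte(rn$end, 6e6 - 2000)

  # no homozygous windows -> empty list
  none <- make_aoh_chrom("chr1", 1e6)
  expect_equal(nrow(assemble_regions(none, scan_homozygosity(none))), 0L)
})

test_that("only terminal runs of at least 5 Mb are reported", {
  lens <- c(chrA = 3e7, chrB = 3e7, chrC = 3e7)
  snps <- rbind(
    make_aoh_chrom("chrA", 3e7,
                   hom_runs = data.frame(start = 1, end = 3e6)),
    make_aoh_chrom("chrB", 3e7,
                   hom_runs = data.frame(start = 1, end = 5e6)),
    make_aoh_chrom("chrC", 3e7,
                   hom_runs = data.frame(start = 2.4e7, end = 3e7)))
  res <- detect_aoh(snps, lens)
  rep_r <- res$regions[res$regions$reported, ]
  expect_equal(sort(rep_r$chrom), c("chrB", "chrC"))
  expect_true(all(rep_r$classification == "terminal"))
  expect_true(all(rep_r$length >= 5e6))
  # the 3 Mb terminal run is detected but not reported
  cand_a <- res$regions[res$regions$chrom == "chrA", ]
  expect_equal(nrow(cand_a), 1L)
  expect_false(cand_a$reported)
})

test_that("interstitial reporting is off by default and obeys its own floor when enabled", {
  snps <- make_aoh_chrom("chr1", 6e7, hom_runs = data.frame(
    start = 20e6, end = 32e6))   # 12 Mb mid-chromosome run
  off <- detect_aoh(snps, c(chr1 = 6e7))
  expect_false(any(off$regions$reported))
  on <- detect_aoh(snps, c(chr1 = 6e7),
                   aoh_config(interstitial_min_length = 1e7))
  rep_r <- on$regions[on$regions$reported, ]
  expect_equal(rep_r$classification, "interstitial")
  expect_gte(rep_r$length, 1e7)
})

test_that("an all-het genome has no regions and near-zero homozygous proportion", {
  snps <- make_aoh_chrom("chr1", 2e7)
  res <- detect_aoh(snps, c(chr1 = 2e7))
  expect_equal(nrow(res$regions), 0L)
  expect_equal(res$proportion_homozygous, 0)
})

test_that("a planted 6 Mb terminal run is found across window sizes", {
  sim <- simulate_snp_table(
    seed = 17L, chrom_lengths = c(chr1 = 3e7), snp_spacing = 2000,
    aoh_regions = data.frame(chrom = "chr1", start = 1, end = 6e6))
  for (w in c(10, 20, 50)) {
    res <- detect_aoh(sim$snps, c(chr1 = 3e7), aoh_config(window_snps = w))
    rep_r <- res$regions[res$regions$reported, ]
    expect_gte(nrow(rep_r), 1L)
    expect_lte(min(rep_r$start), 1e6)
  }
})

test_that("het interruptions split a long run into subregions covering most of it", {
  # 12 Mb run broken by a 700 kb het stretch (wider than the join gap)
  runs <- data.frame(start = c(1, 6.7e6), end = c(6e6, 12e6))
  snps <- make_aoh_chrom("chr1", 3e7, hom_runs = runs)
  res <- detect_aoh(snps, c(chr1 = 3e7))
  regs <- res$regions
  expect_gte(nrow(regs), 2L)
  covered <- sum(pmin(regs$end, 12e6) - pmax(regs$start, 1) + 1)
  expect_gte(covered / 12e6, 0.9)
})

test_that("reported terminal regions are >= 5 Mb and non-overlapping on randomized genomes", {
  for (s in 1:10) {
    withr::with_seed(100 + s, {
      run_len <- runif(1, 2e6, 9e6)
      term <- sample(c(TRUE, FALSE), 1)
    })
    region <- if (term) data.frame(chrom = "chr2", start = 1, end = run_len)
    else data.frame(chrom = "chr2", start = 2e7, end = 2e7 + run_len)
    sim <- simulate_snp_table(seed = 200 + s, aoh_regions = region)
    res <- detect_aoh(sim$snps, model_genome())
    rep_r <- res$regions[res$regions$reported, ]
    expect_true(all(rep_r$length >= 5e6))
    expect_true(all(rep_r$classification == "terminal"))
    for (ch in unique(res$regions$chrom)) {
      r <- res$regions[res$regions$chrom == ch, ]
      r <- r[order(r$start), ]
      expect_true(all(diff(r$start) > 0))
      if (nrow(r) > 1) expect_true(all(r$start[-1] > r$end[-nrow(r)]))
    }
  }
})
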