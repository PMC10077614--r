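test_that("windows tile unique regions with the half-window remainder rule", {
  region <- data.frame(chrom = "chr16", start = 1, end = 10000)
  dt <- data.frame(chrom = "chr16", start = 1, end = 10000, count = 100,
                   gc_fraction = 0.4)
  w <- bin_and_count(dt, region, window_size = 1000)
  expect_equal(nrow(w), 10L)
  # 10.4 kb region: the 400 bp remainder (< half window) is dropped
  region2 <- data.frame(chrom = "chr16", start = 1, end = 10400)
  w2 <- bin_and_count(dt, region2, window_size = 1000)
  expect_equal(nrow(w2), 10L)
  # a 600 bp remainder (>= half window) is kept
  region3 <- data.frame(chrom = "chr16", start = 1, end = 10600)
  w3 <- bin_and_count(dt, region3, window_size = 1000)
  expect_equal(nrow(w3), 11L)
})

test_that("window counts equal a brute-force overlap-weighted sum", {
  withr::with_seed(12, {
    starts <- seq(1, 4801, by = 300)
    dt <- data.frame(chrom = "chr16", start = starts,
                     end = starts + 299,
                     count = sample(50:150, length(starts), replace = TRUE),
                     gc_fraction = runif(length(starts), 0.3, 0.6))
  })
  region <- data.frame(chrom = "chr16", start = 1, end = 5000)
  w <- bin_and_count(dt, region, window_size = 500)
  oracle <- vapply(seq_len(nrow(w)), function(i) {
    ov <- pmax(0, pmin(w$end[i], dt$end) - pmax(w$start[i], dt$start) + 1)
    sum(dt$count * ov / (dt$end - dt$start + 1))
  }, numeric(1))
  expect_equal(w$raw_count, oracle, tolerance = 1e-12)
})

test_that("GC correction flattens an injected linear bias and preserves planted ratios", {
  withr::with_seed(13, {
    n <- 600
    gc <- runif(n, 0.3, 0.6)
  })
  # deterministic linear bias: count proportional to 1 + 0.5 * gc
  counts <- 100 * (1 + 0.5 * gc)
  w <- data.frame(chrom = "chr16", start = seq(1, by = 500, length.out = n),
                  end = seq(500, by = 500, length.out = n),
                  raw_count = counts, gc_fraction = gc)
  corr <- gc_batch_correct(w)
  expect_lt(sqrt(mean((corr$corrected_ratio - 1)^2)), 0.05)

  # CN1 stretch at half counts survives correction at ratio ~0.5
  prof <- simulate_depth_profile(
    data.frame(chrom = "chr16", start = 1, end = 3e5),
    cnv_events = data.frame(chrom = "chr16", start = 100001,
                            end = 150000, copy_number = 1),
    gc_bias_slope = 0.4, seed = 14L)
  wins <- bin_and_count(prof$depth_table,
                        data.frame(chrom = "chr16", start = 1, end = 3e5))
  wins <- gc_batch_correct(wins)
  inside <- wins$start >= 100001 & wins$end <= 150000
  expect_lt(abs(mean(wins$corrected_ratio[inside]) - 0.5), 0.05)
  expect_lt(abs(mean(wins$corrected_ratio[!inside]) - 1), 0.05)

  # flat input: correcting the corrected ratios changes nothing (1e-9)
  w2 <- w
  w2$raw_count <- corr$corrected_ratio
  twice <- gc_batch_correct(w2)
  expect_lt(max(abs(twice$corrected_ratio - corr$corrected_ratio)), 1e-9)

  all_zero <- w
  all_zero$raw_count <- 0
  expect_error(gc_batch_correct(all_zero), "zero")
})

test_that("Viterbi decoding equals exhaustive path enumeration on small instances", {
  params <- hmm_params()
  for (s in 1:20) {
    withr::with_seed(900 + s, {
      truth <- sample(0:4, 1)
      obs <- c(rnorm(3, 1, 0.12), rnorm(2, truth / 2, 0.12),
               rnorm(2, 1, 0.12))
    })
    w <- data.frame(chrom = "c", start = 1:7 * 500 - 499, end = 1:7 * 500,
                    corrected_ratio = obs)
    segs <- hmm_segment(w, params)
    path <- rep(segs$copy_number, segs$n_windows)
    expect_identical(path, viterbi_oracle(obs, params))
  }
})

test_that("segmentation recovers planted events with exact boundaries on clean input", {
  ratios <- rep(1, 50)
  ratios[20:29] <- 0.5
  w <- data.frame(chrom = "c", start = (1:50) * 500 - 499,
                  end = (1:50) * 500, corrected_ratio = ratios)
  segs <- hmm_segment(w)
  expect_equal(segs$copy_number, c(2L, 1L, 2L))
  expect_equal(segs$start[2], w$start[20])
  expect_equal(segs$end[2], w$end[29])

  ratios0 <- rep(1, 50)
  ratios0[20:29] <- 0.01
  w$corrected_ratio <- ratios0
  expect_equal(hmm_segment(w)$copy_number, c(2L, 0L, 2L))

  # all-normal profile is one CN2 segment; single window works
  w$corrected_ratio <- rep(1, 50)
  expect_equal(nrow(hmm_segment(w)), 1L)
  expect_equal(nrow(hmm_segment(w[1, ])), 1L)
})

test_that("genotypes are assigned by breakpoint matching against the registry", {
  locus <- thal_synthetic_locus()
  run_case <- function(events, seed) {
    prof <- simulate_depth_profile(locus$region, cnv_events = events,
                                   gc_bias_slope = 0.3, seed = seed)
    wins <- gc_batch_correct(bin_and_count(prof$depth_table, locus$region))
    call_thal_genotype(hmm_segment(wins), locus$alleles)
  }
  expect_equal(run_case(NULL, 21L)$genotype, "aa/aa")
  sea <- data.frame(chrom = "chr16", start = 200001, end = 219300,
                    copy_number = 1)
  expect_equal(run_case(sea, 22L)$genotype, "--SEA/aa")
  sea0 <- sea; sea0$copy_number <- 0
  expect_equal(run_case(sea0, 23L)$genotype, "--SEA/--SEA")
  a37 <- data.frame(chrom = "chr16", start = 150001, end = 153800,
                    copy_number = 1)
  expect_equal(run_case(a37, 24L)$genotype, "-a3.7/aa")
  # a deletion far from every registry breakpoint is reported as novel
  novel <- data.frame(chrom = "chr16", start = 320001, end = 340000,
                      copy_number = 1)
  res <- run_case(novel, 25L)
  expect_match(res$genotype, "novel_del")
  expect_equal(nrow(res$matches), 0L)
})

test_that("breakpoints are recovered within one window in almost all replicates", {
  locus <- thal_synthetic_locus()
  sea <- data.frame(chrom = "chr16", start = 200001, end = 219300,
                    copy_number = 1)
  hit <- vapply(1:50, function(r) {
    prof <- simulate_depth_profile(locus$region, cnv_events = sea,
                                   seed = 3000L + r)
    wins <- gc_batch_correct(bin_and_count(prof$depth_table, locus$region))
    segs <- hmm_segment(wins)
    dels <- segs[segs$copy_number == 1, , drop = FALSE]
    nrow(dels) == 1 && abs(dels$start - 200001) <= 500 &&
      abs(dels$end - 219300) <= 500
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("genotype calls are invariant to library size", {
  locus <- thal_synthetic_locus()
  sea <- data.frame(chrom = "chr16", start = 200001, end = 219300,
                    copy_number = 1)
  prof <- simulate_depth_profile(locus$region, cnv_events = sea, seed = 31L)
  gt_of <- function(scale) {
    dt <- prof$depth_table
    dt$count <- dt$count * scale
    wins <- gc_batch_correct(bin_and_count(dt, locus$region))
    call_thal_genotype(hmm_segment(wins), locus$alleles)$genotype
  }
  expect_equal(gt_of(1), "--SEA/aa")
  expect_equal(gt_of(4), "--SEA/aa")
  expect_equal(gt_of(0.5), "--SEA/aa")
})
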