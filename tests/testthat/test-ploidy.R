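test_that("het-site extraction partitions by genotype, depth and chromosome", {
  s <- snp_table(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    pos = 1:6 * 100,
    ref = rep("A", 6), alt = rep("G", 6),
    ref_depth = c(20, 18, 22, 0, 1, 15),
    alt_depth = c(20, 21, 19, 40, 38, 16),
    genotype = c("het", "het", "het", "hom_alt", "hom_alt", "het"))
  groups <- extract_het_counts(s, min_depth = 10)
  expect_equal(names(groups), c("chr1", "chr2"))
  expect_length(groups$chr1$alt, 3L)
  expect_length(groups$chr2$alt, 1L)
  # depth gate: a het site at depth 5 is excluded
  s2 <- snp_table("chr1", 700, "A", "G", 2, 3, "het")
  expect_length(extract_het_counts(rbind(s, s2), min_depth = 10)$chr1$alt,
                3L)

  # fixture re-filter oracle on simulated data
  sim <- simulate_snp_table(seed = 3L, chrom_lengths = c(chr1 = 2e6),
                            snp_spacing = 2e4)
  got <- extract_het_counts(sim$snps, min_depth = 10)
  manual <- sim$snps[sim$snps$genotype == "het" &
                       sim$snps$ref_depth + sim$snps$alt_depth >= 10, ]
  expect_equal(got$chr1$alt, manual$alt_depth)
})

test_that("binomial log-likelihoods match a brute-force oracle to 1e-6", {
  withr::with_seed(7, {
    n <- rpois(50, 40) + 1L
    alt <- rbinom(50, n, 0.45)
  })
  fit <- fit_ploidy_models(alt, n, min_sites = 10)
  # independent oracle: explicit binomial mass from log-gamma terms
  lbin <- function(k, n, p) {
    lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1) +
      k * log(p) + (n - k) * log(1 - p)
  }
  ll_dip <- sum(lbin(alt, n, 0.5))
  ll_tri <- sum(log(0.5 * exp(lbin(alt, n, 1 / 3)) +
                      0.5 * exp(lbin(alt, n, 2 / 3))))
  p_hat <- sum(alt) / sum(n)
  ll_free <- sum(lbin(alt, n, p_hat))
  expect_lt(abs(fit$loglik_diploid - ll_dip), 1e-6)
  expect_lt(abs(fit$loglik_triploid - ll_tri), 1e-6)
  expect_lt(abs(fit$loglik_free - ll_free), 1e-6)
  expect_equal(fit$fitted_p_free, p_hat)
})

test_that("allele relabelling leaves the symmetric models unchanged and free-p nests diploid", {
  withr::with_seed(11, {
    n <- rpois(300, 40) + 1L
    alt <- rbinom(300, n, 0.55)
  })
  a <- fit_ploidy_models(alt, n, min_sites = 10)
  b <- fit_ploidy_models(n - alt, n, min_sites = 10)
  expect_identical(a$loglik_diploid, b$loglik_diploid)
  expect_equal(a$loglik_triploid, b$loglik_triploid, tolerance = 1e-12)
  expect_gte(a$loglik_free, a$loglik_diploid)
  # boundary: single site with alt == n is clipped, all finite
  one <- fit_ploidy_models(30L, 30L, min_sites = 1)
  expect_true(is.finite(one$loglik_free))
  expect_lt(one$fitted_p_free, 1)
})

test_that("the generating model wins the likelihood comparison in almost all seeded replicates", {
  dip_wins <- tri_wins <- logical(50)
  for (s in 1:50) {
    withr::with_seed(1000 + s, {
      n <- rpois(1000, 40) + 1L
      alt_d <- rbinom(1000, n, 0.5)
      comp <- rbinom(1000, 1, 0.5)
      alt_t <- rbinom(1000, n, ifelse(comp == 1, 2 / 3, 1 / 3))
    })
    fd <- fit_ploidy_models(alt_d, n)
    ft <- fit_ploidy_models(alt_t, n)
    dip_wins[s] <- fd$loglik_diploid > fd$loglik_triploid
    tri_wins[s] <- ft$loglik_triploid > ft$loglik_diploid
  }
  expect_gte(mean(dip_wins), 0.98)
  expect_gte(mean(tri_wins), 0.98)
})

test_that("the mixture-model advantage grows with the simulated trisomy cell fraction", {
  adv <- sapply(c(0, 0.5, 1), function(f) {
    mean(sapply(1:20, function(r) {
      withr::with_seed(5000 + 100 * f + r, {
        n <- rpois(500, 40) + 1L
        p <- (1 - f) * 0.5 + f * ifelse(rbinom(500, 1, 0.5) == 1, 2 / 3, 1 / 3)
        alt <- rbinom(500, n, p)
      })
      fit <- fit_ploidy_models(alt, n)
      fit$loglik_triploid - fit$loglik_diploid
    }))
  })
  expect_true(all(diff(adv) > 0))
})

test_that("chromosome status calls integrate depth ratios and allele evidence", {
  # simulated trisomy of one chromosome: gain there, diploid genome call
  sim <- simulate_snp_table(seed = 21L, ploidy = c(chr4 = "trisomy"))
  depths <- simulate_chrom_depth(seed = 22L, ploidy = c(chr4 = "trisomy"))
  res <- call_ploidy(sim$snps, depths)
  expect_equal(res$genome_call, "diploid")
  expect_equal(res$calls$status[res$calls$chrom == "chr4"],
               "aneuploid_gain")
  expect_true(all(res$calls$status[res$calls$chrom != "chr4"] == "diploid"))

  # monosomy is called from depth alone (almost no het sites)
  sim_m <- simulate_snp_table(seed = 23L, ploidy = c(chr2 = "monosomy"))
  d_m <- simulate_chrom_depth(seed = 24L, ploidy = c(chr2 = "monosomy"))
  res_m <- call_ploidy(sim_m$snps, d_m)
  expect_equal(res_m$calls$status[res_m$calls$chrom == "chr2"],
               "aneuploid_loss")

  # all-diploid null
  sim0 <- simulate_snp_table(seed = 25L)
  d0 <- simulate_chrom_depth(seed = 26L)
  res0 <- call_ploidy(sim0$snps, d0)
  expect_equal(res0$genome_call, "diploid")
  expect_true(all(res0$calls$status == "diploid"))

  # genome-wide 1/3-2/3 mixture at flat depth -> triploid genome call
  sim3 <- simulate_snp_table(seed = 27L, ploidy = "triploid")
  d3 <- simulate_chrom_depth(seed = 28L, ploidy = "triploid")
  res3 <- call_ploidy(sim3$snps, d3)
  expect_equal(res3$genome_call, "triploid")

  # insufficient data is reported, not guessed
  few <- simulate_snp_table(seed = 29L, chrom_lengths = c(chr1 = 6e7,
                                                          chr9 = 2e5))
  resf <- call_ploidy(few$snps, c(chr1 = 40, chr9 = 40),
                      ploidy_config(min_sites = 200))
  expect_equal(resf$calls$status[resf$calls$chrom == "chr9"],
               "insufficient_data")
})

test_that("the EM mixture fit recovers planted component fractions", {
  withr::with_seed(31, {
    n <- rpois(4000, 40) + 1L
    comp <- rbinom(4000, 1, 0.5)
    alt <- rbinom(4000, n, ifelse(comp == 1, 2 / 3, 1 / 3))
  })
  fit <- fit_vaf_mixture(alt, n)
  expect_lt(abs(fit$p[1] - 1 / 3), 0.01)
  expect_lt(abs(fit$p[2] - 2 / 3), 0.01)
})
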