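test_that("Mendelian consistency matches allele-transmission enumeration on all 27 combinations", {
  gts <- c("hom_ref", "het", "hom_alt")
  combos <- expand.grid(child = gts, mother = gts, father = gts,
                        stringsAsFactors = FALSE)
  got <- mendelian_consistent(combos$child, combos$mother, combos$father)
  oracle <- vapply(seq_len(nrow(combos)), function(i)
    mendel_oracle(combos$child[i], combos$mother[i], combos$father[i]),
    logical(1))
  expect_identical(got, oracle)
  # spot checks: impossible transmission and forced het
  expect_false(mendelian_consistent("het", "hom_ref", "hom_ref"))
  expect_true(mendelian_consistent("het", "hom_ref", "hom_alt"))
  # a missing parent is compatible with any transmission
  expect_true(all(mendelian_consistent(gts, "missing", "missing")))
  # a missing child is unevaluable
  expect_true(is.na(mendelian_consistent("missing", "het", "het")))
})

test_that("segregation filtering drops or flags inconsistent sites with exact counts", {
  sites <- data.frame(
    chrom = "chr1", pos = 1:10 * 100,
    child_gt = c("het", "hom_alt", "het", "hom_ref", "het",
                 "hom_alt", "het", "hom_ref", "hom_alt", "het"),
    mother_gt = c("het", "het", "hom_ref", "hom_ref", "hom_ref",
                  "hom_ref", "het", "het", "het", "hom_alt"),
    father_gt = c("het", "het", "hom_ref", "het", "hom_alt",
                  "hom_ref", "hom_ref", "het", "het", "hom_ref"),
    stringsAsFactors = FALSE)
  # rows 3 and 6 are impossible (de novo-like); row 6 hom_alt from two
  # hom_ref parents; row 9 hom_alt needs an alt from each parent (possible)
  removed <- segregation_filter(sites, mode = "remove_inconsistent")
  expect_equal(unname(removed$counts),
               c(consistent = 8L, inconsistent = 2L, unevaluable = 0L),
               ignore_attr = TRUE)
  expect_equal(nrow(removed$sites), 8L)
  flagged <- segregation_filter(sites, mode = "flag_only")
  expect_equal(nrow(flagged$sites), nrow(sites))
  expect_equal(sum(!flagged$sites$consistent), 2L)

  # all-missing parents: everything retained, nothing unevaluable
  all_missing <- data.frame(child_gt = c("het", "hom_alt"),
                            mother_gt = "missing", father_gt = "missing")
  res <- segregation_filter(all_missing, mode = "remove_inconsistent")
  expect_equal(nrow(res$sites), 2L)
  expect_equal(res$counts[["unevaluable"]], 0L)

  empty <- segregation_filter(sites[0, ], mode = "remove_inconsistent")
  expect_equal(nrow(empty$sites), 0L)
})

test_that("trio VCFs parse into per-site genotype triples", {
  vcf <- tempfile(fileext = ".vcf")
  write_fixture_vcf(vcf, c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:20,20\t0/0:30,0\t1/1:0,28",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT:AD\t1/1:0,40\t0/1:15,15\t./.:0,0"
  ), sample_names = c("CHILD", "MOTHER", "FATHER"))
  trio <- read_vcf_trio(vcf, "CHILD", "MOTHER", "FATHER")
  expect_equal(trio$child_gt, c("het", "hom_alt"))
  expect_equal(trio$mother_gt, c("hom_ref", "het"))
  expect_equal(trio$father_gt, c("hom_alt", "missing"))
  expect_error(read_vcf_trio(vcf, "CHILD", "MOTHER", "NOBODY"), "NOBODY")
})

test_that("the validation formulas reproduce the all-detected benchmark", {
  # 6 SNV-positive samples all detected; 39 other-class samples, each with
  # its own variant detected -> sensitivity and specificity both 100%
  samples <- sprintf("S%02d", 1:45)
  own_class <- c(rep("snv_indel", 6), rep("cnv", 23), rep("aneuploidy", 5),
                 rep("mt", 3), rep("balanced", 5), "triploidy", "aoh",
                 "sma")
  rows <- do.call(rbind, lapply(unique(own_class), function(cl)
    data.frame(sample = samples, class = cl,
               expected = own_class == cl, detected = own_class == cl)))
  tab <- detection_table(rows$sample, rows$class, rows$expected,
                         rows$detected)
  m <- sensitivity_specificity(tab, "snv_indel")
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$n_positive, 6L)
  expect_equal(m$n_negative, 39L)

  # nothing detected: sensitivity 0
  none <- tab
  none$detected <- FALSE
  expect_equal(sensitivity_specificity(none, "snv_indel")$sensitivity, 0)
})

test_that("metrics equal a direct counting oracle on random tables", {
  for (s in 1:10) {
    withr::with_seed(700 + s, {
      own <- sample(c("a", "b", "c"), 45, replace = TRUE)
      det_own <- runif(45) < 0.8
      det_cross <- matrix(runif(45 * 3) < 0.1, 45, 3,
                          dimnames = list(NULL, c("a", "b", "c")))
    })
    rows <- do.call(rbind, lapply(c("a", "b", "c"), function(cl)
      data.frame(sample = sprintf("S%02d", 1:45), class = cl,
                 expected = own == cl,
                 detected = ifelse(own == cl, det_own, det_cross[, cl]))))
    tab <- detection_table(rows$sample, rows$class, rows$expected,
                           rows$detected)
    for (cl in c("a", "b", "c")) {
      m <- sensitivity_specificity(tab, cl)
      sens_oracle <- sum(own == cl & det_own) / sum(own == cl)
      spec_oracle <- sum(own != cl & det_own) / sum(own != cl)
      expect_equal(m$sensitivity, sens_oracle)
      expect_equal(m$specificity, spec_oracle)
      # conventional convention: rate of non-false-flagging for class cl
      mc <- sensitivity_specificity(tab, cl, convention = "conventional")
      conv_oracle <- mean(!det_cross[own != cl, cl])
      expect_equal(mc$specificity, conv_oracle)
      expect_true(all(c(m$sensitivity, m$specificity) >= 0 &
                        c(m$sensitivity, m$specificity) <= 1))
    }
  }
})

test_that("zero denominators are signalled as undefined, never 0/0", {
  tab <- detection_table("S1", "a", TRUE, TRUE)
  m <- sensitivity_specificity(tab, "a")
  expect_true(m$specificity_undefined)
  expect_true(is.na(m$specificity))
  expect_false(m$sensitivity_undefined)
})
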