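#' Synthetic thalassemia locus and known-allele registry
#'
#' A 300 kb synthetic alpha-globin-like unique region on chr16 carrying
#' registry entries shaped like the recurrent deletion alleles (`--SEA`
#' ~19.3 kb, `-a3.7` ~3.8 kb, `-a4.2` ~4.2 kb). Coordinates are synthetic:
#' real breakpoints are user-supplied data.
#'
#' @return list with `region` (data.frame `chrom, start, end`) and
#'   `alleles` (GRanges registry with `label`, `dosage_type`).
#' @export
thal_synthetic_locus <- function() {
  list(
    region = data.frame(chrom = "chr16", start = 100001L, end = 400000L),
    alleles = GenomicRanges::GRanges(
      "chr16",
      IRanges::IRanges(start = c(200001L, 150001L, 260001L),
                       end = c(219300L, 153800L, 264200L)),
      label = c("--SEA", "-a3.7", "-a4.2"),
      dosage_type = "deletion")
  )
}

#' Class composition of the synthetic validation panel
#'
#' Mirrors the in-scope class counts of a 45-sample known-variant panel:
#' 5 aneuploidies (trisomies of five model chromosomes), 1 triploidy,
#' 1 sample with multiple AOH regions, 1 SMN1 exon 7-8 deletion, and 4
#' thalassemia deletion genotypes; the remaining samples are negative for
#' every in-scope class (standing in for carriers of out-of-scope variant
#' types).
#'
#' @param n_samples panel size (default 45).
#' @return data.frame with `sample`, `class` and a `detail` string.
#' @export
validation_panel_classes <- function(n_samples = 45L) {
  stopifnot(n_samples >= 12)
  cls <- c(rep("aneuploidy", 5), "triploidy", "aoh", "sma",
           rep("cnv", 4), rep("negative", n_samples - 12))
  detail <- c(paste0("trisomy_chr", 2:6), "triploid", "multi_aoh",
              "smn1_del_exon78",
              "SEA_het", "SEA_hom", "a3.7_het", "a4.2_het",
              rep("none", n_samples - 12))
  data.frame(sample = sprintf("S%02d", seq_len(n_samples)), class = cls,
             detail = detail, stringsAsFactors = FALSE)
}

panel_thal_events <- function(detail, locus) {
  a <- locus$alleles
  pick <- function(label, cn) {
    i <- which(S4Vectors::mcols(a)$label == label)
    data.frame(chrom = as.character(GenomicRanges::seqnames(a))[i],
               start = GenomicRanges::start(a)[i],
               end = GenomicRanges::end(a)[i], copy_number = cn)
  }
  switch(detail,
         SEA_het = pick("--SEA", 1L),
         SEA_hom = pick("--SEA", 0L),
         a3.7_het = pick("-a3.7", 1L),
         a4.2_het = pick("-a4.2", 1L),
         NULL)
}

#' Run the synthetic validation panel through the in-scope detectors
#'
#' Generates every sample of [validation_panel_classes()] with the synthetic
#' module, runs the ploidy, AOH, SMA and thalassemia detectors on each, and
#' assembles the per-sample, per-class detection table. Detection rules:
#' aneuploidy — any chromosome called gain/loss with a diploid genome call;
#' triploidy — genome-level triploid call; aoh — at least one reported AOH
#' region; sma — SMN1 exon 7-8 copy number below 2; cnv — thalassemia
#' genotype other than `aa/aa`.
#'
#' @param seed integer seed; per-sample seeds are derived from it.
#' @param n_samples panel size (default 45).
#' @param mean_depth baseline depth (default 40).
#' @param snp_spacing SNP spacing for the ploidy/AOH input (default 5000).
#' @return object of class `validation_panel`: `detections` (a
#'   [detection_table()]), `classes` (the composition), `details` (named
#'   list of per-sample detector outputs).
#' @export
run_validation_panel <- function(seed = 1L, n_samples = 45L,
                                 mean_depth = 40, snp_spacing = 5000) {
  comp <- validation_panel_classes(n_samples)
  locus <- thal_synthetic_locus()
  classes <- c("aneuploidy", "triploidy", "aoh", "sma", "cnv")
  rows <- list()
  details <- list()
  for (i in seq_len(nrow(comp))) {
    cls <- comp$class[i]
    det <- comp$detail[i]
    s <- derive_seed(seed, i)

    ploidy <- character()
    if (cls == "aneuploidy") {
      chrom <- sub("^trisomy_", "", det)
      ploidy <- setNames("trisomy", chrom)
    } else if (cls == "triploidy") ploidy <- "triploid"
    aoh_regions <- if (cls == "aoh")
      data.frame(chrom = c("chr1", "chr2", "chr3"),
                 start = c(1, 52e6 + 1, 20e6 + 1),
                 end = c(8e6, 6e7, 27e6)) else NULL

    sim <- simulate_snp_table(seed = s, snp_spacing = snp_spacing,
                              mean_depth = mean_depth, ploidy = ploidy,
                              aoh_regions = aoh_regions)
    depths <- simulate_chrom_depth(seed = derive_seed(s, 1L),
                                   mean_depth = mean_depth,
                                   ploidy = ploidy)
    pl <- call_ploidy(sim$snps, depths)
    ao <- detect_aoh(sim$snps, model_genome())

    smn_state <- if (cls == "sma") c(0L, 2L) else c(2L, 2L)
    psv <- simulate_psv_table(smn_state[1], smn_state[2],
                              mean_depth = mean_depth,
                              seed = derive_seed(s, 2L))
    smn <- estimate_smn_copy_numbers(psv, mean_depth)

    events <- panel_thal_events(det, locus)
    prof <- simulate_depth_profile(locus$region, cnv_events = events,
                                   gc_bias_slope = 0.3,
                                   seed = derive_seed(s, 3L))
    wins <- bin_and_count(prof$depth_table, locus$region)
    wins <- gc_batch_correct(wins)
    segs <- hmm_segment(wins)
    thal <- call_thal_genotype(segs, locus$alleles)

    detected <- c(
      aneuploidy = pl$genome_call == "diploid" &&
        any(pl$calls$status %in% c("aneuploid_gain", "aneuploid_loss")),
      triploidy = pl$genome_call == "triploid",
      aoh = any(ao$regions$reported),
      sma = smn$smn1_cn_exon78 < 2L,
      cnv = thal$genotype != "aa/aa")
    rows[[i]] <- data.frame(sample = comp$sample[i], class = classes,
                            expected = classes == cls,
                            detected = unname(detected),
                            stringsAsFactors = FALSE)
    details[[comp$sample[i]]] <- list(ploidy = pl, aoh = ao, smn = smn,
                                      thal = thal)
  }
  all_rows <- do.call(rbind, rows)
  structure(list(
    detections = detection_table(all_rows$sample, all_rows$class,
                                 all_rows$expected, all_rows$detected),
    classes = comp, details = details),
    class = "validation_panel")
}

#' Per-class sensitivity and specificity of a panel run
#'
#' @param panel a `validation_panel` (or a bare [detection_table()]).
#' @param convention passed to [sensitivity_specificity()].
#' @return data.frame with one row per class: `class, sensitivity,
#'   specificity, n_positive, n_negative`.
#' @export
panel_metrics <- function(panel, convention = "paper") {
  tab <- if (inherits(panel, "validation_panel")) panel$detections
  else panel
  classes <- unique(tab$class[tab$expected])
  out <- lapply(classes, function(cl) {
    m <- sensitivity_specificity(tab, cl, convention)
    data.frame(class = cl, sensitivity = m$sensitivity,
               specificity = m$specificity, n_positive = m$n_positive,
               n_negative = m$n_negative, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.validation_panel <- function(x, ...) {
  m <- panel_metrics(x)
  cat(sprintf("validation_panel: %d samples, %d in-scope classes\n",
              length(unique(x$detections$sample)), nrow(m)))
  print(m, row.names = FALSE)
  invisible(x)
}
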