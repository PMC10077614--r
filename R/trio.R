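#' Mendelian consistency of a child genotype given parental genotypes
#'
#' A site is consistent when the child genotype can be formed by taking one
#' allele from each parent; a missing parent is compatible with any
#' transmission. Vectorized over sites.
#'
#' @param child_gt,mother_gt,father_gt genotype labels
#'   (`hom_ref`/`het`/`hom_alt`/`missing`).
#' @return logical vector (`NA` where the child genotype is missing).
#' @export
mendelian_consistent <- function(child_gt, mother_gt, father_gt) {
  ## transmittable alt-dosage sets per genotype
  alleles <- list(hom_ref = 0L, het = c(0L, 1L), hom_alt = 1L,
                  missing = c(0L, 1L))
  child_pair <- list(hom_ref = c(0L, 0L), het = c(0L, 1L),
                     hom_alt = c(1L, 1L))
  n <- max(length(child_gt), length(mother_gt), length(father_gt))
  child_gt <- rep_len(child_gt, n)
  mother_gt <- rep_len(mother_gt, n)
  father_gt <- rep_len(father_gt, n)
  vapply(seq_len(n), function(i) {
    if (child_gt[i] == "missing") return(NA)
    cp <- child_pair[[child_gt[i]]]
    m <- alleles[[mother_gt[i]]]
    f <- alleles[[father_gt[i]]]
    any((cp[1] %in% m & cp[2] %in% f) | (cp[2] %in% m & cp[1] %in% f))
  }, logical(1))
}

#' Filter or annotate trio sites by segregation pattern
#'
#' @param sites data.frame with `child_gt, mother_gt, father_gt` (plus any
#'   site columns, e.g. from [read_vcf_trio()]).
#' @param mode `"flag_only"` annotates every site with a `consistent`
#'   column; `"remove_inconsistent"` drops inconsistent sites.
#' @return list with `sites` (filtered/annotated, never reordered) and
#'   `counts` (`consistent`, `inconsistent`, `unevaluable`).
#' @export
segregation_filter <- function(sites,
                               mode = c("flag_only",
                                        "remove_inconsistent")) {
  mode <- match.arg(mode)
  if (nrow(sites) == 0) {
    sites$consistent <- logical(0)
    return(list(sites = sites,
                counts = c(consistent = 0L, inconsistent = 0L,
                           unevaluable = 0L)))
  }
  ok <- mendelian_consistent(sites$child_gt, sites$mother_gt,
                             sites$father_gt)
  counts <- c(consistent = sum(ok, na.rm = TRUE),
              inconsistent = sum(!ok, na.rm = TRUE),
              unevaluable = sum(is.na(ok)))
  sites$consistent <- ok
  if (mode == "remove_inconsistent")
    sites <- sites[is.na(ok) | ok, , drop = FALSE]
  list(sites = sites, counts = counts)
}

#' Build a detection table row set
#'
#' One row per sample x variant class with expected/detected booleans — the
#' operands of the per-class sensitivity and specificity formulas.
#'
#' @param sample,class,expected,detected equal-length vectors.
#' @return data.frame of class `detection_table`.
#' @export
detection_table <- function(sample, class, expected, detected) {
  stopifnot(length(sample) == length(class),
            length(class) == length(expected),
            length(expected) == length(detected))
  if (anyDuplicated(paste(sample, class)))
    stop("detection_table: duplicate sample x class row")
  out <- data.frame(sample = as.character(sample),
                    class = as.character(class),
                    expected = as.logical(expected),
                    detected = as.logical(detected),
                    stringsAsFactors = FALSE)
  class(out) <- c("detection_table", "data.frame")
  out
}

#' Per-class sensitivity and specificity of a detection table
#'
#' In the study's convention, the positives for a class are the samples
#' carrying that class of variant; samples carrying *other* classes form the
#' negative set. Sensitivity is the fraction of class positives detected.
#' Specificity (convention `"paper"`) is the fraction of other-class
#' positive samples whose own variant was detected — the printed formula —
#' while convention `"conventional"` is the usual true-negative rate:
#' the fraction of non-class samples *not* falsely detected for this class.
#'
#' @param table a [detection_table()].
#' @param variant_class class to evaluate.
#' @param convention `"paper"` (default) or `"conventional"`.
#' @return list with `sensitivity`, `specificity` (each `NA_real_` with
#'   `undefined = TRUE` in the companion fields when a denominator is zero),
#'   `sensitivity_undefined`, `specificity_undefined`, `n_positive`,
#'   `n_negative`.
#' @export
sensitivity_specificity <- function(table, variant_class,
                                    convention = c("paper",
                                                   "conventional")) {
  convention <- match.arg(convention)
  cls <- table[table$class == variant_class, , drop = FALSE]
  if (nrow(cls) == 0)
    stop("sensitivity_specificity: no rows for class '", variant_class, "'")
  pos <- cls[cls$expected, , drop = FALSE]
  sens <- if (nrow(pos) == 0) NA_real_ else mean(pos$detected)
  ## samples whose expected class is some other class
  other <- table[table$expected & table$class != variant_class, ,
                 drop = FALSE]
  if (convention == "paper") {
    spec <- if (nrow(other) == 0) NA_real_ else mean(other$detected)
    n_neg <- nrow(other)
  } else {
    neg_samples <- unique(other$sample)
    neg_rows <- cls[cls$sample %in% neg_samples & !cls$expected, ,
                    drop = FALSE]
    spec <- if (nrow(neg_rows) == 0) NA_real_ else mean(!neg_rows$detected)
    n_neg <- nrow(neg_rows)
  }
  list(sensitivity = sens, specificity = spec,
       sensitivity_undefined = is.na(sens),
       specificity_undefined = is.na(spec),
       n_positive = nrow(pos), n_negative = n_neg)
}
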