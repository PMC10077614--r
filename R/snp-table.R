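#' Construct a table of biallelic SNP records
#'
#' The central exchange format between the I/O layer and the detectors: one
#' row per biallelic site with allelic depths, a genotype call, and the
#' variant allele fraction (VAF), defined as `alt_depth / (ref_depth +
#' alt_depth)`. When no genotype is supplied it is classified from the VAF
#' (`< 0.1` hom_ref, `[0.1, 0.9]` het, `> 0.9` hom_alt), mirroring how
#' caller-less synthetic fixtures are handled.
#'
#' @param chrom chromosome identifiers.
#' @param pos 1-based positions (`>= 1`).
#' @param ref,alt single reference / alternate bases; must differ row-wise.
#' @param ref_depth,alt_depth non-negative read counts supporting each allele.
#' @param genotype optional character vector over
#'   `c("hom_ref","het","hom_alt","missing")`; derived from VAF when `NULL`.
#' @return a `data.frame` of class `snp_table` with columns `chrom, pos, ref,
#'   alt, ref_depth, alt_depth, genotype, vaf`. `vaf` is `NA` where total
#'   depth is zero.
#' @export
snp_table <- function(chrom, pos, ref, alt, ref_depth, alt_depth,
                      genotype = NULL) {
  n <- length(pos)
  stopifnot(
    length(chrom) == n, length(ref) == n, length(alt) == n,
    length(ref_depth) == n, length(alt_depth) == n
  )
  pos <- as.integer(pos)
  ref_depth <- as.integer(ref_depth)
  alt_depth <- as.integer(alt_depth)
  if (n > 0) {
    if (any(pos < 1L)) stop("snp_table: positions must be >= 1")
    if (any(ref_depth < 0L) || any(alt_depth < 0L))
      stop("snp_table: allelic depths must be non-negative")
    if (any(ref == alt)) stop("snp_table: ref and alt alleles must differ")
  }
  total <- ref_depth + alt_depth
  vaf <- ifelse(total > 0L, alt_depth / total, NA_real_)
  if (is.null(genotype)) {
    genotype <- genotype_from_vaf(vaf)
  } else {
    genotype <- as.character(genotype)
    bad <- !genotype %in% GT_LEVELS
    if (any(bad))
      stop("snp_table: unknown genotype label(s): ",
           paste(unique(genotype[bad]), collapse = ", "))
  }
  out <- data.frame(
    chrom = as.character(chrom), pos = pos,
    ref = as.character(ref), alt = as.character(alt),
    ref_depth = ref_depth, alt_depth = alt_depth,
    genotype = genotype, vaf = vaf,
    stringsAsFactors = FALSE
  )
  class(out) <- c("snp_table", "data.frame")
  out
}

#' Classify a genotype from the variant allele fraction
#'
#' VAF bands: `< 0.1` hom_ref, `[0.1, 0.9]` het, `> 0.9` hom_alt; `NA`
#' (zero-depth) becomes missing.
#'
#' @param vaf numeric vector of allele fractions in `[0, 1]` (or `NA`).
#' @return character vector of genotype labels.
#' @export
genotype_from_vaf <- function(vaf) {
  out <- rep("missing", length(vaf))
  out[!is.na(vaf) & vaf < 0.1] <- "hom_ref"
  out[!is.na(vaf) & vaf >= 0.1 & vaf <= 0.9] <- "het"
  out[!is.na(vaf) & vaf > 0.9] <- "hom_alt"
  out
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d sites on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x) > 0) {
    tab <- table(factor(x$genotype, levels = GT_LEVELS))
    cat("  genotypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  NextMethod()
  invisible(x)
}
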