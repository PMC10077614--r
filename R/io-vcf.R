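#' Read biallelic SNPs from a single-sample VCF
#'
#' Parses a VCF (via \pkg{vcfR}) and returns only biallelic SNP rows with
#' total allelic depth at or above `min_depth`. Genotypes come from the GT
#' field when present, otherwise from VAF bands. Multi-allelic rows, indels,
#' zero-depth and sub-threshold rows are skipped and counted in the returned
#' tally.
#'
#' @param path path to a VCF (optionally gzipped) with GT and AD FORMAT
#'   fields for exactly one sample.
#' @param min_depth minimum total allelic depth to keep a row (default 0).
#' @param chrom_style passed to [normalize_chrom()].
#' @return list with elements `snps` (a [snp_table()]) and `skipped`, a named
#'   integer vector with counts of `multiallelic`, `indel`, `zero_depth` and
#'   `low_depth` rows.
#' @export
read_vcf_snps <- function(path, min_depth = 0L, chrom_style = "asis") {
  if (!file.exists(path)) stop("read_vcf_snps: cannot read '", path, "'")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (!is.null(fix) && is.null(dim(fix)))   # single record drops to vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (is.null(fix) || nrow(fix) == 0) {
    return(list(snps = snp_table(character(), integer(), character(),
                                 character(), integer(), integer()),
                skipped = c(multiallelic = 0L, indel = 0L,
                            zero_depth = 0L, low_depth = 0L)))
  }
  if (ncol(vcf@gt) != 2L)
    stop("read_vcf_snps: expected exactly one sample, found ",
         ncol(vcf@gt) - 1L)
  fmt <- vcf@gt[, "FORMAT"]
  has_ad <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) "AD" %in% f, logical(1))
  if (any(!has_ad))
    stop("read_vcf_snps: record ", which(!has_ad)[1],
         " (", fix[which(!has_ad)[1], "CHROM"], ":",
         fix[which(!has_ad)[1], "POS"], ") lacks the AD field")
  ad <- vcfR::extract.gt(vcf, element = "AD")[, 1]
  gt <- tryCatch(vcfR::extract.gt(vcf, element = "GT")[, 1],
                 error = function(e) rep(NA_character_, nrow(fix)))

  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])

  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L |
                       ref == "*" | alt == "*" | is.na(alt))
  keep0 <- !multi & !indel

  parse_ad <- function(x) {
    if (is.na(x)) return(c(NA_integer_, NA_integer_))
    parts <- suppressWarnings(as.integer(strsplit(x, ",", fixed = TRUE)[[1]]))
    c(parts[1], parts[2])
  }
  depths <- vapply(ad, parse_ad, integer(2))
  rd <- depths[1, ]
  ad2 <- depths[2, ]
  rd[is.na(rd)] <- 0L
  ad2[is.na(ad2)] <- 0L
  total <- rd + ad2

  zero <- keep0 & total == 0L
  low <- keep0 & !zero & total < min_depth
  keep <- keep0 & !zero & !low

  geno <- gt_to_label(gt)
  snps <- snp_table(
    chrom = normalize_chrom(chrom[keep], chrom_style),
    pos = pos[keep], ref = ref[keep], alt = alt[keep],
    ref_depth = rd[keep], alt_depth = ad2[keep],
    genotype = if (all(is.na(gt))) NULL else geno[keep]
  )
  list(snps = snps,
       skipped = c(multiallelic = sum(multi), indel = sum(indel),
                   zero_depth = sum(zero), low_depth = sum(low)))
}

gt_to_label <- function(gt) {
  g <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep("missing", length(g))
  out[g %in% "0/0"] <- "hom_ref"
  out[g %in% c("0/1", "1/0")] <- "het"
  out[g %in% "1/1"] <- "hom_alt"
  out
}

#' Write a snp_table as a minimal single-sample VCF
#'
#' Emits a VCF 4.2 text file carrying GT and AD so that records round-trip
#' through [read_vcf_snps()] field-by-field. Parsing always goes through
#' \pkg{vcfR}; this writer only formats the package's own records.
#'
#' @param snps a [snp_table()].
#' @param path output path (plain text).
#' @param sample sample name for the header column.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path, sample = "SAMPLE") {
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  body <- if (nrow(snps) == 0) character() else sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD\t%s:%d,%d",
    snps$chrom, snps$pos, snps$ref, snps$alt,
    gt_code[snps$genotype], snps$ref_depth, snps$alt_depth
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a trio VCF into per-site genotype triples
#'
#' @param path VCF with (at least) the three named samples.
#' @param child,mother,father sample column names.
#' @return data.frame with columns `chrom, pos, child_gt, mother_gt,
#'   father_gt` using the package's genotype labels.
#' @export
read_vcf_trio <- function(path, child, mother, father) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  missing_cols <- setdiff(c(child, mother, father), colnames(gt))
  if (length(missing_cols) > 0)
    stop("read_vcf_trio: sample(s) not in VCF: ",
         paste(missing_cols, collapse = ", "))
  fix <- vcfR::getFIX(vcf)
  data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    child_gt = gt_to_label(gt[, child]),
    mother_gt = gt_to_label(gt[, mother]),
    father_gt = gt_to_label(gt[, father]),
    stringsAsFactors = FALSE
  )
}
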