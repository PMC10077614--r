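#' Built-in SMN paralog-discriminating site registry
#'
#' SMN1 and SMN2 are near-identical paralogs distinguished only at a handful
#' of paralogous sequence variants (PSVs); reads are assigned to a paralog by
#' the base they carry at those positions. The registry ships the exon 7
#' c.840C/T splice-determining site plus synthetic placeholder PSVs (the
#' positions are in a combined SMN alignment coordinate space, not a genome
#' build) so the caller can be exercised end-to-end; a clinical-coordinate
#' registry is supplied by the user in practice. Eight sites cover the
#' exon 7-8 group: the copy-number estimate averages Poisson read depths
#' over them, and eight sites keep the integer-rounding error rate well
#' below 5% at 40X.
#'
#' @return data.frame with columns `pos, smn1_base, smn2_base, exon_group`
#'   (`exon1_6` or `exon7_8`).
#' @export
smn_psv_sites <- function() {
  data.frame(
    pos = c(1100L, 2300L, 3600L, 4800L,
            6100L, 6550L, 7200L, 7650L, 8400L, 8800L, 9100L, 9500L),
    smn1_base = c("G", "A", "T", "C",
                  "C", "G", "C", "T", "A", "C", "G", "A"),
    smn2_base = c("A", "G", "C", "T",
                  "T", "A", "T", "G", "G", "T", "A", "G"),
    exon_group = c(rep("exon1_6", 4), rep("exon7_8", 8)),
    stringsAsFactors = FALSE
  )
}

#' Read a PSV registry from TSV
#'
#' Columns: `chrom` (optional), `pos`, `smn1_base`, `smn2_base`,
#' `exon_group`.
#'
#' @param path TSV path (header required).
#' @return data.frame in the [smn_psv_sites()] layout.
#' @export
read_psv_sites <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("pos", "smn1_base", "smn2_base", "exon_group")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("read_psv_sites: missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(df$smn1_base == df$smn2_base))
    stop("read_psv_sites: PSV with identical discriminating bases")
  df
}

#' Build a PSV depth table from allelic depths at PSV positions
#'
#' Maps each site's observed ref/alt allelic depths onto paralog support:
#' reads carrying the SMN1 base count as `gene1_support`, the SMN2 base as
#' `gene2_support`, anything else as `other`.
#'
#' @param snps a [snp_table()] restricted to (or containing) the PSV
#'   positions; matching is by position.
#' @param psv PSV registry ([smn_psv_sites()] layout).
#' @return data.frame: `pos, exon_group, gene1_support, gene2_support,
#'   other`.
#' @export
psv_depth_from_alleles <- function(snps, psv = smn_psv_sites()) {
  idx <- match(psv$pos, snps$pos)
  g1 <- g2 <- oth <- integer(nrow(psv))
  for (i in seq_len(nrow(psv))) {
    j <- idx[i]
    if (is.na(j)) next
    depths <- c(snps$ref_depth[j], snps$alt_depth[j])
    alleles <- c(snps$ref[j], snps$alt[j])
    g1[i] <- sum(depths[alleles == psv$smn1_base[i]])
    g2[i] <- sum(depths[alleles == psv$smn2_base[i]])
    oth[i] <- sum(depths) - g1[i] - g2[i]
  }
  data.frame(pos = psv$pos, exon_group = psv$exon_group,
             gene1_support = g1, gene2_support = g2, other = oth,
             stringsAsFactors = FALSE)
}

#' Estimate SMN1/SMN2 integer copy numbers and the SMA status
#'
#' The combined read depth at PSV sites measures the total SMN copy number
#' (`2 * mean PSV depth / genome mean depth`, diploid baseline 2); the
#' fraction of PSV reads carrying the SMN1 base splits it between paralogs.
#' Exon 7-8 sites determine the clinical status (`affected` iff SMN1 copy
#' number 0, `carrier` iff 1); exon 1-6 copy numbers are reported when sites
#' are present. Integers are obtained by nearest rounding with
#' reconciliation so the parts always sum to the rounded total; a call is
#' atypical when any continuous value is more than `atypical_margin` from
#' its integer.
#'
#' @param psv_table output of [psv_depth_from_alleles()] or
#'   [simulate_psv_table()].
#' @param genome_mean_depth genome-wide mean depth (X).
#' @param atypical_margin continuous-to-integer distance above which the
#'   call is marked atypical (default 0.35).
#' @return object of class `smn_call`: per-exon-group continuous and integer
#'   copy numbers, `status` (`affected`/`carrier`/`normal`/`atypical`),
#'   `atypical` flag, `partial` flag when an exon group is absent.
#' @export
estimate_smn_copy_numbers <- function(psv_table, genome_mean_depth,
                                      atypical_margin = 0.35) {
  stopifnot(genome_mean_depth > 0)
  group_cn <- function(rows) {
    combined <- rows$gene1_support + rows$gene2_support
    if (sum(combined) == 0)
      stop("estimate_smn_copy_numbers: zero combined PSV depth")
    total_cont <- 2 * mean(combined) / genome_mean_depth
    frac1 <- sum(rows$gene1_support) / sum(combined)
    smn1_cont <- total_cont * frac1
    smn2_cont <- total_cont - smn1_cont
    total_int <- as.integer(round(total_cont))
    smn1_int <- as.integer(min(max(round(smn1_cont), 0), total_int))
    smn2_int <- total_int - smn1_int
    atyp <- any(abs(c(total_cont, smn1_cont, smn2_cont) -
                      c(total_int, smn1_int, smn2_int)) > atypical_margin)
    list(total_cont = total_cont, smn1_cont = smn1_cont,
         smn2_cont = smn2_cont, total_cn = total_int, smn1_cn = smn1_int,
         smn2_cn = smn2_int, atypical = atyp)
  }
  e78 <- psv_table[psv_table$exon_group == "exon7_8", , drop = FALSE]
  e16 <- psv_table[psv_table$exon_group == "exon1_6", , drop = FALSE]
  partial <- nrow(e78) == 0 || nrow(e16) == 0
  if (nrow(e78) == 0)
    stop("estimate_smn_copy_numbers: no exon 7-8 PSV sites")
  cn78 <- group_cn(e78)
  cn16 <- if (nrow(e16) > 0) group_cn(e16) else NULL
  status <- if (cn78$smn1_cn == 0L) "affected"
  else if (cn78$smn1_cn == 1L) "carrier"
  else if (cn78$atypical) "atypical"
  else "normal"
  structure(list(
    smn1_cn_exon78 = cn78$smn1_cn, smn2_cn_exon78 = cn78$smn2_cn,
    total_cn_exon78 = cn78$total_cn,
    continuous_exon78 = c(total = cn78$total_cont, smn1 = cn78$smn1_cont,
                          smn2 = cn78$smn2_cont),
    exon1_6 = cn16, status = status,
    atypical = cn78$atypical || (!is.null(cn16) && cn16$atypical),
    partial = partial),
    class = "smn_call")
}

#' @export
print.smn_call <- function(x, ...) {
  cat(sprintf(
    "smn_call: SMN1=%d SMN2=%d (exon 7-8; continuous %.2f/%.2f) status=%s%s\n",
    x$smn1_cn_exon78, x$smn2_cn_exon78,
    x$continuous_exon78["smn1"], x$continuous_exon78["smn2"], x$status,
    if (x$atypical) " [atypical]" else ""))
  invisible(x)
}
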