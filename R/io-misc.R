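#' Read a FASTQ file into a quality-scaled read set
#'
#' Thin wrapper around [Biostrings::readQualityScaledDNAStringSet()]
#' (Phred+33), preserving read order and identifiers.
#'
#' @param path FASTQ path (optionally gzipped), 4-line records.
#' @return a [Biostrings::QualityScaledDNAStringSet].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("read_fastq: cannot read '", path, "'")
  tryCatch(
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path,
                                                quality.scoring = "phred"),
      # the reader parses qualities via a metadata column and then drops
      # it; that internal detail is not a user-facing condition
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) stop("read_fastq: malformed FASTQ in '", path,
                             "': ", conditionMessage(e))
  )
}

#' Write a quality-scaled read set as FASTQ
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param path output path; `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeXStringSet(as(reads, "DNAStringSet"), path,
                              format = "fastq", qualities = quality(reads),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

## per-read integer Phred scores as a plain list
read_qualities <- function(reads) {
  as(as(quality(reads), "IntegerList"), "list")
}

#' Load a registry of known deletion/duplication alleles from BED
#'
#' BED is 0-based half-open. Columns: chrom, start, end, label (name), and
#' optionally score, strand, dosage_type (`deletion`/`duplication`; defaults
#' to deletion). Labels must be unique.
#'
#' @param bed_path path to the BED file.
#' @return a [GenomicRanges::GRanges] with metadata columns `label` and
#'   `dosage_type`.
#' @export
load_known_alleles <- function(bed_path) {
  lines <- readLines(bed_path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(GenomicRanges::GRanges(label = character(),
                                  dosage_type = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("load_known_alleles: line ", which(nf < 4)[1],
         " has fewer than 4 columns")
  chrom <- vapply(fields, `[`, "", 1)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  if (any(is.na(start0)) || any(is.na(end0)))
    stop("load_known_alleles: non-numeric coordinates at line ",
         which(is.na(start0) | is.na(end0))[1])
  if (any(start0 >= end0))
    stop("load_known_alleles: start >= end at line ",
         which(start0 >= end0)[1])
  label <- vapply(fields, `[`, "", 4)
  if (anyDuplicated(label))
    stop("load_known_alleles: duplicate label '",
         label[duplicated(label)][1], "'")
  dosage <- ifelse(nf >= 7, vapply(fields, function(f) f[7] %||% "", ""),
                   "deletion")
  dosage[!nzchar(dosage) | is.na(dosage)] <- "deletion"
  bad <- !dosage %in% c("deletion", "duplication")
  if (any(bad))
    stop("load_known_alleles: unknown dosage_type '", dosage[bad][1], "'")
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1L, end = end0),
                         label = label, dosage_type = dosage)
}

#' Write a known-allele registry as BED
#'
#' Inverse of [load_known_alleles()] (0-based half-open on disk).
#'
#' @param alleles GRanges with `label` and `dosage_type` metadata columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_known_alleles <- function(alleles, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(alleles)),
    start = GenomicRanges::start(alleles) - 1L,
    end = GenomicRanges::end(alleles),
    label = S4Vectors::mcols(alleles)$label,
    score = 0L, strand = ".",
    dosage = S4Vectors::mcols(alleles)$dosage_type
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a depth table (TSV)
#'
#' Columns: `chrom, start, end, count[, gc_fraction]` with 0-based half-open
#' intervals; `count` is either a read count per bin (CNV use) or a constant
#' per-base depth over the interval (coverage use).
#'
#' @param path TSV path; a header line is auto-detected.
#' @return data.frame with 1-based inclusive `start`/`end` columns
#'   (`start`, `end`), plus `count` and optional `gc_fraction`.
#' @export
read_depth_table <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("chrom", first, fixed = TRUE)
  df <- read.table(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE)
  if (!has_header) {
    nm <- c("chrom", "start", "end", "count", "gc_fraction")
    names(df)[seq_len(min(ncol(df), 5))] <- nm[seq_len(min(ncol(df), 5))]
  }
  df$start <- as.integer(df$start) + 1L
  df$end <- as.integer(df$end)
  df
}

#' Read chromosome lengths from a two-column TSV
#'
#' @param path TSV with columns chrom, length (no header required).
#' @return named integer vector of lengths.
#' @export
read_chrom_lengths <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Read a population allele-frequency table
#'
#' @param path TSV with columns chrom, pos, alt_af (header optional).
#' @return data.frame with columns `chrom`, `pos`, `alt_af`.
#' @export
read_pop_af <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("chrom", first, fixed = TRUE)
  df <- read.table(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE)
  if (!has_header) names(df)[1:3] <- c("chrom", "pos", "alt_af")
  df$pos <- as.integer(df$pos)
  df$alt_af <- as.numeric(df$alt_af)
  df
}

## data.frame(chrom,start,end) [1-based inclusive] or GRanges -> GRanges
as_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start, end = x$end))
}
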