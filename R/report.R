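#' Run all enabled detectors on one sample and assemble a JSON-able report
#'
#' The configuration is a nested list (usually parsed from YAML, see
#' [read_run_config()]). Top-level keys: `sample` (name), `seed`, and one
#' block per module — `coverage`, `ploidy`, `contamination`, `aoh`, `sma`,
#' `thal`, `trio` — each with `enabled` plus its input paths and parameter
#' overrides. A module whose inputs are missing is reported as `not_run`
#' with a reason rather than failing the whole sample.
#'
#' @param config nested configuration list.
#' @return list of class `sample_report`; serialize with
#'   [write_report_json()].
#' @export
run_sample <- function(config) {
  stopifnot(is.list(config))
  report <- list(
    tool = "germvar",
    version = as.character(utils::packageVersion("germvar")),
    sample = config$sample %||% "sample",
    modules = list()
  )
  enabled <- function(block) isTRUE(block$enabled %||% FALSE)
  add <- function(name, value) {
    report$modules[[name]] <<- value
  }
  not_run <- function(reason) list(status = "not_run", reason = reason)
  wrap <- function(expr, reason_prefix) {
    tryCatch(expr, error = function(e)
      not_run(paste0(reason_prefix, ": ", conditionMessage(e))))
  }

  snps <- NULL
  need_snps <- function(block) {
    if (is.null(snps) && !is.null(block$vcf))
      snps <<- read_vcf_snps(block$vcf,
                             min_depth = block$min_depth %||% 0L)$snps
    snps
  }

  cov <- config$coverage
  if (enabled(cov)) add("coverage", wrap({
    depth <- read_depth_table(cov$depth)
    targets <- read_depth_table(cov$targets)[, c("chrom", "start", "end")]
    cs <- coverage_summary(depth, targets,
                           thresholds = cov$thresholds %||% c(1, 10, 20))
    list(status = "ok", mean_depth = cs$mean_depth,
         target_size = cs$target_size,
         coverage_fractions = as.list(cs$coverage_fractions))
  }, "coverage"))

  pl <- config$ploidy
  if (enabled(pl)) add("ploidy", wrap({
    sn <- need_snps(pl)
    depth <- if (!is.null(pl$depth)) read_depth_table(pl$depth) else NULL
    res <- call_ploidy(sn, depth,
                       config = do.call(ploidy_config,
                                        pl$params %||% list()))
    list(status = "ok", genome_call = res$genome_call, calls = res$calls)
  }, "ploidy"))

  ct <- config$contamination
  if (enabled(ct)) add("contamination", wrap({
    sn <- need_snps(ct)
    af <- read_pop_af(ct$pop_af)
    est <- estimate_contamination(sn, af,
                                  config = do.call(contam_config,
                                                   ct$params %||% list()))
    list(status = "ok", alpha = est$alpha, flagged = est$flagged,
         exceeds_threshold = est$exceeds_threshold, n_sites = est$n_sites)
  }, "contamination"))

  ao <- config$aoh
  if (enabled(ao)) add("aoh", wrap({
    sn <- need_snps(ao)
    lens <- read_chrom_lengths(ao$chrom_lengths)
    res <- detect_aoh(sn, lens,
                      config = do.call(aoh_config, ao$params %||% list()))
    list(status = "ok",
         proportion_homozygous = res$proportion_homozygous,
         regions = res$regions[res$regions$reported, , drop = FALSE])
  }, "aoh"))

  sm <- config$sma
  if (enabled(sm)) add("sma", wrap({
    psv <- if (!is.null(sm[["psv"]])) read_psv_sites(sm[["psv"]])
    else smn_psv_sites()
    sn <- need_snps(sm)
    tab <- if (!is.null(sm[["psv_depth"]]))
      read.table(sm[["psv_depth"]], sep = "\t", header = TRUE,
                 stringsAsFactors = FALSE)
    else psv_depth_from_alleles(sn, psv)
    call <- estimate_smn_copy_numbers(tab, sm$genome_mean_depth %||% 40)
    list(status = "ok", smn1_cn = call$smn1_cn_exon78,
         smn2_cn = call$smn2_cn_exon78, smn_status = call$status,
         atypical = call$atypical)
  }, "sma"))

  th <- config$thal
  if (enabled(th)) add("thal", wrap({
    depth <- read_depth_table(th$depth)
    regions <- read_depth_table(th$unique_regions)[, c("chrom", "start",
                                                       "end")]
    alleles <- load_known_alleles(th$alleles)
    wins <- bin_and_count(depth, regions,
                          window_size = th$window %||% 500L)
    panel <- if (!is.null(th$panel))
      read.table(th$panel, header = FALSE)[[1]] else NULL
    wins <- gc_batch_correct(wins, panel = panel)
    segs <- hmm_segment(wins)
    gt <- call_thal_genotype(segs, alleles)
    list(status = "ok", genotype = gt$genotype, matches = gt$matches,
         novel = gt$novel)
  }, "thal"))

  tr <- config$trio
  if (enabled(tr)) add("trio", wrap({
    sites <- read_vcf_trio(tr$vcf, tr$child, tr$mother, tr$father)
    res <- segregation_filter(sites, mode = tr$mode %||% "flag_only")
    list(status = "ok", counts = as.list(res$counts))
  }, "trio"))

  class(report) <- "sample_report"
  report
}

#' Parse a YAML run configuration
#'
#' @param path YAML file.
#' @return the configuration list for [run_sample()].
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Serialize a sample report to JSON
#'
#' @param report a `sample_report` from [run_sample()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Structural validation of a sample report
#'
#' Checks the report against the shipped schema
#' (`inst/schema/report-schema.json`): required top-level keys, and that
#' every module block carries a `status` field.
#'
#' @param report a `sample_report` (or a list parsed back from JSON).
#' @return TRUE invisibly; stops with a message on violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("schema",
                                            "report-schema.json",
                                            package = "germvar"))
  required <- unlist(schema$required)
  missing <- setdiff(required, names(report))
  if (length(missing) > 0)
    stop("validate_report: missing key(s): ",
         paste(missing, collapse = ", "))
  if (!is.list(report$modules))
    stop("validate_report: 'modules' must be a mapping")
  for (nm in names(report$modules)) {
    if (is.null(report$modules[[nm]]$status))
      stop("validate_report: module '", nm, "' lacks a status field")
  }
  invisible(TRUE)
}
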