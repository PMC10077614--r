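# Fixtures are built in code at test time; nothing binary ships with the
# package.

write_fixture_vcf <- function(path, rows,
                              sample_names = "SAMPLE",
                              format = "GT:AD") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste(sample_names, collapse = "\t"))
  )
  writeLines(c(header, rows), path)
  path
}

## A deterministic single-chromosome SNP table: het everywhere except the
## given runs (forced hom_alt), SNPs every `spacing` bp, constant depth.
make_aoh_chrom <- function(chrom, chrom_len, spacing = 2000,
                           hom_runs = NULL, depth = 40L) {
  pos <- seq(spacing, chrom_len, by = spacing)
  gt <- rep("het", length(pos))
  if (!is.null(hom_runs)) {
    for (i in seq_len(nrow(hom_runs))) {
      gt[pos >= hom_runs$start[i] & pos <= hom_runs$end[i]] <- "hom_alt"
    }
  }
  alt <- ifelse(gt == "het", depth %/% 2L, depth)
  snp_table(rep(chrom, length(pos)), pos,
            rep("A", length(pos)), rep("G", length(pos)),
            ref_depth = depth - alt, alt_depth = alt, genotype = gt)
}

## Brute-force per-base coverage oracle over 1-based inclusive intervals
coverage_oracle <- function(depth_table, targets, thresholds) {
  stopifnot(length(unique(targets$chrom)) >= 1)
  per_base <- list()
  for (ch in unique(targets$chrom)) {
    tg <- targets[targets$chrom == ch, , drop = FALSE]
    bases <- unlist(lapply(seq_len(nrow(tg)), function(i)
      tg$start[i]:tg$end[i]))
    depth <- rep(0, length(bases))
    dt <- depth_table[depth_table$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(dt))) {
      hit <- bases >= dt$start[i] & bases <= dt$end[i]
      depth[hit] <- depth[hit] + dt$count[i]
    }
    per_base[[ch]] <- depth
  }
  depth <- unlist(per_base)
  list(mean_depth = mean(depth),
       fractions = vapply(sort(thresholds),
                          function(th) mean(depth >= th), numeric(1)))
}

## Exhaustive Viterbi oracle: enumerate every state path
viterbi_oracle <- function(obs, params) {
  S <- length(params$states)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), length(obs))))
  lp <- apply(paths, 1, function(p) {
    v <- params$log_init[p[1]] +
      sum(stats::dnorm(obs, params$means[p], params$sd, log = TRUE))
    if (length(p) > 1)
      v <- v + sum(params$log_trans[cbind(p[-length(p)], p[-1])])
    v
  })
  params$states[paths[which.max(lp), ]]
}

## Allele-transmission enumeration oracle for Mendelian consistency
mendel_oracle <- function(child, mother, father) {
  alleles <- list(hom_ref = c(0L, 0L), het = c(0L, 1L),
                  hom_alt = c(1L, 1L), missing = c(0L, 1L))
  m <- alleles[[mother]]
  f <- alleles[[father]]
  possible <- unique(t(apply(expand.grid(m, f), 1, sort)))
  cp <- sort(alleles[[child]])
  any(apply(possible, 1, function(x) all(x == cp)))
}
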