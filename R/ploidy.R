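#' Ploidy-calling configuration
#'
#' Parameters for the binomial allele-fraction ploidy caller. A diploid
#' heterozygous site has allele fraction near 1/2; on a trisomic chromosome
#' (or a triploid genome) het-site fractions shift to 1/3 or 2/3. Depth
#' thresholds sit midway between the copy-number expectations (CN3/CN2 ratio
#' 1.5, CN1/CN2 ratio 0.5).
#'
#' @param min_sites minimum het sites for a model fit (default 200).
#' @param bic_margin decision margin on the BIC difference between the
#'   triploid mixture and the diploid model (default 10).
#' @param gain_ratio depth ratio at or above which a chromosome may be
#'   called a gain (default 1.35).
#' @param loss_ratio depth ratio at or below which a chromosome is called a
#'   loss (default 0.65).
#' @param min_het_depth minimum total depth for a het site to enter the fit
#'   (default 10).
#' @return list of class `ploidy_config`.
#' @export
ploidy_config <- function(min_sites = 200L, bic_margin = 10,
                          gain_ratio = 1.35, loss_ratio = 0.65,
                          min_het_depth = 10L) {
  structure(list(min_sites = as.integer(min_sites), bic_margin = bic_margin,
                 gain_ratio = gain_ratio, loss_ratio = loss_ratio,
                 min_het_depth = as.integer(min_het_depth)),
            class = "ploidy_config")
}

#' Extract per-chromosome heterozygous-site counts
#'
#' Keeps sites classified het (genotype field, else VAF band) with total
#' depth at or above `min_depth`, grouped by chromosome.
#'
#' @param snps a [snp_table()].
#' @param min_depth minimum total depth (default 10).
#' @return named list; each element is a list with `chrom`, `alt` and `n`
#'   (integer vectors of alt and total depths at het sites).
#' @export
extract_het_counts <- function(snps, min_depth = 10L) {
  total <- snps$ref_depth + snps$alt_depth
  keep <- snps$genotype == "het" & total >= min_depth
  sub <- snps[keep, , drop = FALSE]
  out <- lapply(split(seq_len(nrow(sub)), sub$chrom), function(idx) {
    list(chrom = sub$chrom[idx[1]],
         alt = sub$alt_depth[idx],
         n = sub$ref_depth[idx] + sub$alt_depth[idx])
  })
  out[order(names(out))]
}

#' Fit binomial allele-fraction models to het-site counts
#'
#' Three models for the alt-read count at het sites: diploid
#' (`Binomial(n, 1/2)`), triploid (equal-weight mixture of
#' `Binomial(n, 1/3)` and `Binomial(n, 2/3)`), and free
#' (`Binomial(n, p)` with the closed-form MLE `p = sum(alt)/sum(n)`,
#' clipped away from the boundary).
#'
#' @param alt,n integer vectors of alt and total depths (0 <= alt <= n,
#'   n > 0).
#' @param min_sites minimum number of sites; fewer returns an
#'   insufficient-data marker without likelihoods.
#' @return list with `n_sites`, `loglik_diploid`, `loglik_triploid`,
#'   `loglik_free`, `fitted_p_free` and `insufficient` (logical).
#' @export
fit_ploidy_models <- function(alt, n, min_sites = 200L) {
  stopifnot(length(alt) == length(n))
  if (length(n) > 0) stopifnot(all(n > 0), all(alt >= 0), all(alt <= n))
  if (length(n) < min_sites) {
    return(list(n_sites = length(n), loglik_diploid = NA_real_,
                loglik_triploid = NA_real_, loglik_free = NA_real_,
                fitted_p_free = NA_real_, insufficient = TRUE))
  }
  ll_dip <- sum(dbinom(alt, n, 0.5, log = TRUE))
  ll_tri <- sum(logaddexp(dbinom(alt, n, 1 / 3, log = TRUE),
                          dbinom(alt, n, 2 / 3, log = TRUE)) - log(2))
  p_hat <- clip_unit(sum(alt) / sum(n))
  ll_free <- sum(dbinom(alt, n, p_hat, log = TRUE))
  list(n_sites = length(n), loglik_diploid = ll_dip,
       loglik_triploid = ll_tri, loglik_free = ll_free,
       fitted_p_free = p_hat, insufficient = FALSE)
}

#' Fit a two-component binomial mixture to het-site counts by EM
#'
#' Free component probabilities and weights; used to recover the 1/3 and 2/3
#' modes of a triploid allele-fraction distribution without assuming them.
#' Initialization from the empirical VAF quartiles; components returned in
#' increasing order of `p`.
#'
#' @param alt,n alt and total depths at het sites.
#' @param max_iter,tol EM iteration cap and loglik convergence tolerance.
#' @return list with `p` (length 2), `weight` (length 2), `loglik`,
#'   `iterations`.
#' @export
fit_vaf_mixture <- function(alt, n, max_iter = 500L, tol = 1e-8) {
  stopifnot(length(alt) == length(n), length(n) >= 2)
  vaf <- alt / n
  p <- clip_unit(quantile(vaf, c(0.25, 0.75), names = FALSE))
  if (diff(p) < 1e-3) p <- clip_unit(p + c(-0.05, 0.05))
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    la <- log(w[1]) + dbinom(alt, n, p[1], log = TRUE)
    lb <- log(w[2]) + dbinom(alt, n, p[2], log = TRUE)
    norm <- logaddexp(la, lb)
    ll <- sum(norm)
    resp <- exp(la - norm)
    w <- c(mean(resp), 1 - mean(resp))
    w <- pmin(pmax(w, 1e-8), 1 - 1e-8)
    p <- clip_unit(c(sum(resp * alt) / sum(resp * n),
                     sum((1 - resp) * alt) / sum((1 - resp) * n)))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(p)
  list(p = p[ord], weight = w[ord], loglik = ll, iterations = it)
}

#' Call per-chromosome ploidy status and a genome-level triploidy verdict
#'
#' Model selection is by BIC (the diploid and fixed-mixture triploid models
#' have no free parameters, the free-p model has one). The genome is called
#' triploid when the triploid mixture beats the diploid model by more than
#' `bic_margin` on a majority of autosomes with sufficient data. Otherwise,
#' per chromosome: `aneuploid_loss` when the depth ratio is at or below
#' `loss_ratio` (no allele-fraction evidence required — a monosomy has almost
#' no het sites); `aneuploid_gain` when the ratio is at or above `gain_ratio`
#' and the 1/3–2/3 mixture wins on that chromosome; `insufficient_data` when
#' too few het sites and no depth evidence of loss; else `diploid`. A
#' chromosome with no depth information is called on allele-fraction
#' evidence alone and flagged in `note`. Sex chromosomes never vote on the
#' genome-level call.
#'
#' @param snps a [snp_table()] for one sample (all chromosomes).
#' @param chrom_depth named numeric vector of per-chromosome mean depths, or
#'   a depth table data.frame (`chrom, start, end, count`) from which
#'   per-chromosome means are taken.
#' @param config a [ploidy_config()].
#' @return object of class `ploidy_result`: list with `calls` (data.frame:
#'   chrom, n_het_sites, loglik_diploid, loglik_triploid, loglik_free,
#'   fitted_p_free, depth_ratio, status, note), `genome_call`
#'   (`"diploid"`/`"triploid"`) and `config`.
#' @export
call_ploidy <- function(snps, chrom_depth = NULL, config = ploidy_config()) {
  het <- extract_het_counts(snps, min_depth = config$min_het_depth)
  chroms <- sort(unique(snps$chrom))
  if (is.data.frame(chrom_depth)) {
    chrom_depth <- vapply(split(chrom_depth$count, chrom_depth$chrom),
                          mean, numeric(1))
  }
  ratios <- setNames(rep(NA_real_, length(chroms)), chroms)
  if (!is.null(chrom_depth)) {
    auto <- chrom_depth[!is_sex_chrom(names(chrom_depth))]
    baseline <- median(auto)
    shared <- intersect(chroms, names(chrom_depth))
    ratios[shared] <- chrom_depth[shared] / baseline
  }
  fits <- lapply(chroms, function(ch) {
    h <- het[[ch]]
    if (is.null(h)) return(fit_ploidy_models(integer(), integer(),
                                             config$min_sites))
    fit_ploidy_models(h$alt, h$n, config$min_sites)
  })
  names(fits) <- chroms

  ## BIC with k = 0 for both fixed models: the difference is 2 * delta-loglik
  tri_wins <- vapply(fits, function(f) {
    !f$insufficient && 2 * (f$loglik_triploid - f$loglik_diploid) >
      config$bic_margin
  }, logical(1))
  autosome <- !is_sex_chrom(chroms)
  voting <- autosome & !vapply(fits, `[[`, TRUE, "insufficient")
  genome_call <- if (sum(voting) > 0 &&
                     sum(tri_wins[voting]) > sum(voting) / 2)
    "triploid" else "diploid"

  status <- character(length(chroms))
  note <- character(length(chroms))
  for (i in seq_along(chroms)) {
    f <- fits[[i]]
    r <- ratios[i]
    if (genome_call == "triploid" && autosome[i] && !f$insufficient) {
      status[i] <- "triploid"
    } else if (!is.na(r) && r <= config$loss_ratio) {
      status[i] <- "aneuploid_loss"
    } else if (f$insufficient) {
      status[i] <- "insufficient_data"
    } else if (!is.na(r) && r >= config$gain_ratio && tri_wins[i]) {
      status[i] <- "aneuploid_gain"
    } else if (is.na(r) && tri_wins[i]) {
      status[i] <- "aneuploid_gain"
      note[i] <- "allele_evidence_only"
    } else {
      status[i] <- "diploid"
      if (is.na(r)) note[i] <- "no_depth"
    }
  }
  calls <- data.frame(
    chrom = chroms,
    n_het_sites = vapply(fits, `[[`, 0L, "n_sites"),
    loglik_diploid = vapply(fits, `[[`, 0, "loglik_diploid"),
    loglik_triploid = vapply(fits, `[[`, 0, "loglik_triploid"),
    loglik_free = vapply(fits, `[[`, 0, "loglik_free"),
    fitted_p_free = vapply(fits, `[[`, 0, "fitted_p_free"),
    depth_ratio = as.numeric(ratios),
    status = status, note = note,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(calls = calls, genome_call = genome_call, config = config),
            class = "ploidy_result")
}

#' @export
print.ploidy_result <- function(x, ...) {
  cat("ploidy_result: genome call =", x$genome_call, "\n")
  abn <- x$calls[!x$calls$status %in% c("diploid", "triploid"), ]
  if (nrow(abn) > 0) {
    cat("  non-diploid chromosomes:\n")
    for (i in seq_len(nrow(abn)))
      cat(sprintf("    %s: %s (depth ratio %.2f, %d het sites)\n",
                  abn$chrom[i], abn$status[i], abn$depth_ratio[i],
                  abn$n_het_sites[i]))
  } else cat("  all chromosomes consistent with the genome call\n")
  invisible(x)
}
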