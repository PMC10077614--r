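#' Contamination-model configuration
#'
#' The estimator models each site's alt-read count as
#' `Binomial(depth, mu)` with `mu = (1 - alpha) * m(g_sample) +
#' alpha * m(g_contaminant)`, where `m(hom_ref) = error`, `m(het) = 0.5`,
#' `m(hom_alt) = 1 - error`, marginalizing the genotype pair over
#' Hardy-Weinberg priors built from the population allele frequency. The
#' contaminant is an unrelated individual by default; `relation = "maternal"`
#' constrains the pair to share one transmitted allele (mother contaminating
#' a fetal specimen).
#'
#' @param min_sites minimum usable sites (default 1000).
#' @param min_depth minimum site depth (default 10).
#' @param af_range population allele-frequency window for informative sites
#'   (default `c(0.05, 0.95)`, exclusive).
#' @param error per-read sequencing error rate (default 0.002).
#' @param threshold contamination fraction above which `exceeds_threshold`
#'   is set (default 0.05, the clinical reporting level).
#' @param relation contaminant relationship: `"unrelated"` or `"maternal"`.
#' @param grid_step step of the coarse alpha profile on `[0, 0.5]` (default
#'   0.01); the maximum is then refined by [stats::optimize()] inside the
#'   bracketing interval.
#' @param min_reportable smallest alpha reported as a detection (default
#'   0.01).
#' @param lrt_crit critical value for the likelihood-ratio statistic
#'   `2 * (loglik(alpha_hat) - loglik(0))` used by the detection flag
#'   (default `qchisq(0.999, 1)`).
#' @return list of class `contam_config`.
#' @export
contam_config <- function(min_sites = 1000L, min_depth = 10L,
                          af_range = c(0.05, 0.95), error = 0.002,
                          threshold = 0.05,
                          relation = c("unrelated", "maternal"),
                          grid_step = 0.01, min_reportable = 0.01,
                          lrt_crit = qchisq(0.999, 1)) {
  structure(list(min_sites = as.integer(min_sites),
                 min_depth = as.integer(min_depth), af_range = af_range,
                 error = error, threshold = threshold,
                 relation = match.arg(relation), grid_step = grid_step,
                 min_reportable = min_reportable, lrt_crit = lrt_crit),
            class = "contam_config")
}

## 3x3 genotype-pair prior weights (sample x contaminant), one row per site.
## Genotype coding 0/1/2 alt-allele dosage; column order gs0c0, gs1c0, ...
genotype_pair_weights <- function(af, relation) {
  hwe <- cbind((1 - af)^2, 2 * af * (1 - af), af^2)
  if (relation == "unrelated") {
    w <- matrix(0, length(af), 9)
    k <- 0
    for (gc in 0:2) for (gs in 0:2) {
      k <- k + 1
      w[, k] <- hwe[, gs + 1] * hwe[, gc + 1]
    }
    return(w)
  }
  ## maternal: contaminant is the mother; the sample (child) receives one of
  ## her alleles plus a population allele at frequency af
  w <- matrix(0, length(af), 9)
  trans <- c(0, 0.5, 1)              # P(alt transmitted | mother dosage)
  k <- 0
  for (gc in 0:2) {
    t <- trans[gc + 1]
    child <- cbind((1 - t) * (1 - af), t * (1 - af) + (1 - t) * af, t * af)
    for (gs in 0:2) {
      k <- k + 1
      w[, k] <- hwe[, gc + 1] * child[, gs + 1]
    }
  }
  w
}

## Factory for the summed log-likelihood over a vector of alphas.
## Binomial coefficients and the three alpha-independent genotype pairs
## (sample and contaminant genotype equal) are precomputed once.
make_contam_loglik <- function(alt, n, w, error) {
  m <- c(error, 0.5, 1 - error)
  ms <- rep(m, times = 3)            # sample genotype per column
  mc <- rep(m, each = 3)             # contaminant genotype per column
  lch <- lchoose(n, alt)
  dens <- function(mu) exp(lch + alt * log(mu) + (n - alt) * log1p(-mu))
  static_k <- which(ms == mc)
  dynamic_k <- which(ms != mc)
  lik_static <- 0
  for (k in static_k) lik_static <- lik_static + w[, k] * dens(ms[k])
  function(alpha) {
    vapply(alpha, function(a) {
      lik <- lik_static
      for (k in dynamic_k)
        lik <- lik + w[, k] * dens((1 - a) * ms[k] + a * mc[k])
      sum(log(lik))
    }, numeric(1))
  }
}

#' Estimate the foreign-DNA contamination fraction from VAFs
#'
#' Maximum-likelihood estimate of the contamination fraction `alpha` in
#' `[0, 0.5]` under the genotype-pair mixture model of [contam_config()].
#' The sample is flagged (`flagged`) when contamination is statistically
#' detected: the likelihood-ratio test against `alpha = 0` exceeds
#' `lrt_crit` and the estimate is at least `min_reportable`. The literal
#' threshold comparison is reported separately as `exceeds_threshold`
#' (`alpha > threshold`).
#'
#' @param snps a [snp_table()].
#' @param pop_af data.frame with `chrom, pos, alt_af` (population alternate
#'   allele frequencies; see [read_pop_af()]).
#' @param config a [contam_config()].
#' @return object of class `contamination_estimate`: `alpha`,
#'   `loglik_profile` (data.frame alpha/loglik on the coarse grid),
#'   `flagged`, `exceeds_threshold`, `lrt`, `n_sites`, `sequencing_error`,
#'   `insufficient`.
#' @export
estimate_contamination <- function(snps, pop_af, config = contam_config()) {
  key <- paste(snps$chrom, snps$pos)
  af <- pop_af$alt_af[match(key, paste(pop_af$chrom, pop_af$pos))]
  if (all(is.na(af))) stop("estimate_contamination: no site has a ",
                           "population allele frequency")
  n_tot <- snps$ref_depth + snps$alt_depth
  keep <- !is.na(af) & n_tot >= config$min_depth &
    af > config$af_range[1] & af < config$af_range[2]
  alt <- snps$alt_depth[keep]
  n <- n_tot[keep]
  af <- af[keep]
  if (length(alt) < config$min_sites) {
    return(structure(list(alpha = NA_real_, loglik_profile = NULL,
                          flagged = FALSE, exceeds_threshold = FALSE,
                          lrt = NA_real_, n_sites = length(alt),
                          sequencing_error = config$error,
                          insufficient = TRUE),
                     class = "contamination_estimate"))
  }
  w <- genotype_pair_weights(af, config$relation)
  loglik_fn <- make_contam_loglik(alt, n, w, config$error)
  grid <- seq(0, 0.5, by = config$grid_step)
  ll <- loglik_fn(grid)
  best <- which.max(ll)
  lo <- grid[max(1, best - 1)]
  hi <- grid[min(length(grid), best + 1)]
  opt <- optimize(loglik_fn, interval = c(lo, hi), maximum = TRUE,
                  tol = 1e-5)
  alpha <- opt$maximum
  ll_hat <- opt$objective
  if (ll[best] > ll_hat) { alpha <- grid[best]; ll_hat <- ll[best] }
  lrt <- 2 * (ll_hat - ll[1])
  flagged <- alpha >= config$min_reportable && lrt > config$lrt_crit
  structure(list(alpha = alpha,
                 loglik_profile = data.frame(alpha = grid, loglik = ll),
                 flagged = flagged,
                 exceeds_threshold = alpha > config$threshold,
                 lrt = lrt, n_sites = length(alt),
                 sequencing_error = config$error, insufficient = FALSE),
            class = "contamination_estimate")
}

#' Empirical detection-rate curve for the contamination model
#'
#' Simulates two-genome mixtures at each requested contamination fraction
#' (via [simulate_contamination_sites()]) and reports the raw fraction of
#' replicates flagged by [estimate_contamination()]; no smoothing is
#' applied.
#'
#' @param alphas contamination fractions to characterize.
#' @param replicates simulated samples per fraction.
#' @param n_sites,mean_depth simulation size per sample (defaults 10000
#'   sites at 40X).
#' @param config a [contam_config()].
#' @param seed base seed; replicate seeds are derived deterministically.
#' @return named numeric vector: detection rate per alpha (names are the
#'   alpha values).
#' @export
contamination_power_curve <- function(alphas, replicates,
                                      n_sites = 10000L, mean_depth = 40,
                                      config = contam_config(), seed = 1L) {
  if (length(alphas) == 0) return(setNames(numeric(0), character(0)))
  stopifnot(replicates >= 1)
  rates <- vapply(seq_along(alphas), function(i) {
    flags <- vapply(seq_len(replicates), function(r) {
      sim <- simulate_contamination_sites(
        n_sites = n_sites, alpha = alphas[i], mean_depth = mean_depth,
        relation = config$relation, error = config$error,
        seed = derive_seed(seed, i * 1000L + r))
      est <- estimate_contamination(sim$snps, sim$pop_af, config)
      isTRUE(est$flagged)
    }, logical(1))
    mean(flags)
  }, numeric(1))
  setNames(rates, format(alphas, trim = TRUE))
}

#' @export
print.contamination_estimate <- function(x, ...) {
  if (x$insufficient) {
    cat("contamination_estimate: insufficient data (", x$n_sites,
        " usable sites)\n", sep = "")
  } else {
    cat(sprintf(
      "contamination_estimate: alpha = %.4f (%d sites, LRT %.1f)%s%s\n",
      x$alpha, x$n_sites, x$lrt,
      if (x$flagged) " [FLAGGED]" else "",
      if (x$exceeds_threshold) " [> threshold]" else ""))
  }
  invisible(x)
}
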