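# germvar

Detection programs for clinical whole-genome sequencing (WGS) of genetic
disorders.

A clinical WGS pipeline surrounds its standard aligner/caller core with a
set of bespoke detectors for variant classes that short-read callers do not
report directly: whole-chromosome aneuploidy and triploidy, maternal-cell
contamination of fetal specimens, absence of heterozygosity (AOH), SMN1/SMN2
copy number for spinal muscular atrophy (SMA), and the recurrent large
deletions that cause alpha-thalassemia. `germvar` implements those
detectors, the raw-read and coverage QC in front of them, the trio
segregation filter behind them, and the per-class validation metrics used to
benchmark the whole — together with a seeded synthetic-data generator that
emulates every input, so the complete surface is testable without patient
genomes.

## The models

**Ploidy from allele fractions.** At a heterozygous biallelic site with
total depth $n_i$ and alt-supporting depth $k_i$, the alt fraction is near
$1/2$ in a diploid genome. A trisomic chromosome (or a triploid genome)
carries its heterozygous alleles in 1:2 or 2:1 dosage, so the fractions
shift to $1/3$ and $2/3$. The caller compares, per chromosome,

$$\ell_{\mathrm{dip}} = \sum_i \log \mathrm{Bin}(k_i \mid n_i, 1/2),
\qquad
\ell_{\mathrm{tri}} = \sum_i \log\left[\tfrac12 \mathrm{Bin}(k_i \mid n_i, 1/3)
 + \tfrac12 \mathrm{Bin}(k_i \mid n_i, 2/3)\right]$$

by BIC, and combines the verdict with the chromosome's depth ratio
(chromosome mean depth over the autosomal median): a gain needs both the
mixture win and ratio ≥ 1.35, a loss needs only ratio ≤ 0.65, and the
genome is triploid when the mixture wins on a majority of autosomes at flat
depth.

**Contamination from VAFs.** A fraction $\alpha$ of foreign DNA moves
variant allele fractions away from $\{0, 1/2, 1\}$. Each site's alt count
is modelled as $\mathrm{Bin}(n_i, \mu_i)$ with
$\mu_i = (1-\alpha)\,m(g_s) + \alpha\,m(g_c)$, where $m$ maps a genotype to
its expected alt fraction ($\varepsilon$, $1/2$, $1-\varepsilon$;
$\varepsilon$ the sequencing error rate) and the unobserved genotype pair
$(g_s, g_c)$ is marginalized over Hardy–Weinberg priors from population
allele frequencies (an unrelated or a maternal contaminant). $\hat\alpha$
maximizes the summed log-likelihood on $[0, 0.5]$; a sample is flagged when
the likelihood-ratio test against $\alpha = 0$ is decisive.

**AOH.** Overlapping windows of 20 consecutive SNPs advance one SNP at a
time; a window with at most one het call is homozygous. Overlapping
homozygous windows are unioned, merged across gaps ≤ 500 kb, and classified
terminal when they come within 1 Mb of a chromosome end. Terminal regions
≥ 5 Mb are reported.

**SMN1/SMN2.** Reads at paralogous sequence variants (PSVs) are split by
the base they carry. The combined PSV depth over exon 7–8 sites, scaled by
the genome mean depth, gives the total SMN copy number; the SMN1-base read
fraction splits it. SMN1 copy 0 = affected, 1 = carrier.

**Thalassemia CNV.** Read counts in 500-bp windows over uniquely mappable
regions are GC-corrected (stratified medians) and optionally
batch-corrected against a reference panel, then segmented by a 5-state
(CN 0–4) Gaussian-emission HMM via Viterbi decoding. Deletion segments are
matched to known alleles (`--SEA`, `-a3.7`, `-a4.2`) by ≥ 0.8 reciprocal
overlap and ≤ 5 kb breakpoint distance, yielding genotypes such as
`--SEA/aa` or `--SEA/--SEA`.

**Trio and validation.** Sites whose child genotype cannot be formed from
one allele of each parent are flagged or removed. Per variant class,
sensitivity is the fraction of class-positive samples detected and
specificity treats samples carrying *other* classes as the negative set.

## Worked example

Simulate a 40X genome with a trisomy of one model chromosome, then call
ploidy from the het-site allele fractions plus depth ratios:

```r
library(germvar)
sim    <- simulate_snp_table(seed = 1, ploidy = c(chr4 = "trisomy"))
depths <- simulate_chrom_depth(seed = 2, ploidy = c(chr4 = "trisomy"))
call_ploidy(sim$snps, depths)
#> ploidy_result: genome call = diploid
#>   non-diploid chromosomes:
#>     chr4: aneuploid_gain (depth ratio 1.49, 7062 het sites)
```

The genome-level call stays diploid (only one chromosome shows the 1/3–2/3
mixture), while chr4 is called a gain: its depth runs at 1.49× the
autosomal median and its het-site fractions fit the trisomic mixture.

```r
mix <- simulate_contamination_sites(n_sites = 10000, alpha = 0.10, seed = 3)
estimate_contamination(mix$snps, mix$pop_af)
#> contamination_estimate: alpha = 0.0998 (10000 sites, LRT 29892.8) [FLAGGED] [> threshold]
```

A simulated 10% two-genome mixture is estimated at 9.98% contamination,
flagged as detected, and marked above the 5% clinical reporting threshold.

A thin command-line dispatcher over the same functions ships at
`inst/cli/germvar.R` (subcommands `run`, `qc-reads`, `coverage`, `ploidy`,
`contam`, `aoh`, `sma`, `thal`, `trio-filter`, `validate`).

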