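---
title: "germvar: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{germvar: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germvar)
```

`germvar` implements the bespoke detectors of a clinical whole-genome
sequencing workflow for genetic disorders. This vignette is the package's
own account of the science: the models, their assumptions, the parameters
that matter, what the synthetic generator does and does not emulate, and
the numerical choices made where the design was genuinely open. It states
no empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## Raw-read and coverage QC

A read is rejected when it meets at least one of three rules: N-base
fraction ≥ `max_n_fraction` (default 0.10, inclusive), fraction of bases
with Phred quality below `low_q_cutoff` (default 5) at or above
`max_low_q_fraction` (default 0.50, inclusive), or mean quality strictly
below `min_mean_quality` (default 10). The inequality directions are part
of the contract and are pinned by boundary tests (a read at exactly 10% N
is rejected; a read with mean quality exactly 10 is retained).

"Mean quality" is read as the arithmetic mean of Phred scores. Averaging
on the error-probability scale instead would punish single very bad bases
much harder; both readings are defensible, so the alternative is exposed as
`mean_quality_mode = "error"` and the Phred mean is the default as the
smallest-surprise interpretation. Adapter trimming is deliberately out of
scope — it belongs to upstream tooling.

Coverage summaries treat the depth table's `count` column as a constant
per-base depth over each interval; target bases not covered by any row
count as depth 0, so mean depth and the ≥1X/≥10X/≥20X fractions are always
computed over the full target denominator.

## Ploidy: binomial models on het-site allele fractions

At a heterozygous site with depth $n_i$ and alt count $k_i$, a diploid
genome puts the alt fraction near 1/2; a chromosome present in three
copies carries het alleles in 1:2 or 2:1 dosage, moving fractions to 1/3
or 2/3. Three models are fitted per chromosome to het sites (genotype
field, else VAF in [0.1, 0.9]; depth ≥ 10; at least 200 sites):

* diploid: $k_i \sim \mathrm{Bin}(n_i, 1/2)$;
* triploid: an equal-weight mixture of $\mathrm{Bin}(n_i, 1/3)$ and
  $\mathrm{Bin}(n_i, 2/3)$ — the weights are fixed at 1/2 because the two
  parental-duplication configurations are symmetric a priori, and skewed
  data are caught by the third model;
* free: $\mathrm{Bin}(n_i, p)$ with the closed-form MLE
  $\hat p = \sum k_i / \sum n_i$, clipped to $(10^{-6}, 1 - 10^{-6})$ so a
  degenerate chromosome (e.g. a single site with $k = n$) never produces an
  infinite log-likelihood.

Model selection is by BIC with zero free parameters for the two fixed
models and one for the free model; since the fixed models tie on
complexity, their comparison reduces to twice the log-likelihood
difference, and a decision margin (default 10) guards against noise-level
wins. The genome is called triploid when the mixture wins by more than the
margin on a majority of autosomes; sex chromosomes never vote because
their het-site expectations depend on karyotype.

Depth enters through the ratio of each chromosome's mean depth to the
autosomal median. The gain and loss thresholds (1.35 and 0.65) sit midway
between the copy-number expectations (CN3/CN2 → 1.5, CN1/CN2 → 0.5) and
are configurable. A gain call requires both depth and allele-fraction
evidence; a loss call requires depth evidence only, because a monosomic
chromosome has essentially no heterozygous sites — for the same reason the
`insufficient_data` label applies only where depth gives no verdict
either. A chromosome with no depth information at all is called on allele
evidence alone and flagged. Mosaic and segmental aneuploidy are out of
scope (the whole-chromosome status is the unit of report; partial events
belong to the CNV module).

A free-weight two-component binomial mixture fitted by EM
(`fit_vaf_mixture()`, initialized from the empirical VAF quartiles so the
1/3–2/3 answer is not baked in) serves as a diagnostic: on triploid data
its components should land on 1/3 and 2/3 without being told to.

## Contamination: a genotype-pair mixture likelihood

Foreign DNA at fraction $\alpha$ mixes a second genotype into every site.
With $m(\mathrm{hom\_ref}) = \varepsilon$, $m(\mathrm{het}) = 1/2$,
$m(\mathrm{hom\_alt}) = 1-\varepsilon$ (sequencing error
$\varepsilon = 0.002$), the alt count at a site is
$\mathrm{Bin}(n_i,\; (1-\alpha)m(g_s) + \alpha m(g_c))$, and the unobserved
pair $(g_s, g_c)$ is marginalized under Hardy–Weinberg priors from the
population allele frequency — the standard single-sample formulation for
sequence-only contamination checks. The contaminant prior is an unrelated
individual by default; a `maternal` mode constrains the pair to share one
transmitted allele, matching the clinically dominant scenario of maternal
cells in a chorionic-villus or amniotic-fluid specimen. Sites need depth
≥ 10 and a population frequency in (0.05, 0.95); at least 1000 such sites
are required. $\alpha$ is capped at 0.5: the majority component defines
the sample.

The estimate maximizes the summed log-likelihood with a coarse profile
(step 0.01 on [0, 0.5], returned to the caller for inspection) followed by
`stats::optimize()` inside the bracketing interval, which resolves the
maximizer to ~1e-5 with an order of magnitude fewer likelihood evaluations
than a fine fixed grid; the likelihood is smooth and unimodal in $\alpha$
under this model, so the two-stage search finds the same maximum.

Two decisions are reported separately because they answer different
questions. `flagged` answers "is there contamination?": the
likelihood-ratio statistic against $\alpha = 0$ must exceed
`qchisq(0.999, 1)` and the estimate must reach a minimum reportable level
(0.01) — an unbiased estimator hovering around a hard threshold would
otherwise flag a truly threshold-level sample only half the time, which is
not what a screening QC step should do. `exceeds_threshold` answers "is
the estimate above the 5% reporting level?" as a literal comparison.
`contamination_power_curve()` characterizes the detection rule empirically
by simulating mixtures at each requested fraction and reporting raw flag
rates, no smoothing.

## AOH: sliding SNP windows with terminal reporting

Windows span exactly 20 consecutive genotyped SNPs and advance one SNP at
a time; a window with at most one het call is homozygous. The window size
follows the operating point established for this class of detector; the
one-het tolerance absorbs isolated genotyping errors inside a true run
while two hets in any 20 SNPs still break it, and both are configurable.

Overlapping homozygous windows are unioned; leading/trailing het SNPs are
trimmed so regions start and end on homozygous calls. Region coordinates
then extend across the uninformative flanks — from the base after the
previous het SNP to the base before the next, clamped to the chromosome
ends for runs that reach the first or last genotyped SNP. The rationale:
homozygosity is unobserved between SNPs, and the maximal extent consistent
with the data is bounded by the flanking het sites; measuring only the SNP
span would systematically shorten every run by about one SNP spacing and
make a run of exactly the reporting length unreportable. The first/last
homozygous SNP positions are retained (`snp_start`, `snp_end`) for
span-level reporting. Regions separated by ≤ 500 kb merge.

A region is terminal when it comes within 1 Mb of a chromosome end (the
margin accommodates SNP sparsity near telomeres); terminal regions ≥ 5 Mb
are reported. Interstitial reporting is disabled by default and can be
enabled with its own length floor for general run-of-homozygosity use. The
genome-wide proportion of homozygous sites is computed over genotyped
biallelic SNPs only, so the denominator is well defined; per-region SNP
and het counts are also emitted.

## SMN1/SMN2 copy number

SMN1 and SMN2 differ at a handful of paralogous sequence variants; reads
are assigned to a paralog by the base they carry. Over the exon 7–8 PSV
rows, the total copy number is `2 * mean(combined PSV depth) /
genome_mean_depth` (diploid baseline 2) and SMN1's share is the fraction
of PSV reads carrying the SMN1 base. Integers come from nearest rounding
with reconciliation (SMN2 = total − SMN1, SMN1 clamped into [0, total]) so
the parts always sum to the rounded total; a call whose continuous value
sits more than 0.35 from its integer is marked atypical. Clinical status
uses exon 7–8 only — SMN1 copy 0 is affected, 1 is carrier — while exon
1–6 copy numbers are reported when sites are available.

The shipped registry is synthetic (positions in a combined SMN alignment
space, not a genome build) and carries eight exon 7–8 sites: the estimate
averages Poisson-distributed depths across sites, and with only four sites
the continuous total's standard deviation at 40X (~0.22 copies) would make
integer rounding fail a few percent of the time; eight sites brings that
below 1%. Real-coordinate registries are user-supplied. Silent (2+0)
carriers and SMN2 splice modifiers are out of scope.

## Thalassemia CNV: corrected depth ratios and an HMM

Windows of 500 bp (configurable) tile caller-supplied uniquely mappable
regions — restricting to unique regions is the package's entire answer to
paralog homology in the globin clusters; no mappability computation is
performed. A terminal remainder shorter than half a window is dropped as
too noisy to score. GC correction stratifies windows into 0.01-wide GC
bins and divides each count by its bin median (bins with fewer than 10
windows borrow the nearest populated bin), then by the global median, so
copy-number-2 windows center on ratio 1; batch correction further divides
by a reference panel's per-window normalized medians when a panel is
given. Median-based correction is robust to planted events occupying a
minority of windows.

Segmentation decodes the most probable copy-number path (states CN 0–4)
under Gaussian emissions on the ratio scale with means CN/2 (CN0 floored
at 0.05 — a literal zero mean would be degenerate against residual
mis-mapping) and a shared sd of 0.12, matching the Poisson noise of
~100-read windows. The stay probability 1 − 1e-4 encodes roughly one
breakpoint per 10,000 windows: deletions here are rare and long, and a
cheaper exit would fragment segments at noise level. The initial
distribution puts 0.96 on CN2. Viterbi is decoded in log space per
chromosome; equal-state windows merge into segments. A negative-binomial
emission on raw counts would be the natural extension for overdispersed
libraries and is noted, not implemented.

Deletion segments match a known allele when reciprocal overlap is ≥ 0.8
and both breakpoints agree within 5 kb (10 windows at the default size —
loose enough for window quantization, tight enough to separate the ~19 kb
and ~4 kb allele shapes). CN1 over an allele yields a heterozygous
genotype (`--SEA/aa`), CN0 homozygous, two different matched CN1 alleles a
compound; unmatched deletions are reported as novel with coordinates.
Labels are ASCII (`aa` denotes the intact haplotype) to keep genotype
strings encoding-safe. The shipped locus and allele coordinates are
synthetic, flagged as such; clinical registries are data, not code.

## Trio filter and validation metrics

A site is Mendelian-consistent when the child genotype can be formed from
one allele of each parent; a missing parent is compatible by convention,
and a missing child genotype is unevaluable. Both a flag-only and a
removal mode exist because downstream policy (hard filter vs annotation)
is a lab decision. X-chromosome hemizygous rules are gated behind an
off-by-default sex-aware mode.

Per variant class, sensitivity is the detected fraction of class-positive
samples. Specificity follows the benchmark convention in which samples
carrying *other* variant classes form the negative set and count as
correctly handled when their own variant is detected; the conventional
true-negative rate (no false call of *this* class on non-class samples) is
available via `convention = "conventional"`, and the test suite checks the
panel under both. Zero denominators are reported as explicitly undefined,
never as 0/0.

## The synthetic generator

Every detector input can be generated from a single seed (all randomness
flows through `withr::with_seed`; the session RNG is untouched, and
identical seeds give byte-identical outputs — asserted in tests):

* SNP tables: positions uniform at ~1 per 5 kb, population allele
  frequencies Uniform(0.1, 0.9), Hardy–Weinberg genotypes, per-site depth
  Poisson with mean 40 × CN/2, alt counts binomial in the allele dosage
  with per-read error 0.002; AOH regions force homozygosity; contamination
  mixes a second genotype draw (unrelated or maternal) into the binomial
  success probability.
* Per-chromosome depths: windowed Poisson means (trisomy 1.5×, monosomy
  0.5×, triploidy flat — which is exactly why triploidy needs allele
  evidence).
* Depth profiles: window counts Poisson with mean
  `mean_count · (CN/2) · (1 + slope · (gc − 0.5))`, GC Uniform(0.3, 0.6).
* PSV tables: combined depth Poisson in the total SMN copy number, SMN1
  support binomial in its share.
* Reads: templated N-fraction and quality composition to hit each QC rule
  on demand.

The model genome is six 60-Mb autosomes — large enough that every detector
operates in its intended statistical regime (thousands of het sites per
chromosome at 40X) and small enough that the full 45-sample panel runs in
about a minute; the acceptance script's AOH scenario uses three 30-Mb
chromosomes at ~1 SNP per 2 kb for the same reason. These sizes are the
package's chosen study conditions, stated here once.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: linkage disequilibrium and realistic allele
frequency spectra; mapping and reference bias; GC effects on SNP depth
(only windowed counts get a GC term); segmental duplications beyond the
unique-region restriction; mosaicism; index hopping or cross-species
contamination; caller-specific genotyping error patterns. Results on this
generator demonstrate correctness of the statistical machinery at the
stated operating points, not clinical performance.

## The validation panel

`run_validation_panel()` mirrors a 45-sample known-variant benchmark for
the in-scope classes: 5 aneuploidies (trisomies of five model
chromosomes), 1 triploidy, 1 multi-AOH sample (two terminal runs ≥ 5 Mb
plus one interstitial run), 1 SMN1 exon 7–8 deletion, 4 thalassemia
genotypes (`--SEA` het and hom, `-a3.7` het, `-a4.2` het), and 33 samples
negative for every in-scope class, standing in for carriers of variant
types handled by external tools. Trisomies rather than monosomies were
chosen for the aneuploidy slots because a monosomic chromosome is entirely
homozygous and would legitimately light up the AOH detector as well —
biologically real, but it would muddy the per-class attribution the panel
exists to measure; monosomy is exercised in unit tests. Detection rules
per class are deliberately simple (any gain/loss chromosome under a
diploid genome call; a triploid genome call; any reported AOH region; SMN1
exon 7–8 copy < 2; any thalassemia genotype other than `aa/aa`).

## Numerical and degenerate-input choices

* Log-sum-exp is used for every mixture log-likelihood; `-Inf` inputs are
  handled explicitly.
* The free-p MLE and all probability parameters are clipped away from
  {0, 1} by 1e-6.
* Zero-depth VCF rows are skipped and tallied, never given a VAF;
  zero-length reads are rejected and tallied separately, never divided by.
* EM for the VAF mixture caps at 500 iterations with a 1e-8 loglik
  tolerance and collapses gracefully when initialization quartiles
  coincide.
* Viterbi ties break toward the lower state index (`max.col` first-match);
  with continuous emissions ties have measure zero and the exhaustive
  enumeration oracle in the tests confirms exact path equality.
* Coordinates are 1-based inclusive inside the package; BED and depth-table
  files are 0-based half-open on disk, converted only at I/O boundaries.
  Chromosome naming is normalized by an explicit `chr`-prefix switch; the
  reference build is configuration, not code.

## Known limitations

Single-sample contamination estimation cannot separate a maternal from an
unrelated contaminant at low α without external genotypes; the ploidy
caller does not quantify mosaic fraction; AOH parent-of-origin (isodisomy
vs heterodisomy) needs trio haplotypes and is out of scope; the
thalassemia module genotypes deletions only (non-deletional point alleles
are the domain of the small-variant caller); and the validation panel's
100% figures are properties of the synthetic operating point, not clinical
claims.
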