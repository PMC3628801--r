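---
title: "Methods: homozygosity mapping and variant prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homozygosity mapping and variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recessmap)
```

# The scientific problem

A fully penetrant autosomal recessive disorder in an inbred population
(the motivating case is a hereditary disorder in a closed dog breed) has a
special genetic structure: every affected individual carries two copies of
the same causal allele descended from one recent ancestor. The affected
individuals are therefore *identical by descent* (IBD) not only at the
causal site but across the surrounding haplotype, so all of them are
homozygous, for the same alleles, over an extended chromosomal segment.

This turns gene discovery into a positional pipeline that works with
remarkably small cohorts (here: 7 cases and 7 controls):

1. **Marker QC** — clean a genome-wide SNP-array dataset;
2. **Association** — find the chromosome carrying the signal;
3. **Autozygosity mapping** — delineate the shared homozygous segment
   (the *critical interval* that must contain the mutation);
4. **Prioritization** — intersect the proband's whole-genome variant
   calls with the interval and successively discard implausible calls;
5. **Consequence annotation** — predict the protein-level effect of the
   survivors;
6. **Segregation** — confirm genotype/phenotype concordance in a large
   validation cohort.

`recessmap` implements each stage as a composable function with an S3
result class, plus a simulator that generates cohorts with *planted*
ground truth so that the whole pipeline can be exercised and its
operating characteristics measured end to end.

# Stage by stage

## Marker QC

`qc_filter()` removes samples with call rate below 0.90, then markers
with call rate < 0.90, minor allele frequency < 0.05, or an exact
Hardy–Weinberg test p-value < 1e-5 *in controls only* (cases are expected
to deviate at trait-associated markers, so including them would remove
exactly the signal being sought). Every exclusion is recorded with its
reason, and retained + removed always equals the input count.

The Hardy–Weinberg test is the exact conditional test: given the minor
allele count, the probability of each possible heterozygote count is
computed by the standard recurrence (anchored at the mid-range
configuration for numerical stability), and the p-value is the sum of all
configurations no more probable than the observed one. Because the "no
more probable" comparison is between floating-point numbers that are
mathematically equal for symmetric configurations, the tie rule accepts
configurations with `p_i <= p_obs * (1 + 1e-12)`; without the epsilon,
rounding error can drop a tied configuration and halve the p-value. The
test suite checks the implementation against an independent
full-enumeration oracle (log-factorials, no recurrence) to 1e-12 over
hundreds of random tables.

## Association

`run_gwas()` computes, per marker, the 1-df Pearson chi-square on the
2×2 allele-count table (cases vs controls × allele), with no continuity
correction — the classical allelic test. With 7 cases and 7 controls the
most extreme attainable configuration (cases 14:0, controls 2:12) gives
χ² = 21.0 and p = 4.6×10⁻⁶, which is why a handful of inbred cases can
carry genome-wide signal.

Two multiple-testing diagnostics are provided:

* `genomic_inflation()` — λ = median(χ²) / 0.4549364 (the null median of
  χ²₁), diagnosing stratification. Inbred cohorts routinely show λ > 1
  even without confounding, which is precisely why permutation rather
  than Bonferroni correction is used for inference.
* `max_t_permutation()` — the max-T family-wise correction: case/control
  labels are permuted, the genome-wide maximum χ² recorded per
  permutation, and each marker's corrected p-value is the fraction of
  permutations whose maximum reaches its observed χ². The estimator is
  `(1 + k) / (1 + N)` (k exceedances in N permutations): this is the
  standard bias-avoiding form that can never report p = 0 and is valid as
  a p-value for any N. Permutations are computed for all markers at once
  as an indicator-matrix × dosage-matrix product in blocks, which keeps
  10,000 genome-wide permutations in the seconds-to-a-minute range.

The test suite validates the permutation machinery against an exhaustive
oracle: with 4 cases and 4 controls all C(8,4) = 70 labelings can be
enumerated exactly, and the sampled estimate must agree within three
binomial standard errors.

**Calibration testing note.** The suite also checks that raw p-values are
calibrated (rejection rate ≈ α) under the null. This cannot be done at
the pipeline's native 7v7 scale: with 28 alleles the test statistic takes
only a handful of discrete values and uniformity of p-values is
mathematically impossible. Calibration is therefore asserted at 250 cases
vs 250 controls, where the chi-square approximation is accurate; the 7v7
scale is covered instead by the exact-oracle comparison above, which is
the appropriate notion of correctness for small samples.

## Autozygosity mapping

`find_shared_runs()` scans each chromosome for maximal runs of
consecutive markers at which *every case* is homozygous for the *same*
allele. Individual missing genotypes are tolerated (missingness is not
evidence against sharing) but a marker where all cases are missing breaks
a run. `delineate_interval()` then returns the critical interval bounded
by the nearest discordant marker on either side — the causal mutation
cannot lie beyond the first marker that violates sharing.

`map_critical_interval()` adds one pragmatic layer: *bridging*. A single
genotyping error in a single case is enough to shatter a true IBD segment
under the strict criterion; at realistic error rates (10⁻³ per genotype)
the probability that a ~40-marker segment × 7 cases survives unbroken is
only about one in three. Runs-of-homozygosity callers tolerate a bounded
number of discordant genotypes per window for exactly this reason. The
compromise implemented here keeps `find_shared_runs()` strict (so the
core definition stays exact and oracle-testable) and lets
`map_critical_interval()` bridge isolated discordant gaps of at most
`max_bridge` markers (default 1) when flanked by at least `bridge_flank`
compatible markers (default 5) on each side. A genuine segment boundary
is followed by a dense stretch of discordant markers and is never
bridged; bridged markers are reported in the run's `bridged` attribute
and never serve as interval bounds. With bridging, the planted interval
is recovered within one marker spacing in ≥ 95% of simulated replicates;
without it, recovery fails in the majority of noisy replicates.

## Prioritization

`run_cascade()` applies the positional-candidate funnel to the proband's
variant calls:

1. **filter_pass** — drop calls failing hard filters: `HardToValidate`
   (MQ0 ≥ 4 and MQ0/DP > 0.1), `LowQual` (QUAL < 30 or QD < 5 or
   HRun > 5 or SB > 0), or `SnpCluster` (≥ 3 SNVs within 10 bp; indels
   neither count toward nor receive cluster flags);
2. **total_homozygous** — the proband must be homozygous-alt;
3. **in_interval** — the call must lie inside the critical interval;
4. **absent_from_panel** — the alt allele must be absent from a panel of
   unaffected genomes (a recent breed-specific mutation cannot segregate
   in unrelated animals). Missing panel genotypes do *not* exclude a
   variant, but are counted and reported, since "absent" and "not
   assayed" are different strengths of evidence;
5. **nonsynonymous** — missense, nonsense or frameshift consequence.

Steps 2–5 are set intersections, so the surviving set is order-invariant;
the funnel order is fixed only for reporting. Counts are verified
non-increasing on every run.

## Consequence annotation

`annotate_coding_variant()` classifies a CDS-coordinate variant against a
validated transcript model and emits HGVS `c.`/`p.` strings. The
conventions that matter:

* Deletions are 3′-normalized within repeated sequence before naming
  (the HGVS rule: the most 3′ of the indistinguishable representations
  is reported).
* A frameshift is reported as `p.<wt><pos><new>fs*<n>`, where `pos` is
  the first codon whose residue changes and `n` the position of the new
  stop counting that codon as 1 — so `fs*3` places the stop two codons
  downstream of the first altered one, and the mutant ORF length is
  `pos + n − 2`. This identity is enforced as a test invariant, and all
  protein predictions are checked against a mutate-the-string-and-
  translate oracle.
* ORF lengths exclude the stop codon on both the wildtype and mutant
  side, so truncation deltas are in residues actually lost.

## Segregation

`recessive_concordance()` encodes full penetrance: every case
homozygous-alt and no control homozygous-alt; heterozygous controls are
expected carriers, not violations. `carrier_frequency()` is the
heterozygote fraction among successfully genotyped individuals of a
group, and `genotype_r2()` is the squared Pearson correlation of 0/1/2
dosages — two variants carried by exactly the same individuals (as for
two mutations on one founder haplotype) give r² = 1, which is the
signature that association alone cannot separate them and functional
knowledge must arbitrate.

# The simulator

`simulate_cohort()` generates the marker dataset: positions uniform on
one chromosome, MAFs drawn as `0.05 + 0.45 · Beta(1.5, 1.5)` (spanning
exactly the post-QC frequency range), genotypes Hardy–Weinberg at each
marker, and — the signal — every case overwritten with one fixed founder
homozygote across the planted segment. Genotype error and missingness
are applied last, *after* the segment is planted, so noise degrades the
signal exactly as it would on a real array.

**Scale.** The default is 5,000 markers on an 80 Mb chromosome with a
3.5 Mb planted segment. This preserves the marker density of a ~170k
genome-wide array (≈ 40 markers in the segment) while keeping the full
pipeline with a 10,000-permutation scan under a few minutes on one CPU.
The genome-wide multiple-testing burden is emulated by the out-of-segment
markers.

`simulate_variants()` plants a causal single-base coding deletion and a
linked passenger nonsense SNV inside the segment — both homozygous,
clean, and panel-absent — among hundreds of background variants whose QC
annotations straddle every filter threshold with a configurable failure
fraction. Variants are laid on a ≥ 20 bp grid so no accidental SNV
cluster can form. `simulate_validation_cohort()` draws the genotyping
cohort with a configurable carrier frequency among breed controls and
identical carrier vectors for the causal/passenger pair (perfect LD).

Everything is a deterministic function of the configuration seed
(cohort: `seed`; variants: `seed + 1`; validation cohort: `seed + 2`;
pipeline permutations: `seed + 3`), and determinism is asserted at the
byte level on the written PED/MAP/VCF artifacts.

**Non-goals.** The simulator makes no claim of population-genetic
realism: no recombination or coalescent model, no breed demography, and
parametric QC-statistic distributions chosen only to straddle the filter
thresholds. It exists to provide planted ground truth for correctness
and operating-characteristic tests, not to forecast power in real
cohorts.

# Numerical conventions

* Exact HWE tie rule: `p_i <= p_obs * (1 + 1e-12)` (see above).
* Permutation p-values use the `(1 + k) / (1 + N)` estimator.
* Reported percentages and Mb sizes round *halves up* at the printed
  precision (`round_half_up()`), matching the convention of published
  tables rather than R's round-halves-to-even default; e.g. a carrier
  fraction of 12/193 prints as "6.2%" and a 3,534,378 bp interval as
  "3.53 Mb".
* Chi-square comparisons against permutation maxima use a 1e-12 slack so
  ties arising from identical tables are counted as exceedances.

# Worked example

```{r, eval = FALSE}
cfg <- sim_config(seed = 1)
result <- run_pipeline(cfg, n_perm = 10000)
print(result)
```

The printed report shows the post-QC marker count, the best raw and
corrected p-values, the genomic inflation factor, the mapped critical
interval, the prioritization funnel, the HGVS consequences of the
surviving candidates, and the validation-cohort segregation summary.

# Limitations

* The interval is only as sharp as the marker map: bounds are flanking
  discordant markers, so resolution is one inter-marker gap.
* Bridging trades a small risk of spanning a true double-recombination
  boundary for robustness to genotyping error; set `max_bridge = 0` for
  the strict criterion.
* Perfectly linked variants (r² = 1) cannot be separated by any of the
  statistical machinery here; candidate arbitration then rests on
  functional annotation.
* The consequence annotator models a single uninterrupted CDS; splice
  sites, UTRs and multi-exon genomic coordinates are out of scope.
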