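---
title: "Pooled-DNA allelotyping on SNP microarrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-DNA allelotyping on SNP microarrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolmap)
```

## The problem

Genotyping every individual in a large case-control cohort is expensive. The
SNP-MaP (SNP Microarrays and Pooling) design sidesteps this by pooling equal
amounts of genomic DNA from dozens of individuals and hybridizing each pool to
a single genotyping array. The allele-A fraction of a pool's signal at a SNP
— the relative allele signal, RAS = A/(A+B) — estimates the pool's allele
frequency, so frequency *differences* between case pools and control pools can
be scanned genome-wide at a fraction of the genotyping cost. The price is that
each pool contributes one noisy frequency estimate instead of dozens of exact
genotypes, and that array-design details (probe redundancy, mismatch probes,
feature size) and DNA quality (venous blood vs buccal swab) directly limit
accuracy.

`poolmap` implements the full workflow — stratified pool construction, probe
intensity simulation, RAS allelotyping, pool-level association scanning and
the validation statistics used to judge whether a pooling study worked — as
testable, seed-reproducible code. Because real pooled-hybridization cohorts of
this kind are not publicly deposited, the package is built around a synthetic
data generator that reproduces the statistical structure the analysis assumes;
the generator is itself a first-class, tested component.

## The simulation model

### Cohort and genotypes

Individuals are unrelated; SNPs are independent and biallelic (no linkage
disequilibrium — a deliberate non-goal). Control allele-A frequencies are
drawn uniformly from a configurable minor-allele band (default 0.05–0.5) and
flipped to $1-f$ with probability 0.5 so that the measured allele is minor or
major with equal chance. Genotypes are Hardy-Weinberg: $g \sim
\mathrm{Bin}(2, f)$. Effect SNPs shift the case-allele frequency at the
allele level by an odds ratio,

$$f_{case} = \frac{\mathrm{OR}\, f}{\mathrm{OR}\, f + 1 - f},$$

a simpler parameterization than genotype penetrances and sufficient for a
method whose target is the frequency difference itself. Sex, a three-level
covariate stratum (a body-mass-index band) and DNA source (blood/buccal) are
assigned independently; by default cases are all blood DNA and controls are
blood with probability 10/28, matching a realistic mixed-recruitment control
arm.

### Pools

Pools are constructed within each (phenotype, sex, stratum, DNA-source) cell:
individuals are randomly partitioned into $\max(1, \mathrm{round}(n/48))$
pools whose sizes differ by at most one. The target of 48 reflects typical
pooling practice (published pools average ~47.7 individuals with a SD near 9,
i.e. a distribution, not a constant — hence the remainder-balancing rule
rather than fixed-size pools). Each member's DNA contribution weight is a
gamma draw with coefficient of variation `pipetting_cv` (default 0.05,
representing a few percent of quantification/pipetting error around the
intended equal 100 ng contributions), renormalized to sum to one; gamma keeps
weights positive at any CV. A pool's *true* allele frequency is the
weight-averaged dosage $\sum_i w_i g_i / 2$ — this is what confirmatory
individual genotyping of the pool's members would measure.

### Probe intensities

Each SNP is interrogated by 6–8 probe quartets by default (the low-redundancy
regime of modern 1M-SNP arrays; older generations used 24–40 and can be
emulated by setting `probes_per_snp`). For pool frequency $f$, probe $j$ with
lognormal affinity $\phi_j$ (unit median, `probe_affinity_sdlog` = 0.3 — the
standard intensity heteroscedasticity assumption) and DNA-quality multipliers
$(m_{sig}, m_{bg}, m_{noise})$:

$$PM_A = m_{sig} S \phi_j \,(f + \kappa(1-f)) + m_{bg} b + \varepsilon,\qquad
  PM_B = m_{sig} S \phi_j \,((1-f) + \kappa f) + m_{bg} b + \varepsilon'$$

with signal scale $S$ (default 2000 intensity units), shared background $b$
(default 200), cross-hybridization fraction $\kappa$ (default 0.05), and
independent zero-mean noise with SD equal to `noise_cv` times the channel
mean (multiplicative error — array noise scales with signal), truncated by
clamping intensities at zero. In mismatch designs the MM channels capture
background only: $MM = m_{bg} b + \varepsilon''$. Technical replicates
redraw only $\varepsilon$ — the same pool hybridized to a second array shares
its realized weights and true frequencies.

Two consequences of this model are the package's central mechanistic checks:

* **The slump toward 0.5.** In PM-only mode,
  $\mathrm{RAS} = (S\phi f + b)/(S\phi + 2b)$ (at $\kappa=0$), an affine
  compression of $f$ toward 0.5 that strengthens with $b$. Mismatch
  subtraction removes exactly $b$ and restores $f$ (or
  $(f+\kappa(1-f))/(1+\kappa)$ when cross-hybridization is present). This is
  why arrays that dropped mismatch probes yield RAS scores that are poor
  *absolute* frequency estimates while remaining usable for *differences*.
* **Quality degradation.** Buccal DNA is modelled as attenuated signal and
  inflated background and noise (defaults $0.4, 2.0, 2.0$), pushing pools
  into the degraded regime where pooled estimates stop tracking real
  frequencies.

### Parameter defaults and their calibration

All intensity-model parameters are stand-in assumptions, not estimates of any
specific commercial platform — no public probe-level pooled data exist to fit
them. Where a published quantity offered an anchor we used it once and froze
the value: the base `noise_cv` = 0.15 was chosen so that technical-replicate
Pearson correlations of default blood runs land near the low-0.9s, the band
reported for duplicate pooled hybridizations; pool size 48, probes-per-SNP
6–8, the MAF < 0.05 exclusion and the genome-wide threshold
$7.2\times10^{-8}$ are the published study conditions. Everything is
overridable through `snpmap_config()`.

## The analysis

**Allelotyping.** Per probe, RAS$_j$ = $PM_A/(PM_A+PM_B)$ (PM-only) or the
same ratio of MM-subtracted, zero-clamped signals (mismatch mode). The SNP
score is the unweighted mean of per-probe ratios; the ratio-of-summed-
intensities alternative is available as `summarization = "ratio_of_sums"`.
Mean-of-ratios was chosen to match the per-quartet-averaging lineage of RAS
scoring; both are tested. Probes with zero total signal are dropped rather
than imputed at 0.5, which would manufacture slump artifactually; a SNP whose
probes are all dropped is reported `NA` and excluded downstream rather than
propagated as NaN.

**Scanning.** Technical replicate arrays are averaged into one value per pool
first — arrays are repeated measures of one hybridized pool, so the pool, not
the array, sets the degrees of freedom (the alternative, treating arrays as
independent observations, would overstate df; whether the original analyses
did this is unstated, so the collapse is a documented decision). Each SNP
then gets an independent two-sample Student's t-test (pooled variance,
df = $n_1+n_2-2$; Welch available as an option) comparing case-pool and
control-pool RAS, vectorized across SNPs. The MAF estimate is the folded mean
RAS, $\min(\hat f, 1-\hat f)$; SNPs below the threshold (default 0.05) are
excluded, and surviving SNPs with $p \le 7.2\times10^{-8}$ are flagged
genome-wide significant. Degenerate zero-variance SNPs with unequal means
return the smallest representable positive p with a warning rather than
infinity.

**Validation.** Three analyses mirror how a pooling study is judged:
technical and biological replicate Pearson correlations; the correlation of
SNP-level mean RAS with the true pooled frequencies, per phenotype ×
DNA-source stratum; and the ratio-of-ratios concordance
$R = (\bar f_{ctrl}/\bar f_{case}) / (\overline{RAS}_{ctrl}/
\overline{RAS}_{case})$, summarized by mean, sample SD (the population/sample
choice is unspecified in the literature; sample SD is used) and the
percentage of SNPs within one SD of the mean, over a follow-up subset that
takes top-ranked scan hits padded with a random draw (default 110 SNPs,
guarded by an $\epsilon = 10^{-6}$ denominator floor). "Mean allele frequency
of controls" is the across-group mean per SNP, mirrored on the RAS side as
the mean over the group's pools — symmetry demands matched construction.

## Reproducibility machinery

A single top-level seed drives every stage through named substreams (a
deterministic hash of seed and stage name), so re-running one stage never
perturbs another and the whole pipeline is byte-identical under rerun; the
manifest records SHA-256 hashes per output file. All I/O is plain text (TSV;
minimal GT-only VCF optional for genotypes).

## What the tests show — and what they cannot

The simulation reproduces the *structure* the method assumes: Hardy-Weinberg
sampling, stratified pooling with pipetting error, probe-level multiplicative
noise, background-induced slump, mismatch-probe rescue, and quality-dependent
degradation. Checks at study scale use desk-sized problems chosen to keep the
full suite in the low tens of seconds: 10,000 null SNPs across ~57 pools of
~48 for type-I error calibration; 200 effect SNPs per odds-ratio level
(1.2/1.5/2.0) for power monotonicity; 20 paired-seed replicates of 2,000 SNPs
for the blood/buccal contrast; a fixed 110-SNP subset over three shrinking
noise scales for ratio-of-ratios consistency. The shrinking-noise check runs
with every SNP carrying an OR = 1.5 shift, because under a null simulation
the slump is affine in $f$ and cancels between equal-frequency groups,
leaving mean($R$) at 1 up to Monte-Carlo noise; a real frequency difference
makes the bias systematic, which is the mechanism the check is about.

Features of real pooled-array data that the model deliberately omits: linkage
disequilibrium; allele-specific probe affinities (here $\phi_j$ multiplies
both channels equally, so SNP-specific bias averages out across pools — real
arrays show per-SNP biases that do not, which is why published RAS-vs-truth
correlations are substantially lower than this generator produces at matched
replicate noise); batch and spatial artifacts; CNV probes; genotype-calling
of individuals. Published headline numbers from private cohorts are therefore
plausibility corridors, not targets, for this package's outputs.

## A worked run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  simulation = list(n_cases = 480, n_controls = 480, n_snps = 2000,
                    n_effect_snps = 20, effect_odds_ratio = 2),
  seed = 1)
res <- run_pipeline(cfg, "snpmap_run")
summary(res$gwas)
print(res$validation)
plot(res$gwas)
```
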