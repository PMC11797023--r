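---
title: "Detecting biased supergene transmission in fire-ant males: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting biased supergene transmission in fire-ant males: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbdrive)
```

## The problem

In polygyne (multiple-queen) colonies of the fire ant *Solenopsis invicta*,
social organisation is controlled by a supergene with two haplotypes, SB and
Sb. Every reproductive polygyne queen in the invasive range is an SB/Sb
heterozygote, and fertile males develop from her unfertilised (haploid) eggs.
Under Mendelian transmission, haploid males should therefore carry SB and Sb
in a 50:50 ratio. A departure from that ratio in the male breeding pool is
direct evidence that the supergene biases its own transmission in males.

Measuring the ratio is harder than it sounds, for three reasons that shape
everything in this package:

1. **Most polygyne males are diploid.** Matched matings at the complementary
   sex-determination (CSD) locus turn fertilised eggs into sterile diploid
   males, which make up 80--95% of all males. Diploids must be removed before
   haplotype frequencies mean anything.
2. **A single-band marker assay cannot do that alone.** The Gp-9 PCR assay
   yields a 517 bp product for the B (SB) allele and 423 bp for b (Sb). Two
   bands prove a heterozygous diploid, but haploid males and diploid
   homozygotes both show one band.
3. **Males are not independent samples.** Nestmates are relatives, and
   colonies contribute wildly uneven numbers of males, so pooled frequencies
   over-weight a few prolific colonies.

The pipeline addresses each in turn: a ploidy classifier that combines the
band pattern with multilocus microsatellite hemizygosity, a misclassification
probability for the residual ambiguity, and colony-weighted resampling
estimators with a relatedness analysis that quantifies the nonindependence.

## Ploidy classification

A male with two Gp-9 bands is a diploid SB/Sb, whatever its microsatellites
say. A single-band male is genotyped at a panel of four polymorphic
microsatellite loci (`Sol42_f`, `Sol49`, `C536`, `cassidy`): any heterozygous
locus proves diploidy (the supergene genotype is then SB/SB or Sb/Sb by the
band), while homozygosity at every locus is taken as hemizygosity, i.e. a
haploid male. Genotypes are recorded as two allele labels even for haploids,
because a chromatogram scorer cannot distinguish one copy from two identical
copies; hemizygosity is an inference, never an input.

The price of that inference is the chance that a true diploid is homozygous
at all panel loci. Under Hardy--Weinberg with independent loci,

$$
P(\text{false haploid}) \;=\; \prod_{l \in \text{panel}} \sum_a p_{l,a}^2 ,
$$

implemented in `false_haploid_probability()`. An optional inbreeding
coefficient $F_{IS}$ inflates each locus term to
$F + (1-F)\sum_a p_{l,a}^2$; the default is $F = 0$ because the study system
reports an aggregate figure without an inbreeding correction. The bundled
default panel (`default_allele_freqs()`) has per-locus expected
homozygosities near 0.30/0.27/0.25/0.24, chosen so the product is about
0.005 — the 0.5% aggregate misclassification probability reported for this
marker set. Adding a locus can only shrink the product (property-tested).
Records with a missing call (the reserved label `.`) at any panel locus are
`unresolved`, excluded from every downstream estimate, and counted in the
classification summary.

## Colony-weighted resampling

The uncorrected (pooled) haplotype frequency is the SB share among confirmed
haploids of a stage, with a 5000-replicate bootstrap-of-the-proportion 95%
CI. The corrected estimator weights colonies equally: each replicate draws
one haploid male uniformly at random from every colony that has one and
takes the SB proportion across the drawn males; 500 independent replicates
are averaged. Its expectation is the unweighted mean of the per-colony
frequencies, so duplicating every male inside one colony leaves it unchanged
while the pooled estimate moves — the contract that distinguishes the two
estimators, and a property the tests exercise directly.

Two 95% interval constructions are reported for the resampled estimate,
because they answer different questions:

* the **percentile interval** of the 500 replicate values reflects the
  between-colony dispersion of single-male draws (with ~25 contributing
  colonies a replicate value has granularity ≈ 0.04, so this interval is
  wide);
* the **interval of the replicate mean** (mean ± 1.96·SD/√500) quantifies
  only the Monte-Carlo error of the resampling average and is narrow.

The mean interval is the default in the output tables; calibration checks
that ask whether an interval covers the true value use the percentile
interval, because only its width tracks sampling variability. Degenerate
inputs are permitted and exact: a one-male colony always contributes that
male; an all-SB input gives a constant replicate stream at 1.

The weight analogue draws one male per colony *per haplotype* (a colony with
no SB haploids is excluded from the SB stream only), averages the drawn
weights, and reports one-tailed 95% limits as the 5th and 95th percentiles
of the replicate values. `resampled_weight_difference()` compares two
replicate streams by the fraction of replicates in which the difference is
non-positive, reporting `P < 1/n_reps` when the streams never cross.

## Relatedness and effective queen number

Pairwise relatedness between haploid males uses an identity-in-state moment
estimator (the haploid reduction of the Queller--Goodnight family) against
reference allele frequencies $p_{l,a}$:

$$
r \;=\; \frac{\sum_l (s_l - h_l)}{\sum_l (1 - h_l)},
\qquad h_l = \sum_a p_{l,a}^2 ,
$$

with $s_l$ the indicator that the two males carry the same allele at locus
$l$. Unrelated pairs have expectation 0, brothers 0.5, identical genotypes
give exactly 1. Published relatedness software offers many estimators and
weightings; this closed form was chosen for transparency and because its
pedigree expectations are exact, which is what the recovery tests need.
Exact numerical agreement with any particular third-party setting is not
claimed, and the reference sample behind the published relatedness values is
not redistributable, so those values enter this package only as inputs to
the effective-queen calculation.

Population relatedness is the unweighted mean of colony means (each colony
one value, consistent with the colony-equalising philosophy; pair-weighting
is available via a flag), with a percentile bootstrap over colonies for the
CI and a bootstrap difference test between stages. With $q$ equally
contributing unrelated queens per colony (mates also unrelated), expected
nestmate relatedness is $0.5/q$, so the effective queen number is
$n_e = 0.5/r$ — `effective_queen_number()`. Applied to published nestmate
relatedness values of 0.198 (adults) and 0.169 (pupae) this gives 2.53 and
2.96 effective queens, the quantities the acceptance script recomputes.

## The synthetic colony generator

`simulate_population()` forward-simulates the breeding system so every
downstream stage can be tested against known truth:

* `n_colonies = 40` colonies; queens per colony `max(1, Poisson(2.75))`,
  giving roughly 2.5--3 effective queens; every queen SB/Sb.
* Haploid males are impaternate sons of a uniformly chosen queen and carry
  Sb with probability `distortion_delta`. The default 0.78 emulates the
  strong Sb bias the pipeline is designed to detect; Mendelian 0.5 is used
  explicitly in calibration tests.
* Haploid production is zero-inflated negative binomial
  (`haploid_zero_prob = 15/40`, mean 10.8 across all colonies, size 0.9), so
  a substantial minority of colonies produce no haploid males and a couple
  of colonies dominate the sample.
* Diploid males arise only from matched queens (per-queen Bernoulli,
  rate 0.2); their total is calibrated so diploids are 85% of males in
  expectation. Their supergene genotype combines a Mendelian maternal allele
  with a paternal haplotype drawn from a father pool that defaults,
  self-consistently, to the haploid-male frequency.
* Microsatellites follow the pedigree: a haploid son inherits one maternal
  allele per locus; a diploid adds his father's allele. Nestmate haploid
  relatedness therefore has expectation 0.5/(queens in the colony).
* Weight = group mean + colony effect + residual. Group means default to
  6.12 mg (haploid Sb), 7.07 mg (haploid SB) and 9.5 mg (diploid). No
  variance decomposition for colony effects is published for this system;
  0.5 mg colony and 0.5 mg residual SDs are calibration choices that
  reproduce clearly significant colony and haplotype terms in the two-way
  ANOVA without swamping the haplotype gap.
* `apply_sampling_design()` mimics the collection protocol: every adult
  below 8.0 mg is kept, bins of 0.25 mg between 8.0 and 10.0 mg are capped
  at 20 males, heavier adults are dropped. Pupae are exempt because pupae
  were collected opportunistically and all genotyped; the produced-pupae
  fraction defaults to 0.06 so the genotyped sample runs about 4:1
  adults:pupae after the design.

What the generator does **not** emulate: genotyping error and allelic
dropout, linkage between the microsatellite panel and the supergene,
inbreeding and population structure in the reference frequencies, queen
turnover and polyandry, and any weight--genotype interaction beyond additive
colony effects. Passing tests on synthetic data therefore validate the
estimators' contracts (unbiasedness, equal colony weighting, classifier
guarantees), not the field accuracy of any particular published number.

## Statistical battery

Exact binomial tests against 0.5, Fisher's exact 2×2 tests (both defined by
point-probability ordering, matching the conventional implementations and
verified against full-enumeration oracles for all tables with margins ≤ 12
and all $n \le 20$), Welch or Student t tests, and a sequential (type-I)
two-way ANOVA of weight with colony entered before haplotype. The published
colony df of 16 implies a filtered colony subset whose rule is unstated, so
`anova_weight()` takes an explicit colony-inclusion predicate (default:
colonies with ≥ 2 adult haploid males carrying both haplotypes) and reports
the realised df. Execution-assay proportions use Wilson score intervals by
default (the published interval construction is unstated; Clopper--Pearson
and bootstrap are available), with the four planned contrasts run as Fisher
tests and empty groups skipped with a warning.

## Numerical and design choices

* "Repeated with replacement" is read as: replicates are independent and a
  male may be redrawn across replicates, while within one replicate each
  colony contributes exactly one male — the only reading consistent with
  one-male-per-colony.
* Only colonies that contain an eligible male can be drawn from; colonies
  without one are excluded and counted, since drawing from an empty colony
  is undefined.
* Bootstrap p-values are clipped to `[2/n_iter, 1]`; zero is never reported.
* Stage sub-seeds are derived deterministically from the master seed and the
  stage name, so adding a stage never perturbs earlier streams; identical
  seeds reproduce byte-identical reports.
* Validation is total: malformed rows, unknown columns, frequency tables
  that do not sum to one, and degenerate parameters all raise typed errors
  rather than coercing silently.

Test problem sizes were chosen to make Monte-Carlo bounds sharp while the
whole suite stays quick: 200 simulated datasets per distortion level for
parameter recovery, 200 paired datasets for the colony-weighting contract,
15,000--20,000 synthetic diploids for the misclassification rate, and 11
pedigree simulations per queen number for the relatedness recovery.

## Limitations

The classifier's error model assumes Hardy--Weinberg and locus independence
in the reference frequencies; the relatedness estimator is a moment
estimator whose per-pair variance is large at four loci (only colony- and
population-level means are reported); and the resampled frequency point
estimate targets the *unweighted mean of colony frequencies*, which differs
from the egg-level transmission parameter whenever production covaries with
genotype frequency. The execution-assay analysis treats trials as
independent Bernoulli outcomes and ignores observation-time censoring.
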