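---
title: "Rare-variant burden analysis of birth weight in mother-child duos: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant burden analysis of birth weight in mother-child duos: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duoburden)
```

## The scientific problem

Birth weight is shaped by two distinct genetic channels: the fetus's own
genotype (direct effects on fetal growth) and the mother's genotype, which
acts on the intrauterine environment (e.g. maternal glycaemia, placental
function). Because a child inherits half of each maternal genome, maternal
and fetal genotypes are correlated at r = 0.5, and any "fetal" association
estimated in a sample of genotyped individuals with known birth weight is
partially a shadow of a maternal effect, and vice versa. Glucokinase
deficiency is the canonical example: a loss-of-function variant raises
birth weight when carried by the mother (higher glucose supply) and lowers
it when carried by the fetus (impaired insulin secretion), so the two
channels partially cancel in marginal analyses.

`duoburden` implements the full analysis chain used in biobank exome
studies of birth weight: genotype-level sequencing QC, rare-variant
collapsing masks, per-gene carrier ("burden") regression in a fetal arm
(participants reporting their own birth weight) and a maternal arm
(mothers reporting their first child's birth weight), a weighted-linear-
model (WLM) decomposition of the two marginal estimates into conditional
fetal and maternal effects, and the secondary inferences used on
identified genes: sex-dimorphism heterogeneity tests, conditional
attenuation against common GWAS sentinel variants, leave-one-out masks,
and exact sign-test replication concordance. A mother-child duo simulator
generates every input the pipeline consumes, so the whole chain is
testable without restricted biobank data.

## The duo simulator

`simulate_duos()` draws each mother's genotype from Hardy-Weinberg
equilibrium at the variant's allele frequency, transmits one maternal
allele to the child at random, and draws the child's other allele from the
population frequency. Fathers are not modelled explicitly: the
untransmitted paternal allele is a population draw, which is sufficient to
induce the r = 0.5 mother-child dosage correlation (for any allele
frequency) and for every analysis in scope, none of which uses paternal
data.

The child's latent phenotype on the standardised (SD) scale is

    latent = sum_genes [ bF * fetal_carrier + bM * maternal_carrier ] +
             covariate effects + Normal(0, noise_sd)

where `fetal_carrier`/`maternal_carrier` indicate carriage of any
alternate allele in the gene, and optional sex-specific fetal effects
replace `bF` per stratum. The latent value maps to kilograms as
`bw_mean_kg + bw_sd_kg * latent` (defaults 3.5 and 0.5 kg, conventional
values for term birth weight; the distribution of birth weight is not
otherwise pinned down by the study design, so these defaults are
conventional rather than source-derived). Simulating on the SD scale and
mapping to kg keeps the kg-domain exclusion rules (< 1 kg, >= 7 kg)
exercisable while effects remain in SD units.

Raw phenotype reports are deliberately messy, because the derivation rules
exist to clean them: children report their own birth weight at repeated
assessment visits with reporting noise; mothers report their first child's
birth weight via self-report and, at a configurable rate, an accurate
hospital record. Discordant repeat reports, extreme values, and
multiple-birth flags are injected independently at configured rates (the
rates are plumbing for the QC and derivation rules, not estimates of any
real cohort's error rates). `simulate_reads()` adds per-call read data:
Poisson depth (mean 30), heterozygote alternate-allele depth
Binomial(DP, 0.5) — or Binomial(DP, 0.2) at variants flagged
allele-biased — plus low-depth, low-GQ and missing-call artifacts.

What the simulator does **not** emulate: linkage disequilibrium and
haplotype structure, relatedness beyond the duo, population
stratification, sibling or grandparental structure, gestational age, and
assortative mating. Passing tests therefore demonstrate correctness of the
estimators under the stated generative model, not robustness to
confounding that mixed models address in real cohorts (see "Design
choices" below).

## Genotype QC

Applied in order by `apply_genotype_qc()`:

1. **Depth / genotype quality.** SNV calls need DP >= 7 and GQ >= 20;
   indel calls DP >= 10 and GQ >= 20; failures are set missing.
   The defining sentence of this rule is grammatically ambiguous between
   a conjunctive and a disjunctive reading; the default here is
   disjunctive (failing either criterion sets the call missing), matching
   common exome-QC practice, with the conjunctive reading available via
   `rule = "and"`.
2. **Allele balance.** Heterozygous SNV calls are tested against the 50%
   alternate-read expectation with an exact binomial test over
   `ad_ref + ad_alt` informative reads (not DP, since the balance is
   between reference and alternate reads); two-sided p defined as the
   doubled smaller tail capped at 1 — at p0 = 0.5 the pmf is symmetric and
   all common two-sided definitions coincide. Calls at p <= 1e-3 are set
   missing; calls with zero informative reads are skipped.
3. **Missingness.** Variants with strictly more than 50% missing calls are
   dropped.
4. **AD-on-DP slope** (replication dialect, `slope_filter = TRUE`). A
   well-behaved variant has E[AD | GT] = 0, DP/2, DP for hom-ref, het,
   hom-alt, i.e. AD on the identity line against the genotype-expected
   fraction of DP. We fit the single no-intercept slope
   `b = sum(AD * wDP) / sum((wDP)^2)` with w = 0/0.5/1 and drop variants
   with b < 0.5. Variants with fewer than 5 informative carrier calls are
   skipped rather than dropped.
5. **AAscore.** When the annotation table carries a variant-level
   true-positive probability score, variants with score <= 0.8 are
   dropped. The score's computation is external (a property of the
   caller); it is consumed as a pass-through column.

## Collapsing masks and carrier vectors

Masks are rule sets over the annotation table (one prioritised consequence
per variant, LOFTEE confidence, CADD score). Three dialects are built in:

* **discovery** — `PTV`: LOFTEE high-confidence stop-gained, splice
  donor/acceptor, frameshift; `Missense+PTV`: PTV plus missense with
  CADD >= 25 (inclusive).
* **regenie** (confirmatory) — as discovery, additionally admitting
  in-frame indels with CADD >= 25 into the damaging set.
* **decode** (replication) — `LOF` adds start-lost and stop-lost to the
  truncating set; `LOF+MIS` adds the moderate-impact classes (missense,
  splice region, in-frame indels) at CADD >= 25. Splice-region variants
  never qualify as truncating in any dialect.

Custom masks (`build_custom_mask()`) take an explicit variant list, as
used for clinically curated pathogenic panels and score-defined subsets;
`leave_one_out()` removes one variant for sensitivity analyses.

Qualifying variants must be rare: minor allele frequency < 0.1% (strict),
computed in-sample over post-QC non-missing calls, per analysis arm, and
folded to the minor allele. At biobank scale the in-sample frequency
resolves this cutoff; at simulation scale (thousands of samples) a single
carrier already exceeds 0.1%, so the pipeline accepts an external
reference frequency column (`maf_external`, which the simulator emits)
via `use_external_maf = TRUE`, or a relaxed `maf_max`.

Collapsing produces the "dummy genotype": carrier status 1 for samples
with at least one alternate allele at at least one qualifying variant,
missing for samples missing at every qualifying variant (those samples are
excluded from that gene's regression; the handling of such samples is a
conservative choice), 0 otherwise. Binary carrier coding is used rather
than allele counts — at MAF < 0.1% the two coincide almost everywhere —
and a gene x mask combination is testable only with >= 10 carriers
(applied to the sex-combined analysis; sex-stratified fits inherit the
gene list, since strata with as few as 3 carriers are still reported).

## Phenotype derivation and the burden regression

Own birth weight is the mean of repeat visit reports unless the person is
excluded: multiple birth, discordant repeats (range > 1 kg; the
confirmatory dialect's >= 1 kg reading is available via
`discordance_strict = FALSE`), or an extreme mean (< 1 kg or >= 7 kg,
upper bound inclusive). Offspring birth weight prefers hospital records
when present, otherwise averages self-reports, with the same rules.
Phenotypes are z-scored after all exclusions, within arm, sexes combined —
a single SD per arm, because per-sex standardisation would distort the
dimorphism comparison downstream.

The burden fit is OLS of the standardised phenotype on carrier status plus
covariates: the fetal arm uses the child's age, age^2, sex, PC1-PC10 and
sequencing batch; the maternal arm the mother's age at first birth (and
its square), PCs and batch, with no sex term. The discovery-scale studies
use linear mixed models (BOLT-LMM / REGENIE) whose whole-genome random
effect absorbs relatedness and stratification; the simulated cohorts
contain neither, and for unrelated samples the carrier fixed effect is the
same estimand, so OLS is the estimator here. P-values come from the t
distribution at the residual degrees of freedom — exact at simulated
sample sizes, indistinguishable from the normal at biobank n. Collinear
covariates are dropped with a message; rank-deficiency of the carrier
itself skips the gene.

Significance: the exome-wide threshold is Bonferroni, 0.05 divided by the
number of gene x mask combinations actually tested, summed across masks
within an arm. The Benjamini-Hochberg step-up procedure is provided as a
generic operation for restricted candidate-gene sets.

## The WLM decomposition

With mother-child genotype correlation r, the marginal regressions have
expectations

    E[bF_hat] = bF + r * bM        E[bM_hat] = bM + r * bF

The conditional estimates invert this two-by-two linear map; at r = 0.5
the inverse is

    bF_adj = (4 bF_hat - 2 bM_hat) / 3
    bM_adj = (4 bM_hat - 2 bF_hat) / 3

with variances by linear propagation, e.g.
`var(bF_adj) = (16/9) seF^2 + (4/9) seM^2 - (16/9) rho seF seM`, where
`rho` is the correlation between the two marginal estimates induced by
sample overlap (women contributing to both arms). The coefficients are
derived here directly from the stated marginal-expectation map — they are
its unique linear inversion — rather than imported from elsewhere. `rho`
defaults to 0 with a configuration override; the point estimates are
unbiased regardless of `rho`, which affects only the adjusted standard
errors, and the simulator can estimate it empirically when needed.
Two-sided p-values use the normal. Genes are classified `fetal_only`,
`maternal_only`, `both`, or `neither` by which adjusted p-values fall
below alpha = 0.05.

The decomposition assumes that all qualifying variants in a gene share one
fetal and one maternal effect. The simulator's default architectures
honour this; simulating heterogeneous per-variant effects demonstrates the
resulting bias (the package makes no attempt to correct it, matching the
scope of the method).

Two numerical facts are enforced by tests: the inversion is exact to
machine precision on noiseless marginals for arbitrary effect pairs, and
the adjusted estimates are strictly noisier than the marginals at rho = 0
(the price of de-confounding).

## Downstream inference

* **Sex dimorphism.** Stratified estimates are compared with
  `z = (bF - bM) / sqrt(seF^2 + seM^2)` and a two-sided normal p — the
  large-df limit of the two-sample t-test; no degrees of freedom are
  defined for the summary-statistic comparison, and at biobank stratum
  sizes the two coincide (the package reproduces the reference dimorphism
  p-value of 2.46e-2 from rounded stratified inputs to two significant
  figures). Dimorphic means p < 0.05.
* **Conditional attenuation.** Following the two-step description in the
  source protocol, the phenotype is residualised on the covariates, then
  the residuals are regressed on carrier status alone and on carrier plus
  sentinel dosage jointly; an absolute relative change of the carrier
  estimate above 10% flags attenuation, with sign flips flagged specially
  and estimates below a numerical floor (|b| < 1e-12) reported undefined.
  The difference between this two-step procedure and a single joint model
  is exercised on simulated data in the test suite.
* **Sign test.** Discovery/replication effect pairs are reduced to
  concordance indicators (zero effects dropped with a message) and tested
  against Binomial(n, 1/2) with the exact doubled-tail two-sided p.
  Sidedness is not stated by the reference analysis; two-sided is chosen
  because it reproduces the printed 10/11 concordance p of 0.01 (the
  one-sided value would be 0.006).

## Numerical and design choices

* All randomness flows from a single integer seed; `simulate_reads()`
  derives its stream from `seed + 1` so genotypes are unchanged by adding
  read-level data. Identical config and seed give byte-identical emitted
  files; the analysis pipeline itself is deterministic.
* Genomic coordinates are 1-based inclusive (VCF convention) throughout;
  strand is irrelevant to every in-scope computation and is not modelled.
  Multi-allelic records are a hard error naming the site: splitting and
  left-normalisation are upstream responsibilities.
* Numeric TSV columns are written with 17 significant digits so emitted
  cohorts round-trip losslessly.
* Effects are reported in observed-phenotype SD units. When comparing
  against effects planted on the simulator's latent scale, multiply by
  `attr(analysis_table(...), "sd_kg") / bw_sd_kg` (the tests do this
  explicitly); at biobank scale with noise_sd = 1 the factor is ~1.

## Problem sizes used by the test suite

The suite verifies, among others: dosage correlation 0.5 +/- 0.02 at
100,000 duos; WLM recovery of three planted effect pairs — (0.3, -0.2),
(-0.311, 0.430), (0.33, 0) — within two Monte-Carlo standard errors over
500 replicates of 2,500 duos each; type-I error of the burden test at
alpha = 0.05 within the exact binomial 95% interval over 2,000 null genes
(with a Kolmogorov-Smirnov uniformity check); and exact agreement of the
allele-balance and sign tests with exhaustive pmf enumeration up to totals
of 30 and 12. These sizes were chosen so each property is sharp enough to
catch implementation errors while the full suite stays fast.

## Known limitations

* OLS in place of a mixed model means real-data relatedness and
  stratification are out of scope; a precomputed relatedness adjustment
  can only enter as an extra covariate column.
* The WLM assumes equal effects across qualifying variants and exactly
  r = 0.5 genotype correlation; rare-variant carrier indicators have
  correlation 0.5 - O(carrier frequency), a negligible bias at MAF < 0.1%
  but visible if the generator is pushed to common variants.
* The in-sample MAF filter is meaningful only at large n; small cohorts
  should use the external-MAF column.
* Annotation (VEP consequences, LOFTEE, CADD, AAscore) is consumed, never
  computed; imputation, phasing and variant calling are out of scope.
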