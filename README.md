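# duoburden

Rare-variant gene-burden association analysis of birth weight with
maternal–fetal effect decomposition, plus a mother–child duo simulator
that makes the whole pipeline testable end to end.

## The problem

Birth weight responds to two genetic channels: the fetus's own genotype
(direct growth effects) and the mother's genotype acting through the
intrauterine environment. Because a child inherits half of each maternal
genome, maternal and fetal genotypes correlate at r = 0.5, so a marginal
"fetal" burden estimate is contaminated by maternal effects and vice
versa — in genes like *GCK* the two channels act in opposite directions
and partially cancel. This package implements, for users analysing
exome-sequenced cohorts (or validating methods against simulated ones):

* **Genotype QC** — depth/GQ call filtering (SNV: DP ≥ 7 & GQ ≥ 20;
  indel: DP ≥ 10 & GQ ≥ 20), an exact binomial allele-balance test on
  heterozygous SNVs (calls with p ≤ 1e-3 set missing), a > 50%
  missingness variant filter, an AD-on-DP regression slope filter
  (drop slope < 0.5), and an AAscore ≤ 0.8 cutoff.
* **Collapsing masks** — PTV and Missense+PTV masks over LOFTEE/CADD
  annotations in discovery, confirmatory (REGENIE-style) and replication
  (LOF incl. start/stop-lost) dialects, custom variant panels, and
  leave-one-out sets; MAF < 0.1% qualifying filter; per-gene binary
  carrier vectors with the ≥ 10 carrier rule.
* **Burden regression** — birth-weight derivation from messy repeat
  reports (multiple-birth, > 1 kg discordance, < 1 / ≥ 7 kg extreme-value
  exclusions; hospital records preferred for offspring weight),
  standardisation to SD units, and covariate-adjusted OLS of phenotype on
  carrier status in fetal and maternal arms, with Bonferroni exome-wide
  thresholds and a Benjamini–Hochberg helper.
* **WLM decomposition** — with marginal expectations
  E[β̂F] = βF + ½βM and E[β̂M] = βM + ½βF, the conditional estimates are

      βF_adj = (4β̂F − 2β̂M)/3,   βM_adj = (4β̂M − 2β̂F)/3

  with variances by error propagation, and classification of each gene as
  fetal-only / maternal-only / both / neither.
* **Downstream tests** — sex-dimorphism heterogeneity z-tests,
  conditional attenuation on GWAS sentinel dosages (> 10% change rule),
  and exact two-sided sign tests of replication concordance.
* **Duo simulator** — Mendelian transmission (inducing the r = 0.5 dosage
  correlation), gene-level fetal/maternal/sex-specific effects in SD
  units, sequencing artifacts (low DP/GQ, allele-imbalanced hets,
  missingness) and raw phenotype reports with all the failure modes the
  derivation rules clean up; emitted as VCF 4.2 (`GT:DP:GQ:AD`) + TSVs
  that round-trip losslessly.

## Worked example

Simulate 3,500 duos with a *GCK*-like gene (fetal βF = −0.311, maternal
βM = +0.430, opposing directions), a purely fetal gene, and a null gene;
emit files; run the pipeline:

```r
library(duoburden)

genes <- list(
  gene_spec("GCKL",  n_variants = 12, af = 1.5e-3,
            beta_fetal = -0.311, beta_maternal = 0.430),
  gene_spec("FETL",  n_variants = 12, af = 1.5e-3, beta_fetal = 1.0),
  gene_spec("NULLG", n_variants = 12, af = 1.5e-3))
cfg <- sim_config(n_duos = 3500, gene_specs = genes, noise_sd = 0.6, seed = 59)
cohort <- simulate_reads(simulate_duos(cfg))
paths <- emit_cohort(cohort, "demo")

pcfg <- pipeline_config(
  vcf = paths$vcf, annotations = paths$annotations,
  covariates = paths$covariates, own_bw = paths$own_bw,
  offspring_bw = paths$offspring_bw, out_dir = "demo/results",
  use_external_maf = TRUE, maf_max = 0.01)
res <- run_pipeline(pcfg)

subset(res$assoc, mask_name == "Missense+PTV",
       select = c(gene_id, arm, beta_sd, se, p, n_carriers))
```

```
   gene_id      arm beta_sd     se        p n_carriers
4     GCKL    fetal -0.1490 0.0922 1.06e-01        118
5     FETL    fetal  1.6265 0.0900 9.86e-70        113
6    NULLG    fetal -0.0742 0.0920 4.20e-01        119
10    GCKL maternal  0.4189 0.0885 2.31e-06        132
11    FETL maternal  0.8112 0.0960 4.24e-17        110
12   NULLG maternal -0.0837 0.0988 3.97e-01        106
```

The marginal estimates show the confounding: GCKL's fetal effect is
washed out (−0.149, p = 0.11) because the opposing maternal effect leaks
in through the genotype correlation, while FETL's purely fetal effect
casts a maternal shadow (+0.81). The WLM undoes both:

```r
res$partition[res$partition$mask_name == "Missense+PTV",
              c("gene_id", "beta_fetal_adj", "p_fetal_adj",
                "beta_maternal_adj", "p_maternal_adj", "classification")]
```

```
  gene_id beta_fetal_adj p_fetal_adj beta_maternal_adj p_maternal_adj
1    FETL         1.6278    5.26e-33          -0.00269       9.85e-01
3    GCKL        -0.4779    4.57e-04           0.65782       7.67e-07
5   NULLG        -0.0431    7.57e-01          -0.06212       6.69e-01
  classification
1     fetal_only
3           both
5        neither
```

GCKL is recovered as genuinely both fetal- and maternal-acting with
opposite signs; FETL's maternal shadow collapses to zero; the null gene
stays null. (Estimates are in observed-phenotype SD units; with
`noise_sd = 0.6` one observed SD ≈ 0.65 latent SD, so −0.478 corresponds
to the planted −0.311 latent units.) Every exclusion along the way is
accounted for in `res$log`, and `res$thresholds` holds the per-arm
Bonferroni cutoffs.

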