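# rarefib

Rare cardiomyopathy-gene variants and CMR-quantified myocardial fibrosis.

`rarefib` is an R package plus a set of analysis drivers for asking whether
rare, putatively pathogenic variants in cardiomyopathy (CM) genes are
enriched in adults with extensive interstitial myocardial fibrosis, where
fibrosis is quantified non-invasively by cardiac MRI T1 mapping. It is aimed
at cardiovascular-genetics analysts who have (i) genotype calls, (ii) a
per-variant annotation table (consequences, population frequencies,
in-silico scores, ClinVar assertions) and (iii) a participant phenotype
table with T1-mapping measurements — and who want a tested, reproducible
implementation of the whole chain from VCF to an exact-test p-value.

## What it computes

**Fibrosis phenotyping.** The extracellular volume fraction is computed from
pre/post-contrast T1 relaxation times of myocardium and blood and the
hematocrit:

    lambda = (1/T1_myo_post − 1/T1_myo_pre) / (1/T1_blood_post − 1/T1_blood_pre)
    ECV    = 100 · (1 − Hct) · lambda        [%]

Participants with a history of myocardial infarction or heart failure are
excluded (their fibrosis could be replacement scar). **Cases** are
participants in the highest quartile of ECV *or* of native T1 (strict
inequality, union rule); everyone else is a control.

**Rare-variant prioritization.** A seven-stage filter cascade: gene-panel
membership (82 CM genes, user-replaceable) → non-monomorphic in the
phenotyped subsample → coding or canonical-splice consequence (worst across
transcripts) → allele frequency < 0.1% in both gnomAD and 1000 Genomes →
non-synonymous → in-silico deleteriousness (PolyPhen+CADD, or SIFT+FATHMM,
lenient to missing scores) → no benign/likely-benign ClinVar assertion.

**ACMG/AMP classification.** Evidence codes computable from the input files
(PVS1, PM2, PP3, BP4, PP5/BP6, BA1, BS1) are assigned automatically, a
manual-evidence table supplies the rest, and the full guideline combining
rules produce the 5-tier call. A VUS is flagged **VUS+** when one additional
supporting phenotype criterion would lift it to Likely Pathogenic.

**Enrichment statistics.** Person-level carrier 2×2 tables (AR genes count
homozygotes only), a two-sided exact test (minimum-likelihood convention,
log-factorial arithmetic), odds ratios, group comparisons (Welch t /
chi-square) and Monte-Carlo power for the two-proportion design.

**Synthetic cohorts.** `generate_cohort()` produces complete inputs (VCF +
annotation TSV + phenotype CSV) with planted carriers, per-stage decoy
variants and a truth table, so the entire pipeline is testable without any
protected data.

## Worked example

The package ships a nine-variant fixture — curated rare variants in *SCN5A*,
*CRYAB*, *MYH7*, *MYBPC3*, *MYL2* and *TNNT2* embedded in a deterministic
cohort of 1,164 participants (420 cases / 715 controls after 29 exclusions):

```r
library(rarefib)
fx <- load_nine_variant_fixture()
report <- run_pipeline(list(
  vcf             = fx$paths$vcf,
  annotations     = fx$paths$annotations,
  phenotypes      = fx$paths$phenotypes,
  manual_evidence = fx$paths$manual_evidence,
  case_thresholds = fx$thresholds
))
print(report)
```

```
run_report: 1164 -> 1135 participants after exclusion; 9 variants selected
  plp: carriers 5/420 cases (1.2%) vs 1/715 controls (0.1%); OR 8.6; p = 0.0285
  plp_vusplus: carriers 7/420 cases (1.7%) vs 2/715 controls (0.3%); OR 6.04; p = 0.0154
```

Reading: all nine variants survive the filter cascade and classify as
6 Pathogenic/Likely-Pathogenic and 3 VUS+. Carriers of a P/LP variant are
roughly nine times more prevalent among high-fibrosis cases than controls
(1.2% vs 0.1%), and the two-sided exact test puts that difference at
p ≈ 0.03; adding VUS+ carriers gives 1.7% vs 0.3%.

The numbered drivers under `analysis/` run the same machinery as a
narrative workflow — `01_simulate_cohort.R` (synthetic cohort),
`02_pipeline_synthetic.R` (planted-truth recovery), `03_fixture_reproduction.R`
(the example above), `04_power.R` (power curve) — writing their tables under
`results/`.

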