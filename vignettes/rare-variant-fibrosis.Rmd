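---
title: "Rare cardiomyopathy-gene variants and CMR-quantified myocardial fibrosis: methods"
author: "rarefib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare cardiomyopathy-gene variants and CMR-quantified myocardial fibrosis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarefib)
```

## The scientific question

Interstitial myocardial fibrosis precedes the overt structural changes of
cardiomyopathy (CM) and can be quantified non-invasively by cardiac MRI T1
mapping. If rare pathogenic variants in CM genes predispose to fibrosis,
their carriers should be over-represented among asymptomatic adults with
high fibrosis burden. `rarefib` implements that comparison as a pipeline:
phenotype-based case definition, rare-variant prioritization, ACMG/AMP
classification, and a case/control carrier-enrichment test — with a
synthetic-cohort generator so the whole chain is testable end to end
without access to protected cohort data.

## Fibrosis phenotyping

Gadolinium contrast shortens T1 in proportion to its local concentration,
and its steady-state distribution volume in myocardium relative to blood is
the partition coefficient

$$\lambda \;=\; \frac{1/T1_{myo,post} - 1/T1_{myo,pre}}
                     {1/T1_{blood,post} - 1/T1_{blood,pre}},$$

from which the extracellular volume fraction is
$ECV = 100\,(1-Hct)\,\lambda$ (percent). Both are implemented as closed
forms (`partition_coefficient()`, `ecv_percent()`) with validity checks:
all T1 values positive, post-contrast T1 strictly below native T1 in both
tissues (anything else is degenerate contrast dynamics and raises an
error rather than returning a sign-flipped value). A supplied `ecv` column
takes precedence; derivation from T1 values is the fallback.

Participants with a history of myocardial infarction or heart failure are
excluded first, because their fibrosis could be focal replacement scar
rather than the diffuse interstitial process of interest.

**Case definition.** A participant is a case when ECV *or* native T1 lies
strictly above the respective top-quartile boundary of the post-exclusion
population. Two choices here were genuinely open:

* *Quantile estimator.* The boundary uses linear interpolation between
  order statistics (R's default type 7), the most common convention in
  scientific software; the `type` argument exposes the alternatives, and
  explicit thresholds can be supplied instead (e.g. to reproduce a
  published split exactly).
* *Before vs after exclusion.* Quartiles are computed on the
  post-exclusion population. Computing them before exclusion would let
  scarred hearts inflate the thresholds; callers who need the other
  convention can pass explicit thresholds.
* *Boundary.* Strict inequality: a value exactly at the boundary is a
  control.

## Rare-variant prioritization

The cascade applies, in order: (1) panel membership — the gene symbol of
the variant's annotation is in the configured panel; (2) non-monomorphism
within the phenotyped subsample, ignoring missing genotypes (a variant seen
only outside the phenotyped participants carries no information for the
comparison); (3) coding or canonical splice donor/acceptor consequence,
where each variant carries the worst consequence across transcripts under a
documented severity order; (4) allele frequency strictly below 0.1% in
*both* gnomAD and 1000 Genomes, with a missing frequency treated as "not
observed" and therefore passing; (5) non-synonymous (start/stop losses and
splice-site terms count as non-synonymous — a start-codon loss is a
protein-altering event); (6) in-silico deleteriousness; (7) no
benign/likely-benign ClinVar assertion, with "absent from ClinVar"
passing — absence of evidence is not benign evidence.

The in-silico screen is two tool branches, each lenient to missing
predictions: PolyPhen damaging-spectrum (including `possibly_damaging`
by default; a strict flag restricts to `probably_damaging`) together with
CADD phred ≥ 20, or SIFT deleterious together with FATHMM damaging. A
variant with no prediction from any tool passes — the filter removes
variants with affirmative evidence of being tolerated, it does not punish
missing annotation. CADD ≥ 20 (top 1% of scores genome-wide) is the
conventional cutoff; it is configurable because no single threshold is
canonical.

Numeric PolyPhen/SIFT scores, if supplied instead of categorical calls,
are binned at the published cutpoints (PolyPhen ≥ 0.446 possibly damaging,
≥ 0.908 probably damaging; SIFT < 0.05 deleterious).

The cascade's funnel (`filter_trace`) records each stage's surviving set,
and the test suite asserts the subset-chain property plus equivalence with
an independent intersection-of-predicates oracle.

## ACMG/AMP classification

`auto_evidence()` assigns only criteria computable from the input files:
PVS1 (LoF consequence in a gene whose panel entry marks loss of function as
an established mechanism), PM2 (below the rarity threshold in both
frequency sources), PP3/BP4 (≥ 2 concordant non-missing in-silico calls),
PP5/BP6 (ClinVar assertions; retained despite later guidance deprecating
them because ClinVar-aware pipelines remain common — a flag disables them;
conflicting assertions contribute neither), BA1 (gnomAD > 5%) and BS1
(gnomAD above a configurable disease-incidence bound, default 0.1%).
Family-dependent criteria (PS2, BS4, PP1, PP4) are never assigned
automatically; a manual-evidence TSV supplies curated codes, mirroring how
interactive interpretation platforms are used in practice.

`combine_evidence()` implements the full guideline rule table over
effective strengths (overrides allowed). Conflict handling: a profile is
conflicting — and returns VUS — when both sides are *substantial*, i.e.
each side either qualifies under its own combining rules or carries
evidence of strong or greater strength. Thus BA1 alongside a strong
pathogenic criterion yields VUS rather than Benign, while BA1 alongside
merely supporting pathogenic evidence is still Benign. The suite checks
the combiner against an independent clause-enumeration oracle exhaustively
for all profiles of up to four codes, plus monotonicity (adding
pathogenic-side evidence never moves a call toward Benign, and vice versa).

**VUS+.** A VUS is flagged VUS+ when adding one phenotype-based supporting
criterion to its evidence would lift the combined call to Likely
Pathogenic or Pathogenic. The strength of that hypothetical criterion is
configurable (supporting by default, the most conservative choice); the
tier itself never changes — VUS+ is a report-level flag, not an upgrade.

## Enrichment statistics

Carriers are counted at the person level: a participant carrying two
qualifying variants counts once, and for strictly autosomal-recessive panel
genes only homozygous-alternate genotypes count. Tables are built for two
tier sets — P/LP, and P/LP plus VUS+.

The two-sided exact test conditions on the table margins: the case-carrier
count follows a hypergeometric distribution, and the p-value sums the
probabilities of all tables whose point probability does not exceed the
observed one (minimum-likelihood convention, with a 1e-7 relative tolerance
on the comparison; probabilities via log-factorials). This is the most
common convention for the two-sided exact test; a doubled one-sided variant
is exposed because published analyses do not always name theirs. The suite
verifies the implementation against direct hypergeometric enumeration for
every table with total count ≤ 60 (tolerance 1e-10), and against
`stats::fisher.test` on random tables.

Group comparisons use the Welch unequal-variance t test for continuous
variables and the chi-square test for categorical ones; when both groups
are constant the t test degenerates and the comparison returns p = 1 for
identical means. `welch_from_summary()` reproduces summary-statistic
comparisons without raw data.

**Power.** `power_simulation()` draws case/control carrier counts as
independent binomials, applies the exact test to each simulated table
(memoized over distinct tables, so 10^5 replicates cost well under a
second) and reports the rejection fraction with its binomial Monte-Carlo
standard error. At the design point — 420 cases vs 715 controls, carrier
prevalence 1.6% vs 0.1% (a 1.5 percentage-point difference), α = 0.05 —
the power computed by `scripts/acceptance.R` from 100,000 replicates is
just above 80%; the replicate count was chosen so the Monte-Carlo SE
(≈ 0.13 points) is small against that margin. The null-calibration test
(equal prevalences) confirms the exact test's conservatism: rejection
fraction at or below α.

## The synthetic-cohort generator

`generate_cohort()` emulates the study conditions, not any real cohort's
joint distribution:

* 1,164 participants, 29 flagged for MI/HF exclusion; race mix
  38/28/23/11 percent White / African American / Hispanic / Chinese
  American; sex ratio near parity; ages 45–84.
* Fibrosis phenotypes from a latent two-component bivariate normal:
  a high-fibrosis component (ECV 29.4 (2.5) %, native T1 1,014 (37.1) ms;
  37% of the non-excluded) and a remainder component (25.6 (1.8) % and
  957.2 (30.7) ms), with within-component ECV–T1 correlation 0.5 — a
  moderate value reflecting that the two markers index the same biology
  through different measurements. Case status is then *derived* by the
  top-quartile union rule on the generated data, so the realized case
  fraction (~33–40%) and thresholds come out of the rule rather than being set directly.
* Carrier genotypes planted at prevalences 1.2%/0.1% (P/LP,
  case/control) and 1.7%/0.3% (adding VUS+), one heterozygous carrier per
  variant in autosomal-dominant panel genes: stop-gained alleles in
  LoF-mechanism genes for P/LP, missense alleles with manual PM1 evidence
  for VUS+ (one supporting criterion short of Likely Pathogenic). Variant
  positions are drawn inside per-gene windows shipped with the panel; no
  reference genome is involved.
* One decoy variant per filter stage, constructed to fail exactly that
  stage, plus one filter-passing variant that classifies VUS and must be
  counted in neither tier set.
* A truth table (JSON) recording every planted fact; the suite asserts
  exact recovery of the carrier tables and decoy removal stages across ten
  generator seeds, and byte-identical outputs under a fixed seed.
  Phenotype values are written at three (ECV) and two (T1) decimals so
  that derived rank order is stable in the output files.

What it does **not** emulate: linkage disequilibrium, a realistic
site-frequency spectrum, sequencing error, genotype missingness patterns,
covariate structure (age/sex effects on fibrosis), or the measurement
error of T1 mapping. Passing tests on synthetic cohorts therefore
demonstrate correctness of the computational chain under the stated
model — they say nothing about robustness to the messiness of real
sequencing or imaging data.

## The packaged nine-variant fixture

`load_nine_variant_fixture()` returns a deterministic case study: nine curated
rare variants (seven in cases, two in controls) at their published
coordinates and gnomAD frequencies, embedded in a fixed cohort of 1,164
participants whose phenotype blocks (139 ECV-only / 139 T1-only / 142 both
/ 715 controls / 29 excluded, against explicit thresholds ECV > 28.8%,
native T1 > 1,006 ms) place each carrier in a participant matching the
variant's reported criteria. The per-variant in-silico scores and manual
evidence codes are synthetic: the original curation is not public, so they
were reverse-engineered to make the evidence combiner reproduce each
variant's published tier (1 Pathogenic, 5 Likely pathogenic, 3 VUS+). The
fixture is the package's reference for the headline arithmetic: carrier
prevalences 1.2% vs 0.1% (P/LP; two-sided exact p ≈ 0.028, rounding to
0.03) and 1.7% vs 0.3% (adding VUS+).

For the extended tier set the minimum-likelihood exact test gives
p ≈ 0.015 while a chi-square approximation gives ≈ 0.011; published
analyses that report ≈ 0.01 for such a table may have used either
convention, which is exactly why both are exposed.

## Numerical and design choices

* Exact-test tie tolerance 1e-7 (relative) when comparing point
  probabilities; log-factorial arithmetic throughout.
* Frequencies must parse into [0, 1]; out-of-range values are an error,
  not a clamp.
* Genotype codes are alt-allele counts; partial calls (`./1`) are treated
  as missing; multi-allelic sites decompose into biallelic records with
  per-allele counts, conserving allele totals.
* The 82-gene panel is a documented placeholder of well-established CM
  genes (including the six the fixture uses) with per-gene inheritance
  and LoF-mechanism flags; it is a configuration file, not a clinical
  recommendation, and is expected to be replaced for real analyses.
* Problem sizes in the test suite: exhaustive oracles run to 4 evidence
  codes and table totals of 60; cascade equivalence uses 1,000 random
  variants; planted-truth recovery runs ten full cohorts of 1,164; the
  distributional check uses one cohort of 10,000.

## Known limitations

* ACMG automation covers only file-computable criteria; everything else
  enters through the manual-evidence table, so classifications are only
  as complete as that curation.
* No covariate adjustment in the enrichment comparison (by design — the
  implemented analysis is a crude prevalence contrast), and no
  multiple-testing correction.
* The exact test's two-sided definition is a convention; tables near the
  boundary can round differently under the doubled-one-sided variant.
* VCF support is deliberately minimal (GT-only, biallelic after
  decomposition, no phasing, no structural variants).
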