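---
title: "Methods: joint genetic evaluation of familial early-onset Alzheimer cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint genetic evaluation of familial early-onset Alzheimer cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famalz)
```

## Scope and rationale

`famalz` models the situation of a clinical genetics unit holding exome and
array data for a set of small families densely affected by early-onset
Alzheimer's disease (EOAD): two to four patients per family, occasionally a
cognitively healthy elderly relative, and no prior knowledge of which
samples are related. The package answers, for each family, four questions
in sequence: who is related to whom; which rare variants segregate with
disease; do any of them constitute a reportable monogenic cause; and, when
none does, how much risk is explained by APOE and by a polygenic score.
The closing step condenses the answers into one of three clinical
actionability categories.

Because real patient-level data of this kind cannot be redistributed, the
package pairs every analysis stage with a synthetic-cohort generator whose
outputs carry a machine-readable truth record, and a packaged 36-family
summary table that stands in for a realistic cohort's per-family results.
All statistical claims made by the test suite are computed from these two
sources at run time; nothing is asserted that the code does not itself
recompute.

## Relatedness

Kinship between two samples is estimated from common biallelic variants
with the robust moment estimator
$$\hat\phi = \frac{N_{het,het} - 2\,N_{opp.hom}}
{N^{(i)}_{het} + N^{(j)}_{het}},$$
computed over sites non-missing in both samples (pairwise-complete
deletion, which matches the count definitions exactly). The estimator is
exact for duplicates ($\hat\phi = 0.5$ with zero opposite homozygotes) and
unbiased for unrelated pairs, and needs only unlinked sites, which is why
the generator simulates common SNPs without linkage disequilibrium.

Parameters:

* `maf_filter` (allele fraction, default 0.05): sites at or below this
  minor allele frequency are excluded. Rare sites contribute almost no
  double heterozygotes and only destabilise the ratio. The frequency is
  computed once from the whole input sample set; an external frequency
  vector can be supplied instead.
* Degree cutpoints (dimensionless, fixed): duplicate/MZ above
  $2^{-3/2} \approx 0.354$, then 1st, 2nd, 3rd degree on the half-open
  intervals down to $2^{-9/2} \approx 0.0442$. These are the standard
  inference bands halfway (on a log scale) between the theoretical values
  0.5, 0.25, 0.125, 0.0625. A coefficient exactly on a boundary falls in
  the closer-relationship band above it; `NaN` (zero denominator) is
  classified `unknown`.
* `max_degree` (default `"2nd"`): families are connected components of the
  graph with edges at or closer than this degree, keeping components with
  at least two patients. Second degree is the default because affected
  members of small clinical pedigrees are rarely more distant; the
  argument remains open to `"3rd"` for exhaustive clustering. Mild
  cognitive impairment counts as affected throughout the package, since
  MCI relatives in such families are typically prodromal.

Estimates with fewer than 100 usable sites carry a `low_sites` flag rather
than an error: tiny overlaps occur legitimately with capture-kit mixtures.

## Segregation filtering

Four conjunctive stages with these defaults: quality-by-depth `min_qd = 5`
(inclusive); consequence in {missense, nonsense, frameshift} or within
`splice_window = 2` bp of an exon–intron junction; gnomAD allele frequency
strictly below `max_maf = 0.001`; heterozygous in all affected and
homozygous reference in all unaffected members. Because the stages are
conjunctive, the surviving set is invariant to stage order; only the audit
attribution changes, which the tests exploit.

Missing annotations follow a deliberate asymmetry: a missing QD or allele
frequency passes (absence of evidence — novel variants are absent from
gnomAD by definition), while a missing consequence class fails (coding
status cannot be confirmed). A missing genotype in an affected member
fails segregation; in an unaffected member it is not held against the
variant. The total-population gnomAD frequency is filtered by default,
with the non-Finnish-European column available behind `use_nfe`.

## Classification and prioritization

The triage encodes clinical practice in two explicit rules evaluated in
order: *pathogenic* when database-flagged, or when truncating in a gene
whose protein-truncating variants are established as highly penetrant
(`ptv_genes`, default `SORL1` and `GRN` — this is what lets a novel
frameshift absent from every database be called pathogenic); *likely
benign* when at least two of three in-silico tools call "tolerated"
and/or CADD < 10 (an intentionally permissive "and/or": either criterion
suffices); everything else is a VUS. Variants with no predictor calls and
no CADD score are VUS with rationale "insufficient evidence".

Novel genes outside the panel are prioritized, after dropping families
with a confirmed monogenic cause, by three rules in precedence order:
identical variant in ≥ 2 families; same gene in ≥ 3 distinct families
(each contributing at least one qualifying variant — the rule does not
require the alleles to be distinct); same gene in exactly two families
with per-family maximum CADD > 15 and a curated literature link (a
boolean input, not text mining). Variant identity across families is
exact chrom+pos+ref+alt after biallelic decomposition. Blacklisted calls
(known false-positive regions) are removed from a candidate's support
after selection; candidates that no longer qualify are returned flagged
but excluded from the selected set.

## Ordinal burden test

Replication uses the cumulative-logit (proportional-odds) model
$$P(Y \le k \mid x) = \mathrm{logit}^{-1}(\alpha_k - x'\beta),$$
with the outcome ordered control < LOAD < EOAD, so genetic burden
enriched towards earlier onset yields $\beta > 0$. The model assumes a
common effect across the two cutpoints, which is exactly the "risk
enriched towards EOAD" hypothesis.

Numerical choices: Newton–Raphson with analytic gradient and Hessian,
cutpoints initialised at the empirical cumulative logits and $\beta = 0$,
step-halving whenever a step would decrease the likelihood or disorder
the cutpoints, convergence when the maximum absolute score falls below
1e-8 (cap 100 iterations). With two outcome levels the model collapses to
binary logistic regression, which the tests verify against `glm` to 1e-6;
three-level fits are cross-checked against `MASS::polr`. Zero-variance
covariates are inestimable next to the cutpoints and are reported as
$\beta = 0$, $p = 1$ rather than failing. Complete separation (a
coefficient diverging past 10 on the log-odds scale) is flagged and the
Wald p-value replaced by a likelihood-ratio test against the
covariates-only model; the Wald test is the default elsewhere because it
is standard in large-scale burden scans and costs one fit per gene.

Carrier semantics are dominant (≥ 1 qualifying allele); minima are 10
carriers per gene and 5 per variant; CADD strata are cumulative (stratum
20 means CADD ≥ 20); 10 ancestry principal components are included,
computed once per cohort rather than per stratum; p-values are
Benjamini–Hochberg adjusted across all tests in a call.

## Risk scoring

The PRS is $\sum_k d_k w_k$ over non-APOE loci with imputation
$R^2 \ge$ `min_r2` (default 0.3 for imputed sequence dosages; 0.6 is the
conventional gate for array-genotyped sources). APOE risk is scored
separately on the same scale: +1.20 log-odds per ε4 allele, −0.47 per ε2
allele, minus a population-mean offset. The offset default of 0.36 is the
value implied by anchoring the ε3ε3 genotype at −0.36 against an
ε4-carrying control population; it is a plain argument of `apoe_model()`
and can be recomputed from any control set. Both scores are centred so 0
is the population mean and `exp(score)` an odds ratio; family scores
average the affected members only, a deliberate simplification that
represents the shared familial burden while remaining comparable across
family sizes.

## Family statistics and categorization

Subgroup comparisons use the classic pooled-variance unpaired t-test for
PRS (`var_equal = TRUE`; this is the package default because it is the
convention in the clinical-genetics reports this summary format mirrors —
Welch's correction is one flag away) and the Mann–Whitney U test with
tie-corrected normal approximation and continuity correction for APOE
risk, whose family averages are heavily tied by construction. Rank
correlation between APOE risk and PRS uses average ranks and the
asymptotic p-value; `correlate_apoe_prs()` excludes monogenic families by
default (their cause is already known), with the full-cohort correlation
available via `exclude_pv = FALSE`. With two-decimal family values the
two subsets give noticeably different coefficients, so reports should
state which set was used.

Categorization raises per-family flags — PV, VUS, APOE (≥ 1 affected ε4ε4
homozygote), PRS (family score ≥ `prs_flag_threshold`, default 0.45, a
midpoint separating elevated family scores around 0.47–0.61 from
unremarkable ones around 0.42 and below) — and maps them to: *monogenic*
iff PV; *risk factors* iff any other flag; *unresolved* otherwise. Report
rounding is half-away-from-zero at two decimals (`round_half_up()`),
matching clinical table formatting rather than R's banker's rounding.

## The synthetic generator: what it does and does not emulate

`sim_config()` defaults describe the cohort the package is designed
around: 36 families (77 patients) with sizes 2–4, four families
contributing one unaffected elderly relative, eight planted pathogenic
panel variants (APP, GRN, five PSEN1, one truncating SORL1), eight panel
VUS, an APOE plan whose family averages span −0.36 to 2.04 (seven
families fully ε4ε4-segregating, eighteen with at least one homozygote, a
single ε2 carrier), 76 background rare variants per family each violating
exactly one filter stage, 35 unlinked PRS loci, a population control panel
of 980, and a replication cohort of 833 EOAD / 521 LOAD / 6949 controls
with 10 standard-normal PCs.

Pedigrees are three generations deep (grandparental couple, two parental
sibs with founder spouses, an affected sibship, a first cousin) so that
1st-, 2nd- and 3rd-degree truth pairs all exist while every affected pair
stays within 2nd degree. Founders are Hardy–Weinberg at site frequencies
drawn from `common_maf_range`; transmission is Mendelian with unlinked
sites. Annotations (CADD, predictor calls, gnomAD frequencies) are
generated fields, as they would be consumed from an annotation pipeline,
not derived from sequence. The generator does **not** emulate linkage
disequilibrium, X-chromosome inheritance, capture-kit or imputation
artefacts, genotyping error, or population stratification within the
family cohort; passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative model, not robustness
to those real-data complications. Genotype missingness defaults to 0 and
is configurable.

Determinism: every stage derives its RNG stream from `config$seed` plus a
fixed per-stage offset, so identical configurations produce byte-identical
cohorts and pipeline reports.

## Validation problem sizes

The package's own validation battery uses: 20 simulated cohorts at 50,000
unlinked SNPs for kinship class means (tolerance 0.02 around 0.25 / 0.125
/ 0.0625, with exact duplicate detection and exact family recovery); a
single-family audit with 76 tagged background variants; a null burden
calibration with 1,000 genes at n = 2,000 (10 PCs, ~2% carriers) checked
at nominal levels 0.05 and 0.01; and effect recovery of β = 1 at
n = 5,000 averaged over 50 replicates. These sizes were chosen so each
property is measured with comfortable Monte-Carlo margin while the whole
battery remains a routine desk run.

## Known limitations

* The ACMG-style triage is two rules, not the full 28-criterion
  framework; it is intended to reproduce panel-report behaviour, not to
  replace curation.
* The family PRS is an average over affected members, which understates
  within-family dosage variance; it is a comparability device, not a
  penetrance model.
* Ordinal burden results on simulated replication cohorts are
  calibration/power characterisations; real replication requires real
  case–control data.
* `APP` copy-number events, repeat expansions (e.g. *C9orf72*) and
  structural variation are outside the variant model entirely.
* With family-level scores rounded to two decimals, rank-based statistics
  (Mann–Whitney, Spearman) operate on heavily tied data; their asymptotic
  p-values are approximations.
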