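---
title: "Screening for protective rare variants in APOE e4 carriers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for protective rare variants in APOE e4 carriers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

APOE e4 is the strongest common genetic risk factor for late-onset
Alzheimer's disease, yet a minority of e4 homozygotes stay cognitively
healthy into old age. One explanation is that some of these resilient
carriers harbour rare protective variants. A family-based screen for such
variants compares the genomes of cognitively unaffected elderly e4 carriers
against e4 non-carriers and e4-carrier AD cases: a variant that is carried by
a meaningful fraction of resilient homozygotes, never by non-carriers in the
same families, and rarely or never by affected carriers is a protective
candidate. `e4screen` implements that screen end to end — genotype QC,
stratification, the segregation cascade, stratum frequency tables — together
with the replication statistics used to test a candidate in external
case-control collections, and the group-comparison statistics used for
per-vessel immunofluorescence morphometry. A synthetic family-cohort
generator drives the whole workflow, so everything runs and is tested
without access to restricted human data.

## The discovery screen

Genotype-level QC keeps calls with GQ >= 20 and DP >= 10 (both inclusive);
failing calls become missing rather than being deleted, and all denominators
downstream count genotyped individuals only. Variant-level filters keep rare
(reference-population AF strictly < 1%) variants in potentially damaging
coding classes (missense, LOF by default). A variant with no
reference-panel frequency is kept with a warning: absence from the panel is
itself evidence of rarity, and the rarity filter must not discard it.

Samples are stratified by e4 dosage (an e2/e4 genotype counts as dosage 1 —
the screen conditions on e4 carriage only), diagnosis, and age. "Elderly"
means >= 70 years for homozygotes and >= 80 for heterozygotes; both
thresholds are inclusive and applied after flooring ages to whole years, so
"over the age of 70" includes a 70.4-year-old. Control ages are ages at last
examination; case ages are onset ages, and AD strata carry no age floor.

The cascade then applies, in order:

1. **non-carrier absence** — zero alt alleles among all genotyped e4
   non-carriers, any diagnosis or age;
2. **resilient-carrier support** — at least 1% of genotyped elderly healthy
   e4/4 individuals carry the variant. This is a carrier-individual
   fraction, not an allele frequency: rare-variant carriers are nearly
   always heterozygous, and counting individuals matches how the discovery
   stratum is reported;
3. **heterozygote support** — at least one carrier among elderly healthy
   heterozygotes (a count, not a frequency: the supporting evidence is
   qualitative);
4. **case absence** — flags for absence in e4/4 AD cases and in all
   e4-carrier AD cases, used by default for *ranking* (tier 1 = absent in
   all e4 AD, tier 2 = absent in e4/4 AD only, tier 3 = otherwise).

Case absence is a prioritization signal rather than a hard gate because a
protective allele with OR ~ 0.3 is far from deterministic: at any realistic
e4/4 penetrance, roughly a third of protected carriers still develop AD, so
demanding absolute absence in cases throws away true positives whenever more
than a handful of carriers exist. Hard modes (`hard_hom_AD_only`,
`hard_all_e4_AD`) remain available for sensitivity analyses. Ties in the
ranking are broken by genomic coordinate so output order is reproducible.
With multiple cohorts the cascade runs per cohort by default and reports the
intersection separately, mirroring how separate discovery cohorts are
usually screened and then intersected.

Stratum MAFs are `alt_alleles / (2 * n_genotyped)` over non-missing
genotypes, reported as percents with two decimals; an empty stratum yields a
missing value, never 0. Because denominators count genotyped individuals,
published cells whose denominators are smaller than the demographic totals
(e.g. an all-healthy-homozygote cell of 5.17% alongside 30 listed
homozygotes) are reproducible by marking the difference as missing
genotypes; the package's toy-reconstruction helpers do exactly that.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` generate two-generation families
(founder couple plus 2–5 offspring), with APOE alleles drawn from e4-enriched
frequencies (e2/e3/e4 = 0.05/0.65/0.30, as in multiplex AD family
collections) and Mendelian transmission of one uniformly chosen allele per
parent per locus, independently across loci.

Disease liability follows

P(AD) = logit^-1( logit(b_d) + k·ln(OR)·1[d >= 1] ),

where `d` is e4 dosage with baseline risks `b = (0.15, 0.45, 0.60)` at
reference age, `k` is the protective-allele dosage, and OR = 0.29 per allele
by default. Cases draw an age at onset from N(mu_d + 3.37·k, 6^2) with
mu = (78, 74, 70) years; controls draw a censoring age uniform on
[65, 95] years. The baseline risks and onset means are not estimated from
any specific dataset; they are chosen to reproduce the qualitative structure
of multiplex AD families (majority-affected e4/4 stratum, earlier onset with
higher dosage, a usable pool of elderly unaffected carriers).

The planted protective variant has a population-scale founder allele
frequency of 0.8% but is seeded only in e4/4 founders (at the conditional
frequency 0.008 / P(e4/4)). Because an e4/4 parent always transmits an e4
allele, every descendant carrier is an e4 carrier, which emulates the
co-segregation of candidate variants with e4 inside ascertained families —
the very signal the screen exploits — while keeping transmission itself
unlinked. Without this seeding the non-carrier-absence gate would remove the
planted variant almost surely (200 background sites seeded across all
founders show exactly that behaviour and give the cascade true negatives to
reject). Setting `plant_in_e4_hom = FALSE` restores unrestricted
Hardy-Weinberg seeding, which is how the exclusion property (a variant seen
in a non-carrier is never a candidate) is exercised.

Sequencing artifacts: depth is Poisson(30) per call, GQ is truncated normal
(mean 65, sd 15), and a configurable fraction (5% by default) of calls is
degraded below the GQ 20 / DP 10 thresholds — degraded, not deleted, so the
QC filter itself is what removes them. One root seed drives everything;
per-family substreams are derived from it up front, so outputs are
byte-identical across runs and independent of family processing order.

Under these defaults a cohort carries ~28 planted-variant carriers among
~1,900 individuals (cohort-level AF ~ 0.7%), several of them in the elderly
healthy e4/4 stratum, and the cascade recovers the planted variant in ~98%
of replicates. The expected carrier fraction in the discovery stratum
(~10–15%) is deliberately higher than the single observed carrier (1/27)
behind the published discovery: with only one expected carrier, no screen
can be consistently sensitive, and the generator's job is to verify the
machinery at a signal strength where recovery is statistically guaranteed.

What the generator does **not** emulate: recombination and linkage beyond
the e4-restricted seeding, genotyping/imputation error in dosages (only
quality-field degradation), pedigree loops or multi-generation families,
population stratification, and ascertainment beyond an optional
"at least m affected members" filter (the exact ascertainment scheme of
family studies is rarely published; the filter defaults to off). Passing
tests therefore demonstrate correctness of the analysis machinery under a
clean generative model, not robustness to these real-data complications.

## Replication statistics

Carrier-based effect-allele frequencies assume single-copy carriers
(`EAF% = 100·carriers/(2·total)`), the standard rare-variant reading of
published carrier tables, and reproduce all printed EAFs exactly. The 2x2
odds ratio is the cross-product with a Wald CI; the Haldane-Anscombe 0.5
correction is applied only when a zero cell exists. The 97.5% normal
quantile is fixed at 1.959964 so CI round-trips through `se_from_ci()`
(`se = Δln(CI)/3.919928`) are bit-stable.

The fixed-effects inverse-variance-weighted meta-analysis pools log odds
ratios with weights `1/se²`; heterogeneity is Cochran's
`Q = Σ w_i (θ_i − θ̄)²` on k−1 df. When only ORs and CIs are printed, SEs
are recovered from the CI widths; pooling the three printed per-cohort
estimates (0.12 [0.03, 0.58], 0.42 [0.02, 10.2], 0.54 [0.14, 2.08]) yields
OR = 0.284 [0.110, 0.735] with non-significant Q — matching the published
combined estimate of 0.29 [0.11, 0.78] to within the rounding of the printed
inputs. The printed per-cohort ORs are covariate-adjusted with covariates
that are not fully specified, so they are treated as *data* for pooling, not
as quantities to recompute; the package's own `odds_ratio_2x2()` and
`logistic_assoc()` compute the unadjusted analogues (e.g. crude ADGC
OR = 0.205), and `logistic_assoc()` accepts arbitrary caller-supplied
covariates. Complete separation is detected and flagged, with the CI
reported as unbounded. Age-at-onset regression is OLS of onset age on
dosage (cases only), the simplest model consistent with a reported
"years of delay per allele".

## Morphometry statistics

Vessels wider than 50 µm are excluded up front (the acquisition rule for the
per-vessel tables). Welch's ANOVA is the heteroscedastic F
(`stats::oneway.test`); the Brown-Forsythe modified F is
`F* = Σ n_i(x̄_i−x̄)² / Σ (1−n_i/N)s_i²` with Satterthwaite df — for balanced
designs F* coincides with the classical F statistic, which the tests exploit
as an exact oracle. The two-stage Benjamini-Krieger-Yekutieli procedure runs
BH at `q/(1+q)`, estimates `m0 = m − r1`, and reruns BH at `q/(1+q)·m/m0`;
adjusted values are `(m0/m)·p_BH`, compared against `q/(1+q)`, which makes
the reported q-values and the rejection rule mutually consistent. Dunn's
pairwise z statistics use tie-corrected mean ranks with Bonferroni
adjustment over the tested pairs (no stronger adjustment is implied by the
name "Dunn's multiple comparison"). The "second-order polynomial robust
regression with no weighting" used for intensity-versus-diameter curves is
implemented as unweighted OLS with a quadratic term: order 2 and absence of
weights are the only stated attributes, and no outlier-downweighting scheme
can be reconstructed from them.

## Numerical and testing choices

* All age thresholds are inclusive and applied to floored ages; a
  `--strict-age`-style analysis is available by passing custom stratum
  definitions.
* Half-calls (`0/.`) and calls failing QC are missing; missing dosages never
  contribute to numerators or denominators.
* Multi-allelic VCF records are split at read time with per-alt dosages;
  left-alignment is not attempted because inputs are generated or
  pre-normalized.
* Null calibration of the group tests uses 1,000 replicates of three
  Gaussian groups of 15 (ANOVAs, Kruskal-Wallis) and two samples of 60 for
  the KS test: the exact two-sample KS statistic is discrete, and at very
  small n its achievable size sits well below the nominal level (about 2% at
  n = 15), which is a property of the test, not of the implementation; at
  n = 60 its size is close to nominal and the 3-binomial-SD calibration band
  is meaningful.
* Problem sizes in the test-suite and acceptance runs: 50 simulated cohorts
  of 350 families for cascade recovery; 20 smaller cohorts (120 families)
  with unrestricted seeding for the exclusion property; 50,000 simulated
  e4/4 individuals for logistic recovery; ~10,000 simulated cases for
  onset-delay recovery; 200 replicates for CI coverage. These sizes put the
  Monte Carlo error well inside the assertion tolerances (recovery within
  2 SE; coverage within 3 binomial SDs).

## Known limitations

Counts are not corrected for family relatedness (carriers cluster in
families, so stratum carrier fractions have higher variance than independent
sampling suggests); no kinship-aware or mixed-model association is provided;
the genome-wide candidate counts, covariate-adjusted per-cohort ORs,
immunohistochemistry percent changes and per-genotype adjusted R² of the
original study depend on individual-level external data and are therefore
covered by parameter-recovery and oracle-equivalence tests on synthetic data
rather than by numeric reproduction.
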