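---
title: "Methods: mutation-CNV epistasis, allelic imbalance, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation-CNV epistasis, allelic imbalance, and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comutcnv)
```

This vignette is the package's own account of its statistics: the models and
their assumptions, the parameters that matter, the numerical conventions, and
what the synthetic cohorts do and do not establish about real tumor data.

## The co-occurrence selection test

The unit of analysis is a gene within one cancer type and one cohort/center.
From the mutation table and the gene-level GISTIC matrix we build two binary
sample×gene incidence matrices: `MUT` (any qualifying mutation) and `CNV`
(deep events only, GISTIC +2 for amplifications or -2 for deletions, one
matrix per direction). Although mutation tables can carry several mutations
per sample and gene, both matrices are *binarized*: the test statistic — the
proportion of mutated samples that also carry the CNV — is defined at sample
level, so presence/absence is the operative unit. Duplicate sample-gene rows
collapse to a single incidence but remain distinct records for the
per-mutation analyses.

The null model must respect two background processes: tumors differ wildly
in overall mutation and CNV burden, and genes differ in how often they are
hit. We therefore randomize each matrix by **checkerboard trades**: pick two
1-cells in distinct rows and columns whose opposite corners are 0 and swap
the 2×2 checkerboard. Every trade preserves all row sums (per-tumor burden)
and all column sums (per-gene frequency), and the trade chain is irreducible
over the set of binary matrices with those margins, so long runs sample the
fixed-margin null. `MUT` and `CNV` run on independent chains and are both
randomized every iteration. A simpler within-sample gene-label shuffle
(preserving row sums only) is available as `null = "shuffle"` for
sensitivity analysis; it is not the default because it lets permuted events
drift toward uniformly-hit genes, understating the null co-occurrence of
recurrently altered genes.

Chain settings: burn-in of 20× the matrix's 1-cell count in attempted
trades, and one sample every 1× the 1-cell count thereafter. These are
standard mixing heuristics for trade chains; because column sums are
invariant, each sampled matrix yields the permuted per-gene co-occurrence
counts directly.

Numerical conventions, all chosen to be conservative with a discrete
statistic:

* "exceeds" is implemented as **≥** — permuted proportions tying the
  observed one count against significance;
* the p-value uses an **add-one pseudocount**, `p = (1 + hits)/(N + 1)`, so
  no p-value is exactly 0 and Benjamini-Hochberg correction remains valid;
  the raw ratio (which can be 0, the reason the combination step must
  tolerate zeros) is available with `pseudocount = FALSE`;
* genes with zero *observed* co-occurrence are removed before permuting —
  there is no data for them and they would only dilute the FDR.

The default `n_perm = 100000` gives a p-value resolution of 1e-5; analyses
in this package's own tests use 2,000–10,000 permutations, which is the
resolution actually needed at the cohort sizes involved.

### Combining centers and FDR scope

Multi-center designs (one matrix pair per center) test the same gene-cancer
pair several times. Per-center p-values are combined with **Edgington's
method**: the combined p is the Irwin-Hall CDF (sum of k iid uniforms)
evaluated at the sum of the component p-values. Unlike Fisher's method it is
finite when a component is exactly 0, which raw permutation ratios produce.
The CDF is evaluated by the exact alternating series for k ≤ 20 (reflected
into the lower tail to limit cancellation; double precision keeps the
relative error below ~1e-10 there) and by a normal approximation with an
Edgeworth kurtosis correction for k > 20, where the alternating series
loses digits faster than the approximation error (~1e-4 at k = 21) matters.
At k = 1 the combined p is the input exactly.

BH correction is applied across all combined gene-cancer pairs of a
direction; per-center q-values are also emitted for per-center tables. The
significance convention is FDR < 0.01 for the co-occurrence screen and
FDR < 0.05 elsewhere.

### Two-hit summary

For deletion-direction hits, `summarize_two_hit()` contrasts two routes to
biallelic inactivation per cancer cohort: the fraction of samples with
mutation + deep deletion of the gene versus the fraction with homozygous
deletion (GISTIC -2), labeling each pair by the larger fraction (ties are
labeled `tie`).

## VAF dosage regression

Per gene-cancer pair, `VAF ~ gistic + purity + ploidy + gender + subtype +
age_at_diagnosis` by ordinary least squares, GISTIC entered as one
continuous regressor (a per-copy-step dosage reading, matching how the
screen is interpreted), VAF untransformed on [0,1]. Amplification screens
restrict to codes {0,1,2}, deletion screens to {-2,-1,0}, so the slope sign
is interpretable within a direction: under amplification, a positive slope
means the mutant allele gains copies. Rows need read depth ≥ 5; pairs need
at least `min_mut_with = 3` mutations with the direction's CNV and
`min_mut_without = 3` at GISTIC 0 — an "enough mutations" rule has no
canonical value, and 3/3 is the minimum giving the slope a contrast; both
thresholds are exposed. Constant covariates are dropped per pair; pairs
without two distinct GISTIC values are flagged unestimable and excluded
from FDR. Missing purity/ploidy/age/gender rows are excluded, never
imputed.

Least squares on a bounded response is a deliberate simplification: with
VAFs away from the boundaries and modest slopes it is unbiased for the
linear trend, which is all the screen reports. Logit transformation was
considered and rejected as the default because boundary VAFs (common under
LOH) have no finite logit.

## Binoculars: matched-background allelic imbalance

Each mutation co-occurring with a CNV (single-copy events included — the
`any` classification; allelic effects do not require deep events) is tested
against a background VAF estimated from mutations *without* co-occurring
CNVs, i.e. whose own locus is GISTIC 0 in that sample. Backgrounds are
pooled **read-weighted** (Σalt / Σtotal, not a mean of VAFs — the estimator
the binomial model calls for) at four levels and searched most-specific
first:

1. (gene, cancer, sample) — controls purity, gene, and local selection;
2. (sample) — controls purity;
3. (gene, cancer) — controls gene-level background rate;
4. (cancer) — the broadest fallback.

A tested mutation can never contaminate its own background (backgrounds are
GISTIC-0 only and tested mutations are not), so no further self-exclusion
is needed. Strata with pooled rate exactly 0 or 1 are unusable (the exact
test is undefined there) and fall through to the next level. Mutations with
no usable background are reported separately, not silently dropped.

The test itself is the exact two-sided binomial test by the
minimum-likelihood convention: sum of probabilities of all outcomes no more
probable than the observed count, with a 1e-7 *relative* tolerance when
comparing probability masses so floating-point ties are counted as ties
across platforms. BH runs across all tested mutations within a
(level, direction) screen; calls at q < 0.05 are `increased` or `decreased`
by the side of the observed VAF relative to its matched background.

Purity-adjusted VAFs are reported alongside raw ones using the capped
diploid-dilution form `min(1, VAF/purity)`: normal cells contribute only
reference reads, so a clonal heterozygous mutation recovers 0.5 regardless
of purity; values capped at 1 indicate copy-number effects beyond dilution.
This is a display adjustment only — no test uses it.

`summarize_mutation_direction()` reports per-protein-change call
proportions for recurrent mutations (≥ 10 occurrences by default), and
`correlate_vaf()` handles the paired-VAF analyses (DNA vs RNA, RNA VAF vs
expression) with a 10-pair minimum, Pearson correlation and BH.

## Expression interaction

Two steps per mutation-class stratum (missense with a functional-impact
flag, or truncating):

1. screen `expression ~ mut + covariates` per gene-cancer (BH within cancer
   type — cancer types differ grossly in baseline expression and sample
   size, and pooling their screens would let one large cancer set the
   threshold for all);
2. for pairs passing FDR < 0.05, fit
   `expression ~ mut + gistic + mut:gistic + covariates`, then BH across
   step-2 fits. No pair failing the gate carries step-2 results.

Samples carrying only other-class mutations in the gene are excluded from
the stratum entirely rather than pooled into wild type — a truncation
carrier is not a clean reference for a missense contrast. Expression input
is taken as already log2-scale; the package applies no transformation.

## eccDNA containment

All coordinates are BED-convention 0-based half-open; loaders for 1-based
inclusive sources must convert at the boundary, keeping a single internal
convention. A fragment counts for a gene only if it contains the entire
gene on the same chromosome; strand is ignored (circles have no useful
strand here). Counting is same-sample: a sample contributes to the
intersection only if *it* has both the mutation-CNA co-occurrence and a
containing fragment. Inputs must share an assembly — coordinate
harmonization is upstream of this package.

## The synthetic cohort generator

`sim_config()` defaults describe the package's reference study condition —
the one its calibration analyses run under: 200 samples × 50 genes per
(cancer, center); per-sample mutation burden gamma-Poisson with mean 5 and
shape 5 (typical driver-panel burdens with realistic overdispersion);
gamma(2) per-gene mutability weights (a few hot genes, many cold ones);
deep CNA/CND base rates 0.10 per sample-gene with gamma(5) per-sample CNV
burden; ten planted CNA-enriched genes at enrichment 5 (in mutated samples
the deep-CNV probability is multiplied by 5, capped at 1); purity
Beta(6, 3) (mean 0.67, the typical bulk-tumor range); Poisson depths 80×
DNA and 50× RNA with 80% RNA coverage; and a 0.9 mutant-allele preference
at planted loci versus 0.5 elsewhere, encoding the biological expectation
that selected amplifications prefer the mutant allele and selected
deletions the reference allele.

Read counts follow the purity/copy model: a locus with `c_mut` mutant and
`c_ref` reference tumor copies at purity ρ has expected VAF
`ρ·c_mut / (ρ·(c_mut+c_ref) + 2(1-ρ))`; GISTIC codes map to copy states
(+1 → one extra copy of the preferred allele, +2 → two extra, -1/-2 → loss
of the non-preferred allele with one copy retained), depth is Poisson and
alt counts binomial. RNA adds an allele-specific expression multiplier
(default 1.5 at planted CNV loci) on the mutant allele before
renormalizing. Expression is linear-Gaussian with per-gene baselines
N(8, 1) on the log2 scale, a global dosage effect of 0.5 per GISTIC unit,
planted `beta_mut`/`beta_int` overrides, covariate effects and residual sd
0.5. eccDNA fragments are Poisson per sample (rate 0.2) with log-normal
lengths; a configurable fraction is forced to contain a planted gene on the
toy genome (25 genes per synthetic chromosome, 10 kb genes 100 kb apart).

All randomness flows from one root seed through six derived stage seeds
(clinical, incidence, annotation, read counts, expression, eccDNA), so a
stage can be regenerated independently and identical configs give
byte-identical cohorts.

**What the generator does not emulate:** mutational signatures, subclonal
architecture and clonal timing, segment-level CNV correlation along
chromosomes, mapping bias in RNA allele counts, panel composition
differences across real centers, and purity *estimation* error (purity is
known exactly to the generator). Passing calibration and recovery tests on
these cohorts therefore demonstrates that the statistics are implemented
correctly and are calibrated under their stated model — not that the model
captures every failure mode of real tumor data; in particular, real
allelic-imbalance tests inherit error from upstream purity and copy-number
callers that the simulation cannot exhibit.

## Analysis problem sizes

The package's own test suite and acceptance analysis use: 60 replicate
cohorts at the reference condition with 10,000 permutations each for FDR
calibration of the co-occurrence pipeline; a 400-sample cohort with burden
mean 6 and near-uniform gene weights (shape 8) for the planted-pair
recovery analysis — recovery is a power property, and power simulations are
sized so the planted effect is detectable by design, with n chosen from the
analytic power of the fixed-margin null at enrichment 5; 200 replicates at
n = 200 for regression parameter recovery; and exhaustive enumeration up to
depth 25 for the exact-test oracle. These sizes were fixed before the
analyses were interpreted and are stated here as the package's reference
configuration.

## Known limitations

* The permutation test conditions on observed margins; planted or real
  co-occurrence inflates the affected gene's CNV column sum, which makes
  the conditional null slightly conservative for strong effects.
* Least-squares VAF regression ignores the mean-variance relation of
  proportions; its p-values are approximate near the boundaries.
* Binoculars treats the matched background rate as known, ignoring its
  (pooled, typically small) estimation error; very sparse backgrounds fall
  through to broad strata that control purity poorly.
* The expression model is linear in the GISTIC code, an ordinal
  simplification of true copy dosage.
* Survival modeling is out of scope; the carrier-group labeling
  (`label_carrier_group()`) is provided for use with external survival
  tooling.
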