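---
title: "Models and methods behind deuteromics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind deuteromics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deuteromics)
```

deuteromics implements the downstream statistics used to characterize
bacterial communities from per-ORF metagenome summary tables — the kind of
table a co-assembly pipeline emits, with one row per predicted ORF carrying
taxonomy, functional annotations, length, completeness flags, G+C content
and one TPM abundance column per sample. The motivating system is a set of
sealed, oligotrophic heavy-water (D~2~O) containers whose microbial
communities show an excess of IS3-family transposases, but every method
here applies to any multi-sample ORF table. This vignette explains the
models, the tunable parameters, the synthetic-data generators that stand in
for sequencing data, and the numerical choices the implementation makes.

## The TPM convention

All abundances are transcripts-per-million: read counts are divided by
feature length and then scaled so that every sample sums to exactly 10^6^
(`normalize_tpm()`). Every downstream statistic assumes this convention;
generated tables enforce it to a relative tolerance of 10^-9^. Whether a
real pipeline derived its TPM from read counts or base coverage does not
matter downstream — only the sum-to-10^6^ property is used.

## Abundance-weighted gene length

For a co-assembled metagenome the natural "average gene length" weights
each ORF by its abundance: `mean = Σ len_i w_i / Σ w_i` with `w_i` the
pooled (cross-sample summed) TPM. The companion spread is the
frequency-weight standard deviation `sqrt(Σ w_i (len_i − mean)² / Σ w_i)`,
with no Bessel correction — the weights are population frequencies, not a
sample of weights, so the estimand matches the weighted mean. Only ORFs
with both start and stop codons are used by default (`require_complete`),
because edge-truncated ORFs bias length downward.

## Diversity

α-richness is the count of distinct species tags with TPM > 0 in a sample.
Species-level placeholders `unknown_<k>` (unclassified lineages) are
excluded unless `include_unknowns = TRUE`; both modes are exposed because
either convention is defensible and published richness is sometimes
reported both ways. β-diversity uses the Jaccard index |A∩B|/|A∪B| on
presence/absence only — abundance-weighted dissimilarities (Bray–Curtis)
are deliberately out of scope.

## Annotation censuses

`transposase_census()` uses an explicit, user-overridable matcher: an ORF
counts if its gene name contains a keyword (default `"transposase"`) or
its annotations intersect a fixed orthogroup set (default the putative
IS3-family transposase orthogroups COG2801 and COG2963). This is a
conservative rule by construction — no fuzzy matching — so the count
percentage is a lower bound on transposase prevalence. The per-sample
count percentage divides by ORFs with TPM > 0 in that sample; an
alternative denominator restricted to annotated ORFs is available via
`denominator = "annotated"` since published prevalence figures do not
always state which denominator they use. Cross-sample mean ± sd are plain
unweighted sample statistics (n−1), appropriate for a handful of replicate
containers.

## Amino-acid composition and enrichment

`composition_matrix()` reduces each protein to its relative frequencies of
the 20 standard residues (non-standard symbols dropped before
normalization, so rows always sum to 1). Two-group comparison uses a
per-residue unpaired t-test; Welch's unequal-variance form is the default
because group variances have no reason to match, with Student's form
behind `var_equal = TRUE`. The default is *no* multiple-testing
correction, mirroring the common practice of classifying 20 residues at a
raw α; Benjamini–Hochberg is available (`correction = "bh"`) and is the
better choice when the count of significant residues is itself the
result. The compositional dependence among the 20 columns (rows sum to 1)
is acknowledged and ignored — no CLR/ilr transform — matching how such
tests are usually reported. Because six truly null residues tested at raw
α = 0.05 carry a ~26% chance of at least one false positive per draw,
pattern-recovery checks in the test suite classify residues by their
majority class across replicate simulations rather than a single draw.

## Nei–Gojobori ka/ks

The NG86 estimator is implemented from first principles:

* **Sites.** For each codon position, the synonymous site fraction is the
  share of the three possible single-nucleotide changes that preserve the
  amino acid; changes creating stop codons count as nonsynonymous. Hence
  `s + n = 3` exactly for every sense codon.
* **Differences.** Codon pairs differing at k positions average the
  synonymous/nonsynonymous step counts over all k! orderings of
  single-nucleotide steps. Pathways passing through a stop codon are
  excluded; in the rare case that *every* pathway passes through a stop,
  all pathways are retained with stop-touching steps counted
  nonsynonymous. These conventions follow dominant NG86 practice and are
  unit-tested against an independent exhaustive path enumerator.
* **Distances.** Proportions `pS = Sd/S`, `pN = Nd/N` are corrected with
  the Jukes–Cantor formula `d = −(3/4)·ln(1 − 4p/3)`; a proportion at or
  above 3/4 is flagged saturated and the distance left undefined rather
  than extrapolated.
* **Classification.** `dN/dS < 0.9` is called purifying, values in
  `[0.9, 1.1]` neutral, `> 1.1` positive. The band operationalizes
  "ka/ks ≈ 1" and is configurable. `dS = 0 < dN` is positive with an
  infinite ratio; no differences at all is undefined.

The 61×61 site and pathway tables are computed once per session from the
standard genetic code (Biostrings' `GENETIC_CODE`) and cached; alternate
code tables are not supported. Maximum-likelihood codon models (PAML/GY94)
are out of scope — NG86 is the implemented estimator.

## The richness power law and δ deviations

For each taxon, `A` is the summed TPM of its unique ORF variants and
`d_obs` the number of variants. The model `d_exp = c·A^γ` is fitted by
ordinary least squares of log₁₀ d on log₁₀ A; γ measures how fast unique
variants accrue with abundance, and the analytic OLS standard error of the
slope feeds the two-sample z comparison
`z = (γ_a − γ_b)/sqrt(se_a² + se_b²)` between environments. Logarithms are
base 10 throughout; the base cancels in γ and only rescales the intercept.
Taxa with zero richness are excluded from the fit (their log is undefined)
and reported in `n_excluded` — retaining them would require a count-model
likelihood, which is deliberately out of scope.

The deviation coefficient is `δ = d_obs/d_exp`, reported on the log₁₀ axis
so 0 means "richness exactly as expected from abundance". Because OLS
residuals in log space average zero, the geometric mean of δ over the
fitted points is exactly 1 — a useful invariant that the tests assert to
10^-9^. The δ distribution is summarized by a Gaussian KDE (Scott's
bandwidth by default, overridable) evaluated on a grid spanning the
observed range ± 3 bandwidths, and by its spread (sd of log₁₀ δ), which
`compare_spread()` ratios between environments.

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline consumes, deterministically
given a seed.

`generate_orf_table()` draws per-taxon log₁₀ abundances uniformly on a
configurable interval, rescales them to sum to 10^6^ so they live on the
TPM scale, and realizes each taxon's variant count as
Poisson(`c·A^γ`) — or `round(c·A^γ)` in noiseless mode, in which the
downstream fit recovers the generating (c, γ) up to integer rounding.
Because a target table size and an explicit intercept cannot both be fixed
at once, the intercept is calibrated to the requested `n_orfs` when left
`NULL`, and honored verbatim (with the realized size following the law)
when given. Gene lengths follow a lognormal law (median 650 bp, σ = 0.6,
giving a mean near 780 bp) truncated by rejection to [60, 8748] bp — the
extreme lengths observed in the motivating dataset — and rounded to codon
multiples; G+C is clipped normal around 0.663; completeness flags are
independent Bernoulli(0.95); a Bernoulli subset of ORFs is labelled
transposase with an IS3-family COG; an independent Bernoulli subset is
orphan (no annotation, no gene name; default rate 5.95%). Per-sample
abundances add lognormal taxon- and ORF-level jitter, an optional
per-taxon presence probability (default 0.9) that creates the partial
species overlap β-diversity measures, and an optional calibration of the
transposase TPM share applied as one pooled scale factor *before* the
final per-sample renormalization, so the censused TPM varies around the
target with sampling noise. What the generator does **not** emulate:
assembly artefacts and chimeras, read-level error, annotation noise,
correlated taxon abundances, or phylogenetic structure — so passing
recovery tests demonstrates estimator correctness under the stated
statistical model, not robustness to real-data pathologies upstream of
the summary table.

`generate_codon_pair()` evolves a random sense-codon ancestor by proposed
single-nucleotide substitutions accepted with probability ω/(1+ω) if
nonsynonymous and 1/(1+ω) if synonymous (stop-creating proposals always
rejected), so the realized nonsynonymous/synonymous rate ratio equals ω
without simulating a full codon rate matrix. This is sufficient because
only rank behaviour — recovering purifying/neutral/positive regimes — is
asserted, not distances under a specific substitution model. One subtlety:
NG86 counts mutations *to* stop codons as nonsynonymous sites while the
generator never realizes them, so at ω = 1 the expected estimated ratio
sits slightly below 1 (≈0.95), still well inside the neutral band.

`generate_aa_groups()` draws composition rows from a Dirichlet
distribution (concentration 500 by default, i.e. per-residue noise sd
≈ 0.01 at frequency 0.05), with group means separated by a zero-sum
per-residue effect profile. `generate_presence_sets()` constructs species
sets with exact sizes and pairwise overlaps from shared and private label
pools; the three-way overlap defaults to the minimum pairwise request.

## Problem sizes used in the validation suite

The package's recovery simulations use sizes chosen for statistical power,
not to mimic any particular dataset: slope recovery runs 100 replicates at
n = 319 and n = 351 taxa with c = 0.5 over three abundance decades
(2.5–4.5 in log₁₀), placing the smallest expected per-taxon count near 20
so the log-of-Poisson bias on the slope stays below ~0.005; regime
recovery uses 50 seeds per ω at 3,000 codons and 1,200 proposed events,
enough synonymous differences (~10²) for the ratio's sampling error to
resolve a ±10% neutral band; census recovery uses three samples of
~50,000 ORFs, where the binomial error on a 2.71% fraction is under 0.1
percentage points; type-I calibration of the enrichment test runs 1,000
null replicates at 20 sequences per group.

## Known limitations

* The OLS slope comparison assumes independent fits and analytic standard
  errors; resampled errors are not implemented.
* δ diagnostics drop zero-richness taxa; heavy zero inflation would call
  for a different model.
* The ka/ks screen requires in-frame, pre-aligned pairs; alignment and
  ortholog search are out of scope.
* Composition tests treat residues independently; strongly compositional
  effects can leak across columns.
* The table reader loads whole tables into memory; very large tables
  (tens of millions of ORFs) are out of scope.
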