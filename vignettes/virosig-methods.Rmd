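---
title: "Methods and design of the virosig pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the virosig pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`virosig` implements a complete case-control gut-virome analysis:
catalogue construction, annotation, host prediction, community
profiling, a two-cohort differential-abundance meta-analysis, a
virus-bacterium dependency network, and transfer statistics for
external cohorts. This vignette explains each model, the parameters
that matter, the numerical choices, what the synthetic-data generator
does and does not emulate, and the design decisions taken where the
conventions of the field leave the procedure open.

## Catalogue construction

Putative viral sequences from metagenomic assembly carry bacterial
contamination. We screen by the **BUSCO ratio** — the number of
bacterial universal single-copy ortholog hits divided by the sequence's
total predicted genes — and remove sequences with a ratio of 5% or more
(`busco_filter()`, `max_ratio = 0.05`, applied as `ratio < max_ratio`).
Sequences with zero predicted genes are defined to have ratio 0 and are
kept; a BUSCO count exceeding the gene count is a data error.

Species-level **vOTU clustering** links two sequences when alignment
rows with ≥ 95% nucleotide identity, merged by interval union, cover
≥ 75% of the *shorter* sequence. Two points were genuinely open:

* *Coverage denominator.* We use the shorter sequence of the pair, the
  standard species-level convention; it also lets a provirus fragment
  cluster with the full-length genome that contains it.
* *Clustering algorithm.* Greedy longest-first clustering: sort by
  length descending (ties broken lexicographically by id), seed a
  cluster with the longest unassigned sequence, absorb every unassigned
  sequence linked *to the seed* (no transitive chaining), repeat. This
  is the de-facto standard for viral dereplication and makes the
  longest member the representative by construction. It is
  deterministic and order-independent given the sort; the test suite
  checks it against an independently coded brute-force oracle.

Completeness tiers follow the usual bands: high > 90%, medium 50–90%,
everything else (including missing estimates) low/unknown.

## Annotation

**Family voting.** Each protein votes once, for the family of its
highest-bitscore hit; a vOTU is assigned the top family only when its
vote fraction strictly exceeds 0.25 ("over 25%", implemented as
`> 0.25`, not `≥`) of *all* predicted proteins, unmatched proteins
included in the denominator. Ties for the top family yield
`unclassified`. Counting one vote per protein (rather than per hit) is
the simplest faithful reading of best-hit voting when searches return
multiple targets per protein. Raising the threshold can only
unclassify, never classify — a monotonicity property the tests enforce.

**KO / AMG annotation.** Each protein takes the KEGG orthologue of its
best hit; equal-score ties are broken deterministically by KO
identifier order and flagged. A vOTU's auxiliary-metabolic-gene set is
its KO set intersected with a curated enzyme panel. Two panels ship
with the package (`amg_panel()`): a general gut-phage AMG list and an
NAD⁺ biosynthesis/salvage panel (NAD⁺ synthase K01916,
nicotinate-nucleotide adenylyltransferase K00969, pncA K08281, pncB
K00763).

## Host prediction

**CRISPR route.** A spacer match must span the entire spacer, ungapped,
on either strand. Raw score S = (+1)·matches + (−2)·mismatches is
converted to bits, B = (λS − ln K)/ln 2, with λ = 1.28 and K = 0.46 —
the standard ungapped Karlin–Altschul constants for the +1/−2 pair —
and links require B ≥ 45. A perfect 32-nt match scores ≈ 60.2 bits, a
perfect 20-nt match ≈ 38.1; the threshold therefore demands roughly 24
matching positions, and every allowed mismatch costs 3 score units
(≈ 5.5 bits). Positions containing N score as mismatches. Gapped
matches are ignored: under the full-length requirement a gap costs more
than the budget allows in practice. The scan is exhaustive
(`Biostrings::matchPattern` with the mismatch budget implied by the
threshold), so the bit rule — not a heuristic seed — decides every
candidate; B is strictly increasing in S since λ > 0, and matching is
reverse-complement invariant.

**Homology route.** Per (vOTU, species), query intervals of all
alignments with ≥ 90% identity against any genome of the species are
merged by union; a link requires ≥ 30% of the vOTU covered. Links are
aggregated at species level (not genome level) because the dependency
analysis operates on species.

## Profiling

Counts are **rarefied** to a fixed depth (default 20,000 reads in the
reference design; the field standard for deep faecal viromes is
2,000,000) by sampling *without replacement* (multivariate
hypergeometric, via `vegan::rrarefy`) with a fixed seed; samples below
the target are dropped with a warning rather than scaled. Relative
abundance is the rarefied count over the target depth, so rows sum to
one, and family roll-ups preserve row sums.

Alpha diversity: observed richness, Shannon (natural log), Simpson as
1 − Σ p² (the common default of the ecology toolkits; the reciprocal
variant 1/Σ p² is not used). Beta diversity: Bray-Curtis. Ordination:
classical scaling of −D²/2; negative eigenvalues (non-Euclidean
content) are dropped without correction and variance fractions are
reported over the positive eigenvalues only; axis signs are arbitrary.

**PERMANOVA** (`permanova()`, via `vegan::adonis2`) partitions the
distance matrix sequentially (Type-I) in the given term order — the
covariate model is `composition ~ sex + age + BMI + group`, so the
group effect is what remains after the host factors — with p-values
from free permutation of observations, p = (1 + #{F\* ≥ F})/(1 + n),
1,000 permutations by default. Each term's R² is Ezekiel-adjusted for
its degrees of freedom (`vegan::RsquareAdj`). Single-level factors are
rejected as degenerate.

## Differential-abundance meta-analysis

Per cohort, each vOTU is tested with a two-sided Wilcoxon rank-sum test
(normal approximation with tie correction — sample sizes here make the
exact test unnecessary) and fold changes come from group means with a
pseudo-abundance ε: fold = (mean_case + ε)/(mean_control + ε), with
ε = half the smallest nonzero relative abundance in the cohort, so
absent taxa cannot produce infinite folds. The fold threshold applies
to max(fold, 1/fold) with the direction taken from the larger mean.
FDR is Benjamini–Hochberg; the empirical-null estimator some studies
use is a deliberate, documented deviation — BH is deterministic,
assumption-light and standard.

Cohorts are combined with **Fisher's method**, X = −2 Σ ln pᵢ ~ χ²(2k);
p-values of exactly 0 are floored at the smallest positive double with
a warning. A vOTU is a signature when both cohorts pass fold ≥ 1.2 and
q ≤ 0.2 (inclusive) in the same direction and the combined p is
strictly below 0.001. The combined-p threshold is a configuration
parameter because published analyses have used both 0.001 and 0.005;
0.001 is the default.

**Covariate adjustment.** The field does not standardise this step; we
rank-transform each vOTU's abundance and fit
`rank ~ sex + age + BMI + group`, reporting the group-term p. The rank
transform keeps the check aligned with the Wilcoxon analysis (their
p-value rankings correlate > 0.9 under null covariates, a property the
tests verify) while allowing continuous confounders.

## Dependency network

**SparCC** is implemented from first principles: with log-ratio
variances t_ij = var(log(x_i/x_j)) computed on fractions, the basis
variances ω solve the sparse linear system (diagonal D−1, off-diagonal
1), and r_ij = (ω_i + ω_j − t_ij)/(2√(ω_i ω_j)), clipped to [−1, 1].
The most strongly correlated pair with |r| above the exclusion
threshold (0.1) is removed from the system and the basis re-solved, up
to 10 times, so a few true correlations do not bias the estimates; a
pair is never excluded if that would leave a feature in fewer than two
equations. Fractions use a fixed pseudocount of 1 by default — this
makes the estimate deterministic — with Dirichlet resampling (median
over 20 draws) available behind `dirichlet = TRUE` for the classical
behaviour. Bootstrap p-values permute every feature independently
across samples and use the add-one rule, so p ≥ 1/(n_boot + 1); BH
runs over the upper triangle.

**Co-occurrence** uses presence = any nonzero rarefied count (no
abundance floor is standardised, so the simplest rule is used) and a
two-sided Fisher exact test per (signature vOTU, species) pair — only
those pairs, which matches the analysis scope and bounds multiplicity.

A signature vOTU is **bacterium-dependent** with ≥ 1 evidence of any
type: host link, co-abundance (signed r > 0.60 and q < 0.001 — the
threshold is applied to the signed correlation, since an exclusion
relationship is not a dependency), or co-occurrence (q < 0.001).
Dependent and independent labels partition the signature set.

AMG occurrence rates (carriers over group size) are compared between
case-enriched and control-enriched signatures by Fisher's exact test
with BH adjustment, optionally restricted to a named panel.

## Transfer analysis

The **consistency rate** is the fraction of signature vOTUs whose
external case-minus-control mean-abundance sign matches the discovery
direction. vOTUs with exactly zero difference are excluded from both
numerator and denominator (the count of evaluable vOTUs is reported) —
with continuous abundances this is a measure-zero event, but rarefied
data can produce it. The permutation test shuffles external labels
within the cohort (not pooled across cohorts) and uses the one-sided
add-one rule; 1,000 permutations by default, matching the granularity
needed for p ≈ 0.001 claims.

Detection requires presence in strictly more than 20% of individuals.
Gross abundances (per-sample sums over a signature set) are compared
with the equal-variance two-sample t-test, BH-adjusted over the
reported tests (global, not per-disease — the tighter choice). The
random-forest classifier uses 500 trees and default feature
subsampling, 70/30 stratified splits repeated 10 times with the mean
AUC as the performance measure; hyperparameters are fixed and logged
since none are standardised. AUC is computed on the predicted case
probability and is invariant to monotone transforms of the scores.

## The synthetic-data generator

`synth_community()` emulates the study design the statistics are built
for: two case-control cohorts drawn from one community. Baseline vOTU
proportions are log-normal (log-sd 1.5), giving the heavy-tailed
dominance structure of real gut viromes. Each sample adds log-normal
biological noise (log-sd 1, a realistic person-to-person dispersion),
cases multiply planted-enriched proportions by `effect_fold` and divide
planted-depleted ones by it, proportions are renormalised, and counts
are drawn multinomially at a per-sample depth uniform over
`depth_range` (default 40–60k, exercising the rarefaction stage).
Species counts are generated alongside; planted co-abundant vOTUs
inherit their partner species' per-sample log-deviations plus coupling
noise (log-sd 0.3).

Two structural choices deserve emphasis:

* **Truth is seed-independent.** Which vOTUs are enriched/depleted,
  which host links exist, family labels and AMG carriage are
  deterministic functions of the configuration (round-robin
  assignments); the seed drives only abundances, sequences and decoys.
  Planted truth is therefore exactly recoverable from the returned
  objects and identical across seeds.
* **Planted signatures sit in the middle abundance ranks.** Multiplying
  proportions and renormalising moves mass; if planted effects landed
  on the dominant community members, every unplanted vOTU would shift
  systematically in cases — a compositional artefact, not a planted
  signal — and "false discovery" would be ill-defined. The generator
  therefore assigns the planted vOTUs baseline abundances from below
  the top 30% of ranks, so the planted mass share is small and the
  unplanted background stays at parity. Real compositional data do not
  offer this courtesy; passing tests show the statistics recover
  planted structure, not that fold-change analysis is immune to
  compositional effects.

`synth_evidence()` plants, per host link, alternating CRISPR evidence
(an exact full-length spacer substring, random strand) and homology
evidence (92% identity over 35% of the vOTU), plus decoys designed to
fall below thresholds: 18-nt exact spacers (≈ 34 bits < 45), random
32-nt spacers, homology hits at 15% coverage or 84% identity,
alignment pairs below the clustering thresholds, and
BUSCO-contaminated records. Protein tables realise each classified
vOTU's family at vote fraction ≈ 0.45–0.5 with a decoy family at ≈ 0.2.

The generator does **not** simulate raw reads, assembly error, provirus
boundaries, real phylogenetic structure, batch effects between cohorts,
or abundance-dependent detection noise beyond multinomial sampling.
Transfer results on synthetic cohorts are therefore optimistic relative
to real external datasets, which add platform and population shifts.

## Validation problem sizes

The reference design used by the acceptance script and the heavier
tests: two cohorts of 60 cases + 60 controls, 200 vOTUs with 40
enriched + 40 depleted at fold 3, depth ~50k rarefied to 20,000. Null
calibrations use 500 replicates (PERMANOVA at n = 40 with 200
permutations; consistency test at n = 60 with 99 permutations), the
null-signature control 100 replicates, classifier nulls average five
independent label permutations of a 150 + 150 cohort, and SparCC
recovery uses 200 samples × 30 features at depth 50k. These sizes give
Monte-Carlo error comfortably inside the asserted bands while keeping
the whole suite quick on a laptop.

## Known limitations

* Fold changes on relative abundances are compositional; no
  log-ratio-based differential-abundance method is included by design.
* The covariate adjustment is a rank-linear interpretation, not a
  standardised procedure.
* SparCC's fixed-pseudocount default slightly shrinks correlations for
  very sparse features compared to Dirichlet averaging.
* The CRISPR scan scores ungapped full-length matches only.
* Permutation p-values are bounded below by 1/(n_perm + 1); claims
  beyond that resolution require more permutations.
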