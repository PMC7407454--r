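---
title: "Methods and design notes for sealpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for sealpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sealpanel)
```

This vignette documents the statistical procedures implemented in
`sealpanel`, the assumptions behind them, the parameter defaults and why
they were chosen, and the design decisions taken where more than one
reasonable implementation exists. The package grew out of the analysis
chain used to build and exploit a custom ~85K Axiom SNP array for an
intensively monitored Antarctic fur seal breeding colony; the defaults
throughout are that study system's operating point.

## 1. Panel design

Candidate SNPs arrive with flanking sequences (probe context), BLAST
mapping summaries against the reference genome, strand-specific array
design-score recommendations, and (for RAD loci) a discovery-pool MAF.
Design scores are consumed, never computed: the scorer is proprietary, so
a candidate without scores carries recommendation `"unknown"`, which
fails both the "recommended" and "neutral" tests.

The seven-tier priority cascade (`assign_priority()`) is evaluated
strictly in order with first match winning. The rules trade design
quality against marker supply: the top tiers demand a recommended score,
a unique full-length genomic mapping and a non-A/T, non-C/G substitution
(A/T and C/G SNPs need twice the probes); lower tiers progressively relax
the mapping and score requirements for RAD loci. Pre-validated and MHC
loci enter tier one unconditionally because their biological value
justifies tiling regardless of predicted performance. Treating the
cascade as strictly ordered makes the scheme a total, deterministic
function of the candidate's attributes; permuting the input never changes
a priority, and upgrading any single attribute never worsens one.

The tier-three MAF cutoff is not arbitrary: `p3_maf_cutoff()` computes it
as the frequency of two minor-allele copies among the 57 diploid
discovery-pool animals from the study population, floored to three
decimals (2/114 → 0.017). Flooring, rather than rounding, keeps a locus
observed exactly twice on the right side of the `>=` comparison.

Distance thinning is greedy per scaffold in order of (priority,
descending discovery MAF, ascending position), so when two SNPs conflict
the more informative one survives deterministically. Spacing is enforced
across priority classes: a retained pair must satisfy the stricter of the
two members' rules (100 bp for priority 1–2, 1 kb for RAD priority ≥ 3,
none for the rare non-RAD tier-5 SNPs). The cross-class choice is
deliberate and conservative — it guarantees that the final panel
satisfies every printed spacing constraint under exhaustive checking,
which a per-class-only rule does not. Deduplication keeps one record per
(scaffold, position) with preference pre-validated/MHC > RAD >
transcriptomic and a lexicographic tie-break.

## 2. Genotype QC

Samples are filtered on the platform's dish-QC metric (< 0.82 fails) and
then on call rate (< 97% fails); a sample lands in at most one failure
list because dish QC is checked first, and the call-rate threshold is
applied over the full locus set before any locus filtering — the same
order the array workflow uses. Locus statistics (call rate, MAF, MAC,
exact HWE p) exclude pups and replicate entries by default to avoid
pseudo-replication of parental alleles. "Polymorphic" is operationalised
as minor-allele count ≥ 1 among the retained samples; the platform's
cluster-quality classes need raw intensities, which are out of scope.

The Hardy–Weinberg test is the exact conditional enumeration: given the
minor-allele count m in n diploids, heterozygote counts h of the same
parity as m have probability ∝ 2^h / (n_hom_minor! · h! · n_hom_major!),
and the p-value sums all outcomes no more likely than the observed one.
The cumulative rule (no mid-p) matches common tool behaviour. Log-space
factorials keep the enumeration stable to n in the hundreds; a property
test confirms the distribution sums to 1 within 1e-12 across the (n, m)
grid up to n = 200. The inbreeding-dataset locus filter is strict where
the thresholds were stated as strict: call rate > 0.90 and MAF > 0.01,
but HWE p ≥ 0.001.

Replicate-based error estimation reports, per replicate pair (a
triplicate yields all three pairs), the genotype discordance over jointly
called loci and the method-of-moments Z2 (probability of sharing both
alleles IBD), the quantity used for array error-rate reporting. Since a
pairwise comparison accumulates errors from two assays, the per-assay
error rate reported by the acceptance script is half the mean
discordance.

## 3. Genomic inbreeding

Four estimators target the same latent quantity, the realized proportion
of the genome identical by descent:

* **sMLH** — individual heterozygosity over the mean population
  heterozygosity at the individual's typed loci; self-normalising, so the
  population mean is ~1 whenever individuals are typed at comparable
  panels.
* **F̂III** — per-locus terms (x² − (1+2p)x + 2p²) / (2p(1−p)) averaged
  over typed polymorphic loci, with x the allele-a dosage. Expectation 0
  under Hardy–Weinberg; ±1 at p = 0.5 for fully homozygous/heterozygous
  genomes. Loci with p ∈ {0, 1} are skipped, never propagated as NaN.
  Allele frequencies come from the analysed sample itself (post-QC,
  replicates removed) because the study system has no external reference
  panel; this is a known, small, shared-sample bias.
* **F_ROH** — sum of called ROH lengths over the assembly length
  (default 2.3e9 bp, configurable).
* **g2** — identity disequilibrium, the population-level signal that
  inbreeding varies among individuals.

The ROH caller reproduces a PLINK-style two-stage screen with the
parameters fixed by the study design: 20-SNP windows with at most 1
heterozygous and 5 missing calls; a SNP is a hit when ≥ 5% of the windows
containing it are homozygous; maximal hit runs become segments if they
hold ≥ 20 SNPs, span ≥ 1000 kb, average ≤ 100 kb per SNP and contain ≤ 1
heterozygote, splitting wherever adjacent SNPs are > 1000 kb apart. Two
choices needed to be made where the window and segment rules do not state
their interaction:

* The hit-rate denominator counts only windows that physically fit on the
  scaffold and contain the SNP, so scaffold-edge SNPs (with fewer
  covering windows) are not penalised.
* A hit run carrying more heterozygotes than the segment allowance is cut
  immediately before each heterozygote beyond the first, and the pieces
  are re-tested, rather than discarding the whole run. This makes the
  response to an inserted heterozygote binary — absorbed (first het) or
  split (subsequent hets) — and total ROH bp provably non-increasing in
  the number of heterozygotes, both of which are property-tested.

Segment bounds are the first/last SNP positions, 1-based inclusive
internally; BED-like exports convert to 0-based half-open at the
boundary. `length_kb` is (end − start + 1)/1000.

The g2 estimator is authored from the two-locus definition. For loci k
and l, the joint-heterozygosity term averages h_ik·h_il over individuals
typed at both loci; the independence reference averages h_ik·h_jl over
ordered pairs of distinct individuals typed at k and l respectively; g2
is the ratio of the pair-summed terms minus 1. With complete data this
reduces to the classic row/column-sum form; with missing data every term
is normalised by the exact count of observations entering it, which is
the estimator's missing-data correction. The production path evaluates
the sums with matrix cross-products — an exact algebraic rearrangement,
not an approximation — and `g2_direct()` is the transparent O(L²) loop
kept as a cross-check; the two agree to 1e-10 by test. Confidence
intervals bootstrap individuals (percentile, resampling rows with
replacement); the p-value permutes each locus column independently to
destroy cross-locus correlation while preserving locus-wise
heterozygosity, with p = (b + 1)/(B + 1). All randomness is seeded.
Because a 95% interval misses the truth one run in twenty by design, the
null-coverage tests check coverage across several independent replicates
rather than a single draw.

## 4. Relatedness

LD pruning regresses each mean-imputed dosage on the other loci in a
50-SNP window (step 5) and repeatedly removes the highest-VIF locus until
all VIF ≤ 2 (R² ≤ 0.5); removals are global, ties go to the later locus,
and perfect collinearity (R² within 1e-12 of 1) is treated as infinite
VIF. Mean imputation affects pruning only — downstream statistics always
honour true missingness. The informative subset keeps loci with MAF ≥
0.3, call rate ≥ 0.90 and HWE p ≥ 0.001: with only biallelic markers,
high-MAF loci carry the most information per genotype for IBD inference.

Allele-sharing statistics come from the nine genotype-combination counts
of each pair: KING-robust kinship (HETHET − 2·IBS0)/(HET_a + HET_b),
R0 = IBS0/HETHET and R1 = HETHET/DISC with DISC the count of all
discordant-genotype sites. These need no allele frequencies and are
robust to ascertainment. R1's denominator is the one place where the
published definitions live in a cited figure rather than a formula; the
choice is isolated in `allele_sharing_stats()` so it can be swapped
without touching anything else. Undefined ratios (zero denominators, as
for duplicates where DISC = 0) are reported as NA, never as infinities.

The method-of-moments IBD solver equates observed IBS counts to their
expectations given IBD state. Expected probabilities use sample allele
frequencies with without-replacement finite-sample corrections — each
power of p and q is replaced by the corresponding falling-factorial
product of allele counts (e.g. p²q² → X(X−1)Y(Y−1)/T(T−1)(T−2)(T−3)),
the same device PLINK's --genome uses. Z0, Z1, Z2 are solved
sequentially (IBS0 identifies Z0, and so on), then bounded: z0 > 1 maps
to (1, 0, 0); negative components are zeroed and the vector renormalised
to sum 1. PI_HAT = Z2 + Z1/2. Monomorphic loci and loci whose frequency
rests on fewer than two genotypes are excluded. The pairwise engine
evaluates all of this with n×n matrix products, so a 270-animal colony
(≈36k pairs) takes seconds.

Classification compares (z0, z1, z2, pi_hat) against a threshold table
evaluated in declared order with first match winning; pairs matching no
category are `unknown`. The default table is built from kinship-degree
midpoints and is fully replaceable by a user-supplied table (e.g. from a
published supplement). Ranges are closed; the half-open feel of adjacent
categories is realised by evaluation order. A call is `difficult` when
any coefficient lies within 0.01 of a bounding threshold of the assigned
or an adjacent category — excluding bounds at exactly 0 or 1, which are
theoretical extremes rather than inference thresholds (otherwise every
textbook parent–offspring point z = (0, 1, 0) would be flagged).

## 5. Conversion model

Conversion success (a tiled SNP yielding usable genotypes) is modelled as
Bernoulli with a logit link on six binary design covariates. The fit is
IRLS (`stats::glm`, tolerance 1e-8, ≤ 100 iterations) — an ordinary model
fit, cross-checked in tests against a hand-rolled Newton optimiser and
closed forms (intercept-only = logit of the success fraction; a single
2×2 predictor = log odds ratio). Confidence intervals are parametric
bootstrap on the log-odds scale: responses resampled from
Bernoulli(fitted p), percentile bounds (not BCa — the simplest method
consistent with "parametric bootstrap"), and an error if over 1% of
refits fail to converge. Constant covariates are dropped with a warning;
suspected separation is flagged, never silently returned. The real
study's per-SNP covariates are not fully recoverable from public data, so
this module targets structural fidelity and recovery-on-synthetic:
coefficients planted at the magnitudes reported for the real array
(0.85, −3.19, 1.46, 0.26) are recovered within their bootstrap CIs at
n = 50,000. The synthetic design keeps every covariate at ≥ 2% frequency
so each coefficient is identifiable with a stable sampling distribution.
The real intercept was never published, so predicted probabilities from
synthetic fits illustrate the inverse-logit formula rather than reproduce
a published percentage.

## 6. The simulator

`simulate_founders()` + `gene_drop()` implement gene dropping: founder
haplotypes get unique integer labels; each transmitted gamete draws a
Poisson number of crossovers per scaffold (sex-averaged uniform map,
default 1 cM/Mb, no interference) with uniform integer positions, and
alternates parental haplotypes. Labels are tracked both per locus and as
exact bp intervals, which yields exact ground truth: autozygous segments
(equal labels on both haplotypes), realized inbreeding (autozygous bp /
genome bp), and true pairwise IBD-sharing fractions via an interval
sweep. Genome defaults (20 × 115 Mb = 2.3 Gb) match the F_ROH
denominator; MAF is uniform on (0.05, 0.5), the post-discovery-filter
range; genotyping error (default 0.004 per call — the replicate-derived
array error) replaces a call with one of the other two codes uniformly,
then missingness (default 0.5%, matching ~99.5% call rates) is applied.
Founders are in linkage equilibrium by default; the block-LD mode
(blockwise copies from a small haplotype pool) exists solely to give the
LD pruner something to remove. `build_pedigree()` composes disjoint
family units per relationship class, so designed pairs have exact
theoretical expectations and everything across units is unrelated;
consanguineous half-sib and full-sib matings produce pedigree F of 0.125
and 0.25. `simulate_colony()` assembles the study-shaped dataset (270
animals, 53 mother–offspring pairs, 4 paternal half-sib pairs, a few
consanguineous matings, optional triplicate, field records with
unrecorded and planted-false maternal links).

What the simulator does **not** emulate — and hence what passing tests do
not demonstrate about real data: population structure and drift between
colonies, ascertainment bias in the SNP panel, genotype-clustering
artefacts (the error model is symmetric and independent), linkage
disequilibrium beyond the optional block mode, sex chromosomes, and
mutation. Tests against it validate the estimators' mathematics, not the
biology of any particular dataset.

## 7. Problem sizes and numerical choices

Test and acceptance runs use deliberately scaled simulation sizes chosen
to hold the targeted statistical properties with margin: colony-scale
relatedness at 270 animals × 2,500 SNPs (≈2,000 informative), class-
accuracy checks at ~5,000 informative SNPs (the point where unrelated
pairs separate cleanly from third-degree), ROH recovery on dense maps of
1 SNP / 50 kb over 0.4 Gb genomes, F̂III calibration at n = 500 ×
L = 5,000, g2 at n = 150–200 × L = 800–1,000 with 200-replicate
bootstraps, and GLM recovery at n = 50,000 with 200 bootstrap refits.
Fixed seeds make every stochastic check reproducible; genotype codes are
integers with a dedicated NA for missing (never a sentinel that could
leak into arithmetic); ratio statistics return NA on empty denominators;
and all coordinates are 1-based inclusive internally with conversion to
0-based half-open only at BED-style boundaries.

Known limitations: the ROH caller is map-free (physical distance only);
g2's matrix path materialises L×L cross-products with missing data, which
is memory-hungry beyond ~20k loci (the direct estimator definition, not
an approximation, so exactness is kept at the cost of scale);
relationship classification is rule-based, not likelihood-based, and
inherits the resolution limits of Z-score space — second- versus
third-degree assignment near the π thresholds is intrinsically noisy at
array scale, which is exactly why the 0.01 difficult-call margin exists.
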