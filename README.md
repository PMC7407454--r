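# sealpanel

Tools for designing and analysing custom SNP genotyping arrays in wild
diploid populations, built around the analysis chain of an Antarctic fur
seal (*Arctocephalus gazella*) breeding-colony array. The package covers
the full path from candidate variants to population-genetic inference:

* **Panel design** — discovery filters (per-genotype depth 5–18, MAF ≥
  0.05, call rate ≥ 60%), flanking-sequence checks, BLAST mapping context,
  a seven-tier priority cascade, distance thinning (100 bp for priority
  1–2, 1 kb for RAD priority ≥ 3) and site deduplication.
* **Genotype QC** — sample filters (dish QC ≥ 0.82, call rate ≥ 97%),
  per-locus call rate/MAF/MAC, an exact Hardy–Weinberg test, and
  replicate-based genotyping-error estimation.
* **Genomic inbreeding** — standardised multi-locus heterozygosity (sMLH),
  the correlation-of-uniting-gametes estimator
  F̂III(i) = (1/mᵢ) Σₗ [xᵢₗ² − (1+2pₗ)xᵢₗ + 2pₗ²] / (2pₗ(1−pₗ)),
  a PLINK-style sliding-window ROH caller (20-SNP windows, ≤1 het,
  ≤5 missing, 5% hit threshold; segments ≥ 20 SNPs, ≥ 1 Mb, ≤ 100 kb/SNP,
  split at > 1 Mb gaps), F_ROH = Σ ROH length / 2.3 Gb, and the g2
  identity-disequilibrium estimator with bootstrap CIs and permutation
  p-values.
* **Relatedness** — VIF-based LD pruning (50-SNP windows, step 5,
  VIF ≤ 2), a maximally informative subset (MAF ≥ 0.3, call rate ≥ 90%),
  nine-cell genotype-combination counts, KING-robust kinship
  φ = (HETHET − 2·IBS0) / (HET_a + HET_b), R0, R1, method-of-moments
  Z0/Z1/Z2 and PI_HAT = Z2 + Z1/2, plus rule-based classification into
  parent–offspring, full-sib, second-degree, third-degree and unrelated
  with a 0.01 "difficult call" margin.
* **Conversion model** — binomial logistic regression of SNP conversion
  success on design covariates, with parametric-bootstrap CIs and inverse-
  logit probability prediction.
* **Simulator** — pedigree gene dropping over founder haplotypes with
  recombination and full IBD-label tracking, so every estimator above can
  be validated against exact ground truth (realized inbreeding, true
  pairwise IBD fractions, designed relationship classes).

## Worked example

Simulate a genotyped breeding colony (270 animals, 53 true
mother–offspring pairs, paternal half-sibs, consanguineous matings, 0.4%
genotyping error) and recover its relatedness structure:

```r
library(sealpanel)
cfg <- sim_config(n_snps = 2500, n_scaffolds = 10, maf_range = c(0.25, 0.5))
col <- simulate_colony(n_total = 270, n_mo = 53, n_hs = 4,
                       n_halfsib_matings = 3, n_fullsib_matings = 2,
                       config = cfg, seed = 1)
x  <- col$matrix
st <- locus_stats(x, metadata = col$metadata)
pr <- relatedness_pairs(subset_geno(x, loci = informative_subset(st)))
table(pr$category)
known_pair_audit(pr, col$metadata)
```

Output from this exact script:

```
geno_matrix: 270 samples x 2500 loci
  overall call rate: 0.9952
polymorphic loci: 2500 of 2500
informative subset (MAF >= 0.3): 2004 loci

parent_offspring    second_degree     third_degree        unrelated
              53                4              306            35952

confirmed maternal links: 50   novel PO pairs: 3   contradicted links: 3
mean sMLH 1.000, mean Fhat3 0.0024
```

All 53 true mother–offspring pairs are recovered (50 confirm the field
records, 3 were deliberately left unrecorded and surface as novel), the 4
planted paternal half-sib pairs land in the second-degree class, and the 3
planted false maternal links are flagged as contradicted. The
third-degree count includes borderline pairs from the noise tail of the
unrelated distribution at this marker count; it shrinks as the
informative-SNP panel grows (see the methods vignette).

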