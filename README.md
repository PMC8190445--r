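# rohload

Tools for dissecting inbreeding depression by the age of the haplotypes
that cause it, using runs of homozygosity (ROH) measured on genetic-map
coordinates.

## The problem

When both copies of a genomic region descend from a single recent
ancestor, the region is a run of homozygosity, and recombination ties
its *genetic* length to the age of the shared haplotype: a segment whose
underlying haplotypes coalesce *g* generations ago has expected length

    L = 100 / (2 g)  cM

Long ROH (> 12.5 cM, MRCA ≤ 4 generations) come from recent close
inbreeding; medium ROH (1.56–12.5 cM, 4–32 generations) reflect recent
demography; short ROH (0.39–1.56 cM, 32–128 generations) reflect deep
history. Because purifying selection keeps removing deleterious
recessives, older haplotypes should carry less mutation load per cM —
so inbreeding depression should be dominated by long ROH. `rohload`
implements everything needed to test this in a wild sheep population
with a documented island history:

* **Genetic map** — linkage-map interpolation of SNP positions
  (constant recombination rate between anchors), the age ↔ length
  conversions, total map length (3146 cM for the sex-averaged autosomal
  map used throughout).
* **ROH caller** — windowed detection on cM × 1e6 pseudo-coordinates
  with the standard tool's parameters (25-SNP windows, ≤ 2
  heterozygous/missing calls per window, minimum 25 SNPs and 0.39 cM,
  maximum 0.25 cM gap, density 0.1 cM/SNP), length classes, and
  per-class inbreeding coefficients F_ROH = Σ length / 3146 cM, held to
  exact agreement with a brute-force enumeration oracle in the tests.
* **Forward Wright–Fisher simulator** (Rcpp) — 100 Mb genome, μ = r =
  1e-8 per bp (1 Mb ≡ 1 cM), 70% deleterious / 30% neutral mutations,
  gamma distribution of fitness effects (mean s ∈ {−0.01, −0.03,
  −0.05}, shape 0.2), dominance h ∈ {0, 0.05, 0.2}, multiplicative
  fitness (1+s homozygous, 1+hs heterozygous), island demography
  1000 → 200 → crash to 10 → exponential recovery to 200, with staged
  rescaling for desk-scale runs (ancestral burn-in rescaled by Q, the
  island phase at full resolution).
* **Mutation-load statistics** — per individual and ROH class: load per
  cM (Σs / Σ length), deleterious mutations per cM, and mean allele
  frequency; replicate summaries with percent contrasts against long
  ROH.
* **Survival GLMM** — binomial logit mixed model of first-year survival
  on the three F_ROH coefficients (× 100, i.e. per 1% of genome), sex
  and twin effects, and random intercepts for birth year and mother;
  MCMC (JAGS, Normal(0,5) fixed-effect priors, half-Student-t group-SD
  priors, Gelman–Rubin diagnostics) and fast lme4 backends; odds-ratio
  reporting.
* **Synthetic data** — genotype fixtures with planted homozygous
  segments and exact truth tables, random linkage maps, and survival
  cohorts generated at known effect sizes for parameter-recovery
  studies.

## Worked example

```r
library(rohload)

## interpolate an unmapped SNP halfway between two anchors at 3 and 4 cM
gm <- GeneticMap(data.frame(chromosome = "1", bp = c(100, 300), cm = c(3, 4)))
interpolatePositions(gm, data.frame(marker_id = "snp1", chromosome = "1", bp = 200))
#>   marker_id chromosome  bp  cm
#> 1      snp1          1 200 3.5

expectedRohLength(c(4, 32, 128))   # the class boundaries, in cM
#> [1] 12.500000  1.562500  0.390625

## a planted 4.95 cM homozygous segment is recovered and classified
fx <- generateGenotypeFixture(n_individuals = 1, n_markers = 100,
                              segment_markers = 100, background_het = 0,
                              seed = 1)
segs <- classifySegments(callRoh(fx$genotypes))
segs[, c("start_cm", "end_cm", "length_cm", "n_snps", "length_class")]
#>   start_cm end_cm length_cm n_snps length_class
#> 1        0   4.95      4.95    100       medium

## recover the survival effects from a synthetic cohort (n = 4879)
## generated at odds ratios 0.876 / 0.923 / 0.977 per 1% of genome
coh <- generateCohort(seed = 1)
fit <- fitSurvivalModel(coh$records, backend = "glmer")
oddsRatioTable(fit)[2:4, ]
#>       term        or  or_lower  or_upper percent_reduction
#> 2   f_long 0.8792834 0.8520239 0.9074150         12.071661
#> 3 f_medium 0.9273231 0.9113224 0.9436047          7.267692
#> 4  f_short 0.9786526 0.9493431 1.0088670          2.134740
```

The recovered odds ratios sit on the generating values: a 1% genomic
increase in long ROH cuts the odds of first-year survival by ~12%,
medium ROH by ~7%, and short ROH shows no clear effect — the
age-dependence of inbreeding depression the package exists to study.

A full simulation study (20 desk-scale replicates, ~5 minutes) runs
with:

```r
study <- simulateLoadStudy(n_replicates = 20, seed = 101)
colMeans(study[, c("load_contrast_medium", "load_contrast_short",
                   "count_contrast_medium")], na.rm = TRUE)
```

giving the percent reduction in mutation load per cM of medium and
short ROH relative to long ROH, and the same contrast for
deleterious-mutation counts.

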