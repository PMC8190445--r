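---
title: "Runs of homozygosity, mutation load and inbreeding depression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Runs of homozygosity, mutation load and inbreeding depression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The scientific problem

Inbreeding exposes recessive deleterious mutations as homozygotes. The
genomic footprint of inbreeding is the run of homozygosity (ROH): a
contiguous stretch of homozygous genotypes created when an individual
inherits two copies of the same ancestral haplotype. Because
recombination whittles haplotypes down over generations, the *genetic
map length* of an ROH carries a clock: a segment whose underlying
haplotypes coalesce $g$ generations ago has expected length

$$L = \frac{100}{2g}\ \text{cM}.$$

Young haplotypes (recent inbreeding) produce long ROH; old haplotypes
produce short ones. Purifying selection has had more time to purge
deleterious variants from old haplotypes, so the mutation load carried
per cM of ROH should *decrease* with haplotype age — and inbreeding
depression should be driven disproportionately by long ROH. This package
implements the full chain needed to study that prediction in a wild
sheep population: genetic-map interpolation, ROH detection on cM
coordinates, length-class inbreeding coefficients, forward simulation of
deleterious-mutation dynamics under the population's demographic
history, per-class mutation-load statistics, and a binomial mixed model
of first-year survival.

# Genetic map and haplotype-age classes

`interpolatePositions()` fills cM positions for markers absent from the
linkage map by assuming a constant recombination rate between mapped
anchors (piecewise-linear interpolation in bp). Edge conventions:
markers before a chromosome's first anchor sit at 0 cM; markers beyond
the last anchor take the last anchor's cM; markers between anchors of
equal cM take that shared value; a marker exactly at an anchor bp takes
the anchor's cM. Positions are doubles compared with an absolute
tolerance of 1e-9 cM; chromosomes are fully independent.

Three ROH length classes follow from $L = 100/(2g)$ at $g$ = 4, 32 and
128 generations:

| class  | length (cM)    | expected MRCA (generations) |
|--------|----------------|-----------------------------|
| long   | > 12.5         | up to 4 (close inbreeding)  |
| medium | 1.56 – 12.5    | 4 – 32                      |
| short  | 0.39 – 1.56    | 32 – 128                    |

The printed interval notation leaves the boundary points ambiguous; we
assign short = [0.39, 1.56), medium = [1.56, 12.5], long = (12.5, Inf)
so every segment has exactly one class. Per-class inbreeding
coefficients divide the summed class length by the total sex-averaged
autosomal map length, 3146 cM.

# ROH detection

`callRoh()` re-implements the documented windowed-detection semantics of
the standard tool on cM coordinates multiplied by 1e6, so the cM
thresholds map exactly onto kb-scale parameters (0.39 cM ↔ 390 "kb").
Defaults: 25-SNP windows with at most 2 heterozygous and 2 missing calls
per window; a marker participates in a run when at least 5% of the
windows covering it pass (the tool's default hit threshold, which is not
part of the printed command; it is exposed as a parameter); runs split
at inter-marker gaps above 0.25 cM; at most 2 heterozygous calls per
final segment; minimum 25 SNPs, 0.39 cM, and average spacing at most
0.1 cM per SNP. The per-segment heterozygote allowance of 2 follows the
executable record of the original analysis (its prose says one).

Choices the underlying tool leaves undocumented, fixed here for
determinism and testability:

* **Excess heterozygotes.** Walking left to right, the call that would
  be the third heterozygote closes the current segment just before it
  and opens the next just after it. This keeps detection deterministic
  and makes coverage (and hence $F_\mathrm{ROH}$) monotone
  non-increasing as heterozygous calls are added, which we verify on
  fixtures.
* **Edges.** Segments are trimmed so their first and last markers are
  homozygous non-missing calls, and spans are measured first-to-last
  marker — never extrapolated beyond observed markers.
* **Gaps.** Runs always split at gaps above the threshold; we never
  bridge a gap even when a window spans it.
* **Window-edge shaving.** With a 5% hit threshold and 25-SNP windows, a
  marker needs two passing windows; the outermost marker of an interior
  homozygous run is covered by only one fully-homozygous window, so
  called segments begin one marker inside the underlying run. This is a
  property of windowed detection itself, shared with the original tool,
  and is why planted-segment recovery in the tests is scored by overlap.

The test suite holds the caller to *exact* equality with a brute-force
oracle that re-derives the same semantics by explicit enumeration
(window eligibility marker by marker, maximal runs, the heterozygote
walk, and the final filters) on hundreds of randomized instances.

# Forward Wright–Fisher simulation

`runSimulation()` simulates a diploid, monoecious, randomly mating
(selfing permitted) population with discrete generations and soft
selection: each offspring draws two parents with probability
proportional to fitness. The genome is a single 100 Mb chromosome with
uniform recombination and mutation at $10^{-8}$ per bp per generation,
so 1 Mb ≡ 1 cM. Each transmitted haplotype receives Poisson($rL$)
crossovers and Poisson($\mu L$) new mutations at uniform positions
(infinite-sites; position collisions are re-drawn). 70% of new mutations
are deleterious with selection coefficients drawn from a gamma
distribution (default mean $s = -0.03$, shape 0.2, negated) and a fixed
dominance coefficient (default $h = 0.05$); 30% are neutral. Fitness is
multiplicative: $1+s$ per homozygous and $1 + hs$ per heterozygous
deleterious genotype, clamped below at zero. (We use the standard
$1 + hs$ heterozygote convention of the simulator this design follows;
a published description that reads "h(1 + hs)" is internally
inconsistent — it would annihilate fitness for near-neutral
heterozygotes — and is treated as a typographical slip.) Mutations that
fix are removed from the segregating set, so all reported load
statistics concern segregating variants only. Neutral variation is
simulated forward in time at $0.3\mu$ rather than overlaid
retrospectively on a coalescent tree; the load statistics depend only on
deleterious mutations, so this changes nothing that is measured.

The island demographic history: 1000 diploids for 10,000 generations,
an instantaneous change to 200 for 970 generations, a crash to 10 at
generation 10,970, exponential recovery
$N(t) = \mathrm{round}(10\cdot 20^{t/20})$ back to 200 within 20
generations, then 200 until generation 10,999. The engine is written in
C++ (Rcpp), as is usual for forward simulators.

## Desk-scale execution: staged rescaling

Classical population rescaling by $Q$ (sizes and durations divided by
$Q$; $\mu$, $r$ and $s$ multiplied by $Q$) preserves $N\mu$, $Nr$ and
$Ns$ and makes the 11,000-generation history tractable. But it also
compresses the recent timescale: with $Q = 10$, the youngest possible
coalescence (one rescaled generation) corresponds to ten real
generations, so haplotypes younger than ten generations — precisely the
ones that produce long ROH (> 12.5 cM, MRCA ≤ 4 generations) — cannot
exist in a uniformly rescaled run. We verified this directly: uniformly
rescaled runs produce no segment anywhere near the long-class boundary,
whatever the selection parameters.

`runSimulation()` therefore defaults to *staged* rescaling
(`rescale_mode = "ancestral"`): only the first, ancestral epoch is
rescaled (1000 → 100 diploids for 1000 generations, rates and $s$
scaled by $Q$), while the island phase — 200 individuals, the crash to
10, and the recovery, i.e. the 1000 generations in which all three
haplotype-age classes live — runs at full size and full rates. At the
seam the standing selection coefficients are divided by $Q$: rescaling
preserves $N s$, so the burn-in hands over standing variation with the
correct joint structure of frequency and population-scaled effect. The
approximations are (i) the allele-frequency grid of the burn-in is
coarser (1/200 rather than 1/2000), and (ii) deleterious-mutation
interference during the burn-in is stronger than in the full model, as
in any rescaled run. The final population (200 individuals) is analysed
whole, as in the original design.

## Problem sizes used

The packaged simulation study runs 20 replicates at $Q = 10$ (about
15 s each, ~5 minutes in total), samples 200 individuals per replicate,
and yields roughly 3000–4000 segregating sites per run. We regard 20
replicates as adequate because the replicate-level contrasts have
standard errors of a few percentage points, small against the
inter-class differences of interest.

# Load statistics

For each individual and class, `rohLoadStats()` reports

* load per cM: $\sum s / \sum \mathrm{length}$ over deleterious
  mutations counted inside the class's segments (expected fitness
  decline per cM of ROH, ≤ 0);
* count per cM: $n / \sum \mathrm{length}$;
* mean allele frequency of the counted mutations.

Only mutations *homozygous* for the deleterious allele inside the
segment span (closed interval) are counted by default: ROH are taken as
IBD tracts, and heterozygous calls inside them are tolerated errors.
The alternative — counting any carried copy — is available via
`homozygous_only = FALSE`. Mean frequencies pool one entry per
individual-occurrence rather than one per distinct mutation, so common
variants weigh in proportion to how often they actually sit inside ROH.
Individuals without segments of a class are excluded from that class's
mean ("per cM of ROH" is undefined without ROH) and missing values are
reported as missing, never as zero. Replicate summaries
(`summarizeReplicate()`) average each statistic over individuals and
express medium- and short-class values as percent contrasts against the
long class, $100(1 - \bar{x}_\mathrm{class}/\bar{x}_\mathrm{long})$,
matching how the study phrases its results.

# The survival model

`fitSurvivalModel()` fits

$$\Pr(\mathrm{surv}_i = 1) = \mathrm{logit}^{-1}\!\big(\beta_0 +
100 F_{\mathrm{long},i}\beta_1 + 100 F_{\mathrm{medium},i}\beta_2 +
100 F_{\mathrm{short},i}\beta_3 + \mathrm{sex}_i\beta_4 +
\mathrm{twin}_i\beta_5 + \alpha_{\mathrm{year}(i)} +
\alpha_{\mathrm{mother}(i)}\big)$$

with Normal random intercepts for birth year and mother. The factor 100
makes each $\beta$ the change in log-odds per 1% of genome; effects are
reported as odds ratios with 95% intervals, and percent reduction in
the odds of survival, $100(1-\mathrm{OR})$, for odds reductions.

Two backends share one contract:

* `backend = "mcmc"` (JAGS): Normal(0, 5) priors on fixed effects,
  half-Student-t priors on the group SDs, 4 chains × 10,000 iterations
  with 5,000 warmup by default, posterior means with 2.5/97.5 percentile
  intervals, Gelman–Rubin diagnostics per parameter, and a
  non-convergence flag at $\hat R \ge 1.1$. The half-t hyperparameters
  are not part of the published description; we adopt (df 3, scale 2.5)
  — a common weakly-informative default — and expose both.
* `backend = "glmer"` (lme4, Laplace ML): Wald 95% intervals. With the
  weak priors above and cohorts of thousands, posterior means and MLEs
  agree closely (asserted in the tests on a shared cohort), so the
  likelihood backend is the one used by the bundled parameter-recovery
  harness and acceptance script, where dozens of paper-sized fits are
  needed; full MCMC at that scale costs hours per fit in JAGS.

Records with a missing mother are dropped with a message (their
handling is not described in the original analysis); a single-level
grouping factor or a constant covariate raises an informative error
rather than a silent degenerate fit.

# Synthetic data

`generateCohort()` draws class inbreeding coefficients with the
population's means — $F_\mathrm{long}$ from a zero-inflated gamma
(right-skewed, many zeros, mean 0.013), $F_\mathrm{medium}$ and
$F_\mathrm{short}$ from truncated normals (means 0.213 and 0.107) — and
generates Bernoulli survival from the logit model above. The
distribution families are a modelling choice: the study describes the
shapes only qualitatively, and only the means enter any assertion.
Remaining defaults, chosen once as plausible for the study population
and exposed as parameters: intercept 2.6 (overall first-year survival
≈ 0.57 once the covariate and sex/twin effects act), sex effect −0.2,
twin effect −0.5, twin probability 0.15, 39 birth years × 29 mothers
(≈ 1130 mothers, near the study's 1118), group-intercept SDs 0.3.

`generateGenotypeFixture()` plants homozygous segments of known span
(optionally contaminated with interior heterozygotes) in random
background genotypes and returns the exact truth table, so caller
sensitivity is scored against known answers. `generateMapFixture()`
builds random monotone linkage maps with a denser unmapped marker set
for interpolation tests.

What the synthetic data deliberately do not emulate: the real pedigree
and its connection between twins and mothers, linkage disequilibrium
and allele-frequency structure of the SNP chip, genotyping and
imputation error, spatial structure, and year-specific mortality.
Passing tests therefore demonstrate that the algorithms implement their
definitions and recover known parameters under the stated model — not
that the model captures every property of the real system.

# Numerical conventions and degenerate inputs

cM positions are doubles; all caller arithmetic runs on integer
pseudo-coordinates `round(cm * 1e6)`; class F sums are checked to 1e-9.
A chromosome with fewer markers than one window yields no segments (not
an error); an empty segment set yields $F = 0$ with a missing mean
length; load statistics for a class with no ROH are missing, and
contrasts propagate missingness. Simulation seeds are mandatory
arguments — there is no hidden default RNG state — and replicate
sub-seeds are derived from the master seed by increment.

# Known limitations

* The ROH caller reproduces documented windowed-detection semantics,
  not any one binary's undocumented internals; boundary behaviour at
  shaved edges can differ from other implementations by a marker.
* Staged rescaling preserves the island phase exactly but approximates
  the ancestral equilibrium (coarser frequency grid, stronger
  interference during burn-in).
* The simulator models a single chromosome, uniform rates, and no
  positive or balancing selection.
* The likelihood backend reports Wald intervals, which are slightly
  narrower than posterior percentile intervals in small samples; use
  the MCMC backend when interval calibration matters more than speed.
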