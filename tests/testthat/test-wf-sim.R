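test_that("the island demography schedule is realized exactly", {
  tr <- demographySizes(soayDemography())
  expect_length(tr, 11000L)
  expect_equal(tr[1], 1000L)          # ancestral epoch
  expect_equal(tr[10000], 1000L)
  expect_equal(tr[10970], 200L)       # generation 10,969 (0-based)
  expect_equal(tr[10971], 10L)        # crash at generation 10,970
  expect_equal(tr[10991], 200L)       # recovered at generation 10,990
  expect_equal(tr[11000], 200L)
  # exponential recovery: N(t) = round(10 * 20^(t/20))
  expect_equal(tr[10971 + 1:20], as.integer(round(10 * 20^((1:20) / 20))))
})

test_that("rescaling preserves the population-scaled products", {
  dem <- soayDemography()
  gen <- genomeConfig()
  dfe <- dfeConfig()
  id <- rescaleConfig(dem, gen, dfe, 1)
  expect_identical(id$demography, dem)
  expect_identical(id$genome, gen)

  rs <- rescaleConfig(dem, gen, dfe, 10)
  expect_equal(rs$demography$epochs$n, c(100, 20))
  expect_equal(rs$demography$epochs$duration, c(1000, 97))
  expect_equal(rs$demography$size_at_crash, 2)
  expect_equal(rs$genome$mutation_rate, 1e-7)
  expect_equal(rs$dfe$mean_s, -0.3)
  # theta = 4 N mu and N s invariant
  expect_equal(rs$demography$epochs$n[1] * rs$genome$mutation_rate,
               dem$epochs$n[1] * gen$mutation_rate)
  expect_equal(rs$demography$epochs$n[1] * rs$dfe$mean_s,
               dem$epochs$n[1] * dfe$mean_s)
})

test_that("DFE draws have the configured gamma mean and variance", {
  set.seed(1)
  dfe <- dfeConfig(mean_s = -0.03, shape = 0.2)
  s <- sampleDfe(1e6, dfe)
  expect_true(all(s < 0))
  se_mean <- sqrt(0.03^2 / 0.2 / 1e6)
  expect_lt(abs(mean(s) - (-0.03)), 3 * se_mean)
  expect_lt(abs(var(s) - 0.0045), 3 * 0.0045 * sqrt(2 / 0.2 / 1e6) * 3)
  expect_identical(sampleDfe(0, dfe), numeric())
})

test_that("diploid fitness is multiplicative with partial dominance", {
  expect_equal(genomeFitness(2L, -0.03, 0), 0.97)
  expect_equal(genomeFitness(integer(), numeric(), numeric()), 1)
  expect_equal(genomeFitness(1L, -0.03, 0.05), 0.9985)
  expect_equal(genomeFitness(c(2L, 1L), c(-0.5, -0.2), c(0, 0.5)),
               0.5 * 0.9)
  expect_equal(genomeFitness(2L, -1.5, 0), 0)  # clamped at zero
  expect_equal(genomeFitness(c(2L, 2L), c(-1.5, -1.5), c(0, 0)), 0)
})

test_that("simulation bookkeeping: trace, seed determinism, mutation flux", {
  dem <- demographyConfig(data.frame(n = 30, duration = 150))
  gen <- genomeConfig(length_bp = 1e6, recombination_rate = 1e-7,
                      mutation_rate = 1e-6)
  dfe <- dfeConfig(p_deleterious = 0.5)
  s1 <- runSimulation(dem, dfe, gen, seed = 5)
  s2 <- runSimulation(dem, dfe, gen, seed = 5)
  expect_identical(demographyTrace(s1), demographySizes(dem))
  expect_identical(genotypeCalls(s1@genotypes), genotypeCalls(s2@genotypes))
  expect_identical(mutationTable(s1), mutationTable(s2))

  nm <- attr(s1, "new_mutations_per_generation")
  expect_length(nm, 150L)
  # mean new mutations per generation: 2 N mu L = 60
  expect_lt(abs(mean(nm[-1]) - 60), 3 * sd(nm[-1]) / sqrt(149))

  # genotype dosages consistent with reported frequencies
  mt <- mutationTable(s1)
  expect_equal(unname(colSums(genotypeCalls(s1@genotypes))),
               as.integer(round(2 * 30 * mt$frequency)))
})

test_that("neutral equilibrium diversity matches 4 N mu", {
  gen <- genomeConfig(length_bp = 1e6, recombination_rate = 1e-7,
                      mutation_rate = 1e-6)
  dem <- demographyConfig(data.frame(n = 40, duration = 450))
  dfe <- dfeConfig(p_deleterious = 1e-12)
  pis <- vapply(1:8, function(s)
    pairwiseDiversity(runSimulation(dem, dfe, gen, seed = 100 + s), gen), 0)
  target <- 4 * 40 * 1e-6
  expect_lt(abs(mean(pis) - target), 3 * sd(pis) / sqrt(length(pis)))
})

test_that("purifying selection depresses fitness more for larger |s|", {
  gen <- genomeConfig(length_bp = 1e6, recombination_rate = 1e-7,
                      mutation_rate = 1e-6)
  dem <- demographyConfig(data.frame(n = 40, duration = 300))
  meanFit <- function(mean_s, seed) {
    sim <- runSimulation(dem, dfeConfig(mean_s = mean_s, h = 0.2),
                         gen, seed = seed)
    mt <- mutationTable(sim)
    g <- genotypeCalls(sim@genotypes)
    mean(vapply(seq_len(nrow(g)), function(i)
      genomeFitness(g[i, ], mt$s, mt$h), 0))
  }
  w_weak <- mean(vapply(1:4, function(s) meanFit(-0.005, s), 0))
  w_strong <- mean(vapply(1:4, function(s) meanFit(-0.1, s), 0))
  expect_lte(w_weak, 1)
  expect_lt(w_strong, w_weak)
})

test_that("staged rescaling keeps the island phase at full resolution", {
  sim <- runSimulation(seed = 1, rescale = 10)
  tr <- demographyTrace(sim)
  expect_length(tr, 2000L)          # 1000 rescaled + 1000 island
  expect_equal(tr[1], 100L)         # ancestral 1000 / Q
  expect_equal(tr[1001], 200L)      # island epoch unrescaled
  expect_equal(tr[1971], 10L)       # crash at full size
  expect_equal(tr[2000], 200L)
  expect_equal(nrow(genotypeCalls(sim@genotypes)), 200L)
})

test_that("uniform rescaling compresses every epoch", {
  sim <- runSimulation(demographyConfig(data.frame(n = 100, duration = 50)),
                       dfeConfig(), genomeConfig(length_bp = 1e6),
                       seed = 2, rescale = 10, rescale_mode = "uniform")
  expect_identical(demographyTrace(sim), rep(10L, 5))
})

test_that("VCF export round-trips and reports consistent allele counts", {
  gen <- genomeConfig(length_bp = 1e6, recombination_rate = 1e-7,
                      mutation_rate = 1e-6)
  sim <- runSimulation(demographyConfig(data.frame(n = 25, duration = 80)),
                       dfeConfig(p_deleterious = 0.5), gen, seed = 9)
  path <- tempfile(fileext = ".vcf")
  exportVcf(sim, path, contig_length = 1e6)
  back <- readSimVcf(path)
  expect_equal(unname(genotypeCalls(back$genotypes)),
               unname(genotypeCalls(sim@genotypes)))
  expect_equal(back$mutations$position_bp, mutationTable(sim)$position_bp)
  expect_equal(back$mutations$s, mutationTable(sim)$s, tolerance = 1e-6)
  expect_equal(back$mutations$kind, mutationTable(sim)$kind)
  expect_true(file.exists(sub("\\.vcf$", "_mutations.tsv", path)))
})
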