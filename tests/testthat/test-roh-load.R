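# small hand-built scenario: one individual, markers every 1 cM on [0, 60]
mkLoadScenario <- function(dosages, positions_cm, segs) {
  mk <- data.frame(marker_id = paste0("m", seq_along(positions_cm)),
                   chromosome = "1",
                   bp = as.integer(positions_cm * 1e6),
                   cm = positions_cm)
  gm <- GenotypeMatrix(matrix(as.integer(dosages), nrow = 1), mk, "i1")
  segs$individual <- "i1"
  segs$chromosome <- "1"
  segs$length_cm <- segs$end_cm - segs$start_cm
  segs$n_snps <- 30L
  segs$n_het <- 0L
  segs$snp1 <- "a"; segs$snp2 <- "b"
  list(gm = gm, segs = classifySegments(segs))
}

test_that("only homozygous deleterious mutations inside segments count", {
  sc <- mkLoadScenario(c(2L, 1L, 2L, 2L), c(12, 15, 18, 30),
                       data.frame(start_cm = 10, end_cm = 20))
  mut <- data.frame(id = 1:4, position_bp = c(12, 15, 18, 30) * 1e6,
                    s = c(-0.01, -0.02, -0.02, -0.05), h = 0.05,
                    kind = "deleterious", origin_generation = 1L,
                    frequency = c(0.1, 0.3, 0.2, 0.4))
  hits <- mutationsInRoh(sc$gm, sc$segs, mut)
  expect_equal(nrow(hits), 2L)           # het at 15 and outside at 30 excluded
  expect_equal(hits$mutation_id, c(1L, 3L))
  # any-carried-copy mode also counts the heterozygous call
  hits2 <- mutationsInRoh(sc$gm, sc$segs, mut, homozygous_only = FALSE)
  expect_equal(nrow(hits2), 3L)
})

test_that("segment boundaries are closed intervals", {
  sc <- mkLoadScenario(c(2L, 2L), c(10, 20),
                       data.frame(start_cm = 10, end_cm = 20))
  mut <- data.frame(id = 1:2, position_bp = c(10, 20) * 1e6, s = -0.01,
                    h = 0, kind = "deleterious", origin_generation = 1L,
                    frequency = 0.1)
  expect_equal(nrow(mutationsInRoh(sc$gm, sc$segs, mut)), 2L)
})

test_that("load and count per cM follow the sum-over-class definition", {
  # one 10 cM medium segment holding s = -0.01 and -0.02
  sc <- mkLoadScenario(c(2L, 2L), c(12, 18),
                       data.frame(start_cm = 10, end_cm = 20))
  mut <- data.frame(id = 1:2, position_bp = c(12, 18) * 1e6,
                    s = c(-0.01, -0.02), h = 0, kind = "deleterious",
                    origin_generation = 1L, frequency = c(0.1, 0.3))
  st <- rohLoadStats(sc$gm, sc$segs, mut)
  expect_equal(st$load_per_cm[st$length_class == "medium"], -0.003)
  expect_equal(st$count_per_cm[st$length_class == "medium"], 0.2)
  expect_equal(st$mean_allele_frequency[st$length_class == "medium"], 0.2)

  # two 5 cM segments with one s = -0.02 mutation each: (-0.04)/10
  sc2 <- mkLoadScenario(c(2L, 2L), c(2, 32),
                        data.frame(start_cm = c(0, 30), end_cm = c(5, 35)))
  mut2 <- data.frame(id = 1:2, position_bp = c(2, 32) * 1e6, s = -0.02,
                     h = 0, kind = "deleterious", origin_generation = 1L,
                     frequency = 0.5)
  st2 <- rohLoadStats(sc2$gm, sc2$segs, mut2)
  med2 <- st2[st2$length_class == "medium", ]
  expect_equal(med2$load_per_cm, -0.004)
  expect_equal(med2$count_per_cm, 0.2)

  # segments with no mutations: load 0, frequency missing
  st3 <- rohLoadStats(sc$gm, sc$segs, mut[0, ])
  expect_equal(st3$load_per_cm[st3$length_class == "medium"], 0)
  expect_true(is.na(st3$mean_allele_frequency[st3$length_class == "medium"]))
})

test_that("statistics are invariant to splitting a segment in two", {
  sc1 <- mkLoadScenario(c(2L, 2L, 2L), c(11, 14, 19),
                        data.frame(start_cm = 10, end_cm = 20))
  sc2 <- mkLoadScenario(c(2L, 2L, 2L), c(11, 14, 19),
                        data.frame(start_cm = c(10, 15), end_cm = c(15, 20)))
  # force equal classes for the split pieces
  sc2$segs$length_class <- factor("medium", c("short", "medium", "long"))
  sc1$segs$length_class <- factor("medium", c("short", "medium", "long"))
  mut <- data.frame(id = 1:3, position_bp = c(11, 14, 19) * 1e6,
                    s = c(-0.01, -0.03, -0.02), h = 0,
                    kind = "deleterious", origin_generation = 1L,
                    frequency = 0.2)
  a <- rohLoadStats(sc1$gm, sc1$segs, mut)
  b <- rohLoadStats(sc2$gm, sc2$segs, mut)
  expect_equal(a$load_per_cm, b$load_per_cm)
  expect_equal(a$count_per_cm, b$count_per_cm)
})

test_that("replicate summaries compute the percent contrasts of the study", {
  st <- data.frame(individual = "i1",
                   length_class = factor(c("short", "medium", "long"),
                                         c("short", "medium", "long")),
                   total_cm = 10, n_mutations = 1L,
                   load_per_cm = c(-0.0022, -0.0037, -0.005),
                   count_per_cm = c(1, 2, 3),
                   mean_allele_frequency = c(0.3, 0.2, 0.1))
  sm <- summarizeReplicate(st)
  expect_equal(sm$load_contrast_medium, 26, tolerance = 0.01)
  expect_equal(sm$load_contrast_short, 56, tolerance = 0.01)
  expect_equal(sm$count_contrast_medium, 100 * (1 - 2 / 3))

  # no long ROH: contrasts undefined, not zero
  st2 <- st[st$length_class != "long", ]
  sm2 <- summarizeReplicate(st2)
  expect_true(is.na(sm2$load_contrast_medium))
  expect_true(is.na(sm2$load_long))
})

test_that("a coordinate-space mismatch is detected", {
  sc <- mkLoadScenario(c(2L, 2L), c(12, 18),
                       data.frame(start_cm = 10, end_cm = 20))
  mut <- data.frame(id = 1L, position_bp = 1234, s = -0.01, h = 0,
                    kind = "deleterious", origin_generation = 1L,
                    frequency = 0.1)
  expect_error(mutationsInRoh(sc$gm, sc$segs, mut), "coordinate")
})

test_that("statistics reproduce bit-identically from exported files", {
  gen <- genomeConfig(length_bp = 5e6, recombination_rate = 1e-7,
                      mutation_rate = 1e-6)
  sim <- runSimulation(demographyConfig(data.frame(n = 30, duration = 120)),
                       dfeConfig(mean_s = -0.05, p_deleterious = 0.6),
                       gen, seed = 31)
  segs <- classifySegments(callRoh(sim@genotypes))
  if (nrow(segs) == 0) skip("no segments in this fixture")
  direct <- rohLoadStats(sim@genotypes, segs, mutationTable(sim))
  vcf <- tempfile(fileext = ".vcf")
  roh <- tempfile(fileext = ".tsv")
  exportVcf(sim, vcf, contig_length = 5e6)
  writeRohTable(segs, roh)
  back <- readSimVcf(vcf)
  reread <- rohLoadStats(back$genotypes, readRohTable(roh), back$mutations)
  expect_equal(direct$load_per_cm, reread$load_per_cm, tolerance = 1e-6)
  expect_equal(direct$count_per_cm, reread$count_per_cm)
})
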