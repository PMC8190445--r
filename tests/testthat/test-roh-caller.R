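mkGm <- function(g, spacing = 0.05) {
  m <- length(g)
  cm <- (seq_len(m) - 1) * spacing
  mk <- data.frame(marker_id = paste0("m", seq_len(m)), chromosome = "1",
                   bp = seq_len(m), cm = cm)
  GenotypeMatrix(matrix(as.integer(g), nrow = 1), mk, "i1")
}

test_that("cM scaling produces the kb-equivalent integer coordinates", {
  expect_equal(scaleCmCoordinates(c(0.39, 0.25, 0)), c(390000, 250000, 0))
})

test_that("a fully homozygous chromosome yields one full-span segment", {
  gm <- mkGm(rep(0L, 100))
  seg <- callRoh(gm)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 100L)
  expect_equal(seg$length_cm, 4.95)
  expect_equal(seg$n_het, 0L)
})

test_that("an all-heterozygous chromosome yields no segments", {
  expect_equal(nrow(callRoh(mkGm(rep(1L, 100)))), 0L)
})

test_that("heterozygote-contaminated runs match the brute-force oracle", {
  g <- rep(0L, 60)
  g[c(20, 40)] <- 1L
  expect_true(oracleCompare(g, (0:59) * 0.05))
  # three hets force a split at the excess heterozygous call
  g3 <- rep(2L, 120)
  g3[c(30, 60, 90)] <- 1L
  expect_true(oracleCompare(g3, (0:119) * 0.05))
})

test_that("caller equals the enumeration oracle on random instances", {
  set.seed(2024)
  for (i in 1:30) {
    inst <- randomRohInstance(sample(40:200, 1))
    expect_true(oracleCompare(inst$g, inst$cm),
                label = sprintf("random instance %d", i))
  }
})

test_that("reported segments respect every parameter constraint", {
  set.seed(7)
  p <- rohParams()
  for (i in 1:10) {
    inst <- randomRohInstance(200)
    gm <- mkGm(inst$g)
    gm@markers$cm <- inst$cm
    segs <- callRoh(gm, p)
    if (!nrow(segs)) next
    expect_true(all(segs$n_snps >= p$min_snps))
    expect_true(all(segs$length_cm >= p$min_length_cm - 1e-9))
    expect_true(all(segs$n_het <= p$segment_het))
    expect_true(all(segs$length_cm / segs$n_snps <=
                      p$max_avg_spacing_cm_per_snp + 1e-12))
    # non-overlapping within the individual
    if (nrow(segs) > 1)
      expect_true(all(segs$start_cm[-1] > segs$end_cm[-nrow(segs)]))
  }
})

test_that("adding heterozygous calls never increases F_ROH total", {
  set.seed(11)
  g <- ifelse(runif(400) < 0.02, 1L, 2L)
  gm <- mkGm(g)
  f0 <- computeFroh(classifySegments(callRoh(gm)), 100, "i1")$f_total
  for (k in c(5, 20, 60)) {
    g2 <- g
    g2[sample(400, k)] <- 1L
    f1 <- computeFroh(classifySegments(callRoh(mkGm(g2))), 100, "i1")$f_total
    expect_lte(f1, f0 + 1e-12)
  }
})

test_that("detection is deterministic", {
  set.seed(3)
  inst <- randomRohInstance(150)
  gm <- mkGm(inst$g)
  expect_identical(callRoh(gm), callRoh(gm))
})

test_that("length classes follow the boundary conventions", {
  segs <- data.frame(length_cm = c(80.55, 1.0, 12.5, 1.56, 0.39, 13))
  cls <- classifySegments(segs)$length_class
  expect_equal(as.character(cls),
               c("long", "short", "medium", "medium", "short", "long"))
  expect_error(classifySegments(data.frame(length_cm = 0.1)), "minimum")
})

test_that("F_ROH coefficients sum by class and handle empty inputs", {
  segs <- classifySegments(data.frame(individual = "i1", chromosome = "1",
                                      start_cm = c(0, 50), end_cm = c(15, 55),
                                      length_cm = c(15, 5),
                                      n_snps = c(100L, 50L),
                                      n_het = c(0L, 0L),
                                      snp1 = "a", snp2 = "b"))
  fr <- computeFroh(segs, total_map_cm = 100)
  expect_equal(fr$f_long, 0.15)
  expect_equal(fr$f_medium, 0.05)
  expect_equal(fr$f_total, 0.20)
  expect_equal(fr$mean_roh_length_cm, 10)

  none <- computeFroh(segs[0, ], 100, individuals = "i9")
  expect_equal(none$f_total, 0)
  expect_true(is.na(none$mean_roh_length_cm))

  whole <- classifySegments(data.frame(individual = "i1", chromosome = "1",
                                       start_cm = 0, end_cm = 3146,
                                       length_cm = 3146, n_snps = 1000L,
                                       n_het = 0L, snp1 = "a", snp2 = "b"))
  expect_equal(computeFroh(whole, 3146)$f_total, 1)
})

test_that("class F values add to the total for called genotypes", {
  fx <- generateGenotypeFixture(n_individuals = 5, n_markers = 600,
                                segments_per_individual = 2,
                                segment_markers = 60, seed = 42)
  fr <- computeFroh(classifySegments(callRoh(fx$genotypes)), 30,
                    individuals = individualIds(fx$genotypes))
  expect_equal(fr$f_long + fr$f_medium + fr$f_short, fr$f_total,
               tolerance = 1e-9)
})

test_that("ROH tables round-trip through the .hom-style TSV", {
  fx <- generateGenotypeFixture(n_individuals = 3, n_markers = 300,
                                segment_markers = 80, seed = 5)
  segs <- classifySegments(callRoh(fx$genotypes))
  path <- tempfile(fileext = ".tsv")
  writeRohTable(segs, path)
  back <- readRohTable(path)
  expect_equal(back$start_cm, segs$start_cm)
  expect_equal(back$length_cm, segs$length_cm)
  expect_equal(as.character(back$length_class),
               as.character(segs$length_class))
})
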